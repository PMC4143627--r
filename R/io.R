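# TSV dialects. All files are tab-delimited, LF-terminated, dot-decimal,
# "NA" for missing values; lines starting with "#" are comments (used to
# record seeds). Doubles are written with %.17g so read(write(x))
# round-trips bit-exactly.

fmtCol <- function(x) {
  if (is.double(x)) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NA"
    out
  } else as.character(x)
}

writeDialectTsv <- function(df, path, comments = character()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- character(0)
  if (length(comments)) lines <- paste0("# ", comments)
  lines <- c(lines, paste(names(df), collapse = "\t"))
  cols <- lapply(df, fmtCol)
  if (nrow(df)) lines <- c(lines, do.call(paste, c(cols, sep = "\t")))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

readDialectTsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write / read the genotype TSV dialect
#'
#' Header `snp_id` followed by one column per individual; entries are
#' integer nonreference allele counts 0/1/2 (NA for missing). Counts are
#' halved on load into the dosage scale \{0, 0.5, 1\}.
#'
#' @param geno SNP x individual dosage matrix in \{0, 0.5, 1\}.
#' @param path output file.
#' @param comments optional comment lines (e.g. the seed).
#' @return `path`, invisibly.
#' @export
writeGenotypesTsv <- function(geno, path, comments = character()) {
  df <- data.frame(snp_id = rownames(geno),
                   matrix(as.integer(round(2 * geno)), nrow(geno),
                          dimnames = list(NULL, colnames(geno))),
                   check.names = FALSE, stringsAsFactors = FALSE)
  writeDialectTsv(df, path, comments)
}

#' Read genotypes from TSV or VCF
#'
#' SNPs whose missingness exceeds `maxMissing` (default 20%) are dropped
#' with a message; multi-allelic VCF records are skipped with a message.
#' VCF genotypes are converted from GT (unphased or phased) to dosages;
#' genetic positions are assigned at 1 cM/Mb from the physical positions
#' (supply a real map for downstream analyses that need one).
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`.
#' @param maxMissing per-SNP missingness threshold.
#' @return List with `dosage` (SNP x individual matrix in \{0, 0.5, 1\},
#'   NA for missing), `map` (a [GeneticMap-class] for VCF input, NULL for
#'   TSV), `nDropped` and `nSkipped`.
#' @rdname readGenotypes
#' @export
readGenotypes <- function(path, format = c("tsv", "vcf"), maxMissing = 0.2) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- readDialectTsv(path)
    if (names(df)[1L] != "snp_id") stop("genotype TSV must start with snp_id")
    counts <- as.matrix(df[, -1L, drop = FALSE])
    if (any(!is.na(counts) & !(counts %in% 0:2)))
      stop("allele counts must be 0, 1, 2 or NA in ", path)
    rownames(counts) <- df$snp_id
    dosage <- counts / 2
    map <- NULL
    nSkipped <- 0L
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
    nSkipped <- sum(multi)
    if (nSkipped) {
      message(nSkipped, " multi-allelic record(s) skipped")
      v <- v[!multi, ]
      fix <- vcfR::getFIX(v)
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    a1 <- substr(gt, 1L, 1L); a2 <- substr(gt, 3L, 3L)
    counts <- suppressWarnings(as.integer(a1) + as.integer(a2))
    counts <- matrix(counts, nrow(gt), dimnames = dimnames(gt))
    dosage <- counts / 2
    bp <- as.numeric(fix[, "POS"])
    ids <- fix[, "ID"]
    ids[is.na(ids) | ids == "."] <- paste0("snp_at_", bp[is.na(ids) | ids == "."])
    rownames(dosage) <- ids
    map <- GeneticMap(ids, bp = bp, cm = (bp - bp[1L]) / 1e6,
                      chrom = fix[1L, "CHROM"])
  }
  miss <- rowMeans(is.na(dosage))
  drop <- miss > maxMissing
  nDropped <- sum(drop)
  if (nDropped) {
    message(nDropped, " SNP(s) dropped for missingness > ",
            round(100 * maxMissing), "%")
    dosage <- dosage[!drop, , drop = FALSE]
    if (!is.null(map))
      map <- GeneticMap(map@snpId[!drop], map@bp[!drop], map@cm[!drop],
                        map@chrom)
  }
  list(dosage = dosage, map = map, nDropped = nDropped, nSkipped = nSkipped)
}

#' Write genotypes as a minimal VCF
#'
#' GT-only VCFv4.2 with placeholder REF/ALT alleles; dosages 0/0.5/1 map to
#' 0/0, 0/1 and 1/1, NA to "./.".
#'
#' @param geno SNP x individual dosage matrix.
#' @param map aligned [GeneticMap-class].
#' @param path output file.
#' @param comments optional meta lines (written as `##` headers).
#' @return `path`, invisibly.
#' @export
writeVcf <- function(geno, map, path, comments = character()) {
  gtOf <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  cnt <- round(2 * geno)
  gt <- matrix(gtOf[as.character(cnt)], nrow(geno))
  gt[is.na(cnt)] <- "./."
  ids <- colnames(geno)
  if (is.null(ids)) ids <- sprintf("ind%04d", seq_len(ncol(geno)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c("##fileformat=VCFv4.2", "##source=admixscan",
           if (length(comments)) paste0("##", comments),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", ids), collapse = "\t"))
  body <- paste(map@chrom, format(map@bp, scientific = FALSE, trim = TRUE),
                map@snpId, "A", "G", ".", ".", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

#' Write / read the local-ancestry TSV dialect
#'
#' Long format: `snp_id`, `individual`, then one dosage column per
#' population, entries in \{0, 0.5, 1\}.
#'
#' @param callset a [LocalAncestryCallset-class].
#' @param path output file.
#' @param comments optional comment lines.
#' @return `path`, invisibly.
#' @export
writeLocalAncestryTsv <- function(callset, path, comments = character()) {
  d <- callset@dosage
  m <- dim(d)[1L]; n <- dim(d)[2L]
  ids <- dimnames(d)[[2L]]
  if (is.null(ids)) ids <- sprintf("ind%04d", seq_len(n))
  df <- data.frame(snp_id = rep(callset@map@snpId, times = n),
                   individual = rep(ids, each = m),
                   stringsAsFactors = FALSE)
  for (k in seq_along(callset@popLabels))
    df[[callset@popLabels[k]]] <- as.vector(d[, , k])
  writeDialectTsv(df, path, comments)
}

#' @param map the [GeneticMap-class] the call set is aligned to.
#' @rdname writeLocalAncestryTsv
#' @export
readLocalAncestryTsv <- function(path, map) {
  df <- readDialectTsv(path)
  if (!all(c("snp_id", "individual") %in% names(df)))
    stop("local-ancestry TSV needs snp_id and individual columns")
  pops <- setdiff(names(df), c("snp_id", "individual"))
  ids <- unique(df$individual)
  m <- nSnps(map); n <- length(ids)
  si <- match(df$snp_id, map@snpId)
  if (anyNA(si)) stop("unknown SNP id(s) in ", path)
  ii <- match(df$individual, ids)
  d <- array(NA_real_, c(m, n, length(pops)),
             dimnames = list(map@snpId, ids, pops))
  for (k in seq_along(pops)) d[cbind(si, ii, k)] <- df[[pops[k]]]
  LocalAncestryCallset(d, map, pops)
}

#' Write / read the phenotype TSV dialect
#'
#' Columns: id, age (years), sex (0/1), sbp, dbp (mmHg), hyp (0/1).
#'
#' @param pheno phenotype data.frame.
#' @param path output file.
#' @param comments optional comment lines.
#' @export
writePhenotypesTsv <- function(pheno, path, comments = character()) {
  writeDialectTsv(pheno, path, comments)
}

#' @rdname writePhenotypesTsv
#' @export
readPhenotypesTsv <- function(path) {
  df <- readDialectTsv(path)
  need <- c("id", "age", "sex", "sbp", "dbp", "hyp")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype TSV missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Write / read the genetic-map TSV dialect
#'
#' Columns: snp_id, chrom, bp (1-based), cm.
#'
#' @param map a [GeneticMap-class].
#' @param path output file.
#' @param comments optional comment lines.
#' @export
writeMapTsv <- function(map, path, comments = character()) {
  writeDialectTsv(as.data.frame(map), path, comments)
}

#' @rdname writeMapTsv
#' @export
readMapTsv <- function(path) {
  df <- readDialectTsv(path)
  need <- c("snp_id", "chrom", "bp", "cm")
  if (!all(need %in% names(df)))
    stop("map TSV must have columns snp_id, chrom, bp, cm")
  GeneticMap(df$snp_id, df$bp, df$cm, chrom = df$chrom[1L])
}

#' Write / read the allele-frequency TSV dialect
#'
#' Columns: snp_id, then one frequency column per population.
#'
#' @param freqs an [AncestralPanel-class] or a data.frame with `snp_id`
#'   plus one column per population.
#' @param path output file.
#' @param comments optional comment lines.
#' @export
writeFreqTsv <- function(freqs, path, comments = character()) {
  if (is(freqs, "AncestralPanel"))
    freqs <- data.frame(snp_id = freqs@map@snpId, freqs@freqs,
                        check.names = FALSE, stringsAsFactors = FALSE)
  writeDialectTsv(freqs, path, comments)
}

#' @rdname writeFreqTsv
#' @export
readFreqTsv <- function(path) {
  df <- readDialectTsv(path)
  if (names(df)[1L] != "snp_id") stop("frequency TSV must start with snp_id")
  for (k in names(df)[-1L]) stopIfNot01(df[[k]], paste("frequency", k))
  df
}

#' Write a scan result as TSV
#'
#' One row per SNP (snp_id, beta, se, t, p, q, flag) preceded by comment
#' lines recording the model, lambda and the number of FDR discoveries.
#'
#' @param scan a [ScanResult-class].
#' @param path output file.
#' @param comments extra comment lines.
#' @export
writeScanTsv <- function(scan, path, comments = character()) {
  hdr <- c(comments,
           paste0("model=", scan@model),
           sprintf("lambda=%.6g", scan@lambda),
           sprintf("n_fdr_lt_0.05=%d", sum(scan@table$q < 0.05, na.rm = TRUE)))
  writeDialectTsv(scan@table, path, hdr)
}
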