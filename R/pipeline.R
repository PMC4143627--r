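#' Default pipeline configuration
#'
#' Nested list of all pipeline settings: simulation parameters (n = 109
#' individuals, 2000 SNPs, 10 generations, mean proportions 0.6/0.1/0.3),
#' AIM-filter thresholds (within Fst < 0.1, between Fst > 0.2, LD r^2 <
#' 0.1), scan settings (diastolic blood pressure, log-transformed, European
#' ancestry), permutation settings (t* = 3, B = 200 by default in the
#' pipeline; the standalone test defaults to B = 3000) and the power
#' design. Any subset can be overridden via `runPipeline(config)` or a YAML
#' file with the same structure.
#'
#' @param outdir output directory.
#' @param seed master integer seed.
#' @return A named list.
#' @export
defaultPipelineConfig <- function(outdir = "admixscan_out", seed = 42) {
  list(
    outdir = outdir,
    seed = seed,
    stages = c("simulate", "aims", "generations", "admixmap", "assoc",
               "permtest", "power"),
    sim = list(n = 109, n_snps = 2000, g = 10,
               mean_props = c(0.6, 0.1, 0.3), concentration = 30,
               divergence = c(0.15, 0.15, 0.15), format = "tsv",
               flip_rate = 0),
    aims = list(within = c("MAY", "PMA"), between = c("EUR", "AFR"),
                within_thresh = 0.1, between_thresh = 0.2, ld_cutoff = 0.1,
                window = 250, split_divergence = 0.02),
    generations = list(european_prop = 0.6, target_pop = "EUR"),
    admixmap = list(trait = "dbp", log_transform = TRUE, ancestry = "EUR"),
    assoc = list(trait = "dbp", log_transform = TRUE, intercept = FALSE),
    permtest = list(threshold = 3, B = 200, signed = FALSE),
    power = list(maf = 0.05, grr = 14.4, n_case = 36, n_control = 72,
                 alpha = 0.05 / 37438)
  )
}

validatePipelineConfig <- function(config) {
  known <- names(defaultPipelineConfig())
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  badStage <- setdiff(config$stages,
                      c("simulate", "aims", "generations", "admixmap",
                        "assoc", "permtest", "power"))
  if (length(badStage))
    stop("unknown stage(s): ", paste(badStage, collapse = ", "))
  with(config$sim, {
    if (n < 4) stop("sim$n must be >= 4")
    if (n_snps < 2) stop("sim$n_snps must be >= 2")
    if (g < 0) stop("sim$g must be >= 0")
    if (abs(sum(mean_props) - 1) > 1e-8) stop("sim$mean_props must sum to 1")
    if (flip_rate < 0 || flip_rate > 1) stop("sim$flip_rate must lie in [0, 1]")
  })
  for (tr in c(config$admixmap$trait, config$assoc$trait))
    if (!tr %in% c("sbp", "dbp", "hyp"))
      stop("unknown trait column '", tr, "': must be sbp, dbp or hyp")
  with(config$aims, {
    if (within_thresh <= 0 || between_thresh <= 0 || ld_cutoff <= 0 ||
        ld_cutoff > 1)
      stop("aims thresholds out of range")
  })
  if (config$permtest$B < 1) stop("permtest$B must be >= 1")
  with(config$power, {
    if (alpha <= 0 || alpha >= 1) stop("power$alpha must lie in (0, 1)")
  })
  invisible(config)
}

mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Run the full admixture-mapping pipeline
#'
#' Executes the requested stages in order — simulate a cohort, select AIMs,
#' estimate generations since admixture, run the admixture-mapping and
#' ancestry-adjusted association scans, the permutation excess-signal test,
#' and the power calculation — writing each stage's TSV outputs, a
#' structured log (seeds, versions, counts at each filter) and a manifest
#' to `config$outdir`. The configuration is validated before any output is
#' written; on a stage failure the manifest marks the completed stages and
#' the error is re-thrown.
#'
#' @param config a config list (see [defaultPipelineConfig()]; partial
#'   lists are merged over the defaults) or the path to a YAML file with
#'   the same structure.
#' @return Invisibly, a list with `status` (0 on success), `files` (named
#'   vector of output paths), and the key computed objects/numbers
#'   (`cohort`, `aims`, `generations`, `admixmap`, `assoc`, `permtest`,
#'   `power`).
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- mergeConfig(defaultPipelineConfig(), config)
  validatePipelineConfig(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  seedComment <- paste0("seed=", cfg$seed)
  files <- character(0)
  logLines <- c(paste0("admixscan_version=",
                       as.character(utils::packageVersion("admixscan"))),
                seedComment)
  results <- list()
  done <- character(0)
  fp <- function(name) file.path(cfg$outdir, name)
  writeManifest <- function(failedStage) {
    writeDialectTsv(
      data.frame(stage = cfg$stages,
                 status = ifelse(cfg$stages %in% done, "done",
                                 ifelse(cfg$stages %in% failedStage, "failed",
                                        "not_run")),
                 stringsAsFactors = FALSE),
      fp("manifest.tsv"), comments = seedComment)
  }

  runStage <- function(stage, fun) {
    if (!stage %in% cfg$stages) return(invisible(NULL))
    tryCatch(fun(), error = function(e) {
      writeManifest(stage)
      writeLines(logLines, fp("pipeline.log"))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    done <<- c(done, stage)
    invisible(NULL)
  }

  cohort <- NULL; panel <- NULL; callset <- NULL

  runStage("simulate", function() {
    panel <<- drawAncestralFreqs(cfg$sim$n_snps, K = 3,
                                 divergence = cfg$sim$divergence,
                                 seed = substreamSeed(cfg$seed, .STAGE[["panel"]]))
    cohort <<- simulateCohort(panel, n = cfg$sim$n,
                              meanProps = cfg$sim$mean_props,
                              concentration = cfg$sim$concentration,
                              g = cfg$sim$g, seed = cfg$seed)
    callset <<- trueAncestry(cohort)
    if (cfg$sim$flip_rate > 0)
      callset <<- perturbAncestry(callset, cfg$sim$flip_rate,
                                  seed = substreamSeed(cfg$seed, 99))
    writeMapTsv(geneticMap(cohort), fp("map.tsv"), seedComment)
    writeFreqTsv(panel, fp("ancestral_freqs.tsv"), seedComment)
    if (identical(cfg$sim$format, "vcf"))
      writeVcf(genoDosage(cohort), geneticMap(cohort), fp("genotypes.vcf"),
               seedComment)
    else
      writeGenotypesTsv(genoDosage(cohort), fp("genotypes.tsv"), seedComment)
    writeLocalAncestryTsv(callset, fp("local_ancestry.tsv"), seedComment)
    writePhenotypesTsv(phenotypes(cohort), fp("phenotypes.tsv"), seedComment)
    files <<- c(files, map = fp("map.tsv"), freqs = fp("ancestral_freqs.tsv"),
                genotypes = fp(if (identical(cfg$sim$format, "vcf"))
                               "genotypes.vcf" else "genotypes.tsv"),
                ancestry = fp("local_ancestry.tsv"),
                phenotypes = fp("phenotypes.tsv"))
    logLines <<- c(logLines,
                   paste0("simulate.n=", cfg$sim$n),
                   paste0("simulate.n_snps=", cfg$sim$n_snps),
                   paste0("simulate.prevalence=",
                          mean(phenotypes(cohort)$hyp)))
    results$cohort <<- cohort
  })

  runStage("aims", function() {
    freqTab <- splitPopulation(panel, "NAM",
                               into = cfg$aims$within,
                               divergence = cfg$aims$split_divergence,
                               seed = substreamSeed(cfg$seed, .STAGE[["aims"]]))
    aims <- selectAims(freqTab, genoDosage(cohort), geneticMap(cohort),
                       within = cfg$aims$within, between = cfg$aims$between,
                       withinThresh = cfg$aims$within_thresh,
                       betweenThresh = cfg$aims$between_thresh,
                       ldCutoff = cfg$aims$ld_cutoff,
                       window = cfg$aims$window)
    mapDf <- as.data.frame(geneticMap(cohort))
    sel <- mapDf[aims$index, c("snp_id", "chrom", "bp")]
    out <- cbind(sel, aims$fst[aims$index, -1L, drop = FALSE])
    writeDialectTsv(out, fp("aims.tsv"), seedComment)
    files <<- c(files, aims = fp("aims.tsv"))
    logLines <<- c(logLines,
                   paste0("aims.pass_freq=", sum(aims$pass_freq)),
                   paste0("aims.selected=", length(aims$snp_id)))
    results$aims <<- aims
  })

  runStage("generations", function() {
    seg <- countSegments(cohort, targetPop = cfg$generations$target_pop)
    st <- segmentSummaryStats(seg)
    N <- estimateGenerations(st[["mean"]], a = cfg$generations$european_prop,
                             L = mapLengthMorgans(geneticMap(cohort)))
    writeDialectTsv(
      data.frame(mean_segments = st[["mean"]], sd_segments = st[["sd"]],
                 european_prop = cfg$generations$european_prop,
                 map_length_morgans = mapLengthMorgans(geneticMap(cohort)),
                 generations = N),
      fp("generations.tsv"), seedComment)
    files <<- c(files, generations = fp("generations.tsv"))
    logLines <<- c(logLines, paste0("generations.estimate=", N))
    results$generations <<- N
  })

  yFor <- function(spec) {
    ph <- phenotypes(cohort)
    residualizeTrait(ph[[spec$trait]], ph$age, ph$sex,
                     logTransform = isTRUE(spec$log_transform) &&
                       spec$trait != "hyp")
  }

  runStage("admixmap", function() {
    scan <- admixtureScan(yFor(cfg$admixmap), callset,
                          ancestry = cfg$admixmap$ancestry)
    writeScanTsv(scan, fp("admixmap_scan.tsv"), seedComment)
    files <<- c(files, admixmap = fp("admixmap_scan.tsv"))
    logLines <<- c(logLines, paste0("admixmap.lambda=", gcLambda(scan)))
    results$admixmap <<- scan
  })

  runStage("assoc", function() {
    scan <- ancestryAdjustedScan(yFor(cfg$assoc), genoDosage(cohort),
                                 callset, panel,
                                 intercept = isTRUE(cfg$assoc$intercept))
    writeScanTsv(scan, fp("assoc_scan.tsv"), seedComment)
    files <<- c(files, assoc = fp("assoc_scan.tsv"))
    logLines <<- c(logLines, paste0("assoc.lambda=", gcLambda(scan)))
    results$assoc <<- scan
  })

  runStage("permtest", function() {
    y <- yFor(cfg$admixmap)
    pt <- permutationExcessTest(
      y, function(yy) admixtureScan(yy, callset,
                                    ancestry = cfg$admixmap$ancestry),
      threshold = cfg$permtest$threshold, B = cfg$permtest$B,
      seed = substreamSeed(cfg$seed, .STAGE[["perm"]]),
      signed = isTRUE(cfg$permtest$signed))
    writeDialectTsv(
      data.frame(threshold = pt@threshold, observed = pt@observed,
                 B = length(pt@counts), p = pt@p),
      fp("permtest.tsv"), seedComment)
    files <<- c(files, permtest = fp("permtest.tsv"))
    logLines <<- c(logLines, paste0("permtest.p=", pt@p))
    results$permtest <<- pt
  })

  runStage("power", function() {
    des <- powerDesign(cfg$power$maf, cfg$power$grr, cfg$power$n_case,
                       cfg$power$n_control, cfg$power$alpha)
    pw <- powerTwoProp(des)
    writeDialectTsv(
      data.frame(maf = cfg$power$maf, exposure_p0 = dominantExposureProb(cfg$power$maf),
                 grr = cfg$power$grr, n_case = cfg$power$n_case,
                 n_control = cfg$power$n_control, alpha = cfg$power$alpha,
                 power = pw),
      fp("power.tsv"), seedComment)
    files <<- c(files, power = fp("power.tsv"))
    logLines <<- c(logLines, paste0("power.value=", pw))
    results$power <<- pw
  })

  writeManifest(character(0))
  writeLines(logLines, fp("pipeline.log"))
  files <- c(files, manifest = fp("manifest.tsv"), log = fp("pipeline.log"))
  invisible(c(list(status = 0L, files = files), results))
}
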