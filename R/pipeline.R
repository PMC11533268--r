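.configDefaults <- function() {
  list(
    inputs = list(referenceFasta = NULL, mutationTable = NULL),
    synthetic = list(nGenes = 40L, lengthRange = c(200L, 3000L),
                     nMutations = 696L, skew = 1.7, effectSize = 0,
                     seed = 1L, motif = "GAC"),
    features = list(hahnU = 0, hahnV = 0),
    networks = list(hiddenWidth = 128L, denseWidth = 64L, dropoutRate = 0.3,
                    batchSize = 32L, learningRate = 1e-3),
    evaluation = list(protocol = "ist", seed = 1L, epochsProfile = "paper",
                      threshold = 0.5, testFraction = 0.2, k = 10L),
    paths = list(outDir = "seqmomentstack-out")
  )
}

.suggestKey <- function(key, valid) {
  d <- utils::adist(key, valid)
  valid[which.min(d)]
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a nested list, fills every missing field with
#' its default, rejects unknown keys (with a nearest-key suggestion) and
#' checks all value bounds, reporting the aggregated list of violations
#' rather than only the first.
#'
#' @param config A YAML file path or a nested list with (subsets of) the
#'   sections `inputs`, `synthetic`, `features`, `networks`, `evaluation`,
#'   `paths`.
#' @return The normalized configuration, class `"runConfig"`.
#' @export
validateConfig <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  defaults <- .configDefaults()
  errors <- character(0)
  unknownTop <- setdiff(names(config), names(defaults))
  for (k in unknownTop)
    errors <- c(errors, sprintf("unknown section '%s' (did you mean '%s'?)",
                                k, .suggestKey(k, names(defaults))))
  out <- defaults
  for (sec in intersect(names(config), names(defaults))) {
    given <- config[[sec]]
    if (!is.list(given)) {
      errors <- c(errors, sprintf("section '%s' must be a mapping", sec))
      next
    }
    unknown <- setdiff(names(given), names(defaults[[sec]]))
    for (k in unknown)
      errors <- c(errors,
                  sprintf("unknown key '%s.%s' (did you mean '%s.%s'?)", sec,
                          k, sec, .suggestKey(k, names(defaults[[sec]]))))
    for (k in intersect(names(given), names(defaults[[sec]])))
      out[[sec]][[k]] <- given[[k]]
  }
  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  nw <- out$networks; ev <- out$evaluation; sy <- out$synthetic
  chk(nw$dropoutRate > 0 && nw$dropoutRate < 1,
      sprintf("networks.dropoutRate must lie in (0,1), got %s", nw$dropoutRate))
  chk(ev$threshold > 0 && ev$threshold < 1,
      sprintf("evaluation.threshold must lie in (0,1), got %s", ev$threshold))
  chk(ev$protocol %in% c("sct", "ist", "kfold"),
      sprintf("evaluation.protocol must be sct, ist or kfold, got '%s'",
              ev$protocol))
  chk(ev$epochsProfile %in% c("paper", "test"),
      sprintf("evaluation.epochsProfile must be 'paper' (300) or 'test' (30), got '%s'",
              ev$epochsProfile))
  chk(sy$effectSize >= 0 && sy$effectSize <= 1,
      sprintf("synthetic.effectSize must lie in [0,1], got %s", sy$effectSize))
  chk(sy$skew >= 1, sprintf("synthetic.skew must be >= 1, got %s", sy$skew))
  chk(length(sy$lengthRange) == 2L && sy$lengthRange[1] >= 18,
      "synthetic.lengthRange must be (min, max) with min >= 18")
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  structure(out, class = "runConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline: corpus, features, training, evaluation
#'
#' Orchestrates corpus construction (from input files if configured,
#' otherwise from the synthetic generator), feature extraction, ensemble
#' training and protocol evaluation, writing every stage artifact plus a
#' reproducibility manifest (configuration, seeds, md5 hashes of outputs)
#' under `paths.outDir`. Reruns with an identical configuration reproduce
#' identical feature files bit for bit and identical metrics.
#'
#' @param config A YAML path or list accepted by [validateConfig()].
#' @return Invisibly, a list with the corpus, the featurized
#'   `SummarizedExperiment`, the metrics report(s) and the artifact paths.
#' @export
runPipeline <- function(config = list()) {
  cfg <- validateConfig(config)
  outDir <- cfg$paths$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  useFiles <- !is.null(cfg$inputs$referenceFasta) ||
    !is.null(cfg$inputs$mutationTable)
  if (useFiles) {
    paths <- list(referenceFasta = cfg$inputs$referenceFasta,
                  mutationTable = cfg$inputs$mutationTable)
    for (nm in names(paths))
      if (is.null(paths[[nm]]) || !file.exists(paths[[nm]]))
        stop("pipeline stage 'corpus' failed: input path missing or not found: ",
             "inputs.", nm, " = ",
             if (is.null(paths[[nm]])) "(unset)" else paths[[nm]],
             call. = FALSE)
  }
  corpus <- .stage("corpus", {
    if (useFiles) {
      refs <- readReferenceFasta(cfg$inputs$referenceFasta)
      muts <- readMutationTable(cfg$inputs$mutationTable)
      buildLabeledDataset(refs, muts)
    } else {
      generateLabeledCorpus(do.call(syntheticConfig, cfg$synthetic))
    }
  })
  corpusFa <- file.path(outDir, "corpus.fa")
  .stage("corpus", writeCorpusFasta(corpus, corpusFa))
  se <- .stage("featurize",
               featurize(corpus, cfg$features$hahnU, cfg$features$hahnV))
  featCsv <- file.path(outDir, "features.csv")
  .stage("featurize", writeFeatureCsv(se, featCsv))
  epochs <- if (cfg$evaluation$epochsProfile == "paper") 300L else 30L
  configs <- baseConfigs(epochs = epochs, seed = cfg$evaluation$seed,
                         hiddenWidth = cfg$networks$hiddenWidth,
                         denseWidth = cfg$networks$denseWidth,
                         dropoutRate = cfg$networks$dropoutRate,
                         batchSize = cfg$networks$batchSize,
                         learningRate = cfg$networks$learningRate)
  report <- .stage("evaluate", switch(cfg$evaluation$protocol,
    sct = runSCT(se, configs, seed = cfg$evaluation$seed),
    ist = runIST(se, configs, seed = cfg$evaluation$seed,
                 testFraction = cfg$evaluation$testFraction),
    kfold = run10FCV(se, configs, seed = cfg$evaluation$seed,
                     k = cfg$evaluation$k)))
  headline <- if (cfg$evaluation$protocol == "kfold") report$pooled else report
  metricsJson <- file.path(outDir, "metrics.json")
  rocCsv <- file.path(outDir, "roc.csv")
  .stage("evaluate", writeMetricsReport(headline, metricsJson, rocCsv))
  manifest <- list(
    config = unclass(cfg),
    files = as.list(tools::md5sum(c(corpusFa, featCsv, metricsJson, rocCsv))),
    epochs = epochs)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(list(corpus = corpus, features = se, report = report,
                 paths = list(corpus = corpusFa, features = featCsv,
                              metrics = metricsJson, roc = rocCsv,
                              manifest = file.path(outDir, "manifest.json"))))
}
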