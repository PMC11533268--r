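#' Min-max feature standardizer
#'
#' Fits per-feature minimum and range on the training portion only (the
#' protocols guarantee no leakage: under the self-consistency protocol the
#' training portion is the full set by definition). Constant features map
#' to 0. Applied test values may fall outside `[0, 1]`; they are not
#' clipped.
#'
#' @param features Numeric matrix, samples in rows.
#' @return A list with `min` and `range`, class `"featureStandardizer"`.
#' @export
fitStandardizer <- function(features) {
  X <- as.matrix(features)
  mn <- apply(X, 2L, min)
  rg <- apply(X, 2L, max) - mn
  structure(list(min = mn, range = rg), class = "featureStandardizer")
}

#' @rdname fitStandardizer
#' @param standardizer A fitted `"featureStandardizer"`.
#' @export
applyStandardizer <- function(standardizer, features) {
  stopifnot(inherits(standardizer, "featureStandardizer"))
  X <- as.matrix(features)
  rg <- ifelse(standardizer$range == 0, 1, standardizer$range)
  out <- sweep(sweep(X, 2L, standardizer$min), 2L, rg, "/")
  out[, standardizer$range == 0] <- 0
  out
}

#' Plan an evaluation split
#'
#' Builds the sample partition of one of the three protocols:
#' self-consistency (`"sct"`, train == test == everything), independent-set
#' (`"ist"`, stratified 80/20) or stratified k-fold (`"kfold"`). Folds are
#' disjoint, cover all samples, have sizes differing by at most one, and are
#' class-stratified.
#'
#' @param labels 0-1 vector.
#' @param protocol `"sct"`, `"ist"` or `"kfold"`.
#' @param k Number of folds for `"kfold"` (default 10).
#' @param testFraction Held-out fraction for `"ist"` (default 0.2).
#' @param seed Seed for the stratified shuffles.
#' @return A list of class `"splitPlan"`: `protocol`, `seed` and either
#'   `test` (logical vector, `"ist"`), `fold` (integer vector, `"kfold"`) or
#'   neither (`"sct"`).
#' @export
makeSplitPlan <- function(labels, protocol = c("sct", "ist", "kfold"),
                          k = 10L, testFraction = 0.2, seed = 1L) {
  protocol <- match.arg(protocol)
  n <- length(labels)
  plan <- list(protocol = protocol, seed = seed, n = n)
  if (protocol == "ist") {
    set.seed(seed)
    test <- logical(n)
    for (cl in sort(unique(labels))) {
      i <- which(labels == cl)
      nTest <- round(testFraction * length(i))
      if (nTest < 1L || nTest >= length(i))
        stop("cannot form a stratified ", testFraction * 100,
             "% split for class ", cl, " with ", length(i), " samples")
      test[sample(i, nTest)] <- TRUE
    }
    plan$test <- test
  } else if (protocol == "kfold") {
    if (n < k) stop("k-fold protocol needs at least k = ", k, " samples")
    plan$k <- as.integer(k)
    plan$fold <- .stratifiedFolds(labels, k, seed)
    for (f in seq_len(k))
      if (length(unique(labels[plan$fold != f])) < 2L)
        stop("fold ", f, " leaves a single-class training partition")
  }
  structure(plan, class = "splitPlan")
}

.featuresAndLabels <- function(se) {
  X <- t(SummarizedExperiment::assay(se, "features"))
  y <- SummarizedExperiment::colData(se)$label
  if (is.null(y)) stop("colData must carry a 'label' column")
  list(X = X, y = as.numeric(y))
}

#' Self-consistency test (SCT)
#'
#' Trains on the entire dataset and evaluates on that same dataset;
#' standardization is fitted on the full set (the protocol's training
#' portion).
#'
#' @param se A featurized `SummarizedExperiment` from [featurize()].
#' @param configs Base-network configurations, e.g. [baseConfigs()].
#' @param seed Seed for the stacking folds.
#' @return A [MetricsReport-class] tagged `"sct"`.
#' @export
runSCT <- function(se, configs = baseConfigs(), seed = 1L) {
  d <- .featuresAndLabels(se)
  if (length(unique(d$y)) < 2L)
    stop("self-consistency protocol requires both classes")
  std <- fitStandardizer(d$X)
  Xs <- applyStandardizer(std, d$X)
  ens <- fitEnsemble(Xs, d$y, configs, seed = seed)
  pred <- ensemblePredict(ens, Xs)
  computeMetrics(confusionCounts(d$y, pred$label), pred$probability, d$y,
                 protocol = "sct")
}

#' Independent-set test (IST)
#'
#' Stratified 80/20 split: the ensemble and the feature standardizer are
#' fitted on the 80% training portion only and evaluated on the held-out
#' 20%.
#'
#' @inheritParams runSCT
#' @param testFraction Held-out fraction (default 0.2).
#' @return A [MetricsReport-class] tagged `"ist"`.
#' @export
runIST <- function(se, configs = baseConfigs(), seed = 1L,
                   testFraction = 0.2) {
  d <- .featuresAndLabels(se)
  plan <- makeSplitPlan(d$y, "ist", testFraction = testFraction, seed = seed)
  tr <- !plan$test
  std <- fitStandardizer(d$X[tr, , drop = FALSE])
  Xtr <- applyStandardizer(std, d$X[tr, , drop = FALSE])
  Xte <- applyStandardizer(std, d$X[!tr, , drop = FALSE])
  ens <- fitEnsemble(Xtr, d$y[tr], configs, seed = seed)
  pred <- ensemblePredict(ens, Xte)
  computeMetrics(confusionCounts(d$y[!tr], pred$label), pred$probability,
                 d$y[!tr], protocol = "ist")
}

#' 10-fold cross-validation test (10-FCVT)
#'
#' Stratified k-fold cross-validation: each fold is held out once while the
#' ensemble and standardizer are fitted on the remaining folds. The headline
#' report pools the confusion counts (and probabilities, for the AUC) across
#' folds; per-fold reports are also returned.
#'
#' @inheritParams runSCT
#' @param k Number of folds (default 10).
#' @return A list with `pooled` (a [MetricsReport-class] tagged `"kfold"`)
#'   and `perFold` (list of per-fold reports).
#' @export
run10FCV <- function(se, configs = baseConfigs(), seed = 1L, k = 10L) {
  d <- .featuresAndLabels(se)
  plan <- makeSplitPlan(d$y, "kfold", k = k, seed = seed)
  pooledPred <- integer(plan$n)
  pooledProb <- numeric(plan$n)
  perFold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- plan$fold != f
    std <- fitStandardizer(d$X[tr, , drop = FALSE])
    Xtr <- applyStandardizer(std, d$X[tr, , drop = FALSE])
    Xte <- applyStandardizer(std, d$X[!tr, , drop = FALSE])
    ens <- fitEnsemble(Xtr, d$y[tr], configs, seed = seed + f)
    pred <- ensemblePredict(ens, Xte)
    pooledPred[!tr] <- pred$label
    pooledProb[!tr] <- pred$probability
    perFold[[f]] <- computeMetrics(confusionCounts(d$y[!tr], pred$label),
                                   pred$probability, d$y[!tr],
                                   protocol = "kfold")
  }
  pooled <- computeMetrics(confusionCounts(d$y, pooledPred), pooledProb,
                           d$y, protocol = "kfold")
  list(pooled = pooled, perFold = perFold)
}

#' Write a metrics report (JSON) and its ROC curve (CSV)
#'
#' @param report A [MetricsReport-class].
#' @param jsonPath Output JSON path.
#' @param rocPath Optional ROC CSV path.
#' @return `jsonPath`, invisibly.
#' @export
writeMetricsReport <- function(report, jsonPath, rocPath = NULL) {
  stopifnot(methods::is(report, "MetricsReport"))
  out <- list(protocol = report@protocol,
              counts = as.list(report@counts),
              metrics = as.list(report@metrics),
              agreement = as.list(report@agreement),
              flags = report@flags)
  jsonlite::write_json(out, jsonPath, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(rocPath))
    utils::write.csv(report@roc, rocPath, row.names = FALSE)
  invisible(jsonPath)
}
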