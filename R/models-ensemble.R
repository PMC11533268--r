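# Stratified fold assignment: shuffle within class, concatenate the class
# blocks, and deal folds cyclically, so overall fold sizes differ by at most
# one and each class is spread across folds as evenly as possible.
.stratifiedFolds <- function(labels, k, seed) {
  set.seed(seed)
  ord <- unlist(lapply(sort(unique(labels)), function(cl) {
    i <- which(labels == cl)
    if (length(i) > 1L) sample(i) else i
  }))
  folds <- integer(length(labels))
  folds[ord] <- rep_len(seq_len(k), length(labels))
  folds
}

#' Fit the stacked ensemble of three recurrent networks
#'
#' Trains an LSTM, a GRU and a bidirectional LSTM as base learners and
#' combines them by stacking: a logistic-regression meta-learner is fitted
#' on out-of-fold base probabilities (internal stratified 5-fold over the
#' training data, so the meta-learner never sees a base prediction made on
#' the data that trained that base model), after which the base models are
#' refitted on the full training set.
#'
#' @param features Numeric matrix, samples in rows (standardized by the
#'   caller; the evaluation protocols handle this).
#' @param labels 0-1 vector; both classes must be present.
#' @param configs Named list of three [networkConfig()]s as from
#'   [baseConfigs()].
#' @param threshold Decision threshold on the meta probability.
#' @param oofFolds Internal folds for the out-of-fold predictions.
#' @param seed Seed for the internal fold assignment.
#' @return An [EnsembleModel-class].
#' @export
fitEnsemble <- function(features, labels, configs = baseConfigs(),
                        threshold = 0.5, oofFolds = 5L, seed = 1L) {
  X <- as.matrix(features)
  y <- as.numeric(labels)
  if (length(unique(y)) < 2L)
    stop("ensemble training requires both classes to be present")
  stopifnot(length(configs) == 3L,
            setequal(names(configs), c("lstm", "gru", "blstm")))
  folds <- .stratifiedFolds(y, oofFolds, seed)
  oof <- matrix(NA_real_, nrow(X), 3L,
                dimnames = list(NULL, names(configs)))
  for (f in seq_len(oofFolds)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L)
      stop("internal fold ", f, " lost a class; dataset too small for stacking")
    for (nm in names(configs)) {
      cfg <- configs[[nm]]
      cfg$seed <- cfg$seed + 1000L * f
      fit <- trainBase(buildBase(cfg), X[tr, , drop = FALSE], y[tr])
      oof[!tr, nm] <- predictProba(fit, X[!tr, , drop = FALSE])
    }
  }
  metaData <- data.frame(y = y, oof)
  meta <- suppressWarnings(
    stats::glm(y ~ ., family = stats::binomial(), data = metaData))
  coefs <- stats::coef(meta)
  coefs[is.na(coefs)] <- 0
  bases <- lapply(configs, function(cfg) trainBase(buildBase(cfg), X, y))
  methods::new("EnsembleModel", baseModels = bases,
               metaCoef = as.numeric(coefs), threshold = threshold,
               standardizer = NULL)
}

#' Predict with a fitted stacked ensemble
#'
#' @param ensemble An [EnsembleModel-class] from [fitEnsemble()].
#' @param features Numeric matrix, samples in rows (same standardization as
#'   at fit time).
#' @return A list with `probability` (meta-learner probability per row),
#'   `label` (1 iff probability >= threshold) and `base` (matrix of the three
#'   base probabilities).
#' @export
ensemblePredict <- function(ensemble, features) {
  stopifnot(methods::is(ensemble, "EnsembleModel"))
  X <- as.matrix(features)
  B <- vapply(ensemble@baseModels, predictProba, numeric(nrow(X)), features = X)
  if (nrow(X) == 1L) B <- matrix(B, nrow = 1L,
                                 dimnames = list(NULL, names(ensemble@baseModels)))
  eta <- cbind(1, B) %*% ensemble@metaCoef
  prob <- as.numeric(.sigmoid(eta))
  list(probability = prob,
       label = as.integer(prob >= ensemble@threshold),
       base = B)
}
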