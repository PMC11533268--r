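#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom S4Vectors DataFrame
NULL

#' LabeledCorpus: a balanced normal/mutated sequence corpus
#'
#' Container for a labeled gene-sequence corpus: the union of normal
#' (label 0) and mutated (label 1) sequences, with per-record gene symbol,
#' sample identifier and, for mutated records, the provenance of the applied
#' mutation (1-based position, reference and alternate alleles).
#'
#' @slot sequences A [Biostrings::DNAStringSet] of the corpus sequences.
#' @slot label Integer vector, 0 = normal, 1 = mutated.
#' @slot geneSymbol Character vector of gene symbols, one per record.
#' @slot sampleId Character vector of sample identifiers, one per record.
#' @slot provenance A [S4Vectors::DataFrame] with columns `position`, `ref`,
#'   `alt` (NA for normal records).
#'
#' @seealso [buildLabeledDataset()], [generateLabeledCorpus()], [featurize()]
#' @exportClass LabeledCorpus
setClass("LabeledCorpus",
  representation(
    sequences  = "DNAStringSet",
    label      = "integer",
    geneSymbol = "character",
    sampleId   = "character",
    provenance = "DataFrame"
  )
)

setValidity("LabeledCorpus", function(object) {
  n <- length(object@sequences)
  msg <- character(0)
  if (length(object@label) != n ||
      length(object@geneSymbol) != n ||
      length(object@sampleId) != n ||
      nrow(object@provenance) != n)
    msg <- c(msg, "sequences, label, geneSymbol, sampleId and provenance must have equal length")
  if (!all(object@label %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 (normal) or 1 (mutated)")
  if (!all(c("position", "ref", "alt") %in% colnames(object@provenance)))
    msg <- c(msg, "provenance must have columns position, ref, alt")
  else if (any(object@label == 1L & is.na(object@provenance$position)))
    msg <- c(msg, "every mutated record must carry mutation provenance")
  if (length(msg)) msg else TRUE
})

#' Construct a LabeledCorpus
#'
#' @param sequences A `DNAStringSet` or named character vector of sequences.
#' @param label Integer or numeric vector of 0/1 labels.
#' @param geneSymbol Character vector of gene symbols.
#' @param sampleId Character vector of sample identifiers.
#' @param provenance Optional `DataFrame`/data.frame with columns `position`,
#'   `ref`, `alt`; defaults to all-NA (valid only if all labels are 0).
#' @return A [LabeledCorpus-class] object.
#' @export
LabeledCorpus <- function(sequences, label, geneSymbol, sampleId,
                          provenance = NULL) {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  n <- length(sequences)
  if (is.null(provenance))
    provenance <- S4Vectors::DataFrame(position = rep(NA_integer_, n),
                                       ref = rep(NA_character_, n),
                                       alt = rep(NA_character_, n))
  if (is.data.frame(provenance)) provenance <- S4Vectors::DataFrame(provenance)
  methods::new("LabeledCorpus",
               sequences = sequences,
               label = as.integer(label),
               geneSymbol = as.character(geneSymbol),
               sampleId = as.character(sampleId),
               provenance = provenance)
}

#' MetricsReport: confusion counts and the derived evaluation panel
#'
#' Holds the confusion matrix of one evaluation run together with the nine
#' derived metrics (accuracy, precision, recall, sensitivity, specificity,
#' F1, MCC, Cohen's kappa, AUC) and the ROC curve. Degenerate metrics
#' (zero denominators, single-class AUC) are reported as `NaN`/`NA` and
#' listed in `flags` rather than raised as errors.
#'
#' @slot protocol Character tag ("sct", "ist", "kfold" or "").
#' @slot counts Named integer vector `TP`, `FP`, `TN`, `FN`.
#' @slot metrics Named numeric vector of the derived metrics.
#' @slot agreement Named numeric vector `P_o`, `P_e` backing Cohen's kappa.
#' @slot roc data.frame with columns `fpr`, `tpr`, `threshold`.
#' @slot flags Character vector naming metrics that were undefined.
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(
    protocol  = "character",
    counts    = "integer",
    metrics   = "numeric",
    agreement = "numeric",
    roc       = "data.frame",
    flags     = "character"
  )
)

setValidity("MetricsReport", function(object) {
  msg <- character(0)
  if (!all(c("TP", "FP", "TN", "FN") %in% names(object@counts)))
    msg <- c(msg, "counts must be named TP, FP, TN, FN")
  else if (any(object@counts < 0L))
    msg <- c(msg, "confusion counts must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' EnsembleModel: stacked ensemble of three recurrent base networks
#'
#' Three trained base networks (LSTM, GRU, bidirectional LSTM) whose output
#' probabilities feed a logistic-regression meta-learner; the meta-learner is
#' fitted on out-of-fold base predictions to avoid stacking leakage.
#'
#' @slot baseModels Named list of three trained base networks.
#' @slot metaCoef Numeric vector of meta-learner coefficients
#'   (intercept + one weight per base model).
#' @slot threshold Decision threshold on the meta probability (default 0.5).
#' @slot standardizer Feature standardizer fitted on the training portion
#'   (list with `min` and `range`), or NULL when standardization is external.
#' @exportClass EnsembleModel
setClass("EnsembleModel",
  representation(
    baseModels   = "list",
    metaCoef     = "numeric",
    threshold    = "numeric",
    standardizer = "ANY"
  )
)

setValidity("EnsembleModel", function(object) {
  msg <- character(0)
  if (length(object@metaCoef) != length(object@baseModels) + 1L)
    msg <- c(msg, "meta-learner dimension must be number of base models + intercept")
  if (length(object@threshold) != 1L || object@threshold <= 0 || object@threshold >= 1)
    msg <- c(msg, "threshold must be a single value in (0,1)")
  if (length(msg)) msg else TRUE
})
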