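#' @rdname LabeledCorpus-class
#' @param x,object A `LabeledCorpus`.
#' @export
setGeneric("corpusSequences", function(x) standardGeneric("corpusSequences"))

#' @rdname LabeledCorpus-class
#' @export
setGeneric("corpusLabels", function(x) standardGeneric("corpusLabels"))

#' @rdname LabeledCorpus-class
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @rdname LabeledCorpus-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname LabeledCorpus-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

setMethod("corpusSequences", "LabeledCorpus", function(x) x@sequences)
setMethod("corpusLabels", "LabeledCorpus", function(x) x@label)
setMethod("geneSymbols", "LabeledCorpus", function(x) x@geneSymbol)
setMethod("sampleIds", "LabeledCorpus", function(x) x@sampleId)
setMethod("provenance", "LabeledCorpus", function(x) x@provenance)

#' @rdname LabeledCorpus-class
#' @export
setMethod("length", "LabeledCorpus", function(x) length(x@sequences))

#' @rdname LabeledCorpus-class
#' @param i Index vector.
#' @param j,drop,... Ignored (matrix-style subsetting is not supported).
#' @export
setMethod("[", "LabeledCorpus", function(x, i, j, ..., drop = TRUE) {
  methods::initialize(x,
    sequences = x@sequences[i],
    label = x@label[i],
    geneSymbol = x@geneSymbol[i],
    sampleId = x@sampleId[i],
    provenance = x@provenance[i, , drop = FALSE])
})

setMethod("show", "LabeledCorpus", function(object) {
  n <- length(object)
  cat("LabeledCorpus with", n, "sequences (",
      sum(object@label == 1L), "mutated /", sum(object@label == 0L),
      "normal ) across", length(unique(object@geneSymbol)), "genes\n")
  if (n > 0) {
    w <- range(Biostrings::width(object@sequences))
    cat("  sequence lengths:", w[1], "-", w[2], "nt\n")
  }
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport",
      if (nzchar(object@protocol)) sprintf("[%s]", object@protocol), "\n")
  cc <- object@counts
  cat(sprintf("  confusion: TP=%d FP=%d TN=%d FN=%d\n",
              cc["TP"], cc["FP"], cc["TN"], cc["FN"]))
  m <- object@metrics
  for (nm in names(m)) cat(sprintf("  %-12s %.4f\n", nm, m[nm]))
  if (length(object@flags))
    cat("  undefined:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "EnsembleModel", function(object) {
  cat("EnsembleModel: stacked", paste(names(object@baseModels), collapse = " + "),
      "\n  meta-learner coefficients:",
      paste(sprintf("%.3f", object@metaCoef), collapse = ", "),
      "\n  decision threshold:", object@threshold, "\n")
})

#' @rdname MetricsReport-class
#' @param x A `MetricsReport`.
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))
setMethod("metricValues", "MetricsReport", function(x) x@metrics)

#' @rdname MetricsReport-class
#' @export
setGeneric("confusionOf", function(x) standardGeneric("confusionOf"))
setMethod("confusionOf", "MetricsReport", function(x) x@counts)

#' @rdname MetricsReport-class
#' @export
setGeneric("rocCurve", function(x) standardGeneric("rocCurve"))
setMethod("rocCurve", "MetricsReport", function(x) x@roc)
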