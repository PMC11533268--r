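kmerNames <- function(k) {
  b <- c("A", "C", "G", "T")
  out <- ""
  for (i in seq_len(k)) out <- as.vector(t(outer(out, b, paste0)))
  out
}

#' Layout manifest of the 522-component feature vector
#'
#' The descriptor concatenates, per k-mer configuration k = 1, 2, 3
#' (alphabet sizes 4, 16, 64): the frequency vector, the forward AAPIV and
#' the reverse AAPIV (252 values), then the 30-value moment set (10 raw, 10
#' central, 10 Hahn; orders (a,b) with a+b <= 3) of each of the sequence
#' matrix, the PRIM and the RPRIM (270 values). Totals 522.
#'
#' @return A data.frame with one row per feature: `name`, `block`, `k`,
#'   `offset` (1-based), and the within-block index.
#' @export
featureLayout <- function() {
  rows <- list()
  add <- function(block, k, names) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = paste0("k", k, ".", block, ".", names),
      block = block, k = k, index = seq_along(names),
      stringsAsFactors = FALSE)
  }
  for (k in 1:3) {
    nm <- kmerNames(k)
    add("fv", k, nm)
    add("aapiv", k, nm)
    add("raapiv", k, nm)
  }
  ord <- momentOrders()
  momNames <- c(sprintf("raw.%d%d", ord[, 1], ord[, 2]),
                sprintf("central.%d%d", ord[, 1], ord[, 2]),
                sprintf("hahn.%d%d", ord[, 1], ord[, 2]))
  for (k in 1:3)
    for (mat in c("seqmat", "prim", "rprim"))
      add(mat, k, momNames)
  out <- do.call(rbind, rows)
  out$offset <- seq_len(nrow(out))
  stopifnot(nrow(out) == 522L)
  out
}

#' Extract the 522-component feature vector of one sequence
#'
#' Computes, for single-, bi- and tri-nucleotide configurations, the
#' frequency vector, forward and reverse accumulative absolute position
#' incidence vectors, and the raw/central/Hahn moment sets of the square
#' sequence matrix, the position-relative incidence matrix (PRIM) and its
#' reverse (RPRIM). See [featureLayout()] for the exact ordering.
#'
#' @param sequence Character string or `DNAString` over A/C/G/T, length
#'   >= 18 (so the trinucleotide code list fills a 4x4 grid).
#' @param hahnU,hahnV Hahn polynomial parameters (default 0; recorded in the
#'   layout attributes).
#' @return Named numeric vector of length 522; deterministic in its input.
#' @examples
#' length(extractFeatures(strrep("ACGT", 5)))  # 522
#' @export
extractFeatures <- function(sequence, hahnU = 0, hahnV = 0) {
  s <- as.character(sequence)
  if (nchar(s) < 18L)
    stop("sequence must be at least 18 nt (got ", nchar(s), ")")
  blocks <- vector("list", 18L)
  b <- 0L
  moments <- vector("list", 9L)
  m <- 0L
  for (k in 1:3) {
    K <- 4L ^ k
    codes <- encodeKmers(s, k)
    blocks[[b <- b + 1L]] <- frequencyVector(codes, K)
    blocks[[b <- b + 1L]] <- aapiv(codes, K, "forward")
    blocks[[b <- b + 1L]] <- aapiv(codes, K, "reverse")
    moments[[m <- m + 1L]] <- momentSet(sequenceMatrix(codes), hahnU, hahnV)
    moments[[m <- m + 1L]] <- momentSet(prim(codes, K), hahnU, hahnV)
    moments[[m <- m + 1L]] <- momentSet(rprim(codes, K), hahnU, hahnV)
  }
  out <- c(unlist(blocks, use.names = FALSE),
           unlist(moments, use.names = FALSE))
  layout <- featureLayout()
  stopifnot(length(out) == 522L)
  if (!all(is.finite(out)))
    stop("non-finite feature value at: ",
         paste(layout$name[!is.finite(out)], collapse = ", "))
  names(out) <- layout$name
  out
}

#' Featurize a labeled corpus into a SummarizedExperiment
#'
#' Applies [extractFeatures()] to every sequence of the corpus and returns a
#' [SummarizedExperiment::SummarizedExperiment] with the 522 features in
#' rows (rowData = layout manifest) and the sequences in columns
#' (colData = label, gene symbol, sample id).
#'
#' @param corpus A [LabeledCorpus-class].
#' @param hahnU,hahnV Hahn parameters, recorded in `metadata()`.
#' @return A `SummarizedExperiment` with assay `"features"`.
#' @export
featurize <- function(corpus, hahnU = 0, hahnV = 0) {
  stopifnot(methods::is(corpus, "LabeledCorpus"))
  if (length(corpus) == 0L) stop("cannot featurize an empty corpus")
  seqs <- as.character(corpusSequences(corpus))
  mat <- vapply(seqs, extractFeatures, numeric(522L),
                hahnU = hahnU, hahnV = hahnV, USE.NAMES = FALSE)
  layout <- featureLayout()
  rownames(mat) <- layout$name
  colnames(mat) <- names(corpusSequences(corpus))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mat),
    rowData = S4Vectors::DataFrame(layout),
    colData = S4Vectors::DataFrame(
      label = corpusLabels(corpus),
      geneSymbol = geneSymbols(corpus),
      sampleId = sampleIds(corpus),
      row.names = colnames(mat)),
    metadata = list(hahnU = hahnU, hahnV = hahnV))
}

#' Write a featurized corpus to CSV plus a JSON layout manifest
#'
#' One row per sequence: `id`, `label`, then the 522 feature columns in
#' layout order. The JSON manifest records the block layout and the Hahn
#' parameters of the run.
#'
#' @param se A `SummarizedExperiment` from [featurize()].
#' @param csvPath Output CSV path.
#' @param manifestPath Output JSON path (default `csvPath` + `.layout.json`).
#' @return `csvPath`, invisibly.
#' @export
writeFeatureCsv <- function(se, csvPath,
                            manifestPath = paste0(csvPath, ".layout.json")) {
  mat <- t(SummarizedExperiment::assay(se, "features"))
  df <- data.frame(id = rownames(mat),
                   label = SummarizedExperiment::colData(se)$label,
                   mat, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, csvPath, row.names = FALSE)
  layout <- as.data.frame(SummarizedExperiment::rowData(se))
  jsonlite::write_json(
    list(layout = layout,
         hahnU = S4Vectors::metadata(se)$hahnU,
         hahnV = S4Vectors::metadata(se)$hahnV),
    manifestPath, auto_unbox = TRUE, digits = NA)
  invisible(csvPath)
}
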