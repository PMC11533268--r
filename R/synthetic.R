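#' Configuration of the synthetic corpus generator
#'
#' The generator emulates the structure of a driver-gene corpus: ~40
#' reference genes with transcript-scale lengths, a mutation table whose
#' per-gene counts follow a Zipf-like law (a few genes dominate, as
#' driver-gene tables do), and a balanced labeled corpus. A class signal is
#' optionally planted by enriching mutated-class sequences for a designated
#' trinucleotide motif; `effectSize = 0` defines the null corpus in which
#' the two classes differ only by single point mutations.
#'
#' @param nGenes Number of reference genes (default 40).
#' @param lengthRange Integer min/max gene length in nt (default 200-3000;
#'   minimum allowed is 18, the feature extractor's shortest valid input).
#' @param nMutations Number of driver mutations (default 696).
#' @param skew Zipf exponent >= 1 concentrating mutations in few genes
#'   (default 1.7).
#' @param effectSize Fraction in `[0, 1]`: mutated-class sequences have
#'   `floor(effectSize * L / 10)` non-overlapping positions rewritten to the
#'   designated motif.
#' @param seed Integer seed; all three generators are fully deterministic
#'   given it.
#' @param motif The designated trinucleotide motif (default `"GAC"`).
#' @return A list of class `"syntheticConfig"`.
#' @export
syntheticConfig <- function(nGenes = 40L, lengthRange = c(200L, 3000L),
                            nMutations = 696L, skew = 1.7, effectSize = 0,
                            seed = 1L, motif = "GAC") {
  stopifnot(length(lengthRange) == 2L)
  lengthRange <- as.integer(lengthRange)
  if (lengthRange[1] < 18L || lengthRange[2] < lengthRange[1])
    stop("lengthRange must satisfy 18 <= min <= max")
  if (nGenes < 1L || nMutations < 0L) stop("nGenes/nMutations out of range")
  if (skew < 1) stop("skew must be >= 1")
  if (effectSize < 0 || effectSize > 1) stop("effectSize must lie in [0, 1]")
  if (nchar(motif) != 3L || grepl("[^ACGT]", motif))
    stop("motif must be a trinucleotide over A/C/G/T")
  structure(list(nGenes = as.integer(nGenes), lengthRange = lengthRange,
                 nMutations = as.integer(nMutations), skew = skew,
                 effectSize = effectSize, seed = as.integer(seed),
                 motif = motif),
            class = "syntheticConfig")
}

#' Generate synthetic reference genes
#'
#' I.i.d. uniform A/C/G/T sequences with lengths uniform over the configured
#' range; deterministic given the seed.
#'
#' @param config A [syntheticConfig()].
#' @return A named [Biostrings::DNAStringSet].
#' @export
generateReferenceGenes <- function(config) {
  stopifnot(inherits(config, "syntheticConfig"))
  set.seed(config$seed)
  lens <- sample(config$lengthRange[1]:config$lengthRange[2],
                 config$nGenes, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("GENE%02d", seq_len(config$nGenes))
  out
}

#' Generate a synthetic driver-mutation table
#'
#' Genes are drawn with Zipf(skew) probabilities (gene 1 most mutated),
#' positions uniformly within the gene, the reference allele is read from
#' the reference sequence (so applying the mutation can never fail a
#' reference-consistency check), and the alternate allele is uniform over
#' the remaining three bases.
#'
#' @param refs Named `DNAStringSet` from [generateReferenceGenes()].
#' @param config A [syntheticConfig()].
#' @return data.frame with columns `gene`, `position`, `ref`, `alt`,
#'   `sample_id`.
#' @export
generateMutationTable <- function(refs, config) {
  stopifnot(inherits(config, "syntheticConfig"), length(refs) > 0L)
  set.seed(config$seed + 1L)
  refChr <- as.character(refs)
  nG <- length(refChr)
  prob <- seq_len(nG) ^ (-config$skew)
  geneIdx <- sample.int(nG, config$nMutations, replace = TRUE,
                        prob = prob / sum(prob))
  bases <- c("A", "C", "G", "T")
  n <- config$nMutations
  position <- integer(n); ref <- character(n); alt <- character(n)
  for (i in seq_len(n)) {
    s <- refChr[[geneIdx[i]]]
    position[i] <- sample.int(nchar(s), 1L)
    ref[i] <- substr(s, position[i], position[i])
    alt[i] <- sample(setdiff(bases, ref[i]), 1L)
  }
  data.frame(gene = names(refChr)[geneIdx], position = position,
             ref = ref, alt = alt,
             sample_id = sprintf("S%04d", seq_len(n)),
             stringsAsFactors = FALSE)
}

#' Generate a balanced labeled corpus with controllable class signal
#'
#' Builds the balanced dataset from synthetic references and mutations, then
#' plants a compositional class difference: in every mutated (label 1)
#' sequence, `floor(effectSize * L / 10)` non-overlapping positions are
#' rewritten to spell the designated trinucleotide motif. With
#' `effectSize = 0` the classes are exchangeable up to single point
#' mutations.
#'
#' @param config A [syntheticConfig()].
#' @return A [LabeledCorpus-class] of size `2 * nMutations`.
#' @export
generateLabeledCorpus <- function(config) {
  stopifnot(inherits(config, "syntheticConfig"))
  refs <- generateReferenceGenes(config)
  muts <- generateMutationTable(refs, config)
  corpus <- buildLabeledDataset(refs, muts)
  if (config$effectSize > 0 && length(corpus) > 0L) {
    set.seed(config$seed + 2L)
    motif <- strsplit(config$motif, "")[[1]]
    seqs <- as.character(corpusSequences(corpus))
    for (i in which(corpusLabels(corpus) == 1L)) {
      chars <- strsplit(seqs[[i]], "")[[1]]
      L <- length(chars)
      nPlant <- floor(config$effectSize * L / 10)
      if (nPlant < 1L) next
      grid <- seq(1L, L - 2L, by = 3L)   # stride-3 grid: plants cannot overlap
      starts <- sample(grid, min(nPlant, length(grid)))
      for (s0 in starts) chars[s0:(s0 + 2L)] <- motif
      seqs[[i]] <- paste(chars, collapse = "")
    }
    newSeqs <- Biostrings::DNAStringSet(seqs)
    names(newSeqs) <- names(corpusSequences(corpus))
    corpus@sequences <- newSeqs
    methods::validObject(corpus)
  }
  corpus
}
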