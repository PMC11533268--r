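#' Read reference gene sequences from FASTA
#'
#' Reads a FASTA file of reference (normal) gene sequences. The first
#' whitespace-delimited token of each header is taken as the gene symbol.
#' Duplicate symbols are rejected, as are characters outside the A/C/G/T
#' alphabet unless `ambiguity = "mask"`, in which case ambiguity codes are
#' replaced by `A` with a warning (the downstream feature equations are
#' defined only on the 4-letter alphabet).
#'
#' @param path Path to a FASTA file.
#' @param ambiguity Either `"error"` (default) or `"mask"`.
#' @return A named [Biostrings::DNAStringSet], one entry per gene.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">BRAF", "ACGT"), fa)
#' readReferenceFasta(fa)
#' @export
readReferenceFasta <- function(path, ambiguity = c("error", "mask")) {
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  refs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) stop("malformed FASTA '", path, "': ",
                                            conditionMessage(e), call. = FALSE))
  names(refs) <- sub("\\s.*$", "", names(refs))
  dup <- unique(names(refs)[duplicated(names(refs))])
  if (length(dup))
    stop("duplicate gene symbols in reference FASTA: ", paste(dup, collapse = ", "))
  bad <- .nonACGT(refs)
  if (length(bad)) {
    if (ambiguity == "error")
      stop("non-ACGT characters in sequences: ", paste(bad, collapse = ", "),
           " (set ambiguity = \"mask\" to replace them with A)")
    warning("masking non-ACGT characters to A in: ", paste(bad, collapse = ", "))
    chr <- as.character(refs)
    chr <- vapply(chr, function(s) gsub("[^ACGT]", "A", s), character(1))
    refs <- Biostrings::DNAStringSet(chr)
  }
  if (any(Biostrings::width(refs) == 0L))
    stop("empty sequence for gene(s): ",
         paste(names(refs)[Biostrings::width(refs) == 0L], collapse = ", "))
  refs
}

.nonACGT <- function(refs) {
  if (length(refs) == 0L) return(character(0))
  freq <- Biostrings::alphabetFrequency(refs)
  other <- rowSums(freq) - rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  names(refs)[other > 0]
}

#' Read a driver-mutation table
#'
#' Reads a delimited text file with header columns
#' `gene,position,ref,alt,sample_id`. The delimiter is auto-detected from the
#' file extension (`.tsv`/`.tab` = tab, otherwise comma). Positions are
#' 1-based and must parse as integers.
#'
#' @param path Path to the mutation table.
#' @return A data.frame with columns `gene` (character), `position` (integer),
#'   `ref`, `alt`, `sample_id` (character). Zero rows for a header-only file.
#' @export
readMutationTable <- function(path) {
  if (!file.exists(path)) stop("mutation table not found: ", path)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "")
  needed <- c("gene", "position", "ref", "alt", "sample_id")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("mutation table is missing column(s): ", paste(missing, collapse = ", "))
  pos <- suppressWarnings(as.integer(tab$position))
  bad <- which(is.na(pos) | as.character(pos) != trimws(tab$position))
  if (length(bad))
    stop("non-integer position in mutation table row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  data.frame(gene = tab$gene, position = pos, ref = toupper(tab$ref),
             alt = toupper(tab$alt), sample_id = tab$sample_id,
             stringsAsFactors = FALSE)
}

#' Apply one mutation to a reference sequence
#'
#' Applies a substitution, insertion or deletion at a 1-based, fully closed
#' coordinate. `ref` must match the reference at `position` (checked); `alt`
#' replaces the `nchar(ref)` characters starting at `position`. An empty
#' `ref` inserts `alt` before `position`; an empty `alt` deletes `ref`.
#' A no-op (`ref == alt`) is allowed with a warning.
#'
#' @param sequence Reference sequence (single character string or
#'   [Biostrings::DNAString]).
#' @param position 1-based position of the first reference base affected.
#' @param ref Reference allele ("" for pure insertion).
#' @param alt Alternate allele ("" for pure deletion).
#' @return The mutated sequence as a character string.
#' @examples
#' applyMutation("ACGTACGT", 2, "C", "T")  # "ATGTACGT"
#' @export
applyMutation <- function(sequence, position, ref, alt) {
  s <- as.character(sequence)
  stopifnot(length(s) == 1L)
  L <- nchar(s)
  position <- as.integer(position)
  ref <- toupper(ref); alt <- toupper(alt)
  if (!nchar(ref) && !nchar(alt))
    stop("mutation with empty ref and empty alt is meaningless")
  if (grepl("[^ACGT]", ref) || grepl("[^ACGT]", alt))
    stop("alleles must be over the A/C/G/T alphabet (got ref='", ref,
         "', alt='", alt, "')")
  if (is.na(position) || position < 1L || position > L + (nchar(ref) == 0L))
    stop("position ", position, " out of range for sequence of length ", L)
  if (nchar(ref)) {
    if (position + nchar(ref) - 1L > L)
      stop("ref allele runs past the end of the sequence (position ",
           position, ", ref length ", nchar(ref), ", sequence length ", L, ")")
    found <- substr(s, position, position + nchar(ref) - 1L)
    if (found != ref)
      stop("reference mismatch at position ", position, ": expected '", ref,
           "', found '", found, "'")
    if (ref == alt) warning("no-op mutation (ref == alt) at position ", position)
  }
  paste0(substr(s, 1L, position - 1L), alt,
         substr(s, position + nchar(ref), L))
}

#' Build the balanced labeled dataset
#'
#' Assembles the union of normal and mutated sequences: one mutated (label 1)
#' record per mutation, and one copy of the gene's normal sequence (label 0)
#' per mutation of that gene, so positives and negatives are balanced within
#' every gene. Records are ordered by gene symbol, then sample id, with the
#' normal copy preceding its mutated partner.
#'
#' @param refs Named `DNAStringSet` (or named character vector) of reference
#'   sequences, e.g. from [readReferenceFasta()].
#' @param mutations data.frame from [readMutationTable()].
#' @return A [LabeledCorpus-class]. Empty mutations give an empty corpus.
#' @export
buildLabeledDataset <- function(refs, mutations) {
  if (!methods::is(refs, "DNAStringSet")) refs <- Biostrings::DNAStringSet(refs)
  refChr <- as.character(refs)
  if (nrow(mutations) == 0L)
    return(LabeledCorpus(Biostrings::DNAStringSet(), integer(0),
                         character(0), character(0)))
  unknown <- setdiff(unique(mutations$gene), names(refChr))
  if (length(unknown))
    stop("mutation table references gene(s) absent from the reference set: ",
         paste(unknown, collapse = ", "))
  ord <- order(mutations$gene, mutations$sample_id, mutations$position)
  mutations <- mutations[ord, , drop = FALSE]
  n <- nrow(mutations)
  mutSeq <- character(n)
  for (i in seq_len(n)) {
    m <- mutations[i, ]
    mutSeq[i] <- applyMutation(refChr[[m$gene]], m$position, m$ref, m$alt)
  }
  # interleave: per mutation, the normal copy then the mutated sequence
  idx <- rep(seq_len(n), each = 2L)
  isMut <- rep(c(FALSE, TRUE), times = n)
  seqs <- ifelse(isMut, mutSeq[idx], refChr[mutations$gene[idx]])
  lab <- as.integer(isMut)
  prov <- S4Vectors::DataFrame(
    position = ifelse(isMut, mutations$position[idx], NA_integer_),
    ref = ifelse(isMut, mutations$ref[idx], NA_character_),
    alt = ifelse(isMut, mutations$alt[idx], NA_character_))
  out <- LabeledCorpus(Biostrings::DNAStringSet(unname(seqs)), lab,
                       mutations$gene[idx], mutations$sample_id[idx], prov)
  names(out@sequences) <- paste(out@geneSymbol, out@sampleId,
                                ifelse(lab == 1L, "mut", "wt"), sep = "|")
  out
}

#' Summarize a labeled corpus per gene
#'
#' Counts mutations (label-1 records) and distinct sample ids per gene,
#' mirroring the Symbol/Mutation/Sample layout of a driver-gene summary
#' table.
#'
#' @param corpus A [LabeledCorpus-class].
#' @return A data.frame with columns `Symbol`, `Mutation`, `Sample`, sorted by
#'   descending mutation count, with attributes `totalMutations` and
#'   `totalSamples`.
#' @export
summarizeCorpus <- function(corpus) {
  if (length(corpus) == 0L) stop("cannot summarize an empty corpus")
  genes <- sort(unique(geneSymbols(corpus)))
  isMut <- corpusLabels(corpus) == 1L
  mutCount <- vapply(genes, function(g)
    sum(isMut & geneSymbols(corpus) == g), integer(1))
  samCount <- vapply(genes, function(g)
    length(unique(sampleIds(corpus)[isMut & geneSymbols(corpus) == g])),
    integer(1))
  out <- data.frame(Symbol = genes, Mutation = mutCount, Sample = samCount,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$Mutation, out$Symbol), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "totalMutations") <- sum(mutCount)
  attr(out, "totalSamples") <- length(unique(sampleIds(corpus)[isMut]))
  out
}

#' Write / read a labeled corpus as FASTA plus manifest
#'
#' The FASTA headers encode `gene|sample|mut` / `gene|sample|wt`; the sidecar
#' CSV manifest carries the label and mutation provenance so the corpus
#' round-trips exactly.
#'
#' @param corpus A [LabeledCorpus-class].
#' @param fastaPath Output FASTA path.
#' @param manifestPath Output CSV path (default: `fastaPath` with
#'   `.manifest.csv` appended).
#' @return `fastaPath`, invisibly.
#' @export
writeCorpusFasta <- function(corpus, fastaPath,
                             manifestPath = paste0(fastaPath, ".manifest.csv")) {
  Biostrings::writeXStringSet(corpusSequences(corpus), fastaPath)
  man <- data.frame(name = names(corpusSequences(corpus)),
                    gene = geneSymbols(corpus),
                    sample_id = sampleIds(corpus),
                    label = corpusLabels(corpus),
                    position = provenance(corpus)$position,
                    ref = provenance(corpus)$ref,
                    alt = provenance(corpus)$alt,
                    stringsAsFactors = FALSE)
  utils::write.csv(man, manifestPath, row.names = FALSE, na = "")
  invisible(fastaPath)
}

#' @rdname writeCorpusFasta
#' @export
readCorpusFasta <- function(fastaPath,
                            manifestPath = paste0(fastaPath, ".manifest.csv")) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  man <- utils::read.csv(manifestPath, colClasses = c(
    name = "character", gene = "character", sample_id = "character",
    label = "integer", position = "integer", ref = "character",
    alt = "character"), na.strings = "")
  if (nrow(man) != length(seqs))
    stop("manifest rows (", nrow(man), ") do not match FASTA records (",
         length(seqs), ")")
  LabeledCorpus(seqs, man$label, man$gene, man$sample_id,
                S4Vectors::DataFrame(position = man$position, ref = man$ref,
                                     alt = man$alt))
}
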