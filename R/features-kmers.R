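#' Encode a sequence as overlapping k-mer codes
#'
#' Maps every overlapping window of `k` nucleotides (step 1) to an integer
#' code in `[0, 4^k)` using base-4 digits A=0, C=1, G=2, T=3, most
#' significant digit first: `code = sum(digit[j] * 4^(k-1-j))`.
#'
#' @param sequence Character string (or `DNAString`) over A/C/G/T.
#' @param k Window width, one of 1, 2, 3.
#' @return Integer vector of length `nchar(sequence) - k + 1`.
#' @examples
#' encodeKmers("ACGT", 2)  # AC=1, CG=6, GT=11
#' @export
encodeKmers <- function(sequence, k) {
  s <- as.character(sequence)
  stopifnot(length(s) == 1L, k %in% 1:3)
  L <- nchar(s)
  if (L < k) stop("sequence shorter than k (length ", L, ", k = ", k, ")")
  base <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")) - 1L
  if (anyNA(base)) stop("sequence contains characters outside A/C/G/T")
  n <- L - k + 1L
  out <- integer(n)
  for (j in seq_len(k)) out <- out * 4L + base[j:(j + n - 1L)]
  out
}

#' Per-symbol frequency vector
#'
#' Occurrence count of each code of the k-mer alphabet; the counts sum to the
#' number of k-mers, `L - k + 1`.
#'
#' @param codes Integer codes from [encodeKmers()].
#' @param K Alphabet size (4, 16 or 64).
#' @return Integer vector of length `K`.
#' @export
frequencyVector <- function(codes, K) {
  stopifnot(all(codes >= 0L), all(codes < K))
  tabulate(codes + 1L, nbins = K)
}

#' Accumulative absolute position incidence vector (AAPIV / RAAPIV)
#'
#' For each symbol of the alphabet, the sum of the 1-based positions at which
#' it occurs. `direction = "reverse"` computes the same quantity on the
#' reversed code list, giving the reverse AAPIV.
#'
#' @param codes Integer codes from [encodeKmers()].
#' @param K Alphabet size.
#' @param direction `"forward"` or `"reverse"`.
#' @return Numeric vector of length `K`; entry i is 0 iff symbol i is absent.
#' @examples
#' aapiv(encodeKmers("AAAA", 1), 4)  # A: 1+2+3+4 = 10
#' @export
aapiv <- function(codes, K, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  if (direction == "reverse") codes <- rev(codes)
  stopifnot(all(codes >= 0L), all(codes < K))
  out <- numeric(K)
  acc <- vapply(split(seq_along(codes), factor(codes, levels = 0:(K - 1L))),
                function(p) sum(as.numeric(p)), numeric(1))
  out[] <- acc
  out
}

#' Position relative incidence matrix (PRIM)
#'
#' A K-by-K summary of where each symbol occurs relative to each other
#' symbol: entry (i, j) accumulates, over every occurrence of symbol j at a
#' 1-based position p strictly after the first occurrence f_i of symbol i,
#' the offset p - f_i. Rows of absent symbols are identically zero, and all
#' entries are nonnegative integers.
#'
#' @param codes Integer codes from [encodeKmers()].
#' @param K Alphabet size.
#' @return Numeric `K x K` matrix.
#' @examples
#' prim(encodeKmers("AAAA", 1), 4)[1, 1]  # (2-1)+(3-1)+(4-1) = 6
#' @export
prim <- function(codes, K) {
  stopifnot(all(codes >= 0L), all(codes < K))
  pos <- split(seq_along(codes), factor(codes, levels = 0:(K - 1L)))
  first <- vapply(pos, function(p)
    if (length(p)) p[[1L]] else NA_integer_, integer(1))
  M <- matrix(0, K, K)
  present <- which(!is.na(first))
  f <- first[present]
  for (j in seq_len(K)) {
    pj <- pos[[j]]
    nj <- length(pj)
    if (nj == 0L) next
    cs <- c(0, cumsum(as.numeric(pj)))
    idx <- findInterval(f, pj)          # occurrences of j at positions <= f_i
    M[present, j] <- (cs[nj + 1L] - cs[idx + 1L]) - f * (nj - idx)
  }
  M
}

#' Reverse position relative incidence matrix (RPRIM)
#'
#' [prim()] applied to the reversed code list.
#'
#' @inheritParams prim
#' @return Numeric `K x K` matrix.
#' @export
rprim <- function(codes, K) prim(rev(codes), K)
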