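# Fixed enumeration of the moment orders (a, b), a + b <= 3, shared by the
# raw, central and Hahn families: 10 orders x 3 families = 30 per matrix.
momentOrders <- function() {
  matrix(c(0L, 0L, 0L, 1L, 1L, 0L, 1L, 1L, 0L, 2L,
           2L, 0L, 1L, 2L, 2L, 1L, 0L, 3L, 3L, 0L),
         ncol = 2L, byrow = TRUE,
         dimnames = list(NULL, c("a", "b")))
}

#' Arrange k-mer codes as a square 2D matrix
#'
#' Row-major fill of the code list into an `N x N` grid with
#' `N = max(4, ceiling(sqrt(length(codes))))`; trailing cells are
#' zero-padded. The minimum side of 4 keeps degree-3 Hahn polynomials
#' well-defined on the grid.
#'
#' @param codes Nonempty integer vector of k-mer codes.
#' @return Numeric `N x N` matrix.
#' @export
sequenceMatrix <- function(codes) {
  if (length(codes) == 0L) stop("cannot build a sequence matrix from zero codes")
  N <- max(4L, ceiling(sqrt(length(codes))))
  matrix(c(as.numeric(codes), numeric(N * N - length(codes))),
         nrow = N, ncol = N, byrow = TRUE)
}

#' Raw moments of a 2D grid
#'
#' `R_ab = sum_p sum_q p^a q^b G(p, q)` with 1-based row index p and column
#' index q, for the 10 orders with a + b <= 3.
#'
#' @param m Square numeric matrix.
#' @return Named numeric vector of 10 raw moments (`raw.ab`).
#' @export
rawMoments <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  N <- nrow(m)
  p <- as.numeric(seq_len(N))
  ord <- momentOrders()
  out <- vapply(seq_len(nrow(ord)), function(i)
    sum((p ^ ord[i, "a"]) * m %*% (p ^ ord[i, "b"])), numeric(1))
  names(out) <- sprintf("raw.%d%d", ord[, "a"], ord[, "b"])
  out
}

#' Central moments of a 2D grid
#'
#' Moments taken about the mass centroid `xbar = R_10 / R_00`,
#' `ybar = R_01 / R_00`:
#' `C_ab = sum_p sum_q (p - xbar)^a (q - ybar)^b G(p, q)`.
#' For an all-zero grid the centroid is undefined; an all-zero moment set is
#' returned with attribute `degenerate = TRUE`.
#'
#' @param m Square numeric matrix.
#' @return Named numeric vector of 10 central moments (`central.ab`) with
#'   attribute `centroid = c(xbar, ybar)`.
#' @export
centralMoments <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  N <- nrow(m)
  p <- as.numeric(seq_len(N))
  ord <- momentOrders()
  R00 <- sum(m)
  nm <- sprintf("central.%d%d", ord[, "a"], ord[, "b"])
  if (R00 == 0) {
    out <- stats::setNames(numeric(nrow(ord)), nm)
    attr(out, "centroid") <- c(NA_real_, NA_real_)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  xbar <- sum(p * rowSums(m)) / R00
  ybar <- sum(p * colSums(m)) / R00
  out <- vapply(seq_len(nrow(ord)), function(i)
    sum(((p - xbar) ^ ord[i, "a"]) * m %*% ((p - ybar) ^ ord[i, "b"])),
    numeric(1))
  names(out) <- nm
  attr(out, "centroid") <- c(xbar, ybar)
  out
}

.pochhammer <- function(x, k) {
  if (k == 0L) return(1)
  prod(x + seq_len(k) - 1)
}

#' Discrete Hahn polynomial
#'
#' Evaluates the degree-n Hahn polynomial on the discrete support
#' `r = 0 .. N-1` as the finite hypergeometric-type sum
#' \deqn{h_n^{u,v}(r, N) = (N+v-1)_n (N-1)_n \sum_{k=0}^{n} (-1)^k
#'   \frac{(-n)_k (-r)_k (2N+u+v-n-1)_k}{(N+v-1)_k (N-1)_k\, k!}}
#' with Pochhammer symbols `(x)_k = x (x+1) ... (x+k-1)`. Under
#' `u = v = 0` the degree-0 polynomial is identically 1.
#'
#' @param n Polynomial degree, `0 <= n <= N-1`.
#' @param r Evaluation point(s) in `0 .. N-1` (vectorized).
#' @param N Support size.
#' @param u,v Nonnegative real parameters (default 0).
#' @return Numeric vector, one value per element of `r`.
#' @export
hahnPolynomial <- function(n, r, N, u = 0, v = 0) {
  stopifnot(n >= 0, N >= 1, u >= 0, v >= 0)
  if (n >= N) stop("polynomial degree n (", n, ") must be < support size N (", N, ")")
  if (any(r < 0 | r > N - 1)) stop("evaluation points must lie in 0 .. N-1")
  pref <- .pochhammer(N + v - 1, n) * .pochhammer(N - 1, n)
  acc <- numeric(length(r))
  for (k in 0:n) {
    num <- (-1) ^ k * .pochhammer(-n, k) *
      .pochhammer(2 * N + u + v - n - 1, k)
    den <- .pochhammer(N + v - 1, k) * .pochhammer(N - 1, k) * factorial(k)
    pr <- if (k == 0L) rep(1, length(r)) else {
      # (-r)_k vectorized over r
      m <- outer(-r, seq_len(k) - 1, `+`)
      apply(m, 1L, prod)
    }
    acc <- acc + num * pr / den
  }
  pref * acc
}

#' Hahn moments of a 2D grid
#'
#' `H_ab = sum_p sum_q G(p, q) h_a(q, N) h_b(p, N)` with 0-based indices p
#' (rows) and q (columns) running over `0 .. N-1`, for the 10 orders with
#' a + b <= 3. Under `u = v = 0`, `H_00` equals the grand sum of the grid.
#'
#' @param m Square numeric matrix with side `N >= 4`.
#' @param u,v Hahn parameters (default 0).
#' @return Named numeric vector of 10 Hahn moments (`hahn.ab`).
#' @export
hahnMoments <- function(m, u = 0, v = 0) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  N <- nrow(m)
  if (N < 4L) stop("Hahn moments require matrix side >= 4 (got ", N, ")")
  r <- 0:(N - 1L)
  h <- vapply(0:3, function(n) hahnPolynomial(n, r, N, u, v), numeric(N))
  ord <- momentOrders()
  out <- vapply(seq_len(nrow(ord)), function(i)
    as.numeric(t(h[, ord[i, "b"] + 1L]) %*% m %*% h[, ord[i, "a"] + 1L]),
    numeric(1))
  names(out) <- sprintf("hahn.%d%d", ord[, "a"], ord[, "b"])
  out
}

# The 30-value moment set of one matrix: raw, central, Hahn, in the fixed
# order enumeration.
momentSet <- function(m, u = 0, v = 0) {
  c(rawMoments(m), .stripAttrs(centralMoments(m)), hahnMoments(m, u, v))
}

.stripAttrs <- function(x) {
  nm <- names(x)
  x <- as.numeric(x)
  names(x) <- nm
  x
}
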