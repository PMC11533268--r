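# Independent brute-force oracles, kept deliberately naive (scalar loops)
# so they share no code path with the package implementations.

orderPairs <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1, 0, 2,
                       2, 0, 1, 2, 2, 1, 0, 3, 3, 0),
                     ncol = 2, byrow = TRUE)

bruteRawMoment <- function(m, a, b) {
  acc <- 0
  for (p in seq_len(nrow(m)))
    for (q in seq_len(ncol(m)))
      acc <- acc + p^a * q^b * m[p, q]
  acc
}

bruteCentralMoment <- function(m, a, b) {
  tot <- 0; sx <- 0; sy <- 0
  for (p in seq_len(nrow(m)))
    for (q in seq_len(ncol(m))) {
      tot <- tot + m[p, q]; sx <- sx + p * m[p, q]; sy <- sy + q * m[p, q]
    }
  if (tot == 0) return(0)
  xb <- sx / tot; yb <- sy / tot
  acc <- 0
  for (p in seq_len(nrow(m)))
    for (q in seq_len(ncol(m)))
      acc <- acc + (p - xb)^a * (q - yb)^b * m[p, q]
  acc
}

poch <- function(x, k) {
  out <- 1
  if (k > 0) for (i in 0:(k - 1)) out <- out * (x + i)
  out
}

# Term-by-term scalar evaluation of the Hahn polynomial's finite sum.
bruteHahn <- function(n, r, N, u = 0, v = 0) {
  acc <- 0
  for (k in 0:n)
    acc <- acc + (-1)^k * poch(-n, k) * poch(-r, k) *
      poch(2 * N + u + v - n - 1, k) /
      (poch(N + v - 1, k) * poch(N - 1, k) * factorial(k))
  poch(N + v - 1, n) * poch(N - 1, n) * acc
}

bruteHahnMoment <- function(m, a, b, u = 0, v = 0) {
  N <- nrow(m)
  acc <- 0
  for (p in 0:(N - 1))
    for (q in 0:(N - 1))
      acc <- acc + m[p + 1, q + 1] * bruteHahn(a, q, N, u, v) *
        bruteHahn(b, p, N, u, v)
  acc
}

# Direct-scan PRIM oracle: for every ordered symbol pair, walk the sequence.
brutePrim <- function(codes, K) {
  M <- matrix(0, K, K)
  for (i in 0:(K - 1)) {
    f <- which(codes == i)[1]
    if (is.na(f)) next
    for (j in 0:(K - 1))
      for (p in seq_along(codes))
        if (codes[p] == j && p > f) M[i + 1, j + 1] <- M[i + 1, j + 1] + (p - f)
  }
  M
}

bruteAapiv <- function(codes, K) {
  out <- numeric(K)
  for (p in seq_along(codes)) out[codes[p] + 1] <- out[codes[p] + 1] + p
  out
}

# Exhaustive concordant-pair AUC (ties count one half).
bruteAuc <- function(prob, truth) {
  pos <- prob[truth == 1]; neg <- prob[truth == 0]
  acc <- 0
  for (a in pos) for (b in neg)
    acc <- acc + if (a > b) 1 else if (a == b) 0.5 else 0
  acc / (length(pos) * length(neg))
}

bruteMetrics <- function(TP, FP, TN, FN) {
  n <- TP + FP + TN + FN
  prec <- TP / (TP + FP)
  rec <- TP / (TP + FN)
  list(
    accuracy = (TP + TN) / n,
    precision = prec,
    recall = rec,
    specificity = TN / (TN + FP),
    f1 = 2 * prec * rec / (prec + rec),
    mcc = (TP * TN - FP * FN) /
      sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)),
    kappa = {
      po <- (TP + TN) / n
      pe <- ((TP + FP) * (TP + FN) + (FN + TN) * (FP + TN)) / n^2
      (po - pe) / (1 - pe)
    })
}

randomSeq <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                               collapse = "")

writeTempFasta <- function(records) {
  fa <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(records), function(n)
    c(paste0(">", n), records[[n]]))), fa)
  fa
}

# Small configurations for fast model unit tests (not the study conditions).
tinyConfigs <- function(inputWidth, epochs = 40L, seed = 1L) {
  baseConfigs(epochs = epochs, seed = seed, inputWidth = inputWidth,
              hiddenWidth = 16L, denseWidth = 8L, batchSize = 8L)
}

# Linearly separable toy features: class means +/- delta on every column.
separableData <- function(n, width, delta = 2, seed = 99) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  X <- matrix(rnorm(n * width), n, width) + outer(ifelse(y == 1, delta, -delta),
                                                  rep(1, width))
  list(X = X, y = y)
}
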