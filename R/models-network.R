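#' Configuration of one recurrent base network
#'
#' The base architecture is: dense input projection (inputWidth -> hidden
#' width 128), a gated recurrent layer of width 128 (LSTM, GRU, or
#' bidirectional LSTM; the feature vector enters as a length-1 sequence),
#' then two dense layers of width 64 with ReLU, each followed by inverted
#' dropout, and a single sigmoid output unit. Training minimizes binary
#' cross-entropy with Adam.
#'
#' @param kind One of `"lstm"`, `"gru"`, `"blstm"`.
#' @param inputWidth Feature width (default 522).
#' @param hiddenWidth Recurrent width (default 128).
#' @param denseWidth Dense-head width (default 64).
#' @param dropoutRate Dropout fraction in (0, 1), default 0.3.
#' @param epochs Training epochs (default 300; tests and quick runs use 30).
#' @param batchSize Minibatch size (default 32).
#' @param learningRate Adam step size (default 1e-3).
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout masks.
#' @return A list of class `"networkConfig"`.
#' @export
networkConfig <- function(kind = c("lstm", "gru", "blstm"),
                          inputWidth = 522L, hiddenWidth = 128L,
                          denseWidth = 64L, dropoutRate = 0.3,
                          epochs = 300L, batchSize = 32L,
                          learningRate = 1e-3, seed = 1L) {
  kind <- match.arg(kind)
  if (any(c(inputWidth, hiddenWidth, denseWidth, epochs, batchSize) < 1L))
    stop("widths, epochs and batch size must be positive")
  if (dropoutRate <= 0 || dropoutRate >= 1)
    stop("dropoutRate must lie strictly in (0, 1), got ", dropoutRate)
  if (learningRate <= 0) stop("learningRate must be positive")
  structure(list(kind = kind, inputWidth = as.integer(inputWidth),
                 hiddenWidth = as.integer(hiddenWidth),
                 denseWidth = as.integer(denseWidth),
                 dropoutRate = dropoutRate, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate, seed = as.integer(seed)),
            class = "networkConfig")
}

#' Default base-network configurations for the stacked ensemble
#'
#' One configuration per kind (LSTM, GRU, BLSTM) with consecutive seeds so
#' the three networks start from different initializations.
#'
#' @inheritParams networkConfig
#' @param ... Passed to [networkConfig()] for every kind.
#' @return Named list of three `networkConfig`s.
#' @export
baseConfigs <- function(epochs = 300L, seed = 1L, ...) {
  list(lstm = networkConfig("lstm", epochs = epochs, seed = seed, ...),
       gru = networkConfig("gru", epochs = epochs, seed = seed + 1L, ...),
       blstm = networkConfig("blstm", epochs = epochs, seed = seed + 2L, ...))
}

.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Build an untrained base network
#'
#' Allocates and initializes (Glorot-uniform, seed-controlled) all
#' parameters of the architecture described in [networkConfig()]. The
#' recurrent layer carries both input and recurrent weight matrices; with a
#' length-1 input sequence the recurrent weights receive no gradient but are
#' part of the declared architecture and parameter count.
#'
#' @param config A [networkConfig()].
#' @return A list of class `"baseNetwork"` with elements `config`, `params`,
#'   `history`, `trained`.
#' @export
buildBase <- function(config) {
  stopifnot(inherits(config, "networkConfig"))
  set.seed(config$seed)
  h <- config$hiddenWidth; d <- config$denseWidth; w <- config$inputWidth
  gates <- switch(config$kind, lstm = 4L, gru = 3L, blstm = 4L)
  recOut <- if (config$kind == "blstm") 2L * h else h
  p <- list(Wp = .glorot(w, h), bp = numeric(h))
  recurrent <- function() list(Wg = .glorot(h, gates * h),
                               Ug = .glorot(h, gates * h),
                               bg = numeric(gates * h))
  if (config$kind == "blstm") {
    rf <- recurrent(); rb <- recurrent()
    p <- c(p, list(Wgf = rf$Wg, Ugf = rf$Ug, bgf = rf$bg,
                   Wgb = rb$Wg, Ugb = rb$Ug, bgb = rb$bg))
  } else {
    r <- recurrent()
    p <- c(p, list(Wg = r$Wg, Ug = r$Ug, bg = r$bg))
  }
  p <- c(p, list(W1 = .glorot(recOut, d), b1 = numeric(d),
                 W2 = .glorot(d, d), b2 = numeric(d),
                 Wo = .glorot(d, 1L), bo = numeric(1L)))
  structure(list(config = config, params = p, history = NULL,
                 trained = FALSE), class = "baseNetwork")
}

#' Total number of parameters of a base network
#'
#' @param model A `"baseNetwork"`.
#' @return Integer parameter count over all weight matrices and biases.
#' @export
countParameters <- function(model) {
  stopifnot(inherits(model, "baseNetwork"))
  sum(vapply(model$params, length, integer(1)))
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# One-timestep LSTM cell (h0 = c0 = 0). Returns h and the cache needed for
# backprop.
.lstmForward <- function(P, Wg, bg) {
  h <- ncol(Wg) / 4L
  A <- P %*% Wg + rep(bg, each = nrow(P))
  i <- .sigmoid(A[, seq_len(h), drop = FALSE])
  g <- tanh(A[, 2L * h + seq_len(h), drop = FALSE])
  o <- .sigmoid(A[, 3L * h + seq_len(h), drop = FALSE])
  cc <- i * g
  tc <- tanh(cc)
  list(h = o * tc, i = i, g = g, o = o, tc = tc)
}

.lstmBackward <- function(dH, cache, P, Wg) {
  h <- ncol(Wg) / 4L
  do <- dH * cache$tc
  dc <- dH * cache$o * (1 - cache$tc ^ 2)
  di <- dc * cache$g
  dg <- dc * cache$i
  dA <- cbind(di * cache$i * (1 - cache$i),
              matrix(0, nrow(dH), h),               # forget gate: c0 = 0
              dg * (1 - cache$g ^ 2),
              do * cache$o * (1 - cache$o))
  list(dWg = crossprod(P, dA), dbg = colSums(dA), dP = dA %*% t(Wg))
}

.gruForward <- function(P, Wg, bg) {
  h <- ncol(Wg) / 3L
  A <- P %*% Wg + rep(bg, each = nrow(P))
  z <- .sigmoid(A[, seq_len(h), drop = FALSE])
  hb <- tanh(A[, 2L * h + seq_len(h), drop = FALSE])
  list(h = (1 - z) * hb, z = z, hb = hb)
}

.gruBackward <- function(dH, cache, P, Wg) {
  h <- ncol(Wg) / 3L
  dz <- -dH * cache$hb
  dhb <- dH * (1 - cache$z)
  dA <- cbind(dz * cache$z * (1 - cache$z),
              matrix(0, nrow(dH), h),               # reset gate: h0 = 0
              dhb * (1 - cache$hb ^ 2))
  list(dWg = crossprod(P, dA), dbg = colSums(dA), dP = dA %*% t(Wg))
}

# Full forward pass. masks = list(m1, m2) of inverted-dropout masks, or NULL
# for inference.
.forwardBase <- function(model, X, masks = NULL) {
  p <- model$params
  P <- X %*% p$Wp + rep(p$bp, each = nrow(X))
  rec <- switch(model$config$kind,
    lstm = .lstmForward(P, p$Wg, p$bg),
    gru = .gruForward(P, p$Wg, p$bg),
    blstm = {
      f <- .lstmForward(P, p$Wgf, p$bgf)
      b <- .lstmForward(P, p$Wgb, p$bgb)
      list(h = cbind(f$h, b$h), f = f, b = b)
    })
  H <- rec$h
  D1p <- H %*% p$W1 + rep(p$b1, each = nrow(X))
  D1 <- pmax(D1p, 0)
  D1d <- if (is.null(masks)) D1 else D1 * masks$m1
  D2p <- D1d %*% p$W2 + rep(p$b2, each = nrow(X))
  D2 <- pmax(D2p, 0)
  D2d <- if (is.null(masks)) D2 else D2 * masks$m2
  Z <- D2d %*% p$Wo + p$bo
  prob <- .sigmoid(Z)
  list(prob = prob, P = P, rec = rec, H = H, D1p = D1p, D1d = D1d,
       D2p = D2p, D2d = D2d)
}

.backwardBase <- function(model, X, y, fw, masks) {
  p <- model$params
  n <- nrow(X)
  dZ <- (fw$prob - y) / n
  g <- list()
  g$Wo <- crossprod(fw$D2d, dZ)
  g$bo <- sum(dZ)
  dD2 <- (dZ %*% t(p$Wo)) * masks$m2
  dD2p <- dD2 * (fw$D2p > 0)
  g$W2 <- crossprod(fw$D1d, dD2p)
  g$b2 <- colSums(dD2p)
  dD1 <- (dD2p %*% t(p$W2)) * masks$m1
  dD1p <- dD1 * (fw$D1p > 0)
  g$W1 <- crossprod(fw$H, dD1p)
  g$b1 <- colSums(dD1p)
  dH <- dD1p %*% t(p$W1)
  h <- model$config$hiddenWidth
  if (model$config$kind == "blstm") {
    bf <- .lstmBackward(dH[, seq_len(h), drop = FALSE], fw$rec$f, fw$P, p$Wgf)
    bb <- .lstmBackward(dH[, h + seq_len(h), drop = FALSE], fw$rec$b, fw$P, p$Wgb)
    g$Wgf <- bf$dWg; g$bgf <- bf$dbg; g$Ugf <- p$Ugf * 0
    g$Wgb <- bb$dWg; g$bgb <- bb$dbg; g$Ugb <- p$Ugb * 0
    dP <- bf$dP + bb$dP
  } else {
    br <- if (model$config$kind == "lstm")
      .lstmBackward(dH, fw$rec, fw$P, p$Wg)
    else .gruBackward(dH, fw$rec, fw$P, p$Wg)
    g$Wg <- br$dWg; g$bg <- br$dbg; g$Ug <- p$Ug * 0
    dP <- br$dP
  }
  g$Wp <- crossprod(X, dP)
  g$bp <- colSums(dP)
  g
}

#' Train a base network
#'
#' Minimizes binary cross-entropy with Adam (beta1 = 0.9, beta2 = 0.999) on
#' shuffled minibatches with inverted dropout. Fully deterministic given the
#' configuration seed. The per-epoch mean minibatch loss and full-training-set
#' accuracy are recorded in `history`.
#'
#' @param model An untrained `"baseNetwork"` from [buildBase()].
#' @param features Numeric matrix, one row per sample, `inputWidth` columns
#'   (standardized by the caller).
#' @param labels Numeric/integer 0-1 vector.
#' @return The trained `"baseNetwork"` with filled `history`.
#' @export
trainBase <- function(model, features, labels) {
  stopifnot(inherits(model, "baseNetwork"))
  cfg <- model$config
  X <- as.matrix(features)
  if (ncol(X) != cfg$inputWidth)
    stop("feature width ", ncol(X), " does not match configured input width ",
         cfg$inputWidth)
  y <- matrix(as.numeric(labels), ncol = 1L)
  if (nrow(X) != nrow(y)) stop("features and labels disagree in length")
  n <- nrow(X)
  set.seed(cfg$seed + 1L)
  adamM <- lapply(model$params, function(x) x * 0)
  adamV <- adamM
  tStep <- 0L
  lr <- cfg$learningRate; b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  keep <- 1 - cfg$dropoutRate
  hist <- data.frame(epoch = seq_len(cfg$epochs), loss = NA_real_,
                     accuracy = NA_real_)
  d <- cfg$denseWidth
  for (e in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    lossSum <- 0
    for (start in seq(1L, n, by = cfg$batchSize)) {
      idx <- perm[start:min(start + cfg$batchSize - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx, , drop = FALSE]
      m <- length(idx)
      masks <- list(m1 = (matrix(stats::runif(m * d), m, d) < keep) / keep,
                    m2 = (matrix(stats::runif(m * d), m, d) < keep) / keep)
      fw <- .forwardBase(model, Xb, masks)
      pr <- pmin(pmax(fw$prob, 1e-12), 1 - 1e-12)
      lossSum <- lossSum + sum(-(yb * log(pr) + (1 - yb) * log(1 - pr)))
      grads <- .backwardBase(model, Xb, yb, fw, masks)
      tStep <- tStep + 1L
      for (nm in names(grads)) {
        gmat <- grads[[nm]]
        adamM[[nm]] <- b1 * adamM[[nm]] + (1 - b1) * gmat
        adamV[[nm]] <- b2 * adamV[[nm]] + (1 - b2) * gmat ^ 2
        mh <- adamM[[nm]] / (1 - b1 ^ tStep)
        vh <- adamV[[nm]] / (1 - b2 ^ tStep)
        model$params[[nm]] <- model$params[[nm]] - lr * mh / (sqrt(vh) + eps)
      }
    }
    epochLoss <- lossSum / n
    if (!is.finite(epochLoss))
      stop("training diverged (non-finite loss) at epoch ", e)
    hist$loss[e] <- epochLoss
    pAll <- .forwardBase(model, X)$prob
    hist$accuracy[e] <- mean((pAll >= 0.5) == (y == 1))
  }
  model$history <- hist
  model$trained <- TRUE
  model
}

#' Predict probabilities from a trained base network
#'
#' @param model A trained `"baseNetwork"`.
#' @param features Numeric matrix with `inputWidth` columns.
#' @return Numeric vector of sigmoid probabilities in `[0, 1]`, one per row.
#' @export
predictProba <- function(model, features) {
  stopifnot(inherits(model, "baseNetwork"))
  X <- as.matrix(features)
  if (ncol(X) != model$config$inputWidth)
    stop("feature width ", ncol(X), " does not match configured input width ",
         model$config$inputWidth)
  as.numeric(.forwardBase(model, X)$prob)
}

#' @export
print.baseNetwork <- function(x, ...) {
  cat(sprintf("baseNetwork <%s>: %d -> %d (recurrent) -> %d -> %d -> 1, %s\n",
              x$config$kind, x$config$inputWidth, x$config$hiddenWidth,
              x$config$denseWidth, x$config$denseWidth,
              if (x$trained) sprintf("trained %d epochs", nrow(x$history))
              else "untrained"))
  invisible(x)
}
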