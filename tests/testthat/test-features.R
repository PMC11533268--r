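test_that("k-mer encoding follows the base-4 A/C/G/T code", {
  expect_identical(encodeKmers("ACGT", 1), c(0L, 1L, 2L, 3L))
  expect_identical(encodeKmers("AA", 2), 0L)
  expect_identical(encodeKmers("ACGT", 2), c(1L, 6L, 11L))
  expect_identical(encodeKmers("ACGT", 3), c(6L, 27L))
  expect_error(encodeKmers("AC", 3), "shorter than k")
  expect_error(encodeKmers("ACGN", 1), "outside A/C/G/T")
})

test_that("sequence matrix obeys the minimum-side and padding rules", {
  expect_equal(dim(sequenceMatrix(0:15)), c(4L, 4L))
  expect_equal(sum(sequenceMatrix(rep(1, 5)) == 0), 11)
  m17 <- sequenceMatrix(rep(2, 17))
  expect_equal(dim(m17), c(5L, 5L))
  expect_equal(sum(m17 == 0), 8)
  # row-major fill
  m <- sequenceMatrix(c(7, 8, 9, 10, 11))
  expect_equal(m[1, ], c(7, 8, 9, 10))
  expect_equal(m[2, 1], 11)
  expect_error(sequenceMatrix(integer(0)), "zero codes")
})

test_that("raw, central and Hahn moments match the brute-force double-sum oracle", {
  expect_equal(unname(rawMoments(matrix(1:4, 2, byrow = TRUE))["raw.00"]), 10)
  expect_equal(unname(rawMoments(matrix(1:4, 2, byrow = TRUE))["raw.10"]), 17)
  expect_equal(unname(rawMoments(matrix(0, 3, 3))), rep(0, 10))
  set.seed(20)
  for (rep in 1:12) {
    N <- sample(4:8, 1)
    m <- matrix(runif(N * N, 0, 50), N, N)
    u <- sample(0:2, 1); v <- sample(0:2, 1)
    raw <- rawMoments(m); cen <- centralMoments(m); hah <- hahnMoments(m, u, v)
    for (i in seq_len(nrow(orderPairs))) {
      a <- orderPairs[i, 1]; b <- orderPairs[i, 2]
      expect_equal(unname(raw[i]), bruteRawMoment(m, a, b),
                   tolerance = 1e-9)
      expect_equal(unname(cen[i]), bruteCentralMoment(m, a, b),
                   tolerance = 1e-9)
      expect_equal(unname(hah[i]), bruteHahnMoment(m, a, b, u, v),
                   tolerance = 1e-9)
    }
  }
})

test_that("central moments vanish at first order and handle the zero matrix", {
  set.seed(21)
  for (rep in 1:20) {
    N <- sample(4:8, 1)
    m <- matrix(rpois(N * N, 5), N, N)
    cen <- centralMoments(m)
    tol <- 1e-9 * max(1, abs(cen["central.00"]))
    expect_lt(abs(cen["central.01"]), tol)
    expect_lt(abs(cen["central.10"]), tol)
    expect_identical(unname(cen["central.00"]),
                     unname(rawMoments(m)["raw.00"]))
  }
  # constant mass: every moment with an odd index vanishes by symmetry
  constant <- matrix(3, 4, 4)
  cm <- centralMoments(constant)
  odd <- c("central.01", "central.10", "central.11", "central.12",
           "central.21", "central.03", "central.30")
  expect_equal(unname(as.numeric(cm[odd])), rep(0, 7))
  expect_gt(cm[["central.20"]], 0)
  z <- centralMoments(matrix(0, 4, 4))
  expect_true(attr(z, "degenerate"))
  expect_equal(as.numeric(z), rep(0, 10))
})

test_that("Hahn polynomials reproduce exact-rational reference values", {
  # frozen from an exact-rational evaluation of the same finite sum
  expect_equal(hahnPolynomial(1, 0:3, 4), c(9, 3, -3, -9))
  expect_equal(hahnPolynomial(2, 0:7, 8, 1, 1),
               c(4032, 1872, 192, -1008, -1728, -1968, -1728, -1008))
  expect_equal(hahnPolynomial(3, 0:5, 6, 2, 0),
               c(44100, -8820, -29400, -25560, -5220, 23700))
  expect_equal(hahnPolynomial(0, 0:5, 6, 1, 2), rep(1, 6))
  expect_error(hahnPolynomial(4, 0, 4), "degree")
  # H of the all-ones 4x4 grid, frozen from the same exact evaluation
  H1 <- hahnMoments(matrix(1, 4, 4))
  expect_equal(unname(H1[c("hahn.00", "hahn.02", "hahn.20", "hahn.03", "hahn.30")]),
               c(16, -576, -576, -12480, -12480))
  expect_equal(unname(H1[c("hahn.01", "hahn.10", "hahn.11", "hahn.12", "hahn.21")]),
               rep(0, 5), tolerance = 1e-9)
  # H_00 equals the grand sum under u = v = 0
  set.seed(22)
  m <- matrix(runif(36), 6, 6)
  expect_equal(unname(hahnMoments(m)["hahn.00"]), sum(m), tolerance = 1e-12)
  expect_equal(unname(hahnMoments(matrix(0, 5, 5))), rep(0, 10))
})

test_that("PRIM accumulates forward offsets from first occurrences", {
  p <- prim(encodeKmers("ACGT", 1), 4)
  expect_equal(p[1, 3], 2)  # A -> G: position 3 - first A at 1
  expect_equal(p[2, 1], 0)  # first A precedes first C
  expect_equal(prim(encodeKmers("AAAA", 1), 4)[1, 1], 6)
  expect_equal(sum(prim(encodeKmers("AAAA", 1), 4)), 6)
  # absent symbol rows are identically zero
  p2 <- prim(encodeKmers("AACC", 1), 4)
  expect_equal(p2[3, ], rep(0, 4))
  expect_equal(p2[4, ], rep(0, 4))
  # rprim is prim of the reversed list
  expect_equal(rprim(encodeKmers("ACGT", 1), 4), prim(encodeKmers("TGCA", 1), 4))
  expect_equal(rprim(encodeKmers("AAC", 1), 4)[2, 1], 3)  # reversed "CAA"
  pal <- c(0L, 1L, 1L, 0L)
  expect_equal(rprim(pal, 4), prim(pal, 4))
})

test_that("PRIM and RPRIM match a direct-scan oracle with nonneg integer entries", {
  set.seed(23)
  for (k in 1:2) {
    K <- 4L^k
    for (rep in 1:5) {
      codes <- encodeKmers(randomSeq(sample(20:60, 1)), k)
      M <- prim(codes, K)
      expect_equal(M, brutePrim(codes, K))
      expect_true(all(M >= 0))
      expect_equal(M, round(M))
      expect_equal(rprim(codes, K), brutePrim(rev(codes), K))
    }
  }
})

test_that("frequency vectors and AAPIVs obey their conservation laws", {
  expect_equal(frequencyVector(encodeKmers("ACGT", 1), 4), rep(1L, 4))
  expect_equal(frequencyVector(encodeKmers("AACG", 1), 4), c(2L, 1L, 1L, 0L))
  expect_equal(aapiv(encodeKmers("AAAA", 1), 4), c(10, 0, 0, 0))
  expect_equal(aapiv(encodeKmers("ACGT", 1), 4), c(1, 2, 3, 4))
  expect_equal(aapiv(encodeKmers("ACGT", 1), 4, "reverse"), c(4, 3, 2, 1))
  set.seed(24)
  for (k in 1:3) {
    K <- 4L^k
    for (rep in 1:8) {
      L <- sample(25:80, 1)
      s <- randomSeq(L)
      codes <- encodeKmers(s, k)
      Lp <- L - k + 1
      expect_equal(sum(frequencyVector(codes, K)), Lp)
      fwd <- aapiv(codes, K)
      expect_equal(sum(fwd), Lp * (Lp + 1) / 2)
      expect_equal(sum(aapiv(codes, K, "reverse")), Lp * (Lp + 1) / 2)
      expect_equal(fwd, bruteAapiv(codes, K))
      expect_equal(aapiv(codes, K, "reverse"), bruteAapiv(rev(codes), K))
      # zero iff absent
      expect_identical(fwd == 0, frequencyVector(codes, K) == 0L)
    }
  }
})

test_that("the full descriptor has 522 components in the documented layout", {
  layout <- featureLayout()
  expect_equal(nrow(layout), 522L)
  expect_equal(layout$offset, seq_len(522L))
  blockLens <- table(layout$block)
  expect_equal(unname(blockLens[c("fv", "aapiv", "raapiv")]),
               rep(4L + 16L + 64L, 3), ignore_attr = TRUE)
  expect_equal(unname(blockLens[c("seqmat", "prim", "rprim")]),
               rep(90L, 3), ignore_attr = TRUE)

  s <- "ACGTACGTACGTACGTAC"
  f <- extractFeatures(s)
  expect_length(f, 522L)
  expect_true(all(is.finite(f)))
  expect_identical(f, extractFeatures(s))
  expect_equal(unname(f[layout$block == "fv" & layout$k == 1]), c(5, 5, 4, 4))
  # blocks line up with the standalone operations
  codes2 <- encodeKmers(s, 2)
  expect_equal(unname(f[layout$block == "aapiv" & layout$k == 2]),
               aapiv(codes2, 16))
  expect_equal(unname(f[layout$block == "prim" & layout$k == 2]),
               unname(momentSet <- c(rawMoments(prim(codes2, 16)),
                                     as.numeric(centralMoments(prim(codes2, 16))),
                                     hahnMoments(prim(codes2, 16)))))
  expect_error(extractFeatures("ACGTACGTACGTACGTA"), "18")
})

test_that("featurize produces a SummarizedExperiment with layout and labels", {
  cfg <- syntheticConfig(nGenes = 2L, lengthRange = c(30L, 40L),
                         nMutations = 3L, seed = 8L)
  corpus <- generateLabeledCorpus(cfg)
  se <- featurize(corpus, hahnU = 1, hahnV = 1)
  expect_s4_class(se, "SummarizedExperiment")
  expect_equal(dim(se), c(522L, 6L))
  expect_equal(SummarizedExperiment::rowData(se)$name, featureLayout()$name)
  expect_equal(SummarizedExperiment::colData(se)$label, corpusLabels(corpus))
  expect_equal(S4Vectors::metadata(se)$hahnU, 1)
  # per-column features equal direct extraction with the same Hahn params
  expect_equal(unname(SummarizedExperiment::assay(se)[, 3]),
               unname(extractFeatures(as.character(corpusSequences(corpus)[[3]]),
                                      hahnU = 1, hahnV = 1)))
})
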