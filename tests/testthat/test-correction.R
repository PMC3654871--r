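# Peer windows and the empirical significance correction.

test_that("percentiles are mid-rank, tie-sharing and monotone in level", {
  idx <- annotationIndex(c(a = 5, b = 5, c = 10, d = 20))
  pct <- annotationPercentiles(idx)
  expect_identical(unname(pct["a"]), unname(pct["b"]))
  o <- order(annotationLevels(idx))
  expect_false(is.unsorted(pct[o]))
  # mid-rank: 4 entities -> percentiles from (rank - .5)/4
  expect_equal(unname(pct["d"]), 100 * (4 - 0.5) / 4)
  expect_equal(unname(pct["c"]), 100 * (3 - 0.5) / 4)
})

test_that("peer windows truncate at the boundary and include the query", {
  # total ties: the peer set is the whole class
  idx <- annotationIndex(stats::setNames(rep(7, 9), paste0("e", 1:9)))
  expect_setequal(peerSet(idx, "e4", 5), paste0("e", 1:9))

  # 100 distinct levels: +/-5 percentile window at the median holds 11 peers
  idx2 <- annotationIndex(stats::setNames(1:100, sprintf("x%03d", 1:100)))
  med <- peerSet(idx2, "x050", 5)
  # brute-force percentile scan
  pct <- 100 * (seq_len(100) - 0.5) / 100
  expect_setequal(med, sprintf("x%03d", which(abs(pct - pct[50]) <= 5)))
  expect_length(med, 11)

  # bottom entity: window truncates below 0; peers are the bottom block
  bot <- peerSet(idx2, "x001", 5)
  expect_setequal(bot, sprintf("x%03d", which(pct <= pct[1] + 5)))
  expect_length(bot, 6)
  expect_true("x001" %in% bot)

  expect_error(peerSet(idx2, "nope"), "unknown entity")
  expect_error(peerSet(idx2, "x001", 0), "halfWidth")
})

.scoreMat <- function(v, metric = "cosine_p") {
  methods::new("ScoreMatrix", metric = metricSpec(metric), values = v)
}

test_that("corrected scores count strictly-more-extreme peers with smoothing", {
  # pool {1..5} under higher-is-similar, query score 3 -> (1+2)/6
  v <- matrix(1:5 * 1.0, 1, 5,
              dimnames = list("c1", paste0("d", 1:5)))
  idxC <- annotationIndex(c(c1 = 3))
  idxD <- annotationIndex(stats::setNames(rep(2, 5), paste0("d", 1:5)))
  sm <- .scoreMat(v)
  expect_equal(correctedScore(sm, idxC, idxD, "c1", "d3", 50), 0.5)
  # most extreme score in the pool
  expect_equal(correctedScore(sm, idxC, idxD, "c1", "d5", 50), 1 / 6)
  # all pool scores identical: nothing strictly more extreme
  sm2 <- .scoreMat(matrix(2, 1, 5, dimnames = dimnames(v)))
  expect_equal(correctedScore(sm2, idxC, idxD, "c1", "d2", 50), 1 / 6)
  # 1x1 degenerate pool
  sm3 <- .scoreMat(matrix(4, 1, 1, dimnames = list("c1", "d1")))
  idx1 <- annotationIndex(c(d1 = 1))
  expect_equal(correctedScore(sm3, idxC, idx1, "c1", "d1", 5), 0.5)
})

test_that("lower-is-similar metrics count in the reversed direction", {
  v <- matrix(1:5 * 1.0, 1, 5, dimnames = list("c1", paste0("d", 1:5)))
  idxC <- annotationIndex(c(c1 = 3))
  idxD <- annotationIndex(stats::setNames(rep(2, 5), paste0("d", 1:5)))
  sm <- .scoreMat(v, metric = "l2_p_all")
  # score 1 is now the most extreme (most similar)
  expect_equal(correctedScore(sm, idxC, idxD, "c1", "d1", 50), 1 / 6)
  expect_equal(correctedScore(sm, idxC, idxD, "c1", "d5", 50), 5 / 6)
})

test_that("the matrix form matches the elementwise form and permutes with axes", {
  set.seed(11)
  n <- 12
  v <- matrix(rnorm(n * n), n, n,
              dimnames = list(sprintf("c%02d", 1:n), sprintf("d%02d", 1:n)))
  lvC <- stats::setNames(sample(5:40, n, TRUE), rownames(v))
  lvD <- stats::setNames(sample(5:40, n, TRUE), colnames(v))
  sm <- .scoreMat(v)
  cm <- correctedMatrix(sm, annotationIndex(lvC), annotationIndex(lvD), 10)
  for (i in c(1, 5, 12)) for (j in c(2, 7))
    expect_equal(scoreValues(cm)[i, j],
                 correctedScore(sm, annotationIndex(lvC), annotationIndex(lvD),
                                rownames(v)[i], colnames(v)[j], 10))
  # permuting drug rows permutes the corrected rows identically
  perm <- sample(n)
  smP <- .scoreMat(v[perm, ])
  cmP <- correctedMatrix(smP, annotationIndex(lvC[perm]),
                         annotationIndex(lvD), 10)
  expect_equal(scoreValues(cmP), scoreValues(cm)[perm, ])
})

test_that("the correction agrees exactly with the double-loop oracle", {
  set.seed(23)
  for (rep in 1:3) {
    nC <- sample(20:40, 1); nD <- sample(20:40, 1)
    v <- matrix(rnorm(nC * nD), nC, nD,
                dimnames = list(sprintf("c%02d", 1:nC), sprintf("d%02d", 1:nD)))
    lvC <- stats::setNames(sample(1:30, nC, TRUE), rownames(v))
    lvD <- stats::setNames(sample(1:30, nD, TRUE), colnames(v))
    cm <- correctedMatrix(.scoreMat(v), annotationIndex(lvC),
                          annotationIndex(lvD), 5)
    expect_identical(scoreValues(cm), naiveCorrected(v, lvC, lvD, 5))
  }
})

test_that("corrected values are non-increasing in raw-score extremeness", {
  set.seed(31)
  n <- 15
  v <- matrix(sample(1:50, n * n, TRUE) * 1.0, n, n,
              dimnames = list(sprintf("c%02d", 1:n), sprintf("d%02d", 1:n)))
  # one shared annotation level: every pair shares one pool
  idx <- annotationIndex(stats::setNames(rep(3, n), rownames(v)))
  idxD <- annotationIndex(stats::setNames(rep(3, n), colnames(v)))
  cm <- correctedMatrix(.scoreMat(v), idx, idxD, 5)
  o <- order(as.vector(v))
  expect_false(is.unsorted(rev(as.vector(scoreValues(cm))[o])))
})

test_that("null scores give approximately uniform corrected values", {
  set.seed(41)
  n <- 80
  v <- matrix(rnorm(n * n), n, n,
              dimnames = list(sprintf("c%02d", 1:n), sprintf("d%02d", 1:n)))
  lvC <- stats::setNames(sample(1:500, n), rownames(v))
  lvD <- stats::setNames(sample(1:500, n), colnames(v))
  cm <- correctedMatrix(.scoreMat(v), annotationIndex(lvC),
                        annotationIndex(lvD), 10)
  u <- as.vector(scoreValues(cm))
  expect_gt(min(u), 0); expect_lte(max(u), 1)
  expect_lt(abs(mean(u) - 0.5), 0.03)
})

test_that("a level-driven score gradient is flattened by the correction", {
  set.seed(43)
  n <- 80
  lvC <- stats::setNames(sample(5:300, n), sprintf("c%02d", 1:n))
  lvD <- stats::setNames(sample(5:300, n), sprintf("d%02d", 1:n))
  v <- outer(rep(1, n), lvD * 0.05) + matrix(rnorm(n * n, sd = 2), n, n)
  dimnames(v) <- list(names(lvC), names(lvD))
  sm <- .scoreMat(v)
  idxC <- annotationIndex(lvC); idxD <- annotationIndex(lvD)
  rRaw <- annotationCorrelation(sm, idxD, "disease")
  cm <- correctedMatrix(sm, idxC, idxD, 5)
  rCor <- annotationCorrelation(cm, idxD, "disease")
  expect_gt(abs(rRaw), 0.5)
  expect_lt(abs(rCor), 0.1)
})

test_that("corrected matrices serialize with raw scores and pool sizes", {
  set.seed(53)
  v <- matrix(rnorm(16), 4, 4,
              dimnames = list(paste0("c", 1:4), paste0("d", 1:4)))
  idx <- annotationIndex(stats::setNames(1:4, rownames(v)))
  idxD <- annotationIndex(stats::setNames(1:4, colnames(v)))
  cm <- correctedMatrix(.scoreMat(v), idx, idxD, 30)
  f <- tempfile()
  writeCorrected(cm, f)
  df <- utils::read.delim(f)
  expect_identical(nrow(df), 16L)
  expect_true(all(c("raw_score", "corrected_score", "n_pool") %in% names(df)))
  expect_equal(sort(df$corrected_score), sort(as.vector(scoreValues(cm))),
               tolerance = 1e-12)
})
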