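# Temporal / reference labels, ROC AUC, and the bias audit.

# Fixture: 3 drugs x 4 diseases; defining terms are leaves of a small tree.
.valFixture <- function() {
  tree <- loadTermTree(writeTempTree(c(
    "C1\tA01", "C2\tA02", "C3\tA03",
    "Z1\tB01", "Z2\tB02", "Z3\tB03", "Z4\tB04", "Z4a\tB04.100")))
  ents <- entitySet(data.frame(
    entity_id = c("c1", "c2", "c3", "z1", "z2", "z3", "z4"),
    class = c("drug", "drug", "drug", "disease", "disease", "disease", "disease"),
    defining_term = c("C1", "C2", "C3", "Z1", "Z2", "Z3", "Z4")), tree)
  # pre-cutoff co-annotations: (c1,z1), (c1,z2), (c2,z1); novel post-cutoff:
  # (c2,z2), (c3,z3); (c3,z4) via a descendant term of Z4
  corpus <- loadCorpus(writeTempCorpus(list(
    list(article_id = "p1", year = 2004L, terms = c("C1", "Z1")),
    list(article_id = "p2", year = 2005L, terms = c("C1", "Z2")),
    list(article_id = "p3", year = 2006L, terms = c("C2", "Z1")),
    list(article_id = "p4", year = 2009L, terms = c("C1", "Z1")),
    list(article_id = "f1", year = 2008L, terms = c("C2", "Z2")),
    list(article_id = "f2", year = 2010L, terms = c("C3", "Z3")),
    list(article_id = "f3", year = 2010L, terms = c("C3", "Z4a")),
    list(article_id = "x1", year = 2003L, terms = "C3"))), tree)
  list(tree = tree, ents = ents, corpus = corpus)
}

test_that("co-annotated pairs are detected on propagated terms", {
  fx <- .valFixture()
  pre <- cooccurringPairs(fx$corpus, fx$ents, yearMax = 2007)
  expect_identical(nrow(pre), 3L)
  expect_setequal(paste(pre$drug_id, pre$disease_id),
                  c("c1 z1", "c1 z2", "c2 z1"))
  all <- cooccurringPairs(fx$corpus, fx$ents)
  expect_identical(nrow(all), 6L)
  # descendant annotation counts as the disease term (pair c3/z4 via Z4a)
  expect_true("c3 z4" %in% paste(all$drug_id, all$disease_id))
  # a corpus without co-annotation yields no pairs
  lone <- loadCorpus(writeTempCorpus(list(
    list(article_id = "s1", year = 2001L, terms = "C1"))), fx$tree)
  expect_identical(nrow(cooccurringPairs(lone, fx$ents)), 0L)
})

test_that("temporal labels partition pairs into excluded/positive/negative", {
  fx <- .valFixture()
  ls <- temporalLabels(fx$corpus, fx$ents, 2007)
  lm <- labelMatrix(ls)
  # pre-cutoff pairs are excluded even when they also co-occur later (c1,z1)
  expect_identical(unname(lm["c1", "z1"]), "excluded")
  expect_identical(unname(lm["c1", "z2"]), "excluded")
  expect_identical(unname(lm["c2", "z1"]), "excluded")
  # first co-occurrence after the cutoff is positive
  expect_identical(unname(lm["c2", "z2"]), "positive")
  expect_identical(unname(lm["c3", "z3"]), "positive")
  expect_identical(unname(lm["c3", "z4"]), "positive")
  # hand-enumerated partition of the 12 pairs
  expect_identical(as.vector(table(factor(lm))[c("excluded", "positive", "negative")]),
                   c(3L, 3L, 6L))
  # every pair has exactly one label
  expect_identical(length(lm), 12L)
  # no post-cutoff article -> labeling error
  pre <- filterCorpus(fx$corpus, 2007)
  expect_error(temporalLabels(pre, fx$ents, 2007), "no article after")
})

test_that("reference labels resolve, skip, and yield to pre-cutoff exclusion", {
  fx <- .valFixture()
  f <- tempfile()
  writeLines(c("drug_id\tdisease_id", "c2\tz2", "c3\tz3", "c1\tz1",
               "ghost\tz1", "c2\tz4"), f)
  ls <- referenceLabels(f, fx$ents, fx$corpus, 2007)
  lm <- labelMatrix(ls)
  expect_identical(unname(lm["c2", "z2"]), "positive")
  expect_identical(unname(lm["c3", "z3"]), "positive")
  expect_identical(unname(lm["c2", "z4"]), "positive")
  # listed but co-annotated pre-cutoff: exclusion wins
  expect_identical(unname(lm["c1", "z1"]), "excluded")
  expect_identical(labelReport(ls)$n_unresolvable, 1L)
  # header is optional
  f2 <- tempfile(); writeLines("c2\tz2", f2)
  expect_identical(unname(labelMatrix(
    referenceLabels(f2, fx$ents, fx$corpus, 2007))["c2", "z2"]), "positive")
  # degenerate files
  f3 <- tempfile(); writeLines(character(0), f3)
  expect_error(referenceLabels(f3, fx$ents, fx$corpus, 2007), "empty")
  f4 <- tempfile(); writeLines("ghost\tzz", f4)
  expect_error(referenceLabels(f4, fx$ents, fx$corpus, 2007), "no reference pair")
})

test_that("rank-sum AUC handles separation, ties and pair counting", {
  expect_identical(rocAuc(c(5, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_identical(rocAuc(rep(2, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  # pos {3, 1}, neg {2, 0}: 3 of 4 pos-neg pairs concordant
  expect_identical(rocAuc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_error(rocAuc(1:3, c(TRUE, TRUE, TRUE)), "positive and.*negative")
  # exhaustive concordant-pair oracle, tie-heavy random sets
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(10:200, 1)
    x <- sample(0:12, n, TRUE) * 1.0
    pos <- seq_len(n) %in% sample(n, sample(2:(n - 2), 1))
    expect_equal(rocAuc(x, pos), naiveAuc(x, pos), tolerance = 1e-12)
  }
})

test_that("AUC is rank-invariant and flips with polarity", {
  set.seed(19)
  x <- rnorm(100); pos <- rep(c(TRUE, FALSE), 50)
  a <- rocAuc(x, pos)
  expect_equal(rocAuc(exp(2 * x) + 5, pos), a, tolerance = 1e-12)
  v <- matrix(x, 10, 10, dimnames = list(paste0("c", 1:10), paste0("d", 1:10)))
  lm <- matrix(ifelse(pos, "positive", "negative"), 10, 10,
               dimnames = dimnames(v))
  ls <- methods::new("LabelSet", labels = lm, provenance = "future-cooccurrence",
                     report = list())
  smH <- methods::new("ScoreMatrix", metric = metricSpec("cosine_p"), values = v)
  expect_equal(rocAuc(smH, ls), a, tolerance = 1e-12)
  expect_equal(rocAuc(smH, ls, polarity = "lower-is-similar"), 1 - a,
               tolerance = 1e-12)
  expect_equal(rocAuc(smH, ls, polarity = "lower-is-similar", autoOrient = TRUE),
               max(a, 1 - a), tolerance = 1e-12)
})

test_that("random scores give AUC near one half", {
  set.seed(29)
  aucs <- replicate(50, rocAuc(stats::runif(400),
                               seq_len(400) %in% sample(400, 40)))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("the panel reduces to rocAuc and is shift-invariant", {
  res <- benchmarkPipeline(simConfig(nTerms = 200L, nDrugs = 15L,
                                     nDiseases = 15L, nTopics = 10L,
                                     termsPerTopic = 8L, logMu = 1.6,
                                     seed = 71L),
                           metrics = c("l2_logp_overlap", "n_disease_terms"))
  sm <- scoreMatrix("l2_logp_overlap", res$drugProfiles, res$diseaseProfiles)
  expect_equal(res$panel$auc[res$panel$metric_id == "l2_logp_overlap"],
               rocAuc(sm, res$labels), tolerance = 1e-12)
  # rank invariance: adding a constant cannot change the AUC
  sm2 <- sm; sm2@values <- sm@values + 100
  expect_equal(rocAuc(sm2, res$labels), rocAuc(sm, res$labels),
               tolerance = 1e-12)
  # corrected variant appears when requested
  panel2 <- metricPanelAuc(res$drugProfiles, res$diseaseProfiles, res$labels,
                           metrics = "l2_logp_overlap", withCorrection = TRUE)
  expect_true("corrected_l2_logp_overlap" %in% panel2$metric_id)
  expect_true(all(panel2$auc >= 0 & panel2$auc <= 1))
})

test_that("annotation correlation matches the textbook formula and errors cleanly", {
  set.seed(37)
  n <- 20
  v <- matrix(rnorm(n * n), n, n,
              dimnames = list(sprintf("c%02d", 1:n), sprintf("d%02d", 1:n)))
  lv <- stats::setNames(sample(3:80, n), colnames(v))
  sm <- methods::new("ScoreMatrix", metric = metricSpec("cosine_p"), values = v)
  idx <- annotationIndex(lv)
  r <- annotationCorrelation(sm, idx, "disease")
  # direct Pearson formula
  x <- as.vector(v); y <- as.vector(matrix(lv, n, n, byrow = TRUE))
  rOracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r, rOracle, tolerance = 1e-12)
  # scores equal to the disease level correlate perfectly
  smLv <- methods::new("ScoreMatrix", metric = metricSpec("cosine_p"),
                       values = matrix(lv, n, n, byrow = TRUE,
                                       dimnames = dimnames(v)))
  expect_equal(annotationCorrelation(smLv, idx, "disease"), 1, tolerance = 1e-12)
  # degenerate inputs
  smConst <- methods::new("ScoreMatrix", metric = metricSpec("cosine_p"),
                          values = matrix(1, n, n, dimnames = dimnames(v)))
  expect_error(annotationCorrelation(smConst, idx, "disease"), "zero variance")
  idxFlat <- annotationIndex(stats::setNames(rep(4, n), colnames(v)))
  expect_error(annotationCorrelation(sm, idxFlat, "disease"), "distinct")
})
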