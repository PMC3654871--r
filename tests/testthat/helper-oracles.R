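# Independent oracles and fixture builders shared across tests. Each oracle
# is a deliberately naive reimplementation (loops, exhaustive enumeration)
# kept separate from the package's code paths.

# --- fixtures -------------------------------------------------------------

writeTempTree <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

writeTempCorpus <- function(records) {
  f <- tempfile(fileext = ".jsonl")
  lines <- vapply(records, function(r)
    as.character(jsonlite::toJSON(list(
      article_id = jsonlite::unbox(r$article_id),
      year = jsonlite::unbox(r$year),
      terms = r$terms))), character(1))
  writeLines(lines, f)
  f
}

# chain tree X > Y > Z plus an off-branch W
chainTree <- function() {
  loadTermTree(writeTempTree(c("X\tA01", "Y\tA01.200", "Z\tA01.200.300",
                               "W\tB01")))
}

# corpus of 3 articles annotated {Z}, {Y}, {X} on the chain tree
chainCorpus <- function(tree = chainTree()) {
  loadCorpus(writeTempCorpus(list(
    list(article_id = "a1", year = 2001L, terms = "Z"),
    list(article_id = "a2", year = 2003L, terms = "Y"),
    list(article_id = "a3", year = 2005L, terms = "X"))), tree)
}

# hand-constructed profile; defaults give internally consistent fractions
makeProfile <- function(id, terms, count, n, p, w = NULL, f = NULL,
                        defining = terms[[1L]], kind = "universal") {
  f <- f %||% (count / n)
  w <- w %||% (f * 1.5)
  ord <- order(p, terms)
  methods::new("MeSHOP", entityId = id, definingTerm = defining,
               nArticles = as.integer(n),
               entries = data.frame(term = terms[ord], count = count[ord],
                                    fraction = f[ord], p_value = p[ord],
                                    weight = w[ord], stringsAsFactors = FALSE),
               backgroundKind = kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random small profile drawing from a shared term pool (RNG state is the
# caller's responsibility)
randomProfile <- function(id, pool = sprintf("t%02d", 1:25)) {
  n <- sample(3:20, 1)
  nt <- sample(3:12, 1)
  terms <- sample(pool, nt)
  count <- sample.int(n, nt, replace = TRUE)
  p <- pmax(stats::runif(nt)^4, 1e-12)
  makeProfile(id, terms, count, n, p, w = (count / n) * stats::runif(nt, 0, 5))
}

# --- oracle: exhaustive hypergeometric upper tail -------------------------

bruteHyperTail <- function(k, n, K, N) {
  js <- k:n
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

# --- oracle: naive per-formula metric recomputation -----------------------

naiveScorePair <- function(metricId, pc, pd) {
  ec <- profileEntries(pc); ed <- profileEntries(pd)
  look <- function(df, term, col, default) {
    i <- which(df$term == term)
    if (length(i)) df[[col]][[i]] else default
  }
  C <- ec$term; D <- ed$term
  U <- union(C, D); I <- intersect(C, D)
  cosine <- function(col, default) {
    num <- na <- nb <- 0
    for (t in U) {
      a <- look(ec, t, col, default); b <- look(ed, t, col, default)
      num <- num + a * b; na <- na + a^2; nb <- nb + b^2
    }
    if (na == 0 || nb == 0) 0 else num / (sqrt(na) * sqrt(nb))
  }
  l2 <- function(col, default, terms, logged = FALSE) {
    s <- 0
    for (t in terms) {
      a <- look(ec, t, col, default); b <- look(ed, t, col, default)
      if (logged) { a <- log(a); b <- log(b) }
      s <- s + (a - b)^2
    }
    sqrt(s)
  }
  switch(metricId,
    cosine_tfidf = cosine("weight", 0),
    cosine_p = cosine("p_value", 1),
    cosine_fraction = cosine("fraction", 0),
    sum_log_combined_p = {
      s <- 0
      for (t in U) {
        a <- look(ec, t, "p_value", 1); b <- look(ed, t, "p_value", 1)
        s <- s + log(a + b - a * b)
      }
      s
    },
    sum_diff_log_p = {
      s <- 0
      for (t in U)
        s <- s + log(look(ec, t, "p_value", 1)) - log(look(ed, t, "p_value", 1))
      s
    },
    l2_logp_overlap = l2("p_value", 1, I, logged = TRUE),
    l2_fraction_overlap = l2("fraction", 0, I),
    l2_logp_all = l2("p_value", 1, U, logged = TRUE),
    l2_p_all = l2("p_value", 1, U),
    l2_fraction_all = l2("fraction", 0, U),
    l2_freq_all = l2("count", 0, U),
    term_coverage = length(U),
    total_terms = length(C) + length(D),
    term_overlap = length(I),
    n_drug_terms = length(C),
    n_disease_terms = length(D),
    stop("unknown metric in oracle: ", metricId))
}

# --- oracle: exhaustive concordant-pair AUC -------------------------------

naiveAuc <- function(scores, positive) {
  xp <- scores[positive]; xn <- scores[!positive]
  cmp <- outer(xp, xn, `>`) + 0.5 * outer(xp, xn, `==`)
  sum(cmp) / (length(xp) * length(xn))
}

# --- oracle: double-loop peer-window correction ---------------------------

naiveCorrected <- function(raw, levelsDrug, levelsDisease, halfWidth,
                           higherIsSimilar = TRUE) {
  or <- if (higherIsSimilar) raw else -raw
  pc <- 100 * (rank(levelsDrug, ties.method = "average") - 0.5) / length(levelsDrug)
  pd <- 100 * (rank(levelsDisease, ties.method = "average") - 0.5) / length(levelsDisease)
  out <- raw * 0
  for (i in seq_along(levelsDrug)) {
    pi <- which(pc >= max(0, pc[i] - halfWidth) & pc <= min(100, pc[i] + halfWidth))
    for (j in seq_along(levelsDisease)) {
      pj <- which(pd >= max(0, pd[j] - halfWidth) & pd <= min(100, pd[j] + halfWidth))
      pool <- or[pi, pj]
      out[i, j] <- (1 + sum(pool > or[i, j])) / (1 + length(pool))
    }
  }
  out
}
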