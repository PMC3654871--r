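# Synthetic corpus generator with known ground truth. It emulates the
# statistical structure the method depends on: a term hierarchy, entities
# defined by leaf terms, latent topics driving per-article annotations,
# heavy-tailed (log-normal) per-entity publication counts, planted
# drug-disease links at the *topic* level (so profile similarity is an
# emergent signal, not a tautology), and a tunable coupling between link
# placement and publication volume (the annotation-bias confound).

#' Construct a simulation configuration
#'
#' Defaults describe a desk-scale study: a 500-term vocabulary of depth 4,
#' 40 latent topics of 15 terms, 60 drugs and 60 diseases with two topics
#' each, log-normal(2.2, 0.8) publication counts (median ~9 articles, a
#' heavy tail of heavily studied entities), 8 topic terms per article with a
#' 2% uniform-noise replacement rate, a 30% link rate among topic-sharing
#' pairs, and half of the planted links evidenced only after the 2007
#' cutoff.
#'
#' @param nTerms,treeDepth,nTopics,termsPerTopic,nDrugs,nDiseases,topicsPerEntity
#'   vocabulary / topic / entity sizes.
#' @param logMu,logSigma log-normal parameters of publication counts.
#' @param termsPerArticle,noiseTermRate article composition.
#' @param linkRate,biasStrength,futureFraction,cutoffYear link planting.
#' @param seed RNG seed.
#' @return a [SimConfig].
#' @export
simConfig <- function(nTerms = 500L, treeDepth = 4L, nTopics = 40L,
                      termsPerTopic = 15L, nDrugs = 60L, nDiseases = 60L,
                      topicsPerEntity = 2L, logMu = 2.2, logSigma = 0.8,
                      termsPerArticle = 8L, noiseTermRate = 0.02,
                      linkRate = 0.3, biasStrength = 0,
                      futureFraction = 0.5, cutoffYear = 2007L, seed = 1L) {
  new("SimConfig", nTerms = as.integer(nTerms), treeDepth = as.integer(treeDepth),
      nTopics = as.integer(nTopics), termsPerTopic = as.integer(termsPerTopic),
      nDrugs = as.integer(nDrugs), nDiseases = as.integer(nDiseases),
      topicsPerEntity = as.integer(topicsPerEntity), logMu = logMu,
      logSigma = logSigma, termsPerArticle = as.integer(termsPerArticle),
      noiseTermRate = noiseTermRate, linkRate = linkRate,
      biasStrength = biasStrength, futureFraction = futureFraction,
      cutoffYear = as.integer(cutoffYear), seed = as.integer(seed))
}

#' Frozen benchmark scenarios
#'
#' Two named configurations used throughout the test suite:
#' \describe{
#'   \item{unbiased}{`biasStrength = 0`: planted links are independent of
#'     publication volume, isolating the profile-similarity signal.}
#'   \item{biased}{links preferentially attach to heavily published
#'     entities (`biasStrength = 8`), with a larger entity panel, a wider
#'     publication-count spread and a higher annotation-noise rate,
#'     reproducing the annotation-bias phenomenon: count baselines become
#'     predictive of future links and raw similarity scores correlate with
#'     annotation level until corrected.}
#' }
#'
#' @param name "unbiased" or "biased".
#' @param seed optional seed override (the frozen defaults are 101 and 202).
#' @return a [SimConfig].
#' @export
benchmarkScenario <- function(name = c("unbiased", "biased"), seed = NULL) {
  name <- match.arg(name)
  cfg <- switch(name,
    unbiased = simConfig(biasStrength = 0, seed = 101L),
    biased   = simConfig(nDrugs = 120L, nDiseases = 120L, biasStrength = 8,
                         linkRate = 1.0, noiseTermRate = 0.2, logMu = 2.3,
                         logSigma = 1.2, seed = 202L))
  if (!is.null(seed)) cfg@seed <- as.integer(seed)
  cfg
}

#' Generate a synthetic corpus with planted ground truth
#'
#' Writes the on-disk formats of the loaders — `tree.tsv`, `corpus.jsonl`,
#' `entities.tsv` and `truth.json` — into `dir`, so the full pipeline
#' (including the command-line interface) can be exercised end to end.
#' Identical config and seed produce byte-identical files.
#'
#' Generation steps: (1) a random tree of `nTerms` terms with maximum depth
#' `treeDepth`; (2) topics as random term subsets; (3) each entity receives
#' `topicsPerEntity` topics, a distinct leaf defining term, and a
#' publication count ~ round(lognormal(logMu, logSigma)) floored at 1;
#' (4) each article samples `termsPerArticle` terms from the entity's topic
#' terms, each replaced by a uniform random vocabulary term with probability
#' `noiseTermRate`, and always carries the defining term; (5) topic-sharing
#' drug-disease pairs become true links with probability `linkRate` scaled
#' by `((uc + ud) / 2)^biasStrength` where uc, ud are the entities'
#' publication-count percentiles (unit scale); (6) each true link yields
#' co-annotated evidence articles, dated entirely after the cutoff with
#' probability `futureFraction` (the temporal positives) and entirely before
#' it otherwise (excluded pairs).
#'
#' @param config a [SimConfig].
#' @param dir output directory (created if needed).
#' @return list with elements `tree`, `corpus`, `entities`, `truthFile`
#'   (file paths) and `truth` (a [SimTruth]).
#' @export
simulateCorpus <- function(config, dir = tempfile("meshop_sim_")) {
  stopifnot(is(config, "SimConfig"))
  methods::validObject(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (exists(".Random.seed", globalenv())) {
    oldSeed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", oldSeed, globalenv()), add = TRUE)
  }
  set.seed(config@seed)

  ## (1) vocabulary tree
  nT <- config@nTerms
  termIds <- sprintf("T%04d", seq_len(nT))
  nRoots <- max(2L, ceiling(nT * 0.02))
  depth <- integer(nT); treeNum <- character(nT); nChild <- integer(nT)
  for (i in seq_len(nT)) {
    if (i <= nRoots) {
      depth[i] <- 1L
      treeNum[i] <- sprintf("A%02d", i)
    } else {
      elig <- which(depth[seq_len(i - 1L)] < config@treeDepth)
      p <- elig[sample.int(length(elig), 1L)]
      nChild[p] <- nChild[p] + 1L
      treeNum[i] <- paste0(treeNum[p], ".", sprintf("%03d", nChild[p]))
      depth[i] <- depth[p] + 1L
    }
  }

  ## (2)-(3) entities, defining terms (leaves), topics, publication counts
  nDrugs <- config@nDrugs; nDis <- config@nDiseases; nEnt <- nDrugs + nDis
  leaves <- which(nChild == 0L)
  if (length(leaves) < nEnt)
    stop("infeasible config: fewer leaf terms than entities")
  defIdx <- leaves[sample.int(length(leaves), nEnt)]
  entIds <- c(sprintf("DRUG%03d", seq_len(nDrugs)),
              sprintf("DIS%03d", seq_len(nDis)))
  entClass <- rep(c("drug", "disease"), c(nDrugs, nDis))
  defTerm <- termIds[defIdx]
  nonDef <- setdiff(seq_len(nT), defIdx)
  topics <- lapply(seq_len(config@nTopics), function(k)
    termIds[nonDef[sample.int(length(nonDef), config@termsPerTopic)]])
  entTopics <- lapply(seq_len(nEnt), function(i)
    sort(sample.int(config@nTopics, config@topicsPerEntity)))
  names(entTopics) <- entIds
  pubCounts <- pmax(1, round(stats::rlnorm(nEnt, config@logMu, config@logSigma)))

  ## (4) per-entity articles (all pre-cutoff: the profile-building era)
  cut <- config@cutoffYear
  preYears <- (cut - 9L):cut
  ids <- character(0); yrs <- integer(0); terms <- list()
  nextId <- 0L
  addArticle <- function(year, tset) {
    nextId <<- nextId + 1L
    ids[[nextId]] <<- sprintf("PMID%06d", nextId)
    yrs[[nextId]] <<- as.integer(year)
    terms[[nextId]] <<- tset
  }
  sampleTerms <- function(pool, k) {
    k <- min(k, length(pool))
    base <- pool[sample.int(length(pool), k)]
    noisy <- stats::runif(k) < config@noiseTermRate
    if (any(noisy))
      base[noisy] <- termIds[sample.int(nT, sum(noisy), replace = TRUE)]
    base
  }
  for (i in seq_len(nEnt)) {
    pool <- unique(unlist(topics[entTopics[[i]]], use.names = FALSE))
    m <- pubCounts[[i]]
    ay <- preYears[sample.int(length(preYears), m, replace = TRUE)]
    for (a in seq_len(m))
      addArticle(ay[[a]],
                 unique(c(defTerm[[i]], sampleTerms(pool, config@termsPerArticle))))
  }

  ## (5)-(6) planted links and their co-annotated evidence articles
  uDrug <- (rank(pubCounts[seq_len(nDrugs)], ties.method = "average") - 0.5) / nDrugs
  uDis <- (rank(pubCounts[nDrugs + seq_len(nDis)], ties.method = "average") - 0.5) / nDis
  tpDrug <- character(0); tpDis <- character(0); tpFuture <- logical(0)
  for (ci in seq_len(nDrugs)) {
    for (di in seq_len(nDis)) {
      shared <- intersect(entTopics[[ci]], entTopics[[nDrugs + di]])
      if (!length(shared)) next
      pLink <- config@linkRate *
        ((uDrug[[ci]] + uDis[[di]]) / 2)^config@biasStrength
      if (stats::runif(1) >= pLink) next
      future <- stats::runif(1) < config@futureFraction
      nArt <- 1L + stats::rpois(1, 1)
      span <- if (future) (cut + 1L):(cut + 3L) else (cut - 5L):cut
      ay <- span[sample.int(length(span), nArt, replace = TRUE)]
      sharedTerms <- unique(unlist(topics[shared], use.names = FALSE))
      for (a in seq_len(nArt))
        addArticle(ay[[a]],
                   unique(c(defTerm[[ci]], defTerm[[nDrugs + di]],
                            sampleTerms(sharedTerms, max(0L, config@termsPerArticle - 2L)))))
      tpDrug <- c(tpDrug, entIds[[ci]])
      tpDis <- c(tpDis, entIds[[nDrugs + di]])
      tpFuture <- c(tpFuture, future)
    }
  }
  truePairs <- data.frame(drug_id = tpDrug, disease_id = tpDis,
                          future = tpFuture, stringsAsFactors = FALSE)
  linked <- entIds %in% c(tpDrug, tpDis)
  plantedBias <- if (length(unique(linked)) < 2L) NA_real_ else
    stats::cor(log(pubCounts), as.numeric(linked))
  truth <- new("SimTruth", truePairs = truePairs,
               topicAssignments = entTopics, plantedBias = plantedBias)

  ## (7) write the loader formats
  treePath <- file.path(dir, "tree.tsv")
  writeLines(paste(termIds, treeNum, sep = "\t"), treePath, useBytes = TRUE)
  entPath <- file.path(dir, "entities.tsv")
  writeEntities(entitySet(data.frame(entity_id = entIds, class = entClass,
                                     defining_term = defTerm,
                                     stringsAsFactors = FALSE)), entPath)
  corpusPath <- file.path(dir, "corpus.jsonl")
  lines <- vapply(seq_len(nextId), function(i)
    as.character(jsonlite::toJSON(list(article_id = jsonlite::unbox(ids[[i]]),
                                       year = jsonlite::unbox(yrs[[i]]),
                                       terms = sort(terms[[i]])))),
    character(1))
  writeLines(lines, corpusPath, useBytes = TRUE)
  truthPath <- file.path(dir, "truth.json")
  jsonlite::write_json(list(true_pairs = truePairs,
                            topic_assignments = entTopics,
                            planted_bias = plantedBias,
                            seed = config@seed),
                       truthPath, auto_unbox = TRUE, digits = NA, null = "null")

  list(tree = treePath, corpus = corpusPath, entities = entPath,
       truthFile = truthPath, truth = truth)
}

#' @describeIn simulateCorpus compact display of the planted truth.
#' @param object a [SimTruth].
#' @export
setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", nrow(object@truePairs), "planted links (",
      sum(object@truePairs$future), "future ),",
      "publication/link correlation", round(object@plantedBias, 3), "\n")
})

#' Planted true links
#' @param truth a [SimTruth].
#' @return data.frame with columns drug_id, disease_id, future.
#' @export
truePairs <- function(truth) { stopifnot(is(truth, "SimTruth")); truth@truePairs }

#' Run the full pipeline on a simulated corpus
#'
#' Generates (or reuses) a corpus, reloads everything from disk through the
#' standard loaders, builds universal-background profiles from the
#' pre-cutoff literature, computes temporal-split labels on the full corpus,
#' and returns the pieces downstream analyses need. This is the harness used
#' by benchmarks and examples.
#'
#' @param config a [SimConfig].
#' @param dir simulation directory.
#' @param metrics metric ids for the AUC panel (NULL skips the panel).
#' @param withCorrection include the corrected variant in the panel.
#' @param halfWidth peer-window half-width for the correction.
#' @return list with elements `config`, `truth`, `tree`, `corpus`,
#'   `preCorpus`, `entities`, `drugProfiles`, `diseaseProfiles`, `labels`,
#'   `indexDrugs`, `indexDiseases`, and `panel` (data.frame or NULL).
#' @export
benchmarkPipeline <- function(config, dir = tempfile("meshop_sim_"),
                              metrics = c("l2_logp_overlap", "n_drug_terms",
                                          "n_disease_terms"),
                              withCorrection = FALSE, halfWidth = 5) {
  sim <- simulateCorpus(config, dir)
  tree <- loadTermTree(sim$tree)
  corpus <- loadCorpus(sim$corpus, tree)
  entities <- loadEntities(sim$entities, tree)
  pre <- filterCorpus(corpus, config@cutoffYear)
  bg <- backgroundCounts(pre, kind = "universal")
  drugProfiles <- buildProfiles(pre, entities, bg, class = "drug")
  diseaseProfiles <- buildProfiles(pre, entities, bg, class = "disease")
  labels <- temporalLabels(corpus, entities, config@cutoffYear)
  panel <- if (is.null(metrics)) NULL else
    metricPanelAuc(drugProfiles, diseaseProfiles, labels, metrics = metrics,
                   withCorrection = withCorrection, halfWidth = halfWidth)
  list(config = config, truth = sim$truth, tree = tree, corpus = corpus,
       preCorpus = pre, entities = entities, drugProfiles = drugProfiles,
       diseaseProfiles = diseaseProfiles, labels = labels,
       indexDrugs = annotationIndex(drugProfiles),
       indexDiseases = annotationIndex(diseaseProfiles), panel = panel)
}
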