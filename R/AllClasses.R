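# Central S4 containers for the pipeline:
#   TermTree -> Corpus -> MeSHOP profiles -> ScoreMatrix -> CorrectedMatrix
# plus EntitySet / Background / AnnotationIndex / LabelSet support objects
# and the SimConfig / SimTruth pair used by the synthetic-corpus generator.

#' TermTree: a controlled vocabulary addressed by tree numbers
#'
#' Holds the vocabulary hierarchy: for every term its dot-delimited tree
#' numbers (a term may occupy several positions), the owner of every tree
#' number, and the precomputed strict-ancestor closure obtained by repeated
#' one-step parent application. Tree-number prefixes with no owning term
#' ("dangling" prefixes) are recorded for the load report.
#'
#' @slot treeNumbers named list, term id -> character vector of tree numbers.
#' @slot numberOwner named character, tree number -> owning term id.
#' @slot ancestors named list, term id -> character vector of strict ancestors.
#' @slot dangling character, tree-number prefixes encountered during closure
#'   computation that no term owns.
#' @seealso [loadTermTree()], [termAncestors()]
#' @export
setClass("TermTree", representation(
  treeNumbers = "list",
  numberOwner = "character",
  ancestors   = "list",
  dangling    = "character"
))

setValidity("TermTree", function(object) {
  msg <- character(0)
  if (is.null(names(object@treeNumbers)) && length(object@treeNumbers))
    msg <- c(msg, "treeNumbers must be a named list")
  if (!setequal(names(object@treeNumbers), names(object@ancestors)))
    msg <- c(msg, "ancestors must cover exactly the known terms")
  if (length(msg)) msg else TRUE
})

#' Corpus: dated articles with term annotations
#'
#' Articles keep both their raw curator-assigned terms (so the corpus can be
#' written back to disk unchanged) and the propagated term set closed under
#' the vocabulary's ancestor relation. An inverted index maps every term to
#' the ids of articles carrying it post-propagation.
#'
#' @slot articleIds character vector of unique article ids.
#' @slot years integer publication years, parallel to `articleIds`.
#' @slot terms list of character vectors: propagated (ancestor-closed) term
#'   sets, parallel to `articleIds`.
#' @slot rawTerms list of character vectors: the raw annotations as read.
#' @slot termIndex named list, term id -> character vector of article ids.
#' @slot unknownTerms character: annotation terms absent from the tree
#'   (legal, but propagation-inert), recorded for the load report.
#' @seealso [loadCorpus()], [bibliography()]
#' @export
setClass("Corpus", representation(
  articleIds   = "character",
  years        = "integer",
  terms        = "list",
  rawTerms     = "list",
  termIndex    = "list",
  unknownTerms = "character"
))

setValidity("Corpus", function(object) {
  n <- length(object@articleIds)
  msg <- character(0)
  if (anyDuplicated(object@articleIds))
    msg <- c(msg, "article ids must be unique")
  if (length(object@years) != n || length(object@terms) != n ||
      length(object@rawTerms) != n)
    msg <- c(msg, "years/terms/rawTerms must parallel articleIds")
  if (n && any(object@years < 1000 | object@years > 9999))
    msg <- c(msg, "years must be 4-digit positive integers")
  if (length(msg)) msg else TRUE
})

#' EntitySet: the drug and disease entities under study
#'
#' @slot entities data.frame with columns `entity_id`, `class`
#'   (one of "drug"/"disease") and `defining_term` (the vocabulary term whose
#'   bibliography defines the entity).
#' @seealso [loadEntities()]
#' @export
setClass("EntitySet", representation(entities = "data.frame"))

setValidity("EntitySet", function(object) {
  df <- object@entities
  msg <- character(0)
  need <- c("entity_id", "class", "defining_term")
  if (!all(need %in% names(df)))
    return(paste("entities needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(df$entity_id)) msg <- c(msg, "entity ids must be unique")
  if (!all(df$class %in% c("drug", "disease")))
    msg <- c(msg, "class must be 'drug' or 'disease'")
  if (length(msg)) msg else TRUE
})

#' Background: term counts over a background article set
#'
#' Supplies the margins of the enrichment test: how many background articles
#' carry each term (K) and how large the background is (N). A universal
#' background counts over all corpus articles; a class-specific background
#' counts only over articles associated with at least one entity of a class.
#'
#' @slot termCounts named numeric, term id -> number of background articles
#'   annotated (post-propagation) with the term.
#' @slot nTotal integer, background size.
#' @slot kind "universal" or "class-specific".
#' @seealso [backgroundCounts()]
#' @export
setClass("Background", representation(
  termCounts = "numeric",
  nTotal     = "integer",
  kind       = "character"
))

setValidity("Background", function(object) {
  msg <- character(0)
  if (object@nTotal < 1L) msg <- c(msg, "background must be non-empty")
  if (length(object@termCounts) &&
      (min(object@termCounts) < 0 || max(object@termCounts) > object@nTotal))
    msg <- c(msg, "term counts must lie in [0, nTotal]")
  if (!object@kind %in% c("universal", "class-specific"))
    msg <- c(msg, "kind must be 'universal' or 'class-specific'")
  if (length(msg)) msg else TRUE
})

#' MeSHOP: a term over-representation profile for one entity
#'
#' One row per distinct term observed in the entity's bibliography, carrying
#' the observed article count, the bibliography fraction, the one-sided
#' hypergeometric over-representation p-value against the background, and a
#' tf-idf weight. Rows are ordered by ascending p-value, ties broken by term
#' id, so profiles serialize deterministically.
#'
#' @slot entityId character scalar.
#' @slot definingTerm the vocabulary term defining the entity's bibliography.
#' @slot nArticles integer bibliography size.
#' @slot entries data.frame with columns `term`, `count`, `fraction`,
#'   `p_value` (floored at 1e-300), `weight`.
#' @slot backgroundKind the kind of [Background] the profile was built against.
#' @seealso [buildProfile()], [annotationLevel()]
#' @export
setClass("MeSHOP", representation(
  entityId       = "character",
  definingTerm   = "character",
  nArticles      = "integer",
  entries        = "data.frame",
  backgroundKind = "character"
))

setValidity("MeSHOP", function(object) {
  e <- object@entries
  msg <- character(0)
  need <- c("term", "count", "fraction", "p_value", "weight")
  if (!all(need %in% names(e)))
    return(paste("entries needs columns:", paste(need, collapse = ", ")))
  if (nrow(e) == 0) msg <- c(msg, "profile must be non-empty")
  if (nrow(e) && (any(e$count < 1) || any(e$count > object@nArticles)))
    msg <- c(msg, "counts must lie in [1, nArticles]")
  if (nrow(e) && (any(e$p_value <= 0) || any(e$p_value > 1)))
    msg <- c(msg, "p-values must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' MetricSpec: one registered profile-similarity metric
#'
#' @slot metricId metric identifier (see [metricRegistry()]).
#' @slot polarity "higher-is-similar" or "lower-is-similar": the direction in
#'   which the metric indicates a more similar pair (used to orient ROC
#'   analysis and the "more extreme" comparison of the bias correction).
#' @slot domain "all-terms" (union of observed terms), "overlap-only"
#'   (intersection) or "single-profile".
#' @slot useMagnitude if TRUE the metric is scored on |value| (used for the
#'   signed sum-of-differences-of-log-p metric).
#' @export
setClass("MetricSpec", representation(
  metricId     = "character",
  polarity     = "character",
  domain       = "character",
  useMagnitude = "logical"
))

#' ScoreMatrix: drug x disease values of one similarity metric
#'
#' @slot metric the [MetricSpec] the values were computed under.
#' @slot values numeric matrix, rows = drugs, columns = diseases, with
#'   dimnames carrying the entity ids; all values finite.
#' @seealso [scoreMatrix()], [rocAuc()]
#' @export
setClass("ScoreMatrix", representation(
  metric = "MetricSpec",
  values = "matrix"
))

setValidity("ScoreMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must have drug rownames and disease colnames")
  if (length(v) && !all(is.finite(v)))
    msg <- c(msg, "all scores must be finite")
  if (length(msg)) msg else TRUE
})

#' AnnotationIndex: annotation levels and their empirical percentiles
#'
#' Annotation level = number of distinct terms in an entity's profile (the
#' bias covariate). Percentiles are mid-rank within the entity class, so tied
#' levels share a percentile.
#'
#' @slot levels named numeric, entity id -> annotation level.
#' @slot percentile named numeric in [0, 100], parallel to `levels`.
#' @seealso [annotationIndex()], [peerSet()]
#' @export
setClass("AnnotationIndex", representation(
  levels     = "numeric",
  percentile = "numeric"
))

setValidity("AnnotationIndex", function(object) {
  msg <- character(0)
  if (!identical(names(object@levels), names(object@percentile)))
    msg <- c(msg, "levels and percentile must share names")
  if (length(object@percentile) &&
      (min(object@percentile) < 0 || max(object@percentile) > 100))
    msg <- c(msg, "percentiles must lie in [0, 100]")
  o <- order(object@levels)
  if (is.unsorted(object@percentile[o]))
    msg <- c(msg, "percentile must be non-decreasing in level")
  if (length(msg)) msg else TRUE
})

#' CorrectedMatrix: empirical significance of scores given annotation levels
#'
#' Values are P(score more extreme than observed | drug and disease annotation
#' levels within a +/- half-width percentile window), estimated from the pool
#' of peer-pair scores with add-one smoothing; values lie in (0, 1] and
#' smaller means more unexpectedly similar.
#'
#' @slot metric the [MetricSpec] of the underlying raw scores.
#' @slot raw the raw score matrix.
#' @slot values the corrected (empirical significance) matrix.
#' @slot nPool integer matrix of peer-pool sizes.
#' @slot halfWidth the percentile half-width of the peer windows.
#' @seealso [correctedMatrix()]
#' @export
setClass("CorrectedMatrix", representation(
  metric    = "MetricSpec",
  raw       = "matrix",
  values    = "matrix",
  nPool     = "matrix",
  halfWidth = "numeric"
))

setValidity("CorrectedMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (length(v) && (any(v <= 0) || any(v > 1)))
    msg <- c(msg, "corrected values must lie in (0, 1]")
  if (!identical(dim(v), dim(object@raw)))
    msg <- c(msg, "raw and corrected matrices must be conformable")
  if (length(msg)) msg else TRUE
})

#' LabelSet: positive / negative / excluded assignment per drug-disease pair
#'
#' @slot labels character matrix (rows = drugs, columns = diseases) with
#'   entries "positive", "negative" or "excluded"; excluded pairs never enter
#'   ROC computation.
#' @slot provenance "future-cooccurrence" or "reference-collection".
#' @slot report list of loader diagnostics (e.g. unresolvable reference rows).
#' @seealso [temporalLabels()], [referenceLabels()]
#' @export
setClass("LabelSet", representation(
  labels     = "matrix",
  provenance = "character",
  report     = "list"
))

setValidity("LabelSet", function(object) {
  l <- object@labels
  msg <- character(0)
  if (length(l) && !all(l %in% c("positive", "negative", "excluded")))
    msg <- c(msg, "labels must be positive/negative/excluded")
  if (is.null(rownames(l)) || is.null(colnames(l)))
    msg <- c(msg, "labels must carry drug rownames and disease colnames")
  if (!object@provenance %in% c("future-cooccurrence", "reference-collection"))
    msg <- c(msg, "unknown provenance")
  if (length(msg)) msg else TRUE
})

#' SimConfig: parameters of the synthetic-corpus generator
#'
#' @slot nTerms vocabulary size.
#' @slot treeDepth maximum depth of the generated hierarchy.
#' @slot nTopics number of latent topics (random term subsets).
#' @slot termsPerTopic terms per topic.
#' @slot nDrugs,nDiseases entity counts.
#' @slot topicsPerEntity topics assigned to each entity.
#' @slot logMu,logSigma log-normal parameters of per-entity publication counts
#'   (heavy-tailed annotation bias).
#' @slot termsPerArticle terms sampled per article from the entity's topics.
#' @slot noiseTermRate probability a sampled term is replaced by a uniform
#'   random vocabulary term.
#' @slot linkRate probability a topic-sharing drug-disease pair is planted as
#'   a true link (before the bias factor).
#' @slot biasStrength exponent tying link probability to the two entities'
#'   publication-count percentiles; 0 = links independent of publication
#'   volume.
#' @slot futureFraction fraction of planted links whose co-annotated evidence
#'   articles are dated after the cutoff year (the temporal positives); the
#'   remainder are dated before it (excluded pairs).
#' @slot cutoffYear temporal-split cutoff.
#' @slot seed RNG seed; identical config + seed gives byte-identical output.
#' @seealso [simConfig()], [simulateCorpus()], [benchmarkScenario()]
#' @export
setClass("SimConfig", representation(
  nTerms          = "integer",
  treeDepth       = "integer",
  nTopics         = "integer",
  termsPerTopic   = "integer",
  nDrugs          = "integer",
  nDiseases       = "integer",
  topicsPerEntity = "integer",
  logMu           = "numeric",
  logSigma        = "numeric",
  termsPerArticle = "integer",
  noiseTermRate   = "numeric",
  linkRate        = "numeric",
  biasStrength    = "numeric",
  futureFraction  = "numeric",
  cutoffYear      = "integer",
  seed            = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character(0)
  pos <- c("nTerms", "treeDepth", "nTopics", "termsPerTopic", "nDrugs",
           "nDiseases", "topicsPerEntity", "termsPerArticle")
  for (s in pos) if (slot(object, s) < 1L)
    msg <- c(msg, paste(s, "must be positive"))
  for (s in c("noiseTermRate", "linkRate"))
    if (slot(object, s) < 0 || slot(object, s) > 1)
      msg <- c(msg, paste(s, "must lie in [0, 1]"))
  if (object@futureFraction <= 0 || object@futureFraction >= 1)
    msg <- c(msg, "futureFraction must lie in (0, 1)")
  if (object@biasStrength < 0) msg <- c(msg, "biasStrength must be >= 0")
  if (object@termsPerTopic > object@nTerms)
    msg <- c(msg, "termsPerTopic cannot exceed nTerms")
  if (object@nDrugs + object@nDiseases > object@nTerms)
    msg <- c(msg, "need at least one distinct defining term per entity")
  if (object@topicsPerEntity > object@nTopics)
    msg <- c(msg, "topicsPerEntity cannot exceed nTopics")
  if (length(msg)) msg else TRUE
})

#' SimTruth: the ground truth planted by the generator
#'
#' @slot truePairs data.frame with columns `drug_id`, `disease_id`, `future`
#'   (logical: evidence articles dated after the cutoff).
#' @slot topicAssignments named list, entity id -> integer topic ids.
#' @slot plantedBias realized correlation between log publication count and
#'   link membership across entities (NA when degenerate).
#' @export
setClass("SimTruth", representation(
  truePairs        = "data.frame",
  topicAssignments = "list",
  plantedBias      = "numeric"
))
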