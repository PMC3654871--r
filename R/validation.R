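# Validation: temporal-split and reference-collection label sets, rank-sum
# ROC AUC, the per-metric AUC panel, and the score-vs-annotation-level
# correlation audit.

# Scan articles for drug-disease co-annotation; returns one row per pair
# with the earliest co-annotation year.
.cooccurrenceScan <- function(corpus, entities, yearMax = NULL) {
  et <- entityTable(entities)
  drugTerm <- et$defining_term[et$class == "drug"]
  drugId <- et$entity_id[et$class == "drug"]
  disTerm <- et$defining_term[et$class == "disease"]
  disId <- et$entity_id[et$class == "disease"]
  acc <- new.env(parent = emptyenv())
  for (i in seq_along(corpus@articleIds)) {
    y <- corpus@years[[i]]
    if (!is.null(yearMax) && y > yearMax) next
    tt <- corpus@terms[[i]]
    dHit <- which(drugTerm %in% tt)
    if (!length(dHit)) next
    zHit <- which(disTerm %in% tt)
    if (!length(zHit)) next
    for (a in dHit) for (b in zHit) {
      key <- paste0(drugId[[a]], "\r", disId[[b]])
      prev <- acc[[key]]
      if (is.null(prev) || y < prev) acc[[key]] <- y
    }
  }
  keys <- sort(ls(acc))
  if (!length(keys))
    return(data.frame(drug_id = character(0), disease_id = character(0),
                      min_year = integer(0), stringsAsFactors = FALSE))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(drug_id = vapply(parts, `[[`, character(1), 1L),
             disease_id = vapply(parts, `[[`, character(1), 2L),
             min_year = vapply(keys, function(k) as.integer(acc[[k]]), integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Co-annotated drug-disease pairs
#'
#' All (drug, disease) pairs for which some article carries both defining
#' terms post-propagation (an article indexed under a descendant counts),
#' optionally restricted to articles up to `yearMax`.
#'
#' @param corpus a [Corpus].
#' @param entities an [EntitySet].
#' @param yearMax optional inclusive year bound.
#' @return data.frame with columns drug_id, disease_id, min_year (earliest
#'   co-annotation year).
#' @export
cooccurringPairs <- function(corpus, entities, yearMax = NULL) {
  stopifnot(is(corpus, "Corpus"), is(entities, "EntitySet"))
  .cooccurrenceScan(corpus, entities, yearMax)
}

.emptyLabels <- function(entities) {
  et <- entityTable(entities)
  drugs <- et$entity_id[et$class == "drug"]
  dis <- et$entity_id[et$class == "disease"]
  matrix("negative", length(drugs), length(dis), dimnames = list(drugs, dis))
}

#' Temporal-split labels
#'
#' Pairs co-annotated at or before the cutoff year are excluded (already
#' known), pairs first co-annotated after the cutoff are positives (novel
#' future associations), and all remaining drug x disease pairs are
#' negatives.
#'
#' @param corpus a [Corpus] spanning years on both sides of the cutoff.
#' @param entities an [EntitySet].
#' @param cutoffYear the split year.
#' @return a [LabelSet] with provenance "future-cooccurrence".
#' @export
temporalLabels <- function(corpus, entities, cutoffYear) {
  stopifnot(is(corpus, "Corpus"), is(entities, "EntitySet"))
  if (!length(corpus@years) || max(corpus@years) <= cutoffYear)
    stop("no article after the cutoff year ", cutoffYear,
         ": temporal labels are undefined")
  co <- .cooccurrenceScan(corpus, entities)
  labels <- .emptyLabels(entities)
  if (nrow(co)) {
    idx <- cbind(co$drug_id, co$disease_id)
    labels[idx] <- ifelse(co$min_year <= cutoffYear, "excluded", "positive")
  }
  new("LabelSet", labels = labels, provenance = "future-cooccurrence",
      report = list(cutoff_year = cutoffYear,
                    n_cooccurring = nrow(co)))
}

#' Reference-collection labels
#'
#' Reads a TSV of (drug_id, disease_id) pairs (header optional, detected),
#' resolves them against the entity set (unresolvable rows are reported, not
#' fatal), and labels resolvable listed pairs positive. Pairs co-annotated
#' at or before the cutoff are excluded even when listed — the reference
#' collection is meant to capture novel relationships. Everything else is
#' negative.
#'
#' @param path TSV path of reference pairs.
#' @param entities an [EntitySet].
#' @param corpus a [Corpus] (supplies pre-cutoff co-annotation for the
#'   exclusion rule).
#' @param cutoffYear the novelty cutoff.
#' @return a [LabelSet] with provenance "reference-collection".
#' @export
referenceLabels <- function(path, entities, corpus, cutoffYear) {
  stopifnot(is(entities, "EntitySet"), is(corpus, "Corpus"))
  if (!file.exists(path)) stop("reference pair file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty reference pair file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop("malformed reference line ", bad[1L], ": expected 2 columns")
  first <- tolower(fields[[1L]])
  if (identical(first, c("drug_id", "disease_id"))) fields <- fields[-1L]
  if (!length(fields)) stop("reference pair file has a header but no pairs")
  drug <- vapply(fields, `[[`, character(1), 1L)
  dis <- vapply(fields, `[[`, character(1), 2L)

  et <- entityTable(entities)
  drugs <- et$entity_id[et$class == "drug"]
  diseases <- et$entity_id[et$class == "disease"]
  ok <- drug %in% drugs & dis %in% diseases
  if (!any(ok)) stop("no reference pair resolves against the entity set")
  labels <- .emptyLabels(entities)
  labels[cbind(drug[ok], dis[ok])] <- "positive"
  pre <- .cooccurrenceScan(corpus, entities, yearMax = cutoffYear)
  if (nrow(pre)) labels[cbind(pre$drug_id, pre$disease_id)] <- "excluded"
  new("LabelSet", labels = labels, provenance = "reference-collection",
      report = list(cutoff_year = cutoffYear,
                    n_listed = length(drug),
                    n_unresolvable = sum(!ok),
                    unresolvable = utils::head(
                      paste(drug[!ok], dis[!ok], sep = "/"), 20)))
}

#' @describeIn temporalLabels label matrix.
#' @param x a [LabelSet].
#' @export
setMethod("labelMatrix", "LabelSet", function(x) x@labels)

#' @describeIn temporalLabels drug axis.
#' @export
setMethod("drugIds", "LabelSet", function(x) rownames(x@labels))

#' @describeIn temporalLabels disease axis.
#' @export
setMethod("diseaseIds", "LabelSet", function(x) colnames(x@labels))

#' Loader/labeling diagnostics of a label set
#' @param x a [LabelSet].
#' @return list.
#' @export
labelReport <- function(x) { stopifnot(is(x, "LabelSet")); x@report }

#' @describeIn temporalLabels compact display.
#' @param object a [LabelSet].
#' @export
setMethod("show", "LabelSet", function(object) {
  tab <- table(factor(object@labels,
                      levels = c("positive", "negative", "excluded")))
  cat("LabelSet (", object@provenance, "): ", tab[["positive"]], " positive, ",
      tab[["negative"]], " negative, ", tab[["excluded"]], " excluded\n",
      sep = "")
})

# Rank-sum AUC with average ranks for ties.
.aucRankSum <- function(x, positive) {
  nPos <- sum(positive); nNeg <- sum(!positive)
  if (nPos == 0L || nNeg == 0L)
    stop("AUC needs at least one positive and one negative")
  r <- rank(x, ties.method = "average")
  (sum(r[positive]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' @describeIn rocAuc numeric scores and a logical positive mask.
#' @export
setMethod("rocAuc", signature("numeric", "logical"), function(scores, labels, ...) {
  stopifnot(length(scores) == length(labels))
  .aucRankSum(scores, labels)
})

#' @describeIn rocAuc a score matrix against a label set. Scores are
#'   oriented by the metric's polarity (overridable via `polarity`);
#'   excluded pairs are dropped. With `autoOrient = TRUE` returns
#'   max(AUC, 1 - AUC).
#' @param polarity optional polarity override ("higher-is-similar" /
#'   "lower-is-similar").
#' @param autoOrient report the orientation-free AUC.
#' @export
setMethod("rocAuc", signature("ScoreMatrix", "LabelSet"),
          function(scores, labels, polarity = NULL, autoOrient = FALSE, ...) {
  spec <- scores@metric
  if (!is.null(polarity)) spec <- metricSpec(spec@metricId, polarity = polarity)
  oriented <- orientScores(scores@values, spec)
  lab <- .alignLabels(labels, rownames(oriented), colnames(oriented))
  keep <- lab != "excluded"
  a <- .aucRankSum(oriented[keep], lab[keep] == "positive")
  if (autoOrient) max(a, 1 - a) else a
})

.alignLabels <- function(labels, drugs, diseases) {
  missD <- setdiff(drugs, rownames(labels@labels))
  missZ <- setdiff(diseases, colnames(labels@labels))
  if (length(missD) || length(missZ))
    stop("label set does not cover the score axes (missing ",
         length(missD), " drugs, ", length(missZ), " diseases)")
  labels@labels[drugs, diseases, drop = FALSE]
}

#' AUC panel across metrics
#'
#' Computes, for every requested metric, the registry-polarity AUC and the
#' auto-oriented AUC (max of AUC and 1 - AUC) on the given labels. When
#' `withCorrection` is set, one extra row reports the annotation-bias
#' corrected variant of `correctionBase` (corrected values are empirical
#' significances: smaller is more similar).
#'
#' @param drugProfiles,diseaseProfiles named lists of [MeSHOP] objects.
#' @param labels a [LabelSet].
#' @param metrics metric ids (default: full registry).
#' @param withCorrection add the corrected variant of `correctionBase`.
#' @param correctionBase metric id to correct (default the overlap-restricted
#'   log-p Euclidean distance, the panel's consistently strongest metric).
#' @param halfWidth peer-window half-width for the correction.
#' @return data.frame with columns metric_id, auc, auc_auto_oriented, n_pos,
#'   n_neg, n_excluded.
#' @export
metricPanelAuc <- function(drugProfiles, diseaseProfiles, labels,
                           metrics = metricRegistry()$metric_id,
                           withCorrection = FALSE,
                           correctionBase = "l2_logp_overlap",
                           halfWidth = 5) {
  panel <- scorePanel(drugProfiles, diseaseProfiles, metrics = metrics)
  lab <- .alignLabels(labels, rownames(panel[[1L]]@values),
                      colnames(panel[[1L]]@values))
  keep <- lab != "excluded"
  pos <- lab[keep] == "positive"
  rows <- lapply(metrics, function(m) {
    oriented <- orientScores(panel[[m]]@values, panel[[m]]@metric)
    a <- .aucRankSum(oriented[keep], pos)
    data.frame(metric_id = m, auc = a, auc_auto_oriented = max(a, 1 - a),
               n_pos = sum(pos), n_neg = sum(!pos), n_excluded = sum(!keep),
               stringsAsFactors = FALSE)
  })
  if (withCorrection) {
    base <- panel[[correctionBase]] %||%
      scoreMatrix(correctionBase, drugProfiles, diseaseProfiles)
    idxC <- annotationIndex(drugProfiles)
    idxD <- annotationIndex(diseaseProfiles)
    cm <- correctedMatrix(base, idxC, idxD, halfWidth = halfWidth)
    oriented <- -cm@values  # smaller corrected value = more similar
    a <- .aucRankSum(oriented[keep], pos)
    rows <- c(rows, list(data.frame(
      metric_id = paste0("corrected_", correctionBase), auc = a,
      auc_auto_oriented = max(a, 1 - a), n_pos = sum(pos), n_neg = sum(!pos),
      n_excluded = sum(!keep), stringsAsFactors = FALSE)))
  }
  do.call(rbind, rows)
}

#' Correlation between scores and annotation level
#'
#' Pearson correlation between each pair's score and the annotation level of
#' the pair's drug (axis = "drug") or disease (axis = "disease"), over all
#' non-excluded pairs. This is the audit that exposes annotation bias in raw
#' similarity scores, and its disappearance after correction.
#'
#' @param scores a [ScoreMatrix] or [CorrectedMatrix].
#' @param index the [AnnotationIndex] of the chosen axis's class.
#' @param axis "drug" or "disease".
#' @param labels optional [LabelSet]; excluded pairs are dropped when given.
#' @return Pearson correlation coefficient.
#' @export
annotationCorrelation <- function(scores, index, axis = c("drug", "disease"),
                                  labels = NULL) {
  axis <- match.arg(axis)
  v <- scoreValues(scores)
  lv <- index@levels[if (axis == "drug") rownames(v) else colnames(v)]
  if (any(is.na(lv))) stop("annotation index does not cover the ", axis, " axis")
  lvm <- if (axis == "drug") matrix(lv, nrow(v), ncol(v))
         else matrix(lv, nrow(v), ncol(v), byrow = TRUE)
  keep <- rep(TRUE, length(v))
  if (!is.null(labels))
    keep <- .alignLabels(labels, rownames(v), colnames(v)) != "excluded"
  x <- as.vector(v)[keep]; y <- as.vector(lvm)[keep]
  if (stats::sd(x) == 0)
    stop("scores have zero variance: correlation undefined")
  if (length(unique(y)) < 2L)
    stop("need at least two distinct annotation levels on the ", axis, " axis")
  stats::cor(x, y)
}
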