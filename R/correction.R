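# Empirical annotation-bias correction. A pair's raw similarity score is
# converted into the probability that a random pair between comparably
# annotated peers (drugs and diseases within +/- halfWidth percentile of
# annotation level) scores more extremely. Smaller corrected values mean
# more unexpectedly similar pairs given how heavily the entities are
# studied.

#' Annotation-level index for one entity class
#'
#' Records each entity's annotation level (distinct terms in its profile)
#' and its mid-rank empirical percentile within the class: percentile =
#' 100 * (rank - 0.5) / n with average ranks, so tied levels share a
#' percentile and percentiles are non-decreasing in level.
#'
#' @param profiles named list of [MeSHOP] objects (one entity class), or a
#'   named numeric vector of annotation levels.
#' @return an [AnnotationIndex].
#' @export
annotationIndex <- function(profiles) {
  if (is.numeric(profiles)) {
    levels <- profiles
    if (is.null(names(levels))) stop("levels must be named by entity id")
  } else {
    levels <- vapply(profiles, annotationLevel, numeric(1))
    names(levels) <- vapply(profiles, entityId, character(1))
  }
  pct <- 100 * (rank(levels, ties.method = "average") - 0.5) / length(levels)
  new("AnnotationIndex", levels = levels,
      percentile = stats::setNames(pct, names(levels)))
}

#' Annotation levels of an index
#' @param index an [AnnotationIndex].
#' @return named numeric vector.
#' @export
annotationLevels <- function(index) index@levels

#' Annotation percentiles of an index
#' @param index an [AnnotationIndex].
#' @return named numeric vector in [0, 100].
#' @export
annotationPercentiles <- function(index) index@percentile

#' Peers of an entity by annotation level
#'
#' All same-class entities whose annotation-level percentile lies within
#' [p - halfWidth, p + halfWidth] of the query's percentile p. The window is
#' truncated at [0, 100] — no wrap-around and no widening at the boundary —
#' and always contains the entity itself.
#'
#' @param index an [AnnotationIndex].
#' @param entity an entity id in the index.
#' @param halfWidth window half-width in percentile units, in (0, 50];
#'   the default 5 compares against the ~10% most comparably annotated
#'   entities.
#' @return character vector of peer entity ids (query included).
#' @export
peerSet <- function(index, entity, halfWidth = 5) {
  stopifnot(is(index, "AnnotationIndex"), halfWidth > 0, halfWidth <= 50)
  p <- index@percentile[entity]
  if (is.na(p)) stop("unknown entity: ", entity)
  lo <- max(0, p - halfWidth); hi <- min(100, p + halfWidth)
  names(index@percentile)[index@percentile >= lo & index@percentile <= hi]
}

#' Empirical significance of one pair's score
#'
#' With x the pair's raw score and E the pool of raw scores of every pair
#' between the drug's peers and the disease's peers (the query pair
#' included), returns (1 + #\{e in E strictly more extreme than x\}) /
#' (1 + |E|), where "more extreme" follows the metric's polarity. The
#' add-one smoothing keeps the value in (0, 1].
#'
#' @param scores a [ScoreMatrix].
#' @param indexDrugs,indexDiseases [AnnotationIndex] objects for the two
#'   classes (covering the score axes).
#' @param drug,disease entity ids on the score axes.
#' @param halfWidth peer-window half-width in percentile units.
#' @return empirical significance in (0, 1].
#' @export
correctedScore <- function(scores, indexDrugs, indexDiseases, drug, disease,
                           halfWidth = 5) {
  stopifnot(is(scores, "ScoreMatrix"))
  oriented <- orientScores(scores@values, scores@metric)
  peersC <- peerSet(indexDrugs, drug, halfWidth)
  peersD <- peerSet(indexDiseases, disease, halfWidth)
  peersC <- intersect(peersC, rownames(oriented))
  peersD <- intersect(peersD, colnames(oriented))
  pool <- oriented[peersC, peersD, drop = FALSE]
  if (!length(pool)) stop("empty peer pool for (", drug, ", ", disease, ")")
  x <- oriented[drug, disease]
  (1 + sum(pool > x)) / (1 + length(pool))
}

#' Correct a whole score matrix for annotation bias
#'
#' Elementwise [correctedScore()] with peer sets cached per entity.
#'
#' @inheritParams correctedScore
#' @return a [CorrectedMatrix].
#' @export
correctedMatrix <- function(scores, indexDrugs, indexDiseases, halfWidth = 5) {
  stopifnot(is(scores, "ScoreMatrix"))
  v <- scores@values
  oriented <- orientScores(v, scores@metric)
  drugs <- rownames(v); dis <- colnames(v)
  peersC <- lapply(stats::setNames(drugs, drugs), function(d)
    match(intersect(peerSet(indexDrugs, d, halfWidth), drugs), drugs))
  peersD <- lapply(stats::setNames(dis, dis), function(d)
    match(intersect(peerSet(indexDiseases, d, halfWidth), dis), dis))
  out <- matrix(NA_real_, nrow(v), ncol(v), dimnames = dimnames(v))
  np <- matrix(NA_integer_, nrow(v), ncol(v), dimnames = dimnames(v))
  for (j in seq_along(dis)) {
    pj <- peersD[[j]]
    for (i in seq_along(drugs)) {
      pool <- oriented[peersC[[i]], pj]
      out[i, j] <- (1 + sum(pool > oriented[i, j])) / (1 + length(pool))
      np[i, j] <- length(pool)
    }
  }
  new("CorrectedMatrix", metric = scores@metric, raw = v, values = out,
      nPool = np, halfWidth = halfWidth)
}

#' @describeIn correctedMatrix corrected values.
#' @export
setMethod("scoreValues", "CorrectedMatrix", function(x) x@values)

#' @describeIn correctedMatrix drug axis.
#' @export
setMethod("drugIds", "CorrectedMatrix", function(x) rownames(x@values))

#' @describeIn correctedMatrix disease axis.
#' @export
setMethod("diseaseIds", "CorrectedMatrix", function(x) colnames(x@values))

#' @describeIn correctedMatrix metric of the underlying raw scores.
#' @export
setMethod("scoreMetric", "CorrectedMatrix", function(x) x@metric)

#' Raw score matrix behind a corrected matrix
#' @param x a [CorrectedMatrix].
#' @return numeric matrix.
#' @export
rawScores <- function(x) { stopifnot(is(x, "CorrectedMatrix")); x@raw }

#' Peer-pool sizes of a corrected matrix
#' @param x a [CorrectedMatrix].
#' @return integer matrix.
#' @export
poolSizes <- function(x) { stopifnot(is(x, "CorrectedMatrix")); x@nPool }

#' @describeIn correctedMatrix compact display.
#' @param object a [CorrectedMatrix].
#' @export
setMethod("show", "CorrectedMatrix", function(object) {
  cat("CorrectedMatrix [", object@metric@metricId, ", +/-", object@halfWidth,
      " percentile]: ", nrow(object@values), " drugs x ", ncol(object@values),
      " diseases, median pool ", stats::median(object@nPool), "\n", sep = "")
})

#' Write corrected scores in long format
#'
#' TSV with header `drug_id, disease_id, metric_id, raw_score,
#' corrected_score, n_pool`.
#'
#' @param corrected a [CorrectedMatrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCorrected <- function(corrected, path) {
  stopifnot(is(corrected, "CorrectedMatrix"))
  v <- corrected@values
  df <- data.frame(drug_id = rep(rownames(v), times = ncol(v)),
                   disease_id = rep(colnames(v), each = nrow(v)),
                   metric_id = corrected@metric@metricId,
                   raw_score = as.vector(corrected@raw),
                   corrected_score = as.vector(v),
                   n_pool = as.vector(corrected@nPool),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
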