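# Generics for accessors shared across the pipeline classes.

#' Number of articles behind an object
#'
#' For a [Corpus], the corpus size; for a [MeSHOP], the bibliography size.
#' @param x object.
#' @return integer scalar.
#' @export
setGeneric("nArticles", function(x) standardGeneric("nArticles"))

#' Entity id of a profile
#' @param x a [MeSHOP].
#' @return character scalar.
#' @export
setGeneric("entityId", function(x) standardGeneric("entityId"))

#' Annotation level: number of distinct terms in a profile
#'
#' The bias covariate of the correction procedure: how many distinct
#' vocabulary terms appear in the entity's bibliography.
#' @param x a [MeSHOP].
#' @return integer scalar.
#' @export
setGeneric("annotationLevel", function(x) standardGeneric("annotationLevel"))

#' Profile entries table
#' @param x a [MeSHOP].
#' @return data.frame with columns term, count, fraction, p_value, weight.
#' @export
setGeneric("profileEntries", function(x) standardGeneric("profileEntries"))

#' Score values matrix
#' @param x a [ScoreMatrix] or [CorrectedMatrix].
#' @return numeric matrix (drugs x diseases).
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))

#' Drug ids on the row axis
#' @param x a [ScoreMatrix], [CorrectedMatrix] or [LabelSet].
#' @return character vector.
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))

#' Disease ids on the column axis
#' @param x a [ScoreMatrix], [CorrectedMatrix] or [LabelSet].
#' @return character vector.
#' @export
setGeneric("diseaseIds", function(x) standardGeneric("diseaseIds"))

#' Metric specification of a score object
#' @param x a [ScoreMatrix] or [CorrectedMatrix].
#' @return a [MetricSpec].
#' @export
setGeneric("scoreMetric", function(x) standardGeneric("scoreMetric"))

#' Label matrix of a label set
#' @param x a [LabelSet].
#' @return character matrix with entries positive/negative/excluded.
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' ROC area under the curve
#'
#' Rank-sum (Mann-Whitney) AUC with average ranks for ties. The
#' [ScoreMatrix] method orients scores by the metric's polarity first so
#' that "more similar" always ranks higher.
#' @param scores a [ScoreMatrix], or a numeric vector of scores.
#' @param labels a [LabelSet], or a logical vector marking positives.
#' @param ... method-specific arguments.
#' @return AUC in [0, 1].
#' @export
setGeneric("rocAuc", function(scores, labels, ...) standardGeneric("rocAuc"))
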