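# The pairwise profile-similarity panel. Conventions for terms absent from
# a profile: p = 1, fraction = 0, count = 0, weight = 0. "All-terms" sums
# range over the union of terms present in either profile; "overlap-only"
# metrics use the intersection. log is the natural logarithm (a fixed base
# only rescales values and cannot change ranks or AUC).

.METRICS <- data.frame(
  metric_id = c("cosine_tfidf", "cosine_p", "cosine_fraction",
                "sum_log_combined_p", "sum_diff_log_p",
                "l2_logp_overlap", "l2_fraction_overlap",
                "l2_logp_all", "l2_p_all", "l2_fraction_all", "l2_freq_all",
                "term_coverage", "total_terms", "term_overlap",
                "n_drug_terms", "n_disease_terms"),
  polarity = c("higher-is-similar", "higher-is-similar", "higher-is-similar",
               "higher-is-similar", "lower-is-similar",
               "higher-is-similar", "higher-is-similar",
               "lower-is-similar", "lower-is-similar", "lower-is-similar",
               "lower-is-similar",
               "higher-is-similar", "higher-is-similar", "higher-is-similar",
               "higher-is-similar", "higher-is-similar"),
  domain = c("all-terms", "all-terms", "all-terms",
             "all-terms", "all-terms",
             "overlap-only", "overlap-only",
             "all-terms", "all-terms", "all-terms", "all-terms",
             "all-terms", "single-profile", "overlap-only",
             "single-profile", "single-profile"),
  use_magnitude = c(FALSE, FALSE, FALSE, FALSE, TRUE,
                    FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                    FALSE, FALSE, FALSE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

#' The registered similarity metrics
#'
#' The full scoring panel: three cosine similarities (tf-idf weights,
#' p-values, fractions), the sum of log combined p-values, the signed sum of
#' differences of log p-values (scored on its magnitude), Euclidean (L2)
#' distances of log-p and fractions over overlapping terms only and of
#' log-p / p / fractions / counts over all terms, and the counting measures:
#' term coverage |C u D|, total terms |C| + |D|, term overlap |C n D|, and
#' the single-profile baselines |C| and |D|. Each metric carries a polarity
#' (whether larger values mean a more similar pair) used to orient ROC
#' analysis and the bias correction; the overlap-restricted L2 metrics grow
#' with the shared-term set and are registered higher-is-similar.
#'
#' @return data.frame with columns metric_id, polarity, domain, use_magnitude.
#' @export
metricRegistry <- function() .METRICS

#' Look up one metric
#'
#' @param metricId a metric id from [metricRegistry()].
#' @param polarity optional override of the registered polarity.
#' @return a [MetricSpec].
#' @export
metricSpec <- function(metricId, polarity = NULL) {
  i <- match(metricId, .METRICS$metric_id)
  if (is.na(i)) stop("unknown metric: ", metricId, " (see metricRegistry())")
  new("MetricSpec", metricId = metricId,
      polarity = polarity %||% .METRICS$polarity[[i]],
      domain = .METRICS$domain[[i]],
      useMagnitude = .METRICS$use_magnitude[[i]])
}

.cosine <- function(a, b) {
  na2 <- sum(a * a); nb2 <- sum(b * b)
  if (na2 == 0 || nb2 == 0) return(0)
  sum(a * b) / sqrt(na2 * nb2)
}

# All metric values for one profile pair, as a named vector. Computing the
# whole panel per pair amortizes the union/match bookkeeping.
.scoreAll <- function(drugProfile, diseaseProfile) {
  ec <- drugProfile@entries
  ed <- diseaseProfile@entries
  tc <- ec$term; td <- ed$term
  u <- union(tc, td)
  ic <- match(u, tc); id <- match(u, td)
  inC <- !is.na(ic); inD <- !is.na(id)
  fill <- function(values, idx, default) {
    out <- rep(default, length(u))
    out[!is.na(idx)] <- values[idx[!is.na(idx)]]
    out
  }
  cp <- fill(ec$p_value, ic, 1); dp <- fill(ed$p_value, id, 1)
  cf <- fill(ec$fraction, ic, 0); df_ <- fill(ed$fraction, id, 0)
  cc <- fill(ec$count, ic, 0); dc <- fill(ed$count, id, 0)
  cw <- fill(ec$weight, ic, 0); dw <- fill(ed$weight, id, 0)
  lcp <- log(cp); ldp <- log(dp)
  ov <- inC & inD
  c(cosine_tfidf = .cosine(cw, dw),
    cosine_p = .cosine(cp, dp),
    cosine_fraction = .cosine(cf, df_),
    sum_log_combined_p = sum(log(cp + dp - cp * dp)),
    sum_diff_log_p = sum(lcp - ldp),
    l2_logp_overlap = sqrt(sum((lcp[ov] - ldp[ov])^2)),
    l2_fraction_overlap = sqrt(sum((cf[ov] - df_[ov])^2)),
    l2_logp_all = sqrt(sum((lcp - ldp)^2)),
    l2_p_all = sqrt(sum((cp - dp)^2)),
    l2_fraction_all = sqrt(sum((cf - df_)^2)),
    l2_freq_all = sqrt(sum((cc - dc)^2)),
    term_coverage = length(u),
    total_terms = length(tc) + length(td),
    term_overlap = sum(ov),
    n_drug_terms = length(tc),
    n_disease_terms = length(td))
}

#' Score one drug-disease profile pair
#'
#' @param metric a [MetricSpec] or metric id.
#' @param drugProfile,diseaseProfile [MeSHOP] objects built against the same
#'   background kind.
#' @return numeric scalar. The sum-of-differences-of-log-p metric returns
#'   its signed value; its polarity is applied to |value| downstream.
#' @export
scorePair <- function(metric, drugProfile, diseaseProfile) {
  if (is.character(metric)) metric <- metricSpec(metric)
  .checkBackgrounds(list(drugProfile), list(diseaseProfile))
  unname(.scoreAll(drugProfile, diseaseProfile)[[metric@metricId]])
}

.checkBackgrounds <- function(drugProfiles, diseaseProfiles) {
  kinds <- unique(vapply(c(drugProfiles, diseaseProfiles),
                         function(p) p@backgroundKind, character(1)))
  if (length(kinds) > 1L)
    stop("profiles were built against mismatched backgrounds: ",
         paste(kinds, collapse = ", "))
  invisible(kinds)
}

#' Score every drug against every disease
#'
#' @param metric a [MetricSpec] or metric id.
#' @param drugProfiles,diseaseProfiles named lists of [MeSHOP] objects
#'   sharing one background kind.
#' @return a [ScoreMatrix] (drugs on rows, diseases on columns).
#' @export
scoreMatrix <- function(metric, drugProfiles, diseaseProfiles) {
  if (is.character(metric)) metric <- metricSpec(metric)
  scorePanel(drugProfiles, diseaseProfiles, metrics = metric@metricId)[[metric@metricId]]
}

#' Score the full metric panel in one pass
#'
#' @param drugProfiles,diseaseProfiles named lists of [MeSHOP] objects.
#' @param metrics metric ids to compute; default the whole registry.
#' @return named list of [ScoreMatrix] objects.
#' @export
scorePanel <- function(drugProfiles, diseaseProfiles,
                       metrics = metricRegistry()$metric_id) {
  stopifnot(length(drugProfiles) >= 1L, length(diseaseProfiles) >= 1L)
  specs <- lapply(metrics, metricSpec)
  .checkBackgrounds(drugProfiles, diseaseProfiles)
  dn <- vapply(drugProfiles, entityId, character(1))
  zn <- vapply(diseaseProfiles, entityId, character(1))
  vals <- array(NA_real_, dim = c(length(dn), length(zn), length(metrics)),
                dimnames = list(dn, zn, metrics))
  for (j in seq_along(diseaseProfiles)) {
    pd <- diseaseProfiles[[j]]
    for (i in seq_along(drugProfiles)) {
      vals[i, j, ] <- .scoreAll(drugProfiles[[i]], pd)[metrics]
    }
  }
  out <- lapply(seq_along(metrics), function(m)
    new("ScoreMatrix", metric = specs[[m]],
        values = matrix(vals[, , m], nrow = length(dn),
                        dimnames = list(dn, zn))))
  names(out) <- metrics
  out
}

#' Orient scores so that larger always means more similar
#'
#' Applies the metric's polarity (and magnitude scoring where registered):
#' the returned values rank pairs from least to most similar regardless of
#' the metric's natural direction.
#'
#' @param values numeric vector/matrix of raw metric values.
#' @param metric a [MetricSpec] or metric id.
#' @return numeric of the same shape.
#' @export
orientScores <- function(values, metric) {
  if (is.character(metric)) metric <- metricSpec(metric)
  if (metric@useMagnitude) values <- -abs(values)
  else if (metric@polarity == "lower-is-similar") values <- -values
  values
}

#' @describeIn scoreMatrix score values.
#' @export
setMethod("scoreValues", "ScoreMatrix", function(x) x@values)

#' @describeIn scoreMatrix drug axis.
#' @export
setMethod("drugIds", "ScoreMatrix", function(x) rownames(x@values))

#' @describeIn scoreMatrix disease axis.
#' @export
setMethod("diseaseIds", "ScoreMatrix", function(x) colnames(x@values))

#' @describeIn scoreMatrix metric specification.
#' @export
setMethod("scoreMetric", "ScoreMatrix", function(x) x@metric)

#' @describeIn scoreMatrix compact display.
#' @param object a [ScoreMatrix].
#' @export
setMethod("show", "ScoreMatrix", function(object) {
  cat("ScoreMatrix [", object@metric@metricId, ", ", object@metric@polarity,
      "]: ", nrow(object@values), " drugs x ", ncol(object@values),
      " diseases\n", sep = "")
})

#' Write score matrices in long format
#'
#' TSV with header `drug_id, disease_id, metric_id, score`.
#'
#' @param scores a [ScoreMatrix] or named list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeScores <- function(scores, path) {
  if (is(scores, "ScoreMatrix")) scores <- list(scores)
  parts <- lapply(scores, function(s) {
    v <- s@values
    data.frame(drug_id = rep(rownames(v), times = ncol(v)),
               disease_id = rep(colnames(v), each = nrow(v)),
               metric_id = s@metric@metricId,
               score = as.vector(v), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, parts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read score matrices written by [writeScores()]
#'
#' @param path TSV path.
#' @return named list of [ScoreMatrix] objects, one per metric_id present.
#' @export
readScores <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = c(drug_id = "character",
                                         disease_id = "character",
                                         metric_id = "character"))
  lapply(split(df, df$metric_id), function(d) {
    drugs <- unique(d$drug_id); dis <- unique(d$disease_id)
    v <- matrix(NA_real_, length(drugs), length(dis),
                dimnames = list(drugs, dis))
    v[cbind(d$drug_id, d$disease_id)] <- as.numeric(d$score)
    new("ScoreMatrix", metric = metricSpec(d$metric_id[[1L]]), values = v)
  })
}
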