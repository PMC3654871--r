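# Over-representation profile construction. For each entity: the observed
# count of every term across the bibliography, its fraction of the
# bibliography, a one-sided hypergeometric (Fisher exact) enrichment p-value
# against a background article set, and a tf-idf weight.

P_FLOOR <- 1e-300  # clamp applied before any downstream logarithm

#' Term counts over a background article set
#'
#' @param corpus a [Corpus].
#' @param subset optional character vector of article ids restricting the
#'   background; defaults to the whole corpus.
#' @param kind "universal" (all articles) or "class-specific" (articles
#'   associated with at least one entity of a class; the caller supplies the
#'   corresponding subset, see [classBackground()]).
#' @return a [Background].
#' @export
backgroundCounts <- function(corpus, subset = NULL,
                             kind = c("universal", "class-specific")) {
  stopifnot(is(corpus, "Corpus"))
  kind <- match.arg(kind)
  if (is.null(subset)) {
    keep <- seq_along(corpus@articleIds)
  } else {
    bad <- setdiff(subset, corpus@articleIds)
    if (length(bad))
      stop("background subset contains unknown article ids: ",
           paste(utils::head(bad, 3), collapse = ", "))
    keep <- which(corpus@articleIds %in% subset)
  }
  if (!length(keep)) stop("empty background")
  flat <- unlist(corpus@terms[keep], use.names = FALSE)
  counts <- table(flat)
  new("Background",
      termCounts = stats::setNames(as.numeric(counts), names(counts)),
      nTotal = length(keep), kind = kind)
}

#' Class-specific background
#'
#' Background over the articles associated with at least one entity of the
#' given class (i.e. carrying some entity's defining term post-propagation).
#'
#' @param corpus a [Corpus].
#' @param entities an [EntitySet].
#' @param class "drug" or "disease".
#' @return a [Background] of kind "class-specific".
#' @export
classBackground <- function(corpus, entities, class = c("drug", "disease")) {
  class <- match.arg(class)
  terms <- entityTable(entities, class)$defining_term
  ids <- sort(unique(unlist(corpus@termIndex[intersect(terms, names(corpus@termIndex))],
                            use.names = FALSE)))
  backgroundCounts(corpus, subset = ids, kind = "class-specific")
}

#' Upper tail of the hypergeometric distribution
#'
#' P(X >= k) for X ~ Hypergeometric(N total, K marked, n drawn) — the
#' one-sided over-representation (Fisher exact) p-value for observing k
#' marked articles in a bibliography of n drawn from a background of N of
#' which K carry the term. Vectorized over all arguments; the result is
#' clamped below at 1e-300 so it is always in (0, 1].
#'
#' @param k observed count(s), 0 <= k <= n, k <= K.
#' @param n bibliography size(s).
#' @param K background count(s) of the term.
#' @param N background size(s).
#' @return numeric vector of upper-tail probabilities in (0, 1].
#' @examples
#' hypergeomUpperTail(4, 4, 5, 10)  # 5/210
#' @export
hypergeomUpperTail <- function(k, n, K, N) {
  if (any(k < 0 | n < 0 | K < 0 | N < 1))
    stop("negative margins")
  if (any(k > n) || any(n > N) || any(k > K) || any(K > N))
    stop("margin violation: need 0 <= k <= n <= N and k <= K <= N")
  pmax(stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE), P_FLOOR)
}

#' Build the over-representation profile of one entity
#'
#' Counts every term across the entity's bibliography and attaches, per
#' term: the bibliography fraction k/n, the one-sided hypergeometric
#' enrichment p-value against the background (floored at 1e-300) and a
#' tf-idf weight f * ln(N / K). Entries are sorted by ascending p-value,
#' ties broken by term id. All observed terms are kept: downstream metrics
#' need the full vector, and thresholding would silently change the profile
#' term sets.
#'
#' @param corpus a [Corpus].
#' @param entity one row of [entityTable()] (needs `entity_id` and
#'   `defining_term`).
#' @param background a [Background]; the bibliography must be contained in
#'   it (always true for a universal background over the same corpus).
#' @return a [MeSHOP].
#' @export
buildProfile <- function(corpus, entity, background) {
  stopifnot(is(corpus, "Corpus"), is(background, "Background"))
  bib <- bibliography(corpus, entity)
  id <- if (is.character(entity)) entity else entity$entity_id
  if (!length(bib))
    stop("empty bibliography for entity ", id)
  idx <- match(bib, corpus@articleIds)
  flat <- unlist(corpus@terms[idx], use.names = FALSE)
  tab <- table(flat)
  terms <- names(tab)
  k <- as.numeric(tab)
  n <- length(bib)
  N <- background@nTotal
  K <- unname(background@termCounts[terms])
  if (any(is.na(K)) || any(k > K))
    stop("bibliography not contained in the background (term counts exceed ",
         "background counts); use a background covering the bibliography")
  p <- hypergeomUpperTail(k, n, K, N)
  f <- k / n
  w <- f * log(N / K)
  ord <- order(p, terms)
  entries <- data.frame(term = terms[ord], count = k[ord], fraction = f[ord],
                        p_value = p[ord], weight = w[ord],
                        stringsAsFactors = FALSE)
  defterm <- if (is.character(entity)) entity else entity$defining_term
  new("MeSHOP", entityId = id, definingTerm = defterm,
      nArticles = as.integer(n), entries = entries,
      backgroundKind = background@kind)
}

#' Build profiles for many entities
#'
#' Entities with empty bibliographies are skipped and reported via the
#' "skipped" attribute of the result (the standard treatment for entities
#' with no literature before a temporal cutoff).
#'
#' @param corpus a [Corpus].
#' @param entities an [EntitySet] or entity data.frame.
#' @param background a [Background].
#' @param class optional class filter passed to [entityTable()].
#' @return named list of [MeSHOP] objects, with attribute `skipped` holding
#'   the ids of entities without articles.
#' @export
buildProfiles <- function(corpus, entities, background, class = NULL) {
  df <- if (is(entities, "EntitySet")) entityTable(entities, class) else entities
  out <- list()
  skipped <- character(0)
  for (i in seq_len(nrow(df))) {
    row <- df[i, , drop = FALSE]
    if (!length(bibliography(corpus, row))) {
      skipped <- c(skipped, row$entity_id)
      next
    }
    out[[row$entity_id]] <- buildProfile(corpus, row, background)
  }
  attr(out, "skipped") <- skipped
  out
}

#' @describeIn annotationLevel number of distinct terms with count >= 1.
#' @export
setMethod("annotationLevel", "MeSHOP", function(x) nrow(x@entries))

#' @describeIn entityId profile entity id.
#' @export
setMethod("entityId", "MeSHOP", function(x) x@entityId)

#' @describeIn nArticles bibliography size of a profile.
#' @export
setMethod("nArticles", "MeSHOP", function(x) x@nArticles)

#' @describeIn profileEntries the per-term table.
#' @export
setMethod("profileEntries", "MeSHOP", function(x) x@entries)

#' @describeIn buildProfile compact display.
#' @param object a [MeSHOP].
#' @export
setMethod("show", "MeSHOP", function(object) {
  cat("MeSHOP for", object@entityId, "(", object@nArticles, "articles,",
      nrow(object@entries), "terms,", object@backgroundKind, "background )\n")
  print(utils::head(object@entries, 5))
  if (nrow(object@entries) > 5) cat("...", nrow(object@entries) - 5, "more terms\n")
})

#' Write profiles to TSV
#'
#' Long format with header `entity_id, term_id, count, fraction, p_value,
#' weight`, one row per profile entry, rows in the profile's deterministic
#' order (ascending p-value, then term id).
#'
#' @param profiles list of [MeSHOP] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProfiles <- function(profiles, path) {
  parts <- lapply(profiles, function(p) {
    cbind(entity_id = p@entityId,
          term_id = p@entries$term,
          defining_term = p@definingTerm,
          p@entries[c("count", "fraction", "p_value", "weight")])
  })
  df <- do.call(rbind, parts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read profiles written by [writeProfiles()]
#'
#' @param path TSV path.
#' @param backgroundKind the background kind the profiles were built against.
#' @return named list of [MeSHOP] objects.
#' @export
readProfiles <- function(path, backgroundKind = "universal") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = c(entity_id = "character",
                                         term_id = "character",
                                         defining_term = "character"))
  out <- lapply(split(df, df$entity_id), function(d) {
    d <- d[order(d$p_value, d$term_id), , drop = FALSE]
    entries <- data.frame(term = d$term_id, count = as.numeric(d$count),
                          fraction = as.numeric(d$fraction),
                          p_value = as.numeric(d$p_value),
                          weight = as.numeric(d$weight),
                          stringsAsFactors = FALSE)
    new("MeSHOP", entityId = d$entity_id[[1L]],
        definingTerm = d$defining_term[[1L]],
        nArticles = as.integer(max(entries$count)),
        entries = entries, backgroundKind = backgroundKind)
  })
  out[unique(df$entity_id)]
}
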