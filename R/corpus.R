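# Annotated corpus: JSON-lines I/O, ancestor propagation, inverted term
# index, bibliographies. The on-disk format stores the raw curator-assigned
# terms; propagation to ancestors is a load-time method step, and raw terms
# are kept so a loaded corpus round-trips unchanged.

#' Load an annotated article corpus
#'
#' Reads a JSON-lines file (one object per line with fields `article_id`,
#' `year`, `terms`), replaces every article's term set by its ancestor
#' closure under `tree`, and builds the inverted term -> article index.
#' Annotation terms absent from the tree are legal (e.g. supplementary
#' concepts outside the hierarchy): they are kept as annotations, contribute
#' no ancestors, and are listed in the load report.
#'
#' @param path path to the JSON-lines corpus file.
#' @param tree a [TermTree] used for propagation.
#' @return a [Corpus].
#' @seealso [writeCorpus()], [bibliography()]
#' @export
loadCorpus <- function(path, tree) {
  stopifnot(is(tree, "TermTree"))
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  recs <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) stop("corpus line ", i,
                                             ": invalid JSON (", conditionMessage(e), ")"))
    for (f in c("article_id", "year", "terms"))
      if (is.null(rec[[f]])) stop("corpus line ", i, ": missing field '", f, "'")
    rec
  })
  ids <- vapply(recs, function(r) as.character(r$article_id), character(1))
  if (anyDuplicated(ids))
    stop("duplicate article_id in corpus: ", ids[duplicated(ids)][1L])
  years <- vapply(recs, function(r) as.integer(r$year), integer(1))
  raw <- lapply(recs, function(r) unique(as.character(r$terms)))
  .buildCorpus(ids, years, raw, tree)
}

.buildCorpus <- function(ids, years, raw, tree) {
  known <- treeTerms(tree)
  prop <- lapply(raw, function(tt) .propagate(tt, tree))
  unknown <- sort(unique(as.character(unlist(raw, use.names = FALSE))))
  unknown <- as.character(setdiff(unknown, known))
  new("Corpus", articleIds = ids, years = years, terms = prop,
      rawTerms = raw, termIndex = .invertIndex(ids, prop),
      unknownTerms = unknown)
}

.propagate <- function(terms, tree) {
  anc <- unlist(tree@ancestors[intersect(terms, names(tree@ancestors))],
                use.names = FALSE)
  sort(unique(c(terms, anc)))
}

.invertIndex <- function(ids, termSets) {
  if (!length(ids)) return(structure(list(), names = character(0)))
  flatTerms <- unlist(termSets, use.names = FALSE)
  flatIds <- rep(ids, lengths(termSets))
  lapply(split(flatIds, flatTerms), function(x) sort(unique(x)))
}

#' Write a corpus back to JSON-lines
#'
#' Emits the raw (pre-propagation) annotations, so that writing and
#' reloading a corpus yields identical indexes.
#'
#' @param corpus a [Corpus].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCorpus <- function(corpus, path) {
  stopifnot(is(corpus, "Corpus"))
  lines <- vapply(seq_along(corpus@articleIds), function(i) {
    jsonlite::toJSON(list(article_id = jsonlite::unbox(corpus@articleIds[[i]]),
                          year = jsonlite::unbox(corpus@years[[i]]),
                          terms = corpus@rawTerms[[i]]))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Restrict a corpus to articles up to a given year
#'
#' Used to build profiles from the pre-cutoff literature before temporal
#' validation. Propagated term sets are preserved; the term index is rebuilt
#' over the retained articles.
#'
#' @param corpus a [Corpus].
#' @param yearMax keep articles with year <= `yearMax`.
#' @return a [Corpus].
#' @export
filterCorpus <- function(corpus, yearMax) {
  stopifnot(is(corpus, "Corpus"))
  keep <- which(corpus@years <= yearMax)
  new("Corpus",
      articleIds = corpus@articleIds[keep],
      years = corpus@years[keep],
      terms = corpus@terms[keep],
      rawTerms = corpus@rawTerms[keep],
      termIndex = .invertIndex(corpus@articleIds[keep], corpus@terms[keep]),
      unknownTerms = corpus@unknownTerms)
}

#' Bibliography of an entity
#'
#' The set of article ids annotated (post-propagation) with the entity's
#' defining term. No year filtering happens here; temporal cuts belong to
#' validation (see [filterCorpus()]).
#'
#' @param corpus a [Corpus].
#' @param entity an entity record (one row of [entityTable()]) or a defining
#'   term id.
#' @return character vector of article ids (possibly empty).
#' @export
bibliography <- function(corpus, entity) {
  stopifnot(is(corpus, "Corpus"))
  term <- if (is.character(entity)) entity else entity$defining_term
  stopifnot(length(term) == 1L)
  corpus@termIndex[[term]] %||% character(0)
}

#' Articles annotated with a term
#' @param corpus a [Corpus].
#' @param term a term id.
#' @return character vector of article ids carrying the term post-propagation.
#' @export
articlesWithTerm <- function(corpus, term) corpus@termIndex[[term]] %||% character(0)

#' Article years
#' @param corpus a [Corpus].
#' @return named integer vector of publication years.
#' @export
articleYears <- function(corpus) stats::setNames(corpus@years, corpus@articleIds)

#' @describeIn nArticles corpus size.
#' @export
setMethod("nArticles", "Corpus", function(x) length(x@articleIds))

#' Terms absent from the tree seen in corpus annotations
#' @param corpus a [Corpus].
#' @return character vector (the load report's unknown-term list).
#' @export
unknownTerms <- function(corpus) corpus@unknownTerms

#' @describeIn loadCorpus compact display.
#' @param object a [Corpus].
#' @export
setMethod("show", "Corpus", function(object) {
  yr <- if (length(object@years)) paste0(min(object@years), "-", max(object@years)) else "-"
  cat("Corpus with", length(object@articleIds), "articles (", yr, "),",
      length(object@termIndex), "indexed terms,",
      length(object@unknownTerms), "terms outside the tree\n")
})
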