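# Vocabulary tree: loading, parenthood via tree-number prefixes, ancestor
# closure. Parenthood follows tree-number semantics: the parent position of
# "C04.557.337" is "C04.557"; the parent *term* is the owner of the first
# owned prefix (unowned prefixes are skipped and reported as dangling).

#' Load a vocabulary tree from a two-column TSV
#'
#' The file has no header and two tab-separated columns: term id and
#' dot-delimited tree number. A term may appear on several lines (one per
#' tree position). The strict-ancestor closure of every term is computed at
#' load: the one-step parents of a term are the owners of the first owned
#' prefix of each of its tree numbers, and the closure is the transitive
#' expansion of that relation. Prefixes owned by no term are skipped
#' silently, but recorded in the dangling-prefix report.
#'
#' @param path path to the TSV file.
#' @return a [TermTree].
#' @examples
#' f <- tempfile()
#' writeLines(c("X\tA01", "Y\tA01.200", "Z\tA01.200.300"), f)
#' tree <- loadTermTree(f)
#' termAncestors(tree, "Z")
#' @export
loadTermTree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop("malformed tree line ", bad[1L], ": expected 2 tab-separated columns, got ",
         lengths(fields)[bad[1L]])
  term <- vapply(fields, `[[`, character(1), 1L)
  num  <- vapply(fields, `[[`, character(1), 2L)
  if (anyDuplicated(num)) {
    d <- num[duplicated(num)][1L]
    stop("tree number assigned to multiple terms: ", d)
  }
  treeNumbers <- lapply(split(num, term), unique)
  numberOwner <- stats::setNames(term, num)

  terms <- names(treeNumbers)
  dangling <- character(0)
  parents <- vector("list", length(terms))
  names(parents) <- terms
  for (t in terms) {
    ps <- character(0)
    for (tn in treeNumbers[[t]]) {
      cur <- tn
      repeat {
        cur <- .parentNumber(cur)
        if (is.na(cur)) break
        owner <- unname(numberOwner[cur])
        if (is.na(owner)) {
          dangling <- c(dangling, cur)
        } else if (owner != t) {
          ps <- c(ps, owner)
          break
        }
        # owner == t (a term occupying nested positions): keep walking
      }
    }
    parents[[t]] <- unique(ps)
  }
  dangling <- sort(unique(dangling))

  # transitive closure by memoized ascent (cycle-guarded; input trees are
  # acyclic but malformed input must not hang the loader)
  anc <- vector("list", length(terms))
  names(anc) <- terms
  getAnc <- function(t, stack) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    res <- character(0)
    for (p in parents[[t]]) {
      if (p %in% stack) next
      res <- union(res, c(p, getAnc(p, c(stack, t))))
    }
    res <- sort(setdiff(res, t))
    anc[[t]] <<- res
    res
  }
  for (t in terms) getAnc(t, character(0))

  new("TermTree", treeNumbers = treeNumbers, numberOwner = numberOwner,
      ancestors = anc, dangling = dangling)
}

.parentNumber <- function(num) {
  parts <- strsplit(num, ".", fixed = TRUE)[[1L]]
  if (length(parts) < 2L) return(NA_character_)
  paste(parts[-length(parts)], collapse = ".")
}

#' Strict ancestors of a term
#'
#' @param tree a [TermTree].
#' @param term a term id known to the tree.
#' @return character vector of all strict ancestors (the term itself is
#'   excluded); the union over all the term's tree positions.
#' @export
termAncestors <- function(tree, term) {
  stopifnot(is(tree, "TermTree"))
  a <- tree@ancestors[[term]]
  if (is.null(a)) stop("unknown term: ", term)
  a
}

#' Terms known to a tree
#' @param tree a [TermTree].
#' @return character vector of term ids.
#' @export
treeTerms <- function(tree) names(tree@treeNumbers)

#' Dangling tree-number prefixes found at load
#' @param tree a [TermTree].
#' @return character vector of prefixes no term owns.
#' @export
danglingPrefixes <- function(tree) tree@dangling

#' @describeIn loadTermTree compact display.
#' @param object a [TermTree].
#' @export
setMethod("show", "TermTree", function(object) {
  cat("TermTree with", length(object@treeNumbers), "terms,",
      length(object@numberOwner), "tree numbers,",
      length(object@dangling), "dangling prefixes\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a
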