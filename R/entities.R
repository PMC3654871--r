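# Entity definition tables: drugs (pharmacologic-compound terms) and
# diseases (disease-category terms), each defined by one vocabulary term
# whose bibliography is the entity's literature.

#' Load an entity definition table
#'
#' TSV with a required header row and columns `entity_id`, `class`
#' (`drug` or `disease`) and `defining_term`. When a tree is supplied every
#' defining term must exist in it.
#'
#' @param path path to the TSV file.
#' @param tree optional [TermTree] to validate defining terms against.
#' @return an [EntitySet].
#' @export
loadEntities <- function(path, tree = NULL) {
  if (!file.exists(path)) stop("entity file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  need <- c("entity_id", "class", "defining_term")
  if (!all(need %in% names(df)))
    stop("entity file must have header columns: ", paste(need, collapse = ", "))
  es <- entitySet(df[need], tree = tree)
  es
}

#' Construct an entity set from a data.frame
#'
#' @param df data.frame with columns `entity_id`, `class`, `defining_term`.
#' @param tree optional [TermTree]; when given, defining terms must be known.
#' @return an [EntitySet].
#' @export
entitySet <- function(df, tree = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  if (!is.null(tree)) {
    missing <- setdiff(unique(df$defining_term), treeTerms(tree))
    if (length(missing))
      stop("defining terms absent from the tree: ",
           paste(utils::head(missing, 5), collapse = ", "))
  }
  new("EntitySet", entities = df)
}

#' Write an entity set to TSV
#' @param entities an [EntitySet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEntities <- function(entities, path) {
  stopifnot(is(entities, "EntitySet"))
  utils::write.table(entities@entities, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Entity table
#' @param entities an [EntitySet].
#' @param class optional filter, "drug" or "disease".
#' @return data.frame with columns entity_id, class, defining_term.
#' @export
entityTable <- function(entities, class = NULL) {
  stopifnot(is(entities, "EntitySet"))
  df <- entities@entities
  if (!is.null(class)) df <- df[df$class == class, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @describeIn loadEntities compact display.
#' @param object an [EntitySet].
#' @export
setMethod("show", "EntitySet", function(object) {
  cl <- table(factor(object@entities$class, levels = c("drug", "disease")))
  cat("EntitySet with", cl[["drug"]], "drugs and", cl[["disease"]], "diseases\n")
})
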