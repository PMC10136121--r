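#' Read and write Newick trees
#'
#' Thin validating wrappers around ape's Newick parser. Branch lengths are
#' accepted and preserved but never used by the parsimony machinery.
#'
#' @param source path to a Newick file, or a Newick string.
#' @return an [ape::read.tree()] `"phylo"` object.
#' @export
read_newick <- function(source) {
  text <- if (length(source) == 1L && !grepl("[();]", source)) {
    if (!file.exists(source)) stop_parse(sprintf("file not found: %s", source))
    paste(readLines(source, warn = FALSE), collapse = "")
  } else paste(source, collapse = "")
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop_parse(sprintf("unbalanced parentheses in Newick: %d '(' vs %d ')'",
                       n_open, n_close))
  tree <- tryCatch(ape::read.tree(text = text), error = function(e)
    stop_parse(paste("Newick parse failure:", conditionMessage(e))))
  if (is.null(tree)) stop_parse("Newick parse failure")
  if (anyDuplicated(tree$tip.label))
    stop_parse(sprintf("duplicate tip name: %s",
                       tree$tip.label[duplicated(tree$tip.label)][1L]))
  if (any(!nzchar(tree$tip.label))) stop_parse("empty tip name in Newick")
  tree
}

#' @rdname read_newick
#' @param tree a `"phylo"` object.
#' @param path output file; if `NULL` the Newick string is returned.
#' @export
write_newick <- function(tree, path = NULL) {
  text <- ape::write.tree(tree)
  if (!is.null(path)) writeLines(text, path)
  invisible(text)
}
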