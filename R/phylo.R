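#' Encode character-matrix columns for ancestral reconstruction
#'
#' `binary` mode scores each site as `"1"` (the anaerobic residue) versus
#' `"0"` (any other residue); `residue` mode keeps the raw amino acids.
#' Missing states become `"?"`, the uninformative full state set.
#'
#' @param mat a character matrix from [read_character_matrix()].
#' @param panel a `"marker_panel"`; required for `binary` mode.
#' @param mode `"binary"` or `"residue"`.
#' @param tree optional `"phylo"` tree; species absent from the tree are
#'   handled per `on_extra_species`.
#' @param on_extra_species `"drop"` (with a warning) or `"error"`.
#' @return a character matrix (species x sites) over the encoded states.
#' @export
encode_characters <- function(mat, panel = default_panel(),
                              mode = c("binary", "residue"), tree = NULL,
                              on_extra_species = c("drop", "error")) {
  mode <- match.arg(mode)
  on_extra_species <- match.arg(on_extra_species)
  if (!is.null(tree)) {
    extra <- setdiff(rownames(mat), tree$tip.label)
    if (length(extra)) {
      if (on_extra_species == "error")
        stop_usage(paste("species absent from tree:", paste(extra, collapse = ", ")))
      warning("dropping species absent from tree: ",
              paste(extra, collapse = ", "))
      mat <- mat[setdiff(rownames(mat), extra), , drop = FALSE]
    }
  }
  if (mode == "residue") {
    out <- mat
    out[is.na(out)] <- "?"
    return(out)
  }
  labels <- panel_site_labels(panel)
  if (!setequal(colnames(mat), labels))
    stop_usage("matrix sites do not match the panel sites")
  mat <- mat[, labels, drop = FALSE]
  anaerobic <- unlist(lapply(panel, function(m) m$sites$anaerobic_residue),
                      use.names = FALSE)
  out <- matrix("?", nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (k in seq_len(ncol(mat))) {
    known <- !is.na(mat[, k])
    out[known, k] <- ifelse(mat[known, k] == anaerobic[k], "1", "0")
  }
  out
}

# Root an unrooted binary tree deterministically; reject polytomies
# (equal-cost Fitch on a hard polytomy is not the same problem).
prepare_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop_usage("tree must be a \"phylo\" object")
  if (!ape::is.rooted(tree))
    tree <- ape::root(tree, outgroup = tree$tip.label[1L], resolve.root = TRUE)
  if (!ape::is.binary(tree))
    stop_usage("tree must be fully bifurcating for Fitch parsimony")
  tree
}

#' Fitch-parsimony ancestral-state reconstruction of one character
#'
#' Standard small-parsimony on a rooted bifurcating tree: the bottom-up
#' pass takes the intersection of the child state sets where non-empty and
#' otherwise their union, counting one change per union; `"?"` tips carry
#' the full observed-state alphabet. The top-down pass resolves preferred
#' node sets by intersection with the parent's resolved set (falling back
#' to the node's own preliminary set when the intersection is empty). Tied
#' root or node states are reported as sets, never arbitrarily resolved.
#'
#' @param tree a rooted bifurcating `"phylo"` tree (an unrooted binary tree
#'   is rooted deterministically at its first tip).
#' @param character named character vector of tip states (`"?"` or `NA` for
#'   missing); names must match tip labels. Tips absent from the vector are
#'   treated as `"?"`.
#' @param label character label carried into the result.
#' @return an object of class `"fitch_reconstruction"`: `label`,
#'   `min_changes`, `root_states`, `node_states` (preliminary sets, one per
#'   node in ape node order), `preferred_states` (top-down resolved sets),
#'   `alphabet`, and the (possibly re-rooted) `tree`.
#' @examples
#' tr <- read_newick("((A,B),(C,D));")
#' fitch(tr, c(A = "1", B = "0", C = "1", D = "0"))$min_changes  # 2
#' @export
fitch <- function(tree, character, label = "character") {
  tree <- prepare_tree(tree)
  ntip <- length(tree$tip.label)
  states <- rep("?", ntip)
  names(states) <- tree$tip.label
  known <- intersect(names(character), tree$tip.label)
  states[known] <- as.character(character[known])
  states[is.na(states)] <- "?"
  alphabet <- sort(unique(states[states != "?"]))
  if (length(alphabet) == 0L)
    stop_data(sprintf("uninformative character '%s': all tip states missing", label))
  if (sum(states != "?") < 2L)
    stop_data(sprintf("character '%s' has fewer than two informative tips", label))
  full <- rep(TRUE, length(alphabet))
  nnode <- ntip + tree$Nnode
  sets <- matrix(FALSE, nnode, length(alphabet))
  for (i in seq_len(ntip))
    sets[i, ] <- if (states[i] == "?") full else alphabet == states[i]
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  min_changes <- 0L
  done <- logical(nnode)
  done[seq_len(ntip)] <- TRUE
  # children arrive consecutively in postorder; combine pairwise
  for (parent in unique(edges[, 1L])) {
    kids <- edges[edges[, 1L] == parent, 2L]
    acc <- sets[kids[1L], ]
    for (k in kids[-1L]) {
      inter <- acc & sets[k, ]
      if (any(inter)) acc <- inter
      else { acc <- acc | sets[k, ]; min_changes <- min_changes + 1L }
    }
    sets[parent, ] <- acc
  }
  root <- ntip + 1L
  preferred <- sets
  pre <- edges[rev(seq_len(nrow(edges))), , drop = FALSE]  # preorder
  for (e in seq_len(nrow(pre))) {
    parent <- pre[e, 1L]; child <- pre[e, 2L]
    inter <- sets[child, ] & preferred[parent, ]
    if (any(inter)) preferred[child, ] <- inter
  }
  to_sets <- function(m) apply(m, 1L, function(row) alphabet[row],
                               simplify = FALSE)
  structure(list(label = label, min_changes = min_changes,
                 root_states = alphabet[sets[root, ]],
                 node_states = to_sets(sets),
                 preferred_states = to_sets(preferred),
                 alphabet = alphabet, tree = tree),
            class = "fitch_reconstruction")
}

#' @export
print.fitch_reconstruction <- function(x, ...) {
  cat(sprintf("Fitch reconstruction of %s: %d change(s), root {%s}\n",
              x$label, x$min_changes, paste(x$root_states, collapse = ",")))
  invisible(x)
}

#' Ancestral state set of a named clade
#'
#' @param recon a `"fitch_reconstruction"`.
#' @param clade_tips tip labels whose most recent common ancestor is reported.
#' @param preferred use the top-down resolved sets (default) rather than the
#'   preliminary bottom-up sets.
#' @return character vector of states at the clade's MRCA.
#' @export
clade_ancestor_states <- function(recon, clade_tips, preferred = TRUE) {
  tree <- recon$tree
  missing_tips <- setdiff(clade_tips, tree$tip.label)
  if (length(missing_tips))
    stop_usage(paste("clade tips absent from tree:",
                     paste(missing_tips, collapse = ", ")))
  node <- if (length(clade_tips) == 1L) match(clade_tips, tree$tip.label)
          else ape::getMRCA(tree, clade_tips)
  if (preferred) recon$preferred_states[[node]] else recon$node_states[[node]]
}

#' Reconstruct all sites of a character matrix on a tree
#'
#' Runs [fitch()] per site and tabulates the minimum change counts and the
#' root (and optionally a named clade ancestor's) state sets.
#'
#' @inheritParams encode_characters
#' @param tree a rooted bifurcating `"phylo"` tree.
#' @param clade_tips optional tip set whose MRCA states are reported per
#'   site (e.g. the cnidarian tips, to read the cnidarian ancestor).
#' @return a list of class `"rq_ancestral"`: `reconstructions` (named list)
#'   and `summary` (data.frame with `site`, `min_changes`, `root_states`,
#'   and `clade_states` when `clade_tips` is given).
#' @export
reconstruct_all <- function(tree, mat, panel = default_panel(),
                            mode = c("binary", "residue"), clade_tips = NULL) {
  mode <- match.arg(mode)
  enc <- encode_characters(mat, panel, mode, tree = tree)
  recons <- lapply(colnames(enc), function(lb)
    fitch(tree, setNames(enc[, lb], rownames(enc)), label = lb))
  names(recons) <- colnames(enc)
  fmt <- function(x) paste(x, collapse = "/")
  summary <- data.frame(
    site = colnames(enc),
    min_changes = vapply(recons, `[[`, 0L, "min_changes"),
    root_states = vapply(recons, function(r) fmt(r$root_states), ""),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(clade_tips))
    summary$clade_states <- vapply(recons, function(r)
      fmt(clade_ancestor_states(r, clade_tips)), "")
  structure(list(reconstructions = recons, summary = summary),
            class = "rq_ancestral")
}

#' @export
print.rq_ancestral <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Newick with ancestral-state node comments
#'
#' @param recon a `"fitch_reconstruction"`.
#' @return a Newick string whose internal node labels carry the preferred
#'   state sets (e.g. `"1"` or `"0|1"`).
#' @export
ancestral_newick <- function(recon) {
  tree <- recon$tree
  ntip <- length(tree$tip.label)
  tree$node.label <- vapply(
    (ntip + 1L):(ntip + tree$Nnode),
    function(n) paste(recon$preferred_states[[n]], collapse = "|"), "")
  ape::write.tree(tree)
}
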