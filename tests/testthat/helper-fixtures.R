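# Shared fixtures: synthetic marker references (seed fixed once) and the
# panel built on them; everything is generated in code at test time.
ref_set <- make_reference_set(42)
ref_panel <- default_panel(ref_set)
survey <- read_character_matrix(rq_survey_path())
cnidarians <- setdiff(rownames(survey), rq_reference_species)

random_protein_str <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE),
        collapse = "")
}

# Exhaustive small-parsimony oracle: minimizes changes over all internal
# labelings and all assignments of "?" tips. Independent of fitch().
brute_fitch <- function(tree, states) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  alpha <- sort(unique(states[states != "?"]))
  tipsets <- lapply(tree$tip.label, function(t) {
    s <- states[[t]]
    if (is.null(s) || is.na(s) || s == "?") alpha else s
  })
  internals <- (ntip + 1L):nn
  grid <- do.call(expand.grid,
                  c(rep(list(alpha), length(internals)),
                    stringsAsFactors = FALSE))
  qt <- which(vapply(tipsets, length, 1L) > 1L)
  enum_tips <- if (length(qt))
    do.call(expand.grid, c(lapply(qt, function(i) alpha),
                           stringsAsFactors = FALSE))
  else data.frame(row.names = 1)
  best <- Inf
  lab <- character(nn)
  for (i in seq_len(ntip)) if (!(i %in% qt)) lab[i] <- tipsets[[i]]
  for (g in seq_len(nrow(grid))) {
    lab[internals] <- unlist(grid[g, ])
    for (e in seq_len(nrow(enum_tips))) {
      for (q in seq_along(qt)) lab[qt[q]] <- enum_tips[e, q]
      best <- min(best, sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]]))
    }
  }
  best
}
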