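#' The four-marker rhodoquinone diagnostic panel
#'
#' Builds the marker panel used throughout the screen: COQ-2 with two
#' diagnostic sites (L204, S243, close to the substrate in the active
#' site), the Complex II subunit MEV-1 (G71, near the rhodoquinone ring's
#' binding site), TDO-2 (P133, part of the PLD loop), and ETFDH (F437, near
#' the quinone binding site). Positions are 1-based coordinates in the
#' C. elegans reference proteins; the listed residue is the one required
#' for the RQ-based anaerobic form.
#'
#' @param reference_sequences optional named list/vector of protein strings
#'   (names among COQ2, MEV1, TDO2, ETFDH) to attach as reference sequences,
#'   e.g. the real C. elegans proteins or stand-ins from
#'   [make_reference_set()]. Each must be at least as long as its largest
#'   site position.
#' @return a list of class `"marker_panel"`: one marker definition per
#'   entry, each with `marker_id`, `reference_species`,
#'   `reference_accession`, `reference_sequence` (or `NA`) and a data.frame
#'   of `sites` (`position`, `anaerobic_residue`, `note`).
#' @examples
#' panel <- default_panel()
#' panel$COQ2$sites
#' @export
default_panel <- function(reference_sequences = NULL) {
  def <- list(
    COQ2 = list(acc = "NP_871684.1", sites = data.frame(
      position = c(204L, 243L), anaerobic_residue = c("L", "S"),
      note = c("active-site residue, close to the substrate",
               "active-site residue, close to the substrate"),
      stringsAsFactors = FALSE)),
    MEV1 = list(acc = "NP_001366681.1", sites = data.frame(
      position = 71L, anaerobic_residue = "G",
      note = "near the rhodoquinone ring's binding site in Complex II",
      stringsAsFactors = FALSE)),
    TDO2 = list(acc = "NP_498284.1", sites = data.frame(
      position = 133L, anaerobic_residue = "P",
      note = "part of the PLD loop required for enzyme activity",
      stringsAsFactors = FALSE)),
    ETFDH = list(acc = "NP_001379625.1", sites = data.frame(
      position = 437L, anaerobic_residue = "F",
      note = "near the quinone binding site", stringsAsFactors = FALSE)))
  panel <- lapply(names(def), function(id) {
    seqstr <- NA_character_
    if (!is.null(reference_sequences) && id %in% names(reference_sequences)) {
      seqstr <- check_protein(as.character(reference_sequences[[id]]),
                              paste(id, "reference sequence"))
      if (nchar(seqstr) < max(def[[id]]$sites$position))
        stop_usage(sprintf(
          "%s reference sequence (length %d) shorter than its largest site position (%d)",
          id, nchar(seqstr), max(def[[id]]$sites$position)))
    }
    structure(list(marker_id = id, reference_species = "Caenorhabditis elegans",
                   reference_accession = def[[id]]$acc,
                   reference_sequence = seqstr, sites = def[[id]]$sites),
              class = "marker_definition")
  })
  names(panel) <- names(def)
  structure(panel, class = c("marker_panel", "list"))
}

#' Site labels of a panel, in panel order
#' @param panel a `"marker_panel"`.
#' @return character vector like `c("COQ2:204", "COQ2:243", ...)`.
#' @export
panel_site_labels <- function(panel) {
  unlist(lapply(panel, function(m) paste0(m$marker_id, ":", m$sites$position)),
         use.names = FALSE)
}

#' Homolog acceptance thresholds
#'
#' Conservative homology-screen conventions: at least 30% identity over the
#' aligned region and at least 60% of the reference covered.
#'
#' @param min_identity minimum fraction of identical aligned columns.
#' @param min_coverage minimum fraction of reference residues inside the
#'   local alignment span.
#' @return a list with the two thresholds.
#' @export
homolog_thresholds <- function(min_identity = 0.30, min_coverage = 0.60) {
  stopifnot(min_identity >= 0, min_identity <= 1,
            min_coverage >= 0, min_coverage <= 1)
  list(min_identity = min_identity, min_coverage = min_coverage)
}

alignment_identity <- function(aln) {
  r <- strsplit(aln$aligned_ref, "")[[1]]
  t <- strsplit(aln$aligned_target, "")[[1]]
  if (length(r) == 0L) return(0)
  sum(r == t & r != "-") / length(r)
}

#' Find the best homolog of a marker in a proteome
#'
#' Aligns the marker's reference sequence locally against every protein and
#' returns the best hit passing the identity and coverage thresholds. Score
#' ties are broken by larger reference coverage, then lexicographic target
#' id, so results are deterministic.
#'
#' @param marker a marker definition from [default_panel()] with an attached
#'   reference sequence.
#' @param proteome data.frame of records as from [read_fasta()].
#' @param thresholds a [homolog_thresholds()] list.
#' @param params an [align_params()] object.
#' @return a list of class `"homolog_hit"` (`marker_id`, `target_id`,
#'   `alignment`, `identity`, `coverage`), or `NULL` when no protein passes.
#' @export
find_homolog <- function(marker, proteome, thresholds = homolog_thresholds(),
                         params = align_params()) {
  if (is.na(marker$reference_sequence))
    stop_usage(sprintf("marker %s has no reference sequence attached",
                       marker$marker_id))
  if (is.null(proteome) || nrow(proteome) == 0L) {
    warning(sprintf("empty proteome given to find_homolog for %s",
                    marker$marker_id))
    return(NULL)
  }
  ref <- marker$reference_sequence
  reflen <- nchar(ref)
  best <- NULL
  ord <- order(proteome$id)  # lexicographic id order settles final ties
  for (i in ord) {
    aln <- local_align(ref, proteome$sequence[i], params)
    if (is.na(aln$ref_span[1])) next
    cov <- (aln$ref_span[2] - aln$ref_span[1] + 1L) / reflen
    better <- is.null(best) || aln$score > best$alignment$score ||
      (aln$score == best$alignment$score && cov > best$coverage)
    if (better)
      best <- list(marker_id = marker$marker_id, target_id = proteome$id[i],
                   alignment = aln, identity = alignment_identity(aln),
                   coverage = cov)
  }
  if (is.null(best) || best$identity < thresholds$min_identity ||
      best$coverage < thresholds$min_coverage) return(NULL)
  structure(best, class = "homolog_hit")
}

#' Call the diagnostic sites of a marker from a homolog hit
#'
#' Each site is read off the target through the alignment's position map:
#' no hit, a site outside the aligned reference span, or a site aligned to
#' a gap gives `MISSING`; otherwise the observed target residue is compared
#' with the site's anaerobic residue (`ANAEROBIC_MATCH` or `VARIANT`).
#'
#' @param marker a marker definition.
#' @param hit a `"homolog_hit"` or `NULL`.
#' @return data.frame with one row per site: `marker`, `site` (label),
#'   `position`, `anaerobic_residue`, `observed` (residue or `NA`), `state`.
#' @export
call_sites <- function(marker, hit = NULL) {
  sites <- marker$sites
  observed <- rep(NA_character_, nrow(sites))
  if (!is.null(hit)) {
    pm <- map_positions(hit$alignment)
    tgt <- strsplit(hit$alignment$aligned_target, "")[[1]]
    tgt <- tgt[tgt != "-"]
    for (k in seq_len(nrow(sites))) {
      p <- as.character(sites$position[k])
      if (p %in% names(pm) && !is.na(pm[[p]]))
        observed[k] <- tgt[pm[[p]] - hit$alignment$target_span[1] + 1L]
    }
  }
  state <- ifelse(is.na(observed), "MISSING",
                  ifelse(observed == sites$anaerobic_residue,
                         "ANAEROBIC_MATCH", "VARIANT"))
  data.frame(marker = marker$marker_id,
             site = paste0(marker$marker_id, ":", sites$position),
             position = sites$position,
             anaerobic_residue = sites$anaerobic_residue,
             observed = observed, state = state, stringsAsFactors = FALSE)
}

#' Classify a species from its five residue calls
#'
#' `FULL_SIGNATURE` when all five sites match the anaerobic residues,
#' `NO_SIGNATURE` when none match and none are missing,
#' `INSUFFICIENT_DATA` when none match and at least one is missing,
#' `PARTIAL_SIGNATURE` otherwise. The classification depends only on the
#' multiset of states, never on site order.
#'
#' @param calls data.frame of residue calls covering exactly the five panel
#'   sites (as from [call_sites()] over the whole panel).
#' @param species species name to record.
#' @return an object of class `"species_profile"`: `species`, `calls`,
#'   `counts` (`n_match`, `n_variant`, `n_missing`), `classification`.
#' @export
classify_species <- function(calls, species = "query") {
  expected <- panel_site_labels(default_panel())
  if (!setequal(calls$site, expected) || nrow(calls) != length(expected))
    stop_usage(sprintf("expected exactly the %d panel sites, got: %s",
                       length(expected), paste(calls$site, collapse = ", ")))
  calls <- calls[match(expected, calls$site), , drop = FALSE]
  n_match <- sum(calls$state == "ANAEROBIC_MATCH")
  n_variant <- sum(calls$state == "VARIANT")
  n_missing <- sum(calls$state == "MISSING")
  classification <-
    if (n_match == length(expected)) "FULL_SIGNATURE"
    else if (n_match == 0L && n_missing == 0L) "NO_SIGNATURE"
    else if (n_match == 0L) "INSUFFICIENT_DATA"
    else "PARTIAL_SIGNATURE"
  structure(list(species = species, calls = calls,
                 counts = c(n_match = n_match, n_variant = n_variant,
                            n_missing = n_missing),
                 classification = classification),
            class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("%s: %s (match %d, variant %d, missing %d)\n", x$species,
              x$classification, x$counts["n_match"], x$counts["n_variant"],
              x$counts["n_missing"]))
  obs <- ifelse(is.na(x$calls$observed), "-", x$calls$observed)
  cat(sprintf("  %s;%s %s %s %s\n", obs[1], obs[2], obs[3], obs[4], obs[5]))
  invisible(x)
}

#' Matrix row of a species profile
#' @param profile a `"species_profile"`.
#' @return named character vector of observed residues per site (`NA` for
#'   missing), suitable as a [read_character_matrix()] row.
#' @export
profile_row <- function(profile) {
  setNames(profile$calls$observed, profile$calls$site)
}

#' Screen a proteome or assembly for the RQ signature
#'
#' The end-to-end screen for one species: find the best homolog of each of
#' the four markers, read the diagnostic residues through the alignments,
#' and classify. Nucleotide input is handled as a translated search: every
#' six-frame peptide segment of at least `min_segment` residues becomes a
#' search target and the best segment wins, emulating a tblastn-style
#' database search without a heuristic seeding engine.
#'
#' @param panel a panel with reference sequences attached.
#' @param records data.frame of [read_fasta()] records: proteins, or
#'   nucleotide contigs with `type = "nucleotide"`.
#' @param type `"protein"`, `"nucleotide"` or `"auto"` (guess from the
#'   residue alphabet).
#' @param thresholds a [homolog_thresholds()] list.
#' @param params an [align_params()] object.
#' @param species species name to record in the profile.
#' @param min_segment minimum translated segment length searched (default 30).
#' @return a list of class `"rq_screen"`: `profile` (a
#'   `"species_profile"`), `row` (character-matrix row), `hits` (per-marker
#'   homolog hits or `NULL`).
#' @export
screen_proteome <- function(panel, records,
                            type = c("auto", "protein", "nucleotide"),
                            thresholds = homolog_thresholds(),
                            params = align_params(), species = "query",
                            min_segment = 30L) {
  type <- match.arg(type)
  if (type == "auto") type <- guess_seq_type(records$sequence)
  if (type == "nucleotide") {
    segs <- list()
    for (i in seq_len(nrow(records))) {
      tr <- six_frame_translate(records$sequence[i], min_length = min_segment)
      if (nrow(tr) == 0L) next
      segs[[length(segs) + 1L]] <- data.frame(
        id = sprintf("%s|%+d|%d", records$id[i], tr$frame, tr$nt_start),
        description = "", sequence = tr$peptide, stringsAsFactors = FALSE)
    }
    records <- if (length(segs)) do.call(rbind, segs)
      else data.frame(id = character(0), description = character(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  }
  hits <- lapply(panel, function(m)
    find_homolog(m, records, thresholds, params))
  calls <- do.call(rbind, lapply(names(panel), function(id)
    call_sites(panel[[id]], hits[[id]])))
  profile <- classify_species(calls, species)
  structure(list(profile = profile, row = profile_row(profile), hits = hits),
            class = "rq_screen")
}

guess_seq_type <- function(seqs) {
  ch <- unique(strsplit(paste(toupper(seqs), collapse = ""), "")[[1]])
  if (all(ch %in% c("A", "C", "G", "T", "N"))) "nucleotide" else "protein"
}

#' @export
print.rq_screen <- function(x, ...) {
  print(x$profile)
  for (id in names(x$hits)) {
    h <- x$hits[[id]]
    if (is.null(h)) cat(sprintf("  %s: no homolog passed thresholds\n", id))
    else cat(sprintf("  %s: hit %s (identity %.2f, coverage %.2f, score %.0f)\n",
                     id, h$target_id, h$identity, h$coverage, h$alignment$score))
  }
  invisible(x)
}

#' Classify every species of a character matrix
#'
#' Applies the residue-call and classification logic directly to the
#' printed states of a species-by-site matrix (no alignment involved).
#'
#' @param mat a character matrix from [read_character_matrix()] whose
#'   columns are exactly the five panel sites.
#' @param panel a `"marker_panel"` (sequences not required).
#' @return a list of class `"rq_matrix_classification"`: `profiles` (named
#'   list of `"species_profile"`), `summary` (classification counts) and
#'   `site_matches` (per-site ANAEROBIC_MATCH counts).
#' @export
classify_matrix <- function(mat, panel = default_panel()) {
  labels <- panel_site_labels(panel)
  if (nrow(mat) == 0L)
    return(structure(list(profiles = list(),
                          summary = setNames(integer(4), c(
                            "FULL_SIGNATURE", "PARTIAL_SIGNATURE",
                            "NO_SIGNATURE", "INSUFFICIENT_DATA")),
                          site_matches = setNames(integer(length(labels)), labels)),
                     class = "rq_matrix_classification"))
  if (!setequal(colnames(mat), labels))
    stop_usage(sprintf("matrix sites (%s) do not match the panel sites (%s)",
                       paste(colnames(mat), collapse = ", "),
                       paste(labels, collapse = ", ")))
  mat <- mat[, labels, drop = FALSE]
  site_info <- do.call(rbind, lapply(panel, function(m)
    data.frame(marker = m$marker_id, position = m$sites$position,
               anaerobic_residue = m$sites$anaerobic_residue,
               stringsAsFactors = FALSE)))
  profiles <- lapply(rownames(mat), function(sp) {
    observed <- unname(mat[sp, ])
    state <- ifelse(is.na(observed), "MISSING",
                    ifelse(observed == site_info$anaerobic_residue,
                           "ANAEROBIC_MATCH", "VARIANT"))
    calls <- data.frame(marker = site_info$marker, site = labels,
                        position = site_info$position,
                        anaerobic_residue = site_info$anaerobic_residue,
                        observed = observed, state = state,
                        stringsAsFactors = FALSE)
    classify_species(calls, sp)
  })
  names(profiles) <- rownames(mat)
  cls <- vapply(profiles, `[[`, "", "classification")
  summary <- vapply(c("FULL_SIGNATURE", "PARTIAL_SIGNATURE", "NO_SIGNATURE",
                      "INSUFFICIENT_DATA"),
                    function(c) sum(cls == c), 0L)
  site_matches <- vapply(labels, function(lb)
    sum(vapply(profiles, function(p)
      p$calls$state[p$calls$site == lb] == "ANAEROBIC_MATCH", TRUE)), 0L)
  structure(list(profiles = profiles, summary = summary,
                 site_matches = site_matches),
            class = "rq_matrix_classification")
}

#' @export
print.rq_matrix_classification <- function(x, ...) {
  cat(sprintf("%d species classified\n", length(x$profiles)))
  for (cl in names(x$summary))
    if (x$summary[cl] > 0) cat(sprintf("  %-18s %d\n", cl, x$summary[cl]))
  cat("per-site anaerobic matches:\n")
  for (lb in names(x$site_matches))
    cat(sprintf("  %-10s %d\n", lb, x$site_matches[lb]))
  invisible(x)
}
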