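#' Read a species-by-site character matrix
#'
#' The matrix is a TSV with a header row of site labels
#' (`"<MARKER>:<reference position>"`, e.g. `COQ2:204`), a first column of
#' species names, and one-letter amino-acid codes in the cells. `"-"` marks
#' missing data (no homolog found or assembly region absent) and is stored
#' as `NA`; it is deliberately distinct from alignment gap characters.
#'
#' @param source path to a TSV file or a character vector of its lines.
#' @return a character matrix with species as rownames, site labels as
#'   colnames and `NA` for missing states.
#' @seealso [rq_survey_path()] for the packaged cnidarian residue survey.
#' @export
read_character_matrix <- function(source) {
  lines <- fasta_lines(source)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop_parse("character matrix needs a header line and at least one species row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  sites <- trimws(header[-1L])
  if (length(sites) == 0L) stop_parse("character matrix header has no site labels")
  nst <- length(sites)
  species <- character(length(cells) - 1L)
  grid <- matrix(NA_character_, nrow = length(cells) - 1L, ncol = nst)
  for (r in seq_along(cells)[-1L]) {
    row <- trimws(cells[[r]])
    if (length(row) != nst + 1L)
      stop_parse(sprintf("ragged row at line %d: expected %d cells, found %d",
                         r, nst + 1L, length(row)))
    species[r - 1L] <- row[1L]
    for (k in seq_len(nst)) {
      v <- row[k + 1L]
      if (v == "-") next
      v <- toupper(v)
      if (nchar(v) != 1L || !(v %in% AA_ALPHABET20))
        stop_parse(sprintf(
          "line %d, site %s: cell '%s' is not a one-letter amino-acid code or '-'",
          r, sites[k], row[k + 1L]))
      grid[r - 1L, k] <- v
    }
  }
  if (anyDuplicated(species))
    stop_parse(sprintf("duplicate species name: %s",
                       species[duplicated(species)][1L]))
  dimnames(grid) <- list(species, sites)
  grid
}

#' Write a character matrix as TSV
#'
#' Inverse of [read_character_matrix()]: `NA` states are written as `"-"`.
#'
#' @param mat character matrix with species rownames and site colnames.
#' @param path output file; if `NULL` the TSV text is returned invisibly.
#' @return invisibly, the TSV text.
#' @export
write_character_matrix <- function(mat, path = NULL) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  body <- mat
  body[is.na(body)] <- "-"
  lines <- c(paste(c("species", colnames(mat)), collapse = "\t"),
             vapply(seq_len(nrow(mat)), function(i)
               paste(c(rownames(mat)[i], body[i, ]), collapse = "\t"), ""))
  if (!is.null(path)) writeLines(lines, path)
  invisible(paste0(paste(lines, collapse = "\n"), "\n"))
}

#' Path to the packaged cnidarian RQ-residue survey
#'
#' A transcription of a published survey of the five diagnostic residues
#' (COQ2:204, COQ2:243, MEV1:71, TDO2:133, ETFDH:437) across 16 cnidarian
#' species plus the Caenorhabditis elegans (anaerobic-capable) and Homo
#' sapiens (purely aerobic) reference rows.
#'
#' @return path to the TSV fixture.
#' @export
rq_survey_path <- function() {
  system.file("extdata", "cnidarian_rq_residue_survey.tsv",
              package = "rqscreen", mustWork = TRUE)
}

#' Reference (non-cnidarian) species in the packaged survey
#'
#' @format character vector of length 2.
#' @export
rq_reference_species <- c("Caenorhabditis elegans", "Homo sapiens")
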