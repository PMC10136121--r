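#' Alignment scoring parameters
#'
#' Defaults mirror the conventional protein database-search scoring:
#' BLOSUM62 with affine gap penalties of -11 to open and -1 to extend. A gap
#' of length L scores `gap_open + (L - 1) * gap_extend`. The ambiguity
#' residue X scores 0 against everything.
#'
#' @param substitution substitution matrix: the name `"BLOSUM62"` or a
#'   square numeric matrix with single-letter dimnames.
#' @param gap_open,gap_extend negative gap scores with
#'   `gap_open <= gap_extend < 0`.
#' @return an object of class `"align_params"`.
#' @export
align_params <- function(substitution = "BLOSUM62", gap_open = -11,
                         gap_extend = -1) {
  if (is.character(substitution)) {
    if (!identical(substitution, "BLOSUM62"))
      stop_usage(sprintf("unknown substitution matrix '%s'", substitution))
    mat <- blosum62()
  } else {
    mat <- substitution
    if (!is.matrix(mat) || is.null(rownames(mat)) ||
        !identical(rownames(mat), colnames(mat)))
      stop_usage("substitution matrix must be square with matching dimnames")
  }
  if (!(gap_open <= gap_extend && gap_extend < 0))
    stop_usage("gap scores must satisfy gap_open <= gap_extend < 0")
  structure(list(substitution = mat, gap_open = gap_open,
                 gap_extend = gap_extend), class = "align_params")
}

# BLOSUM62 as shipped with Biostrings, restricted to the 20 standard
# residues plus X, with X rescored to 0 against everything.
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      m <- env$BLOSUM62
      keep <- c(AA_ALPHABET20, "X")
      m <- m[keep, keep]
      m["X", ] <- 0
      m[, "X"] <- 0
      cache <<- m
    }
    cache
  }
})

check_protein <- function(x, what = "sequence", allow_x = TRUE) {
  if (length(x) != 1L || !is.character(x) || !nzchar(x))
    stop_usage(sprintf("%s must be a non-empty string", what))
  x <- toupper(x)
  ok <- c(AA_ALPHABET20, if (allow_x) "X")
  ch <- strsplit(x, "")[[1]]
  bad <- which(!(ch %in% ok))
  if (length(bad))
    stop_usage(sprintf("invalid residue '%s' at position %d of %s",
                       ch[bad[1]], bad[1], what))
  x
}

make_alignment <- function(raw, mode) {
  structure(list(aligned_ref = raw$aligned_a, aligned_target = raw$aligned_b,
                 score = raw$score, mode = mode,
                 ref_span = c(raw$a_start, raw$a_end),
                 target_span = c(raw$b_start, raw$b_end)),
            class = "alignment")
}

#' Pairwise protein alignment with affine gaps
#'
#' `global_align()` is Needleman-Wunsch and `local_align()` Smith-Waterman,
#' both under the affine gap model of [align_params()]. The traceback is
#' deterministic: on score ties, diagonal beats a gap in the target beats a
#' gap in the reference; the local end cell is the first best-scoring cell
#' in row-major order.
#'
#' @param a reference protein sequence (string).
#' @param b target protein sequence (string).
#' @param params an [align_params()] object.
#' @return an object of class `"alignment"` with elements `aligned_ref`,
#'   `aligned_target` (gapped strings), `score`, `mode`, and the 1-based
#'   inclusive `ref_span` / `target_span` covered (NA spans for an empty
#'   local alignment).
#' @examples
#' global_align("MKV", "MKV")$score  # 5 + 5 + 4 = 14 under BLOSUM62
#' @export
global_align <- function(a, b, params = align_params()) {
  a <- check_protein(a, "reference sequence"); b <- check_protein(b, "target sequence")
  make_alignment(.gotoh_align(a, b, params$substitution, params$gap_open,
                              params$gap_extend, FALSE), "global")
}

#' @rdname global_align
#' @export
local_align <- function(a, b, params = align_params()) {
  a <- check_protein(a, "reference sequence"); b <- check_protein(b, "target sequence")
  make_alignment(.gotoh_align(a, b, params$substitution, params$gap_open,
                              params$gap_extend, TRUE), "local")
}

#' Recompute an alignment's score from its aligned strings
#'
#' Self-consistency check: sums substitution scores over aligned columns and
#' affine penalties over gap runs under the same parameters.
#'
#' @param aln an `"alignment"` object.
#' @param params the [align_params()] used to produce it.
#' @return numeric score.
#' @export
alignment_score <- function(aln, params = align_params()) {
  r <- strsplit(aln$aligned_ref, "")[[1]]
  t <- strsplit(aln$aligned_target, "")[[1]]
  stopifnot(length(r) == length(t))
  if (length(r) == 0L) return(0)
  score <- 0
  in_gap <- 0L  # 0 none, 1 gap in target, 2 gap in ref
  for (k in seq_along(r)) {
    if (r[k] == "-") {
      score <- score + if (in_gap == 2L) params$gap_extend else params$gap_open
      in_gap <- 2L
    } else if (t[k] == "-") {
      score <- score + if (in_gap == 1L) params$gap_extend else params$gap_open
      in_gap <- 1L
    } else {
      score <- score + params$substitution[r[k], t[k]]
      in_gap <- 0L
    }
  }
  score
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("%s alignment, score %.1f\n", x$mode, x$score))
  if (!is.na(x$ref_span[1])) {
    cat(sprintf("  ref    %4d %s %d\n", x$ref_span[1], x$aligned_ref, x$ref_span[2]))
    cat(sprintf("  target %4d %s %d\n", x$target_span[1], x$aligned_target,
                x$target_span[2]))
  } else cat("  (empty alignment)\n")
  invisible(x)
}

#' Map reference positions to target positions through an alignment
#'
#' @param aln an `"alignment"` object.
#' @return an integer vector indexed by the reference positions inside
#'   `ref_span` (names are the positions); `NA` where the reference column
#'   is aligned to a gap. Strictly increasing over mapped positions.
#' @examples
#' map_positions(global_align("MKV", "MV"))  # c(`1` = 1, `2` = NA, `3` = 2)
#' @export
map_positions <- function(aln) {
  if (is.na(aln$ref_span[1])) return(setNames(integer(0), character(0)))
  r <- strsplit(aln$aligned_ref, "")[[1]]
  t <- strsplit(aln$aligned_target, "")[[1]]
  rp <- aln$ref_span[1] - 1L
  tp <- aln$target_span[1] - 1L
  pos <- integer(0); val <- integer(0)
  for (k in seq_along(r)) {
    ref_here <- r[k] != "-"
    tgt_here <- t[k] != "-"
    if (ref_here) rp <- rp + 1L
    if (tgt_here) tp <- tp + 1L
    if (ref_here) {
      pos <- c(pos, rp)
      val <- c(val, if (tgt_here) tp else NA_integer_)
    }
  }
  setNames(val, pos)
}

#' Six-frame translation of a nucleotide sequence
#'
#' Translates the three forward frames (+1, +2, +3) and the three frames of
#' the reverse complement (-1, -2, -3) under the standard genetic code,
#' splitting peptides at stop codons. `N` translates to `X`; other IUPAC
#' ambiguity codes are rejected.
#'
#' @param nt nucleotide sequence (string over ACGTN, case-insensitive).
#' @param min_length drop peptide segments shorter than this (default 1).
#' @return a data.frame with columns `frame` (+1..+3, -1..-3), `nt_start`
#'   (1-based position, in the input sequence, of the first base of the
#'   segment's first codon, read on the segment's strand), `peptide`.
#' @examples
#' six_frame_translate("ATGGCC")
#' @export
six_frame_translate <- function(nt, min_length = 1L) {
  if (length(nt) != 1L || !is.character(nt) || !nzchar(nt))
    stop_usage("nucleotide sequence must be a non-empty string")
  nt <- toupper(nt)
  ch <- strsplit(nt, "")[[1]]
  bad <- which(!(ch %in% c("A", "C", "G", "T", "N")))
  if (length(bad))
    stop_usage(sprintf("invalid nucleotide '%s' at position %d", ch[bad[1]], bad[1]))
  L <- nchar(nt)
  fwd <- Biostrings::DNAString(nt)
  rev <- Biostrings::reverseComplement(fwd)
  out <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) fwd else rev
    for (off in 0:2) {
      start <- off + 1L
      len <- (length(s) - off) %/% 3L * 3L
      if (len < 3L) next
      pep <- as.character(Biostrings::translate(
        Biostrings::subseq(s, start, start + len - 1L), if.fuzzy.codon = "X"))
      # split at stops, track codon offsets of each segment
      segs <- strsplit(pep, "*", fixed = TRUE)[[1]]
      codon0 <- 0L
      for (seg in segs) {
        if (nchar(seg) >= max(1L, min_length)) {
          pos_on_strand <- start + codon0 * 3L
          nt_start <- if (strand == 1L) pos_on_strand else L - pos_on_strand + 1L
          out[[length(out) + 1L]] <- data.frame(
            frame = strand * (off + 1L), nt_start = nt_start, peptide = seg,
            stringsAsFactors = FALSE)
        }
        codon0 <- codon0 + nchar(seg) + 1L
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(frame = integer(0), nt_start = integer(0),
                      peptide = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Reverse complement of a nucleotide string
#' @param nt nucleotide sequence over ACGTN.
#' @return the reverse complement as a string.
#' @export
reverse_complement <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(nt))))
}
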