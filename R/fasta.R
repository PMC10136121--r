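#' Read a FASTA file
#'
#' Parses multi-record, line-wrapped FASTA. The record id is the first
#' whitespace-delimited token of the header; the remainder is kept as the
#' description. Sequence lines are concatenated and uppercased.
#'
#' @param source path to a FASTA file, or a character vector of FASTA lines
#'   (anything containing a newline or starting with ">" is treated as text).
#' @return a data.frame with columns `id`, `description`, `sequence`, one row
#'   per record, in file order.
#' @examples
#' read_fasta(c(">a x", "MK", "VL", ">b", "AC"))
#' @export
read_fasta <- function(source) {
  lines <- fasta_lines(source)
  ids <- character(0); desc <- character(0); seqs <- character(0)
  cur <- NULL; cur_line <- 0L
  chunks <- list()
  flush <- function() {
    if (is.null(cur)) return()
    s <- paste0(unlist(chunks), collapse = "")
    if (!nzchar(s))
      stop_parse(sprintf("empty sequence for record '%s' (header at line %d)",
                         cur[1], cur_line))
    ids <<- c(ids, cur[1]); desc <<- c(desc, cur[2]); seqs <<- c(seqs, s)
  }
  for (k in seq_along(lines)) {
    ln <- lines[[k]]
    if (startsWith(ln, ">")) {
      flush()
      hdr <- sub("^>", "", ln)
      tok <- regmatches(hdr, regexpr("^\\S+", hdr))
      if (length(tok) == 0L || !nzchar(tok))
        stop_parse(sprintf("empty FASTA header at line %d", k))
      rest <- trimws(substring(hdr, nchar(tok) + 1L))
      cur <- c(tok, rest); cur_line <- k
      chunks <- list()
    } else {
      s <- gsub("\\s+", "", ln)
      if (!nzchar(s)) next
      if (is.null(cur))
        stop_parse(sprintf("sequence data before first FASTA header at line %d", k))
      chunks[[length(chunks) + 1L]] <- toupper(s)
    }
  }
  flush()
  if (length(ids) == 0L) stop_parse("no FASTA records found")
  data.frame(id = ids, description = desc, sequence = seqs,
             stringsAsFactors = FALSE)
}

fasta_lines <- function(source) {
  if (length(source) == 1L && !grepl("[\n>]", source)) {
    if (!file.exists(source)) stop_parse(sprintf("file not found: %s", source))
    return(readLines(source, warn = FALSE))
  }
  unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
}

#' Write records as FASTA
#'
#' @param records data.frame with columns `id`, `sequence` and optionally
#'   `description`, as returned by [read_fasta()].
#' @param path output file; if `NULL` the FASTA text is returned invisibly
#'   as a single string.
#' @param width line width for sequence wrapping (default 60).
#' @return invisibly, the FASTA text.
#' @export
write_fasta <- function(records, path = NULL, width = 60L) {
  stopifnot(is.data.frame(records), nrow(records) > 0L, width >= 1L)
  desc <- if ("description" %in% names(records)) records$description
          else rep("", nrow(records))
  out <- character(0)
  for (i in seq_len(nrow(records))) {
    hdr <- paste0(">", records$id[i],
                  if (nzchar(desc[i])) paste0(" ", desc[i]) else "")
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    out <- c(out, hdr, substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) writeLines(out, path)
  invisible(text)
}
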