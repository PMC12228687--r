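#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a tibble of sequence records. Sequences are
#' upper-cased; line wrapping and trailing whitespace are normalised away.
#' The first whitespace-delimited token of each header is the record id, the
#' remainder (if any) its description.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `sequence`, in file
#'   order. An empty file yields a zero-row tibble.
#' @export
read_fasta <- function(path) {
  pm_assert_file(path)
  if (file.size(path) == 0L) {
    return(tibble(id = character(), description = character(),
                  sequence = character()))
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    bad <- names(set)[nchar(seqs) == 0L][1L]
    pm_abort(paste0("FASTA record with empty sequence: ", bad),
             "petminer_format_error")
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) {
    pm_abort("FASTA record with empty id", "petminer_format_error")
  }
  bad_chr <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", seqs)
  if (any(bad_chr)) {
    pm_abort(paste0("non amino-acid characters in record: ", ids[bad_chr][1L]),
             "petminer_format_error")
  }
  tibble(id = unname(ids), description = unname(desc),
         sequence = unname(seqs))
}

#' Write protein sequences to a FASTA file
#'
#' @param records Tibble with columns `id`, `sequence` and optionally
#'   `description` (as returned by [read_fasta()]).
#' @param path Output path.
#' @param line_width Residues per sequence line (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, line_width = 60) {
  stopifnot(is.data.frame(records), line_width >= 1)
  if (anyDuplicated(records$id)) {
    pm_abort("duplicate sequence ids", "petminer_format_error")
  }
  if (any(grepl("\\s", records$id))) {
    pm_abort("sequence ids must not contain whitespace", "petminer_format_error")
  }
  desc <- if ("description" %in% names(records)) records$description else
    rep("", nrow(records))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    header <- if (!is.na(desc[i]) && nzchar(desc[i])) {
      paste0(">", records$id[i], " ", desc[i])
    } else paste0(">", records$id[i])
    writeLines(header, con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = line_width)
    writeLines(substring(s, starts, pmin(starts + line_width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}
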