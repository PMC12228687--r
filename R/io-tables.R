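# Delimited-text (TSV, header row, UTF-8) readers for the tabular inputs:
# annotations, embeddings, candidate properties. Unknown columns are
# preserved on read but ignored downstream.

ec_pattern_ok <- function(ec) {
  parts <- strsplit(ec, ".", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 4L) return(FALSE)
    if (!grepl("^[0-9]+$", p[1L])) return(FALSE)
    digit_or_dash <- grepl("^([0-9]+|-)$", p[2:4])
    if (!all(digit_or_dash)) return(FALSE)
    # '-' only in trailing fields: once a dash appears, the rest are dashes
    dash <- p[2:4] == "-"
    if (any(dash)) all(dash[min(which(dash)):3L]) else TRUE
  }, logical(1L))
}

#' Read an annotation table
#'
#' Expects a tab-separated file with header columns `id`, `ec_numbers`
#' (comma-separated dotted EC strings, `-` allowed in trailing fields;
#' empty for unannotated proteins) and `validated_positive`
#' (`TRUE`/`FALSE`). Ids must be unique.
#'
#' @param path Path to a TSV file.
#' @return Tibble with `id` (character), `ec_numbers` (list column of
#'   character vectors) and `validated_positive` (logical).
#' @export
read_annotation_table <- function(path) {
  pm_assert_file(path)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("id", "ec_numbers", "validated_positive")) {
    if (!col %in% names(df)) {
      pm_abort(paste0("annotation table missing column: ", col),
               "petminer_format_error")
    }
  }
  if (anyDuplicated(df$id)) {
    pm_abort("annotation ids must be unique", "petminer_format_error")
  }
  ecs <- strsplit(ifelse(is.na(df$ec_numbers), "", as.character(df$ec_numbers)),
                  "\\s*,\\s*")
  ecs <- lapply(ecs, function(v) v[nzchar(v)])
  flat <- unlist(ecs)
  if (length(flat) && !all(ec_pattern_ok(flat))) {
    bad <- flat[!ec_pattern_ok(flat)][1L]
    pm_abort(paste0("malformed EC number: ", bad), "petminer_format_error")
  }
  tibble(id = as.character(df$id), ec_numbers = ecs,
         validated_positive = as.logical(df$validated_positive))
}

#' Write an annotation table
#' @param annotations Tibble as returned by [read_annotation_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(annotations, path) {
  out <- tibble(
    id = annotations$id,
    ec_numbers = vapply(annotations$ec_numbers, paste, character(1L),
                        collapse = ","),
    validated_positive = annotations$validated_positive
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an embedding table
#'
#' Tab-separated file: an `id` column plus `d >= 1` numeric embedding
#' columns. All rows must have the same dimension with finite numeric
#' values; `NaN`, empty or non-numeric cells are errors.
#'
#' @param path Path to a TSV file.
#' @return Tibble with `id` plus numeric columns.
#' @export
read_embedding_table <- function(path) {
  pm_assert_file(path)
  df <- suppressWarnings(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(id = readr::col_character(),
                                            .default = readr::col_double()))
  )
  if (!"id" %in% names(df)) {
    pm_abort("embedding table missing 'id' column", "petminer_format_error")
  }
  emb <- as_tibble(df)
  m <- suppressWarnings(embedding_matrix(emb))   # validates finiteness
  emb
}

#' Write an embedding table
#' @param embeddings Tibble with `id` plus numeric columns.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_embedding_table <- function(embeddings, path) {
  readr::write_tsv(embeddings, path, progress = FALSE)
  invisible(path)
}

#' Read a candidate-property table
#'
#' Tab-separated per-candidate predicted properties. Required columns:
#' `id`, `predicted_tm` (degrees C), `predicted_solubility`. Optional:
#' `plddt_mean` (0-100), `tm_score_vs_ref` (0-1), `triad_ok` (logical).
#' Missing optional columns are added as `NA` so the screening cascade can
#' flag them explicitly.
#'
#' @param path Path to a TSV file.
#' @return Tibble of candidate records.
#' @export
read_candidate_table <- function(path) {
  pm_assert_file(path)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("id", "predicted_tm", "predicted_solubility")) {
    if (!col %in% names(df)) {
      pm_abort(paste0("candidate table missing column: ", col),
               "petminer_format_error")
    }
  }
  if (anyDuplicated(df$id)) {
    pm_abort("candidate ids must be unique", "petminer_format_error")
  }
  df$id <- as.character(df$id)
  for (col in c("plddt_mean", "tm_score_vs_ref")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  if (!"triad_ok" %in% names(df)) df$triad_ok <- NA
  df$triad_ok <- as.logical(df$triad_ok)
  ok <- is.na(df$plddt_mean) | (df$plddt_mean >= 0 & df$plddt_mean <= 100)
  if (!all(ok)) {
    pm_abort("plddt_mean must lie in [0, 100]", "petminer_format_error")
  }
  as_tibble(df)
}
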