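# Multi-tier candidate screening. Candidates surviving clade selection are
# filtered in a fixed stage order -- predicted melting temperature, then
# predicted solubility (both must strictly exceed the query enzyme's
# values), then predicted-structure confidence (mean pLDDT), TM-score
# against the reference fold, and catalytic-triad conservation -- and the
# survivors are ranked by predicted Tm, keeping the top k for wet-lab
# validation. A record missing the datum a stage needs is excluded at that
# stage and flagged `missing_data`: a mining run must be explicit about
# data gaps.

pm_stage_names <- c("tm_filter", "solubility_filter", "plddt_filter",
                    "tmscore_filter", "triad_filter", "ranked_top_k")

#' Screening-cascade configuration
#'
#' @param query_tm Predicted melting temperature of the query enzyme
#'   (degrees C); candidates must strictly exceed it.
#' @param query_solubility Predicted solubility of the query; candidates
#'   must strictly exceed it.
#' @param plddt_min Minimum mean pLDDT retained (default 75; values below
#'   are discarded, the boundary is retained).
#' @param tm_min Minimum TM-score vs the reference retained (default 0.5;
#'   the boundary is retained).
#' @param top_k Number of ranked candidates kept (default 34).
#' @return A `pm_screening_config` list.
#' @export
screening_config <- function(query_tm, query_solubility, plddt_min = 75,
                             tm_min = 0.5, top_k = 34) {
  stopifnot(is.finite(query_tm), is.finite(query_solubility),
            is.finite(plddt_min), is.finite(tm_min), top_k >= 1)
  structure(list(query_tm = query_tm, query_solubility = query_solubility,
                 plddt_min = plddt_min, tm_min = tm_min,
                 top_k = as.integer(top_k)),
            class = "pm_screening_config")
}

#' Apply the screening cascade to candidate records
#'
#' @param records Tibble of candidate records (see
#'   [read_candidate_table()]): `id`, `predicted_tm`,
#'   `predicted_solubility`, and optional `plddt_mean`, `tm_score_vs_ref`,
#'   `triad_ok`.
#' @param config A [screening_config()].
#' @return A `pm_screening_report`: list with `stages` (tibble of stage
#'   name, survivor count, survivor id list-column), `exclusions` (tibble
#'   `id`, `stage`, `reason`), and `ranked` (tibble `rank`, `id`,
#'   `predicted_tm` for the final top-k list).
#' @export
apply_cascade <- function(records, config) {
  stopifnot(inherits(config, "pm_screening_config"))
  if (!is.data.frame(records) || nrow(records) == 0L) {
    pm_abort("records must be a non-empty tibble", "petminer_format_error")
  }
  for (col in c("plddt_mean", "tm_score_vs_ref")) {
    if (!col %in% names(records)) records[[col]] <- NA_real_
  }
  if (!"triad_ok" %in% names(records)) records$triad_ok <- NA
  surv <- records
  stages <- list()
  excl <- list()
  run_stage <- function(stage, value, keep) {
    miss <- is.na(value)
    drop <- miss | !ifelse(miss, FALSE, keep)
    if (any(drop)) {
      excl[[length(excl) + 1L]] <<- tibble(
        id = surv$id[drop], stage = stage,
        reason = ifelse(miss[drop], "missing_data", "threshold"))
    }
    surv <<- surv[!drop, , drop = FALSE]
    stages[[length(stages) + 1L]] <<- tibble(
      stage = stage, n_survivors = nrow(surv), ids = list(surv$id))
  }
  run_stage("tm_filter", surv$predicted_tm,
            surv$predicted_tm > config$query_tm)
  run_stage("solubility_filter", surv$predicted_solubility,
            surv$predicted_solubility > config$query_solubility)
  run_stage("plddt_filter", surv$plddt_mean,
            surv$plddt_mean >= config$plddt_min)
  run_stage("tmscore_filter", surv$tm_score_vs_ref,
            surv$tm_score_vs_ref >= config$tm_min)
  run_stage("triad_filter", ifelse(is.na(surv$triad_ok), NA, 1),
            surv$triad_ok)
  ranked_ids <- rank_candidates(surv, top_k = config$top_k)
  ranked <- tibble(rank = seq_along(ranked_ids), id = ranked_ids) |>
    left_join(records[, c("id", "predicted_tm")], by = "id")
  stages[[length(stages) + 1L]] <- tibble(
    stage = "ranked_top_k", n_survivors = nrow(ranked),
    ids = list(ranked$id))
  structure(list(stages = dplyr::bind_rows(stages),
                 exclusions = if (length(excl)) dplyr::bind_rows(excl) else
                   tibble(id = character(), stage = character(),
                          reason = character()),
                 ranked = ranked,
                 config = config,
                 n_input = nrow(records)),
            class = "pm_screening_report")
}

#' Rank candidates by a numeric key
#'
#' Stable descending order on `key`, ties broken by `id` ascending;
#' truncated to `top_k`.
#'
#' @param records Candidate tibble; must contain `id` and the key column.
#' @param key Column name to rank on (default `"predicted_tm"`).
#' @param top_k Maximum number of ids returned (default all).
#' @return Character vector of ranked ids.
#' @export
rank_candidates <- function(records, key = "predicted_tm",
                            top_k = nrow(records)) {
  if (!key %in% names(records)) {
    pm_abort(paste0("ranking key not present: ", key),
             "petminer_format_error")
  }
  v <- records[[key]]
  if (anyNA(v)) {
    pm_abort("ranking key contains missing values", "petminer_format_error")
  }
  ord <- order(-v, records$id)
  utils::head(records$id[ord], top_k)
}

#' @export
print.pm_screening_report <- function(x, ...) {
  cat("<pm_screening_report> ", x$n_input, " candidates in\n", sep = "")
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-18s %d survivors\n", x$stages$stage[i],
                x$stages$n_survivors[i]))
  }
  invisible(x)
}

#' @describeIn apply_cascade Per-stage survivor counts.
#' @param x A `pm_screening_report`.
#' @param ... Unused.
#' @export
tidy.pm_screening_report <- function(x, ...) {
  x$stages |> select("stage", "n_survivors")
}

#' @describeIn apply_cascade One-row cascade summary.
#' @export
glance.pm_screening_report <- function(x, ...) {
  tibble(n_input = x$n_input,
         n_final = nrow(x$ranked),
         n_excluded = nrow(x$exclusions),
         n_missing_data = sum(x$exclusions$reason == "missing_data"))
}

#' @describeIn apply_cascade Funnel plot of survivors per stage.
#' @param object A `pm_screening_report`.
#' @export
autoplot.pm_screening_report <- function(object, ...) {
  df <- tidy.pm_screening_report(object) |>
    mutate(stage = factor(.data$stage, levels = rev(pm_stage_names)))
  ggplot(df, aes(x = .data$n_survivors, y = .data$stage)) +
    geom_col() +
    labs(x = "surviving candidates", y = NULL) +
    theme_minimal()
}

#' Write a screening report as delimited text
#'
#' Emits two TSV files: `<stem>_stages.tsv` (stage, survivor count) and
#' `<stem>_ranked.tsv` (rank, id, predicted_tm).
#'
#' @param report A `pm_screening_report`.
#' @param stem Output path stem.
#' @return The stage-file path, invisibly.
#' @export
write_screening_report <- function(report, stem) {
  p1 <- paste0(stem, "_stages.tsv")
  readr::write_tsv(tidy.pm_screening_report(report), p1, progress = FALSE)
  readr::write_tsv(report$ranked, paste0(stem, "_ranked.tsv"),
                   progress = FALSE)
  if (nrow(report$exclusions)) {
    readr::write_tsv(report$exclusions, paste0(stem, "_exclusions.tsv"),
                     progress = FALSE)
  }
  invisible(p1)
}
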