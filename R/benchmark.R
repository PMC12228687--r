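# EC-retrieval benchmark: score every retrieval method per EC group by
# AUROC and average precision over a labelled pool. Scores are unified as
# "lower = predicted positive" so embedding distances and E-values share
# one code path.

#' Area under the ROC curve for a labelled pool
#'
#' Probability that a randomly drawn positive receives a lower (better)
#' score than a randomly drawn negative, with ties counted half -- the
#' normalised Mann-Whitney pair statistic.
#'
#' @param pool Tibble with columns `score` (lower = more similar) and
#'   `label` (logical or 0/1; `TRUE` = positive).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(pool) {
  lab <- as.logical(pool$label)
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0L || n_neg == 0L) {
    pm_abort("AUROC needs both classes present", "petminer_format_error")
  }
  r <- rank(pool$score, ties.method = "average")
  (sum(r[!lab]) - n_neg * (n_neg + 1) / 2) / (n_pos * n_neg)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-wise average precision over the ascending-score ranking: the
#' precision at each positive's rank, averaged over positives. Score ties
#' are broken by `id` ascending before scanning so the value is
#' deterministic.
#'
#' @param pool Tibble with columns `id`, `score`, `label`.
#' @return Average precision in `(0, 1]`.
#' @export
average_precision <- function(pool) {
  lab <- as.logical(pool$label)
  if (!any(lab)) {
    pm_abort("average precision needs at least one positive",
             "petminer_format_error")
  }
  ord <- order(pool$score, pool$id)
  lab <- lab[ord]
  hits <- cumsum(lab)
  prec_at_pos <- hits[lab] / which(lab)
  mean(prec_at_pos)
}

#' Per-EC retrieval benchmark over embedding distances
#'
#' For each EC group with at least `min_group` members: sample `n_queries`
#' group members as queries (removed from the evaluation pool), score the
#' remaining pool by [min_distance_to_queries()], label the remaining
#' same-EC members positive and everything else negative, and compute
#' AUROC and average precision. Groups below `min_group` are reported as
#' skipped.
#'
#' @param embeddings Embedding tibble (`id` + numeric columns).
#' @param annotations Annotation tibble (see [read_annotation_table()]).
#' @param ec_list Character vector of EC numbers to evaluate; default: all
#'   EC numbers present in the annotations.
#' @param n_queries Query seeds sampled per group (default 10).
#' @param min_group Minimum annotated group size evaluated (default 50).
#' @param seed Integer seed for query sampling (one stream across groups).
#' @return A `pm_benchmark`: tibble with one row per EC group (`ec`,
#'   `n_pos`, `n_neg`, `n_queries`, `skipped`, `auroc`, `aupr`), with the
#'   seed and unweighted means over evaluated groups as attributes
#'   (see [glance.pm_benchmark()]).
#' @export
ec_retrieval_benchmark <- function(embeddings, annotations, ec_list = NULL,
                                   n_queries = 10, min_group = 50, seed) {
  stopifnot(!missing(seed))
  ann_ec <- annotations |>
    select("id", "ec_numbers") |>
    tidyr::unnest_longer("ec_numbers", values_to = "ec")
  if (is.null(ec_list)) ec_list <- sort(unique(ann_ec$ec))
  ids <- embeddings$id
  rows <- with_seed(seed, {
    lapply(ec_list, function(ec) {
      members <- intersect(ann_ec$id[ann_ec$ec == ec], ids)
      if (length(members) < min_group) {
        return(tibble(ec = ec, n_pos = NA_integer_, n_neg = NA_integer_,
                      n_queries = as.integer(n_queries), skipped = TRUE,
                      auroc = NA_real_, aupr = NA_real_))
      }
      if (n_queries >= length(members)) {
        pm_abort("n_queries must be smaller than the group size",
                 "petminer_format_error")
      }
      queries <- sample(members, n_queries)
      pool_ids <- setdiff(ids, queries)
      scores <- min_distance_to_queries(
        embeddings[match(pool_ids, ids), , drop = FALSE],
        embeddings[match(queries, ids), , drop = FALSE])
      pool <- scores |>
        mutate(label = .data$id %in% setdiff(members, queries))
      tibble(ec = ec, n_pos = sum(pool$label), n_neg = sum(!pool$label),
             n_queries = as.integer(n_queries), skipped = FALSE,
             auroc = auroc(pool), aupr = average_precision(pool))
    })
  })
  res <- dplyr::bind_rows(rows)
  structure(res, seed = seed, class = c("pm_benchmark", class(res)))
}

#' @describeIn ec_retrieval_benchmark Aggregate means over evaluated groups.
#' @param x A `pm_benchmark`.
#' @param ... Unused.
#' @export
glance.pm_benchmark <- function(x, ...) {
  ev <- x[!x$skipped, , drop = FALSE]
  tibble(n_groups = nrow(ev), n_skipped = sum(x$skipped),
         mean_auroc = mean(ev$auroc), mean_aupr = mean(ev$aupr),
         seed = attr(x, "seed"))
}

#' @describeIn ec_retrieval_benchmark Dot plot of per-group AUROC / AUPR.
#' @param object A `pm_benchmark`.
#' @export
autoplot.pm_benchmark <- function(object, ...) {
  df <- as_tibble(object) |>
    filter(!.data$skipped) |>
    tidyr::pivot_longer(c("auroc", "aupr"), names_to = "metric")
  ggplot(df, aes(x = .data$value, y = .data$ec)) +
    geom_point() +
    facet_wrap(~metric) +
    labs(x = NULL, y = "EC group") +
    theme_minimal()
}
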