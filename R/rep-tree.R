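# Representation tree: Ward agglomerative clustering over protein
# embeddings, flat cuts into clades, and annotation-guided clade selection.
#
# Linkage follows the Lance-Williams recurrence on squared Euclidean
# distances with the Ward update; reported heights are square roots of the
# recurrence values, so two singletons merge at their Euclidean distance
# (the convention of scipy's `ward` and hclust's `ward.D2`). Ties on the
# merge criterion break lexicographically on node creation indices, making
# the tree fully deterministic.

#' Build a Ward representation tree over embeddings
#'
#' @param embeddings Tibble with `id` plus numeric embedding columns.
#' @return A `pm_tree`: leaf `ids` plus a tibble of `n - 1` merges with
#'   columns `step`, `left`, `right` (negative values index leaves,
#'   positive values earlier merge steps — the [stats::hclust()]
#'   convention), `height` and `size` (members of the merged cluster).
#' @export
ward_tree <- function(embeddings) {
  x <- embedding_matrix(embeddings)
  n <- nrow(x)
  if (n == 1L) {
    return(new_pm_tree(rownames(x), tibble(
      step = integer(), left = integer(), right = integer(),
      height = double(), size = integer())))
  }
  d2 <- as.matrix(dist(x))^2
  active <- rep(TRUE, n)
  size <- rep(1L, n)          # per slot
  node_id <- seq_len(n)       # creation index of the cluster in each slot
  slot_ref <- -seq_len(n)     # hclust-style reference for each slot
  merges <- vector("list", n - 1L)
  for (m in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- d2[idx, idx, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    best <- min(sub)
    cand <- which(sub == best, arr.ind = TRUE)
    # tie-break: smallest (left, right) creation-index pair
    keys <- cbind(pmin(node_id[idx[cand[, 1L]]], node_id[idx[cand[, 2L]]]),
                  pmax(node_id[idx[cand[, 1L]]], node_id[idx[cand[, 2L]]]))
    pick <- order(keys[, 1L], keys[, 2L])[1L]
    si <- idx[cand[pick, 1L]]
    sj <- idx[cand[pick, 2L]]
    if (node_id[si] > node_id[sj]) { tmp <- si; si <- sj; sj <- tmp }
    ni <- size[si]; nj <- size[sj]
    merges[[m]] <- list(step = m, left = slot_ref[si], right = slot_ref[sj],
                        height = sqrt(best), size = ni + nj)
    # Ward / Lance-Williams update into slot si
    others <- setdiff(idx, c(si, sj))
    if (length(others)) {
      nk <- size[others]
      d2new <- ((ni + nk) * d2[si, others] + (nj + nk) * d2[sj, others] -
                  nk * best) / (ni + nj + nk)
      d2[si, others] <- d2new
      d2[others, si] <- d2new
    }
    active[sj] <- FALSE
    size[si] <- ni + nj
    node_id[si] <- n + m
    slot_ref[si] <- m
  }
  new_pm_tree(rownames(x), dplyr::bind_rows(merges))
}

new_pm_tree <- function(ids, merges) {
  h <- merges$height
  if (length(h) > 1L && any(diff(h) < -1e-9 * max(h, 1))) {
    pm_abort("merge heights must be non-decreasing (Ward is monotone)",
             "petminer_internal_error")
  }
  structure(list(ids = ids, merges = merges), class = "pm_tree")
}

#' @export
print.pm_tree <- function(x, ...) {
  cat("<pm_tree> ", length(x$ids), " leaves, ", nrow(x$merges),
      " merges, max height ",
      format(max(c(0, x$merges$height)), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @describeIn ward_tree Merge table of a representation tree.
#' @param x A `pm_tree`.
#' @param ... Unused.
#' @export
tidy.pm_tree <- function(x, ...) as_tibble(x$merges)

#' @describeIn ward_tree One-row summary of a representation tree.
#' @export
glance.pm_tree <- function(x, ...) {
  tibble(n_leaves = length(x$ids), n_merges = nrow(x$merges),
         max_height = max(c(0, x$merges$height)))
}

#' Convert a representation tree to an hclust object
#' @param tree A `pm_tree`.
#' @return A [stats::hclust()] object (for Newick export or base plotting).
#' @export
as_hclust <- function(tree) {
  stopifnot(inherits(tree, "pm_tree"))
  n <- length(tree$ids)
  if (n < 2L) pm_abort("need at least 2 leaves", "petminer_format_error")
  merge <- cbind(tree$merges$left, tree$merges$right)
  # leaf order by walking the tree left-to-right
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  structure(list(merge = merge, height = tree$merges$height,
                 order = walk(n - 1L), labels = tree$ids,
                 method = "ward.D2", dist.method = "euclidean"),
            class = "hclust")
}

#' Export a representation tree as Newick
#'
#' Heights become branch lengths via the standard ultrametric conversion.
#'
#' @param tree A `pm_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  phy <- ape::as.phylo(as_hclust(tree))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Cut a representation tree into k clades
#'
#' Undoes the last `k - 1` merges; the connected subtrees that remain are
#' the clades. Cluster labels `1..k` are assigned in order of first
#' appearance along the input row order (the [stats::cutree()] convention).
#'
#' @param tree A `pm_tree`.
#' @param k Number of clades, `1 <= k <= n`.
#' @return Tibble with `id` and `cluster` (integer in `1..k`), one row per
#'   leaf in input order.
#' @export
cut_to_k <- function(tree, k) {
  n <- length(tree$ids)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > n) {
    pm_abort("k must lie in 1..n", "petminer_format_error")
  }
  k <- as.integer(k)
  comp <- seq_len(n)                # union-find by representative leaf
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  keep <- n - k                     # merges retained
  if (keep > 0L) {
    members <- vector("list", keep) # leaf sets per retained merge
    for (m in seq_len(keep)) {
      gather <- function(node) {
        if (node < 0L) return(-node)
        members[[node]]
      }
      lv <- c(gather(tree$merges$left[m]), gather(tree$merges$right[m]))
      members[[m]] <- lv
      comp[lv] <- lv[1L]
    }
  }
  rep_leaf <- vapply(seq_len(n), find, integer(1L))
  labels <- match(rep_leaf, unique(rep_leaf))
  tibble(id = tree$ids, cluster = labels)
}

#' Score clades by known-positive content and select for screening
#'
#' A clade is selected when it contains at least one reference positive
#' (e.g. an enzyme with previously validated activity). This containment
#' rule mirrors selecting the clades that hold all reported high-activity
#' reference enzymes.
#'
#' @param partition Tibble from [cut_to_k()] (`id`, `cluster`).
#' @param reference_positive_ids Character vector of known-positive ids;
#'   must be a non-empty subset of `partition$id`.
#' @return Tibble with one row per clade: `cluster`, `n_members`,
#'   `n_positives`, `positive_fraction`, `selected`.
#' @export
enrich_and_select <- function(partition, reference_positive_ids) {
  if (length(reference_positive_ids) == 0L) {
    pm_abort("reference positive set must be non-empty",
             "petminer_format_error")
  }
  missing <- setdiff(reference_positive_ids, partition$id)
  if (length(missing)) {
    pm_abort(paste0("reference ids absent from partition: ",
                    paste(utils::head(missing, 3L), collapse = ", ")),
             "petminer_format_error")
  }
  partition |>
    mutate(positive = .data$id %in% reference_positive_ids) |>
    group_by(.data$cluster) |>
    summarise(n_members = n(), n_positives = sum(.data$positive),
              .groups = "drop") |>
    mutate(positive_fraction = .data$n_positives / .data$n_members,
           selected = .data$n_positives >= 1L) |>
    arrange(.data$cluster)
}

#' Plot a representation tree as a dendrogram
#' @param object A `pm_tree`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pm_tree <- function(object, ...) {
  hc <- as_hclust(object)
  n <- length(object$ids)
  xpos <- numeric(n)                 # leaf x by dendrogram order
  xpos[hc$order] <- seq_len(n)
  nodes_x <- numeric(n - 1L)
  segs <- vector("list", n - 1L)
  node_pos <- function(node) {
    if (node < 0L) c(x = xpos[-node], h = 0) else
      c(x = nodes_x[node], h = hc$height[node])
  }
  for (m in seq_len(n - 1L)) {
    l <- node_pos(hc$merge[m, 1L]); r <- node_pos(hc$merge[m, 2L])
    h <- hc$height[m]
    nodes_x[m] <- (l["x"] + r["x"]) / 2
    segs[[m]] <- tibble(
      x = c(l[["x"]], l[["x"]], r[["x"]]),
      xend = c(l[["x"]], r[["x"]], r[["x"]]),
      y = c(l[["h"]], h, h),
      yend = c(h, h, r[["h"]]))
  }
  ggplot(dplyr::bind_rows(segs),
         aes(x = .data$x, y = .data$y,
             xend = .data$xend, yend = .data$yend)) +
    geom_segment() +
    labs(x = NULL, y = "merge height (embedding distance units)") +
    theme_minimal()
}
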