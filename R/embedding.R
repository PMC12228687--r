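# Distance computations over embedding rows. Embeddings live in the
# structure-aware representation space of a protein language model; closer
# vectors (Euclidean) mean more similar predicted structures, which is the
# retrieval primitive for both the representation tree and the EC benchmark.

#' Pairwise Euclidean distances between embedding rows
#'
#' @param embeddings Tibble with an `id` column plus numeric embedding
#'   columns (one row per protein).
#' @return Symmetric numeric matrix (zero diagonal) with ids as dimnames.
#' @export
pairwise_euclidean <- function(embeddings) {
  m <- embedding_matrix(embeddings)
  d <- as.matrix(dist(m, method = "euclidean"))
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Minimum distance from each pool protein to a query set
#'
#' Retrieval score used by the EC benchmark: for each pool row the Euclidean
#' distance to its nearest query. Lower scores mean more similar.
#'
#' @param pool Embedding tibble for the candidate pool.
#' @param queries Embedding tibble for the query set (same dimension).
#' @return Tibble with `id` and `score` (Angstrom-free embedding units),
#'   pool order preserved.
#' @export
min_distance_to_queries <- function(pool, queries) {
  p <- embedding_matrix(pool)
  q <- embedding_matrix(queries)
  if (nrow(q) == 0L) {
    pm_abort("query set must be non-empty", "petminer_format_error")
  }
  if (ncol(p) != ncol(q)) {
    pm_abort("pool and query embeddings must share dimension",
             "petminer_format_error")
  }
  # |p - q|^2 = |p|^2 + |q|^2 - 2 p.q, min over queries, in double precision
  cross <- p %*% t(q)
  d2 <- outer(rowSums(p^2), rep(1, nrow(q))) +
    outer(rep(1, nrow(p)), rowSums(q^2)) - 2 * cross
  d2[d2 < 0] <- 0   # numerical guard
  tibble(id = rownames(p), score = unname(sqrt(apply(d2, 1L, min))))
}
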