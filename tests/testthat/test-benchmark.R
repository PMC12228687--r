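test_that("AUROC matches hand values and pair counting", {
  p1 <- tibble::tibble(id = c("p", "n"), score = c(1, 2),
                       label = c(TRUE, FALSE))
  expect_equal(auroc(p1), 1.0)
  p2 <- tibble::tibble(id = c("p", "n"), score = c(1, 1),
                       label = c(TRUE, FALSE))
  expect_equal(auroc(p2), 0.5)
  p3 <- tibble::tibble(id = letters[1:4], score = c(1, 3, 2, 4),
                       label = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(auroc(p3), 0.75)
  expect_error(auroc(tibble::tibble(id = "a", score = 1, label = TRUE)),
               class = "petminer_format_error")
})

test_that("AUROC equals the brute-force pair statistic on random pools", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:60, 1L)
    pool <- tibble::tibble(id = sprintf("x%03d", seq_len(n)),
                           score = sample(seq_len(20), n, replace = TRUE),
                           label = sample(c(TRUE, FALSE), n, replace = TRUE,
                                          prob = c(0.3, 0.7)))
    if (!any(pool$label) || all(pool$label)) next
    expect_equal(auroc(pool), oracle_auroc(pool$score, pool$label))
    # negating scores while flipping the positive class preserves AUROC
    flipped <- dplyr::mutate(pool, score = -score, label = !label)
    expect_equal(auroc(flipped), auroc(pool))
  }
})

test_that("AUROC cross-checks against pROC on continuous scores", {
  skip_if_not_installed("pROC")
  set.seed(41)
  n <- 80
  pool <- tibble::tibble(id = seq_len(n), score = runif(n),
                         label = runif(n) < 0.4)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = pool$label, predictor = pool$score, direction = ">",
    quiet = TRUE)))
  expect_equal(auroc(pool), ref, tolerance = 1e-12)
})

test_that("average precision matches hand values and the rank-scan oracle", {
  p <- tibble::tibble(id = c("a", "b", "c"), score = c(1, 2, 3),
                      label = c(TRUE, FALSE, FALSE))
  expect_equal(average_precision(p), 1.0)
  p2 <- tibble::tibble(id = c("a", "b", "c"), score = c(1, 2, 3),
                       label = c(TRUE, FALSE, TRUE))
  expect_equal(average_precision(p2), (1 + 2 / 3) / 2)
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:80, 1L)
    pool <- tibble::tibble(id = sprintf("x%03d", seq_len(n)),
                           score = sample(seq_len(15), n, replace = TRUE),
                           label = sample(c(TRUE, FALSE), n,
                                          replace = TRUE))
    if (!any(pool$label)) next
    expect_equal(average_precision(pool),
                 oracle_ap(pool$id, pool$score, pool$label))
  }
  expect_error(average_precision(
    tibble::tibble(id = "a", score = 1, label = FALSE)),
    class = "petminer_format_error")
})

test_that("AP is 1 exactly when all positives precede all negatives", {
  perfect <- tibble::tibble(id = letters[1:5], score = 1:5,
                            label = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(average_precision(perfect), 1.0)
  nearly <- dplyr::mutate(perfect, label = c(TRUE, FALSE, TRUE, FALSE,
                                             FALSE))
  expect_lt(average_precision(nearly), 1.0)
})

test_that("shuffled labels give AP near prevalence on large pools", {
  set.seed(19)
  n <- 4000
  prev <- 0.3
  pool <- tibble::tibble(id = sprintf("x%04d", seq_len(n)),
                         score = runif(n),
                         label = runif(n) < prev)
  expect_equal(average_precision(pool), prev, tolerance = 0.1)
  expect_equal(auroc(pool), 0.5, tolerance = 0.05)
})

test_that("the EC benchmark recovers planted separable groups", {
  fx <- make_gaussian_embedding_clusters(3, 60, 6, separation = 40,
                                         spread = 3, seed = 23)
  bm <- ec_retrieval_benchmark(fx$embeddings, fx$annotations,
                               n_queries = 10, min_group = 50, seed = 5)
  expect_equal(sum(!bm$skipped), 3L)
  expect_true(all(bm$auroc[!bm$skipped] >= 0.95))
  g <- glance(bm)
  expect_gte(g$mean_auroc, 0.95)
  expect_equal(g$seed, 5)
  # permuted labels drive AUROC to chance
  ann_null <- fx$annotations
  set.seed(1)
  ann_null$ec_numbers <- sample(ann_null$ec_numbers)
  bm_null <- ec_retrieval_benchmark(fx$embeddings, ann_null,
                                    n_queries = 10, min_group = 50,
                                    seed = 5)
  expect_true(all(abs(bm_null$auroc[!bm_null$skipped] - 0.5) < 0.12))
})

test_that("groups below min_group are reported skipped", {
  fx <- make_gaussian_embedding_clusters(2, 49, 4, separation = 20,
                                         spread = 2, seed = 31)
  bm <- ec_retrieval_benchmark(fx$embeddings, fx$annotations,
                               n_queries = 5, min_group = 50, seed = 2)
  expect_true(all(bm$skipped))
  bm2 <- ec_retrieval_benchmark(fx$embeddings, fx$annotations,
                                n_queries = 5, min_group = 49, seed = 2)
  expect_false(any(bm2$skipped))
  expect_error(
    ec_retrieval_benchmark(fx$embeddings, fx$annotations, n_queries = 49,
                           min_group = 10, seed = 2),
    class = "petminer_format_error")
})
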