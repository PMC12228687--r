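test_that("degenerate and two-point trees follow the height convention", {
  one <- tibble::tibble(id = "a", e1 = 0)
  t1 <- ward_tree(one)
  expect_equal(nrow(t1$merges), 0L)
  # two singletons merge at their Euclidean distance
  two <- tibble::tibble(id = c("a", "b"), e1 = c(0, 3), e2 = c(0, 4))
  t2 <- ward_tree(two)
  expect_equal(t2$merges$height, 5.0)
  expect_equal(sort(c(t2$merges$left, t2$merges$right)), c(-2L, -1L))
})

test_that("1-D points {0, 1, 10} merge nearest pair first", {
  e <- tibble::tibble(id = c("a", "b", "c"), e1 = c(0, 1, 10))
  tr <- ward_tree(e)
  expect_equal(tr$merges$height[1L], 1.0)
  part <- cut_to_k(tr, 2)
  expect_equal(part$cluster, c(1L, 1L, 2L))
})

test_that("ward_tree agrees with the exhaustive variance-increase oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(3:8, 1L)
    d <- sample(1:3, 1L)
    x <- matrix(rnorm(n * d), nrow = n)
    e <- dplyr::bind_cols(tibble::tibble(id = paste0("p", seq_len(n))),
                          tibble::as_tibble(as.data.frame(x),
                                            .name_repair = ~paste0(
                                              "e", seq_len(d))))
    tr <- ward_tree(e)
    orc <- oracle_ward(x)
    expect_equal(tr$merges$height, orc$heights, tolerance = 1e-9)
    for (m in seq_len(n - 1L)) {
      got <- cut_to_k(tr, n - m)$cluster
      expect_equal(canon_partition(got),
                   canon_partition(orc$partitions[[m]]))
    }
  }
})

test_that("heights are non-decreasing and cuts nest", {
  fx <- make_gaussian_embedding_clusters(3, 10, 4, 12, 2, seed = 21)
  tr <- ward_tree(fx$embeddings)
  expect_true(all(diff(tr$merges$height) >= -1e-9))
  n <- length(tr$ids)
  for (k in 2:6) {
    fine <- cut_to_k(tr, k)$cluster
    coarse <- cut_to_k(tr, k - 1L)$cluster
    # every fine cluster lies inside exactly one coarse cluster
    expect_true(all(tapply(coarse, fine,
                           function(v) length(unique(v))) == 1L))
  }
  expect_equal(unique(sort(cut_to_k(tr, n)$cluster)), seq_len(n))
  expect_equal(unique(cut_to_k(tr, 1)$cluster), 1L)
  expect_error(cut_to_k(tr, 0), class = "petminer_format_error")
  expect_error(cut_to_k(tr, n + 1L), class = "petminer_format_error")
})

test_that("row permutation permutes the partition, not its structure", {
  set.seed(31)
  e <- tibble::tibble(id = paste0("p", 1:12), e1 = rnorm(12),
                      e2 = rnorm(12))
  perm <- sample(12)
  p1 <- cut_to_k(ward_tree(e), 4)
  p2 <- cut_to_k(ward_tree(e[perm, ]), 4)
  joined <- dplyr::left_join(p1, p2, by = "id")
  key <- function(g) sort(unname(vapply(g, function(v) paste(sort(v),
                                                             collapse = ","),
                                        character(1L))))
  expect_equal(key(split(joined$id, joined$cluster.x)),
               key(split(joined$id, joined$cluster.y)))
})

test_that("ward heights cross-check against hclust ward.D2", {
  set.seed(77)
  x <- matrix(rnorm(20 * 3), nrow = 20)
  e <- dplyr::bind_cols(tibble::tibble(id = sprintf("p%02d", 1:20)),
                        tibble::as_tibble(as.data.frame(x),
                                          .name_repair = ~paste0("e", 1:3)))
  tr <- ward_tree(e)
  hc <- stats::hclust(dist(x), method = "ward.D2")
  expect_equal(tr$merges$height, hc$height, tolerance = 1e-9)
  for (k in c(2, 4, 7)) {
    expect_equal(canon_partition(cut_to_k(tr, k)$cluster),
                 canon_partition(unname(stats::cutree(hc, k))))
  }
})

test_that("clade enrichment selects every positive-containing clade", {
  part <- tibble::tibble(id = paste0("p", 1:9),
                         cluster = rep(1:3, each = 3))
  enr <- enrich_and_select(part, c("p4", "p5"))
  expect_equal(enr$selected, c(FALSE, TRUE, FALSE))
  expect_equal(enr$positive_fraction, c(0, 2 / 3, 0))
  expect_equal(sum(enr$n_members), 9L)
  # positives split across clusters 1 and 3 select both
  enr2 <- enrich_and_select(part, c("p1", "p9"))
  expect_equal(enr2$selected, c(TRUE, FALSE, TRUE))
  expect_error(enrich_and_select(part, character(0)),
               class = "petminer_format_error")
  expect_error(enrich_and_select(part, "nope"),
               class = "petminer_format_error")
})

test_that("planted-positive component is recovered at the planted k", {
  fx <- make_gaussian_embedding_clusters(3, 15, 6, separation = 30,
                                         spread = 3, seed = 13)
  tr <- ward_tree(fx$embeddings)
  part <- cut_to_k(tr, 3)
  enr <- enrich_and_select(part,
                           fx$annotations$id[fx$annotations$validated_positive])
  expect_equal(sum(enr$selected), 1L)
  sel <- enr$cluster[enr$selected]
  sel_ids <- part$id[part$cluster == sel]
  expect_setequal(sel_ids, fx$truth$id[fx$truth$component == 1L])
})

test_that("newick export and hclust conversion are structurally sound", {
  fx <- make_gaussian_embedding_clusters(2, 5, 3, 10, 1, seed = 3)
  tr <- ward_tree(fx$embeddings)
  hc <- as_hclust(tr)
  expect_s3_class(hc, "hclust")
  expect_setequal(hc$order, seq_along(tr$ids))
  f <- tempfile(fileext = ".nwk")
  write_newick(tr, f)
  phy <- ape::read.tree(f)
  expect_setequal(phy$tip.label, tr$ids)
})
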