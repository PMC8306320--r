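test_that("inference configuration is validated", {
  expect_error(inference_config(r_threshold = 1.2), "r_threshold")
  expect_error(inference_config(n_permutations = 50), "n_permutations")
  expect_error(inference_config(min_support = 5), "min_support")
})

test_that("pairwise statistics match naive direct recomputation", {
  set.seed(21)
  counts <- matrix(rpois(200, 40), 20, 10,
                   dimnames = list(sprintf("s%02d", 1:20), sprintf("t%02d", 1:10)))
  m <- abundance_matrix(counts)
  meas <- pairwise_measures(m)
  relab <- sweep(counts, 1, rowSums(counts), "/")
  eps <- 1e-6
  q <- sweep(relab + eps, 2, colSums(relab + eps), "/")
  for (i in 1:9) for (j in (i + 1):10) {
    x <- relab[, i]; y <- relab[, j]
    expect_equal(meas$spearman[i, j], cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
    expect_equal(meas$pearson[i, j], cor(x, y), tolerance = 1e-12)
    expect_equal(meas$bray[i, j], sum(abs(x - y)) / sum(x + y),
                 tolerance = 1e-12)
    kl_xy <- sum(q[, i] * log(q[, i] / q[, j]))
    kl_yx <- sum(q[, j] * log(q[, j] / q[, i]))
    expect_equal(meas$kl[i, j], (kl_xy + kl_yx) / 2, tolerance = 1e-12)
  }
})

test_that("self-comparison attains the identity values", {
  set.seed(3)
  counts <- matrix(rpois(40, 30) + 1L, 10, 4,
                   dimnames = list(paste0("s", 1:10), paste0("t", 1:4)))
  m <- abundance_matrix(abundance_matrix(counts)$counts)
  # diagnostic: duplicate one taxon so a pair is a perfect copy
  counts2 <- cbind(counts, t5 = counts[, 1])
  meas <- pairwise_measures(abundance_matrix(counts2))
  expect_equal(meas$spearman["t1", "t5"], 1, tolerance = 1e-12)
  expect_equal(meas$pearson["t1", "t5"], 1, tolerance = 1e-12)
  expect_equal(meas$bray["t1", "t5"], 0, tolerance = 1e-12)
  expect_equal(meas$kl["t1", "t5"], 0, tolerance = 1e-12)
  # perfectly reversed ranks
  rev_counts <- cbind(a = c(10L, 20L, 30L, 40L, 50L),
                      b = c(50L, 40L, 30L, 20L, 10L),
                      c = c(7L, 8L, 9L, 10L, 11L))
  rownames(rev_counts) <- paste0("s", 1:5)
  mr <- pairwise_measures(abundance_matrix(rev_counts))
  expect_equal(mr$spearman["a", "b"], -1, tolerance = 1e-12)
})

test_that("constant taxa are flagged invalid, tiny sample sets error", {
  counts <- cbind(a = c(5L, 6L, 7L, 8L), b = c(0L, 0L, 0L, 0L),
                  c = c(8L, 7L, 6L, 5L))
  rownames(counts) <- paste0("s", 1:4)
  expect_message(meas <- pairwise_measures(abundance_matrix(counts)),
                 "constant")
  expect_false(meas$valid["a", "b"])
  expect_true(meas$valid["a", "c"])
  expect_error(pairwise_measures(abundance_matrix(counts[1:3, ])),
               "4 samples")
})

test_that("permutation p-values are deterministic, floored and sane", {
  d <- planted_design(n_samples = 60, n_taxa = 12, block_sizes = c(4, 4),
                      within_block_corr = 0.95, depth = 5000, seed = 6)
  m <- generate_planted_counts(d)
  cfg <- inference_config(n_permutations = 1000, seed = 4)
  meas <- pairwise_measures(m, cfg)
  pv <- permutation_pvalues(meas, cfg)
  pv2 <- permutation_pvalues(meas, cfg)
  expect_identical(pv, pv2)
  # add-one estimator: no p is 0, floor is 1/(B+1)
  expect_true(all(pv$spearman >= 1 / 1001))
  blk <- attr(m, "block")
  strong <- which(outer(blk, blk, "==") & outer(blk > 0, blk > 0, "&") &
                    upper.tri(diag(12)), arr.ind = TRUE)
  expect_true(all(pv$spearman[strong] <= 0.001 + 1e-12))
  # an independent pair sits well inside the null
  ind <- which(blk == 0)[1:2]
  expect_gt(pv$spearman[ind[1], ind[2]], 0.05)
})

test_that("the built network obeys its own postconditions and recovers planted blocks", {
  d <- planted_design(n_samples = 60, n_taxa = 60, block_sizes = c(10, 10),
                      within_block_corr = 0.9, depth = 20000, seed = 2)
  m <- generate_planted_counts(d)
  cfg <- inference_config(n_permutations = 1000, seed = 1)
  net <- infer_network(m, cfg)
  expect_gt(nrow(net$edges), 0)
  expect_true(all(abs(net$edges$correlation) > 0.8))
  expect_true(all(net$edges$q_value <= 0.05))
  expect_true(all(net$edges$support >= 2))
  expect_true(all(net$edges$sign == sign(net$edges$correlation)))
  # no isolated nodes
  expect_setequal(net$nodes$id, unique(c(net$edges$source, net$edges$target)))
  key <- planted_pairs(m)
  got <- edge_keys(net)
  expect_gte(mean(key %in% got), 0.8)
  expect_equal(sum(!(got %in% key)), 0)
})

test_that("the network is invariant to sample and taxon ordering", {
  d <- planted_design(n_samples = 30, n_taxa = 20, block_sizes = c(6, 6),
                      depth = 5000, seed = 9)
  m <- generate_planted_counts(d)
  cfg <- inference_config(n_permutations = 300, min_support = 1, seed = 5)
  base <- infer_network(m, cfg)
  set.seed(1)
  perm_s <- sample(nrow(m$counts)); perm_t <- sample(ncol(m$counts))
  m2 <- abundance_matrix(m$counts[perm_s, perm_t], taxonomy = m$taxonomy)
  shuf <- infer_network(m2, cfg)
  expect_equal(base$edges[, c("source", "target", "sign")],
               shuf$edges[, c("source", "target", "sign")])
})

test_that("independent data yield edges within the FDR budget", {
  d <- planted_design(n_samples = 60, n_taxa = 40, block_sizes = c(10, 10),
                      within_block_corr = 0, depth = 20000, seed = 13)
  m <- generate_planted_counts(d)
  net <- infer_network(m, inference_config(n_permutations = 500, seed = 2))
  n_pairs <- choose(40, 2)
  expect_lte(nrow(net$edges), 0.05 * n_pairs)
})

test_that("an empty candidate set gives an empty network, not an error", {
  counts <- matrix(rpois(80, 50) + 1L, 20, 4,
                   dimnames = list(paste0("s", 1:20), paste0("t", 1:4)))
  m <- abundance_matrix(counts)
  cfg <- inference_config(n_permutations = 100, min_taxon_total = 0, seed = 1)
  net <- infer_network(m, cfg)
  expect_s3_class(net, "co_network")
  expect_equal(nrow(net$edges), 0)
})
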