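two_triangles <- function() {
  make_net(rbind(c("a", "b"), c("a", "c"), c("b", "c"),
                 c("d", "e"), c("d", "f"), c("e", "f")))
}

test_that("two disconnected triangles split into two modules with Q = 0.5", {
  net <- two_triangles()
  part <- detect_modules(net)
  expect_equal(part$n_modules, 2)
  expect_equal(part$Q, 0.5, tolerance = 1e-12)
  # oracle: exhaustive search over all 203 partitions of 6 nodes
  adj <- bf_adjacency(net)
  best <- max(vapply(all_partitions(6), function(p) bf_modularity(adj, p),
                     numeric(1)))
  expect_equal(part$Q, best, tolerance = 1e-12)
  # detection is deterministic
  expect_identical(part$membership, detect_modules(net)$membership)
})

test_that("a complete graph is a single module with Q = 0", {
  ids <- letters[1:5]
  net <- make_net(t(utils::combn(ids, 2)))
  part <- detect_modules(net)
  expect_equal(part$n_modules, 1)
  expect_equal(part$Q, 0, tolerance = 1e-12)
})

test_that("reported Q matches direct recomputation of the modularity formula", {
  set.seed(31)
  for (rep in 1:10) {
    rng <- runif(choose(15, 2))
    em <- random_edges(15, 0.25, rng)
    if (nrow(em) < 2) next
    net <- make_net(em)
    part <- detect_modules(net)
    adj <- bf_adjacency(net)
    expect_equal(part$Q,
                 bf_modularity(adj, part$membership[rownames(adj)]),
                 tolerance = 1e-12)
  }
})

test_that("planted two-block networks are recovered with high ARI", {
  d <- planted_design(n_samples = 60, n_taxa = 60, block_sizes = c(10, 10),
                      within_block_corr = 0.9, depth = 20000, seed = 2)
  m <- generate_planted_counts(d)
  net <- infer_network(m, inference_config(n_permutations = 1000, seed = 1))
  part <- detect_modules(net)
  blk <- attr(m, "block")[match(net$nodes$id, colnames(m$counts))]
  expect_gte(bf_ari(part$membership[net$nodes$id], blk), 0.8)
})

test_that("zi and pi follow their closed forms", {
  # node x: 4 links split evenly over 2 modules -> pi = 0.5
  net <- make_net(rbind(c("x", "a1"), c("x", "a2"), c("x", "b1"), c("x", "b2"),
                        c("a1", "a2"), c("b1", "b2")))
  memb <- c(x = 1L, a1 = 1L, a2 = 1L, b1 = 2L, b2 = 2L)
  roles <- classify_roles(net, memb)
  expect_equal(roles$pi[roles$node == "x"], 0.5)
  # all links internal -> pi = 0
  expect_equal(roles$pi[roles$node == "a1"], 0)
  # equal within-degrees in module 2 -> zi = 0 there
  expect_equal(roles$zi[roles$node == "b1"], 0)
})

test_that("zi and pi match brute-force recomputation on random partitioned graphs", {
  set.seed(47)
  for (rep in 1:10) {
    rng <- runif(choose(20, 2))
    em <- random_edges(20, 0.3, rng)
    net <- make_net(em)
    memb <- setNames(sample(1:3, nrow(net$nodes), replace = TRUE),
                     net$nodes$id)
    roles <- classify_roles(net, memb)
    adj <- bf_adjacency(net)
    oracle <- bf_zipi(adj, memb[rownames(adj)])
    expect_equal(roles$zi, oracle$zi[match(roles$node, oracle$node)],
                 tolerance = 1e-12)
    expect_equal(roles$pi, oracle$pi[match(roles$node, oracle$node)],
                 tolerance = 1e-12)
    expect_true(all(roles$pi >= 0 & roles$pi < 1))
  }
})

test_that("role classification respects strict thresholds at the boundary", {
  # category must use strict >: exactly 2.5 / 0.62 falls to the lower class
  fake_classify <- function(zi, pi) {
    ifelse(zi > 2.5, ifelse(pi > 0.62, "network hub", "module hub"),
           ifelse(pi > 0.62, "connector", "peripheral"))
  }
  expect_equal(fake_classify(2.5, 0.62), "peripheral")
  expect_equal(fake_classify(2.51, 0.62), "module hub")
  expect_equal(fake_classify(2.5, 0.63), "connector")
  # and the package agrees with the rule on a constructed graph:
  # star hub with 8 leaves + 5-clique elsewhere: hub zi high, pi 0
  em <- rbind(cbind("hub", paste0("l", 1:8)), t(utils::combn(paste0("c", 1:5), 2)))
  net <- make_net(em)
  memb <- setNames(c(1L, rep(1L, 8), rep(2L, 5)),
                   c("hub", paste0("l", 1:8), paste0("c", 1:5)))
  roles <- classify_roles(net, memb)
  expect_equal(roles$category[roles$node == "hub"], "module hub")
  expect_true(all(roles$category[roles$node != "hub"] == "peripheral"))
})

test_that("role classification commutes with node relabeling", {
  set.seed(8)
  rng <- runif(choose(12, 2))
  em <- random_edges(12, 0.35, rng)
  net <- make_net(em)
  memb <- setNames(sample(1:2, nrow(net$nodes), replace = TRUE), net$nodes$id)
  roles <- classify_roles(net, memb)
  relabel <- setNames(sprintf("z%02d", seq_along(net$nodes$id)), net$nodes$id)
  net2 <- make_net(cbind(relabel[em[, 1]], relabel[em[, 2]]))
  memb2 <- setNames(memb, relabel[names(memb)])
  roles2 <- classify_roles(net2, memb2)
  ord <- match(relabel[roles$node], roles2$node)
  expect_equal(roles$zi, roles2$zi[ord], tolerance = 1e-12)
  expect_equal(roles$pi, roles2$pi[ord], tolerance = 1e-12)
  expect_equal(roles$category, roles2$category[ord])
})

test_that("the role census sums to one and finds a forced connector", {
  # 20-node network: node k spreads 5 links over three modules
  # (1 own + 2 + 2): pi = 1 - (0.04 + 0.16 + 0.16) = 0.64 > 0.62
  cl1 <- t(utils::combn(paste0("a", 1:6), 2))
  cl2 <- t(utils::combn(paste0("b", 1:6), 2))
  cl3 <- t(utils::combn(paste0("c", 1:7), 2))
  bridge <- rbind(c("k", "a1"), c("k", "b1"), c("k", "b2"),
                  c("k", "c1"), c("k", "c2"))
  net <- make_net(rbind(cl1, cl2, cl3, bridge))
  memb <- setNames(c(rep(1L, 6), rep(2L, 6), rep(3L, 7), 1L),
                   c(paste0("a", 1:6), paste0("b", 1:6), paste0("c", 1:7), "k"))
  roles <- classify_roles(net, memb)
  cen <- role_census(roles)
  expect_equal(sum(cen$fractions), 1)
  expect_equal(roles$pi[roles$node == "k"], 0.64)
  expect_equal(roles$category[roles$node == "k"], "connector")
  expect_equal(cen$fractions[["connector"]], 0.05)
  expect_equal(cen$keystones, "k")
})

test_that("shared-node statistics reproduce the Venn arithmetic", {
  a <- paste0("t", 1:10); b <- paste0("t", 6:20)
  s <- shared_nodes(a, b)
  expect_equal(s$shared, 5)
  expect_equal(s$pct_shared, 25)
  expect_equal(shared_nodes(a, a)$pct_shared, 100)
  expect_equal(shared_nodes(a, paste0("u", 1:4))$pct_shared, 0)
  # published node counts: |A|=260, |B|=1010, shared 123 -> 10.7%
  s2 <- shared_nodes(sprintf("o%04d", 1:260),
                     sprintf("o%04d", 138:1147))
  expect_equal(s2$shared, 123)
  expect_equal(s2$pct_shared, 10.7)
})

test_that("module profiles partition nodes and edges consistently", {
  net <- two_triangles()
  part <- detect_modules(net)
  prof <- module_profiles(net, part)
  expect_equal(sum(prof$summary$size), nrow(net$nodes))
  expect_equal(sum(prof$summary$intra_pos + prof$summary$intra_neg) +
                 sum(prof$summary$inter) / 2, nrow(net$edges))
  expect_equal(prof$summary$inter, c(0, 0))
  # 6-node module in a 100-node network is major (6 > 5)
  expect_true(6 > 0.05 * 100)
  prof_one <- module_profiles(make_net(rbind(c("a", "b"))),
                              setNames(c(1L, 1L), c("a", "b")))
  expect_equal(prof_one$summary$inter, 0)
})

test_that("major modules inherit their planted phylum composition", {
  d <- planted_design(n_samples = 60, n_taxa = 60, block_sizes = c(10, 10),
                      within_block_corr = 0.9, depth = 20000, seed = 2)
  m <- generate_planted_counts(d)
  net <- infer_network(m, inference_config(n_permutations = 1000, seed = 1))
  part <- detect_modules(net)
  prof <- module_profiles(net, part, taxonomy = m$taxonomy)
  major <- prof$summary$module[prof$summary$is_major]
  expect_gte(length(major), 2)
  for (s in major) {
    expect_gte(max(prof$phylum_fractions[[as.character(s)]]), 0.9)
  }
})
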