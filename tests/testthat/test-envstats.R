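test_that("normality screening transforms exactly the non-normal variables", {
  set.seed(14)
  env <- data.frame(normalvar = rnorm(60),
                    lognormalvar = exp(rnorm(60, 0, 1)),
                    withzeros = c(0, abs(rnorm(59)) * 10))
  out <- normality_transform(env)
  rep <- out$report
  expect_false(rep$transformed[rep$variable == "normalvar"])
  expect_true(rep$transformed[rep$variable == "lognormalvar"])
  # the transformed variable now passes Shapiro-Wilk
  expect_gt(shapiro.test(out$data$lognormalvar)$p.value, 0.05)
  # zeros handled by shifting, never a domain error
  if (rep$transformed[rep$variable == "withzeros"]) {
    expect_true(all(is.finite(out$data$withzeros)))
    expect_gt(rep$shift[rep$variable == "withzeros"], 0)
  }
  # constant variables are skipped
  out2 <- normality_transform(data.frame(k = rep(1.5, 10)))
  expect_match(out2$report$note, "skipped")
})

test_that("correlation tables match the closed-form Pearson formula", {
  x <- data.frame(v = c(1, 2, 4, 7, 11), row.names = paste0("s", 1:5))
  y <- data.frame(w = c(2, 1, 5, 6, 13), row.names = paste0("s", 1:5))
  tab <- correlate_tables(x, y)
  r_hand <- sum((x$v - mean(x$v)) * (y$w - mean(y$w))) /
    sqrt(sum((x$v - mean(x$v))^2) * sum((y$w - mean(y$w))^2))
  expect_equal(tab$r["v", "w"], r_hand, tolerance = 1e-12)
  expect_equal(correlate_tables(x, x)$r["v", "v"], 1)
  # symmetry of roles
  tab2 <- correlate_tables(y, x)
  expect_equal(tab$r["v", "w"], tab2$r["w", "v"], tolerance = 1e-12)
  expect_equal(tab$p["v", "w"], tab2$p["w", "v"], tolerance = 1e-12)
})

test_that("pairwise deletion leaves unrelated cells untouched", {
  set.seed(9)
  x <- data.frame(a = rnorm(10), b = rnorm(10), row.names = paste0("s", 1:10))
  y <- data.frame(c = rnorm(10), d = rnorm(10), row.names = paste0("s", 1:10))
  full <- correlate_tables(x, y)
  x2 <- x; x2$a[3] <- NA
  part <- correlate_tables(x2, y)
  expect_equal(part$r["b", "c"], full$r["b", "c"], tolerance = 1e-12)
  expect_equal(part$r["b", "d"], full$r["b", "d"], tolerance = 1e-12)
  expect_equal(part$n["a", "c"], 9)
  # fewer than 3 complete pairs -> empty cell
  x3 <- x; x3$a[1:8] <- NA
  expect_true(is.na(correlate_tables(x3, y)$r["a", "c"]))
})

test_that("planted environment-block association shows up as a significant cell", {
  d <- planted_design(n_samples = 60, n_taxa = 100, block_sizes = c(10, 10),
                      seed = 4)
  m <- generate_planted_counts(d)
  env <- generate_env_table(m, linked_block = 1, strength = 0.9,
                            variable_names = c("DOC", "T"), seed = 9)
  blk <- attr(m, "block"); sg <- attr(m, "loading_sign")
  relab <- relative_abundance(m)
  aligned <- relab[, blk == 1 & sg == 1, drop = FALSE]
  idx <- data.frame(block1 = rowMeans(aligned),
                    row.names = rownames(relab))
  tab <- correlate_tables(idx, env)
  expect_gt(tab$r["block1", "DOC"], 0.6)
  expect_true(tab$sig["block1", "DOC"])
  # the unlinked variable is at most weakly (chance-level) associated
  expect_lt(abs(tab$r["block1", "T"]), tab$r["block1", "DOC"] - 0.2)
})

test_that("keystone-environment networks keep only strong significant edges", {
  d <- planted_design(n_samples = 60, n_taxa = 100, block_sizes = c(10, 10),
                      seed = 4)
  m <- generate_planted_counts(d)
  env <- generate_env_table(m, linked_block = 1, strength = 0.95,
                            variable_names = c("DOC", "T"), seed = 9)
  blk <- attr(m, "block"); sg <- attr(m, "loading_sign")
  keys <- colnames(m$counts)[blk == 1 & sg == 1][1:3]
  ke <- keystone_env_network(keys, m, env, r_min = 0.6, alpha = 0.05)
  expect_gt(nrow(ke$network$edges), 0)
  # edge pairs are stored in canonical order; the variable endpoint is DOC
  env_end <- ifelse(ke$network$edges$source %in% keys,
                    ke$network$edges$target, ke$network$edges$source)
  expect_true(all(env_end == "DOC"))
  expect_true(all(abs(ke$network$edges$correlation) >= 0.6))
  expect_true(all(ke$network$edges$sign ==
                    sign(ke$network$edges$correlation)))
  # no keystones -> empty network, message not error
  expect_message(e <- keystone_env_network(character(0), m, env), "no keystone")
  expect_equal(nrow(e$network$edges), 0)
})

test_that("group comparison reproduces textbook ANOVA arithmetic", {
  # hand-computed one-way ANOVA: groups {1,2,3}, {2,3,4}, {6,7,8}
  v <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- group_compare(v, g)
  # grand mean 4; SSB = 3*((2-4)^2+(3-4)^2+(7-4)^2) = 42; SSW = 6; MSB=21, MSW=1
  expect_equal(res$F, 21, tolerance = 1e-12)
  expect_equal(res$mse, 1, tolerance = 1e-12)
  expect_equal(res$p, pf(21, 2, 6, lower.tail = FALSE), tolerance = 1e-12)
  # LSD p for a vs b: t = (2-3)/sqrt(1*(1/3+1/3)) on 6 df
  t_ab <- -1 / sqrt(2 / 3)
  lsd_ab <- res$lsd[res$lsd$group1 == "a" & res$lsd$group2 == "b", ]
  expect_equal(lsd_ab$t, t_ab, tolerance = 1e-12)
  expect_equal(lsd_ab$p, 2 * pt(-abs(t_ab), 6), tolerance = 1e-12)
})

test_that("two-group LSD equals the pooled-variance t-test", {
  set.seed(22)
  v <- c(rnorm(10), rnorm(12, 1))
  g <- rep(c("x", "y"), c(10, 12))
  res <- group_compare(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(res$lsd$p, tt$p.value, tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)  # F = t^2 for 2 groups
})

test_that("group comparison has power for large shifts and is null for clones", {
  set.seed(16)
  base <- rnorm(10)
  res0 <- group_compare(c(base, base, base), rep(c("a", "b", "c"), each = 10))
  expect_lt(res0$F, 1e-20)
  expect_gt(res0$p, 0.999)
  v <- c(rnorm(10), rnorm(10, 5))
  res1 <- group_compare(v, rep(c("a", "b"), each = 10))
  expect_lt(res1$p, 0.001)
  expect_warning(group_compare(c(1, 2, 3, 4, 9), c("a", "a", "b", "b", "c")),
                 "singleton")
})
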