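#' Normality screening and log transformation of environmental variables
#'
#' Each numeric variable is tested with the Shapiro-Wilk test; variables
#' failing at `alpha` are log-transformed, `log(x + shift)` with `shift = 0`
#' when all values are positive and `|min| + epsilon` otherwise. Constant
#' variables are skipped.
#'
#' @param env data.frame of environmental variables (numeric columns).
#' @param alpha Normality rejection level (default 0.05).
#' @return List: `data` (transformed table) and `report` (data.frame with
#'   per-variable W, p, decision and shift).
#' @export
normality_transform <- function(env, alpha = 0.05) {
  env <- as.data.frame(env)
  num <- names(env)[vapply(env, is.numeric, logical(1))]
  rep_rows <- list()
  for (v in num) {
    x <- env[[v]]
    xx <- x[!is.na(x)]
    if (length(unique(xx)) < 3) {
      rep_rows[[v]] <- data.frame(variable = v, W = NA_real_, p = NA_real_,
                                  transformed = FALSE, shift = NA_real_,
                                  note = "constant or near-constant; skipped")
      next
    }
    sw <- stats::shapiro.test(xx)
    transformed <- sw$p.value < alpha
    shift <- 0
    if (transformed) {
      if (min(xx) <= 0) shift <- abs(min(xx)) + sqrt(.Machine$double.eps)
      env[[v]] <- log(x + shift)
    }
    rep_rows[[v]] <- data.frame(variable = v, W = sw$statistic, p = sw$p.value,
                                transformed = transformed, shift = shift,
                                note = "")
  }
  report <- do.call(rbind, rep_rows)
  rownames(report) <- NULL
  list(data = env, report = report)
}

#' Pearson correlation table between two sets of variables
#'
#' Correlates every column of `x` with every column of `y` (Pearson, two
#' sided), handling missing values by pairwise deletion. Cells with fewer
#' than 3 complete pairs are reported empty.
#'
#' @param x,y data.frames sharing row keys (rows are observations; `y`
#'   defaults to `x`).
#' @return List of class `correlation_table` with matrices `r`, `p`, `n` and
#'   logical `sig` (`p <= alpha`).
#' @param alpha Significance level for the `sig` flags (default 0.05).
#' @export
correlate_tables <- function(x, y = x, alpha = 0.05) {
  x <- as.data.frame(x); y <- as.data.frame(y)
  common <- intersect(rownames(x), rownames(y))
  if (length(common) < 3) stop("fewer than 3 shared observations")
  x <- x[common, , drop = FALSE]; y <- y[common, , drop = FALSE]
  xn <- names(x)[vapply(x, is.numeric, logical(1))]
  yn <- names(y)[vapply(y, is.numeric, logical(1))]
  r <- p <- n <- matrix(NA_real_, length(xn), length(yn),
                        dimnames = list(xn, yn))
  for (i in xn) for (j in yn) {
    ok <- stats::complete.cases(x[[i]], y[[j]])
    n[i, j] <- sum(ok)
    if (sum(ok) < 3) next
    if (stats::sd(x[[i]][ok]) == 0 || stats::sd(y[[j]][ok]) == 0) next
    ct <- stats::cor.test(x[[i]][ok], y[[j]][ok], method = "pearson")
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  structure(list(r = r, p = p, n = n, sig = !is.na(p) & p <= alpha,
                 alpha = alpha),
            class = "correlation_table")
}

#' Bipartite keystone-taxa / environment correlation network
#'
#' Correlates the relative abundance of each keystone taxon with every
#' environmental variable and keeps edges with `|r| >= r_min` and
#' `p <= alpha`, mirroring the strong-correlation rule of the main
#' co-occurrence network.
#'
#' @param roles A [classify_roles()] result (keystones = non-peripheral
#'   nodes), or a character vector of keystone taxon ids.
#' @param mat The `abundance_matrix` the roles were derived from.
#' @param env data.frame of environmental variables, rows matching samples.
#' @param r_min Minimum absolute Pearson correlation (default 0.8).
#' @param alpha Significance level (default 0.05).
#' @return List: `network` (a bipartite `co_network`, taxa x variables) and
#'   `pos_neg_ratio` (positive:negative edge counts).
#' @export
keystone_env_network <- function(roles, mat, env, r_min = 0.8, alpha = 0.05) {
  keystones <- if (is.data.frame(roles)) role_census(roles)$keystones
               else as.character(roles)
  empty <- co_network(
    data.frame(id = character(), phylum = character(), mean_abundance = numeric()),
    data.frame(source = character(), target = character(), sign = numeric(),
               correlation = numeric(), support = numeric(), q_value = numeric()))
  if (length(keystones) == 0) {
    message("keystone_env_network: no keystone taxa")
    return(list(network = empty, pos = 0, neg = 0, pos_neg_ratio = NA_real_))
  }
  relab <- relative_abundance(mat)
  keystones <- intersect(keystones, colnames(relab))
  tab <- correlate_tables(as.data.frame(relab[, keystones, drop = FALSE]),
                          as.data.frame(env), alpha = alpha)
  hit <- which(!is.na(tab$r) & abs(tab$r) >= r_min & tab$p <= alpha,
               arr.ind = TRUE)
  if (nrow(hit) == 0) {
    message("keystone_env_network: no correlations pass the thresholds")
    return(list(network = empty, pos = 0, neg = 0, pos_neg_ratio = NA_real_))
  }
  edges <- data.frame(source = rownames(tab$r)[hit[, 1]],
                      target = colnames(tab$r)[hit[, 2]],
                      sign = sign(tab$r[hit]), correlation = tab$r[hit],
                      support = 1, q_value = tab$p[hit])
  ids <- sort(unique(c(edges$source, edges$target)))
  nodes <- data.frame(id = ids,
                      phylum = ifelse(ids %in% keystones, "taxon", "variable"),
                      mean_abundance = NA_real_)
  net <- co_network(nodes, edges)
  pos <- sum(edges$sign > 0); neg <- sum(edges$sign < 0)
  list(network = net, pos = pos, neg = neg,
       pos_neg_ratio = if (neg > 0) pos / neg else NA_real_)
}

#' One-way ANOVA with Fisher's LSD post hoc comparisons
#'
#' Classical one-way analysis of variance followed by Fisher's least
#' significant difference pairwise tests: each pair is compared with a t
#' statistic using the pooled within-group variance (ANOVA mean square
#' error) on the residual degrees of freedom, with no additional
#' multiplicity correction (the LSD convention).
#'
#' @param values Numeric vector of observations.
#' @param groups Factor (or coercible) of group labels, >= 2 groups with
#'   >= 2 values each; singleton groups are excluded with a warning.
#' @return List of class `group_compare`: `F`, `p`, `df`, `mse` and
#'   data.frame `lsd` (group pair, mean difference, t, p).
#' @export
group_compare <- function(values, groups) {
  groups <- factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  sizes <- table(groups)
  if (any(sizes < 2)) {
    warning("excluding singleton group(s): ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
    keep <- groups %in% names(sizes)[sizes >= 2]
    values <- values[keep]; groups <- droplevels(groups[keep])
    sizes <- table(groups)
  }
  if (nlevels(groups) < 2) stop("need at least 2 groups with >= 2 values each")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  Fv <- an["groups", "F value"]; pv <- an["groups", "Pr(>F)"]
  mse <- an["Residuals", "Mean Sq"]; dfr <- an["Residuals", "Df"]
  means <- tapply(values, groups, mean)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  lsd <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt(mse * (1 / sizes[[a]] + 1 / sizes[[b]]))
    tv <- (means[[a]] - means[[b]]) / se
    data.frame(group1 = a, group2 = b, diff = means[[a]] - means[[b]],
               t = tv, p = 2 * stats::pt(-abs(tv), dfr))
  }))
  structure(list(F = Fv, p = pv, df = c(an["groups", "Df"], dfr), mse = mse,
                 means = means, lsd = lsd),
            class = "group_compare")
}
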