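#' Configuration for ensemble co-occurrence inference
#'
#' @param r_threshold Minimum absolute correlation for an edge: only strong
#'   positive (r > 0.8) or strong negative (r < -0.8) relationships are kept
#'   by default.
#' @param alpha_fdr Benjamini-Hochberg false-discovery-rate level applied per
#'   measure (default 0.05).
#' @param n_permutations Permutations for the null distributions (>= 100).
#' @param min_support Minimum number of the four measures that must be
#'   significant with concordant direction (default 2).
#' @param min_taxon_total Pre-filter: minimum summed count per taxon
#'   (default 30).
#' @param kl_pseudocount Pseudocount added before per-taxon normalization in
#'   the Kullback-Leibler measure (default 1e-6).
#' @param seed Integer RNG seed for the permutations.
#' @return List of class `inference_config`.
#' @export
inference_config <- function(r_threshold = 0.8, alpha_fdr = 0.05,
                             n_permutations = 1000, min_support = 2,
                             min_taxon_total = 30, kl_pseudocount = 1e-6,
                             seed = 1) {
  if (r_threshold <= 0 || r_threshold >= 1) stop("r_threshold must lie in (0, 1)")
  if (alpha_fdr <= 0 || alpha_fdr >= 1) stop("alpha_fdr must lie in (0, 1)")
  if (n_permutations < 100) stop("n_permutations must be at least 100")
  if (min_support < 1 || min_support > 4) stop("min_support must lie in 1..4")
  structure(list(r_threshold = r_threshold, alpha_fdr = alpha_fdr,
                 n_permutations = n_permutations, min_support = min_support,
                 min_taxon_total = min_taxon_total,
                 kl_pseudocount = kl_pseudocount, seed = seed),
            class = "inference_config")
}

# symmetrized KL divergence between all pairs of taxon profiles; q has taxa
# in columns, each column a probability distribution over samples
.sym_kl <- function(q) {
  l <- log(q)
  self <- unname(colSums(q * l))
  kl <- matrix(self, ncol(q), ncol(q)) - crossprod(q, l)
  kl <- (kl + t(kl)) / 2
  dimnames(kl) <- list(colnames(q), colnames(q))
  kl
}

# taxon profiles over samples, pseudocounted and column-normalized
.kl_profiles <- function(relab, pseudocount) {
  q <- relab + pseudocount
  sweep(q, 2, colSums(q), "/")
}

#' Pairwise association statistics for all taxon pairs
#'
#' Computes, on per-sample relative abundances, the four-measure ensemble:
#' Spearman and Pearson correlation, Bray-Curtis dissimilarity
#' (`sum |x - y| / sum (x + y)` over samples) and symmetrized
#' Kullback-Leibler divergence on pseudocounted, per-taxon-normalized
#' profiles. Constant (zero-variance) taxa yield undefined correlations;
#' their pairs are flagged invalid and excluded downstream.
#'
#' @param mat An `abundance_matrix` with at least 4 samples (taxa should be
#'   pre-filtered by total count).
#' @param config An [inference_config()].
#' @return List of class `pairwise_measures` with p x p matrices `spearman`,
#'   `pearson`, `bray`, `kl`, the relative-abundance matrix, and a logical
#'   `valid` pair mask.
#' @export
pairwise_measures <- function(mat, config = inference_config()) {
  stopifnot(inherits(mat, "abundance_matrix"))
  if (nrow(mat$counts) < 4)
    stop("at least 4 samples are required for association inference")
  relab <- relative_abundance(mat)
  sds <- apply(relab, 2, stats::sd)
  constant <- sds == 0
  if (any(constant))
    message("pairwise_measures: excluding pairs of ", sum(constant),
            " constant taxa: ",
            paste(utils::head(colnames(relab)[constant], 5), collapse = ", "))
  sp <- suppressWarnings(stats::cor(relab, method = "spearman"))
  pe <- suppressWarnings(stats::cor(relab, method = "pearson"))
  bc <- as.matrix(suppressWarnings(vegan::vegdist(t(relab), method = "bray")))
  kl <- .sym_kl(.kl_profiles(relab, config$kl_pseudocount))
  valid <- outer(!constant, !constant, "&")
  diag(valid) <- FALSE
  structure(list(spearman = sp, pearson = pe, bray = bc, kl = kl,
                 relab = relab, valid = valid,
                 taxon_ids = colnames(relab)),
            class = "pairwise_measures")
}

#' Permutation p-values for the four association measures
#'
#' The null distribution for every pair and measure is obtained by
#' independently permuting each taxon's values across samples (destroying
#' all between-taxon alignment while preserving marginals) and recomputing
#' the statistics. Correlations are tested two-sided
#' (`|null| >= |observed|`); the dissimilarities one-sided in both
#' directions — a smaller-than-null Bray-Curtis/KL indicates co-presence, a
#' larger one mutual exclusion — with the smaller tail reported together
#' with its direction. P-values use the add-one estimator
#' `(b + 1) / (B + 1)`, so none is exactly zero.
#'
#' @param measures A [pairwise_measures()] result.
#' @param config An [inference_config()] (permutation count and seed).
#' @return List of class `permutation_pvalues` with p x p p-value matrices
#'   `spearman`, `pearson`, `bray`, `kl` and direction matrices `bray_dir`,
#'   `kl_dir` (+1 co-presence, -1 exclusion).
#' @export
permutation_pvalues <- function(measures, config = inference_config()) {
  stopifnot(inherits(measures, "pairwise_measures"))
  B <- config$n_permutations
  if (B < 100) stop("n_permutations must be at least 100")
  relab <- measures$relab
  n <- nrow(relab); p <- ncol(relab)
  ranks <- apply(relab, 2, rank)
  obs_s <- abs(measures$spearman); obs_p <- abs(measures$pearson)
  obs_bc <- measures$bray; obs_kl <- measures$kl
  cnt_s <- cnt_p <- matrix(0, p, p)
  bc_le <- bc_ge <- kl_le <- kl_ge <- matrix(0, p, p)
  off <- (seq_len(p) - 1L) * n
  set.seed(config$seed)
  for (b in seq_len(B)) {
    idx <- vapply(seq_len(p), function(j) sample.int(n), integer(n))
    lin <- as.vector(idx + rep(off, each = n))
    pm <- matrix(relab[lin], n, p)
    pr <- matrix(ranks[lin], n, p)
    null_s <- abs(suppressWarnings(stats::cor(pr)))
    null_p <- abs(suppressWarnings(stats::cor(pm)))
    null_bc <- as.matrix(suppressWarnings(vegan::vegdist(t(pm), method = "bray")))
    null_kl <- .sym_kl(.kl_profiles(pm, config$kl_pseudocount))
    cnt_s <- cnt_s + (null_s >= obs_s)
    cnt_p <- cnt_p + (null_p >= obs_p)
    bc_le <- bc_le + (null_bc <= obs_bc)
    bc_ge <- bc_ge + (null_bc >= obs_bc)
    kl_le <- kl_le + (null_kl <= obs_kl)
    kl_ge <- kl_ge + (null_kl >= obs_kl)
  }
  addone <- function(cnt) (cnt + 1) / (B + 1)
  p_bc_le <- addone(bc_le); p_bc_ge <- addone(bc_ge)
  p_kl_le <- addone(kl_le); p_kl_ge <- addone(kl_ge)
  structure(list(
    spearman = addone(cnt_s), pearson = addone(cnt_p),
    bray = pmin(p_bc_le, p_bc_ge),
    bray_dir = ifelse(p_bc_le <= p_bc_ge, 1, -1),
    kl = pmin(p_kl_le, p_kl_ge),
    kl_dir = ifelse(p_kl_le <= p_kl_ge, 1, -1),
    n_permutations = B), class = "permutation_pvalues")
}

#' Assemble the co-occurrence network from statistics and p-values
#'
#' Per measure, Benjamini-Hochberg correction is applied over all its valid
#' pairs. An edge is retained iff (a) its Spearman or Pearson correlation
#' exceeds `r_threshold` in magnitude, and (b) at least `min_support`
#' measures are significant at `q <= alpha_fdr` with direction concordant
#' with the edge sign. The sign comes from the Spearman correlation, with
#' Pearson as tie-breaker when the two disagree and `|spearman| <=
#' |pearson|`; the dissimilarity measures contribute support only, a
#' co-presence direction backing a positive edge and an exclusion direction
#' a negative one. Isolated nodes are dropped.
#'
#' @param measures A [pairwise_measures()] result.
#' @param pvalues A [permutation_pvalues()] result.
#' @param config An [inference_config()].
#' @param taxonomy Optional taxonomy data.frame (phylum column used for node
#'   labels).
#' @return A `co_network`.
#' @export
build_network <- function(measures, pvalues, config = inference_config(),
                          taxonomy = NULL) {
  stopifnot(inherits(measures, "pairwise_measures"),
            inherits(pvalues, "permutation_pvalues"))
  p <- length(measures$taxon_ids)
  ut <- upper.tri(matrix(0, p, p)) & measures$valid
  pairs <- which(ut, arr.ind = TRUE)
  if (nrow(pairs) == 0)
    return(co_network(data.frame(id = character(), phylum = character(),
                                 mean_abundance = numeric()),
                      data.frame(source = character(), target = character(),
                                 sign = numeric(), correlation = numeric(),
                                 support = numeric(), q_value = numeric())))
  q_of <- function(pm) {
    q <- rep(NA_real_, nrow(pairs))
    q[] <- stats::p.adjust(pm[pairs], method = "BH")
    q
  }
  q_s <- q_of(pvalues$spearman); q_p <- q_of(pvalues$pearson)
  q_bc <- q_of(pvalues$bray);    q_kl <- q_of(pvalues$kl)
  sp <- measures$spearman[pairs]; pe <- measures$pearson[pairs]
  bc_dir <- pvalues$bray_dir[pairs]; kl_dir <- pvalues$kl_dir[pairs]

  sgn <- sign(sp)
  use_pe <- (sgn != sign(pe) & abs(sp) <= abs(pe)) | sgn == 0
  sgn[use_pe] <- sign(pe)[use_pe]
  # reported correlation: the strongest measure concordant with the edge sign
  # (so a retained edge always carries the value that cleared the threshold)
  cand_sp <- ifelse(sign(sp) == sgn, abs(sp), -Inf)
  cand_pe <- ifelse(sign(pe) == sgn, abs(pe), -Inf)
  corr <- ifelse(cand_pe > cand_sp, pe, sp)

  a <- config$alpha_fdr
  sup_s <- q_s <= a & sign(sp) == sgn & sp != 0
  sup_p <- q_p <= a & sign(pe) == sgn & pe != 0
  sup_bc <- q_bc <= a & bc_dir == sgn
  sup_kl <- q_kl <= a & kl_dir == sgn
  support <- sup_s + sup_p + sup_bc + sup_kl
  # the threshold-clearing correlation must be concordant with the edge sign
  pass_r <- cand_sp > config$r_threshold | cand_pe > config$r_threshold
  keep <- pass_r & support >= config$min_support & sgn != 0
  keep[is.na(keep)] <- FALSE

  ids <- measures$taxon_ids
  edge_q <- pmin(q_s, q_p, na.rm = TRUE)   # reported q: best correlation measure
  edges <- data.frame(
    source = ids[pairs[keep, 1]], target = ids[pairs[keep, 2]],
    sign = sgn[keep], correlation = corr[keep],
    support = support[keep], q_value = edge_q[keep])
  used <- sort(unique(c(edges$source, edges$target)))
  phylum <- rep(NA_character_, length(used))
  if (!is.null(taxonomy) && "phylum" %in% names(taxonomy)) {
    hit <- match(used, rownames(taxonomy))
    phylum <- ifelse(is.na(hit), "unclassified", taxonomy$phylum[hit])
  }
  nodes <- data.frame(id = used, phylum = phylum,
                      mean_abundance = colMeans(measures$relab)[used])
  co_network(nodes, edges)
}

#' Infer a co-occurrence network from a count table
#'
#' Convenience wrapper chaining [filter_taxa()], [pairwise_measures()],
#' [permutation_pvalues()] and [build_network()] under one configuration.
#'
#' @param mat An `abundance_matrix`.
#' @param config An [inference_config()].
#' @return A `co_network`.
#' @export
infer_network <- function(mat, config = inference_config()) {
  mat <- filter_taxa(mat, config$min_taxon_total)
  meas <- pairwise_measures(mat, config)
  pv <- permutation_pvalues(meas, config)
  build_network(meas, pv, config, taxonomy = mat$taxonomy)
}
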