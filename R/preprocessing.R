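#' Rarefy samples to an even depth
#'
#' Random subsampling without replacement (hypergeometric draw) of each
#' sample's reads to a common depth, removing library-size effects before
#' diversity and neutral-model analyses. Samples whose total falls below the
#' target depth are dropped with a warning. A single draw is taken per seed.
#'
#' @param mat An `abundance_matrix`.
#' @param depth Target reads per sample.
#' @param seed Integer RNG seed.
#' @return A rarefied `abundance_matrix`; every retained sample sums exactly
#'   to `depth`.
#' @export
rarefy <- function(mat, depth, seed = 1) {
  stopifnot(inherits(mat, "abundance_matrix"))
  if (depth <= 0) stop("depth must be positive")
  tot <- rowSums(mat$counts)
  keep <- tot >= depth
  if (!all(keep))
    warning("dropping ", sum(!keep), " sample(s) below depth ", depth, ": ",
            paste(rownames(mat$counts)[!keep], collapse = ", "))
  counts <- mat$counts[keep, , drop = FALSE]
  set.seed(seed)
  p <- ncol(counts)
  out <- counts
  for (i in seq_len(nrow(counts))) {
    if (tot[keep][i] == depth) next
    reads <- rep.int(seq_len(p), counts[i, ])
    drawn <- sample(reads, depth)
    out[i, ] <- tabulate(drawn, nbins = p)
  }
  abundance_matrix(out, taxonomy = mat$taxonomy,
                   sample_groups = if (is.null(mat$sample_groups)) NULL else
                     mat$sample_groups[rownames(out), , drop = FALSE])
}

#' Filter low-count taxa
#'
#' Keeps taxa whose total count summed over the samples of the analysis
#' group reaches `min_total`; the default of 30 reads is the customary
#' pre-filter before co-occurrence inference. Taxon order is preserved.
#'
#' @param mat An `abundance_matrix`.
#' @param min_total Minimum summed count (default 30).
#' @return Filtered `abundance_matrix` (possibly with zero taxa).
#' @export
filter_taxa <- function(mat, min_total = 30) {
  stopifnot(inherits(mat, "abundance_matrix"))
  if (min_total < 0) stop("min_total must be nonnegative")
  keep <- colSums(mat$counts) >= min_total
  if (!any(keep)) message("filter_taxa: no taxa pass min_total = ", min_total)
  abundance_matrix(mat$counts[, keep, drop = FALSE],
                   taxonomy = if (is.null(mat$taxonomy)) NULL else
                     mat$taxonomy[intersect(rownames(mat$taxonomy),
                                            colnames(mat$counts)[keep]), ,
                                  drop = FALSE],
                   sample_groups = mat$sample_groups)
}

#' Per-sample alpha diversity and coverage
#'
#' Computes observed richness, the Chao1 richness estimate, Shannon
#' diversity and Good's coverage for every sample.
#'
#' Chao1 defaults to the bias-corrected estimator
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` (`F1` singletons, `F2` doubletons),
#' which is defined even when no doubletons are present; the classical form
#' `S_obs + F1^2 / (2 F2)` is available via `chao1_variant = "classical"`
#' (it falls back to the bias-corrected term when `F2 = 0`). Shannon is
#' reported in nats by default (`shannon_base = exp(1)`); Good's coverage is
#' `1 - F1 / N_reads`.
#'
#' @param mat An `abundance_matrix`.
#' @param chao1_variant `"bias_corrected"` (default) or `"classical"`.
#' @param shannon_base Logarithm base for Shannon diversity.
#' @return data.frame with columns `sample`, `observed_otus`, `chao1`,
#'   `shannon`, `goods_coverage`.
#' @export
alpha_diversity <- function(mat, chao1_variant = c("bias_corrected", "classical"),
                            shannon_base = exp(1)) {
  stopifnot(inherits(mat, "abundance_matrix"))
  chao1_variant <- match.arg(chao1_variant)
  tot <- rowSums(mat$counts)
  if (any(tot == 0))
    stop("all-zero sample: ", paste(rownames(mat$counts)[tot == 0], collapse = ", "))
  res <- t(apply(mat$counts, 1, function(x) {
    x <- x[x > 0]
    S <- length(x)
    F1 <- sum(x == 1); F2 <- sum(x == 2)
    chao1 <- if (chao1_variant == "bias_corrected" || F2 == 0)
      S + F1 * (F1 - 1) / (2 * (F2 + 1))
    else
      S + F1^2 / (2 * F2)
    pr <- x / sum(x)
    shannon <- -sum(pr * log(pr, base = shannon_base))
    c(observed_otus = S, chao1 = chao1, shannon = shannon,
      goods_coverage = 1 - F1 / sum(x))
  }))
  data.frame(sample = rownames(mat$counts), res, row.names = NULL)
}
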