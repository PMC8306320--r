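#' Design for a count table with planted correlation blocks
#'
#' Describes a compositional 16S-like community in which blocks of taxa share
#' a latent factor, so their abundances co-vary with a controllable rank
#' correlation. Block structure is the ground truth that co-occurrence
#' inference and module detection are tested against.
#'
#' @param n_samples Number of samples (default 60, two seasons of a
#'   multi-site river survey pooled per analysis group).
#' @param n_taxa Total number of taxa; taxa outside the blocks vary
#'   independently.
#' @param block_sizes Integer vector, taxa per planted block.
#' @param within_block_corr Target pairwise latent correlation inside a
#'   block, in `[0, 1]`.
#' @param frac_negative Fraction of within-block pairs given a negative
#'   association (planted by sign-flipping factor loadings).
#' @param depth Reads per sample (default 57068, a typical post-rarefaction
#'   depth for river amplicon surveys).
#' @param seed Integer RNG seed.
#' @return A `planted_design` list.
#' @export
planted_design <- function(n_samples = 60, n_taxa = 200,
                           block_sizes = c(10, 10), within_block_corr = 0.9,
                           frac_negative = 0.25, depth = 57068, seed = 1) {
  if (sum(block_sizes) > n_taxa)
    stop("sum(block_sizes) must not exceed n_taxa")
  if (within_block_corr < 0 || within_block_corr > 1)
    stop("within_block_corr must lie in [0, 1]")
  if (frac_negative < 0 || frac_negative > 1)
    stop("frac_negative must lie in [0, 1]")
  if (depth <= 0) stop("depth must be positive")
  structure(list(n_samples = n_samples, n_taxa = n_taxa,
                 block_sizes = block_sizes,
                 within_block_corr = within_block_corr,
                 frac_negative = frac_negative, depth = depth, seed = seed),
            class = "planted_design")
}

# number of flipped loadings k in a block of size B so that the fraction of
# opposite-sign pairs k(B-k)/choose(B,2) best matches the requested fraction
.n_flipped <- function(B, frac_negative) {
  if (B < 2) return(0L)
  k <- 0:floor(B / 2)
  frac <- k * (B - k) / choose(B, 2)
  k[which.min(abs(frac - frac_negative))]
}

#' Generate a count table with planted correlation blocks
#'
#' Taxa in a block share a standard-normal latent factor per sample: taxon j
#' has latent `s_j * (sqrt(rho) * f + sqrt(1 - rho) * eps_j)` with loading
#' sign `s_j` flipped for a subset of taxa to plant negative associations.
#' Because ranks pass through the whole chain, the latent Gaussian
#' correlation is set by the copula relation `rho = 2 sin(pi rho_S / 6)` so
#' that the realized pairwise Spearman correlation matches
#' `within_block_corr`. Latents are placed on the log scale, passed through
#' a softmax to per-sample relative abundances (yielding compositional
#' counts), and counts drawn by multinomial sampling at the design depth.
#'
#' Block taxa receive phylum labels cycling through the dominant freshwater
#' phyla so module-composition reports can be tested; the latent factors and
#' block assignment are attached as attributes for downstream ground-truth
#' checks.
#'
#' @param design A [planted_design()].
#' @return An `abundance_matrix` with attributes `latent_factors`
#'   (samples x blocks), `block` (taxon block index, 0 = background) and
#'   `loading_sign`.
#' @export
generate_planted_counts <- function(design) {
  stopifnot(inherits(design, "planted_design"))
  set.seed(design$seed)
  n <- design$n_samples; p <- design$n_taxa
  nb <- length(design$block_sizes)
  rho <- min(2 * sin(pi * design$within_block_corr / 6), 1)

  block <- integer(p)
  idx <- 1L
  for (b in seq_len(nb)) {
    block[idx:(idx + design$block_sizes[b] - 1L)] <- b
    idx <- idx + design$block_sizes[b]
  }
  loading_sign <- rep(1, p)
  for (b in seq_len(nb)) {
    members <- which(block == b)
    k <- .n_flipped(length(members), design$frac_negative)
    if (k > 0) loading_sign[members[seq_len(k)]] <- -1
  }

  f <- matrix(stats::rnorm(n * nb), n, nb)           # shared factors
  z <- matrix(stats::rnorm(n * p), n, p)             # idiosyncratic part
  for (j in seq_len(p)) {
    if (block[j] > 0)
      z[, j] <- loading_sign[j] * (sqrt(rho) * f[, block[j]] +
                                     sqrt(1 - rho) * z[, j])
  }
  mu <- stats::rnorm(p, 0, 1)                        # base log abundances
  # block taxa are given higher base abundance: the taxa that form reliable
  # network edges in practice are those comfortably above the read filter
  mu[block > 0] <- stats::rnorm(sum(block > 0), 1, 0.5)
  sigma <- 1                                         # latent effect scale
  loglam <- sweep(sigma * z, 2, mu, "+")
  relab <- exp(loglam - apply(loglam, 1, max))
  relab <- relab / rowSums(relab)
  counts <- t(vapply(seq_len(n),
                     function(i) stats::rmultinom(1, design$depth, relab[i, ])[, 1],
                     numeric(p)))
  sample_ids <- sprintf("S%02d", seq_len(n))
  taxon_ids <- sprintf("OTU%04d", seq_len(p))
  dimnames(counts) <- list(sample_ids, taxon_ids)

  phyla <- c("Proteobacteria", "Actinobacteria", "Bacteroidetes",
             "Parcubacteria", "Firmicutes", "Verrucomicrobia",
             "Cyanobacteria", "Gemmatimonadetes")
  tax_phylum <- ifelse(block > 0, phyla[(block - 1L) %% length(phyla) + 1L],
                       sample(phyla, p, replace = TRUE))
  taxonomy <- data.frame(domain = "Bacteria", phylum = tax_phylum,
                         class = NA_character_, order = NA_character_,
                         family = NA_character_, genus = NA_character_,
                         species = NA_character_, row.names = taxon_ids)
  out <- abundance_matrix(counts, taxonomy = taxonomy)
  attr(out, "latent_factors") <- f
  attr(out, "block") <- block
  attr(out, "loading_sign") <- loading_sign
  attr(out, "latent_z") <- z
  out
}

#' Design for a neutrally assembled community
#'
#' @param n_samples Number of samples.
#' @param n_taxa Number of taxa in the source pool.
#' @param m_true Immigration (migration) probability in `(0, 1]`.
#' @param depth Community size `N_T` in reads per sample.
#' @param source_abundances Optional relative-abundance vector of the source
#'   community (nonnegative, summing to 1); defaults to a lognormal
#'   rank-abundance profile.
#' @param seed Integer RNG seed.
#' @return A `neutral_design` list.
#' @export
neutral_design <- function(n_samples = 200, n_taxa = 500, m_true = 0.3,
                           depth = 10000, source_abundances = NULL, seed = 1) {
  if (m_true <= 0 || m_true > 1) stop("m_true must lie in (0, 1]")
  if (depth <= 0) stop("depth must be positive")
  if (is.null(source_abundances)) {
    set.seed(seed + 101L)
    a <- stats::rlnorm(n_taxa, 0, 2)
    source_abundances <- a / sum(a)
  } else {
    if (any(source_abundances < 0)) stop("source_abundances must be nonnegative")
    if (abs(sum(source_abundances) - 1) > 1e-8)
      stop("source_abundances must sum to 1")
    n_taxa <- length(source_abundances)
  }
  structure(list(n_samples = n_samples, n_taxa = n_taxa, m_true = m_true,
                 depth = depth, source_abundances = source_abundances,
                 seed = seed),
            class = "neutral_design")
}

#' Generate counts from a neutral community
#'
#' Each sample's taxon relative abundances are drawn from the Beta latent of
#' the Sloan neutral model, `Beta(N_T m p, N_T m (1 - p))` for a taxon of
#' source relative abundance `p`, then normalized and realized as multinomial
#' counts at the design depth. This matches the fitted model's own sampling
#' assumptions, which is exactly what parameter-recovery tests require.
#'
#' @param design A [neutral_design()].
#' @return An `abundance_matrix`.
#' @export
generate_neutral_counts <- function(design) {
  stopifnot(inherits(design, "neutral_design"))
  set.seed(design$seed)
  n <- design$n_samples
  p <- design$source_abundances
  NTm <- design$depth * design$m_true
  counts <- matrix(0, n, length(p))
  pos <- which(p > 0)
  for (i in seq_len(n)) {
    x <- numeric(length(p))
    x[pos] <- stats::rbeta(length(pos), NTm * p[pos], NTm * (1 - p[pos]))
    s <- sum(x)
    if (s == 0) x[pos] <- p[pos] else x <- x / s
    counts[i, ] <- stats::rmultinom(1, design$depth, x)[, 1]
  }
  dimnames(counts) <- list(sprintf("S%03d", seq_len(n)),
                           sprintf("OTU%04d", seq_along(p)))
  out <- abundance_matrix(counts)
  attr(out, "source_abundances") <- p
  out
}

#' Generate environmental variables covarying with a planted block
#'
#' Variables listed in `linked_vars` are linear functions of the named
#' block's latent factor plus Gaussian noise scaled to achieve the requested
#' correlation; the remaining variables are independent standard noise.
#'
#' @param mat An `abundance_matrix` produced by [generate_planted_counts()].
#' @param linked_block Index of the planted block to covary with.
#' @param strength Target correlation in `[-1, 1]` between linked variables
#'   and the block factor.
#' @param variable_names Names of all environmental columns to emit.
#' @param linked_vars Subset of `variable_names` tied to the block (default:
#'   the first).
#' @param seed Integer RNG seed.
#' @return data.frame, rownames = sample ids.
#' @export
generate_env_table <- function(mat, linked_block, strength,
                               variable_names = c("DOC", "T", "ORP", "pH"),
                               linked_vars = variable_names[1], seed = 1) {
  stopifnot(inherits(mat, "abundance_matrix"))
  f <- attr(mat, "latent_factors")
  if (is.null(f)) stop("mat carries no latent factors (not a planted table)")
  if (linked_block < 1 || linked_block > ncol(f))
    stop("unknown block index: ", linked_block)
  if (abs(strength) > 1) stop("strength must lie in [-1, 1]")
  if (!all(linked_vars %in% variable_names))
    stop("linked_vars must be a subset of variable_names")
  set.seed(seed)
  n <- nrow(mat$counts)
  env <- matrix(stats::rnorm(n * length(variable_names)), n,
                dimnames = list(rownames(mat$counts), variable_names))
  for (v in linked_vars)
    env[, v] <- strength * f[, linked_block] +
      sqrt(1 - strength^2) * stats::rnorm(n)
  as.data.frame(env)
}

#' Generate a land-use area table along a human-activity gradient
#'
#' Produces per-sub-basin areas for the five cover classes such that
#' (farmland + urban) / total equals the requested human-activity fraction.
#' The human share is split 70/30 between farmland and urban, the natural
#' remainder 70/15/15 between forest, freshwater and other cover — the
#' typical make-up of subtropical agricultural watersheds.
#'
#' @param n_subbasins Number of sub-basins.
#' @param gradient Human-activity fractions in `[0, 1]`, one per sub-basin.
#' @param total_areas Total areas in km^2, one per sub-basin (default 100).
#' @return A `landuse_table`.
#' @export
generate_landuse_table <- function(n_subbasins = length(gradient),
                                   gradient,
                                   total_areas = rep(100, n_subbasins)) {
  if (length(gradient) != n_subbasins || length(total_areas) != n_subbasins)
    stop("gradient and total_areas must have length n_subbasins")
  if (any(gradient < 0 | gradient > 1))
    stop("human-activity fractions must lie in [0, 1]")
  human <- gradient * total_areas
  natural <- total_areas - human
  df <- data.frame(
    sub_basin = sprintf("Y%02d", seq_len(n_subbasins)),
    farmlands = 0.7 * human,
    forests = 0.7 * natural,
    freshwaters = 0.15 * natural,
    urban = 0.3 * human,
    others = 0.15 * natural,
    total = total_areas)
  validate_landuse(df)
}
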