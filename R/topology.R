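#' Topological indices of a co-occurrence network
#'
#' Computes the standard 13-index summary reported for molecular ecological
#' networks: total nodes (TN) and links (TL), negative and positive link
#' counts (NL, PL) and their ratio (NP), the R-squared of a power-law fit to
#' the degree distribution (R), average degree (avgK), average clustering
#' coefficient (avgCC), average path distance (APD), degree centralization
#' (CD), graph density (GD) and — when a module partition is supplied —
#' modularity (M) and number of modules (NM).
#'
#' All metrics treat the graph as undirected and unweighted except NP, which
#' uses the edge signs. avgCC is the mean local clustering coefficient with
#' nodes of degree < 2 contributing 0; APD averages shortest-path lengths
#' over connected node pairs only; CD is Freeman's degree centralization
#' `sum(k_max - k_i) / ((TN - 1)(TN - 2))`; R is the coefficient of
#' determination of an ordinary-least-squares line through `log10 P(k)` vs
#' `log10 k` over observed degrees (unit bins, zero-frequency degrees
#' excluded).
#'
#' @param net A `co_network` with at least one node.
#' @param partition Optional named module membership vector (from
#'   [detect_modules()]); when omitted, M and NM are `NA`.
#' @return A one-row data.frame of class `topology_summary`. When `PL = 0`
#'   with `NL > 0`, NP is `NA` with attribute `np_undefined = TRUE`.
#' @export
network_topology <- function(net, partition = NULL) {
  stopifnot(inherits(net, "co_network"))
  if (nrow(net$nodes) == 0) stop("network has no nodes")
  g <- as_igraph(net)
  TN <- igraph::vcount(g)
  TL <- igraph::ecount(g)
  NL <- sum(net$edges$sign < 0)
  PL <- TL - NL
  np_undef <- PL == 0 && NL > 0
  NP <- if (np_undef) NA_real_ else if (NL == 0) 0 else NL / PL
  deg <- igraph::degree(g)
  avgK <- 2 * TL / TN
  GD <- if (TN > 1) avgK / (TN - 1) else NA_real_
  cc <- suppressWarnings(igraph::transitivity(g, type = "local"))
  cc[is.na(cc)] <- 0
  avgCC <- mean(cc)
  d <- igraph::distances(g)
  dv <- d[upper.tri(d)]
  dv <- dv[is.finite(dv) & dv > 0]
  APD <- if (length(dv) > 0) mean(dv) else NA_real_
  CD <- if (TN > 2) sum(max(deg) - deg) / ((TN - 1) * (TN - 2)) else NA_real_
  R <- {
    tab <- table(deg[deg >= 1])
    if (length(tab) >= 2) {
      x <- log10(as.numeric(names(tab)))
      y <- log10(as.numeric(tab) / TN)
      sst <- sum((y - mean(y))^2)
      if (sst == 0) NA_real_   # flat distribution: fit undefined
      else {
        b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
        a <- mean(y) - b * mean(x)
        1 - sum((y - (a + b * x))^2) / sst
      }
    } else NA_real_
  }
  M <- NM <- NA_real_
  if (!is.null(partition)) {
    memb <- partition[igraph::V(g)$name]
    if (anyNA(memb)) stop("partition does not cover all nodes")
    M <- igraph::modularity(g, as.integer(factor(memb)))
    NM <- length(unique(memb))
  }
  out <- data.frame(TN = TN, TL = TL, NL = NL, PL = PL, NP = NP, R = R,
                    avgK = avgK, avgCC = avgCC, APD = APD, CD = CD, GD = GD,
                    M = M, NM = NM)
  class(out) <- c("topology_summary", "data.frame")
  attr(out, "np_undefined") <- np_undef
  attr(out, "apd_rule") <- "connected pairs only"
  out
}

#' Check internal-consistency identities of a printed index table
#'
#' Network index tables obey exact identities: `TL = NL + PL`,
#' `avgK = 2 TL / TN` and `GD = avgK / (TN - 1)`. Given a table of printed
#' values (one column per network, rows named `TN`, `TL`, `NL`, `PL`, `NP`,
#' `avgK`, `GD`), this verifies each identity at the printed 3-decimal
#' rounding and flags — without silently correcting — cells that fail, the
#' way typographically corrupted table entries reveal themselves. For a
#' flagged `TL`/`PL` cell the internally consistent value implied by the
#' other printed cells is reported alongside.
#'
#' @param tab data.frame or matrix of printed values, rows named as above,
#'   one column per network.
#' @return data.frame, one row per (network, identity): recomputed value,
#'   printed value, `ok` flag, and `flagged_cell`/`consistent_value` where an
#'   input cell itself is corrupt.
#' @export
check_printed_indices <- function(tab) {
  tab <- as.matrix(tab)
  need <- c("TN", "TL", "NL", "PL", "NP", "avgK", "GD")
  miss <- setdiff(need, rownames(tab))
  if (length(miss) > 0) stop("missing rows: ", paste(miss, collapse = ", "))
  r3 <- function(x) round(x, 3)
  out <- list()
  for (j in colnames(tab)) {
    TN <- tab["TN", j]; TL <- tab["TL", j]; NL <- tab["NL", j]
    PL <- tab["PL", j]; NP <- tab["NP", j]
    avgK <- tab["avgK", j]; GD <- tab["GD", j]
    # locate corrupted count cells from the avgK identity, which involves TL
    # alone among the link counts
    TL_hat <- avgK * TN / 2
    tl_corrupt <- abs(TL - TL_hat) / TL_hat > 0.01
    TL_use <- if (tl_corrupt) round(TL_hat) else TL
    PL_hat <- TL_use - NL
    pl_corrupt <- abs(PL - PL_hat) / max(PL_hat, 1) > 0.01
    PL_use <- if (pl_corrupt) PL_hat else PL
    rows <- rbind(
      data.frame(network = j, identity = "avgK = 2*TL/TN",
                 recomputed = r3(2 * TL_use / TN), printed = avgK,
                 ok = r3(2 * TL_use / TN) == avgK,
                 flagged_cell = if (tl_corrupt) "TL" else NA_character_,
                 consistent_value = if (tl_corrupt) round(TL_hat) else NA_real_),
      data.frame(network = j, identity = "TL = NL + PL",
                 recomputed = NL + PL_use, printed = TL,
                 ok = !tl_corrupt && !pl_corrupt && TL == NL + PL,
                 flagged_cell = if (pl_corrupt) "PL" else NA_character_,
                 consistent_value = if (pl_corrupt) PL_hat else NA_real_),
      data.frame(network = j, identity = "NP = NL/PL",
                 recomputed = r3(NL / PL_use), printed = NP,
                 ok = r3(NL / PL_use) == NP,
                 flagged_cell = NA_character_, consistent_value = NA_real_),
      data.frame(network = j, identity = "GD = avgK/(TN-1)",
                 recomputed = r3(avgK / (TN - 1)), printed = GD,
                 ok = r3(avgK / (TN - 1)) == GD,
                 flagged_cell = NA_character_, consistent_value = NA_real_))
    out[[j]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Load the bundled published network-index table
#'
#' Thirteen topological indices for six reach-by-season bacterioplankton
#' networks of a human-impacted subtropical river, as printed in the source
#' study's summary tables; used by [check_printed_indices()] to verify the
#' package's identities against independently published values.
#'
#' @return Numeric matrix, rows = indices, columns = networks.
#' @export
published_network_indices <- function() {
  path <- system.file("extdata", "published_network_indices.tsv",
                      package = "rivnet")
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
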