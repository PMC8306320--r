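#' Detect modules by modularity maximization
#'
#' Partitions the network (signs collapsed to an unsigned graph) by greedy
#' agglomerative Newman-Girvan modularity maximization — deterministic, so
#' repeated runs give identical partitions — or optionally by multi-level
#' Louvain optimization.
#'
#' @param net A nonempty `co_network`.
#' @param method `"greedy"` (default, deterministic) or `"louvain"`.
#' @param seed RNG seed (used by the Louvain option only).
#' @return List of class `module_partition`: `membership` (named integer
#'   vector), `Q` (modularity of the partition) and `n_modules`.
#' @export
detect_modules <- function(net, method = c("greedy", "louvain"), seed = 1) {
  stopifnot(inherits(net, "co_network"))
  if (nrow(net$nodes) == 0) stop("network has no nodes")
  method <- match.arg(method)
  g <- as_igraph(net)
  g <- igraph::delete_edge_attr(g, "sign")
  if (igraph::ecount(g) == 0) {
    membership <- seq_len(igraph::vcount(g))
    names(membership) <- igraph::V(g)$name
    return(structure(list(membership = membership, Q = 0,
                          n_modules = length(membership)),
                     class = "module_partition"))
  }
  if (method == "greedy") {
    cm <- igraph::cluster_fast_greedy(g)
    # pick the merge step maximizing Q ourselves; among numerical ties take
    # the coarsest partition (fewest modules)
    qv <- cm$modularity
    i <- max(which(qv >= max(qv) - 1e-12))
    memb <- igraph::cut_at(cm, no = igraph::vcount(g) - (i - 1))
  } else {
    set.seed(seed)
    memb <- igraph::membership(igraph::cluster_louvain(g))
  }
  membership <- as.integer(memb)
  names(membership) <- igraph::V(g)$name
  structure(list(membership = membership,
                 Q = igraph::modularity(g, memb),
                 n_modules = length(unique(membership))),
            class = "module_partition")
}

#' Classify node topological roles from zi and pi
#'
#' For every node, the within-module degree z-score
#' `zi = (k_own - mean_own) / sd_own` (k_own = links inside the node's own
#' module; mean/sd taken over that module's members, zi = 0 when sd = 0) and
#' the participation coefficient `pi = 1 - sum_s (k_is / k_i)^2` over
#' modules s. Categories follow the strict-threshold scheme: network hubs
#' (zi > 2.5 and pi > 0.62), module hubs (zi > 2.5, pi <= 0.62), connectors
#' (zi <= 2.5, pi > 0.62), peripherals otherwise; values exactly at a
#' threshold fall to the lower category.
#'
#' @param net A `co_network`.
#' @param partition A [detect_modules()] result (or a named membership
#'   vector) covering all nodes.
#' @return data.frame with columns `node`, `module`, `zi`, `pi`, `category`.
#' @export
classify_roles <- function(net, partition) {
  stopifnot(inherits(net, "co_network"))
  memb <- if (inherits(partition, "module_partition")) partition$membership
          else partition
  ids <- net$nodes$id
  if (!all(ids %in% names(memb))) stop("partition does not cover all nodes")
  memb <- memb[ids]
  adj <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(net$edges) > 0) {
    adj[cbind(net$edges$source, net$edges$target)] <- 1L
    adj[cbind(net$edges$target, net$edges$source)] <- 1L
  }
  k <- rowSums(adj)
  mods <- sort(unique(memb))
  # k_is: links of node i into module s
  k_is <- vapply(mods, function(s) rowSums(adj[, memb == s, drop = FALSE]),
                 numeric(length(ids)))
  if (length(ids) == 1) k_is <- matrix(k_is, nrow = 1)
  k_own <- k_is[cbind(seq_along(ids), match(memb, mods))]
  zi <- numeric(length(ids))
  for (s in mods) {
    in_s <- memb == s
    mu <- mean(k_own[in_s]); sdv <- stats::sd(k_own[in_s])
    zi[in_s] <- if (is.na(sdv) || sdv == 0) 0 else (k_own[in_s] - mu) / sdv
  }
  pi <- ifelse(k > 0, 1 - rowSums((k_is / pmax(k, 1))^2), 0)
  category <- ifelse(zi > 2.5,
                     ifelse(pi > 0.62, "network hub", "module hub"),
                     ifelse(pi > 0.62, "connector", "peripheral"))
  data.frame(node = ids, module = memb, zi = zi, pi = pi,
             category = category, row.names = NULL)
}

#' Census of node role categories
#'
#' @param roles A [classify_roles()] result.
#' @return List with `fractions` (named vector over the four categories,
#'   summing to 1) and `keystones` (node ids of network hubs, module hubs
#'   and connectors — the keystone taxa).
#' @export
role_census <- function(roles) {
  cats <- c("network hub", "module hub", "connector", "peripheral")
  fr <- vapply(cats, function(cc) mean(roles$category == cc), numeric(1))
  list(fractions = fr,
       keystones = roles$node[roles$category != "peripheral"])
}

#' Shared-node (Venn) statistics between two networks
#'
#' @param net_a,net_b `co_network` objects or character vectors of node ids.
#' @return List: `shared`, `unique_a`, `unique_b` (counts) and `pct_shared`
#'   = `100 |A intersect B| / |A union B|`, rounded to one decimal.
#' @export
shared_nodes <- function(net_a, net_b) {
  ids <- function(x) if (inherits(x, "co_network")) x$nodes$id else as.character(x)
  a <- unique(ids(net_a)); b <- unique(ids(net_b))
  inter <- length(intersect(a, b)); uni <- length(union(a, b))
  list(shared = inter, unique_a = length(setdiff(a, b)),
       unique_b = length(setdiff(b, a)),
       pct_shared = if (uni == 0) NA_real_ else round(100 * inter / uni, 1))
}

#' Per-module composition and edge profiles
#'
#' Summarizes each module: size, whether it is a major module (node count
#' strictly above 5% of the network's nodes), phylum composition, and
#' intra-module edge counts split by sign plus the module's inter-module
#' edge count.
#'
#' @param net A `co_network`.
#' @param partition A [detect_modules()] result or named membership vector.
#' @param taxonomy Optional taxonomy data.frame with a `phylum` column;
#'   nodes without taxonomy are binned as "unclassified".
#' @return List of class `module_profiles`: data.frame `summary` (module,
#'   size, is_major, intra_pos, intra_neg, inter) and list `phylum_fractions`
#'   (named vectors summing to 1 per module).
#' @export
module_profiles <- function(net, partition, taxonomy = NULL) {
  stopifnot(inherits(net, "co_network"))
  memb <- if (inherits(partition, "module_partition")) partition$membership
          else partition
  memb <- memb[net$nodes$id]
  TN <- nrow(net$nodes)
  phylum <- rep("unclassified", TN)
  if (!is.null(taxonomy) && "phylum" %in% names(taxonomy)) {
    hit <- match(net$nodes$id, rownames(taxonomy))
    phylum[!is.na(hit)] <- as.character(taxonomy$phylum[hit[!is.na(hit)]])
    phylum[is.na(phylum) | phylum == ""] <- "unclassified"
  } else if (!is.null(net$nodes$phylum)) {
    phylum <- ifelse(is.na(net$nodes$phylum), "unclassified", net$nodes$phylum)
  }
  e_src <- memb[net$edges$source]; e_tgt <- memb[net$edges$target]
  mods <- sort(unique(memb))
  summ <- do.call(rbind, lapply(mods, function(s) {
    size <- sum(memb == s)
    intra <- e_src == s & e_tgt == s
    data.frame(module = s, size = size, is_major = size > 0.05 * TN,
               intra_pos = sum(intra & net$edges$sign > 0),
               intra_neg = sum(intra & net$edges$sign < 0),
               inter = sum(xor(e_src == s, e_tgt == s)))
  }))
  pf <- lapply(mods, function(s) {
    tb <- table(phylum[memb == s])
    as.numeric(tb) / sum(tb) -> fr
    names(fr) <- names(tb)
    sort(fr, decreasing = TRUE)
  })
  names(pf) <- mods
  structure(list(summary = summ, phylum_fractions = pf),
            class = "module_profiles")
}
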