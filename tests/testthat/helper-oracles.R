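# Brute-force reference implementations, kept deliberately naive and
# independent of the package internals.

# build a co_network from a 2-column edge matrix (character ids)
make_net <- function(edges, signs = NULL, nodes = NULL) {
  edges <- as.matrix(edges)
  if (is.null(signs)) signs <- rep(1, nrow(edges))
  ids <- if (is.null(nodes)) sort(unique(as.vector(edges))) else nodes
  e <- if (nrow(edges) == 0)
    data.frame(source = character(0), target = character(0), sign = numeric(0),
               correlation = numeric(0), support = numeric(0),
               q_value = numeric(0))
  else
    data.frame(source = edges[, 1], target = edges[, 2], sign = signs,
               correlation = signs * 0.9, support = 2, q_value = 0.01)
  co_network(
    data.frame(id = ids, phylum = NA_character_, mean_abundance = NA_real_), e)
}

# random connected-ish simple graph as an edge matrix
random_edges <- function(n_nodes, p_edge, rng) {
  ids <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(utils::combn(ids, 2))
  keep <- rng < p_edge
  pairs[keep, , drop = FALSE]
}

bf_adjacency <- function(net) {
  ids <- net$nodes$id
  a <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(nrow(net$edges))) {
    a[net$edges$source[i], net$edges$target[i]] <- 1L
    a[net$edges$target[i], net$edges$source[i]] <- 1L
  }
  a
}

# all-pairs shortest paths by BFS
bf_apd <- function(adj) {
  n <- nrow(adj)
  total <- 0; cnt <- 0
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n); dist[s] <- 0L
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(adj[v, ] == 1L & is.na(dist))
        dist[nb] <- dist[v] + 1L
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
    reach <- which(!is.na(dist) & dist > 0)
    total <- total + sum(dist[reach]); cnt <- cnt + length(reach)
  }
  if (cnt == 0) NA_real_ else total / cnt   # each unordered pair counted twice
}

# mean local clustering coefficient by direct triangle counting
bf_avgcc <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1L)
    k <- length(nb)
    if (k < 2) { cc[v] <- 0; next }
    links <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb))
      if (a < b && adj[nb[a], nb[b]] == 1L) links <- links + 1
    cc[v] <- 2 * links / (k * (k - 1))
  }
  mean(cc)
}

bf_centralization <- function(adj) {
  deg <- rowSums(adj)
  n <- nrow(adj)
  if (n <= 2) return(NA_real_)
  sum(max(deg) - deg) / ((n - 1) * (n - 2))
}

# OLS R^2 of log10 P(k) on log10 k, hand-rolled
bf_powerlaw_r2 <- function(adj) {
  deg <- rowSums(adj)
  tab <- table(deg[deg >= 1])
  if (length(tab) < 2) return(NA_real_)
  x <- log10(as.numeric(names(tab)))
  y <- log10(as.numeric(tab) / nrow(adj))
  if (sum((y - mean(y))^2) == 0) return(NA_real_)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  1 - sum((y - (a + b * x))^2) / sum((y - mean(y))^2)
}

# Newman-Girvan modularity computed straight from the definition
bf_modularity <- function(adj, memb) {
  m <- sum(adj) / 2
  if (m == 0) return(0)
  deg <- rowSums(adj)
  q <- 0
  for (s in unique(memb)) {
    in_s <- memb == s
    e_s <- sum(adj[in_s, in_s]) / 2
    d_s <- sum(deg[in_s])
    q <- q + e_s / m - (d_s / (2 * m))^2
  }
  q
}

# all set partitions of n elements as restricted-growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    if (length(prefix) == n) { out[[length(out) + 1]] <<- prefix; return() }
    for (v in seq_len(maxv + 1)) rec(c(prefix, v), max(maxv, v))
  }
  rec(integer(0), 0L)
  out
}

# zi / pi straight from the definitions
bf_zipi <- function(adj, memb) {
  ids <- rownames(adj)
  k <- rowSums(adj)
  zi <- pi <- numeric(length(ids))
  for (i in seq_along(ids)) {
    own <- memb[i]
    kin <- sum(adj[i, memb == own])
    members <- which(memb == own)
    kins <- vapply(members, function(j) sum(adj[j, memb == own]), numeric(1))
    sdv <- stats::sd(kins)
    zi[i] <- if (is.na(sdv) || sdv == 0) 0 else (kin - mean(kins)) / sdv
    if (k[i] > 0) {
      pi[i] <- 1 - sum(vapply(unique(memb), function(s)
        (sum(adj[i, memb == s]) / k[i])^2, numeric(1)))
    }
  }
  data.frame(node = ids, zi = zi, pi = pi)
}

# adjusted Rand index between two labelings
bf_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_ij <- sum_a * sum_b / choose(n, 2)
  max_ij <- (sum_a + sum_b) / 2
  if (max_ij == exp_ij) return(1)
  (sum_ij - exp_ij) / (max_ij - exp_ij)
}

# planted within-block pair keys for a generated matrix
planted_pairs <- function(mat) {
  blk <- attr(mat, "block")
  ids <- colnames(mat$counts)
  pp <- which(outer(blk, blk, "==") & outer(blk > 0, blk > 0, "&") &
                upper.tri(diag(length(blk))), arr.ind = TRUE)
  paste(ids[pp[, 1]], ids[pp[, 2]])
}

edge_keys <- function(net) paste(net$edges$source, net$edges$target)
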