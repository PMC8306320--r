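#' Construct a validated abundance matrix
#'
#' The central container of the package: an integer count matrix with samples
#' in rows and taxa (OTUs) in columns, optionally annotated with a ranked
#' taxonomy and per-sample group labels (river reach, hydrological season).
#'
#' @param counts Integer matrix, samples x taxa, with unique dimnames.
#' @param taxonomy Optional data.frame with rownames equal to (a subset of)
#'   the taxon ids and lineage columns such as `domain` ... `species`; a
#'   `phylum` column is used by the network and module reports.
#' @param sample_groups Optional data.frame with rownames equal to the sample
#'   ids; conventional columns are `reach` (upper/middle/lower) and `season`
#'   (wet/dry).
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(counts, taxonomy = NULL, sample_groups = NULL) {
  counts <- as.matrix(counts)
  # an empty taxa set (e.g. after aggressive filtering) is legal; R represents
  # its colnames as NULL
  if (is.null(rownames(counts)) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("counts must carry sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts)) stop("counts must be numeric")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("counts must be nonnegative integers; offending cell: sample '%s', taxon '%s' (value %s)",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
                 format(counts[bad[1, 1], bad[1, 2]])))
  }
  storage.mode(counts) <- "double"  # exact for counts < 2^53
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    extra <- setdiff(rownames(taxonomy), colnames(counts))
    if (length(extra) > 0)
      stop("taxonomy contains ids absent from the count table: ",
           paste(utils::head(extra, 5), collapse = ", "))
  }
  if (!is.null(sample_groups)) {
    sample_groups <- as.data.frame(sample_groups)
    extra <- setdiff(rownames(sample_groups), rownames(counts))
    if (length(extra) > 0)
      stop("sample_groups contains ids absent from the count table: ",
           paste(utils::head(extra, 5), collapse = ", "))
  }
  structure(list(counts = counts, taxonomy = taxonomy,
                 sample_groups = sample_groups),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d samples x %d taxa, %s total reads\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  if (!is.null(x$taxonomy)) cat(sprintf("  taxonomy for %d taxa\n", nrow(x$taxonomy)))
  if (!is.null(x$sample_groups))
    cat("  sample groups: ", paste(colnames(x$sample_groups), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$counts)

#' Per-sample relative abundances
#' @param mat An `abundance_matrix`.
#' @return Numeric matrix, rows summing to 1.
#' @export
relative_abundance <- function(mat) {
  stopifnot(inherits(mat, "abundance_matrix"))
  tot <- rowSums(mat$counts)
  if (any(tot == 0)) stop("all-zero sample: ",
                          paste(rownames(mat$counts)[tot == 0], collapse = ", "))
  sweep(mat$counts, 1, tot, "/")
}

#' Read an OTU count table from a tab-separated file
#'
#' @param path File path. First column holds row ids, first row column ids.
#' @param taxa_as_rows The common OTU-table dialect puts taxa in rows and
#'   samples in columns (default `TRUE`); set `FALSE` for samples-in-rows.
#' @return An `abundance_matrix` (no taxonomy / groups attached).
#' @export
read_abundance <- function(path, taxa_as_rows = TRUE) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(m), nrow(m)))) & !is.na(m),
                 arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-numeric count at row '%s', column '%s': '%s'",
                   rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]],
                   m[bad[1, 1], bad[1, 2]]))
    stop("count table is not numeric")
  }
  if (taxa_as_rows) m <- t(m)
  abundance_matrix(m)
}

#' Write an abundance matrix as a tab-separated file
#' @inheritParams read_abundance
#' @param mat An `abundance_matrix`.
#' @export
write_abundance <- function(mat, path, taxa_as_rows = TRUE) {
  stopifnot(inherits(mat, "abundance_matrix"))
  m <- mat$counts
  if (taxa_as_rows) m <- t(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  names(df)[1] <- if (taxa_as_rows) "OTU_ID" else "Sample_ID"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Numeric columns are typed as numbers; missing values stay missing (they
#' are handled per-analysis by pairwise deletion, never imputed at load).
#'
#' @param path Tab-separated file, one row per sample, first column sample id.
#' @param sample_ids Optional vector of expected sample ids; ids in the file
#'   that do not match are reported with a warning and attached as attribute
#'   `unmatched`.
#' @return data.frame with rownames = sample ids.
#' @export
read_metadata <- function(path, sample_ids = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1,
                          na.strings = c("NA", ""))
  # drop columns that are entirely empty
  df <- df[, !vapply(df, function(x) all(is.na(x)), logical(1)), drop = FALSE]
  if (!is.null(sample_ids)) {
    unmatched <- setdiff(rownames(df), sample_ids)
    if (length(unmatched) > 0)
      warning("metadata sample ids not present in the abundance matrix: ",
              paste(unmatched, collapse = ", "))
    attr(df, "unmatched") <- unmatched
  }
  df
}

.LANDUSE_CLASSES <- c("farmlands", "forests", "freshwaters", "urban", "others")

#' Read a per-sub-basin land-use area table
#'
#' Expects tab-separated columns `sub_basin`, the five cover classes
#' (`farmlands`, `forests`, `freshwaters`, `urban`, `others`, in km^2) and
#' `total`. Class areas must sum to the total within 0.5%.
#'
#' @param path File path.
#' @return data.frame of class `landuse_table`.
#' @export
read_landuse <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  validate_landuse(df)
}

#' Validate a land-use table
#' @param df data.frame with the columns described in [read_landuse()].
#' @export
validate_landuse <- function(df) {
  need <- c("sub_basin", .LANDUSE_CLASSES, "total")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("land-use table missing columns: ",
                             paste(miss, collapse = ", "))
  areas <- as.matrix(df[, .LANDUSE_CLASSES])
  if (any(areas < 0) || any(df$total <= 0))
    stop("land-use areas must be nonnegative with positive totals")
  rel_err <- abs(rowSums(areas) - df$total) / df$total
  if (any(rel_err > 0.005))
    stop("class areas do not sum to the total within 0.5% for sub-basin(s): ",
         paste(df$sub_basin[rel_err > 0.005], collapse = ", "))
  class(df) <- c("landuse_table", "data.frame")
  df
}

#' Write a land-use table
#' @param df A `landuse_table`.
#' @param path Output path.
#' @export
write_landuse <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a signed co-occurrence network
#'
#' @param nodes data.frame with columns `id`, `phylum`, `mean_abundance`.
#' @param edges data.frame with columns `source`, `target`, `sign` (+1/-1),
#'   `correlation`, `support`, `q_value`.
#' @return Object of class `co_network`.
#' @export
co_network <- function(nodes, edges) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    if (any(edges$source == edges$target)) stop("self-loops are not allowed")
    # canonical orientation source < target, then lexicographic sort
    flip <- edges$source > edges$target
    tmp <- edges$source[flip]; edges$source[flip] <- edges$target[flip]
    edges$target[flip] <- tmp
    key <- paste(edges$source, edges$target, sep = "\r")
    if (anyDuplicated(key)) stop("duplicate edges")
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
    if (any(sign(edges$correlation) != edges$sign & edges$correlation != 0))
      stop("edge sign must match the sign of its correlation value")
  }
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  npos <- sum(x$edges$sign > 0)
  cat(sprintf("co_network: %d nodes, %d edges (%d positive, %d negative)\n",
              nrow(x$nodes), nrow(x$edges), npos, nrow(x$edges) - npos))
  invisible(x)
}

#' Convert a co-occurrence network to an igraph graph
#' @param net A `co_network`.
#' @return An undirected `igraph` graph with edge attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "co_network"))
  igraph::graph_from_data_frame(
    net$edges[, c("source", "target", "sign", "correlation", "support", "q_value"),
              drop = FALSE],
    directed = FALSE, vertices = net$nodes)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Write a network to disk
#'
#' The edge-list TSV carries columns source, target, sign, correlation,
#' support, q_value in lexicographic node-pair order; GraphML carries the
#' same attributes and is readable by Cytoscape-style viewers and generic
#' graph libraries. Both writers are deterministic.
#'
#' @param net A `co_network`.
#' @param path Output path.
#' @param format `"tsv"` (edge list) or `"graphml"`.
#' @export
write_network <- function(net, path, format = c("tsv", "graphml")) {
  stopifnot(inherits(net, "co_network"))
  format <- match.arg(format)
  e <- net$edges
  if (format == "tsv") {
    cols <- c("source", "target", "sign", "correlation", "support", "q_value")
    hdr <- paste(cols, collapse = "\t")
    if (nrow(e) == 0) {
      writeLines(hdr, path)
    } else {
      body <- apply(e[, cols], 1, function(r) paste(trimws(r), collapse = "\t"))
      writeLines(c(hdr, body), path)
    }
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
  w('  <key id="phylum" for="node" attr.name="phylum" attr.type="string"/>')
  w('  <key id="mean_abundance" for="node" attr.name="mean_abundance" attr.type="double"/>')
  w('  <key id="sign" for="edge" attr.name="sign" attr.type="int"/>')
  w('  <key id="correlation" for="edge" attr.name="correlation" attr.type="double"/>')
  w('  <key id="support" for="edge" attr.name="support" attr.type="int"/>')
  w('  <key id="q_value" for="edge" attr.name="q_value" attr.type="double"/>')
  w('  <graph id="G" edgedefault="undirected">')
  for (i in seq_len(nrow(net$nodes))) {
    nd <- net$nodes[i, ]
    w('    <node id="%s">', .xml_escape(nd$id))
    if (!is.null(nd$phylum) && !is.na(nd$phylum))
      w('      <data key="phylum">%s</data>', .xml_escape(nd$phylum))
    if (!is.null(nd$mean_abundance) && is.finite(nd$mean_abundance))
      w('      <data key="mean_abundance">%s</data>', format(nd$mean_abundance, digits = 15))
    w('    </node>')
  }
  for (i in seq_len(nrow(e))) {
    w('    <edge source="%s" target="%s">', .xml_escape(e$source[i]), .xml_escape(e$target[i]))
    w('      <data key="sign">%d</data>', as.integer(e$sign[i]))
    w('      <data key="correlation">%s</data>', format(e$correlation[i], digits = 15))
    w('      <data key="support">%d</data>', as.integer(e$support[i]))
    w('      <data key="q_value">%s</data>', format(e$q_value[i], digits = 15))
    w('    </edge>')
  }
  w('  </graph>')
  w('</graphml>')
  invisible(path)
}

#' Read an edge-list TSV written by [write_network()]
#' @param path File path.
#' @param nodes Optional node table; reconstructed from the edge list when
#'   omitted.
#' @return A `co_network`.
#' @export
read_network <- function(path, nodes = NULL) {
  e <- utils::read.delim(path, check.names = FALSE,
                         colClasses = c(source = "character", target = "character"))
  if (is.null(nodes)) {
    ids <- sort(unique(c(e$source, e$target)))
    nodes <- data.frame(id = ids, phylum = NA_character_,
                        mean_abundance = NA_real_)
  }
  co_network(nodes, e)
}
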