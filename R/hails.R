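#' Human activity intensity of land surface (HAILS)
#'
#' HAILS expresses the share of a sub-basin's land surface under direct
#' human-influenced cover: `HAILS = 100 * sum(S_i) / S`, where `S_i` are the
#' areas of the human-influenced cover types and `S` the total area.
#' Directly human-influenced cover defaults to farmland plus urban
#' (residential/constructed) land; the set is overridable.
#'
#' @param landuse A `landuse_table` (see [read_landuse()]).
#' @param human_classes Cover classes counted as human-influenced
#'   (default `c("farmlands", "urban")`).
#' @return data.frame of class `hails_result` with columns `sub_basin`,
#'   `hails_pct`.
#' @export
compute_hails <- function(landuse, human_classes = c("farmlands", "urban")) {
  landuse <- validate_landuse(landuse)
  bad <- setdiff(human_classes, .LANDUSE_CLASSES)
  if (length(bad) > 0)
    stop("unknown land-use classes: ", paste(bad, collapse = ", "))
  if (any(landuse$total <= 0)) stop("zero total area")
  human <- rowSums(as.matrix(landuse[, human_classes, drop = FALSE]))
  out <- data.frame(sub_basin = landuse$sub_basin,
                    hails_pct = 100 * human / landuse$total)
  class(out) <- c("hails_result", "data.frame")
  out
}

#' Classify sub-basins into low / middle / high intensity reaches
#'
#' The tertile method ranks sub-basins by `hails_pct` and splits them into
#' three as-equal-as-possible groups (ties broken by upstream, i.e. input,
#' order); the fixed method applies two user thresholds. A degenerate
#' gradient (all values equal) assigns every sub-basin to "low" with a
#' warning. Realized class boundaries are attached as attribute
#' `boundaries`.
#'
#' @param result A `hails_result` from [compute_hails()].
#' @param method `"tertile"` (default) or `"fixed"`.
#' @param thresholds For `method = "fixed"`: two increasing cut-offs in
#'   percent; values `<= t1` are low, `<= t2` middle, else high.
#' @return The input with a `class_label` column added.
#' @export
classify_reaches <- function(result, method = c("tertile", "fixed"),
                             thresholds = NULL) {
  stopifnot(inherits(result, "hails_result"))
  method <- match.arg(method)
  n <- nrow(result)
  labels <- c("low", "middle", "high")
  if (method == "fixed") {
    if (is.null(thresholds) || length(thresholds) != 2)
      stop("fixed method needs two thresholds")
    if (diff(thresholds) <= 0) stop("thresholds must be strictly increasing")
    lab <- labels[findInterval(result$hails_pct, thresholds, left.open = TRUE) + 1L]
    bounds <- thresholds
  } else {
    if (n < 3) stop("tertile method needs at least 3 sub-basins")
    if (length(unique(result$hails_pct)) == 1) {
      warning("degenerate gradient: all HAILS values equal; assigning all 'low'")
      result$class_label <- "low"
      attr(result, "boundaries") <- NA_real_
      return(result)
    }
    rk <- order(result$hails_pct)          # stable: ties keep upstream order
    sizes <- diff(round(seq(0, n, length.out = 4)))
    lab <- character(n)
    lab[rk] <- rep(labels, times = sizes)
    grp_max <- c(max(result$hails_pct[lab == "low"]),
                 max(result$hails_pct[lab == "middle"]))
    bounds <- grp_max
  }
  result$class_label <- lab
  attr(result, "boundaries") <- bounds
  result
}
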