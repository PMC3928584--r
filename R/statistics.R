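#' @include AllClasses.R AllGenerics.R morphometry.R branch-geometry.R
NULL

#' Vertical compression: one row per branch
#'
#' Compresses a reconstruction's per-point information into a branch-level
#' table: each row holds one branch's topological annotations and its
#' accumulative morphological parameters, joined with the geometry of its
#' proximal attachment (angle to the parent branch) and of its distal
#' bifurcation (Rall exponent), when those exist.  Missing values (for
#' example the Rall exponent of a terminal branch) propagate as \code{NA}.
#'
#' @param x a fully annotated [BranchForest-class].
#' @param cellId identifier stored in the first column (defaults to the
#'   forest's source name).
#' @param m segments per branch for directional vectors (default 5).
#' @param tol relative tolerance for the Rall root (default 1e-8).
#' @param ... unused.
#' @return data.frame with one row per branch of the forest.
#' @rdname verticalCompress
#' @export
setMethod("verticalCompress", "BranchForest",
          function(x, cellId = x@sourceName, m = 5L, tol = 1e-8, ...) {
  met <- branchMetrics(x)
  bif <- bifurcations(x, m = m, tol = tol)
  met$angleToParent <- bif$angle[match(met$firstName, bif$daughterBranch)]
  met$rallExponent <-
    bif$rallExponent[match(met$firstName, bif$parentBranch)]
  met$meanRadius <- met$meanDiameter / 2
  cbind(data.frame(cellId = cellId), met)
})

#' Sturges-rule histogram bin edges
#'
#' Equal-width bins with the bin count set by Sturges' rule,
#' k = ceiling(1 + log2(n)), spanning the data range.  When all values are
#' identical the degenerate zero-width range is widened by +/- 0.5.
#'
#' @param values numeric vector; non-finite values are dropped.
#' @return Numeric vector of k + 1 strictly increasing bin edges.
#' @examples
#' length(sturgesBreaks(rnorm(100))) - 1  # 8 bins
#' @export
sturgesBreaks <- function(values) {
  v <- values[is.finite(values)]
  n <- length(v)
  if (n < 1L) stop("no finite values to bin")
  k <- ceiling(1 + log2(n))
  lo <- min(v); hi <- max(v)
  if (hi - lo <= 1e-9 * max(abs(lo), abs(hi), 1)) {
    lo <- lo - 0.5; hi <- hi + 0.5
  }
  seq(lo, hi, length.out = k + 1L)
}

## per-cell counts on fixed edges: bins are [e_i, e_{i+1}), last bin closed
.binCounts <- function(v, breaks) {
  v <- v[is.finite(v)]
  if (length(v) && (any(v < breaks[1L]) || any(v > breaks[length(breaks)])))
    stop("values fall outside the bin range; compute breaks over the ",
         "pooled groups for shared-bin comparisons")
  idx <- findInterval(v, breaks, rightmost.closed = TRUE)
  tabulate(idx, nbins = length(breaks) - 1L)
}

#' Group frequency distribution of one morphometric parameter
#'
#' Builds a per-cell histogram of one branch-table column on common bin
#' edges and summarizes the group as the per-bin mean count +/- standard
#' error of the mean across cells.  By default the edges follow Sturges'
#' rule on the values pooled over the group's cells; pass explicit
#' \code{breaks} (for example computed over several groups pooled together)
#' to compare groups on the same bin width.
#'
#' @param tables list of branch tables (one per cell), as produced by
#'   [verticalCompress()].
#' @param parameter name of the column to summarize.
#' @param breaks optional explicit bin edges; \code{NULL} (default) applies
#'   [sturgesBreaks()] to the pooled finite values.
#' @return A [DistributionSummary-class].  Per-cell counts always sum to
#'   that cell's number of finite values; a single-cell group reports
#'   \code{NA} SEMs.
#' @export
groupDistribution <- function(tables, parameter, breaks = NULL) {
  if (is.data.frame(tables)) tables <- list(tables)
  for (tb in tables)
    if (!parameter %in% names(tb))
      stop("parameter '", parameter, "' not present in the branch tables")
  pooled <- unlist(lapply(tables, function(tb) tb[[parameter]]))
  if (is.null(breaks)) breaks <- sturgesBreaks(pooled)
  counts <- do.call(rbind, lapply(tables, function(tb)
    .binCounts(tb[[parameter]], breaks)))
  nCells <- length(tables)
  mu <- colMeans(counts)
  sem <- if (nCells > 1L) apply(counts, 2L, stats::sd) / sqrt(nCells)
         else rep(NA_real_, ncol(counts))
  new("DistributionSummary", parameter = parameter, breaks = breaks,
      counts = counts, mean = mu, sem = sem, nCells = nCells)
}
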