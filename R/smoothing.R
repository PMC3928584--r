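#' @include AllClasses.R AllGenerics.R topology.R
NULL

#' Smoothing configuration
#'
#' Digitized reconstructions carry z-axis noise from the acquisition and
#' assembly steps.  The filter replaces each z value by the mean of the z
#' values whose xy-projected arc-length position lies within a half-width
#' window; the xy-projected distance is used as the predictor because the
#' spatial distribution of traced points is not uniform.
#'
#' @param window half-width of the moving-average window, in micrometres of
#'   xy-projected arc length.  \code{window = 0} makes the filter the
#'   identity.
#' @param passes number of filter passes (>= 1).
#' @return A list with elements \code{window} and \code{passes}.
#' @export
smoothingConfig <- function(window = 5, passes = 1L) {
  stopifnot(window >= 0, passes >= 1L)
  list(window = window, passes = as.integer(passes))
}

#' Smooth the z coordinates of one branch
#'
#' Applies the moving-average filter along the branch, with two synthetic
#' boundary points concatenated at the branch endings so that smoothing does
#' not create local z-jumps at bifurcations: the prepended point carries the
#' average of the parent's final z and the branch's own first z (omitted for
#' a root branch), and the appended point carries the average of the initial
#' z of all daughters (omitted for a terminal branch).  The boundary points
#' sit one mean inter-point spacing outside the branch on the predictor
#' axis.  Consecutive points with zero xy spacing are tie-broken by 1e-6 um
#' predictor increments.
#'
#' @param branch a [Branch-class].
#' @param parentFinalZ smoothed final z of the parent branch, or \code{NULL}
#'   for a root branch.
#' @param daughtersInitialZ numeric vector of the daughters' initial z
#'   values (their first point after the bifurcation); empty for a terminal
#'   branch.
#' @param config a [smoothingConfig()] list.
#' @return The branch with smoothed z; x, y, radii and point count are
#'   unchanged.
#' @export
smoothBranchZ <- function(branch, parentFinalZ = NULL,
                          daughtersInitialZ = numeric(),
                          config = smoothingConfig()) {
  pts <- branch@points
  n <- nrow(pts)
  if (n < 2L) {
    warning("branch with fewer than 2 points left unsmoothed")
    return(branch)
  }
  if (config$window == 0) return(branch)
  dxy <- sqrt(diff(pts[, "x"])^2 + diff(pts[, "y"])^2)
  s <- cumsum(c(0, pmax(dxy, 1e-6)))
  dbar <- s[n] / (n - 1L)
  z <- pts[, "z"]
  sAug <- s
  fixedPre <- fixedPost <- FALSE
  if (!is.null(parentFinalZ) && length(parentFinalZ)) {
    sAug <- c(-dbar, sAug)
    fixedPre <- TRUE
  }
  if (length(daughtersInitialZ)) {
    sAug <- c(sAug, s[n] + dbar)
    fixedPost <- TRUE
  }
  zPre <- if (fixedPre) mean(c(parentFinalZ, z[1L])) else numeric()
  zPost <- if (fixedPost) mean(daughtersInitialZ) else numeric()
  core <- seq_len(n) + as.integer(fixedPre)
  for (pass in seq_len(config$passes)) {
    zAug <- c(zPre, z, zPost)
    z <- vapply(core, function(i)
      mean(zAug[abs(sAug - sAug[i]) <= config$window]), numeric(1))
  }
  pts[, "z"] <- z
  branch@points <- pts
  branch
}

#' Smooth the z coordinates of a whole reconstruction
#'
#' Identifies the branches and applies [smoothBranchZ()] to each in
#' root-to-tip order, writing the smoothed z values back into the point
#' records.  Each branch keeps its attachment point pinned to the parent's
#' (already smoothed) endpoint, so sister branches stay spatially continuous
#' at bifurcations.  x, y, radii, indices and topology are untouched; soma
#' points are never smoothed.
#'
#' @param x an [SWCReconstruction-class].
#' @param config a [smoothingConfig()] list.
#' @param ... unused.
#' @return A new [SWCReconstruction-class] with smoothed z.
#' @rdname smoothReconstruction
#' @export
setMethod("smoothReconstruction", "SWCReconstruction",
          function(x, config = smoothingConfig(), ...) {
  if (config$window == 0) return(x)
  forest <- branchForest(x)
  df <- x@records
  rowOf <- integer(max(df$index))
  rowOf[df$index] <- seq_len(nrow(df))
  for (b in seq_along(forest@branches)) {
    br <- forest@branches[[b]]
    rows <- rowOf[br@pointIndices]
    ## current (possibly already-smoothed upstream) z values
    br@points[, "z"] <- df$z[rows]
    parentFinalZ <- if (is.na(br@parentBranch)) NULL else df$z[rows[1L]]
    dz <- vapply(br@daughterBranches, function(d) {
      dbr <- forest@branches[[d]]
      df$z[rowOf[dbr@pointIndices[2L]]]
    }, numeric(1))
    sm <- smoothBranchZ(br, parentFinalZ = parentFinalZ,
                        daughtersInitialZ = dz, config = config)
    ## the attachment point (row 1) belongs to the parent branch or soma
    own <- seq_len(nrow(sm@points))[-1L]
    df$z[rows[own]] <- sm@points[own, "z"]
  }
  out <- x
  out@records <- df
  out
})
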