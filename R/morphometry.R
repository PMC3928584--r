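#' @include AllClasses.R AllGenerics.R topology.R
NULL

.segLengths <- function(pts)
  sqrt(rowSums((pts[-1L, c("x", "y", "z"), drop = FALSE] -
                pts[-nrow(pts), c("x", "y", "z"), drop = FALSE])^2))

#' Branch length
#'
#' The length of a branch is the sum of the 3D Euclidean lengths of all its
#' segments.
#'
#' @param branch a [Branch-class].
#' @return Length in micrometres.
#' @export
branchLength <- function(branch) sum(.segLengths(branch@points))

#' Distance-metric (DM) tortuosity
#'
#' Dimensionless ratio between the actual path length of the branch (along
#' its segments) and the straight-line distance between its endpoints.
#' Always >= 1, with equality exactly for a collinear branch.
#'
#' @param branch a [Branch-class].
#' @return DM tortuosity, or \code{NA} (with a warning) when the endpoints
#'   coincide.
#' @export
dmTortuosity <- function(branch) {
  pts <- branch@points
  chord <- sqrt(sum((pts[nrow(pts), c("x", "y", "z")] -
                     pts[1L, c("x", "y", "z")])^2))
  if (chord == 0) {
    warning("branch endpoints coincide; DM tortuosity undefined")
    return(NA_real_)
  }
  branchLength(branch) / chord
}

#' Sum-of-angles-metric (SOAM) tortuosity
#'
#' Integrates the total curvature along the branch polyline and normalizes
#' it by path length, which makes values comparable between branches of
#' different length and handles tight coils better than DM.  For each
#' interior point P_k the three consecutive difference vectors
#' T1 = P_k - P_{k-1}, T2 = P_{k+1} - P_k, T3 = P_{k+2} - P_{k+1} give the
#' in-plane angle IP_k = arccos(T1.T2 / |T1||T2|) and the torsional angle
#' TP_k = arccos of the dot product of the unit cross products T1 x T2 and
#' T2 x T3 (both angles in [0, pi]); the combined angle is
#' CP_k = sqrt(IP_k^2 + TP_k^2) and SOAM = sum(CP_k) / path length.
#' A straight continuation (zero-magnitude cross product) contributes zero
#' torsion.
#'
#' @param branch a [Branch-class].
#' @param details if \code{TRUE}, also return the per-point IP, TP and CP
#'   angle vectors as attributes.
#' @return SOAM tortuosity in radians per micrometre (0 for a branch with
#'   fewer than 4 points, where no combined angle is defined).
#' @export
soamTortuosity <- function(branch, details = FALSE) {
  pts <- branch@points[, c("x", "y", "z"), drop = FALSE]
  n <- nrow(pts)
  len <- sum(.segLengths(branch@points))
  if (n < 4L) {
    out <- 0
    attr(out, "tooShort") <- TRUE
    return(out)
  }
  Tv <- pts[-1L, , drop = FALSE] - pts[-n, , drop = FALSE]
  clampAcos <- function(x) acos(pmin(1, pmax(-1, x)))
  ip <- tp <- numeric(n - 3L)
  for (k in seq_len(n - 3L)) {
    t1 <- Tv[k, ]; t2 <- Tv[k + 1L, ]; t3 <- Tv[k + 2L, ]
    ip[k] <- clampAcos(sum(t1 * t2) / (sqrt(sum(t1^2)) * sqrt(sum(t2^2))))
    c12 <- c(t1[2L] * t2[3L] - t1[3L] * t2[2L],
             t1[3L] * t2[1L] - t1[1L] * t2[3L],
             t1[1L] * t2[2L] - t1[2L] * t2[1L])
    c23 <- c(t2[2L] * t3[3L] - t2[3L] * t3[2L],
             t2[3L] * t3[1L] - t2[1L] * t3[3L],
             t2[1L] * t3[2L] - t2[2L] * t3[1L])
    n12 <- sqrt(sum(c12^2)); n23 <- sqrt(sum(c23^2))
    ## a cross product is degenerate (straight continuation, zero torsion)
    ## when the sine of the turn angle is at floating-point noise level
    eps12 <- 1e-9 * sqrt(sum(t1^2)) * sqrt(sum(t2^2))
    eps23 <- 1e-9 * sqrt(sum(t2^2)) * sqrt(sum(t3^2))
    tp[k] <- if (n12 <= eps12 || n23 <= eps23) 0
             else clampAcos(sum(c12 * c23) / (n12 * n23))
  }
  cp <- sqrt(ip^2 + tp^2)
  out <- sum(cp) / len
  if (details) {
    attr(out, "IP") <- ip
    attr(out, "TP") <- tp
    attr(out, "CP") <- cp
  }
  out
}

#' Branch tapering and mean diameter
#'
#' Tapering measures the change in diameter along a branch: the slope of an
#' ordinary least-squares regression of point diameter (2 x radius) on
#' cumulative 3D arc length.  The per-branch mean diameter and its standard
#' error of the mean are reported alongside.
#'
#' @param branch a [Branch-class] with at least 2 points.
#' @return Named list: \code{taperSlope} (um diameter per um length;
#'   \code{NA} when all points share one arc-length position),
#'   \code{meanDiameter} and \code{diameterSEM} (um).
#' @export
tapering <- function(branch) {
  pts <- branch@points
  d <- 2 * pts[, "radius"]
  s <- cumsum(c(0, .segLengths(pts)))
  slope <- if (length(unique(s)) < 2L) NA_real_
           else unname(stats::coef(stats::lm(d ~ s))[2L])
  list(taperSlope = slope, meanDiameter = mean(d),
       diameterSEM = stats::sd(d) / sqrt(length(d)))
}

#' Euclidean and path distance from the soma to a branch
#'
#' The Euclidean distance is the straight line from the reconstruction's
#' soma root point to the branch's start point; the path distance is the
#' summed length of all ancestor branches along the genealogy up to that
#' start point.  The path distance can never be smaller than the Euclidean
#' one.
#'
#' @param branch a [Branch-class] with its genealogy assigned.
#' @param forest the [BranchForest-class] the branch belongs to.
#' @return Named list \code{euclideanToSoma}, \code{pathToSoma} (um).
#' @export
somaDistances <- function(branch, forest) {
  if (!length(branch@fullName))
    stop("branch genealogy not assigned; run assignFullNames() first")
  start <- branch@points[1L, c("x", "y", "z")]
  euclid <- sqrt(sum((start - forest@somaPoint)^2))
  ancestors <- branch@fullName[-length(branch@fullName)]
  path <- 0
  for (a in ancestors) path <- path + branchLength(forest@branches[[a]])
  list(euclideanToSoma = euclid, pathToSoma = path)
}

#' Per-branch morphometrics table
#'
#' Computes the accumulative measurements for every branch of a forest:
#' length, distances to the soma, tapering, mean diameter +/- SEM, DM and
#' SOAM tortuosity, together with the topological annotations.
#'
#' @param x a fully annotated [BranchForest-class] (see [branchForest()]).
#' @param ... unused.
#' @return data.frame with one row per branch.
#' @rdname branchMetrics
#' @export
setMethod("branchMetrics", "BranchForest", function(x, ...) {
  br <- x@branches
  rows <- lapply(br, function(b) {
    tp <- tapering(b)
    sd_ <- somaDistances(b, x)
    data.frame(firstName = b@firstName, flag = b@flag,
               nSegments = nrow(b@points) - 1L,
               centrifugalOrder = b@centrifugalOrder,
               strahlerOrder = b@strahlerOrder,
               parentBranch = b@parentBranch,
               nDaughters = length(b@daughterBranches),
               length = branchLength(b),
               euclideanToSoma = sd_$euclideanToSoma,
               pathToSoma = sd_$pathToSoma,
               taperSlope = tp$taperSlope,
               meanDiameter = tp$meanDiameter,
               diameterSEM = tp$diameterSEM,
               dm = suppressWarnings(dmTortuosity(b)),
               soam = as.numeric(soamTortuosity(b)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
})
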