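#' @include AllClasses.R AllGenerics.R topology.R morphometry.R
NULL

#' Directional vector at a branch ending
#'
#' The bifurcation angle between two branches does not depend on their
#' terminal segments alone, so the local direction at a branch ending is
#' estimated over several segments: the first (or last) \code{min(m,
#' available)} segments' points are fitted with a 3D total-least-squares
#' line (first principal axis of the centered points) and the unit vector is
#' oriented in the direction of increasing arc length.
#'
#' @param branch a [Branch-class].
#' @param end \code{"start"} or \code{"finish"}.
#' @param m number of segments to use (default 5; fewer are used when the
#'   branch is shorter).
#' @return Named list: \code{origin} (the ending point), \code{direction}
#'   (unit 3-vector), \code{nSegmentsUsed}.
#' @export
directionalVector <- function(branch, end = c("finish", "start"), m = 5L) {
  end <- match.arg(end)
  pts <- branch@points[, c("x", "y", "z"), drop = FALSE]
  n <- nrow(pts)
  k <- min(m, n - 1L)
  sel <- if (end == "start") seq_len(k + 1L) else seq(n - k, n)
  sub <- pts[sel, , drop = FALSE]
  chord <- sub[nrow(sub), ] - sub[1L, ]
  if (all(abs(sweep(sub, 2L, sub[1L, ])) < 1e-12))
    stop("all points selected for the directional vector coincide")
  ctr <- sweep(sub, 2L, colMeans(sub))
  v <- svd(ctr, nu = 0L, nv = 1L)$v[, 1L]
  if (sum(v * chord) < 0) v <- -v
  v <- v / sqrt(sum(v^2))
  origin <- if (end == "start") pts[1L, ] else pts[n, ]
  list(origin = unname(origin), direction = unname(v), nSegmentsUsed = k)
}

#' Bifurcation angle between a daughter branch and its parent
#'
#' The angle between the parent's finish directional vector (its direction
#' of growth away from the soma) and the daughter's start directional
#' vector, in \[0, pi\].  A daughter continuing exactly along the parent's
#' line has angle 0.
#'
#' @param parent,daughter [Branch-class] objects; the daughter must be a
#'   daughter of the parent.
#' @param m segments per branch for the directional vectors (default 5).
#' @return Angle in radians.
#' @export
bifurcationAngle <- function(parent, daughter, m = 5L) {
  if (is.na(daughter@parentBranch) ||
      daughter@parentBranch != parent@firstName)
    stop("branch ", daughter@firstName, " is not a daughter of branch ",
         parent@firstName)
  vp <- directionalVector(parent, "finish", m)$direction
  vd <- directionalVector(daughter, "start", m)$direction
  acos(min(1, max(-1, sum(vp * vd))))
}

#' Rall exponent of a bifurcation
#'
#' Rall's equivalent-cylinder model for passive dendrites predicts that at a
#' bifurcation the daughter diameters raised to the 3/2 power sum to the
#' parent diameter raised to the 3/2 power (the "3/2 power rule").  The
#' per-bifurcation generalization is the exponent E solving
#' \deqn{d_{eq}^E = \sum_i d_i^E}
#' found by bracketed root finding of
#' \eqn{(\sum_i d_i^E)^{1/E} - d_{eq}} over E in \[0.05, 20\].  A
#' bifurcation obeying the classic rule returns exactly 3/2.
#'
#' @param dEq parent branch diameter at the bifurcation (um).
#' @param d numeric vector (length >= 2) of daughter diameters (um).
#' @param tol relative tolerance of the root (default 1e-8).
#' @return The exponent, or \code{NA} with a \code{"reason"} attribute when
#'   no root exists in the bracket (notably when the parent diameter does
#'   not exceed the largest daughter diameter).
#' @examples
#' rallExponent(2^(2/3), c(1, 1))  # 1.5
#' @export
rallExponent <- function(dEq, d, tol = 1e-8) {
  stopifnot(length(d) >= 2L, all(d > 0), dEq > 0)
  f <- function(E) sum(d^E)^(1 / E) - dEq
  lo <- 0.05; hi <- 20
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0) {
    out <- NA_real_
    attr(out, "reason") <- if (dEq <= max(d))
      "parent diameter does not exceed the largest daughter diameter"
    else "no sign change in the exponent bracket [0.05, 20]"
    return(out)
  }
  stats::uniroot(f, c(lo, hi), tol = tol * max(1, abs(lo)))$root
}

#' Bifurcation table of a branch forest
#'
#' One row per (bifurcation, daughter) pair: the bifurcation location (the
#' parent branch's final point), the parent diameter there, the daughter
#' diameter at its first point after the bifurcation, the bifurcation angle,
#' and the per-bifurcation Rall exponent (repeated across the daughters of
#' one bifurcation).
#'
#' @param x a [BranchForest-class].
#' @param m segments per branch for directional vectors (default 5).
#' @param tol relative tolerance for the Rall root (default 1e-8).
#' @param ... unused.
#' @return data.frame with columns \code{parentBranch}, \code{daughterBranch},
#'   \code{x}, \code{y}, \code{z}, \code{dEq}, \code{dDaughter},
#'   \code{angle} (radians), \code{rallExponent}.
#' @rdname bifurcations
#' @export
setMethod("bifurcations", "BranchForest", function(x, m = 5L, tol = 1e-8, ...) {
  rows <- list()
  for (b in x@branches) {
    ds <- b@daughterBranches
    if (length(ds) < 2L) next
    np <- nrow(b@points)
    loc <- b@points[np, c("x", "y", "z")]
    dEq <- 2 * b@points[np, "radius"]
    dDs <- vapply(ds, function(dn) 2 * x@branches[[dn]]@points[2L, "radius"],
                  numeric(1))
    rall <- as.numeric(rallExponent(dEq, dDs, tol))
    for (i in seq_along(ds)) {
      dbr <- x@branches[[ds[i]]]
      rows[[length(rows) + 1L]] <- data.frame(
        parentBranch = b@firstName, daughterBranch = dbr@firstName,
        x = loc[["x"]], y = loc[["y"]], z = loc[["z"]],
        dEq = dEq, dDaughter = dDs[i],
        angle = bifurcationAngle(b, dbr, m), rallExponent = rall)
    }
  }
  if (!length(rows))
    return(data.frame(parentBranch = integer(), daughterBranch = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      dEq = numeric(), dDaughter = numeric(),
                      angle = numeric(), rallExponent = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
})
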