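#' @include AllClasses.R AllGenerics.R swc-io.R
NULL

## Run expr with a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hadSeed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## 2D rotation of an xy direction by angle a (fixtures are built in the
## xy-plane; z structure enters only as optional additive noise)
.rot2 <- function(v, a)
  c(cos(a) * v[1L] - sin(a) * v[2L], sin(a) * v[1L] + cos(a) * v[2L])

#' Specification of a deterministic synthetic reconstruction
#'
#' Describes a synthetic traced neuron with known topology, known branch
#' lengths, known taper and a planned Rall exponent at every bifurcation,
#' used as ground truth throughout testing.  Geometry is built in the
#' xy-plane (so the noise-free z is identically zero); optional additive
#' Gaussian z-noise emulates the z-axis digitization noise of archive cells.
#'
#' @param template \code{"chain"} (one unbranched branch), \code{"ytree"}
#'   (a stem with two daughters) or \code{"btree"} (a complete binary tree
#'   of \code{depth} levels, 2^depth - 1 branches).
#' @param depth levels of the binary tree (ignored otherwise).
#' @param branchLength axial length of every branch, um.
#' @param pointsPerBranch traced points per branch including the attachment
#'   point (segments = pointsPerBranch - 1).
#' @param startDiameter diameter at the start of the root branch, um.
#' @param taper within-branch diameter slope, um diameter per um length
#'   (0 = cylindrical).
#' @param rallExponent planned exponent; daughter diameters at each
#'   bifurcation are constructed so the parent end diameter raised to this
#'   exponent equals the sum of the daughter diameters so raised.
#' @param angle planar angle (radians) between each daughter and the parent
#'   direction (+/- angle for the two daughters).
#' @param wiggle amplitude (um) of a sinusoidal in-plane lateral
#'   displacement, making branches meander (0 = perfectly straight).
#' @param znoise standard deviation (um) of i.i.d. Gaussian noise added to
#'   the z of every non-soma point (0 = noise-free twin).
#' @param seed RNG seed for the z-noise draw.
#' @param flag SWC structure flag of the dendritic points (default 3,
#'   basal dendrite).
#' @return A list of class \code{"FixtureSpec"}.
#' @seealso [makeFixture()]
#' @export
fixtureSpec <- function(template = c("chain", "ytree", "btree"), depth = 3L,
                        branchLength = 50, pointsPerBranch = 11L,
                        startDiameter = 2, taper = 0, rallExponent = 1.5,
                        angle = pi / 3, wiggle = 0, znoise = 0, seed = 1L,
                        flag = 3L) {
  template <- match.arg(template)
  stopifnot(depth >= 1L, branchLength > 0, pointsPerBranch >= 2L,
            startDiameter > 0, znoise >= 0, wiggle >= 0)
  structure(list(template = template, depth = as.integer(depth),
                 branchLength = branchLength,
                 pointsPerBranch = as.integer(pointsPerBranch),
                 startDiameter = startDiameter, taper = taper,
                 rallExponent = rallExponent, angle = angle,
                 wiggle = wiggle, znoise = znoise, seed = as.integer(seed),
                 flag = as.integer(flag)),
            class = "FixtureSpec")
}

#' Build a deterministic synthetic reconstruction
#'
#' Realizes a [fixtureSpec()] as a valid SWC reconstruction: a single soma
#' point at the origin followed by the planned branches, traversed
#' depth-first.  Identical specs give byte-identical reconstructions, and
#' the spec with \code{znoise = 0} is the exact noise-free twin of any noisy
#' variant (the noise draw never perturbs the construction).
#'
#' @param spec a [fixtureSpec()].
#' @return An [SWCReconstruction-class] that passes
#'   [validateReconstruction()] with no findings.
#' @examples
#' fx <- makeFixture(fixtureSpec("btree", depth = 3))
#' length(branches(branchForest(fx)))  # 7
#' @export
makeFixture <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  nLevels <- switch(spec$template, chain = 1L, ytree = 2L, btree = spec$depth)
  npts <- spec$pointsPerBranch
  step <- spec$branchLength / (npts - 1L)

  rows <- list()
  addRow <- function(flag, x, y, z, radius, parent) {
    idx <- length(rows) + 1L
    rows[[idx]] <<- c(idx, flag, x, y, z, radius, parent)
    idx
  }
  addRow(1L, 0, 0, 0, spec$startDiameter / 2, -1L)

  ## grow one branch from an attachment record; returns its end state
  growBranch <- function(attachIdx, origin, dir, startDiam, level) {
    perp <- .rot2(dir, pi / 2)
    prev <- attachIdx
    pos <- origin
    endDiam <- startDiam
    for (i in seq_len(npts - 1L)) {
      ax <- i * step
      lat <- spec$wiggle * sin(2 * pi * i / (npts - 1L))
      pos <- origin + dir * ax + perp * lat
      endDiam <- startDiam + spec$taper * ax
      prev <- addRow(spec$flag, pos[1L], pos[2L], 0,
                     max(endDiam, 0.01) / 2, prev)
    }
    if (level < nLevels) {
      ## plan the daughter so that its diameter measured at its first own
      ## point satisfies dEq^E = 2 * dDaughter^E exactly, taper included
      dP1 <- max(endDiam, 0.01) / 2^(1 / spec$rallExponent)
      for (sgn in c(1, -1))
        growBranch(prev, pos, .rot2(dir, sgn * spec$angle),
                   dP1 - spec$taper * step, level + 1L)
    }
  }
  growBranch(1L, c(0, 0), c(0, 1), spec$startDiameter, 1L)

  m <- do.call(rbind, rows)
  df <- data.frame(index = m[, 1L], flag = m[, 2L], x = m[, 3L], y = m[, 4L],
                   z = m[, 5L], radius = m[, 6L], parent = m[, 7L])
  if (spec$znoise > 0) {
    noise <- .withSeed(spec$seed, stats::rnorm(nrow(df) - 1L, 0, spec$znoise))
    df$z[-1L] <- df$z[-1L] + noise
  }
  SWCReconstruction(df,
    header = sprintf("# morphotree synthetic fixture: %s", spec$template),
    sourceName = sprintf("fixture-%s-seed%d", spec$template, spec$seed))
}

#' Random tree reconstruction for property testing
#'
#' Generates a random but internally consistent reconstruction: a soma root
#' at the origin and \code{nPoints - 1} dendritic points, each attached to a
#' uniformly chosen earlier point by a random nonzero step.  The resulting
#' trees have arbitrary out-degree (trifurcations included) and exercise
#' branch identification and Strahler ordering on irregular topologies.
#'
#' @param nPoints total number of points including the soma (>= 2).
#' @param seed RNG seed; identical seeds give identical reconstructions.
#' @return An [SWCReconstruction-class] with a single root.
#' @export
randomReconstruction <- function(nPoints, seed = 1L) {
  stopifnot(nPoints >= 2L)
  .withSeed(seed, {
    x <- y <- z <- numeric(nPoints)
    parent <- c(-1L, vapply(2:nPoints, function(i)
      if (i == 2L) 1L else sample.int(i - 1L, 1L), integer(1)))
    for (i in 2:nPoints) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2)) * stats::runif(1, 0.5, 2)
      p <- parent[i]
      x[i] <- x[p] + u[1L]; y[i] <- y[p] + u[2L]; z[i] <- z[p] + u[3L]
    }
    df <- data.frame(index = seq_len(nPoints),
                     flag = c(1L, rep(3L, nPoints - 1L)),
                     x = x, y = y, z = z,
                     radius = c(5, stats::runif(nPoints - 1L, 0.2, 1)),
                     parent = parent)
    SWCReconstruction(df, sourceName = sprintf("random-tree-seed%d", seed))
  })
}
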