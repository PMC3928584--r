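#' @include AllClasses.R AllGenerics.R statistics.R fixtures.R
NULL

#' Fit a morphometry model from branch tables
#'
#' Compresses the neuroanatomy of a cell class into per-centrifugal-order
#' empirical distributions of the branch-level parameters (branch length,
#' taper slope, mean diameter, SOAM tortuosity, angle to the parent), plus
#' the per-order branching probability: the observed fraction of branches at
#' that order that carry daughters.  The raw value lists are stored for
#' direct resampling by the virtual-neuron generator.
#'
#' @param tables a branch table from [verticalCompress()], or a list of them
#'   (one per cell); rows are pooled per centrifugal order.
#' @return A [MorphometryModel-class].
#' @export
fitMorphometryModel <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  if (!length(tables)) stop("no branch tables supplied")
  pooled <- do.call(rbind, tables)
  if (!nrow(pooled)) stop("branch tables contain no branches")
  maxOrder <- max(pooled$centrifugalOrder)
  orders <- lapply(seq_len(maxOrder), function(o) {
    rows <- pooled[pooled$centrifugalOrder == o, , drop = FALSE]
    keep <- function(v) v[is.finite(v)]
    list(length = keep(rows$length),
         taperSlope = keep(rows$taperSlope),
         meanDiameter = keep(rows$meanDiameter),
         soam = keep(rows$soam),
         angle = keep(rows$angleToParent),
         branchProb = mean(rows$nDaughters > 0L))
  })
  new("MorphometryModel", orders = orders, maxOrder = as.integer(maxOrder),
      nBranches = nrow(pooled))
}

#' Growth configuration for the virtual-neuron generator
#'
#' @param seed RNG seed; identical (model, config) pairs give byte-identical
#'   output.
#' @param nTrees number of dendritic trees grown from the soma.
#' @param maxBranches safety cap on the total number of branches; growth is
#'   truncated with a warning beyond it.
#' @param somaPosition xyz of the soma point (um).
#' @param somaRadius soma radius (um); default half the mean order-1 branch
#'   diameter of the model in use.
#' @param segmentsPerBranch polyline resolution of each grown branch.
#' @return A list of class \code{"GrowthConfig"}.
#' @export
growthConfig <- function(seed = 1L, nTrees = 1L, maxBranches = 1000L,
                         somaPosition = c(0, 0, 0), somaRadius = NULL,
                         segmentsPerBranch = 10L) {
  stopifnot(maxBranches > 0L, nTrees >= 1L, segmentsPerBranch >= 1L,
            length(somaPosition) == 3L)
  structure(list(seed = as.integer(seed), nTrees = as.integer(nTrees),
                 maxBranches = as.integer(maxBranches),
                 somaPosition = as.numeric(somaPosition),
                 somaRadius = somaRadius,
                 segmentsPerBranch = as.integer(segmentsPerBranch)),
            class = "GrowthConfig")
}

## draw one value from an empirical sample (resampling), with a fallback
## when the sample is empty
.resample <- function(v, fallback) {
  if (!length(v)) return(fallback)
  v[sample.int(length(v), 1L)]
}

## orthonormal basis perpendicular to unit vector u
.perpBasis <- function(u) {
  ref <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2L] * e1[3L] - u[3L] * e1[2L],
          u[3L] * e1[1L] - u[1L] * e1[3L],
          u[1L] * e1[2L] - u[2L] * e1[1L])
  list(e1 = e1, e2 = e2)
}

## rotate unit vector u by angle a toward azimuth psi around its own axis
.tilt <- function(u, a, psi) {
  b <- .perpBasis(u)
  v <- cos(a) * u + sin(a) * (cos(psi) * b$e1 + sin(psi) * b$e2)
  v / sqrt(sum(v^2))
}

#' Grow a virtual neuron from a morphometry model
#'
#' Stochastically grows a reconstruction by resampling the model's
#' order-conditioned empirical distributions: each branch draws its length,
#' mean diameter, taper and SOAM tortuosity target from its centrifugal
#' order's distributions, is realized as a 3D polyline whose per-step
#' curvature is scaled to the drawn tortuosity (at a random azimuth, so
#' realized branches meander in 3D), and then either terminates or spawns
#' two daughters according to the order's branching probability.  Daughter
#' directions are tilted off the parent's end direction by angles drawn from
#' the next order's bifurcation-angle distribution, at opposite random
#' azimuths.  Output is emitted as a valid, contiguously indexed SWC
#' reconstruction; identical (model, config) pairs reproduce byte-identical
#' output.
#'
#' @param model a [MorphometryModel-class].
#' @param config a [growthConfig()].
#' @param ... unused.
#' @return An [SWCReconstruction-class] passing [validateReconstruction()].
#' @rdname generateVirtualNeuron
#' @export
setMethod("generateVirtualNeuron", "MorphometryModel",
          function(model, config = growthConfig(), ...) {
  stopifnot(inherits(config, "GrowthConfig"))
  nseg <- config$segmentsPerBranch
  somaRadius <- if (is.null(config$somaRadius))
    mean(model@orders[[1L]]$meanDiameter) / 2 else config$somaRadius
  if (!is.finite(somaRadius) || somaRadius <= 0) somaRadius <- 1

  .withSeed(config$seed, {
    rows <- list()
    addRow <- function(flag, xyz, radius, parent) {
      idx <- length(rows) + 1L
      rows[[idx]] <<- c(idx, flag, xyz, radius, parent)
      idx
    }
    addRow(1L, config$somaPosition, somaRadius, -1L)

    ## LIFO stack of branches to grow: attachment record, origin, direction,
    ## centrifugal order
    stack <- list()
    for (t in seq_len(config$nTrees)) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      stack[[length(stack) + 1L]] <-
        list(attach = 1L, origin = config$somaPosition, dir = u, order = 1L)
    }

    nBranches <- 0L
    truncated <- FALSE
    while (length(stack)) {
      job <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (nBranches >= config$maxBranches) { truncated <- TRUE; break }
      nBranches <- nBranches + 1L
      o <- min(job$order, model@maxOrder)
      dist <- model@orders[[o]]
      L <- .resample(dist$length, 50)
      D <- max(.resample(dist$meanDiameter, 1), 0.05)
      taper <- .resample(dist$taperSlope, 0)
      soamTarget <- max(.resample(dist$soam, 0), 0)
      step <- L / nseg
      ## per-step turn so the summed combined angles over path length L
      ## approximate the drawn SOAM; interior points number nseg - 2
      turn <- min(soamTarget * L / max(nseg - 2L, 1L), pi / 3)
      dir <- job$dir
      pos <- job$origin
      prev <- job$attach
      for (i in seq_len(nseg)) {
        if (i > 1L && turn > 0)
          dir <- .tilt(dir, turn, stats::runif(1, 0, 2 * pi))
        pos <- pos + dir * step
        s <- (i - 0.5) * step
        radius <- max(D + taper * (s - L / 2), 0.05) / 2
        prev <- addRow(3L, pos, radius, prev)
      }
      oNext <- min(o + 1L, model@maxOrder)
      if (stats::runif(1) < dist$branchProb) {
        psi <- stats::runif(1, 0, 2 * pi)
        for (k in 0:1) {
          a <- .resample(model@orders[[oNext]]$angle, pi / 4)
          stack[[length(stack) + 1L]] <-
            list(attach = prev, origin = pos,
                 dir = .tilt(dir, a, psi + k * pi), order = job$order + 1L)
        }
      }
    }
    if (truncated)
      warning("virtual-neuron growth truncated at the maxBranches cap (",
              config$maxBranches, ")")

    m <- do.call(rbind, rows)
    SWCReconstruction(
      data.frame(index = m[, 1L], flag = m[, 2L], x = m[, 3L], y = m[, 4L],
                 z = m[, 5L], radius = m[, 6L], parent = m[, 7L]),
      header = c("# morphotree virtual neuron",
                 sprintf("# grown from a %d-branch model, seed %d",
                         model@nBranches, config$seed)),
      sourceName = sprintf("virtual-neuron-seed%d", config$seed))
  })
})

#' Serialize or restore a morphometry model as JSON
#'
#' @param model a [MorphometryModel-class].
#' @param path file path of the JSON document.
#' @return \code{writeMorphometryModel()} returns \code{path} invisibly;
#'   \code{readMorphometryModel()} returns the restored model.
#' @export
writeMorphometryModel <- function(model, path) {
  payload <- list(maxOrder = model@maxOrder, nBranches = model@nBranches,
                  orders = model@orders)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeMorphometryModel
#' @export
readMorphometryModel <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(v) as.numeric(unlist(v, use.names = FALSE))
  orders <- lapply(payload$orders, function(el)
    list(length = num(el$length),
         taperSlope = num(el$taperSlope),
         meanDiameter = num(el$meanDiameter),
         soam = num(el$soam),
         angle = num(el$angle),
         branchProb = num(el$branchProb)))
  new("MorphometryModel", orders = orders,
      maxOrder = as.integer(payload$maxOrder),
      nBranches = as.integer(payload$nBranches))
}
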