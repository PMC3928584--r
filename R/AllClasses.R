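#' @import methods
NULL

## Required column layout of the record table backing a reconstruction.
## One row per traced point, mirroring the 7 SWC columns.
.SWC_COLUMNS <- c("index", "flag", "x", "y", "z", "radius", "parent")

## Conventional SWC structure-flag codes.
.SWC_FLAGS <- c(soma = 1L, axon = 2L, basal = 3L, apical = 4L)

#' SWCReconstruction: a parsed SWC digital reconstruction
#'
#' Holds the point table of a traced neuron (one row per point, seven SWC
#' fields), the raw \code{#} header comment lines, and the source name.
#' Coordinates and radii are in micrometres.  The root sentinel in the
#' \code{parent} column is \code{-1}.
#'
#' @slot records data.frame with columns \code{index}, \code{flag}, \code{x},
#'   \code{y}, \code{z}, \code{radius}, \code{parent}, in file order.
#' @slot header character vector of raw header lines (each starting with
#'   \code{#}), possibly empty.
#' @slot sourceName single string naming the origin (file path or label).
#'
#' @seealso [readSWC()], [writeSWC()], [validateReconstruction()]
#' @export
setClass("SWCReconstruction",
  slots = c(records = "data.frame", header = "character",
            sourceName = "character"),
  prototype = prototype(
    records = data.frame(index = integer(), flag = integer(),
                         x = numeric(), y = numeric(), z = numeric(),
                         radius = numeric(), parent = integer()),
    header = character(), sourceName = NA_character_))

setValidity("SWCReconstruction", function(object) {
  msg <- character()
  rec <- object@records
  if (!all(.SWC_COLUMNS %in% names(rec)))
    msg <- c(msg, paste("records must have columns:",
                        paste(.SWC_COLUMNS, collapse = ", ")))
  if (length(object@sourceName) != 1L)
    msg <- c(msg, "sourceName must be a single string")
  ## value-level consistency (radii, parent references, ...) is the job of
  ## validateReconstruction(), which reports findings as data
  if (all(.SWC_COLUMNS %in% names(rec)) && nrow(rec) > 0L &&
      anyNA(rec$index))
    msg <- c(msg, "point indices must not be missing")
  if (length(msg)) msg else TRUE
})

#' Branch: a maximal unbranched chain of traced segments
#'
#' A branch runs from a soma attachment point or bifurcation to the next
#' bifurcation, structure-flag change, or tip.  Its polyline starts at the
#' attachment point (shared with the parent branch) and all its segments
#' carry one structure flag.
#'
#' @slot firstName unique integer label, assigned depth-first in file order.
#' @slot fullName integer vector of ancestor first-names ending in the
#'   branch's own first-name (the genealogy); length = centrifugal order.
#' @slot flag SWC structure flag shared by all segments of the branch.
#' @slot points numeric matrix, one row per point (columns \code{x},
#'   \code{y}, \code{z}, \code{radius}); row 1 is the attachment point.
#' @slot pointIndices SWC indices of the records backing each point row.
#' @slot parentBranch first-name of the parent branch, or \code{NA} for a
#'   root branch.
#' @slot daughterBranches first-names of daughter branches (may be empty).
#' @slot strahlerOrder Strahler stream order (\code{NA} until assigned).
#' @slot centrifugalOrder number of branches from the soma to this branch,
#'   inclusive (\code{NA} until the genealogy is assigned).
#'
#' @seealso [identifyBranches()], [assignFullNames()], [strahlerOrders()]
#' @export
setClass("Branch",
  slots = c(firstName = "integer", fullName = "integer", flag = "integer",
            points = "matrix", pointIndices = "integer",
            parentBranch = "integer", daughterBranches = "integer",
            strahlerOrder = "integer", centrifugalOrder = "integer"),
  prototype = prototype(fullName = integer(), parentBranch = NA_integer_,
                        daughterBranches = integer(),
                        strahlerOrder = NA_integer_,
                        centrifugalOrder = NA_integer_))

setValidity("Branch", function(object) {
  msg <- character()
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 4L)
    msg <- c(msg, "points must be a numeric matrix with 4 columns (x,y,z,radius)")
  else {
    if (nrow(p) < 2L)
      msg <- c(msg, "a branch needs at least one segment (two points)")
    if (length(object@pointIndices) != nrow(p))
      msg <- c(msg, "pointIndices must parallel the point rows")
  }
  if (length(object@firstName) != 1L || is.na(object@firstName))
    msg <- c(msg, "firstName must be a single integer")
  if (length(object@fullName) &&
      object@fullName[length(object@fullName)] != object@firstName)
    msg <- c(msg, "fullName must end in the branch's own firstName")
  if (!is.na(object@centrifugalOrder) && length(object@fullName) &&
      object@centrifugalOrder != length(object@fullName))
    msg <- c(msg, "centrifugalOrder must equal the full-name length")
  if (!is.na(object@strahlerOrder) && object@strahlerOrder < 1L)
    msg <- c(msg, "strahlerOrder must be >= 1")
  if (length(msg)) msg else TRUE
})

#' BranchForest: all branches of one reconstruction
#'
#' The partition of a reconstruction's non-soma segments into branches,
#' keyed by first-name, together with the root branches (one per dendritic
#' or axonal tree) and the soma root point used for distance measurements.
#'
#' @slot branches list of [Branch-class] objects; element \code{i} has
#'   first-name \code{i}.
#' @slot roots integer first-names of the root branches.
#' @slot somaPoint numeric xyz of the reconstruction's root record.
#' @slot sourceName source label inherited from the reconstruction.
#'
#' @export
setClass("BranchForest",
  slots = c(branches = "list", roots = "integer", somaPoint = "numeric",
            sourceName = "character"),
  prototype = prototype(branches = list(), roots = integer(),
                        somaPoint = c(0, 0, 0), sourceName = NA_character_))

setValidity("BranchForest", function(object) {
  msg <- character()
  if (length(object@branches)) {
    fn <- vapply(object@branches, function(b) b@firstName, integer(1))
    if (!identical(fn, seq_along(object@branches)))
      msg <- c(msg, "branches must be listed in first-name order 1..N")
    for (r in object@roots)
      if (!is.na(object@branches[[r]]@parentBranch))
        msg <- c(msg, "root branches must have no parent")
  }
  if (length(object@somaPoint) != 3L)
    msg <- c(msg, "somaPoint must be xyz")
  if (length(msg)) msg else TRUE
})

#' MorphometryModel: empirical distributions for virtual-neuron growth
#'
#' Per-centrifugal-order empirical distributions of branch morphometrics,
#' fitted from one or more branch tables, that the stochastic generator
#' resamples.  Branching probability at order o is the observed fraction of
#' order-o branches that have daughters.
#'
#' @slot orders list, one element per centrifugal order, each a list with
#'   numeric vectors \code{length}, \code{taperSlope}, \code{meanDiameter},
#'   \code{soam}, \code{angle} and a scalar \code{branchProb}.
#' @slot maxOrder maximum centrifugal order observed.
#' @slot nBranches total number of branches the model was fitted on.
#'
#' @seealso [fitMorphometryModel()], [generateVirtualNeuron()]
#' @export
setClass("MorphometryModel",
  slots = c(orders = "list", maxOrder = "integer", nBranches = "integer"))

setValidity("MorphometryModel", function(object) {
  msg <- character()
  if (length(object@orders) != object@maxOrder)
    msg <- c(msg, "orders must have one element per centrifugal order")
  for (o in seq_along(object@orders)) {
    el <- object@orders[[o]]
    if (!length(el$length))
      msg <- c(msg, sprintf("no branch lengths observed at order %d", o))
    if (is.null(el$branchProb) || el$branchProb < 0 || el$branchProb > 1)
      msg <- c(msg, sprintf("branchProb at order %d must lie in [0,1]", o))
  }
  if (length(msg)) msg else TRUE
})

#' DistributionSummary: a Sturges-binned group histogram summary
#'
#' Per-cell histogram counts of one morphometric parameter on common bin
#' edges, with the across-cell mean and standard error of the mean per bin.
#'
#' @slot parameter name of the summarized branch-table column.
#' @slot breaks ordered bin edges (length = bins + 1); bins are left-closed,
#'   with the last bin closed on both sides.
#' @slot counts integer matrix, one row per cell, one column per bin.
#' @slot mean numeric per-bin mean count across cells.
#' @slot sem numeric per-bin standard error of the mean (\code{NA} for a
#'   single-cell group).
#' @slot nCells number of cells summarized.
#'
#' @seealso [groupDistribution()], [sturgesBreaks()]
#' @export
setClass("DistributionSummary",
  slots = c(parameter = "character", breaks = "numeric", counts = "matrix",
            mean = "numeric", sem = "numeric", nCells = "integer"))

setValidity("DistributionSummary", function(object) {
  msg <- character()
  nb <- length(object@breaks) - 1L
  if (nb < 1L || is.unsorted(object@breaks, strictly = TRUE))
    msg <- c(msg, "breaks must be strictly increasing with >= 2 edges")
  if (ncol(object@counts) != nb)
    msg <- c(msg, "counts must have one column per bin")
  if (nrow(object@counts) != object@nCells)
    msg <- c(msg, "counts must have one row per cell")
  if (length(object@mean) != nb || length(object@sem) != nb)
    msg <- c(msg, "mean and sem must have one value per bin")
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "SWCReconstruction", function(object) {
  rec <- object@records
  nseg <- sum(rec$parent != -1L)
  cat("SWCReconstruction:", object@sourceName, "\n")
  cat(sprintf("  %d points, %d segments, %d header line(s)\n",
              nrow(rec), nseg, length(object@header)))
  if (nrow(rec)) {
    tab <- table(factor(rec$flag))
    lab <- names(.SWC_FLAGS)[match(names(tab), .SWC_FLAGS)]
    lab[is.na(lab)] <- paste0("flag", names(tab)[is.na(lab)])
    cat("  points per structure:",
        paste(sprintf("%s=%d", lab, tab), collapse = ", "), "\n")
  }
  invisible(NULL)
})

setMethod("show", "Branch", function(object) {
  cat(sprintf("Branch %d (flag %d): %d segment(s)\n",
              object@firstName, object@flag, nrow(object@points) - 1L))
  if (length(object@fullName))
    cat("  full name:", paste(object@fullName, collapse = "-"), "\n")
  cat(sprintf("  parent: %s | daughters: %s | Strahler: %s\n",
              ifelse(is.na(object@parentBranch), "none", object@parentBranch),
              if (length(object@daughterBranches))
                paste(object@daughterBranches, collapse = ",") else "none",
              ifelse(is.na(object@strahlerOrder), "?", object@strahlerOrder)))
  invisible(NULL)
})

setMethod("show", "BranchForest", function(object) {
  cat("BranchForest:", object@sourceName, "\n")
  cat(sprintf("  %d branch(es) in %d tree(s)\n",
              length(object@branches), length(object@roots)))
  so <- vapply(object@branches, function(b) b@strahlerOrder, integer(1))
  if (length(so) && !anyNA(so))
    cat("  max Strahler order:", max(so), "\n")
  invisible(NULL)
})

setMethod("show", "MorphometryModel", function(object) {
  cat(sprintf("MorphometryModel: %d branches, max centrifugal order %d\n",
              object@nBranches, object@maxOrder))
  for (o in seq_along(object@orders))
    cat(sprintf("  order %d: n=%d, branching prob %.2f\n", o,
                length(object@orders[[o]]$length),
                object@orders[[o]]$branchProb))
  invisible(NULL)
})

setMethod("show", "DistributionSummary", function(object) {
  cat(sprintf("DistributionSummary of '%s': %d cells, %d bins\n",
              object@parameter, object@nCells, ncol(object@counts)))
  cat("  bin range:", format(min(object@breaks)), "to",
      format(max(object@breaks)), "\n")
  invisible(NULL)
})
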