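#' @include AllClasses.R
NULL

#' @rdname SWCReconstruction-accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname SWCReconstruction-accessors
#' @export
setGeneric("swcHeader", function(x) standardGeneric("swcHeader"))

#' @rdname SWCReconstruction-accessors
#' @export
setGeneric("sourceName", function(x) standardGeneric("sourceName"))

#' @rdname SWCReconstruction-accessors
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname SWCReconstruction-accessors
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))

#' @rdname writeSWC
#' @export
setGeneric("writeSWC", function(x, path, ...) standardGeneric("writeSWC"))

#' @rdname validateReconstruction
#' @export
setGeneric("validateReconstruction",
           function(x, ...) standardGeneric("validateReconstruction"))

#' @rdname identifyBranches
#' @export
setGeneric("identifyBranches", function(x, ...) standardGeneric("identifyBranches"))

#' @rdname assignFullNames
#' @export
setGeneric("assignFullNames", function(x) standardGeneric("assignFullNames"))

#' @rdname strahlerOrders
#' @export
setGeneric("strahlerOrders", function(x) standardGeneric("strahlerOrders"))

#' @rdname BranchForest-accessors
#' @export
setGeneric("branches", function(x) standardGeneric("branches"))

#' @rdname BranchForest-accessors
#' @export
setGeneric("getBranch", function(x, firstName) standardGeneric("getBranch"))

#' @rdname smoothReconstruction
#' @export
setGeneric("smoothReconstruction",
           function(x, ...) standardGeneric("smoothReconstruction"))

#' @rdname branchMetrics
#' @export
setGeneric("branchMetrics", function(x, ...) standardGeneric("branchMetrics"))

#' @rdname bifurcations
#' @export
setGeneric("bifurcations", function(x, ...) standardGeneric("bifurcations"))

#' @rdname verticalCompress
#' @export
setGeneric("verticalCompress", function(x, ...) standardGeneric("verticalCompress"))

#' @rdname generateVirtualNeuron
#' @export
setGeneric("generateVirtualNeuron",
           function(model, config, ...) standardGeneric("generateVirtualNeuron"))
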