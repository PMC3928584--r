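#' @include AllClasses.R AllGenerics.R swc-io.R
NULL

## Two connected segments belong to the same branch only if (i) the second's
## parent index equals the first's index, (ii) both share one structure
## flag, and (iii) no other segment shares that parent index.  A branch is a
## maximal chain under these rules; soma (flag 1) segments never belong to
## branches, so trees hanging off the soma root at their own trees.

#' Partition a reconstruction's segments into branches
#'
#' Walks the traced tree and groups segments into maximal unbranched chains:
#' a branch ends exactly where two or more segments share a parent
#' (a bifurcation), where the structure flag changes, or at a tip.  Soma
#' (flag 1) segments are excluded; branches attached to a soma point are
#' roots of their tree.  First-names are assigned depth-first in file order,
#' so a parent branch always carries a smaller first-name than its
#' daughters.
#'
#' @param x a validated [SWCReconstruction-class].  Reconstructions with
#'   error-level validation findings are refused.
#' @param ... unused.
#' @return A [BranchForest-class]; genealogy (full names) and Strahler
#'   orders are unset until [assignFullNames()] and [strahlerOrders()] run.
#' @seealso [branchForest()] for the full pipeline.
#' @rdname identifyBranches
#' @export
setMethod("identifyBranches", "SWCReconstruction", function(x, ...) {
  findings <- validateReconstruction(x)
  if (any(findings$severity == "error"))
    stop("reconstruction has validation findings; fix them before branch ",
         "identification:\n  ",
         paste(findings$message[findings$severity == "error"],
               collapse = "\n  "))
  df <- x@records
  n <- nrow(df)
  rowOf <- integer(max(df$index))
  rowOf[df$index] <- seq_len(n)
  parentRow <- ifelse(df$parent == -1L, NA_integer_, rowOf[pmax(df$parent, 1L)])
  childrenOf <- vector("list", n)
  for (i in seq_len(n))
    if (!is.na(parentRow[i]))
      childrenOf[[parentRow[i]]] <- c(childrenOf[[parentRow[i]]], i)

  ## branch-start children reachable from a point row, skipping over any
  ## soma-flag (flag 1) sub-chains
  startCandidates <- function(prow) {
    out <- integer()
    for (ch in childrenOf[[prow]]) {
      if (df$flag[ch] == .SWC_FLAGS[["soma"]])
        out <- c(out, startCandidates(ch))
      else out <- c(out, ch)
    }
    out
  }

  rootRows <- which(df$parent == -1L)
  somaPoint <- unlist(df[rootRows[1L], c("x", "y", "z")], use.names = FALSE)

  branchesOut <- list()
  parentName <- integer()
  ## stack entries: c(startChildRow, parentBranchName); pushed in reverse so
  ## traversal is depth-first in file order
  stack <- list()
  push <- function(rows, pname)
    for (ch in rev(rows)) stack[[length(stack) + 1L]] <<- c(ch, pname)
  for (r in rev(rootRows))
    push(startCandidates(r), NA_integer_)

  while (length(stack)) {
    ent <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    ch <- ent[1L]; pname <- ent[2L]
    rows <- c(parentRow[ch], ch)
    cur <- ch
    repeat {
      kids <- childrenOf[[cur]]
      if (length(kids) == 1L && df$flag[kids] == df$flag[cur]) {
        cur <- kids
        rows <- c(rows, cur)
      } else break
    }
    name <- length(branchesOut) + 1L
    pts <- as.matrix(df[rows, c("x", "y", "z", "radius")])
    dimnames(pts) <- list(NULL, c("x", "y", "z", "radius"))
    branchesOut[[name]] <- new("Branch", firstName = name,
                               flag = df$flag[ch], points = pts,
                               pointIndices = df$index[rows],
                               parentBranch = if (is.na(pname)) NA_integer_
                                              else as.integer(pname))
    parentName[name] <- pname
    push(startCandidates(cur), name)
  }

  ## daughter lists from the parent pointers, in first-name order
  for (b in seq_along(branchesOut)) {
    p <- parentName[b]
    if (!is.na(p))
      branchesOut[[p]]@daughterBranches <-
        c(branchesOut[[p]]@daughterBranches, b)
  }
  new("BranchForest", branches = branchesOut,
      roots = which(is.na(parentName)), somaPoint = somaPoint,
      sourceName = x@sourceName)
})

#' Accessors for BranchForest objects
#'
#' @param x a [BranchForest-class].
#' @param firstName integer first-name of a branch.
#' @return \code{branches()} the list of [Branch-class] objects;
#'   \code{getBranch()} one branch by first-name.
#' @name BranchForest-accessors
NULL

#' @rdname BranchForest-accessors
#' @export
setMethod("branches", "BranchForest", function(x) x@branches)

#' @rdname BranchForest-accessors
#' @export
setMethod("getBranch", "BranchForest",
          function(x, firstName) x@branches[[firstName]])

#' Assign full names (branch genealogy) and centrifugal orders
#'
#' The full name of a branch is its parent's full name followed by its own
#' first-name, routed back to the soma; root branches have a one-element
#' full name.  The centrifugal order is the full-name length (number of
#' ancestors + 1), which equals the branch path length in branches from the
#' soma.
#'
#' @param x a [BranchForest-class] from [identifyBranches()].
#' @return The forest with \code{fullName} and \code{centrifugalOrder} set
#'   on every branch.
#' @rdname assignFullNames
#' @export
setMethod("assignFullNames", "BranchForest", function(x) {
  br <- x@branches
  n <- length(br)
  done <- logical(n)
  fulls <- vector("list", n)
  remaining <- seq_len(n)
  while (length(remaining)) {
    progressed <- FALSE
    keep <- integer()
    for (b in remaining) {
      p <- br[[b]]@parentBranch
      if (is.na(p)) {
        fulls[[b]] <- b; done[b] <- TRUE; progressed <- TRUE
      } else if (done[p]) {
        fulls[[b]] <- c(fulls[[p]], b); done[b] <- TRUE; progressed <- TRUE
      } else keep <- c(keep, b)
    }
    if (!progressed)
      stop("cycle detected in branch parent pointers; corrupt genealogy")
    remaining <- keep
  }
  for (b in seq_len(n)) {
    br[[b]]@fullName <- as.integer(fulls[[b]])
    br[[b]]@centrifugalOrder <- length(fulls[[b]])
  }
  x@branches <- br
  x
})

#' Assign Strahler stream orders to all branches
#'
#' Terminal branches get order 1.  A parent whose daughters reach maximum
#' order m with two or more daughters at that order gets m + 1; otherwise it
#' continues the largest daughter order.  The rule is purely topological and
#' generalizes to any out-degree.
#'
#' @param x a [BranchForest-class].
#' @return The forest with \code{strahlerOrder} set on every branch.
#' @rdname strahlerOrders
#' @export
setMethod("strahlerOrders", "BranchForest", function(x) {
  br <- x@branches
  n <- length(br)
  ord <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  while (length(remaining)) {
    progressed <- FALSE
    keep <- integer()
    for (b in remaining) {
      ds <- br[[b]]@daughterBranches
      if (!length(ds)) {
        ord[b] <- 1L; progressed <- TRUE
      } else if (!anyNA(ord[ds])) {
        m <- max(ord[ds])
        ord[b] <- if (sum(ord[ds] == m) >= 2L) m + 1L else m
        progressed <- TRUE
      } else keep <- c(keep, b)
    }
    if (!progressed)
      stop("cycle detected in branch daughter pointers")
    remaining <- keep
  }
  for (b in seq_len(n)) br[[b]]@strahlerOrder <- ord[b]
  x@branches <- br
  x
})

#' Build the fully annotated branch forest of a reconstruction
#'
#' Convenience pipeline: [identifyBranches()], then [assignFullNames()],
#' then [strahlerOrders()].
#'
#' @param x an [SWCReconstruction-class].
#' @return A fully annotated [BranchForest-class].
#' @examples
#' fx <- makeFixture(fixtureSpec("ytree"))
#' forest <- branchForest(fx)
#' length(branches(forest))  # 3
#' @export
branchForest <- function(x) {
  strahlerOrders(assignFullNames(identifyBranches(x)))
}
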