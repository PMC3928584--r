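# Shared scaffolding: ad-hoc Branch construction, SWC text fixtures, and an
# independent brute-force oracle for branch decomposition / Strahler orders
# that walks the record adjacency directly (no use of the package's
# traversal machinery).

makeBranch <- function(x, y, z, radius = rep(0.5, length(x))) {
  new("Branch", firstName = 1L, flag = 3L,
      points = cbind(x = x, y = y, z = z, radius = radius),
      pointIndices = seq_along(x))
}

writeSWCText <- function(lines) {
  tf <- tempfile(fileext = ".swc")
  writeLines(lines, tf)
  tf
}

# minimal 3-point chain: soma -> two basal points
chainLines <- c("1 1 0 0 0 1 -1", "2 3 1 0 0 0.5 1", "3 3 2 0 0 0.5 2")

# ---- brute-force topology oracle ----------------------------------------

# Partition the segment-child records into branches by walking each record
# up to the top of its unbranched same-flag chain; returns a named list
# keyed by canonical record-set strings.
oracleBranches <- function(rec) {
  df <- records(rec)
  rowOf <- integer(max(df$index)); rowOf[df$index] <- seq_len(nrow(df))
  nKids <- integer(nrow(df))
  for (i in seq_len(nrow(df)))
    if (df$parent[i] != -1L) {
      p <- rowOf[df$parent[i]]
      nKids[p] <- nKids[p] + 1L
    }
  isSeg <- df$parent != -1L & df$flag != 1L
  top <- function(i) {
    repeat {
      p <- rowOf[df$parent[i]]
      if (df$parent[p] == -1L || df$flag[p] == 1L ||
          df$flag[p] != df$flag[i] || nKids[p] != 1L)
        return(i)
      i <- p
    }
  }
  groups <- split(df$index[isSeg],
                  vapply(which(isSeg), function(i) df$index[top(i)],
                         integer(1)))
  out <- lapply(groups, sort)
  names(out) <- vapply(out, paste, character(1), collapse = ",")
  out
}

# Strahler order per oracle branch, keyed like oracleBranches(); computed
# recursively on the branch-level tree derived from the partition.
oracleStrahler <- function(rec) {
  br <- oracleBranches(rec)
  df <- records(rec)
  rowOf <- integer(max(df$index)); rowOf[df$index] <- seq_len(nrow(df))
  branchOf <- integer(max(df$index))
  for (k in seq_along(br)) branchOf[br[[k]]] <- k
  parentOf <- vapply(seq_along(br), function(k) {
    # the chain's top record is the one whose parent lies outside the set
    for (ix in br[[k]]) {
      p <- df$parent[rowOf[ix]]
      if (!(p %in% br[[k]])) {
        if (p != -1L && p <= length(branchOf) && branchOf[p] > 0L)
          return(branchOf[p])
        return(NA_integer_)
      }
    }
    NA_integer_
  }, integer(1))
  kids <- lapply(seq_along(br), function(k) which(parentOf == k))
  ord <- rep(NA_integer_, length(br))
  assign_ <- function(k) {
    if (!is.na(ord[k])) return(ord[k])
    if (!length(kids[[k]])) { ord[k] <<- 1L; return(1L) }
    ko <- vapply(kids[[k]], assign_, integer(1))
    m <- max(ko)
    ord[k] <<- if (sum(ko == m) >= 2L) m + 1L else m
    ord[k]
  }
  for (k in seq_along(br)) assign_(k)
  stats::setNames(ord, names(br))
}

# canonical record-set keys of a package-produced forest (child records
# only; the attachment point belongs to the parent branch)
forestKeys <- function(forest) {
  vapply(branches(forest), function(b)
    paste(sort(b@pointIndices[-1L]), collapse = ","), character(1))
}

# two-sample Kolmogorov-Smirnov statistic, written directly from the ECDF
# definition (kept independent of stats::ks.test)
ksStat <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(p) mean(a <= p), numeric(1))
  Fb <- vapply(pts, function(p) mean(b <= p), numeric(1))
  max(abs(Fa - Fb))
}

ksCrit01 <- function(n, m) 1.628 * sqrt((n + m) / (n * m))
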