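#' @include AllClasses.R AllGenerics.R
NULL

#' Construct an SWCReconstruction from a record table
#'
#' Low-level constructor used by the reader, the fixture factory and the
#' virtual-neuron generator.  Any negative parent index is normalized to the
#' standard root sentinel \code{-1}.
#'
#' @param records data.frame with columns \code{index}, \code{flag},
#'   \code{x}, \code{y}, \code{z}, \code{radius}, \code{parent}.
#' @param header character vector of raw \code{#} header lines.
#' @param sourceName label for the reconstruction.
#' @return An [SWCReconstruction-class] object.
#' @export
SWCReconstruction <- function(records,
                              header = character(),
                              sourceName = NA_character_) {
  records <- as.data.frame(records)[.SWC_COLUMNS]
  records$index <- as.integer(records$index)
  records$flag <- as.integer(records$flag)
  records$parent <- as.integer(records$parent)
  records$parent[records$parent < 0L] <- -1L
  for (col in c("x", "y", "z", "radius"))
    records[[col]] <- as.numeric(records[[col]])
  rownames(records) <- NULL
  new("SWCReconstruction", records = records, header = as.character(header),
      sourceName = as.character(sourceName))
}

#' Accessors for SWCReconstruction objects
#'
#' @param x an [SWCReconstruction-class].
#' @return \code{records()} the point table; \code{swcHeader()} the raw
#'   header lines; \code{sourceName()} the source label; \code{nPoints()}
#'   the number of traced points; \code{nSegments()} the number of segments
#'   (points whose parent is not the root sentinel; for a single-root file
#'   this is \code{nPoints - 1}).
#' @name SWCReconstruction-accessors
NULL

#' @rdname SWCReconstruction-accessors
#' @export
setMethod("records", "SWCReconstruction", function(x) x@records)

#' @rdname SWCReconstruction-accessors
#' @export
setMethod("swcHeader", "SWCReconstruction", function(x) x@header)

#' @rdname SWCReconstruction-accessors
#' @export
setMethod("sourceName", "SWCReconstruction", function(x) x@sourceName)

#' @rdname SWCReconstruction-accessors
#' @export
setMethod("nPoints", "SWCReconstruction", function(x) nrow(x@records))

#' @rdname SWCReconstruction-accessors
#' @export
setMethod("nSegments", "SWCReconstruction",
          function(x) sum(x@records$parent != -1L))

#' Read an SWC reconstruction file
#'
#' Parses the standard SWC plain-text format: \code{#}-prefixed header
#' comment lines followed by one record per line with seven
#' whitespace-separated fields (index, structure flag, x, y, z, radius,
#' parent index; micrometres).  Header lines are kept verbatim; records are
#' kept in file order and indices are not renumbered.
#'
#' @param path path to the \code{.swc} file.
#' @param strict if \code{TRUE} (default), run [validateReconstruction()]
#'   and raise an error when any error-level finding is present; warnings
#'   (for example unknown structure flags) are reported as R warnings.
#' @return An [SWCReconstruction-class].
#' @examples
#' tf <- tempfile(fileext = ".swc")
#' writeLines(c("# minimal chain", "1 1 0 0 0 1 -1",
#'              "2 3 1 0 0 0.5 1", "3 3 2 0 0 0.5 2"), tf)
#' rec <- readSWC(tf)
#' nSegments(rec)  # 2
#' @export
readSWC <- function(path, strict = TRUE) {
  if (!file.exists(path))
    stop("SWC file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  isHeader <- grepl("^\\s*#", lines)
  isBlank <- grepl("^\\s*$", lines)
  header <- lines[isHeader]
  dataIdx <- which(!isHeader & !isBlank)
  if (!length(dataIdx))
    stop("no data records in SWC file: ", path)
  toks <- strsplit(trimws(lines[dataIdx]), "\\s+")
  nTok <- lengths(toks)
  if (any(nTok != 7L))
    stop(sprintf("malformed SWC record at line %d of %s: expected 7 fields, got %d",
                 dataIdx[which(nTok != 7L)[1L]], path, nTok[nTok != 7L][1L]))
  m <- matrix(suppressWarnings(as.numeric(unlist(toks))),
              ncol = 7L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(m, 1L, anyNA))[1L]
    stop(sprintf("non-numeric field in SWC record at line %d of %s",
                 dataIdx[bad], path))
  }
  rec <- SWCReconstruction(
    data.frame(index = m[, 1L], flag = m[, 2L], x = m[, 3L], y = m[, 4L],
               z = m[, 5L], radius = m[, 6L], parent = m[, 7L]),
    header = header, sourceName = path)
  if (strict) {
    f <- validateReconstruction(rec)
    if (any(f$severity == "warning"))
      warning("SWC validation warnings in ", path, ":\n  ",
              paste(f$message[f$severity == "warning"], collapse = "\n  "))
    if (any(f$severity == "error"))
      stop("SWC validation failed for ", path, ":\n  ",
           paste(f$message[f$severity == "error"], collapse = "\n  "))
  }
  rec
}

#' Validate the internal consistency of a reconstruction
#'
#' Checks the invariants a well-formed reconstruction must satisfy before
#' morphometric analysis: unique point indices, parent references that point
#' to earlier records (or the root sentinel), no zero-length segments
#' (child coordinates equal to the parent's), non-negative radii, and known
#' structure flags.  Findings are returned as data, never raised.
#'
#' @param x an [SWCReconstruction-class].
#' @return data.frame with columns \code{code}, \code{record} (the SWC index
#'   of the offending record), \code{severity} (\code{"error"} or
#'   \code{"warning"}) and \code{message}.  Zero rows mean the
#'   reconstruction is internally consistent; unknown structure flags are
#'   the only warning-level finding.
#' @rdname validateReconstruction
#' @export
setMethod("validateReconstruction", "SWCReconstruction", function(x, ...) {
  rec <- x@records
  out <- list()
  add <- function(code, record, severity, message)
    out[[length(out) + 1L]] <<- data.frame(code = code, record = record,
                                           severity = severity,
                                           message = message)
  dup <- rec$index[duplicated(rec$index)]
  for (d in unique(dup))
    add("duplicate_index", d, "error",
        sprintf("index %d appears more than once", d))
  if (!any(rec$parent == -1L))
    add("no_root", NA_integer_, "error",
        "no root record (parent index -1) present")
  seen <- rep(FALSE, max(rec$index, 0L))
  for (i in seq_len(nrow(rec))) {
    p <- rec$parent[i]
    if (p != -1L) {
      known <- p >= 1L && p <= length(seen) && seen[p]
      if (!known) {
        code <- if (p %in% rec$index) "forward_parent" else "dangling_parent"
        add(code, rec$index[i], "error",
            sprintf("record %d refers to parent %d which does not appear earlier in the file",
                    rec$index[i], p))
      } else {
        j <- match(p, rec$index)
        if (rec$x[i] == rec$x[j] && rec$y[i] == rec$y[j] &&
            rec$z[i] == rec$z[j])
          add("zero_length_segment", rec$index[i], "error",
              sprintf("record %d coincides with its parent %d (zero-length segment)",
                      rec$index[i], p))
      }
    }
    if (rec$index[i] >= 1L && rec$index[i] <= length(seen))
      seen[rec$index[i]] <- TRUE
  }
  neg <- which(rec$radius < 0)
  for (i in neg)
    add("negative_radius", rec$index[i], "error",
        sprintf("record %d has negative radius", rec$index[i]))
  unk <- which(!(rec$flag %in% 0:7))
  for (i in unk)
    add("unknown_flag", rec$index[i], "warning",
        sprintf("record %d has unconventional structure flag %d",
                rec$index[i], rec$flag[i]))
  if (length(out)) do.call(rbind, out)
  else data.frame(code = character(), record = integer(),
                  severity = character(), message = character())
})

#' Write a reconstruction to an SWC file
#'
#' Emits the stored header lines followed by one record per line with seven
#' whitespace-separated fields, at 6 significant digits for the numeric
#' columns.  Reading the file back reproduces the records at that precision.
#'
#' @param x an [SWCReconstruction-class].
#' @param path output file path.
#' @param ... unused.
#' @return \code{path}, invisibly.
#' @rdname writeSWC
#' @export
setMethod("writeSWC", "SWCReconstruction", function(x, path, ...) {
  rec <- x@records
  fmt <- function(v) formatC(v, format = "g", digits = 6L, width = 1L)
  lines <- c(x@header,
             paste(rec$index, rec$flag, fmt(rec$x), fmt(rec$y), fmt(rec$z),
                   fmt(rec$radius), rec$parent))
  writeLines(lines, path)
  invisible(path)
})

#' Renumber records to contiguous 1..n indices
#'
#' Archives use arbitrary positive indices; the reader preserves them.  This
#' rewrites indices (and parent references) to the contiguous range
#' \code{1..n} in file order, which the virtual-neuron generator uses before
#' emitting SWC output.
#'
#' @param x an [SWCReconstruction-class].
#' @return A renumbered [SWCReconstruction-class].
#' @export
renumberReconstruction <- function(x) {
  rec <- x@records
  newIdx <- seq_len(nrow(rec))
  map <- integer(max(rec$index, 0L))
  map[rec$index] <- newIdx
  parent <- ifelse(rec$parent == -1L, -1L, map[pmax(rec$parent, 1L)])
  parent[rec$parent == -1L] <- -1L
  rec$index <- newIdx
  rec$parent <- as.integer(parent)
  SWCReconstruction(rec, header = x@header, sourceName = x@sourceName)
}
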