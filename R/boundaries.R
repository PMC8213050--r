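#' Boundary set container
#'
#' Holds per-column row positions (0-based, possibly fractional, `NA` =
#' missing) for the five retinal boundaries, ordered inner to outer:
#' ILM, NFL/GCL, IPL/INL, ISOS, RPE/CH.
#'
#' @param rows Named list of numeric vectors (one per boundary, names
#'   `ILM`, `NFL_GCL`, `IPL_INL`, `ISOS`, `RPE_CH`), each of length equal to
#'   the image width.
#' @param provenance Named character vector, one of `"auto"` or `"corrected"`
#'   per boundary.
#' @param max_jump Continuity bound: maximum allowed per-column row change.
#' @return An object of class `boundary_set`.
#' @export
boundary_set <- function(rows, provenance = NULL, max_jump = 3) {
  if (!all(BOUNDARY_NAMES %in% names(rows)))
    stop_retfreq("`rows` must contain all of: ",
                 paste(BOUNDARY_NAMES, collapse = ", "))
  rows <- rows[BOUNDARY_NAMES]
  w <- unique(vapply(rows, length, 1L))
  if (length(w) != 1)
    stop_retfreq("all boundary vectors must have the same length")
  if (is.null(provenance))
    provenance <- setNames(rep("auto", 5L), BOUNDARY_NAMES)
  bs <- structure(
    list(rows = rows, provenance = provenance, width = w, max_jump = max_jump),
    class = "boundary_set")
  validate_boundaries(bs)
  bs
}

#' Validate boundary ordering and continuity
#'
#' Checks that, at every column where all five boundaries are present, the
#' rows are strictly increasing inner to outer, and that each boundary moves
#' by at most `max_jump` pixels between adjacent columns.
#'
#' @param bs A [boundary_set].
#' @param check_continuity Also enforce the per-column jump bound.
#' @return `bs`, invisibly; errors name the first offending column.
#' @export
validate_boundaries <- function(bs, check_continuity = TRUE) {
  m <- do.call(rbind, bs$rows)
  complete <- colSums(is.na(m)) == 0
  if (any(complete)) {
    ord <- apply(m[, complete, drop = FALSE], 2, function(v) all(diff(v) > 0))
    if (!all(ord)) {
      bad <- which(complete)[which(!ord)[1]]
      stop_retfreq("boundary ordering violated at column ", bad - 1L)
    }
  }
  if (check_continuity && is.finite(bs$max_jump)) {
    for (nm in BOUNDARY_NAMES) {
      v <- bs$rows[[nm]]
      d <- abs(diff(v))
      bad <- which(d > bs$max_jump + 1e-9 & !is.na(d))
      if (length(bad))
        stop_retfreq("continuity violated for ", nm, " at column ", bad[1] - 1L)
    }
  }
  invisible(bs)
}

#' Apply programmatic corrections to a boundary set
#'
#' Stand-in for manual review of automated segmentation: replaces spans of a
#' boundary with supplied rows and flags that boundary as corrected. Edits
#' that violate the strict inner-to-outer ordering against the untouched
#' boundaries are rejected, naming the first offending column.
#'
#' @param bs A [boundary_set].
#' @param edits List of edits; each edit is a list with elements `boundary`
#'   (name), `cols` (0-based column indices) and `rows` (replacement row
#'   values, same length as `cols`).
#' @return The corrected [boundary_set].
#' @examples
#' bs <- boundary_set(list(ILM = rep(40, 100), NFL_GCL = rep(60, 100),
#'                         IPL_INL = rep(90, 100), ISOS = rep(140, 100),
#'                         RPE_CH = rep(165, 100)), max_jump = Inf)
#' bs2 <- apply_corrections(bs, list(list(boundary = "ISOS",
#'                                        cols = 10:19, rows = rep(142, 10))))
#' bs2$provenance[["ISOS"]]
#' @export
apply_corrections <- function(bs, edits = list()) {
  stopifnot(inherits(bs, "boundary_set"))
  if (!length(edits)) return(bs)
  rows <- bs$rows
  prov <- bs$provenance
  for (ed in edits) {
    nm <- ed$boundary
    if (!nm %in% BOUNDARY_NAMES) stop_retfreq("unknown boundary: ", nm)
    cols <- as.integer(ed$cols)
    if (any(cols < 0 | cols >= bs$width))
      stop_retfreq("edit columns outside image for ", nm)
    if (length(ed$rows) != length(cols))
      stop_retfreq("`rows` and `cols` must have equal length")
    rows[[nm]][cols + 1L] <- ed$rows
    prov[[nm]] <- "corrected"
  }
  # re-validate ordering; report the first offending column
  m <- do.call(rbind, rows)
  complete <- colSums(is.na(m)) == 0
  ord <- rep(TRUE, ncol(m))
  ord[complete] <- apply(m[, complete, drop = FALSE], 2,
                         function(v) all(diff(v) > 0))
  if (!all(ord))
    stop_retfreq("corrected boundaries violate ordering at column ",
                 which(!ord)[1] - 1L)
  out <- bs
  out$rows <- rows
  out$provenance <- prov
  out
}

#' @export
print.boundary_set <- function(x, ...) {
  miss <- vapply(x$rows, function(v) sum(is.na(v)), 1L)
  cat(sprintf("<boundary_set> width %d, missing per boundary: %s\n",
              x$width, paste(sprintf("%s=%d", names(miss), miss),
                             collapse = " ")))
  invisible(x)
}

#' Boundary set as a long data frame
#'
#' @param x A [boundary_set].
#' @param ... Unused.
#' @return Data frame with columns `column` (0-based), `boundary`, `row`,
#'   `provenance`.
#' @export
as.data.frame.boundary_set <- function(x, ...) {
  do.call(rbind, lapply(BOUNDARY_NAMES, function(nm) {
    data.frame(column = seq_len(x$width) - 1L, boundary = nm,
               row = x$rows[[nm]], provenance = x$provenance[[nm]])
  }))
}
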