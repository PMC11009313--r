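#' Coordinate-convention utilities
#'
#' All external formats the package touches use different coordinate
#' conventions: SAM and GTF are 1-based inclusive, BED is 0-based half-open,
#' and internal crosslink-tag positions are 0-based nucleotide indices.
#' Every conversion goes through these helpers so the off-by-one logic lives
#' in exactly one place.
#'
#' @param pos1,start1,end1 1-based (inclusive) positions.
#' @param pos0,start0,end0 0-based positions; intervals are half-open.
#' @return Converted positions or a list with `start`/`end` for intervals.
#' @name coords
NULL

#' @rdname coords
#' @export
pos_to0 <- function(pos1) {
  stopifnot(all(pos1 >= 1L))
  as.integer(pos1) - 1L
}

#' @rdname coords
#' @export
pos_to1 <- function(pos0) {
  stopifnot(all(pos0 >= 0L))
  as.integer(pos0) + 1L
}

#' @rdname coords
#' @export
interval_to0 <- function(start1, end1) {
  stopifnot(all(start1 >= 1L), all(end1 >= start1))
  list(start = as.integer(start1) - 1L, end = as.integer(end1))
}

#' @rdname coords
#' @export
interval_to1 <- function(start0, end0) {
  stopifnot(all(start0 >= 0L), all(end0 > start0))
  list(start = as.integer(start0) + 1L, end = as.integer(end0))
}
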