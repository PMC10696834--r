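# Centralized coordinate conventions.
#
# All user-facing intervals in this package are 1-based inclusive
# ("Chr12B:1-172535" style). Internal arithmetic that benefits from
# half-open intervals converts through these two helpers and nowhere else.

#' Convert a 1-based inclusive interval to 0-based half-open
#'
#' @param start,end 1-based inclusive coordinates.
#' @return A list with elements `start` and `end` (0-based half-open).
#' @keywords internal
to_halfopen <- function(start, end) {
  stopifnot(all(start >= 1), all(end >= start))
  list(start = start - 1L, end = end)
}

#' Convert a 0-based half-open interval to 1-based inclusive
#'
#' @param start,end 0-based half-open coordinates.
#' @return A list with elements `start` and `end` (1-based inclusive).
#' @keywords internal
from_halfopen <- function(start, end) {
  stopifnot(all(start >= 0), all(end > start))
  list(start = start + 1L, end = end)
}

#' Length of a 1-based inclusive interval
#'
#' @param start,end 1-based inclusive coordinates.
#' @return Integer width `end - start + 1`.
#' @export
interval_len <- function(start, end) end - start + 1

#' Gap between two 1-based inclusive intervals
#'
#' Number of bases strictly between `[.., b1]` and `[a2, ..]` (adjacent
#' intervals have gap 0).
#'
#' @param b1 End of the upstream interval.
#' @param a2 Start of the downstream interval.
#' @return Integer gap width.
#' @export
interval_gap <- function(b1, a2) a2 - b1 - 1
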