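# Depth-based copy-number analysis: normalize window depths against a
# single-copy baseline, call discrete half-grid copy states, infer
# two-state karyotype-mixture fractions for non-integer depths, call
# whole-chromosome gains and losses, and detect loss-of-heterozygosity runs.

#' Normalize window depths to copy ratios
#'
#' Divides each window's depth by the median depth of baseline windows
#' (core, single-copy regions; accessory and known-CNV regions should be
#' excluded from the baseline so they cannot contaminate the median).
#' Optionally renormalizes against a control isolate's ratios at the same
#' windows.
#'
#' @param depth Data frame with `chrom`, `window_start`, `window_end`,
#'   `depth`.
#' @param baseline_regions Data frame `chrom`, `start`, `end` of baseline
#'   regions; must contain at least `min_baseline_windows` windows.
#' @param control Optional normalized ratio data frame of a control isolate
#'   (same windows, column `ratio`).
#' @param min_baseline_windows Minimum baseline windows (default 50).
#' @return The input with a `ratio` column (1.0 = single copy).
#' @export
normalize_depth <- function(depth, baseline_regions, control = NULL,
                            min_baseline_windows = 50) {
  mid <- floor((depth$window_start + depth$window_end) / 2)
  in_base <- rep(FALSE, nrow(depth))
  for (i in seq_len(nrow(baseline_regions))) {
    r <- baseline_regions[i, ]
    in_base <- in_base | (depth$chrom == r$chrom & mid >= r$start & mid <= r$end)
  }
  if (sum(in_base) < min_baseline_windows) {
    stop("need at least ", min_baseline_windows, " baseline windows, got ",
         sum(in_base))
  }
  med <- stats::median(depth$depth[in_base])
  if (med <= 0) stop("zero baseline median depth")
  out <- depth
  out$ratio <- depth$depth / med
  if (!is.null(control)) {
    key <- paste(depth$chrom, depth$window_start)
    ckey <- paste(control$chrom, control$window_start)
    cr <- control$ratio[match(key, ckey)]
    out$ratio <- ifelse(!is.na(cr) & cr > 0, out$ratio / cr, out$ratio)
  }
  out
}

half_grid_state <- function(x) round(x * 2) / 2

#' Call the copy state of a region from its window ratios
#'
#' Computes a 10%-trimmed mean of the window ratios and snaps it to the
#' nearest half-grid state (0, 0.5, 1, 1.5, 2, ...) when within
#' `grid_tolerance`. Otherwise the region is routed to a two-state karyotype
#' mixture between the bracketing integer states. A half-grid call k + 0.5
#' also reports its mixture reading (fraction 0.5 between k and k + 1),
#' since true half-dosage and a balanced mixture are indistinguishable from
#' mean depth alone.
#'
#' @param ratios Numeric window ratios of one region (>= 3 windows).
#' @param grid_tolerance Maximum distance to a half-grid value (default
#'   0.1).
#' @return List of class `copy_call` with `mean_ratio`, `state` (half-grid
#'   value, or `NA` for mixture routing), `mixture` (list with `low`,
#'   `high`, `fraction`, or `NULL`).
#' @export
call_region_state <- function(ratios, grid_tolerance = 0.1) {
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) < 3) stop("need at least 3 windows")
  m <- mean(ratios, trim = 0.1)
  grid <- half_grid_state(m)
  call <- list(mean_ratio = m)
  if (abs(m - grid) <= grid_tolerance) {
    call$state <- grid
    call$mixture <- if (grid %% 1 == 0.5) {
      list(low = floor(grid), high = ceiling(grid), fraction = 0.5)
    } else NULL
  } else {
    lo <- floor(m); hi <- ceiling(m)
    call$state <- NA_real_
    call$mixture <- list(low = lo, high = hi,
                         fraction = infer_mixture_fraction(m, lo, hi))
  }
  structure(call, class = "copy_call")
}

#' Invert the two-state karyotype-mixture model
#'
#' If a fraction `f` of cells carries `high_state` copies and `1 - f`
#' carries `low_state`, the expected depth ratio is
#' `low + f * (high - low)`; this solves for `f`.
#'
#' @param ratio Observed mean copy ratio; must lie in
#'   `[low_state, high_state]`.
#' @param low_state,high_state Integer copy numbers, `low < high`.
#' @return Fraction of cells at `high_state`.
#' @export
infer_mixture_fraction <- function(ratio, low_state, high_state) {
  if (low_state >= high_state) stop("low_state must be < high_state")
  if (ratio < low_state || ratio > high_state) {
    stop("ratio ", ratio, " lies outside [", low_state, ", ", high_state,
         "]; pick bracketing states")
  }
  (ratio - low_state) / (high_state - low_state)
}

#' Call whole-chromosome gains and losses
#'
#' A chromosome is called as a whole-chromosome aneuploidy when its region
#' state differs from the expected copy number and at least
#' `min_consistent` of its windows individually round to the called state.
#'
#' @param ratio_windows Data frame with `chrom` and `ratio` (all windows of
#'   all chromosomes to assess).
#' @param expected Expected copy number (default 1, haploid).
#' @param grid_tolerance Passed to [call_region_state()].
#' @param min_consistent Minimum fraction of windows consistent with the
#'   called state (default 0.9).
#' @return Data frame `chrom`, `state`, `mean_ratio`, `consistency`,
#'   `change` (`"gain"`/`"loss"`), one row per aneuploid chromosome. A
#'   window is consistent when its ratio lies strictly closer to the called
#'   state than to the expected copy number.
#' @export
call_whole_chromosome_aneuploidy <- function(ratio_windows, expected = 1,
                                             grid_tolerance = 0.1,
                                             min_consistent = 0.9) {
  out <- list()
  for (ch in unique(ratio_windows$chrom)) {
    r <- ratio_windows$ratio[ratio_windows$chrom == ch]
    cc <- call_region_state(r, grid_tolerance)
    st <- cc$state
    if (is.na(st) || st == expected) next
    consistency <- mean(abs(r - st) < abs(r - expected))
    if (consistency < min_consistent) next
    out[[length(out) + 1]] <- data.frame(
      chrom = ch, state = st, mean_ratio = cc$mean_ratio,
      consistency = consistency,
      change = if (st < expected) "loss" else "gain",
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), state = numeric(0),
                      mean_ratio = numeric(0), consistency = numeric(0),
                      change = character(0)))
  }
  do.call(rbind, out)
}

#' Detect loss-of-heterozygosity runs in an expected-heterozygous region
#'
#' An extra chromosome carried atop its homologous counterpart makes the
#' shared region heterozygous; maximal runs of `min_run` or more homozygous
#' bins inside such a region indicate replacement of one copy's sequence by
#' the other's.
#'
#' @param calls [classify_bins()] output restricted to the
#'   expected-heterozygous region, ordered by coordinate.
#' @param min_run Minimum run length in bins (default 3).
#' @return Data frame `chrom`, `start`, `end`, `n_bins` of LOH intervals.
#' @export
detect_loh <- function(calls, min_run = 3) {
  out <- list()
  for (ch in unique(calls$chrom)) {
    b <- calls[calls$chrom == ch, ]
    b <- b[order(b$bin_start), ]
    b <- b[!is.na(b$state), ]
    if (!nrow(b)) next
    hom <- b$state %in% c("A", "B")
    r <- rle(hom)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths >= min_run)) {
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = b$bin_start[starts[k]], end = b$bin_end[ends[k]],
        n_bins = r$lengths[k], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_bins = integer(0)))
  }
  do.call(rbind, out)
}
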