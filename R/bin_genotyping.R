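# Monospore origin analysis on the haplotype-A reference frame: classify
# bins as A / B / heterozygous from diagnostic-allele counts, call
# recombination events at origin switches, aggregate events into sites and
# hotspots, and compute per-isolate origin fractions.

#' Classify bins by haplotype origin from diagnostic-allele counts
#'
#' A bin is called `A` when the A-allele share reaches `purity`, `B`
#' symmetrically, `HET` when both alleles reach the `1 - purity` share, and
#' `NA` otherwise (insufficient reads, non-informative bin, or an ambiguous
#' allele balance).
#'
#' @param counts Data frame with `chrom`, `bin_start`, `bin_end`, `nA`,
#'   `nB` and optionally `informative` (default all informative) and
#'   `isolate`.
#' @param min_reads Minimum `nA + nB` to make a call (default 5).
#' @param purity Homozygous-call allele-share threshold (default 0.9).
#' @return The input with a `state` factor column (`A`, `B`, `HET`, `NA`).
#' @export
classify_bins <- function(counts, min_reads = 5, purity = 0.9) {
  if (any(counts$nA < 0 | counts$nB < 0)) stop("negative allele counts")
  stopifnot(purity > 0.5, purity <= 1)
  informative <- if ("informative" %in% names(counts)) counts$informative else TRUE
  n <- counts$nA + counts$nB
  shareA <- ifelse(n > 0, counts$nA / n, NA_real_)
  state <- rep(NA_character_, nrow(counts))
  ok <- informative & n >= min_reads
  state[ok & shareA >= purity] <- "A"
  state[ok & (1 - shareA) >= purity] <- "B"
  both <- ok & is.na(state) & shareA >= (1 - purity) & (1 - shareA) >= (1 - purity)
  state[both] <- "HET"
  out <- counts
  out$state <- state
  out
}

#' Call recombination events from an isolate's ordered bin calls
#'
#' Scans each chromosome's bin states in coordinate order, collapses
#' `NA`/`HET` gaps, suppresses homozygous runs shorter than `min_run` bins
#' (single-bin flickers from allele error), and emits one event per
#' remaining A-B transition. The breakpoint interval spans from the end of
#' the last bin of the left run to the start of the first bin of the right
#' run (it widens across any collapsed gap rather than inventing two
#' events).
#'
#' @param calls Output of [classify_bins()] for one isolate.
#' @param min_run Minimum run length (bins) for a homozygous run to count
#'   (default 2).
#' @return Data frame with `isolate`, `chrom`, `left_state`, `right_state`,
#'   `start`, `end` (the breakpoint interval, 1-based inclusive).
#' @export
call_events <- function(calls, min_run = 2) {
  iso <- if ("isolate" %in% names(calls)) calls$isolate[1] else NA_character_
  out <- list()
  for (ch in unique(calls$chrom)) {
    b <- calls[calls$chrom == ch, ]
    b <- b[order(b$bin_start), ]
    hom <- which(b$state %in% c("A", "B"))
    if (length(hom) < 2) next
    st <- b$state[hom]
    # run-length filter on the homozygous-state sequence
    r <- rle(st)
    keep <- rep(r$lengths >= min_run, r$lengths)
    hom <- hom[keep]
    st <- st[keep]
    if (length(hom) < 2) next
    # after suppression, re-collapse identical neighbours and call transitions
    tr <- which(st[-1] != st[-length(st)])
    for (t in tr) {
      out[[length(out) + 1]] <- data.frame(
        isolate = iso, chrom = ch,
        left_state = st[t], right_state = st[t + 1],
        start = b$bin_end[hom[t]], end = b$bin_start[hom[t + 1]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(isolate = character(0), chrom = character(0),
                      left_state = character(0), right_state = character(0),
                      start = numeric(0), end = numeric(0)))
  }
  do.call(rbind, out)
}

#' Aggregate recombination events across isolates into sites and hotspots
#'
#' Events whose breakpoint intervals lie within `merge_distance` bases of
#' each other (gap between intervals, adjacency = 0) are merged into one
#' recombination site. A site visited by four or more distinct isolates is a
#' hotspot. The default merge distance of 10 bp keeps sites separated by 15
#' bp distinct.
#'
#' @param events Row-bound [call_events()] output across isolates.
#' @param merge_distance Maximum gap (bases) between merged intervals
#'   (default 10).
#' @param hotspot_min_isolates Distinct isolates required for hotspot status
#'   (default 4).
#' @return Data frame with `chrom`, `start`, `end`, `n_isolates`,
#'   `n_events`, `hotspot`.
#' @export
aggregate_sites <- function(events, merge_distance = 10,
                            hotspot_min_isolates = 4) {
  if (nrow(events) == 0) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_isolates = integer(0),
                      n_events = integer(0), hotspot = logical(0)))
  }
  out <- list()
  for (ch in unique(events$chrom)) {
    ev <- events[events$chrom == ch, ]
    ir <- IRanges::IRanges(ev$start, ev$end)
    # reduce() merges ranges whose gap is < min.gapwidth; a gap of
    # merge_distance bases must still merge, merge_distance + 1 must not
    merged <- IRanges::reduce(ir, min.gapwidth = merge_distance + 1)
    hits <- IRanges::findOverlaps(ir, merged,
                                  maxgap = merge_distance, select = "first")
    for (k in seq_along(merged)) {
      sel <- hits == k
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = IRanges::start(merged)[k],
        end = IRanges::end(merged)[k],
        n_isolates = length(unique(ev$isolate[sel])),
        n_events = sum(sel), stringsAsFactors = FALSE)
    }
  }
  sites <- do.call(rbind, out)
  sites$hotspot <- sites$n_isolates >= hotspot_min_isolates
  sites[order(sites$chrom, sites$start), ]
}

#' Per-isolate haplotype-origin fractions
#'
#' Percent of informative, called genome (length-weighted over bins) in
#' state A, B and heterozygous; the three percentages sum to 100.
#'
#' @param calls Output of [classify_bins()] for one isolate.
#' @return List with `pctA`, `pctB`, `pctHET`.
#' @export
origin_fraction <- function(calls) {
  ok <- !is.na(calls$state) &
    (if ("informative" %in% names(calls)) calls$informative else TRUE)
  if (!any(ok)) stop("no informative called bins; origin fraction undefined")
  w <- interval_len(calls$bin_start[ok], calls$bin_end[ok])
  tot <- sum(w)
  pct <- function(s) 100 * sum(w[calls$state[ok] == s]) / tot
  list(pctA = pct("A"), pctB = pct("B"), pctHET = pct("HET"))
}

#' Export an isolate's origin calls as a BED track
#'
#' @param calls Output of [classify_bins()] for one isolate.
#' @param path Output BED path; the state is the BED name field.
#' @return `path`, invisibly.
#' @export
write_origin_bed <- function(calls, path) {
  ok <- !is.na(calls$state)
  write_track_bed(data.frame(chrom = calls$chrom[ok],
                             start = calls$bin_start[ok],
                             end = calls$bin_end[ok],
                             name = calls$state[ok]), path)
}
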