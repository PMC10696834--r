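# Novel-junction analysis and karyotyping: depth inflection points,
# spanning-read junction validation, reconstruction of new chromosome
# models (reverse-complement joins, telomere caps, centromere absence),
# genome-architecture assignment and aneuploidy typing.

#' Find copy-ratio inflection points along a chromosome
#'
#' Slides over window boundaries and reports boundaries where the trimmed
#' mean of the `flank` windows on the right differs from the trimmed mean of
#' the `flank` windows on the left by more than `min_step`. Consecutive
#' qualifying boundaries are collapsed to the one with the largest step.
#'
#' @param ratios Data frame with `window_start`, `window_end`, `ratio` for
#'   one chromosome, ordered by coordinate (>= 10 windows).
#' @param min_step Minimum absolute ratio step (default 0.4).
#' @param flank Windows per flank (default 5).
#' @return Data frame `boundary` (coordinate of the window boundary),
#'   `left_mean`, `right_mean`, `step`.
#' @export
find_depth_inflections <- function(ratios, min_step = 0.4, flank = 5) {
  n <- nrow(ratios)
  if (n < 10) stop("need at least 10 windows")
  steps <- rep(NA_real_, n - 1)
  lm <- rm <- rep(NA_real_, n - 1)
  for (k in seq_len(n - 1)) {
    lo <- max(1, k - flank + 1)
    hi <- min(n, k + flank)
    lm[k] <- mean(ratios$ratio[lo:k], trim = 0.1)
    rm[k] <- mean(ratios$ratio[(k + 1):hi], trim = 0.1)
    steps[k] <- rm[k] - lm[k]
  }
  hit <- which(abs(steps) > min_step)
  if (!length(hit)) {
    return(data.frame(boundary = numeric(0), left_mean = numeric(0),
                      right_mean = numeric(0), step = numeric(0)))
  }
  # collapse runs of consecutive qualifying boundaries to the strongest one
  grp <- cumsum(c(1, diff(hit) > 1))
  best <- vapply(split(hit, grp), function(ix) ix[which.max(abs(steps[ix]))],
                 numeric(1))
  data.frame(boundary = ratios$window_end[best], left_mean = lm[best],
             right_mean = rm[best], step = steps[best])
}

#' Validate a candidate novel junction with spanning-read evidence
#'
#' A junction is accepted when enough reads span the novel join and the
#' broken reference sites are not themselves spanned: the default
#' `max_ref_span = 0` encodes "no reads cross the broken sites". Relax
#' `max_ref_span` when an intact carrier molecule of one site is known to be
#' present in the same isolate (e.g. an intact extra chromosome co-occurring
#' with a new chromosome that reuses one of its arms).
#'
#' @param support_reads Reads spanning the novel junction.
#' @param ref_span_x,ref_span_y Reads crossing the unbroken reference at
#'   each breakpoint.
#' @param min_support Minimum junction-spanning reads (default 3).
#' @param max_ref_span Maximum tolerated reference-spanning reads (default
#'   0).
#' @return Logical: accepted or not.
#' @export
validate_junction <- function(support_reads, ref_span_x, ref_span_y,
                              min_support = 3, max_ref_span = 0) {
  stopifnot(support_reads >= 0, ref_span_x >= 0, ref_span_y >= 0)
  support_reads >= min_support && ref_span_x <= max_ref_span &&
    ref_span_y <= max_ref_span
}

#' Construct a new-chromosome model from ordered oriented segments
#'
#' @param id Model name (e.g. `"ChrN1"`).
#' @param segments List of [oriented_segment()]s in join order.
#' @param telomere_5p,telomere_3p Logical telomere flags at the model ends.
#' @param has_centromere Logical.
#' @param gene_count,essential_count Optional track-derived counts.
#' @return Object of class `new_chromosome_model`; `length` is the exact sum
#'   of segment lengths under 1-based inclusive arithmetic.
#' @export
new_chromosome_model <- function(id, segments, telomere_5p = NA,
                                 telomere_3p = NA, has_centromere = NA,
                                 gene_count = NA_integer_,
                                 essential_count = NA_integer_) {
  len <- sum(vapply(segments, segment_length, numeric(1)))
  structure(list(id = id, segments = segments, length = len,
                 telomere_5p = telomere_5p, telomere_3p = telomere_3p,
                 has_centromere = has_centromere, gene_count = gene_count,
                 essential_count = essential_count,
                 stable = isTRUE(telomere_5p) && isTRUE(telomere_3p)),
            class = "new_chromosome_model")
}

#' @export
print.new_chromosome_model <- function(x, ...) {
  segs <- vapply(x$segments, function(s)
    sprintf("%s:%s-%s%s", s$chrom, format(s$start, big.mark = ",", scientific = FALSE),
            format(s$end, big.mark = ",", scientific = FALSE),
            if (s$orient == "-") " RC" else ""), character(1))
  cat(sprintf("<new chromosome %s: %s bp [%s], telomeres %s/%s, centromere %s>\n",
              x$id, format(x$length, big.mark = ",", scientific = FALSE),
              paste(segs, collapse = " + "),
              if (isTRUE(x$telomere_5p)) "+" else "-",
              if (isTRUE(x$telomere_3p)) "+" else "-",
              if (isTRUE(x$has_centromere)) "+" else "-"))
  invisible(x)
}

# telomere state of a model end that is fed by a source-segment end
segment_end_telomere <- function(seg, chrom, which_model_end) {
  # "5p" model end uses the leading end of the first segment; for a
  # "+" segment that is the source 5' end iff the segment starts at base 1,
  # for a "-" segment it is the source 3' end iff the segment ends at the
  # source terminus
  if (which_model_end == "5p") {
    if (seg$orient == "+") {
      seg$start == 1 && isTRUE(chrom$telomere_5p$present)
    } else {
      seg$end == chrom$length && isTRUE(chrom$telomere_3p$present)
    }
  } else {
    if (seg$orient == "+") {
      seg$end == chrom$length && isTRUE(chrom$telomere_3p$present)
    } else {
      seg$start == 1 && isTRUE(chrom$telomere_5p$present)
    }
  }
}

#' Reconstruct a new chromosome from an accepted junction
#'
#' Resolves the junction's oriented segments against the haplotype genomes:
#' sums segment lengths exactly, looks up telomere flags at the model's
#' terminal ends, flags centromere presence from segment overlap with
#' source centromeres, and counts genes and essential genes from the
#' source tracks. Optionally assembles the nucleotide sequence.
#'
#' @param id Model name.
#' @param segments List of [oriented_segment()]s in join order.
#' @param genomes Named list of [haplotype_genome()]s (searched in order for
#'   each segment's chromosome).
#' @param sequence Assemble the model sequence (requires source sequences).
#' @return A [new_chromosome_model()]; with `sequence = TRUE` the model also
#'   carries a `sequence` element.
#' @export
reconstruct_new_chromosome <- function(id, segments, genomes,
                                       sequence = FALSE) {
  find_chrom <- function(chrom_id) {
    for (g in genomes) {
      if (!is.null(g$chromosomes[[chrom_id]])) return(list(chrom = g$chromosomes[[chrom_id]], genome = g))
    }
    stop("chromosome ", chrom_id, " not found in supplied genomes")
  }
  src <- lapply(segments, function(s) find_chrom(s$chrom))
  for (i in seq_along(segments)) {
    if (segments[[i]]$end > src[[i]]$chrom$length) {
      stop("segment ", i, " exceeds the bounds of ", segments[[i]]$chrom)
    }
  }
  tel5 <- segment_end_telomere(segments[[1]], src[[1]]$chrom, "5p")
  nlast <- length(segments)
  tel3 <- segment_end_telomere(segments[[nlast]], src[[nlast]]$chrom, "3p")
  has_cen <- any(vapply(seq_along(segments), function(i) {
    cen <- src[[i]]$chrom$centromere
    !is.null(cen) && segments[[i]]$start <= cen[2] && segments[[i]]$end >= cen[1]
  }, logical(1)))
  count_track <- function(track_name) {
    total <- 0L
    for (i in seq_along(segments)) {
      tr <- src[[i]]$genome$tracks[[track_name]]
      if (is.null(tr) || !nrow(tr)) next
      s <- segments[[i]]
      tr <- tr[tr$chrom == s$chrom, , drop = FALSE]
      mid <- (tr$start + tr$end) / 2
      total <- total + sum(mid >= s$start & mid <= s$end)
    }
    total
  }
  model <- new_chromosome_model(
    id, segments, telomere_5p = tel5, telomere_3p = tel3,
    has_centromere = has_cen,
    gene_count = count_track("genes"),
    essential_count = count_track("essential_genes"))
  if (sequence) {
    parts <- vapply(seq_along(segments), function(i) {
      s <- segments[[i]]
      seqchr <- src[[i]]$chrom$sequence
      if (is.null(seqchr)) stop("no sequence for ", s$chrom)
      sub <- substr(seqchr, s$start, s$end)
      if (s$orient == "-") revcomp(sub) else sub
    }, character(1))
    model$sequence <- paste(parts, collapse = "")
  }
  model
}

#' Assign genome architecture from breakpoint-spanning evidence
#'
#' The A and B nuclear genomes differ in the arrangement of a small set of
#' structural-variant breakpoints; short-read evidence at each breakpoint
#' counts reads spanning the A arrangement versus the B arrangement. The
#' isolate is called `A` when every informative breakpoint supports the A
#' arrangement, `B` symmetrically, and `unresolved` otherwise (mixed or
#' insufficient evidence).
#'
#' @param breakpoint_evidence Data frame with `breakpoint`, `supportA`,
#'   `supportB`.
#' @param min_support Reads required for a breakpoint to be informative
#'   (default 3).
#' @return List with `architecture` (`"A"`, `"B"`, `"unresolved"`) and
#'   `per_breakpoint` (data frame with a `call` column).
#' @export
assign_architecture <- function(breakpoint_evidence, min_support = 3) {
  ev <- breakpoint_evidence
  call <- rep("uninformative", nrow(ev))
  call[ev$supportA >= min_support & ev$supportB < min_support] <- "A"
  call[ev$supportB >= min_support & ev$supportA < min_support] <- "B"
  call[ev$supportA >= min_support & ev$supportB >= min_support] <- "mixed"
  ev$call <- call
  informative <- call %in% c("A", "B")
  architecture <- if (!any(informative)) "unresolved"
  else if (all(call[informative] == "A") && !any(call == "mixed")) "A"
  else if (all(call[informative] == "B") && !any(call == "mixed")) "B"
  else "unresolved"
  list(architecture = architecture, per_breakpoint = ev)
}

#' Type the aneuploidy class of an isolate from its extra chromosomes
#'
#' Deterministic total mapping from the extra-chromosome set to the
#' aneuploidy typology: Type I = one extra whole acentric Chr12B-like
#' chromosome; Type II = one extra ChrN1-like new chromosome; Type III =
#' one extra ChrN2-like; Type IV = Chr12B-like plus ChrN1-like; the empty
#' set is euploid; any other set is `"other"`, never I-IV.
#'
#' @param extras Character vector of extra-chromosome names.
#' @param architecture `"A"`, `"B"` or `"unresolved"`.
#' @param base_chromosomes Chromosome count of the base architecture
#'   (default 11, the A architecture).
#' @param catalog Named mapping of canonical roles to chromosome names
#'   (defaults `Chr12B`, `ChrN1`, `ChrN2`).
#' @return List of class `karyotype_call` with `architecture`, `extras`,
#'   `aneuploidy_type` (`"euploid"`, `"I"`-`"IV"`, `"other"`) and
#'   `chromosome_count`.
#' @export
type_aneuploidy <- function(extras, architecture = "A",
                            base_chromosomes = 11,
                            catalog = c(whole_extra = "Chr12B",
                                        new1 = "ChrN1", new2 = "ChrN2")) {
  extras <- sort(unique(extras))
  key <- function(...) sort(unname(catalog[c(...)]))
  type <- if (length(extras) == 0) "euploid"
  else if (identical(extras, key("whole_extra"))) "I"
  else if (identical(extras, key("new1"))) "II"
  else if (identical(extras, key("new2"))) "III"
  else if (identical(extras, key("whole_extra", "new1"))) "IV"
  else "other"
  structure(list(architecture = architecture, extras = extras,
                 aneuploidy_type = type,
                 chromosome_count = base_chromosomes + length(extras)),
            class = "karyotype_call")
}

#' Call the extra chromosomes an isolate carries
#'
#' Combines depth and junction evidence: a whole extra acentric chromosome
#' is called from its copy-number footprint (its orphan region present and
#' its arm region at two copies); a new chromosome is called from validated
#' junction support, where the reference-span requirement at a breakpoint is
#' waived when an intact carrier of that reference junction has already been
#' called in the same isolate (its reads legitimately span the site).
#'
#' @param ratios Normalized depth data frame (`chrom`, `window_start`,
#'   `window_end`, `ratio`) for the isolate.
#' @param junctions Junction evidence data frame (`junction`, `support`,
#'   `ref_span_x`, `ref_span_y`).
#' @param truth Truth object from [generate_dikaryon()] (supplies the
#'   extras catalog and junction rules).
#' @param min_support,grid_tolerance Thresholds.
#' @return Character vector of extra-chromosome names.
#' @export
call_extras <- function(ratios, junctions, truth, min_support = 3,
                        grid_tolerance = 0.1) {
  region_ratio <- function(chrom, start, end) {
    mid <- floor((ratios$window_start + ratios$window_end) / 2)
    sel <- ratios$chrom == chrom & mid >= start & mid <= end
    if (sum(sel) < 3) return(NA_real_)
    mean(ratios$ratio[sel], trim = 0.1)
  }
  cat_fp <- truth$extras_catalog
  extras <- character(0)
  # whole extra chromosome: orphan footprint present AND arm region beyond
  # any new-chromosome overlap at ~2 copies
  if (!is.null(cat_fp$Chr12B)) {
    fp <- cat_fp$Chr12B
    arm <- fp[!fp$chrom %in% names(truth$pseudo_chroms), ][1, ]
    # the distal arm part not shared with ChrN2's footprint
    n2 <- cat_fp$ChrN2
    distal_start <- arm$start
    if (!is.null(n2)) {
      shared <- n2[n2$chrom == arm$chrom, ]
      if (nrow(shared)) distal_start <- max(shared$end) + 1
    }
    orphan <- fp[fp$chrom %in% names(truth$pseudo_chroms), ][1, ]
    r_arm <- region_ratio(arm$chrom, distal_start, arm$end)
    r_orphan <- region_ratio(orphan$chrom, orphan$start, orphan$end)
    # decision boundaries at the copy-number midpoints: the distal arm is
    # closer to two copies than one, and the orphan closer to one than zero
    if (!is.na(r_arm) && !is.na(r_orphan) &&
        r_arm > 1.5 && r_orphan > 0.5) {
      extras <- c(extras, "Chr12B")
    }
  }
  # new chromosomes: validated junctions, carrier-aware reference spans
  jr <- truth$junction_rules
  if (!is.null(junctions) && nrow(jr)) {
    for (i in seq_len(nrow(jr))) {
      j <- junctions[junctions$junction == jr$id[i], ]
      if (!nrow(j)) next
      ref_y_waived <- startsWith(jr$ref_y_carrier[i], "extra:") &&
        sub("extra:", "", jr$ref_y_carrier[i]) %in% extras
      ok <- validate_junction(
        j$support[1], j$ref_span_x[1],
        if (ref_y_waived) 0 else j$ref_span_y[1],
        min_support = min_support)
      if (ok) extras <- c(extras, jr$id[i])
    }
  }
  sort(unique(extras))
}
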