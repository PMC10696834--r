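# Data model for phased dikaryotic genomes and the sequence-feature rules
# used throughout: telomere detection, accessory-region classification,
# tandem-repeat copy number from depth, and LTR-family haplotype markers.

TELOMERE_MOTIFS_3P <- c("TTAGGG", "TTAGGGG", "TTAGGGGG")

#' Construct a chromosome
#'
#' A chromosome is a named sequence (optional, for coordinate-only work) with
#' telomere state at each end and an optional centromere interval. An acentric
#' chromosome simply has `centromere = NULL`.
#'
#' @param id Chromosome identifier, e.g. `"Chr05A"`.
#' @param length Length in bases; required when `sequence` is `NULL`.
#' @param sequence Optional nucleotide string (A/C/G/T/N).
#' @param centromere Optional length-2 numeric vector, 1-based inclusive
#'   interval of the centromere.
#' @param telomere_5p,telomere_3p Lists with elements `present` (logical) and
#'   `n` (tandem repeat count at that end).
#' @return An object of class `chromosome`.
#' @export
chromosome <- function(id, length = NULL, sequence = NULL, centromere = NULL,
                       telomere_5p = list(present = FALSE, n = 0L),
                       telomere_3p = list(present = FALSE, n = 0L)) {
  if (is.null(length)) {
    if (is.null(sequence)) stop("chromosome needs a length or a sequence")
    length <- nchar(sequence)
  }
  length <- as.numeric(length)
  if (length <= 0) stop("chromosome length must be > 0")
  if (!is.null(sequence) && nchar(sequence) != length) {
    stop("sequence length disagrees with stated length for ", id)
  }
  if (!is.null(centromere)) {
    centromere <- as.numeric(centromere)
    if (length(centromere) != 2 || centromere[1] < 1 || centromere[2] > length ||
        centromere[1] > centromere[2]) {
      stop("centromere interval of ", id, " must lie within [1, length]")
    }
  }
  stopifnot(telomere_5p$n >= 0, telomere_3p$n >= 0)
  structure(
    list(id = id, length = length, sequence = sequence, centromere = centromere,
         telomere_5p = telomere_5p, telomere_3p = telomere_3p),
    class = "chromosome"
  )
}

#' @export
print.chromosome <- function(x, ...) {
  cat(sprintf(
    "<chromosome %s: %s bp, centromere %s, telomeres %s/%s>\n",
    x$id, format(x$length, big.mark = ",", scientific = FALSE),
    if (is.null(x$centromere)) "none (acentric)"
    else paste0(x$centromere[1], "-", x$centromere[2]),
    if (isTRUE(x$telomere_5p$present)) "+" else "-",
    if (isTRUE(x$telomere_3p$present)) "+" else "-"
  ))
  invisible(x)
}

#' Construct a haplotype genome
#'
#' One nuclear genome of the dikaryon: an ordered set of chromosomes plus
#' named feature tracks. Tracks are data frames with at least
#' `chrom`, `start`, `end` (1-based inclusive) and optionally `name`.
#' The `essential_genes` track must be a subset of `genes` (matched by name
#' when both carry names).
#'
#' @param label Haplotype label, `"A"` or `"B"`.
#' @param chromosomes List of [chromosome()] objects.
#' @param tracks Named list of track data frames
#'   (e.g. `genes`, `essential_genes`, `repeats`, `centromeres`).
#' @return An object of class `haplotype_genome`.
#' @export
haplotype_genome <- function(label, chromosomes, tracks = list()) {
  stopifnot(label %in% c("A", "B"))
  ids <- vapply(chromosomes, function(ch) ch$id, character(1))
  if (anyDuplicated(ids)) stop("chromosome ids must be unique")
  names(chromosomes) <- ids
  lens <- vapply(chromosomes, function(ch) ch$length, numeric(1))
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    if (nrow(tr) == 0) next
    if (!all(tr$chrom %in% ids)) {
      stop("track '", nm, "' references unknown chromosomes")
    }
    if (any(tr$start < 1) || any(tr$end > lens[tr$chrom])) {
      stop("track '", nm, "' has intervals outside chromosome bounds")
    }
  }
  if (!is.null(tracks$essential_genes) && !is.null(tracks$genes) &&
      "name" %in% names(tracks$essential_genes) && "name" %in% names(tracks$genes)) {
    if (!all(tracks$essential_genes$name %in% tracks$genes$name)) {
      stop("essential_genes must be a subset of genes")
    }
  }
  structure(list(label = label, chromosomes = chromosomes, tracks = tracks),
            class = "haplotype_genome")
}

#' @export
print.haplotype_genome <- function(x, ...) {
  cat(sprintf("<haplotype_genome %s: %d chromosomes, %.2f Mb, tracks: %s>\n",
              x$label, length(x$chromosomes),
              sum(vapply(x$chromosomes, function(ch) ch$length, numeric(1))) / 1e6,
              paste(names(x$tracks), collapse = ", ")))
  invisible(x)
}

#' Construct an oriented segment
#'
#' A coordinate interval on a chromosome with an orientation. `"-"` means the
#' reverse complement of the interval is used when the segment is placed into
#' a derived chromosome.
#'
#' @param chrom Chromosome id.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param orient `"+"` or `"-"`.
#' @return An object of class `oriented_segment`.
#' @export
oriented_segment <- function(chrom, start, end, orient = "+") {
  stopifnot(orient %in% c("+", "-"), start >= 1, end >= start)
  structure(list(chrom = chrom, start = as.numeric(start),
                 end = as.numeric(end), orient = orient),
            class = "oriented_segment")
}

#' @export
print.oriented_segment <- function(x, ...) {
  cat(sprintf("<%s:%s-%s (%s)>\n", x$chrom, format(x$start, big.mark = ",", scientific = FALSE),
              format(x$end, big.mark = ",", scientific = FALSE), x$orient))
  invisible(x)
}

#' Length of an oriented segment in bases
#'
#' @param seg An [oriented_segment()].
#' @return Numeric length.
#' @export
segment_length <- function(seg) interval_len(seg$start, seg$end)

#' Build a homology-block table
#'
#' Homology blocks are the pairing substrate of the meiosis model: paired
#' oriented intervals on two (distinct) chromatids with a percent identity.
#'
#' @param chromA,startA,endA,orientA First segment of each block.
#' @param chromB,startB,endB,orientB Second segment of each block.
#' @param identity Fraction in `[0, 1]`.
#' @param max_length_ratio Blocks whose two segments differ in length by more
#'   than this factor are rejected.
#' @return A data frame of class `homology_map`.
#' @export
homology_map <- function(chromA, startA, endA, chromB, startB, endB,
                         identity, orientA = "+", orientB = "+",
                         max_length_ratio = 1.25) {
  df <- data.frame(chromA = chromA, startA = startA, endA = endA,
                   orientA = orientA, chromB = chromB, startB = startB,
                   endB = endB, orientB = orientB, identity = identity,
                   stringsAsFactors = FALSE)
  if (any(df$chromA == df$chromB)) {
    stop("a homology block must pair two distinct chromatids")
  }
  if (any(df$identity < 0 | df$identity > 1)) stop("identity must lie in [0,1]")
  lenA <- interval_len(df$startA, df$endA)
  lenB <- interval_len(df$startB, df$endB)
  ratio <- pmax(lenA, lenB) / pmin(lenA, lenB)
  if (any(ratio > max_length_ratio)) {
    stop("homology block segment lengths differ by more than the tolerance")
  }
  class(df) <- c("homology_map", "data.frame")
  df
}

# ---- telomere detection -----------------------------------------------------

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Detect a telomeric tandem repeat at a chromosome end
#'
#' Counts the maximal run of tandem copies of the telomere motif family
#' TTA(G)3-5 (i.e. TTAGGG, TTAGGGG or TTAGGGGG; the G-run may vary per copy)
#' anchored at the given end. At the 5' end the reverse-complement motifs
#' (C)3-5 TAA are scanned from the start of the sequence. Ambiguous bases (N)
#' never match.
#'
#' @param end_sequence Nucleotide string covering the chromosome end.
#' @param which_end `"5p"` or `"3p"`.
#' @param min_repeats Minimum tandem copies to declare a telomere
#'   (default 10; assembled ends typically show 20-40).
#' @return List with `present` (logical) and `repeat_count` (integer).
#' @export
detect_telomere <- function(end_sequence, which_end = c("3p", "5p"),
                            min_repeats = 10L) {
  which_end <- match.arg(which_end)
  if (length(end_sequence) != 1 || is.na(end_sequence) || nchar(end_sequence) == 0) {
    stop("end_sequence must be a non-empty nucleotide string")
  }
  seq <- toupper(end_sequence)
  if (grepl("[^ACGTN]", seq)) stop("non-nucleotide characters in sequence")
  motifs <- if (which_end == "3p") TELOMERE_MOTIFS_3P else
    vapply(TELOMERE_MOTIFS_3P, revcomp, character(1))
  n <- 0L
  if (which_end == "3p") {
    # walk inward from the 3' terminus, stripping one motif copy at a time;
    # try longer motifs first so TTAGGGG is not consumed as TTAGGG + G mismatch
    pos <- nchar(seq)
    repeat {
      hit <- FALSE
      for (m in motifs[order(-nchar(motifs))]) {
        w <- nchar(m)
        if (pos >= w && substr(seq, pos - w + 1, pos) == m) {
          pos <- pos - w
          n <- n + 1L
          hit <- TRUE
          break
        }
      }
      if (!hit) break
    }
  } else {
    pos <- 1L
    len <- nchar(seq)
    repeat {
      hit <- FALSE
      for (m in motifs[order(-nchar(motifs))]) {
        w <- nchar(m)
        if (pos + w - 1 <= len && substr(seq, pos, pos + w - 1) == m) {
          pos <- pos + w
          n <- n + 1L
          hit <- TRUE
          break
        }
      }
      if (!hit) break
    }
  }
  list(present = n >= min_repeats, repeat_count = n)
}

# ---- region feature summary & accessory classification ----------------------

#' Summarize gene, repeat and essential-gene content of a region
#'
#' @param genome A [haplotype_genome()] with `genes`, `essential_genes` and
#'   `repeats` tracks.
#' @param chrom Chromosome id.
#' @param start,end 1-based inclusive region bounds (defaults: whole
#'   chromosome).
#' @return A list of class `region_feature_summary` with `gene_density`
#'   (genes per 10 kb, counted by gene midpoint), `repeat_pct` (% of bases
#'   covered by the repeat track), `essential_count`, `gc_pct` (NA without
#'   sequence) and the region itself.
#' @export
region_feature_summary <- function(genome, chrom, start = 1,
                                   end = genome$chromosomes[[chrom]]$length) {
  ch <- genome$chromosomes[[chrom]]
  if (is.null(ch)) stop("unknown chromosome ", chrom)
  len <- interval_len(start, end)
  count_mid <- function(tr) {
    if (is.null(tr) || nrow(tr) == 0) return(0L)
    tr <- tr[tr$chrom == chrom, , drop = FALSE]
    mid <- (tr$start + tr$end) / 2
    sum(mid >= start & mid <= end)
  }
  n_genes <- count_mid(genome$tracks$genes)
  n_ess <- count_mid(genome$tracks$essential_genes)
  rep_tr <- genome$tracks$repeats
  rep_bases <- 0
  if (!is.null(rep_tr) && nrow(rep_tr) > 0) {
    rep_tr <- rep_tr[rep_tr$chrom == chrom, , drop = FALSE]
    if (nrow(rep_tr) > 0) {
      ir <- IRanges::reduce(IRanges::IRanges(rep_tr$start, rep_tr$end))
      ir <- IRanges::restrict(ir, start = start, end = end)
      rep_bases <- sum(IRanges::width(ir))
    }
  }
  gc_pct <- NA_real_
  if (!is.null(ch$sequence)) {
    sub <- substr(ch$sequence, start, end)
    bases <- strsplit(toupper(sub), "")[[1]]
    acgt <- sum(bases %in% c("A", "C", "G", "T"))
    if (acgt > 0) gc_pct <- 100 * sum(bases %in% c("G", "C")) / acgt
  }
  structure(list(region = oriented_segment(chrom, start, end),
                 gene_density = n_genes / (len / 1e4),
                 repeat_pct = 100 * rep_bases / len,
                 essential_count = n_ess,
                 gc_pct = gc_pct),
            class = "region_feature_summary")
}

#' Classify a region as core or accessory
#'
#' A region is accessory iff all three two-speed-genome criteria hold:
#' gene density below `gene_density_max`, repeat content above
#' `repeat_pct_min`, and zero essential (conserved single-copy ortholog)
#' genes. The defaults sit between the observed core and accessory group
#' statistics (core gene density >= 2.7/10 kb and repeats <= 25.1%; accessory
#' < 2.4/10 kb and > 50.0%), with absence of essential genes mandatory.
#'
#' @param summary A [region_feature_summary()] (or any list with
#'   `gene_density`, `repeat_pct`, `essential_count`).
#' @param gene_density_max Genes per 10 kb below which a region can be
#'   accessory (default 2.4).
#' @param repeat_pct_min Percent repeat-masked above which a region can be
#'   accessory (default 40).
#' @return `"accessory"` or `"core"`.
#' @export
classify_region <- function(summary, gene_density_max = 2.4,
                            repeat_pct_min = 40) {
  stopifnot(summary$repeat_pct >= 0, summary$repeat_pct <= 100,
            summary$essential_count >= 0)
  accessory <- summary$gene_density < gene_density_max &&
    summary$repeat_pct > repeat_pct_min &&
    summary$essential_count == 0
  if (accessory) "accessory" else "core"
}

# ---- tandem copy number & LTR bias ------------------------------------------

#' Estimate tandem-array copy number from sequencing depth
#'
#' The copy number of a tandem repeat unit (e.g. the rDNA/ITS array) is the
#' ratio of the mean sequencing depth over a probe fragment from the unit to
#' the depth of single-copy sequence.
#'
#' @param probe_mean_depth Mean depth over the probe fragment.
#' @param background_single_copy_depth Depth of single-copy regions (> 0).
#' @return Estimated copy number (float).
#' @export
estimate_tandem_copy_number <- function(probe_mean_depth,
                                        background_single_copy_depth) {
  if (background_single_copy_depth <= 0) {
    stop("background single-copy depth must be > 0")
  }
  if (probe_mean_depth < 0) stop("depth cannot be negative")
  probe_mean_depth / background_single_copy_depth
}

#' Assign a chromosome to a haplotype by LTR marker-family bias
#'
#' Two LTR retrotransposon families are each strongly biased to one nucleus
#' (one family almost exclusively in haplotype A, the other in B), which makes
#' full-length copy counts usable as phasing markers for homologous
#' chromosomes of very low heterozygosity.
#'
#' @param count_markerA Full-length copies of the A-biased family.
#' @param count_markerB Full-length copies of the B-biased family.
#' @param min_fold Required fold-excess of the winning family (default 3).
#' @param min_count Required minimum count of the winning family (default 3).
#' @return `"A"`, `"B"` or `"unresolved"`.
#' @export
assign_haplotype_by_ltr_bias <- function(count_markerA, count_markerB,
                                         min_fold = 3, min_count = 3) {
  stopifnot(count_markerA >= 0, count_markerB >= 0)
  if (count_markerA >= min_count && count_markerA >= min_fold * count_markerB) {
    "A"
  } else if (count_markerB >= min_count &&
             count_markerB >= min_fold * count_markerA) {
    "B"
  } else {
    "unresolved"
  }
}
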