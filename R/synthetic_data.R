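# Synthetic asymmetric dikaryon generator with full planted truth, and the
# per-isolate sequencing-evidence simulator (bin diagnostic-allele counts,
# window depths, junction-spanning read counts).
#
# The default configuration is a scaled miniature of the study system: two
# haploid nuclear genomes (A and B) that share homologous content but differ
# in chromosome number and arm arrangement; haplotype B carries one extra
# acentric chromosome ("Chr12B") built from an orphan terminal segment plus a
# copy of the right arm of Chr05A; heterozygosity follows a gradient mosaic
# of per-bin SNP densities; each haplotype harbors three accessory
# chromosomes and two accessory compartments.

#' Default heterozygosity mosaic
#'
#' Fractions of 10-kb bins per SNP-density class, mirroring the gradient
#' heterozygosity landscape of the dikaryon: ~22% of bins near-identical,
#' four ~15% classes between 0.1% and 4%, and the remainder above 4%.
#' Fractions sum to 1; bins with density > 1% are "informative"
#' (heterozygous enough to carry diagnostic alleles).
#'
#' @return Data frame with columns `fraction` and `snp_per_bp`.
#' @export
default_heterozygosity_mosaic <- function() {
  data.frame(
    fraction   = c(0.218, 0.15, 0.15, 0.15, 0.15, 0.182),
    snp_per_bp = c(0.0004, 0.0055, 0.015, 0.025, 0.035, 0.045)
  )
}

#' Configuration for the synthetic dikaryon generator
#'
#' @param preset `"tr01"` for the asymmetric miniature (arm swaps among
#'   Chr01/Chr02/Chr05, orphan terminal segments, an acentric extra
#'   chromosome, accessory chromosomes and compartments), or `"collinear"`
#'   for two fully collinear haplotypes (used for symmetric-dikaryon
#'   baselines).
#' @param bin_size Bin/window size in bases (default 10 kb).
#' @param heterozygosity_mosaic Data frame (`fraction`, `snp_per_bp`);
#'   fractions must sum to 1.
#' @param force_low_het_accessory Force accessory regions into the lowest
#'   density class (the accessory regions of the real dikaryon are all
#'   low-heterozygosity).
#' @param n_chromosomes,chrom_length Collinear preset geometry.
#' @param orphan_chr01b,orphan_chr12b Lengths (bases) of the haplotype-B
#'   orphan terminal segments.
#' @param acentric_extra Whether haplotype B carries the extra acentric
#'   chromosome.
#' @param telomere_repeats Length-2 range of tandem telomere motif copies
#'   planted at each chromosome end.
#' @param ltr_marker_counts Planted full-length copies of the two
#'   haplotype-biased LTR families, per haplotype: a list with elements `A`
#'   and `B`, each `c(markerA = , markerB = )`.
#' @param emit_sequence Generate nucleotide sequences (disable for large
#'   coordinate-only simulations).
#' @param informative_min_density Bin SNP density above which a bin is
#'   informative for origin calling (default 0.01, i.e. 1%).
#' @param seed Integer RNG seed; the generator is fully deterministic given
#'   the config.
#' @return A list of class `dikaryon_config`.
#' @export
dikaryon_config <- function(preset = c("tr01", "collinear"),
                            bin_size = 1e4,
                            heterozygosity_mosaic = default_heterozygosity_mosaic(),
                            force_low_het_accessory = TRUE,
                            n_chromosomes = 3,
                            chrom_length = 3e5,
                            orphan_chr01b = 3e4,
                            orphan_chr12b = 3.5e4,
                            acentric_extra = TRUE,
                            telomere_repeats = c(20, 40),
                            ltr_marker_counts = list(A = c(markerA = 24, markerB = 2),
                                                     B = c(markerA = 4, markerB = 28)),
                            emit_sequence = TRUE,
                            informative_min_density = 0.01,
                            seed = 1L) {
  preset <- match.arg(preset)
  if (abs(sum(heterozygosity_mosaic$fraction) - 1) > 1e-8) {
    stop("mosaic fractions must sum to 1")
  }
  if (any(heterozygosity_mosaic$snp_per_bp < 0)) stop("SNP densities must be >= 0")
  stopifnot(bin_size > 0, orphan_chr01b > 0, orphan_chr12b > 0)
  structure(list(preset = preset, bin_size = bin_size,
                 heterozygosity_mosaic = heterozygosity_mosaic,
                 force_low_het_accessory = force_low_het_accessory,
                 n_chromosomes = n_chromosomes, chrom_length = chrom_length,
                 orphan_chr01b = orphan_chr01b, orphan_chr12b = orphan_chr12b,
                 acentric_extra = acentric_extra,
                 telomere_repeats = telomere_repeats,
                 ltr_marker_counts = ltr_marker_counts,
                 emit_sequence = emit_sequence,
                 informative_min_density = informative_min_density,
                 seed = as.integer(seed)),
            class = "dikaryon_config")
}

# ---- internal plan ----------------------------------------------------------

# The segment plan is the architectural blueprint: every chromosome of both
# haplotypes is a concatenation of named segments; homology, junction rules
# and architecture breakpoints all derive from it.
tr01_segment_plan <- function(config) {
  o1 <- config$orphan_chr01b
  o12 <- config$orphan_chr12b
  seg <- function(name, len, class, essential) {
    data.frame(segment = name, len = len, class = class,
               essential = essential, stringsAsFactors = FALSE)
  }
  segments <- rbind(
    seg("L1", 280e3, "core", TRUE),
    seg("R1", 420e3, "core", TRUE),
    seg("L2", 200e3, "core", TRUE),
    seg("R2", 240e3, "core", TRUE),
    seg("S3", 300e3, "core", TRUE),
    seg("C4", 60e3, "accessory", FALSE),
    seg("S4", 240e3, "core", TRUE),
    seg("C5", 70e3, "accessory", FALSE),
    seg("M5", 180e3, "core", TRUE),
    seg("R5", 150e3, "core", TRUE),
    seg("S9", 80e3, "accessory", FALSE),
    seg("S10", 70e3, "accessory", FALSE),
    seg("S11", 50e3, "accessory", FALSE),
    seg("C1", o1, "orphan", FALSE),
    seg("C12", o12, "orphan", FALSE)
  )
  chromsA <- list(Chr01A = c("L1", "R1"), Chr02A = c("L2", "R2"),
                  Chr03A = "S3", Chr04A = c("C4", "S4"),
                  Chr05A = c("C5", "M5", "R5"), Chr09A = "S9",
                  Chr10A = "S10", Chr11A = "S11")
  chromsB <- list(Chr01B = c("C1", "R1"), Chr02B = c("L1", "R2"),
                  Chr03B = "S3", Chr04B = c("C4", "S4"),
                  Chr05B = c("L2", "C5", "M5"), Chr09B = "S9",
                  Chr10B = "S10", Chr11B = "S11")
  if (config$acentric_extra) chromsB$Chr12B <- c("C12", "R5")
  acentric <- "Chr12B"
  compartments <- data.frame(
    segment = c("C4", "C5"),
    stringsAsFactors = FALSE
  )
  list(segments = segments, chromsA = chromsA, chromsB = chromsB,
       acentric = acentric, compartments = compartments)
}

collinear_segment_plan <- function(config) {
  n <- config$n_chromosomes
  segments <- data.frame(segment = sprintf("S%02d", seq_len(n)),
                         len = rep(config$chrom_length, n),
                         class = "core", essential = TRUE,
                         stringsAsFactors = FALSE)
  chroms <- stats::setNames(as.list(segments$segment),
                            sprintf("Chr%02d", seq_len(n)))
  chromsA <- stats::setNames(chroms, paste0(names(chroms), "A"))
  chromsB <- stats::setNames(chroms, paste0(names(chroms), "B"))
  list(segments = segments, chromsA = chromsA, chromsB = chromsB,
       acentric = character(0),
       compartments = data.frame(segment = character(0)))
}

# Coordinates of every segment on every chromosome that carries it.
segment_layout <- function(plan) {
  lay <- function(chroms, haplotype) {
    out <- list()
    for (chrom in names(chroms)) {
      segs <- chroms[[chrom]]
      lens <- plan$segments$len[match(segs, plan$segments$segment)]
      end <- cumsum(lens)
      start <- end - lens + 1
      out[[chrom]] <- data.frame(chrom = chrom, haplotype = haplotype,
                                 segment = segs, start = start, end = end,
                                 stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }
  rbind(lay(plan$chromsA, "A"), lay(plan$chromsB, "B"))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a telomere cap string for one end; 3' caps read TTA(G)3-5 tandem, 5' caps
# are the reverse complement family
telomere_cap <- function(n_repeats, which_end) {
  gs <- sample(3:5, n_repeats, replace = TRUE)
  units <- vapply(gs, function(g) paste0("TTA", strrep("G", g)), character(1))
  cap <- paste(units, collapse = "")
  if (which_end == "5p") revcomp(cap) else cap
}

# deterministic-with-jitter feature placement inside [lo, hi]
place_intervals <- function(lo, hi, spacing, width) {
  starts <- seq(lo, hi - width, by = spacing)
  if (length(starts) == 0) return(numeric(0))
  jitter <- stats::runif(length(starts), 0, spacing - width - 1)
  pmin(floor(starts + jitter), hi - width)
}

#' Generate a synthetic asymmetric dikaryon with planted truth
#'
#' Builds both haplotype genomes from a segment plan, plants diagnostic SNPs
#' according to the heterozygosity mosaic, caps all chromosome ends with
#' tandem telomere repeats, places gene / essential-gene / repeat / LTR-marker
#' tracks (core regions gene-dense and repeat-poor, accessory regions the
#' opposite), and records everything planted in a truth object: the segment
#' map, per-bin SNP densities and positions, the homology map (the pairing
#' substrate for meiosis), accessory regions, junction rules for the two new
#' chromosomes the architecture can generate, architecture breakpoints, and
#' the catalog of extra-chromosome copy footprints used by the evidence
#' simulator.
#'
#' @param config A [dikaryon_config()].
#' @return List with `genomeA`, `genomeB` ([haplotype_genome()] objects),
#'   `truth` (list; see Details), and `config`.
#' @export
generate_dikaryon <- function(config = dikaryon_config()) {
  withr::with_seed(config$seed, generate_dikaryon_impl(config))
}

generate_dikaryon_impl <- function(config) {
  plan <- if (config$preset == "tr01") tr01_segment_plan(config) else
    collinear_segment_plan(config)
  layout <- segment_layout(plan)
  margin <- 400  # bases reserved at chromosome ends for telomere caps

  chrom_len <- function(chroms) {
    vapply(chroms, function(segs)
      sum(plan$segments$len[match(segs, plan$segments$segment)]), numeric(1))
  }
  lensA <- chrom_len(plan$chromsA)
  lensB <- chrom_len(plan$chromsB)

  # --- accessory regions (truth, both haplotypes, own frames) ---
  seg_class <- stats::setNames(plan$segments$class, plan$segments$segment)
  acc_rows <- layout[seg_class[layout$segment] == "accessory", , drop = FALSE]
  accessory <- if (nrow(acc_rows)) {
    whole <- acc_rows$segment %in% c("S9", "S10", "S11")
    data.frame(chrom = acc_rows$chrom, start = acc_rows$start,
               end = acc_rows$end, haplotype = acc_rows$haplotype,
               type = ifelse(whole, "chromosome", "compartment"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               haplotype = character(0), type = character(0))
  }

  # --- bins on the A frame with mosaic densities ---
  binsA <- do.call(rbind, lapply(names(plan$chromsA), function(chrom) {
    len <- lensA[[chrom]]
    starts <- seq(1, len, by = config$bin_size)
    data.frame(chrom = chrom, start = starts,
               end = pmin(starts + config$bin_size - 1, len),
               stringsAsFactors = FALSE)
  }))
  mosaic <- config$heterozygosity_mosaic
  cls <- sample.int(nrow(mosaic), nrow(binsA), replace = TRUE,
                    prob = mosaic$fraction)
  if (config$force_low_het_accessory && nrow(accessory)) {
    accA <- accessory[accessory$haplotype == "A", , drop = FALSE]
    low <- which.min(mosaic$snp_per_bp)
    for (i in seq_len(nrow(accA))) {
      hit <- binsA$chrom == accA$chrom[i] &
        binsA$start >= accA$start[i] & binsA$end <= accA$end[i]
      cls[hit] <- low
    }
  }
  binsA$density <- mosaic$snp_per_bp[cls]
  binsA$informative <- binsA$density > config$informative_min_density

  # --- diagnostic SNP positions (A frame), avoiding telomere cap zones ---
  snps <- do.call(rbind, lapply(seq_len(nrow(binsA)), function(i) {
    b <- binsA[i, ]
    lo <- max(b$start, margin + 1)
    hi <- min(b$end, lensA[[b$chrom]] - margin)
    if (hi < lo) return(NULL)
    n <- stats::rbinom(1, hi - lo + 1, b$density)
    if (n == 0) return(NULL)
    data.frame(chrom = b$chrom, pos = sort(sample(lo:hi, n)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(snps)) {
    snps <- data.frame(chrom = character(0), pos = numeric(0))
  }
  binsA$n_snps <- if (nrow(snps)) {
    key <- paste(binsA$chrom, binsA$start %/% config$bin_size)
    tab <- table(paste(snps$chrom, (snps$pos - 1) %/% config$bin_size))
    as.integer(tab[key])
  } else 0L
  binsA$n_snps[is.na(binsA$n_snps)] <- 0L

  # --- homology map: every non-orphan segment pairs its A and B placements ---
  segsA <- layout[layout$haplotype == "A", ]
  segsB <- layout[layout$haplotype == "B", ]
  shared <- intersect(segsA$segment, segsB$segment)
  seg_density <- vapply(shared, function(s) {
    a <- segsA[segsA$segment == s, ]
    in_seg <- binsA$chrom == a$chrom & binsA$start >= a$start & binsA$end <= a$end
    if (!any(in_seg)) mean(binsA$density) else mean(binsA$density[in_seg])
  }, numeric(1))
  hmap <- if (length(shared)) {
    a <- segsA[match(shared, segsA$segment), ]
    b <- segsB[match(shared, segsB$segment), ]
    homology_map(chromA = a$chrom, startA = a$start, endA = a$end,
                 chromB = b$chrom, startB = b$start, endB = b$end,
                 identity = pmin(1, 1 - seg_density))
  } else NULL

  # --- sequences ---
  seqsA <- seqsB <- NULL
  if (config$emit_sequence) {
    seg_seq <- stats::setNames(
      lapply(plan$segments$len, random_dna), plan$segments$segment)
    # plant B alleles at diagnostic SNP positions of each shared segment
    alt_of <- c(A = "C", C = "A", G = "T", T = "G")
    seg_seq_B <- seg_seq
    if (nrow(snps)) {
      for (s in shared) {
        a <- segsA[segsA$segment == s, ]
        hit <- snps$chrom == a$chrom & snps$pos >= a$start & snps$pos <= a$end
        if (!any(hit)) next
        rel <- snps$pos[hit] - a$start + 1
        v <- strsplit(seg_seq[[s]], "")[[1]]
        v[rel] <- alt_of[v[rel]]
        seg_seq_B[[s]] <- paste(v, collapse = "")
      }
    }
    build <- function(chroms, seg_pool) {
      lapply(chroms, function(segs)
        paste(unlist(seg_pool[segs]), collapse = ""))
    }
    seqsA <- build(plan$chromsA, seg_seq)
    seqsB <- build(plan$chromsB, seg_seq_B)
  }

  # --- telomere caps (counts recorded even when sequence is not emitted);
  # homologous chromosomes (same root name) share their caps, so identical
  # configured content yields byte-identical haplotypes ---
  tel_counts <- list()
  cap_cache <- list()
  cap_genome <- function(seqs, lens) {
    for (chrom in names(lens)) {
      root <- sub("[AB]$", "", chrom)
      if (is.null(cap_cache[[root]])) {
        n5 <- sample(config$telomere_repeats[1]:config$telomere_repeats[2], 1)
        n3 <- sample(config$telomere_repeats[1]:config$telomere_repeats[2], 1)
        cap_cache[[root]] <<- list(n5 = n5, n3 = n3,
                                   cap5 = telomere_cap(n5, "5p"),
                                   cap3 = telomere_cap(n3, "3p"))
      }
      cc <- cap_cache[[root]]
      tel_counts[[chrom]] <<- c(n5 = cc$n5, n3 = cc$n3)
      if (!is.null(seqs)) {
        s <- seqs[[chrom]]
        substr(s, 1, nchar(cc$cap5)) <- cc$cap5
        substr(s, nchar(s) - nchar(cc$cap3) + 1, nchar(s)) <- cc$cap3
        seqs[[chrom]] <- s
      }
    }
    seqs
  }
  seqsA <- cap_genome(seqsA, lensA)
  seqsB <- cap_genome(seqsB, lensB)

  # --- feature tracks ---
  gene_par <- list(core = list(spacing = 3200, width = 1400),
                   accessory = list(spacing = 6700, width = 900),
                   orphan = list(spacing = 3600, width = 1200))
  rep_par <- list(core = 1800, accessory = 5500, orphan = 3000)
  seg_genes <- list(); seg_repeats <- list()
  for (i in seq_len(nrow(plan$segments))) {
    s <- plan$segments[i, ]
    gp <- gene_par[[s$class]]
    starts <- place_intervals(500, s$len - 500, gp$spacing, gp$width)
    ess <- if (s$essential) seq_along(starts) %% 4 == 0 else
      rep(FALSE, length(starts))
    seg_genes[[s$segment]] <- data.frame(
      rel_start = starts, rel_end = starts + gp$width - 1,
      name = sprintf("%s_g%03d", s$segment, seq_along(starts)),
      essential = ess, stringsAsFactors = FALSE)
    rw <- rep_par[[s$class]]
    rstarts <- place_intervals(500, s$len - 500, 1e4, rw)
    seg_repeats[[s$segment]] <- data.frame(
      rel_start = rstarts, rel_end = rstarts + rw - 1,
      name = "repeat", stringsAsFactors = FALSE)
  }
  project_track <- function(haplo, pool) {
    rows <- layout[layout$haplotype == haplo, ]
    out <- lapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      f <- pool[[r$segment]]
      if (is.null(f) || nrow(f) == 0) return(NULL)
      data.frame(chrom = r$chrom, start = f$rel_start + r$start - 1,
                 end = f$rel_end + r$start - 1, name = f$name,
                 essential = if ("essential" %in% names(f)) f$essential else FALSE,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  mk_tracks <- function(haplo, lens) {
    genes <- project_track(haplo, seg_genes)
    reps <- project_track(haplo, seg_repeats)
    # plant the two haplotype-biased LTR marker families inside repeat space
    counts <- config$ltr_marker_counts[[haplo]]
    if (!is.null(counts) && nrow(reps)) {
      idx <- sample(nrow(reps), min(nrow(reps), sum(counts)))
      fam <- rep(c("LTR683", "LTR1239"), times = counts)[seq_along(idx)]
      reps$name[idx] <- fam
    }
    list(genes = genes[, c("chrom", "start", "end", "name")],
         essential_genes = genes[genes$essential,
                                 c("chrom", "start", "end", "name")],
         repeats = reps[, c("chrom", "start", "end", "name")])
  }
  tracksA <- mk_tracks("A", lensA)
  tracksB <- mk_tracks("B", lensB)

  # --- chromosome objects (centromere mid-chromosome; extra chromosome acentric) ---
  mk_chroms <- function(chroms, lens, seqs) {
    lapply(names(chroms), function(chrom) {
      cen <- if (chrom %in% plan$acentric) NULL else {
        mid <- floor(lens[[chrom]] / 2)
        c(mid - 2500, mid + 2500)
      }
      tc <- tel_counts[[chrom]]
      chromosome(id = chrom, length = lens[[chrom]],
                 sequence = if (is.null(seqs)) NULL else seqs[[chrom]],
                 centromere = cen,
                 telomere_5p = list(present = TRUE, n = unname(tc["n5"])),
                 telomere_3p = list(present = TRUE, n = unname(tc["n3"])))
    })
  }
  genomeA <- haplotype_genome("A", mk_chroms(plan$chromsA, lensA, seqsA), tracksA)
  genomeB <- haplotype_genome("B", mk_chroms(plan$chromsB, lensB, seqsB), tracksB)

  # --- junction rules, architecture breakpoints, extras catalog ---
  truth <- list(plan = plan, layout = layout, bins = binsA, snps = snps,
                homology = hmap, accessory = accessory,
                compartments = plan$compartments,
                ltr_marker_counts = config$ltr_marker_counts,
                bin_size = config$bin_size)
  if (config$preset == "tr01" && config$acentric_extra) {
    o1 <- config$orphan_chr01b; o12 <- config$orphan_chr12b
    r5 <- segsA[segsA$segment == "R5", ]
    l2 <- segsA[segsA$segment == "L2", ]
    truth$junction_rules <- data.frame(
      id = c("ChrN1", "ChrN2"),
      x_chrom = c("Chr01B", "Chr05B"), x_end = c(o1, 200e3),
      y_chrom = c("Chr12B", "Chr12B"), y_end = c(o12, o12 + 75e3),
      prob = 0.05,
      ref_x_carrier = c("arch:Chr01=B", "arch:Chr05=B"),
      ref_y_carrier = c("extra:Chr12B", "extra:Chr12B"),
      stringsAsFactors = FALSE)
    # copy-number footprints each extra chromosome adds on the evidence frame
    truth$extras_catalog <- list(
      Chr12B = data.frame(chrom = c("Chr12B-C1", r5$chrom),
                          start = c(1, r5$start), end = c(o12, r5$end),
                          stringsAsFactors = FALSE),
      ChrN1 = data.frame(chrom = c("Chr01B-C1", "Chr12B-C1"),
                         start = c(1, 1), end = c(o1, o12),
                         stringsAsFactors = FALSE),
      ChrN2 = data.frame(chrom = c(l2$chrom, "Chr12B-C1", r5$chrom),
                         start = c(l2$start, 1, r5$start),
                         end = c(l2$end, o12, r5$start + 75e3 - 1),
                         stringsAsFactors = FALSE))
    truth$pseudo_chroms <- c(`Chr01B-C1` = o1, `Chr12B-C1` = o12)
    arch_segs <- c(Chr01 = "L1", Chr02 = "L2", Chr05 = "R5")
    truth$arch_breakpoints <- data.frame(
      breakpoint = c("bpChr01", "bpChr02", "bpChr05"),
      chrom = c("Chr01", "Chr02", "Chr05"),
      stringsAsFactors = FALSE)
  } else {
    truth$junction_rules <- data.frame()
    truth$extras_catalog <- list()
    truth$pseudo_chroms <- numeric(0)
    truth$arch_breakpoints <- data.frame(breakpoint = character(0),
                                         chrom = character(0))
  }
  list(genomeA = genomeA, genomeB = genomeB, truth = truth, config = config)
}

# ---- spore genotypes --------------------------------------------------------

#' Construct a monospore-isolate genotype
#'
#' The genotype of a haploid meiotic product, expressed against the
#' haplotype-A reference frame: an origin map assigning each locus of the A
#' frame to its source nucleus, the set of extra (acentric) chromosomes
#' carried, per-chromosome architecture, optional karyotype-mixture weights
#' (a monospore culture may be a population of cells with different
#' karyotypes), and optional loss-of-heterozygosity intervals on the extra
#' chromosome.
#'
#' @param isolate Isolate id.
#' @param origin_map Data frame `chrom`, `start`, `end`, `origin` (`"A"` or
#'   `"B"`), tiling each A-frame chromosome.
#' @param extras Character vector of extra-chromosome names (must exist in
#'   the truth's extras catalog when evidence is simulated).
#' @param arch Named character vector of per-chromosome architecture for the
#'   rearranged chromosomes, e.g. `c(Chr01 = "A", Chr02 = "A", Chr05 = "A")`.
#' @param mixture Optional list with `weights` (summing to 1) and
#'   `extras_sets` (list of character vectors), describing a karyotype
#'   mixture; `extras` is ignored when `mixture` is given.
#' @param loh Optional data frame `chrom`, `start`, `end` of intervals where
#'   the extra chromosome's sequence has been replaced by the A haplotype.
#' @param cnv Optional data frame `chrom`, `start`, `end`, `copies` of
#'   whole-region copy-number overrides on the A frame (e.g. a lost
#'   accessory chromosome at 0 copies).
#' @param b_specific B-specific orphan pseudo-chromosomes carried as part of
#'   the base complement (not extras). Defaults from the architecture: a
#'   B-arranged Chr01 carries `"Chr01B-C1"`, a B-arranged Chr05 complement
#'   carries the intact acentric chromosome and hence `"Chr12B-C1"`.
#' @return Object of class `spore_genotype`.
#' @export
spore_genotype <- function(isolate, origin_map, extras = character(0),
                           arch = c(Chr01 = "A", Chr02 = "A", Chr05 = "A"),
                           mixture = NULL, loh = NULL, cnv = NULL,
                           b_specific = NULL) {
  stopifnot(all(origin_map$origin %in% c("A", "B")))
  if (!is.null(mixture)) {
    stopifnot(abs(sum(mixture$weights) - 1) < 1e-8,
              length(mixture$weights) == length(mixture$extras_sets))
  }
  if (is.null(b_specific)) {
    b_specific <- c(if (identical(unname(arch["Chr01"]), "B")) "Chr01B-C1",
                    if (identical(unname(arch["Chr05"]), "B")) "Chr12B-C1")
    if (is.null(b_specific)) b_specific <- character(0)
  }
  structure(list(isolate = isolate, origin_map = origin_map, extras = extras,
                 arch = arch, mixture = mixture, loh = loh, cnv = cnv,
                 b_specific = b_specific),
            class = "spore_genotype")
}

# mixture members as (weights, extras_sets); a plain genotype is a 1-member mixture
genotype_members <- function(genotype) {
  if (is.null(genotype$mixture)) {
    list(weights = 1, extras_sets = list(genotype$extras))
  } else {
    genotype$mixture
  }
}

origin_at <- function(origin_map, chrom, pos) {
  hit <- origin_map$chrom == chrom & origin_map$start <= pos &
    origin_map$end >= pos
  if (!any(hit)) return(NA_character_)
  origin_map$origin[which(hit)[1]]
}

# expected copy number contributed by extras at an evidence-frame location,
# split by allele origin; honors mixtures and LOH
extra_copies_at <- function(genotype, truth, chrom, pos) {
  mem <- genotype_members(genotype)
  cB <- 0; cA <- 0
  for (k in seq_along(mem$weights)) {
    for (ex in mem$extras_sets[[k]]) {
      fp <- truth$extras_catalog[[ex]]
      if (is.null(fp)) stop("unknown extra chromosome '", ex, "'")
      hit <- fp$chrom == chrom & fp$start <= pos & fp$end >= pos
      if (any(hit)) {
        is_loh <- !is.null(genotype$loh) &&
          any(genotype$loh$chrom == chrom & genotype$loh$start <= pos &
                genotype$loh$end >= pos)
        if (is_loh) cA <- cA + mem$weights[k] else cB <- cB + mem$weights[k]
      }
    }
  }
  c(A = cA, B = cB)
}

#' Simulate sequencing evidence for a monospore isolate
#'
#' Produces the three observables the genotyping pipeline consumes, under
#' the planted truth of a generated dikaryon:
#' * per-bin diagnostic-allele counts on informative A-frame bins
#'   (`n ~ Poisson(coverage x copies)`, `nA ~ Binomial(n, pA)` where `pA`
#'   follows the true origin with flip rate `allele_error`);
#' * per-window mean depth on the evidence frame (A chromosomes plus the
#'   B-specific orphan pseudo-chromosomes), `~ Poisson(coverage x copies)`
#'   with karyotype mixtures entering as weight-averaged copy numbers;
#' * junction-spanning read counts for every cataloged junction, with
#'   reference-span counts at the two broken sites emitted only when an
#'   intact carrier molecule is present; plus architecture-breakpoint
#'   spanning counts.
#'
#' @param genotype A [spore_genotype()].
#' @param truth Truth object from [generate_dikaryon()].
#' @param coverage Mean haploid sequencing depth (default 30).
#' @param allele_error Diagnostic-allele flip rate (default 0.01).
#' @param read_length Nominal read length (bases); recorded in the output.
#' @param seed Integer seed.
#' @return List of class `evidence_set` with data frames `bin_counts`,
#'   `depth`, `junctions`, `arch_breakpoints`.
#' @export
simulate_evidence <- function(genotype, truth, coverage = 30,
                              allele_error = 0.01, read_length = 150,
                              seed = 1L) {
  stopifnot(coverage > 0, allele_error >= 0, allele_error <= 1)
  withr::with_seed(as.integer(seed), {
    bins <- truth$bins
    mid <- floor((bins$start + bins$end) / 2)

    # per-bin expected copies by allele origin
    base_origin <- vapply(seq_len(nrow(bins)), function(i)
      origin_at(genotype$origin_map, bins$chrom[i], mid[i]), character(1))
    base_origin[is.na(base_origin)] <- "A"
    cnv_mult <- rep(1, nrow(bins))
    if (!is.null(genotype$cnv)) {
      for (j in seq_len(nrow(genotype$cnv))) {
        cv <- genotype$cnv[j, ]
        hit <- bins$chrom == cv$chrom & mid >= cv$start & mid <= cv$end
        cnv_mult[hit] <- cv$copies
      }
    }
    extra <- t(vapply(seq_len(nrow(bins)), function(i)
      extra_copies_at(genotype, truth, bins$chrom[i], mid[i]), numeric(2)))
    cA <- ifelse(base_origin == "A", 1, 0) * cnv_mult + extra[, "A"]
    cB <- ifelse(base_origin == "B", 1, 0) * cnv_mult + extra[, "B"]
    ctot <- cA + cB

    n <- stats::rpois(nrow(bins), coverage * ctot)
    pA <- ifelse(ctot > 0,
                 (cA * (1 - allele_error) + cB * allele_error) / ctot, 0.5)
    nA <- stats::rbinom(nrow(bins), n, pA)
    bin_counts <- data.frame(isolate = genotype$isolate, chrom = bins$chrom,
                             bin_start = bins$start, bin_end = bins$end,
                             informative = bins$informative,
                             nA = ifelse(bins$informative, nA, 0L),
                             nB = ifelse(bins$informative, n - nA, 0L),
                             stringsAsFactors = FALSE)

    # depth windows: A-frame bins plus pseudo-chromosome windows
    pseudo <- truth$pseudo_chroms
    pbins <- if (length(pseudo)) do.call(rbind, lapply(names(pseudo), function(pc) {
      starts <- seq(1, pseudo[[pc]], by = truth$bin_size)
      data.frame(chrom = pc, start = starts,
                 end = pmin(starts + truth$bin_size - 1, pseudo[[pc]]),
                 stringsAsFactors = FALSE)
    })) else NULL
    all_w <- rbind(bins[, c("chrom", "start", "end")],
                   if (is.null(pbins)) NULL else pbins)
    wmid <- floor((all_w$start + all_w$end) / 2)
    wcopies <- vapply(seq_len(nrow(all_w)), function(i) {
      ch <- all_w$chrom[i]
      if (ch %in% names(pseudo)) {
        sum(extra_copies_at(genotype, truth, ch, wmid[i])) +
          as.numeric(ch %in% genotype$b_specific)
      } else {
        j <- which(bins$chrom == ch & bins$start == all_w$start[i])
        ctot[j[1]]
      }
    }, numeric(1))
    depth <- data.frame(isolate = genotype$isolate, chrom = all_w$chrom,
                        window_start = all_w$start, window_end = all_w$end,
                        depth = stats::rpois(nrow(all_w), coverage * wcopies),
                        stringsAsFactors = FALSE)

    # junction evidence
    jr <- truth$junction_rules
    junctions <- NULL
    if (nrow(jr)) {
      mem <- genotype_members(genotype)
      carried_w <- vapply(jr$id, function(id)
        sum(mem$weights[vapply(mem$extras_sets, function(s) id %in% s, logical(1))]),
        numeric(1))
      carrier_present <- function(spec) {
        if (startsWith(spec, "arch:")) {
          kv <- strsplit(sub("arch:", "", spec), "=")[[1]]
          identical(unname(genotype$arch[kv[1]]), kv[2])
        } else if (startsWith(spec, "extra:")) {
          ex <- sub("extra:", "", spec)
          carried_extra <- any(vapply(mem$extras_sets, function(s)
            ex %in% s, logical(1)))
          # an intact base copy (B-architecture complement) also spans the
          # reference junction
          carried_base <- ex == "Chr12B" && "Chr12B-C1" %in% genotype$b_specific
          carried_extra || carried_base
        } else FALSE
      }
      refx <- vapply(jr$ref_x_carrier, carrier_present, logical(1))
      refy <- vapply(jr$ref_y_carrier, carrier_present, logical(1))
      junctions <- data.frame(
        isolate = genotype$isolate, junction = jr$id,
        x_chrom = jr$x_chrom, x_pos = jr$x_end,
        y_chrom = jr$y_chrom, y_pos = jr$y_end,
        support = stats::rpois(nrow(jr), coverage * carried_w),
        ref_span_x = ifelse(refx, stats::rpois(nrow(jr), coverage), 0L),
        ref_span_y = ifelse(refy, stats::rpois(nrow(jr), coverage), 0L),
        stringsAsFactors = FALSE)
    }

    # architecture-breakpoint spanning evidence
    ab <- truth$arch_breakpoints
    arch_ev <- NULL
    if (nrow(ab)) {
      isA <- genotype$arch[ab$chrom] == "A"
      arch_ev <- data.frame(
        isolate = genotype$isolate, breakpoint = ab$breakpoint,
        chrom = ab$chrom,
        supportA = ifelse(isA, stats::rpois(nrow(ab), coverage), 0L),
        supportB = ifelse(!isA, stats::rpois(nrow(ab), coverage), 0L),
        stringsAsFactors = FALSE)
    }

    structure(list(isolate = genotype$isolate, bin_counts = bin_counts,
                   depth = depth, junctions = junctions,
                   arch_breakpoints = arch_ev, coverage = coverage,
                   read_length = read_length),
              class = "evidence_set")
  })
}

#' Draw a random recombinant spore genotype with planted origin switches
#'
#' Places a configurable number of haplotype-origin switches per isolate at
#' boundaries between adjacent informative bins (switches inside
#' low-heterozygosity runs are undetectable by construction, as in the real
#' analysis), at least `min_gap_bins` bins apart.
#'
#' @param truth Truth object from [generate_dikaryon()].
#' @param isolate Isolate id.
#' @param n_switches Total origin switches to plant.
#' @param min_gap_bins Minimum separation between switches, in bins.
#' @param extras,arch,mixture,loh,cnv Passed to [spore_genotype()].
#' @param seed Integer seed.
#' @return List with `genotype` ([spore_genotype()]) and `breakpoints`
#'   (data frame `chrom`, `pos` of the planted switch coordinates).
#' @export
random_spore_genotype <- function(truth, isolate = "iso1", n_switches = 3,
                                  min_gap_bins = 3, extras = character(0),
                                  arch = c(Chr01 = "A", Chr02 = "A", Chr05 = "A"),
                                  mixture = NULL, loh = NULL, cnv = NULL,
                                  b_specific = NULL, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    bins <- truth$bins
    # candidate switch sites: boundaries inside a run of >= 4 informative
    # bins, so both flanking homozygous runs are detectable (switches in
    # low-heterozygosity stretches are invisible to origin calling, as in
    # the real analysis)
    cand <- do.call(rbind, lapply(unique(bins$chrom), function(ch) {
      b <- bins[bins$chrom == ch, ]
      n <- nrow(b)
      if (n < 4) return(NULL)
      i <- 2:(n - 2)
      i <- i[b$informative[i - 1] & b$informative[i] & b$informative[i + 1] &
               b$informative[i + 2]]
      if (!length(i)) return(NULL)
      data.frame(chrom = ch, pos = b$end[i], bin_index = i,
                 stringsAsFactors = FALSE)
    }))
    picked <- NULL
    pool <- cand
    while (nrow(pool) && (is.null(picked) || nrow(picked) < n_switches)) {
      j <- sample.int(nrow(pool), 1)
      p <- pool[j, ]
      picked <- rbind(picked, p)
      far <- !(pool$chrom == p$chrom &
                 abs(pool$bin_index - p$bin_index) < min_gap_bins)
      pool <- pool[far, , drop = FALSE]
    }
    if (is.null(picked) || nrow(picked) < n_switches) {
      stop("not enough informative-bin boundaries for the requested switches")
    }
    # origin map: alternate origins between consecutive switches per chromosome
    om <- do.call(rbind, lapply(unique(bins$chrom), function(ch) {
      len <- max(bins$end[bins$chrom == ch])
      cuts <- sort(picked$pos[picked$chrom == ch])
      starts <- c(1, cuts + 1)
      ends <- c(cuts, len)
      first <- sample(c("A", "B"), 1)
      orig <- rep(c(first, setdiff(c("A", "B"), first)),
                  length.out = length(starts))
      data.frame(chrom = ch, start = starts, end = ends, origin = orig,
                 stringsAsFactors = FALSE)
    }))
    list(genotype = spore_genotype(isolate, om, extras = extras, arch = arch,
                                   mixture = mixture, loh = loh, cnv = cnv,
                                   b_specific = b_specific),
         breakpoints = picked[, c("chrom", "pos")])
  })
}

#' Write an evidence set to TSV files
#'
#' One file per observable: `<isolate>_bins.tsv`, `<isolate>_depth.tsv`,
#' `<isolate>_junctions.tsv`, `<isolate>_arch.tsv`.
#'
#' @param evidence An `evidence_set` from [simulate_evidence()].
#' @param dir Output directory (created if needed).
#' @return Character vector of paths written, invisibly.
#' @export
write_evidence_tsv <- function(evidence, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in c("bin_counts", "depth", "junctions", "arch_breakpoints")) {
    x <- evidence[[nm]]
    if (is.null(x)) next
    suffix <- c(bin_counts = "bins", depth = "depth", junctions = "junctions",
                arch_breakpoints = "arch")[[nm]]
    p <- file.path(dir, paste0(evidence$isolate, "_", suffix, ".tsv"))
    write_tsv(x, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
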