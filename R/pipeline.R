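# End-to-end orchestration over the synthetic cohort: simulate -> genotype
# -> cnv -> junctions -> karyotype -> report, with a single seed fanned out
# to per-stage child seeds and a written run manifest.

#' Pipeline configuration
#'
#' @param outdir Output directory.
#' @param seed Master seed; stage s uses child seed `seed * 100 + s`
#'   (documented fixed derivation so stages can be rerun in isolation).
#' @param dikaryon A [dikaryon_config()]; its own seed is replaced by the
#'   simulate-stage child seed.
#' @param cohort Named integer vector of isolate counts per planted class:
#'   `euploid_A`, `euploid_B`, `typeI`, `typeII`, `typeIII`, `typeIV`.
#'   The default mirrors the observed cohort composition (33 isolates,
#'   14 aneuploid).
#' @param coverage,allele_error Evidence-simulation parameters.
#' @param n_switches Planted recombination switches per isolate.
#' @param min_reads,purity,min_run,merge_distance Genotyping thresholds
#'   (see [classify_bins()], [call_events()], [aggregate_sites()]).
#' @param grid_tolerance,min_support CNV and junction thresholds.
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L,
                            dikaryon = dikaryon_config(),
                            cohort = c(euploid_A = 17, euploid_B = 2,
                                       typeI = 8, typeII = 1, typeIII = 2,
                                       typeIV = 3),
                            coverage = 30, allele_error = 0.01,
                            n_switches = 3, min_reads = 5, purity = 0.9,
                            min_run = 2, merge_distance = 10,
                            grid_tolerance = 0.1, min_support = 3) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  structure(list(outdir = outdir, seed = as.integer(seed),
                 dikaryon = dikaryon, cohort = cohort, coverage = coverage,
                 allele_error = allele_error, n_switches = n_switches,
                 min_reads = min_reads, purity = purity, min_run = min_run,
                 merge_distance = merge_distance,
                 grid_tolerance = grid_tolerance, min_support = min_support),
            class = "run_config")
}

stage_seed <- function(config, stage) config$seed * 100L + stage

# planted cohort of spore genotypes mirroring the study composition
build_cohort <- function(truth, config) {
  cls <- rep(names(config$cohort), times = config$cohort)
  n <- length(cls)
  isolates <- sprintf("SIM%02d", seq_len(n))
  arm <- truth$extras_catalog$Chr12B
  arm <- arm[!arm$chrom %in% names(truth$pseudo_chroms), ][1, ]
  genos <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    extras <- switch(cls[i], typeI = "Chr12B", typeII = "ChrN1",
                     typeIII = "ChrN2", typeIV = c("Chr12B", "ChrN1"),
                     character(0))
    arch <- if (cls[i] == "euploid_B") {
      c(Chr01 = "B", Chr02 = "B", Chr05 = "B")
    } else c(Chr01 = "A", Chr02 = "A", Chr05 = "A")
    mixture <- NULL
    if (cls[i] == "typeII" && !any(cls[seq_len(i - 1)] == "typeII")) {
      # one isolate is a karyotype mixture: 80% of cells carry two copies
      # of the new chromosome (expected ratio 1.8)
      mixture <- list(weights = c(0.2, 0.8),
                      extras_sets = list("ChrN1", c("ChrN1", "ChrN1")))
    }
    loh <- NULL
    if (cls[i] == "typeI" && sum(cls[seq_len(i)] == "typeI") == 1) {
      # one extra-chromosome carrier shows loss of heterozygosity over part
      # of the shared arm
      mid <- floor((arm$start + arm$end) / 2)
      loh <- data.frame(chrom = arm$chrom, start = arm$start, end = mid)
    }
    cnv <- NULL
    if (cls[i] == "euploid_A") {
      k <- sum(cls[seq_len(i)] == "euploid_A")
      if (k == 1) {  # whole accessory-chromosome loss
        cnv <- data.frame(chrom = "Chr09A", start = 1, end = 80e3, copies = 0)
      } else if (k == 2) {  # halved accessory-chromosome dosage (mixture)
        cnv <- data.frame(chrom = "Chr11A", start = 1, end = 50e3, copies = 0.5)
      } else if (k == 3) {  # dosage increased by about half
        cnv <- data.frame(chrom = "Chr11A", start = 1, end = 50e3, copies = 1.5)
      }
    }
    rg <- random_spore_genotype(
      truth, isolate = isolates[i], n_switches = config$n_switches,
      extras = extras, arch = arch, mixture = mixture, loh = loh, cnv = cnv,
      seed = stage_seed(config, 1L) + i)
    if (cls[i] == "euploid_B") {
      # the B complement carries the acentric arm copy: its arm locus reads
      # are B-origin
      om <- rg$genotype$origin_map
      om$origin[om$chrom == arm$chrom] <- ifelse(
        om$chrom[om$chrom == arm$chrom] == arm$chrom &
          om$start[om$chrom == arm$chrom] >= arm$start, "B",
        om$origin[om$chrom == arm$chrom])
      rg$genotype$origin_map <- om
    }
    genos[[i]] <- rg$genotype
    truths[[i]] <- data.frame(isolate = isolates[i], class = cls[i],
                              rg$breakpoints, stringsAsFactors = FALSE)
  }
  list(genotypes = genos, breakpoints = do.call(rbind, truths),
       classes = stats::setNames(cls, isolates))
}

# baseline regions for depth normalization: core A-frame segments not
# involved in extra-chromosome footprints
baseline_regions_from_truth <- function(truth) {
  lay <- truth$layout
  segA <- lay[lay$haplotype == "A", ]
  cls <- stats::setNames(truth$plan$segments$class, truth$plan$segments$segment)
  fp_regions <- do.call(rbind, truth$extras_catalog)
  core <- segA[cls[segA$segment] == "core", ]
  keep <- vapply(seq_len(nrow(core)), function(i) {
    r <- core[i, ]
    if (is.null(fp_regions)) return(TRUE)
    !any(fp_regions$chrom == r$chrom & fp_regions$start <= r$end &
           fp_regions$end >= r$start)
  }, logical(1))
  core[keep, c("chrom", "start", "end")]
}

#' Run the full pipeline on a synthetic cohort
#'
#' Stages execute in dependency order: simulate (dikaryon + cohort
#' evidence), genotype (bin origin calls, events, sites, origin fractions),
#' cnv (normalized ratios, whole-chromosome calls, LOH), junctions
#' (validated junctions, extra-chromosome calls), karyotype (architecture +
#' aneuploidy typing), report. All tables are written as TSV under
#' `config$outdir`, a JSON summary and a manifest (inputs, parameters,
#' seeds, output checksums) alongside. Re-running with an identical config
#' reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return List with `tables` (all result data frames), `report` (from
#'   [make_report()]), `manifest`, invisibly also written to disk.
#' @export
run_pipeline <- function(config) {
  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)
  # stage 1: simulate
  dk_config <- config$dikaryon
  dk_config$seed <- stage_seed(config, 0L)
  dk <- generate_dikaryon(dk_config)
  truth <- dk$truth
  cohort <- build_cohort(truth, config)
  evidence <- lapply(seq_along(cohort$genotypes), function(i)
    simulate_evidence(cohort$genotypes[[i]], truth,
                      coverage = config$coverage,
                      allele_error = config$allele_error,
                      seed = stage_seed(config, 2L) + i))
  names(evidence) <- names(cohort$classes)

  # stage 2: genotype
  all_calls <- list(); all_events <- list(); ofr <- list()
  for (ev in evidence) {
    calls <- classify_bins(ev$bin_counts, min_reads = config$min_reads,
                           purity = config$purity)
    all_calls[[ev$isolate]] <- calls
    all_events[[ev$isolate]] <- call_events(calls, min_run = config$min_run)
    f <- origin_fraction(calls)
    ofr[[ev$isolate]] <- data.frame(isolate = ev$isolate, pctA = f$pctA,
                                    pctB = f$pctB, pctHET = f$pctHET)
  }
  events <- do.call(rbind, all_events)
  sites <- aggregate_sites(events, merge_distance = config$merge_distance)
  origin_fractions <- do.call(rbind, ofr)

  # stage 3: cnv
  baseline <- baseline_regions_from_truth(truth)
  ratios <- list(); cnv_calls <- list(); loh_calls <- list()
  for (ev in evidence) {
    r <- normalize_depth(ev$depth, baseline)
    ratios[[ev$isolate]] <- r
    onA <- r[!r$chrom %in% names(truth$pseudo_chroms), ]
    wc <- call_whole_chromosome_aneuploidy(
      data.frame(chrom = onA$chrom, ratio = onA$ratio),
      grid_tolerance = config$grid_tolerance)
    if (nrow(wc)) {
      wc$isolate <- ev$isolate
      cnv_calls[[ev$isolate]] <- wc
    }
  }
  cnv_calls <- if (length(cnv_calls)) do.call(rbind, cnv_calls) else
    data.frame(isolate = character(0), chrom = character(0),
               state = numeric(0), change = character(0))

  # stage 4: junctions + extras
  extras_called <- list()
  for (ev in evidence) {
    extras_called[[ev$isolate]] <- call_extras(
      ratios[[ev$isolate]], ev$junctions, truth,
      min_support = config$min_support,
      grid_tolerance = config$grid_tolerance)
  }
  # LOH on extra-chromosome carriers (shared arm expected heterozygous)
  arm <- truth$extras_catalog$Chr12B
  if (!is.null(arm)) {
    arm <- arm[!arm$chrom %in% names(truth$pseudo_chroms), ][1, ]
    for (iso in names(extras_called)) {
      if (!"Chr12B" %in% extras_called[[iso]]) next
      calls <- all_calls[[iso]]
      reg <- calls[calls$chrom == arm$chrom & calls$bin_start >= arm$start &
                     calls$bin_end <= arm$end, ]
      lo <- detect_loh(reg, min_run = 3)
      if (nrow(lo)) {
        lo$isolate <- iso
        loh_calls[[iso]] <- lo
      }
    }
  }
  loh_calls <- if (length(loh_calls)) do.call(rbind, loh_calls) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               n_bins = integer(0), isolate = character(0))

  # stage 5: karyotype
  base_count_A <- length(unique(truth$layout$chrom[truth$layout$haplotype == "A"]))
  base_count_B <- length(unique(truth$layout$chrom[truth$layout$haplotype == "B"]))
  kary <- list()
  for (ev in evidence) {
    arch <- assign_architecture(ev$arch_breakpoints,
                                min_support = config$min_support)
    extras <- extras_called[[ev$isolate]]
    base <- if (arch$architecture == "B") base_count_B else base_count_A
    kc <- type_aneuploidy(extras, arch$architecture, base_chromosomes = base)
    kary[[ev$isolate]] <- data.frame(
      isolate = ev$isolate, architecture = kc$architecture,
      extras = paste(kc$extras, collapse = ","),
      aneuploidy_type = kc$aneuploidy_type,
      chromosome_count = kc$chromosome_count, stringsAsFactors = FALSE)
  }
  karyotypes <- do.call(rbind, kary)

  tables <- list(events = events, sites = sites,
                 origin_fractions = origin_fractions, cnv_calls = cnv_calls,
                 loh = loh_calls, karyotypes = karyotypes,
                 planted_breakpoints = cohort$breakpoints,
                 planted_classes = data.frame(isolate = names(cohort$classes),
                                              class = unname(cohort$classes)))
  report <- make_report(karyotypes, origin_fractions, sites, cnv_calls)

  # stage 6: write everything + manifest
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(config$outdir, paste0(nm, ".tsv"))
    write_tsv(tables[[nm]], p)
    paths <- c(paths, p)
  }
  sp <- file.path(config$outdir, "summary.json")
  jsonlite::write_json(report$summary, sp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths <- c(paths, sp)
  manifest <- list(
    seed = config$seed,
    stage_seeds = stats::setNames(as.list(config$seed * 100L + 0:5),
                                  paste0("stage", 0:5)),
    parameters = config[setdiff(names(config), c("outdir", "dikaryon"))],
    outputs = lapply(paths, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  mp <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(tables = tables, report = report, manifest = manifest,
                 truth = truth, evidence = evidence, cohort = cohort))
}

#' Build the cohort report from stage outputs
#'
#' Produces the per-isolate karyotype table plus cohort summaries: counts
#' and fractions per aneuploidy type, the chromosome-count distribution of
#' A-architecture isolates, hotspot counts and mean origin fractions. The
#' report refuses inconsistent inputs (mismatched isolate sets, type counts
#' that do not sum to the aneuploid total).
#'
#' @param karyotypes Data frame with `isolate`, `architecture`,
#'   `aneuploidy_type`, `chromosome_count`.
#' @param origin_fractions Data frame with `isolate`, `pctA`, `pctB`,
#'   `pctHET` (optional, may be NULL).
#' @param sites [aggregate_sites()] output (optional).
#' @param cnv_calls Whole-chromosome CNV table (optional).
#' @return List with `karyotypes` and `summary`.
#' @export
make_report <- function(karyotypes, origin_fractions = NULL, sites = NULL,
                        cnv_calls = NULL) {
  if (!is.null(origin_fractions)) {
    if (!setequal(karyotypes$isolate, origin_fractions$isolate)) {
      miss <- c(setdiff(karyotypes$isolate, origin_fractions$isolate),
                setdiff(origin_fractions$isolate, karyotypes$isolate))
      stop("isolate lists disagree between karyotypes and origin fractions: ",
           paste(miss, collapse = ", "))
    }
  }
  n <- nrow(karyotypes)
  type_counts <- table(factor(karyotypes$aneuploidy_type,
                              levels = c("euploid", "I", "II", "III", "IV",
                                         "other")))
  n_aneuploid <- sum(type_counts[c("I", "II", "III", "IV", "other")])
  if (n_aneuploid != sum(karyotypes$aneuploidy_type != "euploid")) {
    stop("aneuploidy type counts inconsistent with the karyotype table")
  }
  archA <- karyotypes[karyotypes$architecture == "A", ]
  chrom_count_A <- table(archA$chromosome_count)
  summary <- list(
    n_isolates = n,
    n_aneuploid = n_aneuploid,
    aneuploid_pct = round(100 * n_aneuploid / n, 1),
    type_counts = as.list(type_counts),
    n_architecture_A = sum(karyotypes$architecture == "A"),
    n_architecture_B = sum(karyotypes$architecture == "B"),
    chromosome_counts_architecture_A = as.list(chrom_count_A),
    n_sites = if (is.null(sites)) NA else nrow(sites),
    n_hotspots = if (is.null(sites)) NA else sum(sites$hotspot),
    n_cnv_calls = if (is.null(cnv_calls)) NA else nrow(cnv_calls),
    mean_pctA = if (is.null(origin_fractions)) NA else
      mean(origin_fractions$pctA))
  list(karyotypes = karyotypes, summary = summary)
}

# ---- study fixtures (printed tables shipped as data) ------------------------

dikaryon_extdata <- function(file) {
  system.file("extdata", file, package = "dikaryon", mustWork = TRUE)
}

#' Load the printed chromosome table of the study dikaryon
#'
#' Chromosome ids, per-haplotype sizes (Mb-precision, as printed), gene
#' counts, centromere presence and telomere state. Coordinate-only
#' chromosome models built from it carry synthetic mid-chromosome
#' centromere placements (the printed table gives presence, not position).
#'
#' @return Data frame.
#' @export
tr01_chromosome_table <- function() read_tsv(dikaryon_extdata("tr01_chromosomes.tsv"))

#' Coordinate-only haplotype genomes of the study dikaryon
#'
#' Builds [haplotype_genome()] objects (no sequence) from the printed
#' chromosome table, for coordinate arithmetic such as new-chromosome
#' reconstruction.
#'
#' @return List with elements `A` and `B`.
#' @export
tr01_genomes <- function() {
  tab <- tr01_chromosome_table()
  build <- function(h) {
    rows <- tab[tab$haplotype == h, ]
    haplotype_genome(h, lapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      len <- r$length_bp
      cen <- if (r$has_centromere) {
        mid <- floor(len / 2)
        c(mid - 20e3, mid + 20e3)  # synthetic placement, 40-kb width
      } else NULL
      chromosome(id = r$chrom, length = len, centromere = cen,
                 telomere_5p = list(present = r$telomere_5p, n = 30L),
                 telomere_3p = list(present = r$telomere_3p, n = 30L))
    }))
  }
  list(A = build("A"), B = build("B"))
}

#' Printed new-chromosome segment catalog
#'
#' The component segments (with orientations) of the new chromosomes
#' observed in monospore isolates.
#'
#' @return Data frame with `id`, `part`, `chrom`, `start`, `end`, `orient`.
#' @export
tr01_new_chromosome_catalog <- function() {
  read_tsv(dikaryon_extdata("tr01_new_chromosomes.tsv"))
}

#' Printed extra-chromosome sizes (Mb)
#'
#' @return Named numeric vector.
#' @export
tr01_extra_sizes <- function() {
  x <- read_tsv(dikaryon_extdata("tr01_extra_sizes.tsv"))
  stats::setNames(x$size_mb, x$name)
}

#' The monospore-isolate karyotype table
#'
#' The 14 aneuploid isolates and the two B-architecture isolates carry
#' their printed ids; the remaining A-architecture euploid ids were not
#' printed and are filled with synthetic ids (`id_source` column).
#'
#' @return Data frame with `isolate`, `architecture`, `extras`,
#'   `aneuploidy_type`, `id_source`.
#' @export
tr01_karyotype_table <- function() {
  read_tsv(dikaryon_extdata("tr01_monospore_karyotypes.tsv"))
}

#' Reconstruct the cataloged new chromosomes against the study genomes
#'
#' @param sequence Ignored (the printed genomes are coordinate-only).
#' @return Named list of [new_chromosome_model()]s.
#' @export
tr01_reconstruct_new_chromosomes <- function(sequence = FALSE) {
  cat_tab <- tr01_new_chromosome_catalog()
  genomes <- tr01_genomes()
  out <- list()
  for (id in unique(cat_tab$id)) {
    rows <- cat_tab[cat_tab$id == id, ]
    rows <- rows[order(rows$part), ]
    segs <- lapply(seq_len(nrow(rows)), function(i)
      oriented_segment(rows$chrom[i], rows$start[i], rows$end[i],
                       rows$orient[i]))
    out[[id]] <- reconstruct_new_chromosome(id, segs, genomes)
  }
  out
}
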