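test_that("generation is fully deterministic under a fixed seed", {
  a <- generate_dikaryon(dikaryon_config(seed = 9))
  b <- generate_dikaryon(dikaryon_config(seed = 9))
  expect_identical(a$genomeA$chromosomes$Chr01A$sequence,
                   b$genomeA$chromosomes$Chr01A$sequence)
  expect_identical(a$truth$snps, b$truth$snps)
  expect_identical(a$truth$bins, b$truth$bins)
  g1 <- simulate_evidence(
    random_spore_genotype(a$truth, seed = 3)$genotype, a$truth, seed = 5)
  g2 <- simulate_evidence(
    random_spore_genotype(b$truth, seed = 3)$genotype, b$truth, seed = 5)
  expect_identical(g1$bin_counts, g2$bin_counts)
  expect_identical(g1$depth, g2$depth)
})

test_that("zero heterozygosity and no asymmetry give identical haplotype sequences", {
  cfg <- dikaryon_config(
    preset = "collinear", n_chromosomes = 2, chrom_length = 1e5,
    heterozygosity_mosaic = data.frame(fraction = 1, snp_per_bp = 0),
    seed = 3)
  dk <- generate_dikaryon(cfg)
  expect_equal(length(dk$genomeA$chromosomes), length(dk$genomeB$chromosomes))
  for (i in seq_along(dk$genomeA$chromosomes)) {
    expect_identical(dk$genomeA$chromosomes[[i]]$sequence,
                     dk$genomeB$chromosomes[[i]]$sequence)
  }
  expect_equal(nrow(dk$truth$snps), 0)
})

test_that("the asymmetric preset plants the acentric extra chromosome correctly", {
  dk <- shared_dikaryon()
  expect_equal(length(dk$genomeB$chromosomes),
               length(dk$genomeA$chromosomes) + 1)
  extra <- dk$genomeB$chromosomes$Chr12B
  expect_null(extra$centromere)
  # most of the extra chromosome is homologous to the donor arm
  hm <- dk$truth$homology
  donor <- hm[hm$chromB == "Chr12B", ]
  expect_gte(sum(interval_len(donor$startB, donor$endB)) / extra$length, 0.8)
  expect_equal(donor$chromA, "Chr05A")
  # all ends telomere-capped, with counts in the configured range
  for (g in list(dk$genomeA, dk$genomeB)) {
    for (ch in g$chromosomes) {
      got5 <- detect_telomere(substr(ch$sequence, 1, 400), "5p")
      got3 <- detect_telomere(substr(ch$sequence, ch$length - 399, ch$length),
                              "3p")
      expect_true(got5$present)
      expect_true(got3$present)
      expect_equal(got5$repeat_count, ch$telomere_5p$n)
      expect_equal(got3$repeat_count, ch$telomere_3p$n)
    }
  }
})

test_that("realized per-bin SNP densities recover the configured mosaic", {
  cfg <- dikaryon_config(
    preset = "collinear", n_chromosomes = 2, chrom_length = 5e6,
    heterozygosity_mosaic = data.frame(fraction = c(0.2, 0.8),
                                       snp_per_bp = c(0.0005, 0.02)),
    emit_sequence = FALSE, seed = 21)
  dk <- generate_dikaryon(cfg)
  bins <- dk$truth$bins
  expect_equal(nrow(bins), 1000)
  realized <- bins$n_snps / interval_len(bins$start, bins$end)
  # classify realized densities at the class midpoint
  frac_low <- mean(realized < 0.01)
  se <- sqrt(0.2 * 0.8 / nrow(bins))
  expect_lt(abs(frac_low - 0.2), 3 * se)
})

test_that("planted SNPs are exactly the A/B sequence mismatches (re-scan closure)", {
  dk <- shared_dikaryon()
  lay <- dk$truth$layout
  # fully collinear homolog: every mismatch must be a recorded SNP
  a <- strsplit(dk$genomeA$chromosomes$Chr03A$sequence, "")[[1]]
  b <- strsplit(dk$genomeB$chromosomes$Chr03B$sequence, "")[[1]]
  mism <- which(a != b)
  # ignore the telomere cap zones, where independently drawn repeat counts differ
  mism <- mism[mism > 400 & mism <= length(a) - 400]
  planted <- dk$truth$snps$pos[dk$truth$snps$chrom == "Chr03A"]
  expect_identical(mism, as.integer(sort(planted)))
})

test_that("evidence depth is unbiased and allele counts follow the true origin", {
  cfg <- dikaryon_config(
    preset = "collinear", n_chromosomes = 2, chrom_length = 5e6,
    heterozygosity_mosaic = data.frame(fraction = 1, snp_per_bp = 0.02),
    emit_sequence = FALSE, seed = 8)
  dk <- generate_dikaryon(cfg)
  om <- do.call(rbind, lapply(names(dk$genomeA$chromosomes), function(ch)
    data.frame(chrom = ch, start = 1, end = 5e6, origin = "A")))
  gt <- spore_genotype("iso_pureA", om, arch = c())
  ev <- simulate_evidence(gt, dk$truth, coverage = 30, allele_error = 0,
                          seed = 4)
  # over 1000 windows the realized/expected depth ratio is within 3%
  expect_equal(nrow(ev$depth), 1000)
  rel <- mean(ev$depth$depth) / 30
  expect_gte(rel, 0.97)
  expect_lte(rel, 1.03)
  # error-free pure-A genotype: no B alleles anywhere
  expect_true(all(ev$bin_counts$nB == 0))
})

test_that("a two-copy region doubles the expected window depth", {
  dk <- shared_dikaryon_light()
  gt <- random_spore_genotype(dk$truth, extras = "Chr12B", seed = 5)$genotype
  ev <- simulate_evidence(gt, dk$truth, coverage = 30, seed = 6)
  arm <- dk$truth$extras_catalog$Chr12B
  arm <- arm[arm$chrom == "Chr05A", ]
  sel <- ev$depth$chrom == "Chr05A" & ev$depth$window_start >= arm$start
  # base copy may be A- or B-origin; either way the arm totals 2 copies
  n <- sum(sel)
  se <- sqrt(60 / n)
  expect_lt(abs(mean(ev$depth$depth[sel]) - 60), 3 * se)
})

test_that("junction reads appear only for carried joins, with broken reference sites silent", {
  dk <- shared_dikaryon_light()
  gt <- random_spore_genotype(dk$truth, extras = "ChrN1", seed = 9)$genotype
  ev <- simulate_evidence(gt, dk$truth, coverage = 30, seed = 10)
  j <- ev$junctions
  expect_gt(j$support[j$junction == "ChrN1"], 0)
  expect_equal(j$ref_span_x[j$junction == "ChrN1"], 0)
  expect_equal(j$ref_span_y[j$junction == "ChrN1"], 0)
  expect_equal(j$support[j$junction == "ChrN2"], 0)
  # an intact extra chromosome legitimately spans its reference site
  gt2 <- random_spore_genotype(dk$truth, extras = c("Chr12B", "ChrN1"),
                               seed = 11)$genotype
  ev2 <- simulate_evidence(gt2, dk$truth, coverage = 30, seed = 12)
  j2 <- ev2$junctions
  expect_gt(j2$ref_span_y[j2$junction == "ChrN1"], 0)
  expect_equal(j2$ref_span_x[j2$junction == "ChrN1"], 0)
})

test_that("karyotype mixtures produce weight-averaged expected copy numbers", {
  dk <- shared_dikaryon_light()
  mix <- list(weights = c(0.2, 0.8),
              extras_sets = list("ChrN1", c("ChrN1", "ChrN1")))
  gt <- random_spore_genotype(dk$truth, mixture = mix, seed = 13)$genotype
  ev <- simulate_evidence(gt, dk$truth, coverage = 100, seed = 14)
  orphan <- ev$depth[ev$depth$chrom == "Chr01B-C1", ]
  expected <- 100 * 1.8
  se <- sqrt(expected / nrow(orphan))
  expect_lt(abs(mean(orphan$depth) - expected), 3 * se)
})

test_that("generator IO round-trips through FASTA, BED and JSON", {
  dk <- shared_dikaryon()
  td <- withr::local_tempdir()
  fa <- file.path(td, "A.fasta")
  write_genome_fasta(dk$genomeA, fa)
  back <- read_genome_fasta(fa)
  expect_identical(unname(back["Chr03A"]),
                   dk$genomeA$chromosomes$Chr03A$sequence)
  bed <- file.path(td, "genes.bed")
  write_track_bed(dk$genomeA$tracks$genes, bed)
  tr <- read_track_bed(bed)
  expect_equal(tr$start, dk$genomeA$tracks$genes$start)
  expect_equal(tr$end, dk$genomeA$tracks$genes$end)
  js <- file.path(td, "A.json")
  write_genome_metadata(dk$genomeA, js)
  meta <- jsonlite::read_json(js)
  expect_equal(length(meta$chromosomes), length(dk$genomeA$chromosomes))
})
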