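mk_counts <- function(states, bin = 1e4, nA = NULL, nB = NULL, chrom = "Chr01A") {
  n <- length(states)
  if (is.null(nA)) {
    nA <- ifelse(states == "A", 20L, ifelse(states == "HET", 10L, 0L))
    nB <- ifelse(states == "B", 20L, ifelse(states == "HET", 10L, 0L))
  }
  data.frame(isolate = "iso", chrom = chrom,
             bin_start = seq(1, by = bin, length.out = n),
             bin_end = seq(bin, by = bin, length.out = n),
             informative = states != "NA", nA = nA, nB = nB)
}

test_that("bin classification follows the purity/min-reads rules", {
  counts <- mk_counts(c("A", "HET", "NA"), nA = c(20, 10, 1), nB = c(0, 10, 0))
  counts$informative <- c(TRUE, TRUE, TRUE)
  calls <- classify_bins(counts)
  expect_equal(calls$state, c("A", "HET", NA))
  # 18/20 = 0.9 meets purity; 17/20 does not but both alleles >= 10% share
  calls <- classify_bins(mk_counts("A", nA = c(18), nB = c(2)))
  expect_equal(calls$state, "A")
  calls <- classify_bins(mk_counts("A", nA = c(17), nB = c(3)))
  expect_equal(calls$state, "HET")
  # non-informative bins are never called
  counts <- mk_counts("NA", nA = 30, nB = 0)
  expect_true(is.na(classify_bins(counts)$state))
  expect_error(classify_bins(mk_counts("A", nA = -1, nB = 0)), "negative")
})

test_that("raising purity never converts an ambiguous bin to a homozygous call", {
  withr::with_seed(5, {
    n <- 200
    counts <- mk_counts(rep("A", n), nA = rpois(n, 12), nB = rpois(n, 6))
    prev <- classify_bins(counts, purity = 0.7)$state
    for (p in c(0.8, 0.9, 0.95)) {
      cur <- classify_bins(counts, purity = p)$state
      was_ambiguous <- is.na(prev) | prev == "HET"
      expect_false(any(was_ambiguous & cur %in% c("A", "B")))
      prev <- cur
    }
  })
})

test_that("event calling finds transitions and suppresses short runs and gaps", {
  calls <- classify_bins(mk_counts(c(rep("A", 50), rep("B", 50))))
  ev <- call_events(calls)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start, 50 * 1e4)       # end of bin 50
  expect_equal(ev$end, 50 * 1e4 + 1)     # start of bin 51
  expect_equal(ev$left_state, "A")
  expect_equal(ev$right_state, "B")

  expect_equal(nrow(call_events(classify_bins(mk_counts(rep("A", 30))))), 0)

  # single-bin flicker suppressed at min_run = 2
  ev <- call_events(classify_bins(mk_counts(c("A", "A", "B", "A", "A"))))
  expect_equal(nrow(ev), 0)

  # a NA/HET gap between opposite runs yields one event spanning the gap
  ev <- call_events(classify_bins(mk_counts(
    c(rep("A", 5), "NA", "HET", rep("B", 5)))))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start, 5 * 1e4)
  expect_equal(ev$end, 7 * 1e4 + 1)
})

test_that("error-free calls reproduce the true origin transitions exactly", {
  dk <- shared_dikaryon_light()
  for (s in 1:10) {
    rg <- random_spore_genotype(dk$truth, isolate = paste0("iso", s),
                                n_switches = 3, seed = 100 + s)
    ev <- simulate_evidence(rg$genotype, dk$truth, coverage = 60,
                            allele_error = 0, seed = 200 + s)
    # error-free evidence needs no flicker suppression (min_run = 1), so
    # calls must equal the oracle's raw transition set exactly
    got <- call_events(classify_bins(ev$bin_counts), min_run = 1)
    want <- oracle_origin_transitions(rg$genotype, dk$truth)
    expect_equal(nrow(got), nrow(want))
    got <- got[order(got$chrom, got$start), ]
    want <- want[order(want$chrom, want$lo), ]
    expect_equal(got$chrom, want$chrom)
    expect_equal(got$left_state, want$left)
    expect_equal(got$right_state, want$right)
    expect_equal(got$start, want$lo)
    expect_equal(got$end, want$hi)
  }
})

test_that("sites merge within the distance threshold and hotspots need 4 isolates", {
  ev5 <- do.call(rbind, lapply(1:5, function(i)
    data.frame(isolate = paste0("iso", i), chrom = "Chr02A",
               left_state = "A", right_state = "B",
               start = 142183 + i, end = 142201 + i)))
  sites <- aggregate_sites(ev5)
  expect_equal(nrow(sites), 1)
  expect_true(sites$hotspot)
  expect_equal(sites$n_isolates, 5)

  # the two printed intervals 15 bp apart stay distinct at the default
  two <- read_tsv(system.file("extdata", "tr01_chr02a_sites.tsv",
                              package = "dikaryon"))
  ev2 <- data.frame(isolate = c("i1", "i2"), chrom = two$chrom,
                    left_state = "A", right_state = "B",
                    start = two$start, end = two$end)
  sites <- aggregate_sites(ev2, merge_distance = 10)
  expect_equal(nrow(sites), 2)
  expect_equal(interval_gap(sites$end[1], sites$start[2]), 15)
  # a wider threshold merges them
  expect_equal(nrow(aggregate_sites(ev2, merge_distance = 15)), 1)

  one <- aggregate_sites(ev2[1, ])
  expect_equal(one$n_isolates, 1)
  expect_false(one$hotspot)
})

test_that("origin fractions are length-weighted and sum to 100", {
  calls <- classify_bins(mk_counts(rep("A", 20)))
  f <- origin_fraction(calls)
  expect_equal(f$pctA, 100)
  expect_equal(f$pctB + f$pctHET, 0)

  calls <- classify_bins(mk_counts(rep(c("A", "B"), 10)))
  f <- origin_fraction(calls)
  expect_equal(f$pctA, 50)
  expect_equal(f$pctB, 50)

  dk <- shared_dikaryon_light()
  for (s in 1:5) {
    rg <- random_spore_genotype(dk$truth, n_switches = 4, seed = 300 + s)
    ev <- simulate_evidence(rg$genotype, dk$truth, seed = 400 + s)
    f <- origin_fraction(classify_bins(ev$bin_counts))
    expect_lt(abs(f$pctA + f$pctB + f$pctHET - 100), 0.1)
  }

  empty <- mk_counts(rep("NA", 5))
  expect_error(origin_fraction(classify_bins(empty)), "informative")
})

test_that("an isolate built 82% from one haplotype yields a matching origin fraction", {
  dk <- shared_dikaryon_light()
  bins <- dk$truth$bins
  # cut each chromosome where 82% of its informative length is upstream, so
  # the origin split measured on informative bins is 82/18 by construction
  om <- do.call(rbind, lapply(unique(bins$chrom), function(ch) {
    b <- bins[bins$chrom == ch, ]
    len <- max(b$end)
    inf <- b[b$informative, ]
    if (!nrow(inf)) {
      return(data.frame(chrom = ch, start = 1, end = len, origin = "A"))
    }
    cum <- cumsum(interval_len(inf$start, inf$end))
    k <- which.min(abs(cum - 0.82 * cum[length(cum)]))
    cut <- inf$end[k]
    if (cut >= len) {
      return(data.frame(chrom = ch, start = 1, end = len, origin = "A"))
    }
    data.frame(chrom = ch, start = c(1, cut + 1), end = c(cut, len),
               origin = c("A", "B"))
  }))
  gt <- spore_genotype("iso82", om)
  ev <- simulate_evidence(gt, dk$truth, coverage = 30, allele_error = 0.01,
                          seed = 77)
  f <- origin_fraction(classify_bins(ev$bin_counts))
  expect_lt(abs(f$pctA - 82), 2)
  expect_gt(f$pctA, f$pctB)
})
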