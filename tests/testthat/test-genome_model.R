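test_that("telomere detection counts tandem motif runs anchored at the end", {
  s <- strrep("TTAGGG", 25)
  res <- detect_telomere(paste0(strrep("ACT", 50), s), "3p", min_repeats = 10)
  expect_true(res$present)
  expect_equal(res$repeat_count, 25)

  # non-repetitive sequence (G-free, so no motif can occur)
  withr::with_seed(1, {
    bland <- paste(sample(c("A", "C", "T"), 200, replace = TRUE), collapse = "")
  })
  res <- detect_telomere(bland, "3p")
  expect_false(res$present)
  expect_equal(res$repeat_count, 0)

  # the G-run length may vary copy to copy
  mix <- paste(rep(c("TTAGGG", "TTAGGGG"), 15), collapse = "")
  res <- detect_telomere(paste0("ACACAC", mix), "3p")
  expect_true(res$present)
  expect_equal(res$repeat_count, 30)

  # 5' ends carry the reverse-complement motif family
  cap5 <- paste(rep(c("CCCTAA", "CCCCTAA"), 11), collapse = "")
  res <- detect_telomere(paste0(cap5, "GATTACA"), "5p")
  expect_true(res$present)
  expect_equal(res$repeat_count, 22)
})

test_that("telomere scan rejects non-nucleotide input and treats N as mismatch", {
  expect_error(detect_telomere("TTAGXG", "3p"), "non-nucleotide")
  res <- detect_telomere(paste0("TTAGGG", "TTANGG"), "3p", min_repeats = 1)
  expect_equal(res$repeat_count, 0)  # run must be anchored at the end
})

test_that("telomere counts agree with a brute-force scanner and are idempotent", {
  withr::with_seed(7, {
    for (i in 1:25) {
      n <- sample(0:40, 1)
      end <- sample(c("3p", "5p"), 1)
      gs <- sample(3:5, n, replace = TRUE)
      units <- vapply(gs, function(g) paste0("TTA", strrep("G", g)), character(1))
      cap <- paste(units, collapse = "")
      if (end == "5p") {
        cap <- chartr("ACGT", "TGCA",
                      paste(rev(strsplit(cap, "")[[1]]), collapse = ""))
      }
      body <- paste(sample(c("A", "C", "T"), 60, replace = TRUE), collapse = "")
      seq <- if (end == "3p") paste0(body, cap) else paste0(cap, body)
      got <- detect_telomere(seq, end)
      expect_equal(got$repeat_count, brute_force_telomere_count(seq, end))
      expect_equal(detect_telomere(seq, end), got)  # idempotent
    }
  })
})

test_that("accessory classification needs all three two-speed criteria", {
  mk <- function(gd, rp, ess) list(gene_density = gd, repeat_pct = rp,
                                   essential_count = ess)
  expect_equal(classify_region(mk(1.7, 50.5, 0)), "accessory")
  expect_equal(classify_region(mk(2.8, 20.0, 12)), "core")
  # repeat-rich but too gene-dense: fails the gene-density arm
  expect_equal(classify_region(mk(2.5, 60.0, 0)), "core")
  # essential genes veto accessory status regardless of the other criteria
  expect_equal(classify_region(mk(1.0, 80.0, 1)), "core")
  expect_equal(classify_region(mk(1.0, 80.0, 0), repeat_pct_min = 85), "core")
})

test_that("the synthetic dikaryon yields 3 accessory chromosomes + 2 compartments per haplotype", {
  dk <- shared_dikaryon()
  for (g in list(dk$genomeA, dk$genomeB)) {
    acc <- dk$truth$accessory
    acc <- acc[acc$haplotype == g$label, ]
    # candidate regions: every whole chromosome plus the compartment truths
    whole <- vapply(names(g$chromosomes), function(ch)
      classify_region(region_feature_summary(g, ch)), character(1))
    acc_chroms <- names(whole)[whole == "accessory"]
    expect_length(acc_chroms, 3)
    expect_setequal(acc_chroms,
                    acc$chrom[acc$type == "chromosome"])
    comp <- acc[acc$type == "compartment", ]
    expect_equal(nrow(comp), 2)
    for (i in seq_len(nrow(comp))) {
      expect_equal(classify_region(region_feature_summary(
        g, comp$chrom[i], comp$start[i], comp$end[i])), "accessory")
    }
  }
})

test_that("tandem copy number is the depth ratio, exactly", {
  expect_equal(estimate_tandem_copy_number(480, 30), 16)
  expect_equal(estimate_tandem_copy_number(30, 30), 1)
  expect_equal(estimate_tandem_copy_number(0, 30), 0)
  expect_error(estimate_tandem_copy_number(10, 0), "> 0")
  for (k in c(0.5, 1, 2, 16, 113)) {
    for (d in c(1, 7, 30)) {
      expect_equal(estimate_tandem_copy_number(k * d, d), k)
    }
  }
})

test_that("LTR-bias phasing assigns the biased haplotype and mirrors consistently", {
  expect_equal(assign_haplotype_by_ltr_bias(181, 4), "A")
  expect_equal(assign_haplotype_by_ltr_bias(4, 221), "B")
  expect_equal(assign_haplotype_by_ltr_bias(0, 0), "unresolved")
  expect_equal(assign_haplotype_by_ltr_bias(2, 0), "unresolved")  # below min_count
  expect_equal(assign_haplotype_by_ltr_bias(9, 4), "unresolved")  # below min_fold
  # mirror-image counts can never send both homologs to the same haplotype
  withr::with_seed(11, {
    for (i in 1:50) {
      a <- sample(0:300, 1); b <- sample(0:300, 1)
      h1 <- assign_haplotype_by_ltr_bias(a, b)
      h2 <- assign_haplotype_by_ltr_bias(b, a)
      expect_false(h1 != "unresolved" && h1 == h2)
    }
  })
})

test_that("genome containers enforce their invariants", {
  expect_error(chromosome("c", length = 0), "length")
  expect_error(chromosome("c", length = 100, centromere = c(90, 120)),
               "centromere")
  ch <- chromosome("Chr01X", length = 1000)
  expect_error(haplotype_genome("A", list(ch, ch)), "unique")
  bad_track <- data.frame(chrom = "Chr01X", start = 900, end = 1200, name = "g")
  expect_error(haplotype_genome("A", list(ch), list(genes = bad_track)),
               "bounds")
  expect_error(
    haplotype_genome("A", list(ch), list(
      genes = data.frame(chrom = "Chr01X", start = 1, end = 10, name = "g1"),
      essential_genes = data.frame(chrom = "Chr01X", start = 1, end = 10,
                                   name = "g9"))),
    "subset")
  expect_error(oriented_segment("c", 10, 5), "end >= start")
  expect_error(homology_map("x", 1, 100, "x", 1, 100, 0.9),
               "distinct")
  expect_error(homology_map("x", 1, 100, "y", 1, 1000, 0.9),
               "tolerance")
  expect_error(homology_map("x", 1, 100, "y", 1, 100, 1.2), "identity")
})
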