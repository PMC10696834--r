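test_that("depth inflections are found at step boundaries and nowhere else", {
  mk <- function(ratios) {
    n <- length(ratios)
    data.frame(window_start = seq(1, by = 1e4, length.out = n),
               window_end = seq(1e4, by = 1e4, length.out = n),
               ratio = ratios)
  }
  prof <- mk(c(rep(1, 15), rep(1.8, 15)))
  hits <- find_depth_inflections(prof)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$boundary, 15 * 1e4)
  expect_gt(hits$step, 0.4)

  expect_equal(nrow(find_depth_inflections(mk(rep(1, 30)))), 0)
  expect_error(find_depth_inflections(mk(rep(1, 5))), "10 windows")

  # two planted steps in noisy data, each recovered within one window
  withr::with_seed(17, {
    true_cn <- c(rep(1, 20), rep(2, 15), rep(1, 20))
    noisy <- mk(rpois(length(true_cn), 30 * true_cn) / 30)
    hits <- find_depth_inflections(noisy)
    expect_equal(nrow(hits), 2)
    expect_lte(abs(hits$boundary[1] - 20e4), 1e4)
    expect_lte(abs(hits$boundary[2] - 35e4), 1e4)
  })
})

test_that("junction validation needs support and silent reference sites", {
  expect_true(validate_junction(205, 0, 0))
  expect_false(validate_junction(2, 0, 0))
  expect_false(validate_junction(60, 20, 0))
  expect_false(validate_junction(60, 0, 20))
  expect_true(validate_junction(60, 20, 0, max_ref_span = 25))
  expect_true(validate_junction(3, 0, 0, min_support = 3))
})

test_that("cataloged new chromosomes reconstruct with exact printed arithmetic", {
  models <- tr01_reconstruct_new_chromosomes()
  n1 <- models$ChrN1
  expect_equal(n1$length, 58690 + 172535)
  expect_equal(n1$length, 231225)
  expect_true(n1$telomere_5p)
  expect_true(n1$telomere_3p)
  expect_false(n1$has_centromere)
  expect_true(n1$stable)
  expect_equal(vapply(n1$segments, function(s) s$orient, character(1)),
               c("+", "-"))

  n2 <- models$ChrN2
  expect_equal(n2$length, 675684 + 834373)
  expect_equal(n2$length, 1510057)
  expect_false(n2$has_centromere)

  genomes <- tr01_genomes()
  expect_error(reconstruct_new_chromosome(
    "bad", list(oriented_segment("Chr12B", 1, 9e9)), genomes), "bounds")
})

test_that("reconstruction assembles the reverse-complement join sequence", {
  dk <- shared_dikaryon()
  genomes <- list(dk$genomeA, dk$genomeB)
  segs <- list(oriented_segment("Chr01B", 1, 30000, "+"),
               oriented_segment("Chr12B", 1, 35000, "-"))
  model <- reconstruct_new_chromosome("ChrN1", segs, genomes, sequence = TRUE)
  expect_equal(nchar(model$sequence), 65000)
  s1 <- substr(dk$genomeB$chromosomes$Chr01B$sequence, 1, 30000)
  s12 <- substr(dk$genomeB$chromosomes$Chr12B$sequence, 1, 35000)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s12)))
  expect_identical(model$sequence, paste0(s1, rc))
  # both component prefixes start at a telomere, so the model is capped
  expect_true(model$telomere_5p)
  expect_true(model$telomere_3p)
  expect_false(model$has_centromere)
  expect_gt(model$gene_count, 0)
})

test_that("simulated junctions round-trip to the planted model exactly", {
  dk <- shared_dikaryon_light()
  genomes <- list(dk$genomeA, dk$genomeB)
  chroms <- c(dk$genomeA$chromosomes, dk$genomeB$chromosomes)
  n_exact <- 0; n_wrong_orient <- 0
  withr::with_seed(23, {
    for (i in 1:50) {
      pair <- sample(names(chroms), 2)
      lens <- c(chroms[[pair[1]]]$length, chroms[[pair[2]]]$length)
      planted <- list(
        oriented_segment(pair[1], 1, sample(2000:lens[1], 1), "+"),
        oriented_segment(pair[2], 1, sample(2000:lens[2], 1), "-"))
      support <- rpois(1, 30)
      if (!validate_junction(support, 0, 0)) next
      model <- reconstruct_new_chromosome("sim", planted, genomes)
      same <- length(model$segments) == 2 &&
        all(vapply(seq_along(planted), function(k)
          identical(unclass(model$segments[[k]]), unclass(planted[[k]])),
          logical(1))) &&
        model$length == sum(vapply(planted, segment_length, numeric(1)))
      if (same) n_exact <- n_exact + 1
      orients <- vapply(model$segments, function(s) s$orient, character(1))
      if (!identical(orients, c("+", "-"))) n_wrong_orient <- n_wrong_orient + 1
    }
  })
  expect_gte(n_exact, 48)
  expect_equal(n_wrong_orient, 0)
})

test_that("architecture is called only on unanimous informative breakpoints", {
  mk <- function(a, b) data.frame(breakpoint = paste0("bp", seq_along(a)),
                                  supportA = a, supportB = b)
  expect_equal(assign_architecture(mk(c(30, 28, 33, 25, 31), rep(0, 5)))$architecture, "A")
  expect_equal(assign_architecture(mk(rep(0, 5), c(30, 28, 33, 25, 31)))$architecture, "B")
  mixed <- assign_architecture(mk(c(30, 30, 30, 0, 0), c(0, 0, 0, 30, 30)))
  expect_equal(mixed$architecture, "unresolved")
  expect_equal(mixed$per_breakpoint$call, c("A", "A", "A", "B", "B"))
  expect_equal(assign_architecture(mk(c(0, 0), c(1, 2)))$architecture,
               "unresolved")
})

test_that("aneuploidy typing is a pure total mapping with correct chromosome counts", {
  t1 <- type_aneuploidy("Chr12B", "A")
  expect_equal(t1$aneuploidy_type, "I")
  expect_equal(t1$chromosome_count, 12)
  expect_equal(type_aneuploidy("ChrN1", "A")$aneuploidy_type, "II")
  expect_equal(type_aneuploidy("ChrN2", "A")$aneuploidy_type, "III")
  t4 <- type_aneuploidy(c("Chr12B", "ChrN1"), "A")
  expect_equal(t4$aneuploidy_type, "IV")
  expect_equal(t4$chromosome_count, 13)
  expect_equal(type_aneuploidy(character(0), "A")$aneuploidy_type, "euploid")
  # sets outside the catalog map to "other", never I-IV
  for (extras in list("ChrX", c("Chr12B", "ChrN2"), c("ChrN1", "ChrN2"),
                      c("Chr12B", "ChrN1", "ChrN2"))) {
    expect_equal(type_aneuploidy(extras, "A")$aneuploidy_type, "other")
  }
  # order-insensitive
  expect_equal(type_aneuploidy(c("ChrN1", "Chr12B"), "A")$aneuploidy_type, "IV")
})
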