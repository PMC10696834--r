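test_that("a collinear homolog pair forms a bivalent with no intersections", {
  cfg <- dikaryon_config(preset = "collinear", n_chromosomes = 1,
                         chrom_length = 2e5, emit_sequence = FALSE, seed = 2)
  dk <- generate_dikaryon(cfg)
  pc <- build_pairing_complex(dk$genomeA, dk$genomeB, dk$truth$homology)
  expect_length(pc$components, 1)
  expect_setequal(pc$components[[1]], c("Chr01A", "Chr01B"))
  expect_equal(nrow(pc$intersections), 0)
  expect_equal(nrow(pc$unpaired), 0)
})

test_that("the asymmetric map forms the seven-chromatid complex with unpaired orphans", {
  dk <- shared_dikaryon_light()
  pc <- build_pairing_complex(dk$genomeA, dk$genomeB, dk$truth$homology)
  sizes <- vapply(pc$components, length, integer(1))
  big <- pc$components[[which.max(sizes)]]
  expect_setequal(big, c("Chr01A", "Chr01B", "Chr02A", "Chr02B",
                         "Chr05A", "Chr05B", "Chr12B"))
  expect_setequal(paste(pc$unpaired$chrom, pc$unpaired$start, pc$unpaired$end),
                  c("Chr01B 1 30000", "Chr12B 1 35000"))
  # intersections occur where blocks to different partners meet
  expect_true(all(c("Chr01A", "Chr02A", "Chr05A") %in% pc$intersections$chrom))

  bad <- dk$truth$homology
  bad$startA[2] <- bad$startA[2] - 5000  # overlap the previous block
  expect_error(build_pairing_complex(dk$genomeA, dk$genomeB, bad),
               "overlapping")
})

test_that("junction rules emit telomere-capped acentric models; absent sites never fire", {
  dk <- shared_dikaryon_light()
  pc <- build_pairing_complex(dk$genomeA, dk$genomeB, dk$truth$homology)
  models <- form_new_chromosomes(pc, dk$truth$junction_rules,
                                 always_fire = TRUE)
  expect_length(models, 2)
  n1 <- models[[1]]
  expect_equal(n1$id, "ChrN1")
  expect_equal(n1$length, 30000 + 35000)
  expect_true(n1$telomere_5p)
  expect_true(n1$telomere_3p)
  expect_false(n1$has_centromere)
  expect_equal(n1$segments[[2]]$orient, "-")

  # a bivalent-only complex lacks the rule chromatids: nothing fires
  cfg <- dikaryon_config(preset = "collinear", n_chromosomes = 1,
                         chrom_length = 2e5, emit_sequence = FALSE, seed = 2)
  dk2 <- generate_dikaryon(cfg)
  pc2 <- build_pairing_complex(dk2$genomeA, dk2$genomeB, dk2$truth$homology)
  expect_length(form_new_chromosomes(pc2, dk$truth$junction_rules,
                                     always_fire = TRUE), 0)
  # coordinates beyond chromatid bounds are rejected
  bad <- dk$truth$junction_rules
  bad$x_end[1] <- 1e9
  expect_error(form_new_chromosomes(pc, bad, always_fire = TRUE), "bounds")
})

test_that("a symmetric dikaryon segregates one copy of everything to each product", {
  m <- meiosis_model(
    pairs = list(c(A = "c1A", B = "c1B"), c(A = "c2A", B = "c2B")),
    acentrics = data.frame(id = character(0), partner = character(0),
                           bias = numeric(0)),
    composition = list(c1A = "s1", c1B = "s1", c2A = "s2", c2B = "s2"),
    essential_segments = c("s1", "s2"))
  withr::with_seed(3, {
    for (i in 1:20) {
      mei <- segregate(m)
      for (p in mei$products) {
        ids <- sort(vapply(p, function(e) e$id, character(1)))
        expect_length(ids, 2)
        expect_true(any(ids %in% c("c1A", "c1B")))
        expect_true(any(ids %in% c("c2A", "c2B")))
      }
    }
  })
  summ <- simulate_cohort(m, n_meioses = 200, seed = 4)
  expect_equal(summ$viability_fraction, 1)
  expect_equal(unname(summ$type_fractions["euploid"]), 1)
})

test_that("acentric migration follows the bias parameter", {
  co_locate_fraction <- function(bias, n) {
    m <- meiosis_model(
      pairs = list(c(A = "Chr05A", B = "Chr05B")),
      acentrics = data.frame(id = "Chr12B", partner = "Chr05A", bias = bias),
      composition = list(Chr05A = "m5", Chr05B = "m5", Chr12B = "r5"),
      essential_segments = character(0))
    hits <- 0; total <- 0
    for (i in seq_len(n)) {
      mei <- segregate(m)
      partner_prods <- which(vapply(mei$products, function(p)
        any(vapply(p, function(e) e$id == "Chr05A", logical(1))), logical(1)))
      for (pi in seq_along(mei$products)) {
        k <- sum(vapply(mei$products[[pi]], function(e) e$id == "Chr12B",
                        logical(1)))
        total <- total + k
        if (pi %in% partner_prods) hits <- hits + k
      }
    }
    hits / total
  }
  withr::with_seed(9, {
    f <- co_locate_fraction(0.5, 3000)
    se <- sqrt(0.25 / 6000)
    expect_lt(abs(f - 0.5), 3 * se)
    expect_equal(co_locate_fraction(1.0, 300), 1.0)
  })
})

test_that("viability requires every essential gene location", {
  essential_map <- data.frame(
    gene = c("g1", "g1", "g2"),
    chrom = c("Chr01A", "Chr02B", "Chr01A"),
    start = c(100, 500, 9000), end = c(200, 600, 9500))
  full_a <- data.frame(chrom = "Chr01A", start = 1, end = 1e4)
  expect_true(viability(full_a, essential_map))
  # losing the g2 interval is lethal even though g1 has an alternative home
  partial <- data.frame(chrom = c("Chr01A", "Chr02B"),
                        start = c(1, 1), end = c(5000, 1e4))
  expect_false(viability(partial, essential_map))
  expect_true(viability(partial, essential_map, required_fraction = 0.5))
})

test_that("segment copies are conserved across the four products", {
  m <- tr01_meiosis_model(junction_prob = 0.3)  # fire often to stress rules
  summ <- simulate_cohort(m, n_meioses = 500, seed = 12,
                          check_conservation = TRUE)
  expect_equal(summ$conservation_violations, 0)
  expect_gt(summ$new_chromosome_incidence, 0)
})

test_that("Monte-Carlo summaries match exhaustive enumeration within sampling error", {
  m <- tr01_meiosis_model()
  en <- simulate_cohort(m, mode = "enumerate")
  n <- 2000
  mc <- simulate_cohort(m, n_meioses = n, seed = 13)
  z <- function(p_hat, p) {
    se <- sqrt(max(p * (1 - p), 1e-6) / n)  # conservative: meioses, not products
    abs(p_hat - p) / se
  }
  expect_lt(z(mc$viability_fraction, en$viability_fraction), 3)
  for (a in c("A", "B", "unresolved")) {
    expect_lt(z(mc$arch_fractions[[a]], en$arch_fractions[[a]]), 3)
  }
  expect_lt(z(mc$new_chromosome_incidence, en$new_chromosome_incidence), 3)
})

test_that("viable spores favor the A architecture; zero junction probability is Mendelian", {
  en <- simulate_cohort(tr01_meiosis_model(), mode = "enumerate")
  expect_gt(en$arch_fractions[["A"]], en$arch_fractions[["B"]])
  # the bias persists even with uniform acentric migration
  en50 <- simulate_cohort(tr01_meiosis_model(acentric_bias = 0.5),
                          mode = "enumerate")
  expect_gt(en50$arch_fractions[["A"]], en50$arch_fractions[["B"]])

  m0 <- tr01_meiosis_model(junction_prob = 0)
  mc <- simulate_cohort(m0, n_meioses = 500, seed = 14)
  expect_equal(mc$new_chromosome_incidence, 0)
  expect_equal(unname(mc$type_fractions[["II"]] + mc$type_fractions[["III"]] +
                        mc$type_fractions[["IV"]]), 0)
  en0 <- simulate_cohort(m0, mode = "enumerate")
  expect_equal(en0$new_chromosome_incidence, 0)
})
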