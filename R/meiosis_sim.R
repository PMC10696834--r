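# Mechanistic meiosis model at segment granularity: homologous pairing into
# a multi-chromatid complex, breakage/rejoining at homology intersections
# producing new telomere-capped acentric chromosomes, segregation
# (centromeric chromosomes by spindle, acentrics by free or biased
# migration), and viability filtering by essential-gene complement.

#' Build the homologous pairing complex
#'
#' Treats chromosomes of both haplotypes as chromatids (nodes) and homology
#' blocks of at least `min_block` bases as pairing edges; connected
#' components are the pairing complexes of prophase I. Intersections are
#' coordinates on one chromatid where two blocks to different partners meet
#' or overlap-adjacently (the physical contact points where breakage can
#' occur); unpaired segments are stretches of `min_block` or more bases with
#' no incident block (haplotype-specific regions with nothing to pair with).
#'
#' @param genomeA,genomeB [haplotype_genome()] objects.
#' @param hmap A [homology_map()].
#' @param min_block Minimum block length in bases (default 5000).
#' @return List of class `pairing_complex` with `components` (list of
#'   chromatid-id vectors), `intersections` (data frame `chrom`, `pos`,
#'   `partners`), `unpaired` (data frame `chrom`, `start`, `end`),
#'   `chrom_lengths`, `telomeres`, `centromeres`.
#' @export
build_pairing_complex <- function(genomeA, genomeB, hmap, min_block = 5000) {
  all_chroms <- c(genomeA$chromosomes, genomeB$chromosomes)
  lens <- vapply(all_chroms, function(ch) ch$length, numeric(1))
  blk_len <- interval_len(hmap$startA, hmap$endA)
  hm <- hmap[blk_len >= min_block, , drop = FALSE]
  if (!all(c(hm$chromA, hm$chromB) %in% names(lens))) {
    stop("homology map references chromosomes absent from the genomes")
  }
  # per-chromatid block list (a block touches both of its chromatids)
  blocks_on <- function(chrom) {
    a <- hm[hm$chromA == chrom, c("startA", "endA", "chromB")]
    names(a) <- c("start", "end", "partner")
    b <- hm[hm$chromB == chrom, c("startB", "endB", "chromA")]
    names(b) <- c("start", "end", "partner")
    rbind(a, b)
  }
  # reject contradictory overlapping blocks on one chromatid
  for (chrom in unique(c(hm$chromA, hm$chromB))) {
    bl <- blocks_on(chrom)
    bl <- bl[order(bl$start), ]
    if (nrow(bl) > 1 && any(bl$start[-1] <= bl$end[-nrow(bl)] - 1)) {
      stop("overlapping homology blocks on ", chrom, "; contradictory map")
    }
  }
  g <- igraph::graph_from_data_frame(
    hm[, c("chromA", "chromB")], directed = FALSE,
    vertices = data.frame(name = names(lens)))
  comp <- igraph::components(g)
  components <- split(names(comp$membership), comp$membership)
  names(components) <- NULL

  inter <- list(); unp <- list()
  for (chrom in names(lens)) {
    bl <- blocks_on(chrom)
    bl <- bl[order(bl$start), ]
    if (nrow(bl) > 1) {
      for (i in seq_len(nrow(bl) - 1)) {
        # adjacent or touching blocks to *different* partners meet here
        if (bl$partner[i] != bl$partner[i + 1] &&
            bl$start[i + 1] - bl$end[i] <= 1) {
          inter[[length(inter) + 1]] <- data.frame(
            chrom = chrom, pos = bl$end[i],
            partners = paste(sort(c(bl$partner[i], bl$partner[i + 1])),
                             collapse = ","),
            stringsAsFactors = FALSE)
        }
      }
    }
    covered <- if (nrow(bl)) IRanges::reduce(IRanges::IRanges(bl$start, bl$end))
      else IRanges::IRanges()
    gaps <- IRanges::setdiff(IRanges::IRanges(1, lens[[chrom]]), covered)
    gaps <- gaps[IRanges::width(gaps) >= min_block]
    if (length(gaps)) {
      unp[[length(unp) + 1]] <- data.frame(
        chrom = chrom, start = IRanges::start(gaps), end = IRanges::end(gaps),
        stringsAsFactors = FALSE)
    }
  }
  empty_i <- data.frame(chrom = character(0), pos = numeric(0),
                        partners = character(0))
  empty_u <- data.frame(chrom = character(0), start = numeric(0),
                        end = numeric(0))
  structure(list(
    components = components,
    intersections = if (length(inter)) do.call(rbind, inter) else empty_i,
    unpaired = if (length(unp)) do.call(rbind, unp) else empty_u,
    chrom_lengths = lens,
    telomeres = lapply(all_chroms, function(ch)
      list(t5 = ch$telomere_5p, t3 = ch$telomere_3p)),
    centromeres = lapply(all_chroms, function(ch) ch$centromere)),
    class = "pairing_complex")
}

#' Form new chromosomes by breakage and rejoining at junction rules
#'
#' Each rule joins a prefix of one chromatid to the reverse complement of a
#' prefix of another (the general orientation is carried by the rule's
#' segments) and fires independently with its per-meiosis probability. The
#' emitted model inherits telomere flags from its terminal segment ends and
#' a centromere flag from whether any component segment contains a
#' centromere; the two source prefixes each carried one telomere and no
#' centromere, so the canonical products are telomere-capped at both ends
#' and acentric.
#'
#' @param complex A [build_pairing_complex()] result.
#' @param rules Data frame with `id`, `x_chrom`, `x_end`, `y_chrom`,
#'   `y_end`, `prob` (prefix-joins; `y` enters reverse-complemented).
#' @param always_fire Ignore probabilities and fire every rule (used for
#'   deterministic reconstruction of the rule catalog).
#' @return List of [new_chromosome_model()]s for the rules that fired.
#' @export
form_new_chromosomes <- function(complex, rules, always_fire = FALSE) {
  out <- list()
  if (is.null(rules) || nrow(rules) == 0) return(out)
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    # sites absent from this complex: the rule has nothing to act on
    if (!all(c(r$x_chrom, r$y_chrom) %in% names(complex$chrom_lengths))) next
    if (r$x_end > complex$chrom_lengths[[r$x_chrom]] ||
        r$y_end > complex$chrom_lengths[[r$y_chrom]]) {
      stop("junction rule ", r$id, " exceeds chromatid bounds")
    }
    if (!always_fire && stats::runif(1) >= r$prob) next
    segs <- list(oriented_segment(r$x_chrom, 1, r$x_end, "+"),
                 oriented_segment(r$y_chrom, 1, r$y_end, "-"))
    tel5 <- isTRUE(complex$telomeres[[r$x_chrom]]$t5$present)
    tel3 <- isTRUE(complex$telomeres[[r$y_chrom]]$t5$present)
    cen_in <- function(chrom, end) {
      cen <- complex$centromeres[[chrom]]
      !is.null(cen) && cen[1] <= end
    }
    out[[length(out) + 1]] <- new_chromosome_model(
      r$id, segs, telomere_5p = tel5, telomere_3p = tel3,
      has_centromere = cen_in(r$x_chrom, r$x_end) || cen_in(r$y_chrom, r$y_end))
  }
  out
}

# ---- segment-granularity meiosis model --------------------------------------

#' Construct a segment-granularity meiosis model
#'
#' @param pairs List of `c(A = , B = )` homologous chromosome id pairs
#'   (centromeric; split 2+2 across the four meiotic products).
#' @param acentrics Data frame `id`, `partner`, `bias`: acentric
#'   chromosomes, each with a designated pairing-partner chromosome and the
#'   probability that a copy co-segregates with a product carrying the
#'   partner (0.5 = uniform migration).
#' @param composition Named list: chromosome id -> character vector of the
#'   named segments it is built from (shared segment names encode homology).
#' @param essential_segments Segments carrying essential genes; a product is
#'   viable iff it carries at least `required_fraction` of them.
#' @param junction_rules List of lists `id`, `x_chrom`, `x_segs`, `y_chrom`,
#'   `y_segs`, `prob`: a fired rule consumes one chromatid of each source
#'   chromosome, emits a new acentric chromosome made of `x_segs` + `y_segs`,
#'   and leaves the unconsumed remainder segments as telomere-lacking
#'   fragments that are dropped after one generation (with a logged count).
#' @param arch_loci Named list: architecture locus -> `c(A = , B = )`
#'   chromosome ids whose arrangement defines the A/B genome architecture.
#' @param required_fraction Fraction of essential segments required for
#'   viability (default 1).
#' @return Object of class `meiosis_model`.
#' @export
meiosis_model <- function(pairs, acentrics, composition, essential_segments,
                          junction_rules = list(),
                          arch_loci = list(), required_fraction = 1) {
  for (r in junction_rules) stopifnot(r$prob >= 0, r$prob <= 1)
  stopifnot(all(acentrics$bias >= 0), all(acentrics$bias <= 1))
  structure(list(pairs = pairs, acentrics = acentrics,
                 composition = composition,
                 essential_segments = essential_segments,
                 junction_rules = junction_rules, arch_loci = arch_loci,
                 required_fraction = required_fraction),
            class = "meiosis_model")
}

#' The reduced Tr01-like meiosis model
#'
#' Three heteromorphic homolog pairs (Chr01, Chr02, Chr05, with arms swapped
#' between architectures) plus the acentric extra chromosome built from an
#' orphan segment and a copy of the Chr05A right arm, and the two junction
#' rules capable of forming the new chromosomes. The B architecture lacks
#' the Chr05 right-arm segment on its centromeric complement, so a
#' B-architecture product is viable only when the acentric chromosome
#' migrates with it -- the asymmetry that biases surviving spores toward the
#' A architecture.
#'
#' @param acentric_bias Probability that an acentric copy co-segregates with
#'   a product carrying its pairing partner (default 0.7; the model's
#'   qualitative claims hold for any value, 0.5 = uniform).
#' @param junction_prob Per-meiosis firing probability of each junction rule
#'   (default 0.05).
#' @param include_collinear Add the collinear chromosome pairs (Chr03, 04,
#'   09, 10, 11) that do not affect viability or architecture.
#' @return A [meiosis_model()].
#' @export
tr01_meiosis_model <- function(acentric_bias = 0.7, junction_prob = 0.05,
                               include_collinear = FALSE) {
  pairs <- list(c(A = "Chr01A", B = "Chr01B"),
                c(A = "Chr02A", B = "Chr02B"),
                c(A = "Chr05A", B = "Chr05B"))
  composition <- list(
    Chr01A = c("L1", "R1"), Chr01B = c("C1", "R1"),
    Chr02A = c("L2", "R2"), Chr02B = c("L1", "R2"),
    Chr05A = c("C5", "M5", "R5"), Chr05B = c("L2", "C5", "M5"),
    Chr12B = c("C12", "R5"))
  essential <- c("L1", "R1", "L2", "R2", "M5", "R5")
  if (include_collinear) {
    for (ch in c("Chr03", "Chr04", "Chr09", "Chr10", "Chr11")) {
      pairs[[length(pairs) + 1]] <- c(A = paste0(ch, "A"), B = paste0(ch, "B"))
      segname <- paste0("S", sub("Chr", "", ch))
      composition[[paste0(ch, "A")]] <- segname
      composition[[paste0(ch, "B")]] <- segname
    }
    essential <- c(essential, "S03", "S04")
  }
  meiosis_model(
    pairs = pairs,
    acentrics = data.frame(id = "Chr12B", partner = "Chr05A",
                           bias = acentric_bias, stringsAsFactors = FALSE),
    composition = composition,
    essential_segments = essential,
    junction_rules = list(
      list(id = "ChrN1", x_chrom = "Chr01B", x_segs = "C1",
           y_chrom = "Chr12B", y_segs = "C12", prob = junction_prob),
      list(id = "ChrN2", x_chrom = "Chr05B", x_segs = "L2",
           y_chrom = "Chr12B", y_segs = c("C12", "R5"), prob = junction_prob)),
    arch_loci = list(Chr01 = c(A = "Chr01A", B = "Chr01B"),
                     Chr02 = c(A = "Chr02A", B = "Chr02B"),
                     Chr05 = c(A = "Chr05A", B = "Chr05B")))
}

# entity constructors: every entity knows which parental (chromosome,
# segment) instances it carries, for conservation accounting
entity_chrom <- function(id, model) {
  list(kind = "chrom", id = id,
       carries = data.frame(chrom = id, segment = model$composition[[id]],
                            stringsAsFactors = FALSE))
}
entity_new <- function(rule) {
  list(kind = "new", id = rule$id,
       carries = rbind(
         data.frame(chrom = rule$x_chrom, segment = rule$x_segs,
                    stringsAsFactors = FALSE),
         data.frame(chrom = rule$y_chrom, segment = rule$y_segs,
                    stringsAsFactors = FALSE)))
}
entity_frag <- function(src_chrom, segs) {
  list(kind = "frag", id = paste0("frag:", src_chrom),
       carries = data.frame(chrom = src_chrom, segment = segs,
                            stringsAsFactors = FALSE))
}

#' Segregate a parental complement into four meiotic products
#'
#' Meiosis I/II semantics: each centromeric homolog pair splits 2+2 across
#' the four products (independent assortment between pairs); each acentric
#' chromosome's two sister copies migrate independently, landing with a
#' product that carries the designated partner chromosome with probability
#' `bias` (0.5 = uniform over all four).
#'
#' @param model A [meiosis_model()].
#' @param fired Optional list of fired junction rules (internal; consumed
#'   chromatids are replaced by fragments and the new chromosomes placed
#'   like acentrics).
#' @return List with `products` (list of four entity lists), `fired`,
#'   `n_fragments`.
#' @export
segregate <- function(model, fired = NULL) {
  consumed <- list()  # chrom -> number of chromatids consumed by rules
  new_entities <- list()
  frag_of <- list()   # chrom -> list of fragment entities (one per consumed)
  for (r in (fired %||% list())) {
    for (side in c("x", "y")) {
      ch <- r[[paste0(side, "_chrom")]]
      consumed[[ch]] <- (consumed[[ch]] %||% 0) + 1
      rem <- setdiff(model$composition[[ch]], r[[paste0(side, "_segs")]])
      frag_of[[ch]] <- c(frag_of[[ch]],
                         list(if (length(rem)) entity_frag(ch, rem) else NULL))
    }
    new_entities[[length(new_entities) + 1]] <- entity_new(r)
  }
  products <- list(list(), list(), list(), list())
  add <- function(p, e) {
    if (!is.null(e)) products[[p]][[length(products[[p]]) + 1]] <<- e
  }
  place_pair_side <- function(chrom, prods) {
    # two sister chromatids to the two products of one meiosis-I cell;
    # consumed sisters deliver their fragment instead
    ncons <- consumed[[chrom]] %||% 0
    frs <- frag_of[[chrom]] %||% list()
    slots <- sample(c(rep("intact", 2 - ncons), rep("frag", ncons)))
    fi <- 0
    for (k in 1:2) {
      if (slots[k] == "intact") add(prods[k], entity_chrom(chrom, model))
      else {
        fi <- fi + 1
        add(prods[k], frs[[fi]])
      }
    }
  }
  for (pair in model$pairs) {
    orient <- sample(1:2, 1)
    sideA <- if (orient == 1) c(1, 2) else c(3, 4)
    sideB <- setdiff(1:4, sideA)
    place_pair_side(pair[["A"]], sideA)
    place_pair_side(pair[["B"]], sideB)
  }
  # acentric chromosomes: biased free migration of each surviving copy
  place_acentric <- function(entity, partner, bias) {
    partner_prods <- which(vapply(products, function(p)
      any(vapply(p, function(e) e$kind == "chrom" && e$id == partner,
                 logical(1))), logical(1)))
    pick <- function(v) v[sample.int(length(v), 1)]
    p <- if (length(partner_prods) && length(partner_prods) < 4) {
      if (stats::runif(1) < bias) pick(partner_prods)
      else pick(setdiff(1:4, partner_prods))
    } else pick(1:4)
    add(p, entity)
  }
  for (i in seq_len(nrow(model$acentrics))) {
    ac <- model$acentrics[i, ]
    ncons <- consumed[[ac$id]] %||% 0
    frs <- frag_of[[ac$id]] %||% list()
    for (f in frs) if (!is.null(f)) add(sample(1:4, 1), f)
    for (k in seq_len(2 - ncons)) {
      place_acentric(entity_chrom(ac$id, model), ac$partner, ac$bias)
    }
  }
  for (e in new_entities) add(sample(1:4, 1), e)
  n_frag <- sum(vapply(products, function(p)
    sum(vapply(p, function(e) e$kind == "frag", logical(1))), numeric(1)))
  list(products = products, fired = fired, n_fragments = n_frag)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tabulate parental segment-instance copies across the four products
#'
#' Before viability filtering (and before fragment loss), every parental
#' (chromosome, segment) instance must total exactly 2 copies across the
#' four products of one meiosis -- the replicated sister chromatids --
#' including segments relocated into new chromosomes and fragments.
#'
#' @param meiosis A [segregate()] result.
#' @return Data frame `chrom`, `segment`, `copies`.
#' @export
segment_copy_table <- function(meiosis) {
  rows <- do.call(rbind, unlist(lapply(meiosis$products, function(p)
    lapply(p, function(e) e$carries)), recursive = FALSE))
  if (is.null(rows)) {
    return(data.frame(chrom = character(0), segment = character(0),
                      copies = integer(0)))
  }
  agg <- stats::aggregate(list(copies = rep(1L, nrow(rows))),
                          by = rows[c("chrom", "segment")], FUN = sum)
  agg[order(agg$chrom, agg$segment), ]
}

#' Viability of a spore by essential-gene complement
#'
#' A spore is viable when at least `required_fraction` of the essential
#' genes in `essential_map` are present in one or more copies. Genes may
#' have several parental locations (homologous segments on different
#' chromosomes); a gene counts as present when any location is fully
#' covered by the spore's parental-coordinate complement.
#'
#' @param covered Data frame `chrom`, `start`, `end`: parental-genome
#'   intervals present in the spore (union over all carried molecules).
#' @param essential_map Data frame `gene`, `chrom`, `start`, `end`; multiple
#'   rows per gene list alternative locations.
#' @param required_fraction Fraction of genes required (default 1; lower
#'   values model a required subset).
#' @return Logical.
#' @export
viability <- function(covered, essential_map, required_fraction = 1) {
  if (!nrow(essential_map)) return(TRUE)
  loc_ok <- vapply(seq_len(nrow(essential_map)), function(i) {
    g <- essential_map[i, ]
    any(covered$chrom == g$chrom & covered$start <= g$start &
          covered$end >= g$end)
  }, logical(1))
  present <- tapply(loc_ok, essential_map$gene, any)
  mean(present) >= required_fraction
}

# segment-level product summary used by the cohort simulator
classify_product <- function(model, entities, extra_comp = list()) {
  intact <- Filter(function(e) e$kind != "frag", entities)
  ids <- vapply(intact, function(e) e$id, character(1))
  segs <- unique(unlist(c(model$composition[ids[ids %in% names(model$composition)]],
                          lapply(intact[vapply(intact, function(e)
                            e$kind == "new", logical(1))],
                            function(e) e$carries$segment))))
  viable <- mean(model$essential_segments %in% segs) >= model$required_fraction
  arch_states <- vapply(model$arch_loci, function(locus) {
    hasA <- locus[["A"]] %in% ids
    hasB <- locus[["B"]] %in% ids
    if (hasA && !hasB) "A" else if (hasB && !hasA) "B"
    else if (hasA && hasB) "both" else "none"
  }, character(1))
  arch <- if (length(arch_states) == 0) "A"
  else if (all(arch_states == "A")) "A"
  else if (all(arch_states == "B")) "B"
  else "unresolved"
  floating <- c(model$acentrics$id,
                vapply(model$junction_rules, function(r) r$id, character(1)))
  extras <- intersect(unique(ids), floating)
  if (arch == "B") extras <- setdiff(extras, model$acentrics$id)
  type <- type_aneuploidy(extras, arch)$aneuploidy_type
  list(viable = viable, arch = arch, extras = extras, type = type)
}

#' Simulate (or exhaustively enumerate) a cohort of meioses
#'
#' Monte-Carlo mode runs `n_meioses` independent meioses, firing junction
#' rules with their probabilities, segregating, and summarizing the four
#' products of each. Enumeration mode computes the exact outcome
#' distribution of one meiosis by summing over all junction-rule firing
#' combinations, homolog assortments and acentric placements with their
#' probabilities (feasible for reduced models).
#'
#' @param model A [meiosis_model()].
#' @param n_meioses Meioses to simulate (Monte-Carlo mode).
#' @param seed Integer seed (Monte-Carlo mode).
#' @param mode `"montecarlo"` or `"enumerate"`.
#' @param check_conservation Verify the segment-copy invariant for every
#'   simulated meiosis (Monte-Carlo mode) and count violations.
#' @return List of class `cohort_summary`: `viability_fraction` (viable
#'   products / all products), `arch_fractions` (among viable spores),
#'   `type_fractions` (among viable spores), `new_chromosome_incidence`
#'   (fraction of products carrying a rule-formed chromosome),
#'   `fragments_dropped` (mean per meiosis), `conservation_violations`,
#'   `n_products`.
#' @export
simulate_cohort <- function(model, n_meioses = 1000, seed = 1L,
                            mode = c("montecarlo", "enumerate"),
                            check_conservation = FALSE) {
  mode <- match.arg(mode)
  if (mode == "enumerate") return(enumerate_meiosis(model))
  stopifnot(n_meioses >= 1)
  withr::with_seed(as.integer(seed), {
    arch_levels <- c("A", "B", "unresolved")
    type_levels <- c("euploid", "I", "II", "III", "IV", "other")
    viable_n <- 0; total <- 0; newchrom_n <- 0; frag_total <- 0
    cons_viol <- 0
    arch_counts <- stats::setNames(numeric(3), arch_levels)
    type_counts <- stats::setNames(numeric(6), type_levels)
    for (m in seq_len(n_meioses)) {
      fired <- Filter(function(r) stats::runif(1) < r$prob,
                      model$junction_rules)
      # each source chromosome has only two chromatids to consume
      if (length(fired) > 1) {
        tab <- table(unlist(lapply(fired, function(r)
          c(r$x_chrom, r$y_chrom))))
        if (any(tab > 2)) fired <- fired[1]
      }
      mei <- segregate(model, fired)
      if (check_conservation) {
        tab <- segment_copy_table(mei)
        if (any(tab$copies != 2)) cons_viol <- cons_viol + 1
      }
      frag_total <- frag_total + mei$n_fragments
      for (p in mei$products) {
        total <- total + 1
        cl <- classify_product(model, p)
        if (any(vapply(p, function(e) e$kind == "new", logical(1)))) {
          newchrom_n <- newchrom_n + 1
        }
        if (cl$viable) {
          viable_n <- viable_n + 1
          arch_counts[cl$arch] <- arch_counts[cl$arch] + 1
          type_counts[cl$type] <- type_counts[cl$type] + 1
        }
      }
    }
    structure(list(
      mode = "montecarlo", n_meioses = n_meioses, n_products = total,
      viability_fraction = viable_n / total,
      arch_fractions = if (viable_n) arch_counts / viable_n else arch_counts,
      type_fractions = if (viable_n) type_counts / viable_n else type_counts,
      new_chromosome_incidence = newchrom_n / total,
      fragments_dropped = frag_total / n_meioses,
      conservation_violations = if (check_conservation) cons_viol else NA),
      class = "cohort_summary")
  })
}

# exact outcome distribution of one meiosis by probability-tree summation
enumerate_meiosis <- function(model) {
  arch_levels <- c("A", "B", "unresolved")
  type_levels <- c("euploid", "I", "II", "III", "IV", "other")
  acc <- new.env()
  acc$viable <- 0; acc$total_w <- 0; acc$newchrom <- 0; acc$frag <- 0
  acc$arch <- stats::setNames(numeric(3), arch_levels)
  acc$type <- stats::setNames(numeric(6), type_levels)

  rules <- model$junction_rules
  nr <- length(rules)
  rule_sets <- if (nr) {
    unlist(lapply(0:(2^nr - 1), function(mask) {
      sel <- which(bitwAnd(mask, 2^(seq_len(nr) - 1)) > 0)
      tab <- table(unlist(lapply(rules[sel], function(r)
        c(r$x_chrom, r$y_chrom))))
      if (length(tab) && any(tab > 2)) return(NULL)  # not enough chromatids
      list(list(sel = sel,
                w = prod(vapply(seq_len(nr), function(i)
                  if (i %in% sel) rules[[i]]$prob else 1 - rules[[i]]$prob,
                  numeric(1)))))
    }), recursive = FALSE)
  } else list(list(sel = integer(0), w = 1))

  npairs <- length(model$pairs)
  orient_grid <- as.matrix(expand.grid(rep(list(1:2), npairs)))

  for (rs in rule_sets) {
    fired <- rules[rs$sel]
    consumed <- list(); frag_of <- list(); new_ids <- character(0)
    new_ent <- list()
    for (r in fired) {
      for (side in c("x", "y")) {
        ch <- r[[paste0(side, "_chrom")]]
        consumed[[ch]] <- (consumed[[ch]] %||% 0) + 1
        rem <- setdiff(model$composition[[ch]], r[[paste0(side, "_segs")]])
        frag_of[[ch]] <- c(frag_of[[ch]], list(rem))
      }
      new_ids <- c(new_ids, r$id)
      new_ent[[r$id]] <- entity_new(r)
    }
    n_frag_entities <- sum(vapply(frag_of, function(l)
      sum(vapply(l, length, numeric(1)) > 0), numeric(1)))
    for (oi in seq_len(nrow(orient_grid))) {
      w_orient <- rs$w * (1 / 2)^npairs
      # fixed chromatid->product assignment within a side (products are
      # exchangeable labels; the acentric placement below distinguishes them)
      base_products <- list(character(0), character(0), character(0),
                            character(0))
      for (pi in seq_len(npairs)) {
        pair <- model$pairs[[pi]]
        sideA <- if (orient_grid[oi, pi] == 1) c(1, 2) else c(3, 4)
        sideB <- setdiff(1:4, sideA)
        for (chrom_side in list(list(ch = pair[["A"]], prods = sideA),
                                list(ch = pair[["B"]], prods = sideB))) {
          ch <- chrom_side$ch
          ncons <- consumed[[ch]] %||% 0
          # consumed chromatid replaces the second slot; symmetric
          if (ncons == 0) {
            base_products[[chrom_side$prods[1]]] <-
              c(base_products[[chrom_side$prods[1]]], ch)
            base_products[[chrom_side$prods[2]]] <-
              c(base_products[[chrom_side$prods[2]]], ch)
          } else {
            base_products[[chrom_side$prods[1]]] <-
              c(base_products[[chrom_side$prods[1]]], ch)
          }
        }
      }
      # floating entities: surviving acentric copies + new chromosomes
      float <- list()
      for (ai in seq_len(nrow(model$acentrics))) {
        ac <- model$acentrics[ai, ]
        ncons <- consumed[[ac$id]] %||% 0
        for (k in seq_len(2 - ncons)) {
          float[[length(float) + 1]] <-
            list(id = ac$id, partner = ac$partner, bias = ac$bias)
        }
      }
      for (id in new_ids) {
        float[[length(float) + 1]] <- list(id = id, partner = NA, bias = 0.5)
      }
      nf <- length(float)
      place_grid <- if (nf) as.matrix(expand.grid(rep(list(1:4), nf)))
        else matrix(0, nrow = 1, ncol = 0)
      probs_of <- lapply(float, function(f) {
        if (is.na(f$partner)) return(rep(0.25, 4))
        pp <- which(vapply(base_products, function(v) f$partner %in% v,
                           logical(1)))
        if (!length(pp) || length(pp) == 4) return(rep(0.25, 4))
        pr <- rep((1 - f$bias) / (4 - length(pp)), 4)
        pr[pp] <- f$bias / length(pp)
        pr
      })
      for (gi in seq_len(nrow(place_grid))) {
        w <- w_orient
        prods <- base_products
        for (fi in seq_len(nf)) {
          tgt <- place_grid[gi, fi]
          w <- w * probs_of[[fi]][tgt]
          prods[[tgt]] <- c(prods[[tgt]], float[[fi]]$id)
        }
        if (w == 0) next
        acc$total_w <- acc$total_w + 4 * w
        acc$frag <- acc$frag + w * n_frag_entities
        for (p in prods) {
          ents <- lapply(p, function(id) {
            if (id %in% new_ids) new_ent[[id]] else entity_chrom(id, model)
          })
          cl <- classify_product(model, ents)
          if (any(p %in% new_ids)) acc$newchrom <- acc$newchrom + w
          if (cl$viable) {
            acc$viable <- acc$viable + w
            acc$arch[cl$arch] <- acc$arch[cl$arch] + w
            acc$type[cl$type] <- acc$type[cl$type] + w
          }
        }
      }
    }
  }
  structure(list(
    mode = "enumerate", n_meioses = 1, n_products = 4,
    viability_fraction = acc$viable / (acc$total_w),
    arch_fractions = if (acc$viable > 0) acc$arch / acc$viable else acc$arch,
    type_fractions = if (acc$viable > 0) acc$type / acc$viable else acc$type,
    new_chromosome_incidence = acc$newchrom / acc$total_w,
    fragments_dropped = acc$frag / (acc$total_w / 4),
    conservation_violations = 0),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort summary (%s): viability %.3f, arch A/B/unres %s, new-chromosome incidence %.4f>\n",
              x$mode, x$viability_fraction,
              paste(sprintf("%.3f", x$arch_fractions), collapse = "/"),
              x$new_chromosome_incidence))
  invisible(x)
}
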