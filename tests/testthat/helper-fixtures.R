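# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# the default Tr01-like synthetic dikaryon (with sequences)
shared_dikaryon <- function() {
  if (is.null(.fixture_cache$dk)) {
    .fixture_cache$dk <- generate_dikaryon(dikaryon_config(seed = 42))
  }
  .fixture_cache$dk
}

# a coordinate-only (no sequence) copy for cheap evidence simulations
shared_dikaryon_light <- function() {
  if (is.null(.fixture_cache$dk_light)) {
    .fixture_cache$dk_light <- generate_dikaryon(
      dikaryon_config(seed = 42, emit_sequence = FALSE))
  }
  .fixture_cache$dk_light
}

# independent brute-force telomere scanner: walks the sequence one motif
# copy at a time using plain string comparison (no shared code with the
# implementation's loop structure is assumed correct a priori)
brute_force_telomere_count <- function(seq, which_end) {
  seq <- toupper(seq)
  motifs3 <- c("TTAGGG", "TTAGGGG", "TTAGGGGG")
  rc <- function(x) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  }
  motifs <- if (which_end == "3p") motifs3 else vapply(motifs3, rc, character(1))
  count <- 0
  if (which_end == "3p") {
    rest <- seq
    repeat {
      matched <- FALSE
      for (m in motifs[order(-nchar(motifs))]) {
        w <- nchar(m)
        if (nchar(rest) >= w &&
            substring(rest, nchar(rest) - w + 1) == m) {
          rest <- substring(rest, 1, nchar(rest) - w)
          count <- count + 1
          matched <- TRUE
          break
        }
      }
      if (!matched) return(count)
    }
  } else {
    rest <- seq
    repeat {
      matched <- FALSE
      for (m in motifs[order(-nchar(motifs))]) {
        w <- nchar(m)
        if (nchar(rest) >= w && substring(rest, 1, w) == m) {
          rest <- substring(rest, w + 1)
          count <- count + 1
          matched <- TRUE
          break
        }
      }
      if (!matched) return(count)
    }
  }
}

# independent origin-string oracle: the true call sequence an error-free
# genotyper should produce (informative bins only, origin looked up in the
# planted origin map), and its A<->B transition set
oracle_origin_transitions <- function(genotype, truth) {
  bins <- truth$bins[truth$bins$informative, ]
  out <- list()
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    b <- b[order(b$start), ]
    mid <- floor((b$start + b$end) / 2)
    orig <- vapply(mid, function(p) {
      om <- genotype$origin_map
      hit <- om$chrom == ch & om$start <= p & om$end >= p
      om$origin[which(hit)[1]]
    }, character(1))
    tr <- which(orig[-1] != orig[-length(orig)])
    if (length(tr)) {
      out[[ch]] <- data.frame(chrom = ch, left = orig[tr],
                              right = orig[tr + 1],
                              lo = b$end[tr], hi = b$start[tr + 1])
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), left = character(0),
                      right = character(0), lo = numeric(0), hi = numeric(0)))
  }
  do.call(rbind, out)
}
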