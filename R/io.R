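# File interchange: FASTA for sequences (via Biostrings), BED (0-based
# half-open, per the BED standard) for feature tracks, TSV for tabular
# evidence and calls, JSON for genome metadata.

#' Write a haplotype genome to FASTA
#'
#' @param genome A [haplotype_genome()] whose chromosomes carry sequences.
#' @param path Output FASTA path (line width 60).
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- lapply(genome$chromosomes, function(ch) {
    if (is.null(ch$sequence)) stop("chromosome ", ch$id, " has no sequence")
    ch$sequence
  })
  dss <- Biostrings::DNAStringSet(unlist(seqs))
  names(dss) <- names(genome$chromosomes)
  Biostrings::writeXStringSet(dss, filepath = path, width = 60L)
  invisible(path)
}

#' Read chromosome sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(dss), names(dss))
}

#' Write a feature track as BED
#'
#' Converts the package's 1-based inclusive intervals to BED's 0-based
#' half-open convention.
#'
#' @param track Data frame with `chrom`, `start`, `end` and optionally
#'   `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_bed <- function(track, path) {
  ho <- to_halfopen(track$start, track$end)
  bed <- data.frame(chrom = track$chrom, start = ho$start, end = ho$end,
                    name = if ("name" %in% names(track)) track$name else ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED track into 1-based inclusive intervals
#'
#' @param path BED path (first three or four columns used).
#' @return Data frame with `chrom`, `start`, `end`, `name`.
#' @export
read_track_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  inc <- from_halfopen(bed[[2]], bed[[3]])
  data.frame(chrom = bed[[1]], start = inc$start, end = inc$end,
             name = if (ncol(bed) >= 4) bed[[4]] else ".",
             stringsAsFactors = FALSE)
}

#' Write / read tab-separated tables
#'
#' Plain TSV with a header row; `#`-prefixed comment lines are skipped on
#' read.
#'
#' @param x Data frame.
#' @param path File path.
#' @return `write_tsv()` returns `path` invisibly; `read_tsv()` returns a
#'   data frame.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write genome metadata (telomere/centromere state) as JSON
#'
#' @param genome A [haplotype_genome()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_genome_metadata <- function(genome, path) {
  meta <- lapply(genome$chromosomes, function(ch) {
    list(id = ch$id, length = ch$length,
         centromere = if (is.null(ch$centromere)) NULL else
           list(start = ch$centromere[1], end = ch$centromere[2]),
         telomere_5p = ch$telomere_5p, telomere_3p = ch$telomere_3p)
  })
  jsonlite::write_json(list(label = genome$label, chromosomes = meta), path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
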