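#!/usr/bin/env Rscript
# Worked examples computable from the printed coordinates and tables of the
# study: new-chromosome reconstruction arithmetic, the spacing of the two
# closely printed recombination sites, and cohort bookkeeping from the
# karyotype typology table.

suppressPackageStartupMessages(library(dikaryon))
outdir <- "results/printed"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

models <- tr01_reconstruct_new_chromosomes()
for (m in models) print(m)
tab <- data.frame(
  id = names(models),
  length_bp = vapply(models, function(m) m$length, numeric(1)),
  length_mb = round(vapply(models, function(m) m$length, numeric(1)) / 1e6, 2),
  telomere_5p = vapply(models, function(m) m$telomere_5p, logical(1)),
  telomere_3p = vapply(models, function(m) m$telomere_3p, logical(1)),
  has_centromere = vapply(models, function(m) m$has_centromere, logical(1)))
write_tsv(tab, file.path(outdir, "new_chromosomes.tsv"))

two <- read_tsv(system.file("extdata", "tr01_chr02a_sites.tsv",
                            package = "dikaryon"))
ev <- data.frame(isolate = c("i1", "i2"), chrom = two$chrom,
                 left_state = "A", right_state = "B",
                 start = two$start, end = two$end)
sites <- aggregate_sites(ev, merge_distance = 10)
cat(sprintf("printed site intervals stay distinct: %d sites, gap %d bp\n",
            nrow(sites), interval_gap(sites$end[1], sites$start[2])))

kt <- tr01_karyotype_table()
kary <- do.call(rbind, lapply(seq_len(nrow(kt)), function(i) {
  extras <- strsplit(kt$extras[i], ",")[[1]]
  extras <- extras[nzchar(extras)]
  base <- if (kt$architecture[i] == "B") 12 else 11
  kc <- type_aneuploidy(extras, kt$architecture[i], base_chromosomes = base)
  data.frame(isolate = kt$isolate[i], architecture = kc$architecture,
             aneuploidy_type = kc$aneuploidy_type,
             chromosome_count = kc$chromosome_count)
}))
rep <- make_report(kary)
cat(sprintf("cohort: %d isolates, %d aneuploid (%.1f%%)\n",
            rep$summary$n_isolates, rep$summary$n_aneuploid,
            rep$summary$aneuploid_pct))
cat("chromosome counts among A-architecture isolates: ")
print(unlist(rep$summary$chromosome_counts_architecture_A))
sizes <- tr01_extra_sizes()
cat(sprintf("Type IV extra-chromosome total: %.2f Mb\n",
            unname(sizes["Chr12B"] + sizes["ChrN1"])))
write_tsv(kary, file.path(outdir, "karyotypes_from_printed_table.tsv"))
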