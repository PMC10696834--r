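#!/usr/bin/env Rscript
# Build the synthetic asymmetric dikaryon and export it: two haplotype
# FASTAs, feature tracks as BED, genome metadata as JSON, and the planted
# truth (bins, homology map, accessory regions) as TSV.
#
# What to look for in the output: haplotype B has one more chromosome than
# haplotype A; the extra chromosome is acentric and >80% homologous to the
# Chr05A right arm; ~63% of 10-kb bins are heterozygous enough (>1% SNPs)
# to be origin-informative; each haplotype carries 3 accessory chromosomes
# and 2 accessory compartments.

suppressPackageStartupMessages(library(dikaryon))
outdir <- "results/simulate"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

dk <- generate_dikaryon(dikaryon_config(seed = 1))

write_genome_fasta(dk$genomeA, file.path(outdir, "haplotypeA.fasta"))
write_genome_fasta(dk$genomeB, file.path(outdir, "haplotypeB.fasta"))
write_genome_metadata(dk$genomeA, file.path(outdir, "haplotypeA.json"))
write_genome_metadata(dk$genomeB, file.path(outdir, "haplotypeB.json"))
for (g in list(dk$genomeA, dk$genomeB)) {
  for (tr in names(g$tracks)) {
    write_track_bed(g$tracks[[tr]],
                    file.path(outdir, sprintf("%s_%s.bed", g$label, tr)))
  }
}
write_tsv(dk$truth$bins, file.path(outdir, "bins.tsv"))
write_tsv(dk$truth$homology, file.path(outdir, "homology_map.tsv"))
write_tsv(dk$truth$accessory, file.path(outdir, "accessory_regions.tsv"))
write_tsv(dk$truth$junction_rules, file.path(outdir, "junction_rules.tsv"))

cat(sprintf("haplotype A: %d chromosomes; haplotype B: %d chromosomes\n",
            length(dk$genomeA$chromosomes), length(dk$genomeB$chromosomes)))
cat(sprintf("informative bins: %d / %d (%.1f%%)\n",
            sum(dk$truth$bins$informative), nrow(dk$truth$bins),
            100 * mean(dk$truth$bins$informative)))
extra <- dk$genomeB$chromosomes$Chr12B
hm <- dk$truth$homology
donor <- hm[hm$chromB == "Chr12B", ]
cat(sprintf("extra chromosome: %s, %.0f kb, centromere: %s, %.0f%% homologous to %s\n",
            extra$id, extra$length / 1e3,
            ifelse(is.null(extra$centromere), "absent", "present"),
            100 * sum(interval_len(donor$startB, donor$endB)) / extra$length,
            donor$chromA[1]))
cat("accessory regions per haplotype:\n")
print(table(dk$truth$accessory$haplotype, dk$truth$accessory$type))
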