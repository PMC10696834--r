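Package: dikaryon
Title: Meiosis and Monospore Genotyping for Asymmetric Dikaryotic Fungal Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models meiosis in an asymmetric dikaryotic fungal genome in which
    the two haploid nuclei differ in chromosome number, arrangement and
    content. Provides a synthetic dikaryon generator with full planted truth
    (gradient heterozygosity, accessory chromosomes and compartments, an
    acentric extra chromosome homologous to another chromosome's arm,
    haplotype-biased LTR marker families), a mechanistic meiosis simulator
    (homologous pairing complex, breakage and rejoining at homology
    intersections forming new telomere-capped acentric chromosomes, spindle
    and free segregation, viability filtering by essential-gene complement),
    and the monospore-isolate genotyping pipeline: bin-wise haplotype origin
    calls from diagnostic-allele counts, recombination events, sites and
    hotspots, depth-based copy-number and aneuploidy calls with karyotype
    mixture fractions, junction-validated new-chromosome reconstruction, and
    genome-architecture and aneuploidy typing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
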