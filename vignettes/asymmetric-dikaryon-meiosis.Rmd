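---
title: "Modeling meiosis and monospore genotyping in an asymmetric dikaryotic genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling meiosis and monospore genotyping in an asymmetric dikaryotic genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dikaryon)
```

## The system

A basidiomycete dikaryon carries two distinct haploid nuclei, here labelled
haplotype A and haplotype B, through most of its life cycle. In the strain
this package models, the two nuclear genomes are *asymmetric*: haplotype B
has one more chromosome than A (12 vs 11), the large chromosomes Chr01,
Chr02 and Chr05 have their arms arranged differently between the two
architectures, and the extra chromosome (Chr12B) is *acentric* — it has
telomeres at both ends but no centromere, and most of its length is a
near-copy of the right arm of Chr05A. Heterozygosity between the nuclei is
a gradient mosaic: about a fifth of 10-kb bins are nearly identical while
others exceed 4% SNP density. Each nucleus also contains a "two-speed"
genome: three accessory minichromosomes and two accessory compartments with
high repeat content, low gene density and no conserved single-copy
orthologs (essential genes).

During meiosis this asymmetry has consequences. Homologous regions of
Chr01A/B, Chr02A/B, Chr05A/B and Chr12B pair into a single multi-chromatid
complex. Breakage at homology intersections followed by rejoining of the
unpaired haplotype-B-specific orphan segments can create *new* chromosomes
(ChrN1 = the Chr01B orphan joined to the reverse complement of the Chr12B
orphan prefix; ChrN2 = a Chr05B prefix joined to a reverse-complemented
Chr12B prefix); because each component prefix carries one telomere and no
centromere, the products are telomere-capped and acentric. The acentric
chromosomes cannot attach to the spindle and migrate irregularly —
preferentially with the products that carry their pairing partner. A
meiotic product is viable only if its chromosome complement covers every
required essential gene; because the B-architecture complement lacks the
Chr05 right-arm copy unless the acentric chromosome co-migrates, viable
spores are strongly biased toward the A architecture, and many of them
carry extra chromosomes (aneuploidy Types I–IV: extra Chr12B, ChrN1, ChrN2,
or Chr12B + ChrN1).

The package implements this end to end: a synthetic dikaryon generator with
full planted truth, a mechanistic meiosis simulator, and the
monospore-isolate genotyping pipeline (bin-wise haplotype origin,
recombination events and hotspots, depth-based copy number and karyotype
mixtures, junction-validated new-chromosome reconstruction, architecture
and aneuploidy typing).

## Coordinates and data model

All user-facing intervals are 1-based inclusive (`Chr12B:1-172535` style);
BED output converts to the standard 0-based half-open convention at the I/O
boundary and nowhere else. Chromosomes carry telomere state at each end and
an optional centromere interval; acentric chromosomes simply have none.
Feature tracks (genes, essential genes, repeats) are plain interval tables
validated against chromosome bounds. Homology blocks — paired oriented
intervals on two chromatids with a percent identity — are the pairing
substrate of the meiosis model.

## Sequence-feature rules and their defaults

**Telomeres.** Ends are scanned for the maximal tandem run of the motif
family TTA(G)~3–5~ (reverse complement at the 5' end), with the G-run free
to vary copy by copy and ambiguous bases never matching. Assembled ends
typically show 20–40 copies; the detection default `min_repeats = 10`
leaves margin for truncated ends and is exposed in the call.

**Accessory regions.** A region is accessory only if all three criteria
hold: gene density below 2.4 per 10 kb, repeat content above 40%, and zero
essential genes. The observed group statistics are separated (core ≥ 2.7
per 10 kb and ≤ 25.1% repeats; accessory < 2.4 and > 50%), so the defaults
sit between the groups; absence of essential genes is mandatory because it
is the most discriminative signal.

**Tandem-array copy number** is the ratio of probe-fragment depth to
single-copy depth — exact arithmetic, no estimation knobs.

**LTR-family phasing markers.** Two LTR families are each strongly biased
to one nucleus; a homolog is assigned to a haplotype when the winning
family has at least `min_count = 3` full-length copies and at least
`min_fold = 3` times the other family's count, otherwise it stays
unresolved. Mirror-image counts can never assign both homologs to the same
nucleus.

## The synthetic generator

`generate_dikaryon()` builds both haplotypes from a named *segment plan*:
every chromosome is a concatenation of named segments, and shared segment
names encode homology. The asymmetric preset is a deliberate miniature of
the study system — eight A chromosomes (0.05–0.7 Mb, ~2.3 Mb per
haplotype), arm swaps among Chr01/Chr02/Chr05 realizing the two
architectures, B-specific orphan prefixes on Chr01B (30 kb) and Chr12B
(35 kb), an acentric Chr12B built from its orphan plus a copy of the Chr05A
right arm (81% donor-derived), three accessory chromosomes and two
accessory compartments per haplotype, and telomere caps at every end. The
scale is chosen so the entire test suite, including 50-isolate property
suites, runs in minutes on one CPU; nothing in the logic depends on it, and
the geometry is configurable.

Per-bin SNP densities follow a configurable mosaic whose default mirrors
the observed histogram (21.8% of bins near-identical; four 15% classes
between 0.1% and 4%; 18.2% above 4% — the printed percentages total 101.1,
so the top class absorbs the rounding to make the fractions sum to 1). Bins
above 1% density are *informative* for origin calling; with the default
mosaic that is ~63% of non-accessory bins, matching the observed fraction.
Accessory regions are forced into the lowest density class by default
because all accessory regions of the real dikaryon lie in
low-heterozygosity territory.

`simulate_evidence()` produces what the genotyping stages consume, on the
haplotype-A reference frame (the study likewise maps isolate reads to the A
genome) plus the two B-specific orphan regions as pseudo-chromosomes:

* bin diagnostic-allele counts: `n ~ Poisson(coverage × copies)`,
  `nA ~ Binomial(n, pA)` with `pA` following the true origin at flip rate
  `allele_error`;
* window depths: `Poisson(coverage × copies)` per 10-kb window — the
  simplest model consistent with step-profile depth traces (a negative
  binomial would add overdispersion; the callers do not assume either);
* junction-spanning counts for each cataloged junction, with
  reference-span counts emitted only when an intact carrier molecule of
  the unbroken site is present; and architecture-breakpoint spanning
  counts.

Karyotype mixtures (a monospore culture that is a population of cells with
different karyotypes) enter as weight-averaged expected copy numbers, so an
80/20 mixture of two-copy and one-copy cells yields the characteristic
~1.8× depth. The mixture fraction is an explicit parameter; the generator
does not infer it from any published depth.

What the generator deliberately does **not** emulate: read-level errors
beyond the allele flip rate, mappability and GC bias, indels and small SVs
within segments, and ambiguous mapping between near-identical regions
(diagnostic reads are assumed to resolve to their source haplotype in
informative bins). Passing tests therefore demonstrate the correctness and
calibration of the callers under the stated sampling model, not robustness
to alignment artifacts in real data.

## The meiosis model

Meiosis is modelled at *segment granularity*: the claims being tested
concern architecture-scale outcomes (which arm combinations end up in which
products), not base-level crossover resolution.

`build_pairing_complex()` treats chromosomes of both haplotypes as
chromatids and homology blocks ≥ `min_block` (default 5 kb) as pairing
edges; connected components are the prophase-I complexes. On the asymmetric
map this yields one seven-chromatid complex (Chr01A/B, Chr02A/B, Chr05A/B,
Chr12B) whose unpaired stretches are exactly the two orphan segments, and
whose block-meeting coordinates — the physical contact points where
breakage can occur — coincide with the architecture breakpoints.
Contradictory (overlapping) blocks on one chromatid reject the map.

Junction rules fire independently per meiosis with configured
probabilities. No rate is quantified in the source material, so the default
is a conservative 0.05 and prominently configurable; setting all
probabilities to 0 reduces the simulator to classical Mendelian
segregation. A fired rule consumes one chromatid of each source chromosome,
emits the new chromosome, and leaves the telomere-lacking remainders as
fragments that are dropped after the meiosis with a logged count (unstable
inheritance). ChrN1 formation and intact-Chr12B transmission can co-occur
in one meiosis (the other sister chromatid remains available), which is
what produces Type IV products; a config with both rule probabilities and
chromatid accounting makes exclusivity emergent rather than hard-coded.

Segregation: each centromeric homolog pair splits 2+2 across the four
products with independent assortment; each acentric copy migrates to a
product carrying its designated partner with probability `acentric_bias`,
else uniformly elsewhere. The default bias is 0.7 — the source material
makes a qualitative claim (the acentric chromosome is "more likely" to
co-migrate with its pairing partner) without quantifying it, so the
package treats the value as a model parameter; the architecture bias among
viable spores holds for any value including the uniform 0.5, which the
tests also check.

Viability requires at least `required_fraction` (default 1) of the
essential genes present in one or more copies; the fraction knob exists
because only a subset of the extra chromosome's essential genes is known to
be strictly required. Essential genes may have several parental locations
(homologous segments on different chromosomes) and any covered location
counts.

`simulate_cohort()` offers two modes: Monte-Carlo over `n_meioses`, and
exhaustive enumeration of one meiosis by probability-tree summation over
junction-rule firing combinations × homolog assortments × acentric
placements (feasible for the reduced model: ≤ a few thousand weighted
outcomes). Enumeration is the oracle against which Monte-Carlo summaries
are tested; a conservation check verifies that every parental (chromosome,
segment) instance totals exactly two copies across the four products before
fragment loss, including segments relocated into new chromosomes.

## Genotyping, CNV, junctions, karyotypes

**Bin origin calling.** A bin is `A` when the A-allele share reaches
`purity` (default 0.9), `B` symmetrically, `HET` when both alleles reach
the 1 − purity share, `NA` otherwise or with fewer than `min_reads = 5`
reads. Raising purity can only move calls toward `HET`/`NA`, never create
homozygous calls.

**Events, sites, hotspots.** Events are A↔B transitions after collapsing
`NA`/`HET` gaps and suppressing homozygous runs shorter than `min_run = 2`
bins (single-bin flickers from allele error). The breakpoint interval runs
from the end of the last left-run bin to the start of the first right-run
bin and widens across a collapsed gap rather than inventing two events —
conservative event counting. Sites merge events whose intervals are within
`merge_distance = 10` bp; the default must and does keep the two printed
sites separated by 15 bp distinct. A site is a hotspot at ≥ 4 distinct
isolates. The observed analyses use both 10-kb and 100-kb bins; rather than
guessing which resolution produced which published total, the bin size is a
single config value used consistently.

**Copy number.** Ratios are window depth over the median of baseline
windows; the baseline excludes accessory regions and the extra-chromosome
footprints so known CNVs cannot contaminate the median. Region states snap
a 10%-trimmed mean to the half grid within `grid_tolerance = 0.1`;
off-grid means are routed to a two-state mixture between the bracketing
integers, and a half-grid call also reports its balanced-mixture reading
because true half-dosage and a 50/50 mixture are indistinguishable from
mean depth. The mixture model is deliberately the minimal two-state
version. Whole-chromosome calls additionally require 90% of windows
consistent with the call, where a window is consistent when its ratio is
strictly closer to the called state than to the expected copy number (an
absolute band is underpowered for gains at 30×). Loss of heterozygosity on
a region expected heterozygous (an extra chromosome atop its homologous
counterpart) is reported as maximal runs of ≥ `min_run` homozygous bins.

**Junctions and karyotypes.** Depth inflections are boundaries where
trimmed flank means differ by more than `min_step = 0.4`. A junction is
validated when `support ≥ 3` spanning reads exist and both broken
reference sites have at most `max_ref_span = 0` crossing reads — the
zero default encodes the observation that no reads cross a truly broken
site. When an intact carrier of one reference junction has already been
called in the same isolate (an intact extra chromosome co-occurring with a
new chromosome that reuses its arm, the Type IV situation), its reads
legitimately span that site, so the extra-chromosome caller waives the
reference-span requirement at exactly that site. Junction orientation is
represented explicitly per segment, covering all dyadic join classes even
though both cataloged examples are prefix + reverse-complement-prefix
joins. Reconstruction resolves segments against the haplotype genomes with
exact 1-based length arithmetic, telomere flags looked up at the model's
terminal source ends, centromere state from track overlap, and optional
sequence assembly. Architecture is called from breakpoint-spanning
evidence (unanimous informative breakpoints, else unresolved) because
monospore isolates are short-read sequenced. Aneuploidy typing is a pure
total mapping from the extras set; anything outside the catalog is
`other`, never a numbered type. Chromosome counts add extras to the
architecture base (11 for A, 12 for B at study scale; 8/9 in the scaled
synthetic genome). The published "17 / 11 / 3 isolates with 11 / 12 / 13
chromosomes" grouping enumerates A-architecture isolates, so the report
exposes that distribution explicitly.

**Printed-table fixtures.** Small TSVs under `inst/extdata/` carry the
published coordinate catalog and karyotype typology as *data*: chromosome
sizes at their printed Mb precision (with synthetic mid-chromosome
centromere placements, since positions are not printed), the
new-chromosome segment catalog, the printed extra-chromosome sizes (the
source tables round the same chromosome to 1.51 or 1.52 Mb in different
places; coordinate arithmetic here reports exact bp and leaves Mb rounding
to the report layer), both variants of the orphan-boundary coordinates,
and the 33-isolate karyotype table in which the unnamed A-architecture
euploid ids are clearly labelled synthetic.

## Determinism and problem sizes

Every stochastic step takes an explicit seed; the pipeline fans a master
seed out to per-stage child seeds by a fixed derivation
(`seed × 100 + stage`), so stages can be rerun in isolation and identical
configs reproduce byte-identical outputs (the run manifest records
checksums). Test and default problem sizes — a ~2.3 Mb genome, 33-isolate
cohorts at 30× with 1% allele error, 50-isolate property suites, 10^3–10^4
meioses with exact enumeration as oracle — were chosen so the whole suite
completes in a few minutes on one CPU while keeping binomial/Poisson
standard errors far from the tested thresholds.

## Known limitations

* The evidence model idealizes mapping: no mappability or GC bias, no
  chimeric reads, and diagnostic reads always resolve their haplotype in
  informative bins.
* Crossover modelling is architecture-scale; no base-level gene conversion
  or repair biochemistry.
* The mixture caller is two-state; "two or more karyotypes" collapses to
  the minimal model.
* Segmentation is half-grid plus runs; no HMM or circular binary
  segmentation.
* The meiosis model's junction probabilities and acentric bias are free
  parameters, not estimates; conclusions drawn from them are qualitative
  (direction of the architecture bias, possibility of co-occurrence), not
  rate predictions.
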