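# Orphan regions (> 50 kb with no alignment in the other haplotype) and
# the junction-breakpoint variants of the two haplotype-B orphan
# boundaries. The alignment-derived and junction-derived boundaries differ
# by a few bases in the source material; both are shipped as data.
region	chrom	start	end	context
Chr01B-C1	Chr01B	1	58696	alignment_orphan
Chr01B-C1	Chr01B	1	58690	junction_breakpoint
Chr12B-C1	Chr12B	1	172532	alignment_orphan
Chr12B-C1	Chr12B	1	172535	junction_breakpoint
Chr05A-orphan	Chr05A	795575	913748	alignment_orphan
Chr07A-orphan	Chr07A	1	125423	alignment_orphan
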