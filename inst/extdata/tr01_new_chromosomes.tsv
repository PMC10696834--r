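# Component segments of the new chromosomes observed in monospore
# isolates; orient "-" = reverse complement of the interval.
id	part	chrom	start	end	orient
ChrN1	1	Chr01B	1	58690	+
ChrN1	2	Chr12B	1	172535	-
ChrN2	1	Chr05B	1	675684	+
ChrN2	2	Chr12B	1	834373	-
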