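# Two closely spaced recombination-site intervals printed for Chr02A
# (1-based inclusive); the gap between them is 15 bp.
chrom	start	end
Chr02A	142183	142201
Chr02A	142217	142302
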