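# Printed sizes (Mb) of the extra chromosomes carried by aneuploid
# monospore isolates, as given in the karyotype typology table.
name	size_mb
Chr12B	1.52
ChrN1	0.23
ChrN2	1.52
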