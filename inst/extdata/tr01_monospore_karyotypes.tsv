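# Karyotype typology of the 33 monospore isolates. The 14 aneuploid
# isolates and the two B-architecture isolates carry their printed ids;
# the 17 A-architecture euploid isolates are only partially named in the
# study text, so the remaining ids are synthetic placeholders
# (id_source = synthetic). Cohort-level bookkeeping (aneuploid fraction,
# type counts, chromosome-count distribution) depends only on row counts.
isolate	architecture	extras	aneuploidy_type	id_source
DBZ18	A	Chr12B	I	printed
DBZ23	A	Chr12B	I	printed
DBZ25	A	Chr12B	I	printed
DBZ28	A	Chr12B	I	printed
DBZ29	A	Chr12B	I	printed
DBZ33	A	Chr12B	I	printed
DBZ46	A	Chr12B	I	printed
DBZ10	A	Chr12B	I	printed
DBZ15	A	ChrN1	II	printed
DBZ02	A	ChrN2	III	printed
DBZ08	A	ChrN2	III	printed
DBZ11	A	Chr12B,ChrN1	IV	printed
DBZ14	A	Chr12B,ChrN1	IV	printed
DBZ20	A	Chr12B,ChrN1	IV	printed
DBZ13	B		euploid	printed
DBZ47	B		euploid	printed
DBZ03	A		euploid	printed
DBZ04	A		euploid	printed
DBZ07	A		euploid	printed
DBZ43	A		euploid	printed
synA01	A		euploid	synthetic
synA02	A		euploid	synthetic
synA03	A		euploid	synthetic
synA04	A		euploid	synthetic
synA05	A		euploid	synthetic
synA06	A		euploid	synthetic
synA07	A		euploid	synthetic
synA08	A		euploid	synthetic
synA09	A		euploid	synthetic
synA10	A		euploid	synthetic
synA11	A		euploid	synthetic
synA12	A		euploid	synthetic
synA13	A		euploid	synthetic
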