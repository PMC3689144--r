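# The eight protein-coding loci of the Uzon MLSA scheme, with aligned
# fragment lengths (nt).  Frame offsets are not recorded in the source
# publication; 0 / bacterial code 11 are package defaults.
name	aligned_length	frame_offset	genetic_code_id
gyrB	1111	0	11
lepA	1264	0	11
leuS	1040	0	11
pyrG	1204	0	11
recA	739	0	11
recG	1227	0	11
rplB	507	0	11
rpoB	911	0	11
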