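# Locus panel: gene / FISH-probe loci used for copy-number queries.
# Columns: label, chromosome, band. Band placements follow standard probe
# designations (D20S108 maps to the 20q12 common deleted region probe).
label	chrom	band
MLL	11	q23.3
JAK2	9	p24.1
CDKN2A	9	p21.3
D20S108	20	q12
TET2	4	q24
TP53	17	p13.1
RUNX1	21	q22.12
FHIT	3	p14.2
MECOM	3	q26.2
MYB	6	q23.3
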