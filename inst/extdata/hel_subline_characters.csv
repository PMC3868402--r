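# SNP-array pattern differences among four HEL sublines (VCCS, DSMZ, ATCC,
# CGP), transcribed as binary presence/absence characters.  Each character
# is one copy-number deviation and the abnormal chromosome matching it in
# the VCCS karyotype.  class = LOH marks loss-of-heterozygosity characters
# (irreversible: heterozygosity cannot be regained); class = CNA marks
# plain copy-number characters (reversible in principle).  "?" marks cells
# whose published array pattern was flagged as conflicting/uncertain, or
# that could not be transcribed unambiguously.
name,class,VCCS,DSMZ,ATCC,CGP
chr3_loss_der_3_18,CNA,1,?,1,?
chr3_loss_der6_t_3_6,CNA,1,1,1,0
chr4_loss_loh_der_4_20,LOH,1,1,1,0
chr4_loss_loh_der8_t_4_8,LOH,1,1,1,0
chr4_loss_der4_t_4_14,CNA,1,?,?,?
chr4_gain_unlocated,CNA,1,0,0,0
chr8_gain_der8_t_4_8_13,CNA,1,0,0,0
chr8_gain_der8_t_4_8,CNA,1,1,1,0
chr10_gain_der_10_19_second_copy,CNA,1,?,?,0
chr11_loss_loh_der9_11q22_amp,LOH,1,0,0,0
chr11_gain_der_4_20,CNA,1,1,1,0
chr13_gain_der8_t_4_8_13,CNA,1,0,0,0
chr14_gain_der4_t_4_14,CNA,1,?,?,?
chr15_gain_der1_t_1_15,CNA,1,0,0,0
chr18_loss_der_3_18,CNA,1,0,1,0
chr18_loss_loh_r18,LOH,1,0,0,0
chr18_loss_loh_18qter_on_der9,LOH,1,0,0,0
chr19_gain_der_10_19_second_copy,CNA,1,?,?,0
chr19_gain_der19,CNA,1,?,1,1
chr20_gain_der_4_20,CNA,1,1,1,0
chr22_loss_monosomy22,CNA,1,1,1,0
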