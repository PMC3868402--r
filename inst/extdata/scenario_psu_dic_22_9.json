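{
  "name": "psu_dic_22_9",
  "description": "Reconstruction of the pseudodicentric (22;9) from an unstable dic(9;22): BFB cycles between the centromeres amplify 9p and 22p material; the broken product is stabilized by capture of the retained 22-centromere fragment and inactivation of the chromosome 9 centromere.",
  "initial": {
    "type": "dicentric",
    "chromA": "9", "bandA": "p24.3",
    "chromB": "22", "bandB": "p12"
  },
  "events": [
    { "op": "break", "frac": 0.9, "keep": "left" },
    { "op": "fuse" },
    { "op": "break", "frac": 0.55, "keep": "left" },
    { "op": "fuse" },
    { "op": "break", "frac": 0.6, "keep": "left" },
    { "op": "capture", "donor": 1 },
    { "op": "inactivate", "chrom": "9" }
  ]
}
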