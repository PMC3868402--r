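{
  "name": "ring20_excision",
  "description": "Formation of the pericentromeric ring 20 by excision from a hypothetical isodicentric intermediate: two inverted copies of the 20 centromere to 20q11.23 region (flanking material unknown); cuts on both sides of one centromere release a centromere-bearing ring of 20p11.1-20q11.21 material with no telomeric termini.",
  "initial": {
    "type": "isodicentric",
    "chrom": "20", "fromBand": "p11.1", "toBand": "q11.23"
  },
  "events": [
    { "op": "excise", "site": 1, "left": 2.5, "right": 5.5 }
  ]
}
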