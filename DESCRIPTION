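Package: karyorecon
Title: Karyotype Parsing, Reconstruction and Clonal Evolution Modelling for
    Complex Cancer Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for working with complex cancer karyotypes at cytogenetic
    band resolution: parsing and rendering ISCN (2013) karyotype strings
    including detailed-system derivative chromosomes, band-interval algebra
    and copy-number queries on a cytoband coordinate system, forward
    simulation of SNP-array (log R ratio / B-allele frequency) and FISH
    (M-FISH, M-BAND, centromere, NOR) observations from a homologue-labelled
    karyotype, inversion of that forward model (segmentation, allele-specific
    copy-number calling, constraint-based assignment of segments to
    derivative chromosomes), inference of subline phylogeny from copy-number
    and loss-of-heterozygosity characters with LOH irreversibility, and
    simulation of breakage-fusion-bridge evolution of dicentric chromosomes
    with stabilization by centromere inactivation, telomere/centromere
    capture or ring excision. The bundled fixtures model the HEL
    erythroleukaemia cell line.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
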