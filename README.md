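# karyorecon

Band-resolution tools for reconstructing and evolving complex cancer
karyotypes, built around the HEL erythroleukaemia cell line as a worked
fixture.

Highly rearranged cancer genomes are usually described twice: once as an
ISCN karyotype string (the cytogeneticist's summary of G-banding, M-FISH,
M-BAND and locus FISH) and once as SNP-array copy-number / B-allele
frequency (BAF) tracks. Neither alone determines the structure of the
abnormal chromosomes; combining them does. `karyorecon` makes that
combination computable, for cancer cytogeneticists and genome-evolution
researchers who want the reasoning steps — not just the conclusions — to
be reproducible and testable:

* **ISCN (2013) parsing and rendering**, including the detailed system
  (`der(20)(15qter->15q11.2::20q10->20q11.1::…)`), whole-arm derivatives,
  rings, pseudodicentrics, `amp`/`del` modifiers and `?`/`~` uncertainty;
  parse → render → parse is a fixed point.
* **Band-interval algebra** on a bundled ~550-band cytoband map: locus
  containment, centromere spanning via `p10`/`q10` markers, copy-number
  queries (with the BAF expectation `E[BAF] = n_B / (n_A + n_B)` for
  homologue counts `n_A`, `n_B`).
* A **forward model** of SNP-array probes
  (`LRR = log2(t/2) + N(0, σ_lrr)`, clamped noisy BAF, seeded and
  reproducible) and of FISH observations (M-FISH source sets, M-BAND
  blocks, centromere and NOR probe counts).
* The **inverse model**: joint binary segmentation of folded BAF and LRR,
  allele-specific calls `(n_A, n_B)` with `n_A ≥ n_B`, and exact
  backtracking assignment of segments to derivatives under paint,
  centromere and terminal-segment constraints.
* **Subline phylogeny** by exhaustive rooted-tree parsimony in which LOH
  characters are irreversible (1 → 0 forbidden; heterozygosity cannot be
  regained), rooted at an all-zero founding clone.
* **Breakage–fusion–bridge simulation** of dicentric chromosomes —
  uniform bridge breaks between active centromeres, palindromic
  sister-chromatid fusions — with stabilization by centromere
  inactivation, telomere/centromere capture or pericentromeric ring
  excision, replayable histories, and consistency tests for copy-number
  profiles.

## Worked example

```r
library(karyorecon)

m <- parseKaryotype(helKaryotype())   # the bundled HEL (VCCS) karyotype

locusCopyNumber(m, "MLL")
#> $count
#> [1] 5
#> $uncertain
#> [1] FALSE

normalCount(m, "9")                   # no normal chromosome 9 remains
#> [1] 0

length(chromCarriers(m, "20"))        # abnormal chromosomes with 20 material
#> [1] 5
length(centromereCarriers(m, "20"))   # ... of which carry the 20 centromere
#> [1] 3

fish <- simulateFish(m)               # XCyte M-BAND panel by default
Filter(function(o) o$label == "der(19)", fish@observations)[[1]]$sources
#> [1] "11" "15" "19" "20"

bestTree(helSublineCharacters())[[1]]
#> LineageTree (score 21): (((VCCS,ATCC),DSMZ),CGP);
#>   ATCC+VCCS: chr3_loss_der_3_18 0->1
#>   ...
```

Reading the numbers: the karyotype implies five copies of the *MLL*
oncogene (a net gain of two over the triploid baseline), five abnormal
chromosomes carrying chromosome-20 material of which three retain the 20
centromere, a der(19) whose paint content is chromosomes 11, 15, 19 and
20, and a unique most-parsimonious subline tree in which CGP diverged
first and VCCS is closest to ATCC, with every LOH character gained
exactly once.

The forward/inverse loop on a synthetic three-derivative karyotype:

```r
toy <- "48,XX,der(1)t(1;5)(p22.1;q23.1),der(3)t(3;8)(q21;q22.1),+der(11)t(11;20)(p11.2;q11.22)"
hk  <- assignHomologues(parseKaryotype(toy))
res <- recover(hk, probeGrid(chroms = c("1","3","5","8","11","20"), d = 50),
               sigmaLrr = 0.15, sigmaBaf = 0.03, seed = 1,
               panel = c("1","3","5","8","11","20"))
res$bandAccuracy        # fraction of bands with the correct (nA, nB) call
#> [1] 1
```

See the vignette (`vignettes/karyotype-reconstruction.Rmd`) for the
model, parameter choices and limitations.

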