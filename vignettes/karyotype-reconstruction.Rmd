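---
title: "Reconstructing complex cancer karyotypes at cytoband resolution"
author: "karyorecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing complex cancer karyotypes at cytoband resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyorecon)
```

# Scope and model

`karyorecon` models a highly rearranged cancer genome — the HEL
erythroleukaemia cell line is the bundled worked example — at cytogenetic
band resolution. Five connected pieces are implemented:

1. a **band-level coordinate system** (cytoband ordinals, interval algebra,
   centromere semantics);
2. an **ISCN (2013) parser and renderer** covering the detailed system, so
   that a printed karyotype string becomes a queryable object;
3. a **forward model** producing synthetic SNP-array (LRR/BAF) and FISH
   (M-FISH / M-BAND / centromere / NOR) observations from a
   homologue-labelled karyotype;
4. the **inverse model**: segmentation of the array signal, allele-specific
   copy-number calling, and constraint-based assignment of segments to
   derivative chromosomes;
5. two evolutionary layers: **subline phylogeny** from CNA/LOH characters
   with LOH irreversibility, and **breakage–fusion–bridge (BFB)
   simulation** of dicentric chromosomes with stabilization events.

## Band-ordinal coordinates

All interval logic is ordinal: band *k* of a chromosome is an integer
position in pter→qter order, `pter` sits below every band and `qter` above,
and synthetic `p10`/`q10` markers flank the centromere. This matches the
information content of a karyotype string, which names bands, not base
pairs. The bundled cytoband table is written at roughly the 550-band ISCN
resolution; its band names and order follow the standard human ideogram
while its base-pair coordinates are nominal (proportional widths), since no
computation in the package consumes them beyond ordering. A sub-band
(`11q23.3`) nests inside its parent designator (`11q23`) by name prefix; a
query at parent resolution resolves to the widest span of its leaves, and a
locus given at parent resolution is contained in an interval iff any of its
sub-bands is.

Uncertain tokens are resolved conservatively: `19p13.?` becomes the widest
`19p13` span, `22p11~2` the union of the `p11` and `p12` spans, and the
uncertainty flag propagates to query results.

## ISCN dialect and bookkeeping

The parser supports exactly the constructs a complex myeloid karyotype
uses: numerical gains/losses, `der` with one or more `t()` clauses
(including three-way translocations), whole-arm `der(A;B)(p10;q10)`,
detailed-system segment lists with `::` junctions, rings, `psu dic`,
`dup`, `del`, trailing `del`/`amp`/`dup` modifier clauses, `?`/`~`
uncertainty, ploidy markers and clone frequencies. Anything else raises an
explicit *unsupported construct* error rather than being skipped silently.
Detailed-system segments are stored exactly as written (written order is
physical order); short forms are expanded to segments at parse time, with
the expansion canonicalized pter→qter along the derivative.

Two bookkeeping decisions deserve justification:

* **Principal clone.** Karyotypes with bracketed cell counts describe a
  population in which some events are alternative subclonal fates of the
  same homologue (in HEL, `-18[4]` and `r(18)[7]` partition the same
  eleven cells). Counting every event would drive the normal-18 tally
  negative. Copy-number queries therefore evaluate the *principal clone*:
  events whose clone frequency exceeds half the modal frequency (events
  without a frequency always count). This reproduces the published
  absence of normal chromosomes 9 and 18 and the five copies of *MLL*.
* **`amp` with no count.** An `amp` clause without a multiplicity is
  stored as "unspecified" and enters copy-number queries as a flagged
  lower bound of two extra copies; every result derived through such a
  segment carries an `uncertain` marker. The true amplification level
  (e.g. the reported eight copies of mutant *JAK2*) is not recoverable
  from the string, and the package does not pretend otherwise.

Rendering produces a canonical string (events sorted by chromosome and
class, descriptive sex losses kept next to the sex designation, additional
copies of a derivative sorted after their definition), and
`parse ∘ render` is a fixed point — a property the test-suite exercises on
the HEL karyotype plus 200 generated karyotypes per run.

# The forward model

`assignHomologues()` turns a parsed karyotype into a ground truth: all
structured segments ride homologue **A** (the rearranged homologue), the
remaining normal copies of an event-carrying chromosome are homologue
**B** (in HEL the un-rearranged homologue is the duplicated one), and
event-free chromosomes split their normals evenly. A chromosome whose
normal count is zero is then fully homozygous — the LOH signature.

`simulateArray()` emulates Illumina-style data per probe at a band with
homologue counts $(n_A, n_B)$, $t = n_A + n_B$:

$$\mathrm{LRR} = \log_2(t/2) + \varepsilon_L,\qquad
  \mathrm{BAF} = \mathrm{clamp}_{[0,1]}\!\left(\frac{n_B}{t} + \varepsilon_B\right)$$

with $\varepsilon_L \sim N(0, \sigma_\mathrm{lrr})$,
$\varepsilon_B \sim N(0, \sigma_\mathrm{baf})$. Site zygosity is Bernoulli
(*h*) per probe from the seeded stream; homozygous sites expect BAF 0 or 1
regardless of copy state; $t = 0$ emits a no-signal sentinel (`NA`).
LRR is **diploid-referenced** regardless of the karyotype's ploidy
baseline, because that is how array software reports near-triploid
genomes; ploidy enters only at calling time.

Defaults, all overridable: `d = 50` probes per band, heterozygosity
`h = 0.35`, `sigmaLrr = 0.15`, `sigmaBaf = 0.03`. These are generator
choices of realistic magnitude (CytoSNP-class arrays yield a few dozen
informative probes per cytoband; LRR noise around 0.1–0.2 and BAF noise
around 0.03 are typical of good-quality cell-line DNA), not published
measurements — no test or acceptance check depends on their exact values
beyond the stated tolerances. Probe positions are evenly spaced within
each band on the band-index pseudo-coordinate; the simulator makes no
attempt at base-pair realism, GC waves, or dye bias.

`simulateFish()` is deterministic: per structured chromosome it reports
the M-FISH source set restricted to a probe panel (default: the XCyte
M-BAND panel {3,4,10,11,13,15,18,19,20} used for HEL), ordered M-BAND
band blocks, centromere-probe counts (segments spanning the tested
centromere), and NOR positivity (acrocentric p11.2–p13 material, with
unwritten `amp` multiplicity counted at its display default).

# The inverse model

Segmentation is binary segmentation jointly on two channels — folded BAF
$|\mathrm{BAF} - 0.5|$ over all probes, and LRR — accepting a split when
it reduces total within-segment squared error by more than `penalty`
(default 1) with at least `minProbes` (default 10) probes per side. Using
*all* probes in the folded channel (not only heterozygous-classified
ones) is deliberate: in an LOH region every probe folds to ≈ 0.5, so the
channel mean shifts with the heterozygous fraction and LOH boundaries
with unchanged total copy number remain detectable.

Calling then classifies probes with BAF outside [0.08, 0.92] as
homozygous-site candidates; the folded-BAF mean over heterozygous
classified probes (0.5 when none classify — the LOH case) and the LRR
mean give

$$t = \mathrm{round}(2 \cdot 2^{\overline{\mathrm{LRR}}}),\qquad
 (n_A, n_B) = \arg\min_{n_A + n_B = t,\; n_A \ge n_B}
 \left|\overline{f} - \left(\tfrac{n_A}{t} - \tfrac12\right)\right|$$

with ties broken toward the more balanced pair and *t* capped at 8.
Phase (which side is homologue A) is *not* inferred from array data —
that mirrors the field's reliance on FISH for structure; the folded
convention $n_A \ge n_B$ is kept until derivative assignment.

`assignSegments()` is an exact backtracking search over assignments of
rearranged segments to derivatives under the paint constraints: source-set
equality, centromere-count equality, at most two terminal
(pter/qter-reaching) segments per derivative and none on rings, and —
when M-BAND blocks are supplied — per-chromosome block-multiset equality
(which guarantees an ordering consistent with the observed block order
exists). All solutions are returned in deterministic order; ambiguity is
reported, never silently resolved, and segments whose chromosome appears
in no paint set are listed as unplaced. Search order is derivatives by
decreasing paint-set size and segments by decreasing span, to fail fast.

`recover()` chains simulation → segmentation → calling → assignment and
scores band-level allele-specific accuracy (fraction of leaf bands whose
called $(n_A, n_B)$, folded, equals the truth) plus derivative-composition
accuracy. The segments offered to the assignment stage are those whose
state differs from the chromosome's *non-rearranged background*, taken as
the state with the smallest total copy number: derivatives add copies of
the rearranged homologue, so the background never has more copies than a
derivative-bearing region. The bundled three-derivative toy karyotype
(`der(1)t(1;5)`, `der(3)t(3;8)`, `+der(11)t(11;20)` over a diploid base)
inverts exactly in the noise-free limit and stays ≥ 95% accurate at the
default noise levels over ten seeds; the test-suite runs it at 50
probes/band over six chromosomes (~12,000 probes), a size chosen to make
segment means tight while keeping the suite quick to run routinely.

# Subline lineage

The bundled character matrix transcribes the published SNP-array
comparison of the four HEL sublines (VCCS, DSMZ, ATCC, CGP) into 21
presence/absence characters, each classed **LOH** (irreversible — lost
heterozygosity cannot be regained) or **CNA** (reversible in principle).
Cells whose published pattern was flagged as conflicting, and the few
cells whose column attribution could not be transcribed unambiguously,
are encoded `?` (free); one row ("17qter gain from the normal homologue")
could not be expressed as a presence/absence character and was dropped.
The transcription lives in a commented CSV so it can be audited without
touching code.

Scoring is small parsimony over rooted binary topologies with the
founding clone fixed in the all-zero state on a **stem edge** above the
sublines' most recent common ancestor (so an aberration shared by every
subline costs one change, on the trunk). LOH characters forbid the 1→0
transition outright — extra independent gains are the only way to explain
a conflicting pattern. With at most 8 taxa every rooted topology
($(2n-3)!!$ of them) is enumerated and all minimizers returned; ties are
reported, not broken. On the bundled matrix the minimizer is unique:
CGP diverges first and (ATCC, VCCS) are the closest pair, with no LOH
character changing more than once. The test-suite cross-checks the scores
against an exhaustive ancestral-labeling oracle and (for reversible
characters) against phangorn's Fitch parsimony with the founder attached
as an outgroup leaf.

`eventOrderConstraints()` encodes the triploid-genome ordering argument:
if one copy of a duplicated homologue is rearranged, the rearrangement
postdates the doubling; a derivative present in identical copies formed
before it duplicated; declared descents (e.g. a der(4;20) remodelled from
a duplicated der(20)) chain formation ≺ duplication ≺ remodelling. The
constraint set is checked for cycles and returned with a topological
order.

# Breakage–fusion–bridge simulation

Structures are ordered, oriented blocks in continuous band-unit source
coordinates (breaks are sub-band), with explicit centromere sites carrying
activity flags and explicit end states. One BFB cycle is: a bridge break
at a position uniform strictly *between* the two active centromeres, the
segregation of one product (always-left, always-right or random), and
sister-chromatid fusion — the product followed by its own mirror image, a
palindrome about the junction that recreates a dicentric. Stabilization
events are centromere inactivation (pseudodicentric), telomere or
centromere capture (donor fragments are explicit inputs, never invented),
and pericentromeric ring excision (ring plus two remnants). Histories log
every event and replay to identical structures.

Two invariants hold for every run: content is conserved at each break
(the products partition the parent), and amplification is confined
between the founding centromeres — the tails outside them are carried
whole at a constant dose, which is exactly the published hallmark of
dicentric-driven amplification restricted to one arm of each partner.
`bfbConsistent()` additionally checks that the fused-arm counts form a
unimodal staircase toward the historical fusion side (band resolution,
ties allowed). Simulation shows this staircase is a *few-cycle*
signature: through three cycles it held in every seeded run we tested,
while from about four cycles the interleaved fold positions of a genuine
BFB history can produce multi-modal profiles. The staircase check is
therefore separable (`checkStaircase = FALSE`) and the universal claims
rest on the confinement conditions.

Two scenario scripts are bundled as JSON event lists. The
pseudodicentric (22;9) replay starts from dic(9;22)(p24.3;p12), runs
seeded break/fusion cycles that amplify 9p and 22p between the
centromeres, and stabilizes by capturing the retained 22-centromere
fragment and inactivating the 9 centromere. The capture step is forced by
the mechanics: once the first bridge break segregates the 22 centromere
away, mirror fusions can only duplicate the surviving centromere, so a
product carrying *both* a 9 and a 22 centromere — as the real
pseudodicentric does — must have re-acquired the 22 side from a retained
fragment. The ring-20 replay excises the pericentromeric
20p11.1–20q11.21 region of a hypothetical isodicentric intermediate into
a centromere-bearing ring with no telomeric termini.

# Degenerate inputs and numerical choices

* Probes over zero-copy regions are NA (dropout) and dropped before
  segmentation; chromosomes with fewer than `2 * minProbes` probes return
  no changepoints and are flagged.
* Segmentation is deterministic for fixed input; all simulation functions
  take integer seeds, restore the caller's RNG state, and are pure
  functions of (inputs, seed).
* Equality tolerances: changepoint acceptance uses the squared-error
  `penalty` on the raw channel scales (LRR jumps of one copy are ≈ 0.58,
  far above noise at the defaults); count comparisons in
  `bfbConsistent()` use a 1e-9 tolerance; tie-breaks (balanced-pair
  calls, parental-state reconstruction) are deterministic.
* Break positions exactly on a block boundary (probability zero under the
  uniform draw) shift the whole block to one product.

# What the synthetic data do and do not show

The generator reproduces the *statistical structure* the interpretation
relies on — per-segment expected BAF equal to the relative homologue
ratio, log-scale diploid-referenced total-copy signal, Gaussian probe
noise, a heterozygous/homozygous germline mixture, and deterministic
paint/centromere/NOR content. It does not reproduce platform artifacts
(GC waves, dye bias, mosaicism, X-inactivation effects), base-pair probe
spacing, or FISH signal-intensity noise. Passing the inversion tests
therefore shows the algorithms are correct against their own forward
model at realistic noise, not that they would match a specific
commercial caller's output on real arrays; concordance with such callers
is out of scope by design.

# Known limitations

* Band-resolution only: segment lengths beyond band spans (e.g. the
  ~3 Mb captured 19-centromere fragment) are not modelled.
* The ISCN dialect is the subset above; composite clones (`[cp]`),
  `inv`/`ins`/`idic` short forms and chromoanagenesis notation are
  rejected.
* Amplification multiplicities written as bare `amp` are lower bounds.
* Lineage inference is exhaustive and limited to 8 taxa; no branch
  lengths or likelihood model.
* The ISCN bookkeeping of the bundled karyotype leaves one normal
  chromosome 20, while two normal copies of one 20 homologue were
  reported — the string under-specifies a gained normal 20; the package
  follows the written string.
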