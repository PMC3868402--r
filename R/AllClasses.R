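#' @import methods
NULL

#' Cytoband coordinate map
#'
#' Ordered cytogenetic band map for a genome, read from a UCSC
#' \code{cytoBand.txt}-dialect file.  Bands are held in pter->qter order per
#' chromosome and indexed by an integer ordinal; synthetic centromeric
#' markers \code{p10} and \code{q10} are inserted at the p/q junction so that
#' centromere-spanning queries work at band resolution.  Base-pair
#' coordinates, when present, are carried along but all interval algebra is
#' ordinal.
#'
#' @slot bands data.frame with columns \code{chrom}, \code{band}, \code{arm},
#'   \code{ordinal}, \code{start}, \code{end}, \code{stain}.
#' @exportClass CytobandMap
setClass("CytobandMap", representation(bands = "data.frame"))

setValidity("CytobandMap", function(object) {
  b <- object@bands
  need <- c("chrom", "band", "arm", "ordinal", "start", "end", "stain")
  if (!all(need %in% names(b))) {
    return(paste("bands must have columns", paste(need, collapse = ", ")))
  }
  for (ch in unique(b$chrom)) {
    x <- b[b$chrom == ch, ]
    if (any(duplicated(x$band))) {
      return(paste0("duplicated band names on chromosome ", ch))
    }
    if (is.unsorted(x$ordinal, strictly = TRUE)) {
      return(paste0("ordinals not strictly increasing on chromosome ", ch))
    }
    if (any(x$arm == "q") && any(x$arm == "p")) {
      if (max(which(x$arm == "p")) > min(which(x$arm == "q"))) {
        return(paste0("p bands must precede q bands on chromosome ", ch))
      }
    }
    if (!all(c("p10", "q10") %in% x$band)) {
      return(paste0("missing p10/q10 centromere markers on chromosome ", ch))
    }
    if (match("q10", x$band) != match("p10", x$band) + 1L) {
      return(paste0("p10 and q10 must be adjacent on chromosome ", ch))
    }
  }
  TRUE
})

setMethod("show", "CytobandMap", function(object) {
  b <- object@bands
  cat("CytobandMap:", length(unique(b$chrom)), "chromosomes,",
      sum(!b$band %in% c("p10", "q10")), "bands",
      "(+ centromere markers)\n")
})

#' A structurally rearranged (or modified) chromosome
#'
#' One structured-chromosome event of a karyotype: a derivative (\code{der}),
#' ring (\code{r}), pseudodicentric (\code{psu dic}), duplication
#' (\code{dup}) or deletion (\code{del}) chromosome.  The physical content is
#' an ordered, oriented list of band-interval segments (as in the ISCN
#' detailed system, where written order is physical order); short-form
#' events are expanded to segments at parse time.  Trailing del/amp/dup
#' clauses are kept as modifiers that adjust copy number over their band
#' range without rewriting the segment list.
#'
#' @slot kind one of "der", "r", "psu dic", "dup", "del".
#' @slot cenChroms chromosomes cited in the event name (their centromeres).
#' @slot gained TRUE for events written with a leading "+".
#' @slot ring TRUE for ring chromosomes.
#' @slot segments data.frame of oriented segments (one row per segment):
#'   \code{chrom}, \code{start}, \code{end} (band tokens as written),
#'   \code{lo}, \code{hi} (resolved ordinal span), \code{inverted},
#'   \code{multiplicity}, \code{multUnspecified}, \code{homologue},
#'   \code{uncertain}.
#' @slot modifiers data.frame of trailing clauses: \code{op} (del/amp/dup),
#'   \code{chrom}, \code{lo}, \code{hi}, \code{uncertain}.
#' @slot activeCen for pseudodicentrics, the chromosome whose centromere is
#'   active (first-cited, per ISCN); NA otherwise.
#' @slot freq clone frequency (bracketed cell count), NA if absent.
#' @slot text normalized ISCN clause (without gain sign or frequency), used
#'   for canonical rendering.
#' @slot label short display label, e.g. "der(4;20)".
#' @slot uncertain TRUE when the event carries "?"/"~" uncertainty.
#' @exportClass StructuredChromosome
setClass("StructuredChromosome", representation(
  kind = "character", cenChroms = "character", gained = "logical",
  ring = "logical", segments = "data.frame", modifiers = "data.frame",
  activeCen = "character", freq = "integer", text = "character",
  label = "character", uncertain = "logical"))

setValidity("StructuredChromosome", function(object) {
  if (!object@kind %in% c("der", "r", "psu dic", "dup", "del")) {
    return("unknown structured-chromosome kind")
  }
  if (object@ring && nrow(object@segments) > 0) {
    segs <- object@segments
    if (any(segs$start %in% c("pter", "qter") | segs$end %in% c("pter", "qter"))) {
      return("ring chromosomes cannot have pter/qter termini")
    }
  }
  if (identical(object@kind, "psu dic")) {
    if (length(object@cenChroms) < 2) {
      return("psu dic must cite at least two centromere chromosomes")
    }
    if (length(object@activeCen) != 1 || is.na(object@activeCen)) {
      return("psu dic must flag exactly one active centromere")
    }
  }
  TRUE
})

setMethod("show", "StructuredChromosome", function(object) {
  cat(if (object@gained) "+" else "", object@text,
      if (!is.na(object@freq)) sprintf("[%d]", object@freq) else "",
      "\n", sep = "")
  if (nrow(object@segments)) {
    cat("  ", nrow(object@segments), "segment(s):",
        paste0(object@segments$chrom, ":", object@segments$start, "->",
               object@segments$end, collapse = " :: "), "\n")
  }
})

#' Parsed karyotype model
#'
#' The result of parsing a single-clone ISCN karyotype string: chromosome
#' count range, ploidy baseline, sex-chromosome designation and an event
#' list of numerical gains/losses and \linkS4class{StructuredChromosome}
#' objects, each with an optional clone frequency.
#'
#' @slot countRange numeric(2): chromosome count range (may be equal).
#' @slot ploidy integer ploidy baseline (e.g. 3 for "<3n>"); 2 if unstated.
#' @slot sex sex-chromosome designation as written (e.g. "XY", "X").
#' @slot events list of events: numerical events are lists with fields
#'   \code{kind = "num"}, \code{chrom}, \code{delta}, \code{freq},
#'   \code{reflected} (TRUE for sex losses already folded into the sex
#'   designation); structured events are StructuredChromosome objects.
#' @exportClass KaryotypeModel
setClass("KaryotypeModel", representation(
  countRange = "numeric", ploidy = "integer", sex = "character",
  events = "list"))

setValidity("KaryotypeModel", function(object) {
  if (!(object@ploidy >= 1 && object@ploidy <= 8)) {
    return("ploidy baseline must be in 1..8")
  }
  for (ev in object@events) {
    if (is(ev, "StructuredChromosome")) next
    if (!identical(ev$kind, "num")) return("unknown event kind")
  }
  TRUE
})

setMethod("show", "KaryotypeModel", function(object) {
  cat("KaryotypeModel: ", renderKaryotype(object), "\n", sep = "")
})

#' Homologue-assigned karyotype
#'
#' A \linkS4class{KaryotypeModel} whose structured segments carry homologue
#' labels (A/B) and whose normal chromosomes are split into per-homologue
#' counts.  This is the ground truth object that the forward models
#' (\code{\link{simulateArray}}, \code{\link{simulateFish}}) consume.
#'
#' @slot model the underlying KaryotypeModel (segments labelled).
#' @slot normalA named integer: normal copies of homologue A per chromosome.
#' @slot normalB named integer: normal copies of homologue B per chromosome.
#' @exportClass HomologueAssignedKaryotype
setClass("HomologueAssignedKaryotype", representation(
  model = "KaryotypeModel", normalA = "integer", normalB = "integer"))

setMethod("show", "HomologueAssignedKaryotype", function(object) {
  cat("HomologueAssignedKaryotype over:\n  ",
      renderKaryotype(object@model), "\n", sep = "")
})

#' Simulated SNP-array observation
#'
#' Per-probe log R ratio (LRR) and B-allele frequency (BAF) values on a
#' band-resolved pseudo-coordinate grid, as produced by
#' \code{\link{simulateArray}}.  LRR is diploid-referenced
#' (\code{log2(t/2)}) regardless of the karyotype's ploidy baseline,
#' matching how SNP-array software reports near-triploid genomes.
#'
#' @slot probes data.frame: \code{probe_id}, \code{chrom}, \code{band},
#'   \code{pos} (band ordinal + within-band fraction), \code{lrr},
#'   \code{baf}.  Probes over zero-copy regions carry NA (no-signal
#'   sentinel).
#' @slot sigmaLrr,sigmaBaf Gaussian noise standard deviations used.
#' @slot seed integer seed the observation was generated from.
#' @exportClass ArrayObservation
setClass("ArrayObservation", representation(
  probes = "data.frame", sigmaLrr = "numeric", sigmaBaf = "numeric",
  seed = "integer"))

setValidity("ArrayObservation", function(object) {
  baf <- object@probes$baf
  if (any(!is.na(baf) & (baf < 0 | baf > 1))) return("BAF must lie in [0,1]")
  TRUE
})

setMethod("show", "ArrayObservation", function(object) {
  cat("ArrayObservation:", nrow(object@probes), "probes on",
      length(unique(object@probes$chrom)), "chromosomes",
      sprintf("(sigma_lrr = %g, sigma_baf = %g, seed = %d)\n",
              object@sigmaLrr, object@sigmaBaf, object@seed))
})

#' Simulated FISH observation set
#'
#' Deterministic whole-chromosome-paint style observations for each
#' structured chromosome of a karyotype: M-FISH source-chromosome sets
#' (restricted to a probe panel), M-BAND ordered band blocks, per-chromosome
#' centromere-probe counts, and NOR-positive site counts (acrocentric
#' short-arm material).
#'
#' @slot panel chromosomes covered by the paint/band probe panel.
#' @slot observations list, one element per structured chromosome:
#'   \code{label}, \code{sources}, \code{mband} (named list of ordered band
#'   blocks), \code{cenCounts} (named integer), \code{norCount}, \code{ring}.
#' @exportClass PaintObservation
setClass("PaintObservation", representation(
  panel = "character", observations = "list"))

setMethod("show", "PaintObservation", function(object) {
  cat("PaintObservation for", length(object@observations),
      "structured chromosomes; panel {",
      paste(object@panel, collapse = ","), "}\n")
  for (o in object@observations) {
    cat("  ", o$label, ": sources {", paste(o$sources, collapse = ","),
        "}, cen counts [", paste(names(o$cenCounts), o$cenCounts,
                                 sep = ":", collapse = " "),
        "], NOR ", o$norCount, "\n", sep = "")
  }
})

#' Taxa-by-aberration character matrix
#'
#' Binary characters (aberration present/absent, "?" unknown) scored across
#' cell-line sublines, each flagged as reversible (plain copy-number change)
#' or irreversible (loss of heterozygosity, which cannot be regained).
#'
#' @slot taxa character vector of taxon names.
#' @slot states integer matrix (characters x taxa) with values 0, 1 or NA
#'   (NA encodes "?").
#' @slot classes character vector per character: "CNA" (reversible) or
#'   "LOH" (irreversible).
#' @exportClass CharacterMatrix
setClass("CharacterMatrix", representation(
  taxa = "character", states = "matrix", classes = "character"))

setValidity("CharacterMatrix", function(object) {
  if (length(object@taxa) < 2) return("need at least two taxa")
  if (ncol(object@states) != length(object@taxa)) {
    return("states must have one column per taxon")
  }
  if (nrow(object@states) != length(object@classes)) {
    return("one class flag per character required")
  }
  if (!all(object@classes %in% c("CNA", "LOH"))) {
    return("classes must be 'CNA' or 'LOH'")
  }
  ok <- object@states %in% c(0L, 1L, NA)
  if (!all(ok)) return("states must be 0, 1 or NA")
  if (!any(apply(object@states, 1, function(r) length(unique(stats::na.omit(r))) > 1))) {
    return("at least one character must vary")
  }
  TRUE
})

setMethod("show", "CharacterMatrix", function(object) {
  cat("CharacterMatrix:", nrow(object@states), "characters x",
      length(object@taxa), "taxa (",
      sum(object@classes == "LOH"), "irreversible LOH )\n")
})

#' Rooted lineage tree with character changes
#'
#' A rooted binary tree over sublines, rooted at the founding clone (all
#' characters in state 0), with the per-edge character-state changes of a
#' most-parsimonious reconstruction under LOH irreversibility.
#'
#' @slot tree an \code{ape::phylo} rooted binary tree.
#' @slot changes data.frame: \code{edge} (child node label/index),
#'   \code{character}, \code{from}, \code{to}.
#' @slot score parsimony score of the tree on its matrix.
#' @exportClass LineageTree
setClass("LineageTree", representation(
  tree = "ANY", changes = "data.frame", score = "numeric"))

setMethod("show", "LineageTree", function(object) {
  cat("LineageTree (score ", object@score, "): ",
      ape::write.tree(object@tree), "\n", sep = "")
  if (nrow(object@changes)) {
    for (i in seq_len(nrow(object@changes))) {
      ch <- object@changes[i, ]
      cat("  ", ch$edge, ": ", ch$character, " ", ch$from, "->", ch$to,
          "\n", sep = "")
    }
  }
})

#' Linear (or ring) chromosome structure for BFB simulation
#'
#' A chromosome modelled as an ordered list of oriented blocks in continuous
#' source coordinates (band ordinal units), with explicit centromere sites
#' (active/inactive) and end states.  A dicentric has two active
#' centromeres; a stable chromosome has one active centromere and both ends
#' telomere-capped, or is a ring with one active centromere and no ends.
#'
#' @slot blocks data.frame: \code{chrom}, \code{lo}, \code{hi} (source
#'   coordinates in band units), \code{orient} (+1 = left end of the block
#'   corresponds to \code{lo}).
#' @slot cens data.frame of centromere sites: \code{block} (index into
#'   blocks), \code{chrom}, \code{active}.
#' @slot ends character(2): left/right end state, each "telomere" or
#'   "broken" ("none" for rings).
#' @slot ring logical.
#' @exportClass LinearChromosome
setClass("LinearChromosome", representation(
  blocks = "data.frame", cens = "data.frame", ends = "character",
  ring = "logical"))

setValidity("LinearChromosome", function(object) {
  b <- object@blocks
  if (nrow(b) && any(b$hi <= b$lo)) return("blocks must have hi > lo")
  if (nrow(object@cens) &&
      any(object@cens$block < 1 | object@cens$block > nrow(b))) {
    return("centromere block index out of range")
  }
  if (object@ring) {
    if (!all(object@ends == "none")) return("ring ends must be 'none'")
  } else if (!all(object@ends %in% c("telomere", "broken"))) {
    return("ends must be 'telomere' or 'broken'")
  }
  TRUE
})

setMethod("show", "LinearChromosome", function(object) {
  b <- object@blocks
  desc <- paste0(b$chrom, "[", round(b$lo, 2), ",", round(b$hi, 2), "]",
                 ifelse(b$orient > 0, "+", "-"))
  cat(if (object@ring) "Ring" else "Linear", "chromosome:",
      paste(desc, collapse = " :: "), "\n")
  if (nrow(object@cens)) {
    cat("  centromeres:",
        paste0(object@cens$chrom,
               ifelse(object@cens$active, "(active)", "(inactive)"),
               collapse = ", "), "\n")
  }
  if (!object@ring) cat("  ends:", paste(object@ends, collapse = " / "), "\n")
})

#' Replayable breakage-fusion-bridge history
#'
#' Ordered event log of a BFB simulation (fusions, break positions, product
#' choices, stabilization events) together with the initial structure, the
#' followed final structure and all unfollowed products.  Replaying the log
#' reproduces the final structures exactly.
#'
#' @slot seed integer seed (NA for fully explicit event scripts).
#' @slot events list of event records.
#' @slot initial starting \linkS4class{LinearChromosome}.
#' @slot final followed end structure.
#' @slot products list of all retained structures (unfollowed break
#'   products, excised remnants), in event order.
#' @exportClass BFBHistory
setClass("BFBHistory", representation(
  seed = "integer", events = "list", initial = "LinearChromosome",
  final = "LinearChromosome", products = "list"))

setMethod("show", "BFBHistory", function(object) {
  cat("BFBHistory:", length(object@events), "events,",
      length(object@products), "retained side products\n")
  cat("final: ")
  show(object@final)
})
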