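# Forward models: homologue-labelled truth -> SNP-array probe data
# (LRR/BAF) and FISH observations (M-FISH paints, M-BAND blocks,
# centromere-probe and NOR counts).

#' Assign homologue labels to a karyotype
#'
#' Builds the ground-truth object for the forward models.  By default all
#' structured-chromosome segments are assigned to homologue A (the
#' rearranged homologue); the remaining normal copies of a chromosome that
#' carries structural or numerical events are assigned to homologue B (the
#' un-rearranged homologue, which in HEL-like genomes is the duplicated
#' one), while chromosomes without events split their normals as evenly as
#' possible.  A chromosome whose normal count is zero and whose segments
#' are all A-labelled is therefore fully homozygous (LOH) in the simulated
#' BAF.
#'
#' @param model a \linkS4class{KaryotypeModel}.
#' @param map a \linkS4class{CytobandMap}.
#' @return a \linkS4class{HomologueAssignedKaryotype}.
#' @export
assignHomologues <- function(model, map = systemCytobandMap()) {
  evs <- model@events
  touched <- character(0)
  for (k in seq_along(evs)) {
    ev <- evs[[k]]
    if (is(ev, "StructuredChromosome")) {
      if (nrow(ev@segments)) ev@segments$homologue <- "A"
      evs[[k]] <- ev
      touched <- union(touched, c(ev@cenChroms, ev@segments$chrom))
    } else if (!isTRUE(ev$reflected)) {
      touched <- union(touched, ev$chrom)
    }
  }
  model@events <- evs
  chroms <- unique(map@bands$chrom)
  nA <- nB <- stats::setNames(integer(length(chroms)), chroms)
  for (ch in chroms) {
    n <- tryCatch(normalCount(model, ch), error = function(e) 0L)
    if (ch %in% touched) {
      nA[ch] <- 0L
      nB[ch] <- n
    } else {
      nA[ch] <- n %/% 2L
      nB[ch] <- n - n %/% 2L
    }
  }
  new("HomologueAssignedKaryotype", model = model, normalA = nA, normalB = nB)
}

#' Per-band allele-specific copy-number truth table
#'
#' Expands a homologue-assigned karyotype into per-leaf-band homologue
#' counts (nA, nB): the per-homologue normal counts plus labelled segment
#' multiplicities over the principal clone, with del/amp/dup modifier
#' adjustments applied to the rearranged homologue.
#'
#' @param hk a \linkS4class{HomologueAssignedKaryotype}.
#' @param map a \linkS4class{CytobandMap}.
#' @param chroms chromosomes to include (default: all autosomes plus X).
#' @param ampDefault copies contributed by "amp" segments with no written
#'   count.
#' @return data.frame: \code{chrom}, \code{band}, \code{idx} (leaf-band
#'   index from pter), \code{nA}, \code{nB}, \code{uncertain}.
#' @export
bandCopyTable <- function(hk, map = systemCytobandMap(), chroms = NULL,
                          ampDefault = 2L) {
  model <- hk@model
  if (is.null(chroms)) {
    chroms <- intersect(unique(map@bands$chrom), c(as.character(1:22), "X"))
  }
  chroms <- .normChrom(chroms)
  evs <- structuredChromosomes(model, principalOnly = TRUE)
  out <- list()
  for (ch in chroms) {
    lb <- leafBands(map, ch)
    nA <- rep(hk@normalA[[ch]], nrow(lb))
    nB <- rep(hk@normalB[[ch]], nrow(lb))
    unc <- rep(FALSE, nrow(lb))
    for (ev in evs) {
      segs <- ev@segments
      for (i in seq_len(nrow(segs))) {
        if (segs$chrom[i] != ch) next
        hit <- lb$ordinal >= segs$lo[i] & lb$ordinal <= segs$hi[i]
        mult <- if (segs$multUnspecified[i]) ampDefault else segs$multiplicity[i]
        if (segs$multUnspecified[i]) unc[hit] <- TRUE
        if (identical(segs$homologue[i], "B")) {
          nB[hit] <- nB[hit] + mult
        } else {
          nA[hit] <- nA[hit] + mult
        }
      }
      mods <- ev@modifiers
      for (i in seq_len(nrow(mods))) {
        if (mods$chrom[i] != ch) next
        hit <- lb$ordinal >= mods$lo[i] & lb$ordinal <= mods$hi[i]
        d <- switch(mods$op[i], del = -1L, dup = 1L, amp = ampDefault)
        if (mods$op[i] == "amp") unc[hit] <- TRUE
        nA[hit] <- pmax(0L, nA[hit] + d)
      }
    }
    out[[ch]] <- data.frame(chrom = ch, band = lb$band,
                            idx = seq_len(nrow(lb)), nA = nA, nB = nB,
                            uncertain = unc, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Expected B-allele frequency
#'
#' The SNP-array BAF measures the relative dose of the two parental
#' homologues: for homologue copy counts (nA, nB) at a germline-heterozygous
#' site the expectation is nB / (nA + nB).  A germline-homozygous site
#' expects 0 or 1 regardless of copy state.  With no copies at all there is
#' no signal: NA is returned (probe dropout sentinel), not a number.
#'
#' @param nA,nB homologue copy counts.
#' @return value in [0, 1], or NA when nA + nB == 0.
#' @export
expectedBaf <- function(nA, nB) {
  t <- nA + nB
  ifelse(t == 0, NA_real_, nB / t)
}

#' Build a probe grid
#'
#' Probe positions at \code{d} probes per leaf band, evenly spaced within
#' each band on the band-index pseudo-coordinate (no base-pair realism);
#' \code{pos} of the j-th probe in band i is \code{(i - 1) + (j - 0.5) / d}.
#' Germline site zygosity is not fixed by the grid: it is drawn
#' per probe (heterozygous with probability \code{h}) from the seeded
#' stream inside \code{\link{simulateArray}}.
#'
#' @param map a \linkS4class{CytobandMap}.
#' @param chroms chromosomes to cover (default all autosomes).
#' @param d probes per band (>= 1).
#' @param h germline heterozygosity fraction in [0, 1].
#' @return data.frame: \code{chrom}, \code{band}, \code{idx}, \code{pos};
#'   with attributes \code{d} and \code{h}.
#' @export
probeGrid <- function(map = systemCytobandMap(), chroms = as.character(1:22),
                      d = 50L, h = 0.35) {
  stopifnot(d >= 1, h >= 0, h <= 1)
  chroms <- .normChrom(chroms)
  out <- list()
  for (ch in chroms) {
    lb <- leafBands(map, ch)
    idx <- rep(seq_len(nrow(lb)), each = d)
    out[[ch]] <- data.frame(
      chrom = ch, band = lb$band[idx], idx = idx,
      pos = (idx - 1) + (rep(seq_len(d), nrow(lb)) - 0.5) / d,
      stringsAsFactors = FALSE)
  }
  g <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  attr(g, "d") <- as.integer(d)
  attr(g, "h") <- h
  g
}

#' Simulate a SNP-array observation
#'
#' Forward model for Illumina-style LRR/BAF data.  Per probe at a band with
#' homologue counts (nA, nB), t = nA + nB:
#' LRR = log2(t / 2) + Gaussian(0, sigmaLrr) (diploid-referenced regardless
#' of the karyotype's ploidy baseline, as array software reports
#' near-triploid genomes); BAF = expected BAF + Gaussian(0, sigmaBaf)
#' clamped to [0, 1] for heterozygous sites, and 0/1 + noise for homozygous
#' sites; site zygosity is Bernoulli(h) from the seeded stream.  Regions
#' with t = 0 emit the no-signal sentinel (NA).  Identical inputs and seed
#' give byte-identical output.
#'
#' @param hk a \linkS4class{HomologueAssignedKaryotype}.
#' @param grid probe grid from \code{\link{probeGrid}}.
#' @param sigmaLrr,sigmaBaf Gaussian noise standard deviations.
#' @param seed integer seed.
#' @param map a \linkS4class{CytobandMap}.
#' @return an \linkS4class{ArrayObservation}.
#' @export
simulateArray <- function(hk, grid = probeGrid(map), sigmaLrr = 0.15,
                          sigmaBaf = 0.03, seed = 1L,
                          map = systemCytobandMap()) {
  truth <- bandCopyTable(hk, map, chroms = unique(grid$chrom))
  key <- paste(truth$chrom, truth$idx)
  hit <- match(paste(grid$chrom, grid$idx), key)
  if (anyNA(hit)) stop("probe grid covers bands absent from the truth table")
  nA <- truth$nA[hit]
  nB <- truth$nB[hit]
  t <- nA + nB
  h <- attr(grid, "h")
  if (is.null(h)) h <- 0.35
  probes <- .withSeed(seed, {
    n <- nrow(grid)
    het <- stats::runif(n) < h
    homAllele <- as.numeric(stats::runif(n) < 0.5)
    ebaf <- ifelse(het, expectedBaf(nA, nB),
                   ifelse(homAllele > 0, 1, 0))
    # for a homozygous site on the retained homologue the expectation is
    # still 0 or 1; with zero copies everything is dropout
    lrr <- log2(t / 2) + stats::rnorm(n, 0, sigmaLrr)
    baf <- .clamp01(ebaf + stats::rnorm(n, 0, sigmaBaf))
    lrr[t == 0] <- NA_real_
    baf[t == 0] <- NA_real_
    data.frame(probe_id = sprintf("p%06d", seq_len(n)), chrom = grid$chrom,
               band = grid$band, idx = grid$idx, pos = grid$pos,
               lrr = lrr, baf = baf, het = het, stringsAsFactors = FALSE)
  })
  new("ArrayObservation", probes = probes, sigmaLrr = sigmaLrr,
      sigmaBaf = sigmaBaf, seed = as.integer(seed))
}

#' Write / read a probe table
#'
#' Tab-delimited interchange format with header
#' \code{probe_id chrom band pos lrr baf}.
#'
#' @param obs an \linkS4class{ArrayObservation}.
#' @param path output path.
#' @export
writeProbeTable <- function(obs, path) {
  utils::write.table(
    obs@probes[, c("probe_id", "chrom", "band", "pos", "lrr", "baf")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.ACROCENTRIC <- c("13", "14", "15", "21", "22")

# NOR-bearing p-arm ordinal span (p13..p11.2) of an acrocentric chromosome
.norSpan <- function(map, chrom) {
  b <- .chromBands(map, chrom)
  ords <- b$ordinal[b$band %in% c("p13", "p12", "p11.2")]
  range(ords)
}

#' Simulate FISH observations
#'
#' Deterministic forward model of whole-chromosome paint (M-FISH), band
#' paint (M-BAND), centromere-probe and NOR-probe results for every
#' structured chromosome of the karyotype: the M-FISH source set is the set
#' of chromosomes contributing at least one band, restricted to the probe
#' panel; M-BAND blocks are the per-panel-chromosome band blocks in
#' physical (written) order; centromere counts are the number of segments
#' spanning the tested chromosome's centromere; NOR positivity counts
#' acrocentric short-arm (p11.2-p13) material, with unwritten "amp"
#' multiplicity counted at its display default.
#'
#' @param hk a \linkS4class{HomologueAssignedKaryotype} or
#'   \linkS4class{KaryotypeModel}.
#' @param panel chromosomes covered by the paint panel (default: the XCyte
#'   M-BAND set used for HEL).
#' @param map a \linkS4class{CytobandMap}.
#' @param includeNormals also emit one observation per remaining normal
#'   chromosome (source set = itself, centromere count 1).
#' @return a \linkS4class{PaintObservation}.
#' @export
simulateFish <- function(hk, panel = c("3", "4", "10", "11", "13", "15",
                                       "18", "19", "20"),
                         map = systemCytobandMap(), includeNormals = FALSE) {
  model <- if (is(hk, "HomologueAssignedKaryotype")) hk@model else hk
  panel <- .normChrom(panel)
  obs <- list()
  for (ev in structuredChromosomes(model, principalOnly = TRUE)) {
    segs <- ev@segments
    srcAll <- unique(c(segs$chrom, ev@modifiers$chrom))
    sources <- intersect(panel, srcAll)
    sources <- sources[order(.chromSortKey(sources))]
    mband <- list()
    for (ch in intersect(panel, srcAll)) {
      rows <- segs[segs$chrom == ch, , drop = FALSE]
      if (nrow(rows)) {
        mband[[ch]] <- data.frame(start = rows$start, end = rows$end,
                                  stringsAsFactors = FALSE)
      }
    }
    cenChk <- unique(c(srcAll, ev@cenChroms))
    cenCounts <- stats::setNames(integer(length(cenChk)), cenChk)
    for (ch in cenChk) {
      cen <- .cenOrdinals(map, ch)
      rows <- segs[segs$chrom == ch, , drop = FALSE]
      cenCounts[ch] <- sum((rows$lo <= cen["p10"] & rows$hi >= cen["p10"]) |
                             (rows$lo <= cen["q10"] & rows$hi >= cen["q10"]))
    }
    nor <- 0L
    for (ch in intersect(.ACROCENTRIC, srcAll)) {
      sp <- .norSpan(map, ch)
      rows <- segs[segs$chrom == ch, , drop = FALSE]
      nor <- nor + sum(rows$hi >= sp[1] & rows$lo <= sp[2])
      mods <- ev@modifiers[ev@modifiers$chrom == ch &
                             ev@modifiers$op == "amp", , drop = FALSE]
      nor <- nor + 2L * sum(mods$hi >= sp[1] & mods$lo <= sp[2])
    }
    obs[[length(obs) + 1L]] <- list(
      label = ev@label, text = ev@text, sources = sources, mband = mband,
      cenCounts = cenCounts, norCount = nor, ring = ev@ring)
  }
  if (includeNormals) {
    for (ch in unique(map@bands$chrom)) {
      n <- tryCatch(normalCount(model, ch), error = function(e) 0L)
      if (n < 1) next
      sp <- if (ch %in% .ACROCENTRIC) 1L else 0L
      obs[[length(obs) + 1L]] <- list(
        label = paste0("normal(", ch, ")"), text = ch,
        sources = intersect(panel, ch),
        mband = stats::setNames(
          list(data.frame(start = "pter", end = "qter")), ch)[
            intersect(panel, ch)],
        cenCounts = stats::setNames(1L, ch), norCount = sp, ring = FALSE)
    }
  }
  new("PaintObservation", panel = panel, observations = obs)
}

#' @rdname simulateFish
#' @param paints a \linkS4class{PaintObservation}.
#' @param path output path for the JSON interchange form.
#' @export
writePaints <- function(paints, path) {
  jsonlite::write_json(
    list(panel = paints@panel,
         observations = lapply(paints@observations, function(o) {
           o$cenCounts <- as.list(o$cenCounts)
           o
         })),
    path, auto_unbox = TRUE, pretty = TRUE)
}
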