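# Inverse model: segmentation of BAF/LRR, allele-specific copy-number
# calling, and constraint-based assignment of segments to derivative
# chromosomes.

# squared-error cost helpers on two channels with prefix sums
.sseFun <- function(x) {
  s <- c(0, cumsum(x))
  s2 <- c(0, cumsum(x^2))
  function(lo, hi) {
    n <- hi - lo + 1
    (s2[hi + 1] - s2[lo]) - (s[hi + 1] - s[lo])^2 / n
  }
}

.binsegChrom <- function(f, l, penalty, minProbes) {
  n <- length(f)
  costF <- .sseFun(f)
  costL <- .sseFun(l)
  cost <- function(lo, hi) costF(lo, hi) + costL(lo, hi)
  cps <- integer(0)
  recurse <- function(lo, hi) {
    if (hi - lo + 1 < 2 * minProbes) return()
    k <- seq(lo + minProbes - 1, hi - minProbes)
    gain <- cost(lo, hi) -
      (vapply(k, function(kk) cost(lo, kk), numeric(1)) +
         vapply(k, function(kk) cost(kk + 1, hi), numeric(1)))
    best <- which.max(gain)
    if (gain[best] > penalty) {
      kb <- k[best]
      cps <<- c(cps, kb)
      recurse(lo, kb)
      recurse(kb + 1, hi)
    }
  }
  recurse(1, n)
  sort(cps)
}

#' Joint changepoint detection on folded BAF and LRR
#'
#' Binary segmentation per chromosome on the two channels (folded BAF
#' |BAF - 0.5| over all probes, and LRR): a split is accepted when it
#' reduces the total within-segment squared error by more than
#' \code{penalty} and leaves at least \code{minProbes} probes on each side.
#' Deterministic for fixed input.  No-signal (NA) probes are dropped before
#' segmentation.  Chromosomes with fewer than \code{2 * minProbes} probes
#' return no changepoints and are flagged.
#'
#' @param obs an \linkS4class{ArrayObservation}.
#' @param penalty positive acceptance threshold on the squared-error
#'   reduction.
#' @param minProbes minimum probes per side.
#' @return named list per chromosome: \code{changepoints} (indices into
#'   that chromosome's probe vector, split after the index) and
#'   \code{flagged}.
#' @export
segmentBafLrr <- function(obs, penalty = 1, minProbes = 10L) {
  stopifnot(penalty > 0)
  p <- obs@probes
  out <- list()
  for (ch in unique(p$chrom)) {
    x <- p[p$chrom == ch & !is.na(p$lrr), ]
    x <- x[order(x$pos), ]
    if (nrow(x) < 2 * minProbes) {
      out[[ch]] <- list(changepoints = integer(0), flagged = TRUE)
      next
    }
    f <- abs(x$baf - 0.5)
    out[[ch]] <- list(
      changepoints = .binsegChrom(f, x$lrr, penalty, minProbes),
      flagged = FALSE)
  }
  out
}

#' Allele-specific copy-number call for one segment
#'
#' Total copies t = round(reference * 2^meanLRR) (capped at
#' \code{maxTotal}); the homologue split (nA, nB) with nA >= nB minimizes
#' |meanFoldedBAF - (nA / t - 0.5)|, ties broken toward the more balanced
#' pair.  t = 0 is the homozygous-deletion call (0, 0).
#'
#' @param meanLrr,meanFoldedBaf segment means (folded BAF over
#'   heterozygous-classified probes; 0.5 when no probe classifies as
#'   heterozygous, the LOH signature).
#' @param maxTotal cap on the called total.
#' @param reference copies at LRR = 0 (diploid-referenced arrays: 2).
#' @return integer c(nA, nB).
#' @export
callAllelicCn <- function(meanLrr, meanFoldedBaf, maxTotal = 8L,
                          reference = 2) {
  t <- round(reference * 2^meanLrr)
  t <- max(0L, min(as.integer(t), as.integer(maxTotal)))
  if (t == 0L) return(c(nA = 0L, nB = 0L))
  nB <- 0:(t %/% 2)
  nA <- t - nB
  err <- abs(meanFoldedBaf - (nA / t - 0.5))
  # ties toward the more balanced pair: among minimal errors take max nB
  best <- which(err <= min(err) + 1e-12)
  nBbest <- max(nB[best])
  c(nA = t - nBbest, nB = nBbest)
}

#' Segment and call an array observation
#'
#' Runs \code{\link{segmentBafLrr}} and summarizes each resulting segment:
#' probe count, mean LRR, mean folded BAF over heterozygous-classified
#' probes (BAF within \code{hetRange}; 0.5 if none classify, i.e. LOH), the
#' allele-specific call from \code{\link{callAllelicCn}}, band interval and
#' terminal (pter/qter-reaching) flags.
#'
#' @inheritParams segmentBafLrr
#' @param hetRange BAF window classifying a probe as heterozygous.
#' @param maxTotal,reference passed to \code{\link{callAllelicCn}}.
#' @param map a \linkS4class{CytobandMap}.
#' @return data.frame of called segments: \code{id}, \code{chrom},
#'   \code{startBand}, \code{endBand}, \code{fromPos}, \code{toPos},
#'   \code{probes}, \code{meanLrr}, \code{meanFoldedBaf}, \code{t},
#'   \code{nA}, \code{nB}, \code{terminal}, \code{spansCen},
#'   \code{uncertain}.
#' @export
callSegments <- function(obs, penalty = 1, minProbes = 10L,
                         hetRange = c(0.08, 0.92), maxTotal = 8L,
                         reference = 2, map = systemCytobandMap()) {
  p <- obs@probes
  cps <- segmentBafLrr(obs, penalty, minProbes)
  rows <- list()
  for (ch in names(cps)) {
    x <- p[p$chrom == ch & !is.na(p$lrr), ]
    x <- x[order(x$pos), ]
    if (!nrow(x)) next
    bounds <- c(0, cps[[ch]]$changepoints, nrow(x))
    chromLo <- min(p$pos[p$chrom == ch])
    chromHi <- max(p$pos[p$chrom == ch])
    cen <- .cenOrdinals(map, ch)
    # centromere position on the probe pseudo-coordinate: number of p-arm
    # leaf bands
    lb <- leafBands(map, ch)
    cenPos <- sum(lb$arm == "p")
    for (s in seq_len(length(bounds) - 1)) {
      i <- (bounds[s] + 1):bounds[s + 1]
      seg <- x[i, ]
      het <- seg$baf >= hetRange[1] & seg$baf <= hetRange[2]
      mfb <- if (any(het)) mean(abs(seg$baf[het] - 0.5)) else 0.5
      ml <- mean(seg$lrr)
      call <- callAllelicCn(ml, mfb, maxTotal, reference)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, startBand = seg$band[1], endBand = seg$band[nrow(seg)],
        fromPos = seg$pos[1], toPos = seg$pos[nrow(seg)],
        probes = nrow(seg), meanLrr = ml, meanFoldedBaf = mfb,
        t = call[["nA"]] + call[["nB"]], nA = call[["nA"]],
        nB = call[["nB"]],
        terminal = seg$pos[1] <= chromLo + 1e-9 |
          seg$pos[nrow(seg)] >= chromHi - 1e-9,
        spansCen = seg$pos[1] <= cenPos && seg$pos[nrow(seg)] >= cenPos,
        uncertain = nrow(seg) < 2 * minProbes,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$id <- sprintf("seg%03d", seq_len(nrow(out)))
  out
}

# multiset equality for character vectors
.sameMultiset <- function(a, b) {
  identical(sort(a), sort(b))
}

#' Assign segments to derivative chromosomes under FISH constraints
#'
#' Exact backtracking search over assignments of rearranged segments to
#' structured chromosomes.  A satisfying assignment must (i) give every
#' derivative a set of segment chromosomes exactly equal to its M-FISH
#' source set; (ii) match the centromere-probe counts (segments spanning
#' the tested chromosome's centromere); (iii) give each derivative at most
#' two terminal (pter/qter-reaching) segments - its two ends - and rings
#' none; (iv) when M-BAND blocks are provided, the multiset of assigned
#' band blocks per panel chromosome must equal the observed blocks (so an
#' ordering consistent with the observed block order exists).  All
#' solutions are returned in deterministic enumeration order; derivatives
#' are searched by decreasing paint-set size and segments by decreasing
#' span (fail-fast).  Segments whose chromosome occurs in no paint set are
#' reported unplaced.
#'
#' @param segments data.frame with columns \code{id}, \code{chrom},
#'   \code{terminal}, \code{spansCen}, and a size column \code{span} (or
#'   \code{probes}).
#' @param paints a \linkS4class{PaintObservation} (observations for the
#'   derivatives to fill).
#' @param checkMband enforce constraint (iv) when blocks are available.
#' @return list with \code{solutions} (list of named character vectors
#'   segment id -> derivative label), \code{unplaced} (segment ids),
#'   \code{feasible}, \code{diagnostics}.
#' @export
assignSegments <- function(segments, paints, checkMband = FALSE) {
  obs <- paints@observations
  labels <- vapply(obs, `[[`, character(1), "label")
  sizes <- if ("span" %in% names(segments)) {
    segments$span
  } else if ("probes" %in% names(segments)) {
    segments$probes
  } else {
    rep(1, nrow(segments))
  }
  allSources <- unique(unlist(lapply(obs, `[[`, "sources")))
  unplaced <- segments$id[!segments$chrom %in% allSources]
  segs <- segments[segments$chrom %in% allSources, , drop = FALSE]
  segs <- segs[order(-sizes[segments$chrom %in% allSources], segs$id), ,
               drop = FALSE]
  derivOrder <- order(-vapply(obs, function(o) length(o$sources), integer(1)),
                      labels)
  obs <- obs[derivOrder]
  labels <- labels[derivOrder]

  # quick infeasibility diagnostics: every source chromosome needs a
  # candidate segment
  for (o in obs) {
    for (ch in o$sources) {
      if (!any(segs$chrom == ch)) {
        return(list(solutions = list(), unplaced = unplaced,
                    feasible = FALSE,
                    diagnostics = paste0("paint set of ", o$label,
                                         " requires chromosome ", ch,
                                         " material but no candidate segment",
                                         " is available")))
      }
    }
  }

  nd <- length(obs)
  ns <- nrow(segs)
  assignment <- integer(ns)
  solutions <- list()
  termCount <- integer(nd)
  cenCount <- lapply(obs, function(o) {
    stats::setNames(integer(length(o$cenCounts)), names(o$cenCounts))
  })
  chromsAssigned <- vector("list", nd)

  search <- function(k) {
    if (k > ns) {
      for (d in seq_len(nd)) {
        if (!setequal(unique(unlist(chromsAssigned[d])), obs[[d]]$sources)) {
          return()
        }
        target <- obs[[d]]$cenCounts
        got <- cenCount[[d]]
        if (!all(got[names(target)] == target)) return()
        if (checkMband && length(obs[[d]]$mband)) {
          ids <- segs$id[assignment == d]
          rows <- segs[segs$id %in% ids, , drop = FALSE]
          for (ch in names(obs[[d]]$mband)) {
            want <- obs[[d]]$mband[[ch]]
            gotB <- rows[rows$chrom == ch, , drop = FALSE]
            wantKey <- paste(want$start, want$end)
            gotKey <- if (all(c("startBand", "endBand") %in% names(gotB))) {
              paste(gotB$startBand, gotB$endBand)
            } else {
              rep("", nrow(gotB))
            }
            if (nrow(want) && any(nzchar(gotKey)) &&
                !.sameMultiset(wantKey, gotKey)) {
              return()
            }
          }
        }
      }
      sol <- stats::setNames(labels[assignment], segs$id)
      solutions[[length(solutions) + 1L]] <<- sol
      return()
    }
    ch <- segs$chrom[k]
    for (d in seq_len(nd)) {
      o <- obs[[d]]
      if (!ch %in% o$sources) next
      newTerm <- termCount[d] + as.integer(isTRUE(segs$terminal[k]))
      maxTerm <- if (isTRUE(o$ring)) 0L else 2L
      if (newTerm > maxTerm) next
      if (isTRUE(segs$spansCen[k])) {
        tgt <- o$cenCounts
        if (ch %in% names(tgt) && cenCount[[d]][ch] + 1L > tgt[ch]) next
      }
      assignment[k] <<- d
      termCount[d] <<- newTerm
      if (isTRUE(segs$spansCen[k]) && ch %in% names(cenCount[[d]])) {
        cenCount[[d]][ch] <<- cenCount[[d]][ch] + 1L
      }
      chromsAssigned[[d]] <<- c(chromsAssigned[[d]], ch)
      search(k + 1L)
      chromsAssigned[[d]] <<- chromsAssigned[[d]][-length(chromsAssigned[[d]])]
      if (isTRUE(segs$spansCen[k]) && ch %in% names(cenCount[[d]])) {
        cenCount[[d]][ch] <<- cenCount[[d]][ch] - 1L
      }
      termCount[d] <<- termCount[d] - as.integer(isTRUE(segs$terminal[k]))
      assignment[k] <<- 0L
    }
  }
  if (ns > 0) search(1L) else if (nd == 0) solutions <- list(stats::setNames(
    character(0), character(0)))
  diag <- if (length(solutions)) {
    sprintf("%d satisfying assignment(s)", length(solutions))
  } else {
    "no assignment satisfies the source-set/centromere/terminal constraints"
  }
  list(solutions = solutions, unplaced = unplaced,
       feasible = length(solutions) > 0, diagnostics = diag)
}

#' End-to-end reconstruction harness
#'
#' Simulates an array observation from a homologue-assigned truth, inverts
#' it (segmentation, allele-specific calling, optional paint-constrained
#' assignment of deviant segments to derivatives) and reports accuracy:
#' the fraction of leaf bands whose called (nA, nB) pair equals the truth
#' (folded, nA >= nB), and - when a paint panel is given - the fraction of
#' derivatives whose assigned segment chromosomes match their true source
#' composition.
#'
#' @param hk truth (\linkS4class{HomologueAssignedKaryotype}).
#' @param grid probe grid.
#' @param sigmaLrr,sigmaBaf,seed forwarded to \code{\link{simulateArray}}.
#' @param panel optional FISH panel; enables the assignment stage.
#' @param penalty,minProbes forwarded to \code{\link{callSegments}}.
#' @param map a \linkS4class{CytobandMap}.
#' @return list: \code{bandAccuracy}, \code{compositionAccuracy} (NA
#'   without panel), \code{called}, \code{truth}, \code{assignment},
#'   \code{seed}.
#' @export
recover <- function(hk, grid = NULL, sigmaLrr = 0.15, sigmaBaf = 0.03,
                    seed = 1L, panel = NULL, penalty = 1, minProbes = 10L,
                    map = systemCytobandMap()) {
  if (is.null(grid)) {
    chroms <- unique(unlist(lapply(
      structuredChromosomes(hk@model), function(e) e@segments$chrom)))
    chroms <- chroms[order(.chromSortKey(chroms))]
    grid <- probeGrid(map, chroms = chroms)
  }
  obs <- simulateArray(hk, grid, sigmaLrr, sigmaBaf, seed, map)
  truth <- bandCopyTable(hk, map, chroms = unique(grid$chrom))
  called <- callSegments(obs, penalty, minProbes, map = map)

  # band-level allele-specific accuracy: compare the call covering each
  # band's centre against the truth, folded to nA >= nB
  ok <- 0L
  tot <- 0L
  for (r in seq_len(nrow(truth))) {
    ch <- truth$chrom[r]
    centre <- truth$idx[r] - 0.5
    cs <- called[called$chrom == ch & called$fromPos <= centre &
                   called$toPos >= centre, , drop = FALSE]
    if (!nrow(cs)) next
    tTruth <- sort(c(truth$nA[r], truth$nB[r]), decreasing = TRUE)
    tCall <- c(cs$nA[1], cs$nB[1])
    tot <- tot + 1L
    if (all(tTruth == tCall)) ok <- ok + 1L
  }
  bandAcc <- if (tot) ok / tot else NA_real_

  compAcc <- NA_real_
  assignment <- NULL
  if (!is.null(panel)) {
    paints <- simulateFish(hk, panel, map)
    # deviant segments: calls differing from the chromosome's non-rearranged
    # background state.  Derivatives add copies of the rearranged homologue,
    # so the background is the state with the smallest total copy number
    # (ties broken toward the more balanced state).
    dev <- list()
    for (ch in unique(called$chrom)) {
      x <- called[called$chrom == ch, , drop = FALSE]
      statekey <- paste(x$nA, x$nB)
      ord <- order(x$t, -x$nB)
      background <- statekey[ord[1]]
      d <- x[statekey != background, , drop = FALSE]
      if (nrow(d)) dev[[ch]] <- d
    }
    dev <- do.call(rbind, c(dev, list(make.row.names = FALSE)))
    if (!is.null(dev) && nrow(dev)) {
      dev$span <- dev$toPos - dev$fromPos
      assignment <- assignSegments(dev, paints)
      if (assignment$feasible) {
        sol <- assignment$solutions[[1]]
        good <- 0L
        derivs <- paints@observations
        for (o in derivs) {
          ids <- names(sol)[sol == o$label]
          gotCh <- sort(unique(dev$chrom[dev$id %in% ids]))
          if (identical(gotCh, sort(o$sources))) good <- good + 1L
        }
        compAcc <- good / length(derivs)
      } else {
        compAcc <- 0
      }
    }
  }
  list(bandAccuracy = bandAcc, compositionAccuracy = compAcc,
       called = called, truth = truth, assignment = assignment,
       seed = as.integer(seed))
}
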