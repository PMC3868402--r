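# Breakage-fusion-bridge simulation on dicentric chromosomes, with
# stabilization by centromere inactivation, telomere/centromere capture or
# pericentromeric ring excision.
#
# Source coordinates are continuous band units: leaf band i of a
# chromosome spans [i-1, i]; the centromere sits at x = P, the number of
# p-arm leaf bands.  Blocks are oriented sub-intervals of a source
# chromosome; breaks split blocks at sub-band resolution.

.leafIdxSpan <- function(map, chrom, band) {
  lb <- leafBands(map, chrom)
  sp <- bandSpan(map, chrom, band)
  idx <- which(lb$ordinal >= sp[1] & lb$ordinal <= sp[2])
  if (!length(idx)) {
    # terminus tokens: pter/qter/p10/q10
    cen <- sum(lb$arm == "p")
    return(switch(band,
                  pter = c(0L, 0L), qter = c(nrow(lb), nrow(lb)),
                  p10 = c(cen, cen), q10 = c(cen, cen),
                  stop("band ", band, " has no leaf extent on chromosome ",
                       chrom)))
  }
  range(idx)
}

.chromUnits <- function(map, chrom) nrow(leafBands(map, chrom))
.cenUnit <- function(map, chrom) sum(leafBands(map, chrom)$arm == "p")

.mkBlocks <- function(chrom, lo, hi, orient) {
  data.frame(chrom = chrom, lo = lo, hi = hi, orient = orient,
             stringsAsFactors = FALSE)
}

.mkCens <- function(block = integer(0), chrom = character(0),
                    active = logical(0)) {
  data.frame(block = as.integer(block), chrom = chrom, active = active,
             stringsAsFactors = FALSE)
}

# centromere sites implied by blocks (each block strictly containing its
# chromosome's centromere position)
.impliedCenBlocks <- function(blocks, map) {
  which(vapply(seq_len(nrow(blocks)), function(i) {
    cen <- .cenUnit(map, blocks$chrom[i])
    blocks$lo[i] < cen && blocks$hi[i] > cen
  }, logical(1)))
}

#' Construct chromosomes for BFB simulation
#'
#' \code{normalChromosome} builds an intact telomere-capped chromosome;
#' \code{dicentricChromosome} a dicentric fusion of two chromosomes broken
#' at the given bands (each retaining its centromere and the far telomere);
#' \code{isodicentricFragment} a mirror-symmetric dicentric made of two
#' inverted copies of a centromere-containing band span, with broken outer
#' ends (content beyond the span unknown).
#'
#' @param map a \linkS4class{CytobandMap}.
#' @param chrom,chromA,chromB chromosome names.
#' @param bandA,bandB fusion breakpoint bands (each on the arm facing the
#'   junction).
#' @param fromBand,toBand band span of the mirrored fragment (must contain
#'   the centromere).
#' @return a \linkS4class{LinearChromosome}.
#' @export
normalChromosome <- function(map, chrom) {
  chrom <- .normChrom(chrom)
  K <- .chromUnits(map, chrom)
  x <- new("LinearChromosome",
           blocks = .mkBlocks(chrom, 0, K, 1L),
           cens = .mkCens(1L, chrom, TRUE),
           ends = c("telomere", "telomere"), ring = FALSE)
  x
}

#' @rdname normalChromosome
#' @export
dicentricChromosome <- function(map, chromA, bandA, chromB, bandB) {
  chromA <- .normChrom(chromA)
  chromB <- .normChrom(chromB)
  spA <- .leafIdxSpan(map, chromA, bandA)
  spB <- .leafIdxSpan(map, chromB, bandB)
  armA <- substr(bandA, 1, 1)
  armB <- substr(bandB, 1, 1)
  bA <- if (armA == "p") {
    .mkBlocks(chromA, spA[1] - 1, .chromUnits(map, chromA), -1L)
  } else {
    .mkBlocks(chromA, 0, spA[2], 1L)
  }
  bB <- if (armB == "p") {
    .mkBlocks(chromB, spB[1] - 1, .chromUnits(map, chromB), 1L)
  } else {
    .mkBlocks(chromB, 0, spB[2], -1L)
  }
  blocks <- rbind(bA, bB)
  x <- new("LinearChromosome", blocks = blocks,
           cens = .mkCens(c(1L, 2L), c(chromA, chromB), c(TRUE, TRUE)),
           ends = c("telomere", "telomere"), ring = FALSE)
  if (length(.impliedCenBlocks(blocks, map)) != 2) {
    stop("dicentric construction lost a centromere; check breakpoint arms")
  }
  x
}

#' @rdname normalChromosome
#' @export
isodicentricFragment <- function(map, chrom, fromBand, toBand) {
  chrom <- .normChrom(chrom)
  sp1 <- .leafIdxSpan(map, chrom, fromBand)
  sp2 <- .leafIdxSpan(map, chrom, toBand)
  lo <- min(sp1[1] - 1, sp2[1] - 1)
  hi <- max(sp1[2], sp2[2])
  cen <- .cenUnit(map, chrom)
  if (!(lo < cen && cen < hi)) {
    stop("isodicentric fragment must contain the centromere")
  }
  new("LinearChromosome",
      blocks = rbind(.mkBlocks(chrom, lo, hi, -1L),
                     .mkBlocks(chrom, lo, hi, 1L)),
      cens = .mkCens(c(1L, 2L), c(chrom, chrom), c(TRUE, TRUE)),
      ends = c("broken", "broken"), ring = FALSE)
}

#' @rdname normalChromosome
#' @param band proximal breakpoint band of a terminal fragment; the
#'   fragment runs from this band to the telomere of the chromosome's
#'   \code{side} arm, with a broken proximal end (a donor for
#'   telomere/centromere capture).
#' @param side which telomere the fragment retains ("q" or "p").
#' @export
terminalFragment <- function(map, chrom, band, side = c("q", "p")) {
  side <- match.arg(side)
  chrom <- .normChrom(chrom)
  sp <- .leafIdxSpan(map, chrom, band)
  K <- .chromUnits(map, chrom)
  blocks <- if (side == "q") {
    .mkBlocks(chrom, sp[1] - 1, K, 1L)
  } else {
    .mkBlocks(chrom, 0, sp[2], -1L)
  }
  ends <- if (side == "q") c("broken", "telomere") else c("broken", "telomere")
  cen <- .cenUnit(map, chrom)
  cens <- if (blocks$lo < cen && cen < blocks$hi) {
    .mkCens(1L, chrom, TRUE)
  } else {
    .mkCens()
  }
  new("LinearChromosome", blocks = blocks, cens = cens, ends = ends,
      ring = FALSE)
}

#' Structure geometry accessors
#'
#' \code{derivLength}: total length of a structure in band units;
#' \code{centromerePositions}: derivative coordinates of its centromere
#' sites (with activity flags).
#'
#' @param x a \linkS4class{LinearChromosome}.
#' @param map a \linkS4class{CytobandMap}.
#' @return \code{derivLength}: numeric; \code{centromerePositions}:
#'   data.frame \code{pos}, \code{chrom}, \code{active}.
#' @export
derivLength <- function(x) sum(x@blocks$hi - x@blocks$lo)

#' @rdname derivLength
#' @export
centromerePositions <- function(x, map = systemCytobandMap()) {
  b <- x@blocks
  offs <- c(0, cumsum(b$hi - b$lo))
  out <- list()
  for (i in seq_len(nrow(x@cens))) {
    k <- x@cens$block[i]
    cen <- .cenUnit(map, x@cens$chrom[i])
    pos <- if (b$orient[k] > 0) {
      offs[k] + (cen - b$lo[k])
    } else {
      offs[k] + (b$hi[k] - cen)
    }
    out[[i]] <- data.frame(pos = pos, chrom = x@cens$chrom[i],
                           active = x@cens$active[i])
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# split a structure at derivative position pos; returns list(leftBlocks,
# rightBlocks, leftCens, rightCens) with block indices remapped
.splitBlocks <- function(x, pos, map) {
  b <- x@blocks
  offs <- c(0, cumsum(b$hi - b$lo))
  if (pos <= 0 || pos >= offs[length(offs)]) {
    stop("split position outside the structure")
  }
  k <- findInterval(pos, offs, rightmost.closed = FALSE)
  within <- pos - offs[k]
  lb <- b[seq_len(k - 1L), , drop = FALSE]
  rb <- b[seq(k + 1L, length.out = nrow(b) - k), , drop = FALSE]
  blk <- b[k, , drop = FALSE]
  if (within > 1e-12 && within < (blk$hi - blk$lo) - 1e-12) {
    if (blk$orient > 0) {
      lpart <- .mkBlocks(blk$chrom, blk$lo, blk$lo + within, 1L)
      rpart <- .mkBlocks(blk$chrom, blk$lo + within, blk$hi, 1L)
    } else {
      lpart <- .mkBlocks(blk$chrom, blk$hi - within, blk$hi, -1L)
      rpart <- .mkBlocks(blk$chrom, blk$lo, blk$hi - within, -1L)
    }
    lb <- rbind(lb, lpart)
    rb <- rbind(rpart, rb)
  } else if (within <= 1e-12) {
    rb <- rbind(blk, rb)
  } else {
    lb <- rbind(lb, blk)
  }
  cp <- centromerePositions(x, map)
  leftSel <- cp$pos < pos
  remap <- function(blocks, cens) {
    if (!nrow(cens)) return(.mkCens())
    idx <- .impliedCenBlocks(blocks, map)
    have <- data.frame(block = idx, chrom = blocks$chrom[idx])
    # pair implied sites with the surviving activity flags in positional
    # order per chromosome
    out <- .mkCens()
    for (ch in unique(have$chrom)) {
      hb <- have$block[have$chrom == ch]
      fl <- cens$active[cens$chrom == ch]
      stopifnot(length(hb) == length(fl))
      out <- rbind(out, .mkCens(hb, rep(ch, length(hb)), fl))
    }
    out[order(out$block), , drop = FALSE]
  }
  lcens0 <- cp[leftSel, , drop = FALSE]
  rcens0 <- cp[!leftSel, , drop = FALSE]
  list(leftBlocks = lb, rightBlocks = rb,
       leftCens = remap(lb, data.frame(chrom = lcens0$chrom,
                                       active = lcens0$active)),
       rightCens = remap(rb, data.frame(chrom = rcens0$chrom,
                                        active = rcens0$active)))
}

#' Anaphase-bridge break of a dicentric chromosome
#'
#' The bridge breaks at a position drawn uniformly (strictly) between the
#' two active centromeres, splitting blocks at sub-band resolution.  The
#' left product keeps the first centromere with a broken right end; the
#' right product keeps the second with a broken left end.
#'
#' @param x a dicentric \linkS4class{LinearChromosome} (exactly two active
#'   centromeres).
#' @param pos break position in derivative coordinates; default: drawn from
#'   the current RNG stream.
#' @param map a \linkS4class{CytobandMap}.
#' @return list \code{left}, \code{right}, \code{pos}.
#' @export
bridgeBreak <- function(x, pos = NULL, map = systemCytobandMap()) {
  cp <- centromerePositions(x, map)
  act <- cp[cp$active, , drop = FALSE]
  if (nrow(act) != 2) {
    stop("bridgeBreak requires a dicentric (exactly two active centromeres), ",
         "found ", nrow(act))
  }
  c1 <- min(act$pos)
  c2 <- max(act$pos)
  if (is.null(pos)) pos <- stats::runif(1, c1, c2)
  if (pos <= c1 || pos >= c2) {
    stop("break position must lie strictly between the active centromeres")
  }
  sp <- .splitBlocks(x, pos, map)
  left <- new("LinearChromosome", blocks = sp$leftBlocks, cens = sp$leftCens,
              ends = c(x@ends[1], "broken"), ring = FALSE)
  right <- new("LinearChromosome", blocks = sp$rightBlocks,
               cens = sp$rightCens, ends = c("broken", x@ends[2]),
               ring = FALSE)
  list(left = left, right = right, pos = pos)
}

.mirrorBlocks <- function(blocks) {
  m <- blocks[rev(seq_len(nrow(blocks))), , drop = FALSE]
  m$orient <- -m$orient
  rownames(m) <- NULL
  m
}

#' Sister-chromatid fusion at a broken end
#'
#' After replication, the broken end fuses with its sister copy: the output
#' is the input followed by its own mirror image (reversed block order,
#' flipped orientations) joined at the broken end - a palindrome about the
#' fusion junction.  A monocentric input yields a new dicentric.
#'
#' @param x a \linkS4class{LinearChromosome} with exactly one broken end.
#' @return a \linkS4class{LinearChromosome}; the fusion junction position
#'   is attached as attribute \code{"junction"}.
#' @export
sisterFusion <- function(x) {
  if (x@ring) stop("cannot fuse a ring")
  broken <- which(x@ends == "broken")
  if (length(broken) != 1) {
    stop("sisterFusion requires exactly one broken end")
  }
  n <- nrow(x@blocks)
  mir <- .mirrorBlocks(x@blocks)
  mirCens <- x@cens
  if (nrow(mirCens)) mirCens$block <- n + 1L - mirCens$block
  if (broken == 2L) {
    blocks <- rbind(x@blocks, mir)
    cens <- rbind(x@cens, within(mirCens, block <- block + n))
    ends <- c(x@ends[1], x@ends[1])
    junction <- derivLength(x)
  } else {
    blocks <- rbind(mir, x@blocks)
    cens <- rbind(within(mirCens, block <- block),
                  within(x@cens, block <- block + n))
    ends <- c(x@ends[2], x@ends[2])
    junction <- derivLength(x)
  }
  cens <- cens[order(cens$block), , drop = FALSE]
  rownames(cens) <- NULL
  out <- new("LinearChromosome", blocks = blocks, cens = cens, ends = ends,
             ring = FALSE)
  attr(out, "junction") <- junction
  out
}

# cap x's broken end with a donor structure that has one broken end and one
# telomeric end
.capEnd <- function(x, donor) {
  broken <- which(x@ends == "broken")
  if (length(broken) != 1) stop("structure has no single broken end to cap")
  dbroken <- which(donor@ends == "broken")
  if (length(dbroken) != 1 || donor@ends[3 - dbroken] != "telomere") {
    stop("donor must have one broken end and one telomeric end")
  }
  n <- nrow(x@blocks)
  dn <- nrow(donor@blocks)
  if (broken == 2L) {
    db <- donor@blocks
    dc <- donor@cens
    if (dbroken == 2L) {
      db <- .mirrorBlocks(db)
      if (nrow(dc)) dc$block <- dn + 1L - dc$block
    }
    blocks <- rbind(x@blocks, db)
    cens <- rbind(x@cens, within(dc, block <- block + n))
    ends <- c(x@ends[1], "telomere")
  } else {
    db <- donor@blocks
    dc <- donor@cens
    if (dbroken == 1L) {
      db <- .mirrorBlocks(db)
      if (nrow(dc)) dc$block <- dn + 1L - dc$block
    }
    blocks <- rbind(db, x@blocks)
    cens <- rbind(dc, within(x@cens, block <- block + dn))
    ends <- c("telomere", x@ends[2])
  }
  cens <- cens[order(cens$block), , drop = FALSE]
  rownames(cens) <- NULL
  new("LinearChromosome", blocks = blocks, cens = cens, ends = ends,
      ring = FALSE)
}

#' Inactivate a centromere
#'
#' Flips one active centromere site to inactive (functional
#' monocentrization of a dicentric: a pseudodicentric).
#'
#' @param x a \linkS4class{LinearChromosome}.
#' @param chrom if given, inactivate the first active site of this
#'   chromosome; otherwise the first active site in derivative order.
#' @param map a \linkS4class{CytobandMap}.
#' @return the modified structure.
#' @export
inactivateCentromere <- function(x, chrom = NULL, map = systemCytobandMap()) {
  idx <- which(x@cens$active &
                 (if (is.null(chrom)) TRUE else x@cens$chrom == .normChrom(chrom)))
  if (!length(idx)) stop("no matching active centromere to inactivate")
  x@cens$active[idx[1]] <- FALSE
  x
}

#' Pericentromeric ring excision
#'
#' Cuts on both sides of one centromere and joins the cut ends into a
#' ring, emitting the ring and the two remnants.  Default cut positions are
#' drawn uniformly between the chosen centromere and its flanking active
#' centromeres (or structure ends).
#'
#' @param x a \linkS4class{LinearChromosome}.
#' @param site index of the centromere site (in derivative order) to
#'   excise around.
#' @param left,right cut positions in derivative coordinates (defaults
#'   drawn from the RNG stream).
#' @param map a \linkS4class{CytobandMap}.
#' @return list \code{ring}, \code{left}, \code{right}.
#' @export
ringExcision <- function(x, site = 1L, left = NULL, right = NULL,
                         map = systemCytobandMap()) {
  cp <- centromerePositions(x, map)
  cp <- cp[order(cp$pos), , drop = FALSE]
  if (site < 1 || site > nrow(cp)) stop("no such centromere site")
  cpos <- cp$pos[site]
  lowBound <- if (site > 1) cp$pos[site - 1] else 0
  highBound <- if (site < nrow(cp)) cp$pos[site + 1] else derivLength(x)
  if (is.null(left)) left <- stats::runif(1, lowBound, cpos)
  if (is.null(right)) right <- stats::runif(1, cpos, highBound)
  if (!(left < cpos && cpos < right)) {
    stop("cut positions must flank the chosen centromere")
  }
  s1 <- .splitBlocks(x, left, map)
  leftPart <- new("LinearChromosome", blocks = s1$leftBlocks,
                  cens = s1$leftCens, ends = c(x@ends[1], "broken"),
                  ring = FALSE)
  restBlocks <- new("LinearChromosome", blocks = s1$rightBlocks,
                    cens = s1$rightCens, ends = c("broken", x@ends[2]),
                    ring = FALSE)
  s2 <- .splitBlocks(restBlocks, right - left, map)
  ring <- new("LinearChromosome", blocks = s2$leftBlocks, cens = s2$leftCens,
              ends = c("none", "none"), ring = TRUE)
  rightPart <- new("LinearChromosome", blocks = s2$rightBlocks,
                   cens = s2$rightCens, ends = c("broken", x@ends[2]),
                   ring = FALSE)
  list(ring = ring, left = leftPart, right = rightPart)
}

#' Run a breakage-fusion-bridge simulation
#'
#' Starting from a dicentric (or a broken structure, which is first
#' sister-fused), iterates break -> segregate one product -> sister-fusion
#' for \code{cycles} cycles, then applies the stabilization event:
#' \describe{
#'   \item{none}{return the current structure.}
#'   \item{centromere_inactivation}{flip one centromere inactive
#'     (pseudodicentric).}
#'   \item{telomere_capture}{one final break, then cap the followed
#'     product's broken end with the donor terminal segment.}
#'   \item{centromere_capture}{as telomere capture but the donor carries a
#'     centromere; the pre-existing centromere can then be inactivated via
#'     \code{inactivate}.}
#'   \item{ring_excision}{cut both sides of one centromere and close the
#'     ring (the two remnants are retained in the history).}
#' }
#' Unfollowed break products are retained in the history; the full event
#' log is replayable with \code{\link{replayHistory}}.
#'
#' @param initial starting \linkS4class{LinearChromosome}.
#' @param cycles number of break/fusion cycles (>= 0).
#' @param stabilization stabilization mode.
#' @param seed integer seed driving break positions and product choice.
#' @param follow which break product to follow: "left", "right" or
#'   "random".
#' @param donor donor structure for the capture modes (one broken end, one
#'   telomere); donors are explicit inputs, never invented.
#' @param inactivate chromosome whose centromere to inactivate
#'   (centromere_inactivation / after centromere_capture); default first
#'   active site.
#' @param map a \linkS4class{CytobandMap}.
#' @return a \linkS4class{BFBHistory}.
#' @export
runBfb <- function(initial, cycles, stabilization = c(
                     "none", "centromere_inactivation", "telomere_capture",
                     "centromere_capture", "ring_excision"),
                   seed = 1L, follow = c("random", "left", "right"),
                   donor = NULL, inactivate = NULL,
                   map = systemCytobandMap()) {
  stabilization <- match.arg(stabilization)
  follow <- match.arg(follow)
  .withSeed(seed, {
    events <- list()
    products <- list()
    cur <- initial
    log <- function(...) events[[length(events) + 1L]] <<- list(...)
    if (sum(cur@ends == "broken") == 1) {
      cur <- sisterFusion(cur)
      log(op = "fuse")
    }
    doBreak <- function(cur) {
      br <- bridgeBreak(cur, map = map)
      side <- switch(follow, left = "left", right = "right",
                     random = if (stats::runif(1) < 0.5) "left" else "right")
      products[[length(products) + 1L]] <<-
        if (side == "left") br$right else br$left
      log(op = "break", pos = br$pos, keep = side)
      br[[side]]
    }
    for (i in seq_len(cycles)) {
      cur <- doBreak(cur)
      cur <- sisterFusion(cur)
      log(op = "fuse")
    }
    if (stabilization == "centromere_inactivation") {
      cur <- inactivateCentromere(cur, inactivate, map)
      log(op = "inactivate", chrom = inactivate)
    } else if (stabilization %in% c("telomere_capture", "centromere_capture")) {
      if (is.null(donor)) {
        stop(stabilization, " requires an explicit donor structure")
      }
      if (sum(cur@ends == "broken") != 1) {
        cur <- doBreak(cur)
      }
      cur <- .capEnd(cur, donor)
      log(op = "capture", mode = stabilization)
      if (stabilization == "centromere_capture" && !is.null(inactivate)) {
        cur <- inactivateCentromere(cur, inactivate, map)
        log(op = "inactivate", chrom = inactivate)
      }
    } else if (stabilization == "ring_excision") {
      cp <- centromerePositions(cur, map)
      site <- which(cp$active[order(cp$pos)])[1]
      ex <- ringExcision(cur, site, map = map)
      products <- c(products, list(ex$left, ex$right))
      log(op = "excise", site = site,
          left = derivLength(ex$left),
          right = derivLength(ex$left) + derivLength(ex$ring))
      cur <- ex$ring
    }
    new("BFBHistory", seed = as.integer(seed), events = events,
        initial = initial, final = cur, products = products)
  })
}

#' Replay a BFB event log
#'
#' Re-executes the logged events of a \linkS4class{BFBHistory} from its
#' initial structure without any randomness; the result equals the
#' history's final structure exactly.
#'
#' @param history a \linkS4class{BFBHistory}.
#' @param donor donor used by capture events (same as in the original run).
#' @param map a \linkS4class{CytobandMap}.
#' @return a \linkS4class{LinearChromosome}.
#' @export
replayHistory <- function(history, donor = NULL,
                          map = systemCytobandMap()) {
  cur <- history@initial
  products <- list()
  for (ev in history@events) {
    if (ev$op == "fuse") {
      cur <- sisterFusion(cur)
    } else if (ev$op == "break") {
      br <- bridgeBreak(cur, pos = ev$pos, map = map)
      products[[length(products) + 1L]] <-
        if (ev$keep == "left") br$right else br$left
      cur <- br[[ev$keep]]
    } else if (ev$op == "inactivate") {
      cur <- inactivateCentromere(cur, ev$chrom, map)
    } else if (ev$op == "capture") {
      d <- if (!is.null(ev$donor)) products[[ev$donor]] else donor
      cur <- .capEnd(cur, d)
    } else if (ev$op == "excise") {
      ex <- ringExcision(cur, ev$site, ev$left, ev$right, map)
      products <- c(products, list(ex$left, ex$right))
      cur <- ex$ring
    } else {
      stop("unknown event op: ", ev$op)
    }
  }
  cur
}

#' Per-band copy-number profile of a structure set
#'
#' For each leaf band of each source chromosome, the number of blocks
#' covering it, weighted by overlap at sub-band resolution.
#'
#' @param structures a \linkS4class{LinearChromosome} or list of them.
#' @param map a \linkS4class{CytobandMap}.
#' @param chroms chromosomes to profile (default: every chromosome with a
#'   block; others are reported at count zero when named here).
#' @return data.frame: \code{chrom}, \code{band}, \code{idx}, \code{count}.
#' @export
cnProfile <- function(structures, map = systemCytobandMap(), chroms = NULL) {
  if (is(structures, "LinearChromosome")) structures <- list(structures)
  blocks <- do.call(rbind, lapply(structures, function(s) s@blocks))
  if (is.null(chroms)) chroms <- unique(blocks$chrom)
  out <- list()
  for (ch in .normChrom(chroms)) {
    lb <- leafBands(map, ch)
    K <- nrow(lb)
    cnt <- numeric(K)
    bb <- blocks[blocks$chrom == ch, , drop = FALSE]
    for (i in seq_len(K)) {
      cnt[i] <- sum(pmax(0, pmin(bb$hi, i) - pmax(bb$lo, i - 1)))
    }
    out[[ch]] <- data.frame(chrom = ch, band = lb$band, idx = seq_len(K),
                            count = cnt, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Test a copy-number profile for BFB consistency
#'
#' A profile over the two arms founding a dicentric is BFB-consistent when
#' (i) outside the founding centromeres each chromosome's counts are
#' constant at its flank dose (the tail is carried whole, never amplified),
#' (ii) every count exceeding the flank dose lies strictly between the two
#' centromeres, and (iii) along each fused arm, scanning from the
#' centromere toward the historical fusion side, the counts form a
#' unimodal staircase (non-decreasing to a single peak, then
#' non-increasing; ties allowed), evaluated at band resolution.
#'
#' Condition (iii) is a signature of few-cycle histories: after roughly
#' four or more cycles the interleaved fold positions of a genuine BFB
#' process can produce multi-modal staircases, so the check can be
#' restricted to the confinement conditions with
#' \code{checkStaircase = FALSE}.
#'
#' @param profile data.frame as from \code{\link{cnProfile}} (columns
#'   \code{chrom}, \code{idx}, \code{count}).
#' @param founding list of two lists \code{list(chrom=, arm=)} naming the
#'   founding centromeres and the arms that face the fusion.
#' @param map a \linkS4class{CytobandMap}.
#' @param tol numeric tolerance on count comparisons.
#' @param checkStaircase also require the unimodal-staircase condition
#'   (iii).
#' @return logical with attribute \code{"diagnostics"} naming the violated
#'   condition (empty when consistent).
#' @export
bfbConsistent <- function(profile, founding, map = systemCytobandMap(),
                          tol = 1e-9, checkStaircase = TRUE) {
  diags <- character(0)
  for (f in founding) {
    ch <- .normChrom(f$chrom)
    P <- .cenUnit(map, ch)
    x <- profile[profile$chrom == ch, , drop = FALSE]
    x <- x[order(x$idx), , drop = FALSE]
    if (f$arm == "p") {
      fused <- x[x$idx <= P, , drop = FALSE]
      fused <- fused[order(-fused$idx), , drop = FALSE]  # cen -> pter
      tail <- x[x$idx > P, , drop = FALSE]
      tail <- tail[order(tail$idx), , drop = FALSE]      # cen -> qter
    } else {
      fused <- x[x$idx > P, , drop = FALSE]
      tail <- x[x$idx <= P, , drop = FALSE]
      tail <- tail[order(-tail$idx), , drop = FALSE]
    }
    flank <- if (nrow(tail)) tail$count[nrow(tail)] else 0
    if (nrow(tail) && any(abs(tail$count - flank) > tol)) {
      diags <- c(diags, paste0("chromosome ", ch, ": counts outside the ",
                               "founding centromere are not constant"))
    }
    if (nrow(tail) && any(tail$count > flank + tol)) {
      diags <- c(diags, paste0("chromosome ", ch, ": amplification distal ",
                               "to the founding centromere"))
    }
    s <- fused$count
    j <- if (checkStaircase && any(s > tol)) max(which(s > tol)) else 0
    if (j > 0) {
      s <- s[seq_len(j)]
      peak <- which.max(s)
      up <- s[seq_len(peak)]
      down <- s[seq(peak, length(s))]
      if (any(diff(up) < -tol) || any(diff(down) > tol)) {
        diags <- c(diags, paste0("chromosome ", ch, ": fused-arm counts are ",
                                 "not a unimodal staircase"))
      }
    }
  }
  out <- length(diags) == 0
  attr(out, "diagnostics") <- diags
  out
}

#' Replay a bundled BFB scenario
#'
#' Executes a JSON scenario script: an initial structure
#' (\code{dicentric} or \code{isodicentric}) followed by an explicit event
#' sequence (\code{break} with a fractional position between the active
#' centromeres and the product to keep, \code{fuse}, \code{capture} using
#' a retained product as donor, \code{inactivate}, \code{excise} with cut
#' positions).  Scenario scripts make a proposed rearrangement history
#' concrete and reproducible; two are bundled, reconstructing the
#' pseudodicentric (22;9) and the pericentromeric ring 20.
#'
#' @param scenario path to a scenario JSON file, or an equivalent list.
#' @param map a \linkS4class{CytobandMap}.
#' @return a \linkS4class{BFBHistory}.
#' @export
replayScenario <- function(scenario, map = systemCytobandMap()) {
  if (is.character(scenario)) {
    scenario <- jsonlite::read_json(scenario, simplifyVector = FALSE)
  }
  init <- scenario$initial
  cur <- switch(init$type,
    dicentric = dicentricChromosome(map, init$chromA, init$bandA,
                                    init$chromB, init$bandB),
    isodicentric = isodicentricFragment(map, init$chrom, init$fromBand,
                                        init$toBand),
    stop("unknown initial structure type: ", init$type))
  initial <- cur
  events <- list()
  products <- list()
  for (ev in scenario$events) {
    if (ev$op == "break") {
      cp <- centromerePositions(cur, map)
      act <- cp[cp$active, , drop = FALSE]
      pos <- min(act$pos) + ev$frac * (max(act$pos) - min(act$pos))
      br <- bridgeBreak(cur, pos = pos, map = map)
      products[[length(products) + 1L]] <-
        if (ev$keep == "left") br$right else br$left
      events[[length(events) + 1L]] <- list(op = "break", pos = pos,
                                            keep = ev$keep)
      cur <- br[[ev$keep]]
    } else if (ev$op == "fuse") {
      cur <- sisterFusion(cur)
      events[[length(events) + 1L]] <- list(op = "fuse")
    } else if (ev$op == "capture") {
      donor <- products[[ev$donor]]
      cur <- .capEnd(cur, donor)
      events[[length(events) + 1L]] <- list(op = "capture", donor = ev$donor)
    } else if (ev$op == "inactivate") {
      cur <- inactivateCentromere(cur, ev$chrom, map)
      events[[length(events) + 1L]] <- list(op = "inactivate",
                                            chrom = ev$chrom)
    } else if (ev$op == "excise") {
      ex <- ringExcision(cur, ev$site, ev$left, ev$right, map)
      products <- c(products, list(ex$left, ex$right))
      events[[length(events) + 1L]] <- list(op = "excise", site = ev$site,
                                            left = ev$left, right = ev$right)
      cur <- ex$ring
    } else {
      stop("unknown scenario op: ", ev$op)
    }
  }
  new("BFBHistory", seed = NA_integer_, events = events, initial = initial,
      final = cur, products = products)
}
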