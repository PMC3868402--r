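# KaryotypeModel queries: bookkeeping of normal homologues, copy-number
# queries, canonical rendering.

#' Structured chromosomes of a karyotype model
#'
#' @param model a \linkS4class{KaryotypeModel}.
#' @param principalOnly restrict to the principal clone (see
#'   \code{\link{normalCount}}).
#' @return list of \linkS4class{StructuredChromosome} objects.
#' @export
structuredChromosomes <- function(model, principalOnly = FALSE) {
  evs <- model@events
  if (principalOnly) evs <- evs[.principalMask(model)]
  Filter(function(e) is(e, "StructuredChromosome"), evs)
}

# Principal-clone mask: karyotypes with clone frequencies describe a cell
# population in which some events are alternative subclonal fates of the
# same homologue (e.g. a chromosome either lost or converted to a ring).
# Bookkeeping queries evaluate the principal clone: events whose frequency
# exceeds half the modal (maximum) frequency; events without a frequency
# are always included.
.principalMask <- function(model) {
  freqs <- vapply(model@events, function(e) {
    if (is(e, "StructuredChromosome")) e@freq else e$freq
  }, integer(1))
  if (all(is.na(freqs))) return(rep(TRUE, length(model@events)))
  modal <- max(freqs, na.rm = TRUE)
  is.na(freqs) | freqs > modal / 2
}

#' Remaining normal copies of a chromosome
#'
#' ISCN bookkeeping over the principal clone: the ploidy baseline, minus
#' explicit numerical losses, plus explicit gains, minus one per un-gained
#' structured chromosome citing the chromosome as a centromere chromosome
#' (a whole-arm der(A;B) consumes one normal A and one normal B).  Gained
#' ("+der", "+r") events consume nothing.  Sex chromosomes are counted from
#' the written sex designation; sex gains/losses written directly after it
#' are descriptive of that complement and are not applied again.
#'
#' @param model a \linkS4class{KaryotypeModel}.
#' @param chrom chromosome name.
#' @return non-negative integer count.
#' @export
normalCount <- function(model, chrom) {
  chrom <- .normChrom(chrom)
  mask <- .principalMask(model)
  if (chrom %in% c("X", "Y")) {
    n <- sum(strsplit(model@sex, "")[[1]] == chrom)
  } else {
    n <- model@ploidy
  }
  for (k in seq_along(model@events)) {
    if (!mask[k]) next
    ev <- model@events[[k]]
    if (is(ev, "StructuredChromosome")) {
      if (!ev@gained) n <- n - sum(ev@cenChroms == chrom)
    } else if (ev$chrom == chrom && !isTRUE(ev$reflected)) {
      n <- n + ev$delta
    }
  }
  if (n < 0) {
    stop("model inconsistency: ", n, " normal copies of chromosome ", chrom)
  }
  as.integer(n)
}

# copy-number contribution of one structured chromosome at (chrom, band);
# returns c(count, uncertain)
.segContribution <- function(ev, map, chrom, band, ampDefault = 2L) {
  sp <- bandSpan(map, chrom, band)
  count <- 0
  uncertain <- FALSE
  segs <- ev@segments
  if (nrow(segs)) {
    hit <- segs$chrom == chrom & segs$hi >= sp[1] & segs$lo <= sp[2]
    for (i in which(hit)) {
      if (segs$multUnspecified[i]) {
        count <- count + ampDefault
        uncertain <- TRUE
      } else {
        count <- count + segs$multiplicity[i]
      }
      if (segs$uncertain[i]) uncertain <- TRUE
    }
  }
  mods <- ev@modifiers
  if (nrow(mods)) {
    hit <- mods$chrom == chrom & mods$hi >= sp[1] & mods$lo <= sp[2]
    for (i in which(hit)) {
      if (mods$op[i] == "del") count <- count - 1
      if (mods$op[i] == "dup") count <- count + 1
      if (mods$op[i] == "amp") {
        # "amp" with no count: flagged lower bound of 2 extra copies
        count <- count + ampDefault
        uncertain <- TRUE
      }
      if (mods$uncertain[i]) uncertain <- TRUE
    }
  }
  list(count = max(count, 0), uncertain = uncertain)
}

#' Copy number of a locus under a karyotype
#'
#' Total copies of a band position in the principal clone: the remaining
#' normal homologue count plus, over every structured chromosome, the
#' multiplicities of the segments containing the locus (with del/amp/dup
#' modifier adjustments).  Segments written "amp" with no count contribute
#' a flagged lower bound and set the \code{uncertain} marker.
#'
#' @param model a \linkS4class{KaryotypeModel}.
#' @param chrom,band locus position (band may be a parent-resolution
#'   designator).
#' @param map a \linkS4class{CytobandMap}.
#' @return list with elements \code{count} and \code{uncertain}.
#' @examples
#' m <- parseKaryotype("46,XY")
#' copyNumber(m, "11", "q23.3")$count  # 2
#' @export
copyNumber <- function(model, chrom, band, map = systemCytobandMap()) {
  chrom <- .normChrom(chrom)
  count <- normalCount(model, chrom)
  uncertain <- FALSE
  for (ev in structuredChromosomes(model, principalOnly = TRUE)) {
    ct <- .segContribution(ev, map, chrom, band)
    count <- count + ct$count
    uncertain <- uncertain || ct$uncertain
  }
  list(count = as.integer(count), uncertain = uncertain)
}

#' @rdname copyNumber
#' @param label locus label looked up in \code{loci}.
#' @param loci locus table (see \code{\link{readLoci}}).
#' @export
locusCopyNumber <- function(model, label, map = systemCytobandMap(),
                            loci = bundledLoci()) {
  hit <- loci[loci$label == label, ]
  if (!nrow(hit)) stop("unknown locus: ", label)
  copyNumber(model, hit$chrom[1], hit$band[1], map)
}

#' Structured chromosomes carrying material or centromeres of a chromosome
#'
#' \code{chromCarriers} returns the structured chromosomes (principal
#' clone) with at least one segment derived from \code{chrom};
#' \code{centromereCarriers} those whose \code{chrom}-derived segments span
#' its centromere.
#'
#' @inheritParams copyNumber
#' @return list of \linkS4class{StructuredChromosome}.
#' @export
chromCarriers <- function(model, chrom, map = systemCytobandMap()) {
  chrom <- .normChrom(chrom)
  Filter(function(ev) {
    any(ev@segments$chrom == chrom) || any(ev@modifiers$chrom == chrom)
  }, structuredChromosomes(model, principalOnly = TRUE))
}

#' @rdname chromCarriers
#' @export
centromereCarriers <- function(model, chrom, map = systemCytobandMap()) {
  chrom <- .normChrom(chrom)
  cen <- .cenOrdinals(map, chrom)
  Filter(function(ev) {
    segs <- ev@segments
    any(segs$chrom == chrom &
          ((segs$lo <= cen["p10"] & segs$hi >= cen["p10"]) |
             (segs$lo <= cen["q10"] & segs$hi >= cen["q10"])))
  }, structuredChromosomes(model, principalOnly = TRUE))
}

.chromSortKey <- function(chrom) {
  n <- suppressWarnings(as.integer(chrom))
  ifelse(is.na(n), ifelse(chrom == "X", 23L, 24L), n)
}

#' Render a karyotype model to a canonical ISCN string
#'
#' Deterministic canonical form: count range, ploidy marker, sex
#' designation and its descriptive sex gains/losses, then all other events
#' sorted by chromosome, event class and clause text.  The output re-parses
#' to an equal model: \code{renderKaryotype(parseKaryotype(s))} is a fixed
#' point of render-then-parse.
#'
#' @param model a \linkS4class{KaryotypeModel}.
#' @return a karyotype string.
#' @export
renderKaryotype <- function(model) {
  cr <- model@countRange
  head <- if (cr[1] == cr[2]) as.character(cr[1]) else paste0(cr[1], "~", cr[2])
  parts <- head
  if (model@ploidy != 2L) parts <- c(parts, paste0("<", model@ploidy, "n>"))
  if (nzchar(model@sex)) parts <- c(parts, model@sex)
  fmt <- function(ev) {
    if (is(ev, "StructuredChromosome")) {
      p <- paste0(if (ev@gained) "+" else "", ev@text)
      if (!is.na(ev@freq)) p <- paste0(p, "[", ev@freq, "]")
      p
    } else {
      p <- paste0(if (ev$delta > 0) "+" else "-", ev$chrom)
      if (!is.na(ev$freq)) p <- paste0(p, "[", ev$freq, "]")
      p
    }
  }
  reflected <- vapply(model@events, function(e) {
    !is(e, "StructuredChromosome") && isTRUE(e$reflected)
  }, logical(1))
  parts <- c(parts, vapply(model@events[reflected], fmt, character(1)))
  rest <- model@events[!reflected]
  if (length(rest)) {
    key <- t(vapply(rest, function(ev) {
      if (is(ev, "StructuredChromosome")) {
        # bare copies ("+der(10;19)") must sort after their definitions
        bare <- identical(ev@text, ev@label)
        c(.chromSortKey(ev@cenChroms[1]), if (bare) 3L else 2L)
      } else {
        c(.chromSortKey(ev$chrom), if (ev$delta < 0) 0L else 1L)
      }
    }, integer(2)))
    txt <- vapply(rest, function(ev) {
      if (is(ev, "StructuredChromosome")) ev@text else fmt(ev)
    }, character(1))
    ord <- order(key[, 1], key[, 2], txt)
    txt <- vapply(rest, fmt, character(1))
    parts <- c(parts, txt[ord])
  }
  paste(parts, collapse = ",")
}

#' Test two karyotype models for equality
#'
#' Models are compared through their canonical rendering.
#'
#' @param a,b \linkS4class{KaryotypeModel} objects.
#' @return logical.
#' @export
sameKaryotype <- function(a, b) {
  identical(renderKaryotype(a), renderKaryotype(b))
}
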