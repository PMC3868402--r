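# Cytoband coordinate system: readers, band ordinals, interval algebra.

.normChrom <- function(x) {
  x <- sub("^chr", "", as.character(x))
  x[x %in% c("x", "y")] <- toupper(x[x %in% c("x", "y")])
  x
}

#' Read a cytoband map
#'
#' Reads a UCSC \code{cytoBand.txt}-dialect tab-delimited file (chrom,
#' start, end, band, stain; no header) and builds a \linkS4class{CytobandMap}
#' with synthetic \code{p10}/\code{q10} centromeric markers inserted at each
#' p/q junction.  Chromosome names are accepted with or without a "chr"
#' prefix.
#'
#' @param path path to the cytoband file.
#' @return a \linkS4class{CytobandMap}.
#' @export
readCytobandMap <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "band", "stain"),
                           colClasses = c("character", "numeric", "numeric",
                                          "character", "character"))
  raw$chrom <- .normChrom(raw$chrom)
  out <- list()
  for (ch in unique(raw$chrom)) {
    x <- raw[raw$chrom == ch, ]
    x <- x[order(x$start), ]
    arm <- substr(x$band, 1, 1)
    if (!all(arm %in% c("p", "q"))) {
      stop("band names on chromosome ", ch, " must start with p or q")
    }
    ip <- which(arm == "p")
    iq <- which(arm == "q")
    if (length(ip) && length(iq) && max(ip) > min(iq)) {
      stop("p bands must precede q bands on chromosome ", ch)
    }
    # p arm is stored pter->cen, i.e. descending band numbers; file order is
    # by position which is already pter->qter
    cenpos <- if (length(ip)) x$end[max(ip)] else 0
    mk <- data.frame(chrom = ch, start = cenpos, end = cenpos,
                     band = c("p10", "q10"), stain = "cen")
    x <- rbind(x[ip, , drop = FALSE], mk, x[iq, , drop = FALSE])
    x$arm <- substr(x$band, 1, 1)
    x$ordinal <- seq_len(nrow(x))
    out[[ch]] <- x[, c("chrom", "band", "arm", "ordinal", "start", "end", "stain")]
  }
  new("CytobandMap", bands = do.call(rbind, c(out, list(make.row.names = FALSE))))
}

.mapCache <- new.env(parent = emptyenv())

#' Bundled cytoband map and locus panel
#'
#' \code{systemCytobandMap()} loads the cytoband table shipped with the
#' package (~550-band ISCN resolution; band names and pter->qter order
#' follow the standard human ideogram, base-pair coordinates are nominal).
#' \code{bundledLoci()} returns the bundled gene/FISH-probe locus panel
#' (MLL, JAK2, CDKN2A, D20S108, ...).
#'
#' @return a \linkS4class{CytobandMap}, or a data.frame of loci with columns
#'   \code{label}, \code{chrom}, \code{band}.
#' @export
systemCytobandMap <- function() {
  if (is.null(.mapCache$map)) {
    .mapCache$map <- readCytobandMap(
      system.file("extdata", "cytobands_550.tsv", package = "karyorecon",
                  mustWork = TRUE))
  }
  .mapCache$map
}

#' Read a locus table
#'
#' Tab-delimited locus panel: columns \code{label}, \code{chrom},
#' \code{band}; "#" comment lines allowed.
#'
#' @param path path to the file.
#' @return data.frame with columns label, chrom, band.
#' @export
readLoci <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         comment.char = "#", colClasses = "character")
  x$chrom <- .normChrom(x$chrom)
  x
}

#' @rdname systemCytobandMap
#' @export
bundledLoci <- function() {
  readLoci(system.file("extdata", "loci.tsv", package = "karyorecon",
                       mustWork = TRUE))
}

.chromBands <- function(map, chrom) {
  chrom <- .normChrom(chrom)
  b <- map@bands[map@bands$chrom == chrom, ]
  if (!nrow(b)) stop("unknown chromosome: ", chrom)
  b
}

#' Leaf bands of a chromosome
#'
#' Bands at the map's own (finest) resolution, excluding the synthetic
#' p10/q10 centromere markers.
#'
#' @param map a \linkS4class{CytobandMap}.
#' @param chrom chromosome name.
#' @return data.frame of band rows in pter->qter order.
#' @export
leafBands <- function(map, chrom) {
  b <- .chromBands(map, chrom)
  b[!b$band %in% c("p10", "q10"), ]
}

# does leaf band `leaf` nest inside (or equal) designator `parent`?
.bandNests <- function(leaf, parent) {
  if (leaf == parent) return(TRUE)
  if (!startsWith(leaf, parent)) return(FALSE)
  nxt <- substr(leaf, nchar(parent) + 1L, nchar(parent) + 1L)
  # "11q23" contains "11q23.3"; "p13.1" contains "p13.11" but not "p13.2"
  nxt == "." || (grepl("\\.", parent) && grepl("^[0-9]$", nxt))
}

# Resolve a band token (possibly a parent-resolution designator, or carrying
# "?"/"~" uncertainty) to an inclusive ordinal span on one chromosome.
# Returns list(lo, hi, uncertain, canonical).
.resolveBandToken <- function(map, chrom, token) {
  b <- .chromBands(map, chrom)
  tok <- token
  uncertain <- FALSE
  if (tok %in% c("pter", "qter")) {
    n <- max(b$ordinal)
    return(list(lo = if (tok == "pter") 0L else n + 1L,
                hi = if (tok == "pter") 0L else n + 1L,
                uncertain = FALSE, canonical = tok))
  }
  if (grepl("\\?", tok)) {
    uncertain <- TRUE
    tok <- gsub("\\.\\?$", "", tok)   # "p13.?" -> widest p13 span
    tok <- gsub("\\?", "", tok)       # "q1?0"  -> "q10"
  }
  cands <- tok
  if (grepl("~", tok)) {
    uncertain <- TRUE
    parts <- strsplit(tok, "~", fixed = TRUE)[[1]]
    # "p11~2": digits after "~" replace the same number of trailing digits
    base <- parts[1]
    suf <- parts[2]
    stem <- substr(base, 1, nchar(base) - nchar(suf))
    first <- as.integer(substr(base, nchar(base) - nchar(suf) + 1L, nchar(base)))
    last <- as.integer(suf)
    if (is.na(first) || is.na(last) || last < first) {
      stop("cannot resolve uncertain band token: ", token)
    }
    cands <- paste0(stem, seq(first, last))
  }
  ords <- integer(0)
  for (cand in cands) {
    hit <- vapply(b$band, .bandNests, logical(1), parent = cand)
    ords <- c(ords, b$ordinal[hit])
  }
  if (!length(ords)) {
    stop("unknown band '", token, "' on chromosome ", chrom)
  }
  list(lo = min(ords), hi = max(ords), uncertain = uncertain,
       canonical = tok)
}

#' Band ordinal position
#'
#' Total pter->qter order over the bands of a chromosome.  \code{pter} maps
#' below all bands (ordinal 0) and \code{qter} above all bands; the
#' synthetic centromeric markers \code{p10} and \code{q10} have ordinals
#' like any band.  A parent-resolution designator (e.g. "11q23" when the map
#' holds 11q23.1-11q23.3) returns the midpoint convention of its span; use
#' \code{\link{bandSpan}} for the full span.
#'
#' @param map a \linkS4class{CytobandMap}.
#' @param chrom chromosome name.
#' @param band band name, or one of \code{pter}, \code{qter}, \code{p10},
#'   \code{q10}.
#' @return integer ordinal.
#' @export
bandIndex <- function(map, chrom, band) {
  r <- .resolveBandToken(map, chrom, band)
  as.integer(r$lo)
}

#' @rdname bandIndex
#' @return \code{bandSpan}: integer(2) inclusive ordinal span.
#' @export
bandSpan <- function(map, chrom, band) {
  r <- .resolveBandToken(map, chrom, band)
  c(r$lo, r$hi)
}

# ordinal span (lo, hi) of an interval given two terminus tokens
.intervalSpan <- function(map, chrom, startBand, endBand) {
  a <- .resolveBandToken(map, chrom, startBand)
  b <- .resolveBandToken(map, chrom, endBand)
  list(lo = min(a$lo, b$lo), hi = max(a$hi, b$hi),
       inverted = (a$lo + a$hi) > (b$lo + b$hi),
       uncertain = a$uncertain || b$uncertain)
}

#' Locus containment in a band interval
#'
#' TRUE iff the locus band's ordinal span intersects the closed ordinal
#' range of the interval's termini, orientation-independent.  A
#' lower-resolution band designator contains all its sub-bands.  A locus on
#' a different chromosome is simply not contained (FALSE, not an error).
#'
#' @param map a \linkS4class{CytobandMap}.
#' @param chrom,startBand,endBand the interval: chromosome and its two
#'   terminus tokens (band names or pter/qter/p10/q10), in written order.
#' @param locusChrom,locusBand the locus position.
#' @return logical.
#' @export
bandContains <- function(map, chrom, startBand, endBand, locusChrom, locusBand) {
  if (.normChrom(chrom) != .normChrom(locusChrom)) return(FALSE)
  iv <- .intervalSpan(map, chrom, startBand, endBand)
  lb <- .resolveBandToken(map, .normChrom(locusChrom), locusBand)
  # a locus given at parent-band resolution is contained iff any of its
  # sub-bands is contained, hence an intersection test on ordinal spans
  lb$hi >= iv$lo && lb$lo <= iv$hi
}

#' Does a band interval span the centromere?
#'
#' TRUE iff the interval includes the \code{p10} or \code{q10} centromeric
#' marker, or its termini lie on opposite arms.
#'
#' @inheritParams bandContains
#' @return logical.
#' @export
spansCentromere <- function(map, chrom, startBand, endBand) {
  chrom <- .normChrom(chrom)
  b <- .chromBands(map, chrom)
  p10 <- b$ordinal[b$band == "p10"]
  q10 <- b$ordinal[b$band == "q10"]
  iv <- .intervalSpan(map, chrom, startBand, endBand)
  (iv$lo <= p10 && iv$hi >= p10) || (iv$lo <= q10 && iv$hi >= q10)
}

# centromere ordinals (p10, q10) for a chromosome
.cenOrdinals <- function(map, chrom) {
  b <- .chromBands(map, chrom)
  c(p10 = b$ordinal[b$band == "p10"], q10 = b$ordinal[b$band == "q10"])
}
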