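# ISCN (2013) karyotype parser: short-form and detailed-system events.
#
# Supported dialect (anything else raises an "unsupported construct" error,
# never a silent skip): chromosome count / count range, ploidy marker
# "<Nn>", sex designation, numerical gains/losses, der with t() short form
# (including three-way), whole-arm der(A;B)(p10;q10), detailed-system
# segment lists with "::" junctions, r (ring), psu dic, dup, del, trailing
# del/amp/dup modifier clauses, "?" and "~" uncertainty, clone frequencies
# "[n]".  Unicode tilde and arrow are accepted.

.BAND_RX <- "(?:[0-9]{1,2}|X|Y)?[pq](?:ter|[0-9?]+(?:\\.[0-9?]+)?(?:~[0-9]+)?)"

.normalizeIscn <- function(text) {
  # Unicode tilde operator (U+223C), plain tilde and Unicode arrow (U+2192)
  # are all accepted
  s <- gsub("\u223c", "~", text)
  s <- gsub("\u2192", "->", s)
  s <- gsub("psu[ ]+dic", "psu_dic", s)
  gsub("[[:space:]]+", "", s)
}

# split at top level (outside parentheses/brackets)
.splitTop <- function(s, sep = ",") {
  out <- character(0)
  depth <- 0L
  cur <- ""
  for (ch in strsplit(s, "")[[1]]) {
    if (ch %in% c("(", "[")) depth <- depth + 1L
    if (ch %in% c(")", "]")) depth <- depth - 1L
    if (ch == sep && depth == 0L) {
      out <- c(out, cur)
      cur <- ""
    } else {
      cur <- paste0(cur, ch)
    }
  }
  c(out, cur)
}

# scan a structured clause into units: name + attached "(...)" groups
.scanUnits <- function(s) {
  units <- list()
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    rest <- substr(s, i, n)
    m <- regmatches(rest, regexpr("^[a-z_]+", rest))
    nm <- if (length(m)) m else ""
    i <- i + nchar(nm)
    groups <- character(0)
    while (i <= n && substr(s, i, i) == "(") {
      depth <- 0L
      j <- i
      repeat {
        ch <- substr(s, j, j)
        if (ch == "(") depth <- depth + 1L
        if (ch == ")") {
          depth <- depth - 1L
          if (depth == 0L) break
        }
        j <- j + 1L
        if (j > n) stop("unbalanced parentheses in '", s, "'")
      }
      groups <- c(groups, substr(s, i + 1L, j - 1L))
      i <- j + 1L
    }
    if (nm == "" && !length(groups)) {
      stop("cannot parse '", rest, "' in '", s, "'")
    }
    units[[length(units) + 1L]] <- list(name = nm, groups = groups)
  }
  units
}

# split a concatenated band pair like "q21.1qter" or "20p11.1q11.21"
.splitBandPair <- function(s) {
  m <- regexpr(paste0("^", .BAND_RX), s, perl = TRUE)
  if (m == -1) stop("cannot parse band range '", s, "'")
  first <- regmatches(s, m)
  rest <- substr(s, nchar(first) + 1L, nchar(s))
  if (!nzchar(rest)) return(c(first, first))
  if (!grepl(paste0("^", .BAND_RX, "$"), rest, perl = TRUE)) {
    stop("cannot parse band range '", s, "'")
  }
  c(first, rest)
}

# split "18qter" / "q10" / "19p13.?" into chromosome (may be "") and band
.splitTerminus <- function(tok) {
  m <- regexec("^(\\??)([0-9]{1,2}|X|Y)?([pq].*)$", tok)
  g <- regmatches(tok, m)[[1]]
  if (!length(g)) stop("cannot parse band terminus '", tok, "'")
  list(chrom = g[3], band = g[4], uncertainChrom = nzchar(g[2]))
}

.segRow <- function(map, chrom, s, e, mult = 1L, multUnspecified = FALSE,
                    homologue = "unknown") {
  iv <- .intervalSpan(map, chrom, s, e)
  data.frame(chrom = chrom, start = s, end = e, lo = iv$lo, hi = iv$hi,
             inverted = iv$inverted, multiplicity = as.integer(mult),
             multUnspecified = multUnspecified, homologue = homologue,
             uncertain = iv$uncertain, stringsAsFactors = FALSE)
}

.emptySegments <- function() {
  data.frame(chrom = character(0), start = character(0), end = character(0),
             lo = integer(0), hi = integer(0), inverted = logical(0),
             multiplicity = integer(0), multUnspecified = logical(0),
             homologue = character(0), uncertain = logical(0))
}

.emptyModifiers <- function() {
  data.frame(op = character(0), chrom = character(0), band1 = character(0),
             band2 = character(0), lo = integer(0), hi = integer(0),
             uncertain = logical(0))
}

# parse a detailed-system segment list ("::"-joined); ring lists start and
# end with "::"
.parseDetailed <- function(group, map, defaultChrom) {
  ring <- startsWith(group, "::")
  pieces <- strsplit(group, "::", fixed = TRUE)[[1]]
  pieces <- pieces[nzchar(pieces)]
  segs <- .emptySegments()
  lastChrom <- defaultChrom
  for (p in pieces) {
    if (grepl("->", p, fixed = TRUE)) {
      ends <- strsplit(p, "->", fixed = TRUE)[[1]]
      if (length(ends) != 2) stop("cannot parse segment '", p, "'")
      a <- .splitTerminus(ends[1])
      b <- .splitTerminus(ends[2])
      chrom <- if (nzchar(a$chrom)) a$chrom else lastChrom
      chromB <- if (nzchar(b$chrom)) b$chrom else chrom
      if (.normChrom(chromB) != .normChrom(chrom)) {
        stop("segment '", p, "' mixes chromosomes ", chrom, " and ", chromB)
      }
      segs <- rbind(segs, .segRow(map, .normChrom(chrom), a$band, b$band))
      lastChrom <- chrom
    } else {
      # concatenated band range, e.g. "20p11.1q11.21"
      pr <- .splitBandPair(p)
      t1 <- .splitTerminus(pr[1])
      t2 <- .splitTerminus(pr[2])
      chrom <- if (nzchar(t1$chrom)) t1$chrom else lastChrom
      segs <- rbind(segs, .segRow(map, .normChrom(chrom), t1$band, t2$band))
      lastChrom <- chrom
    }
  }
  if (!nrow(segs)) stop("empty detailed segment list")
  list(segments = segs, ring = ring)
}

# --- short-form derivative expansion ------------------------------------

.wholePath <- function(map, chrom) {
  .segRow(map, .normChrom(chrom), "pter", "qter")
}

.armTelomere <- function(band) {
  if (startsWith(band, "p")) "pter" else "qter"
}

# row index of the path segment containing band `b` of chromosome `chrom`
.findInPath <- function(path, map, chrom, b) {
  sp <- bandSpan(map, chrom, gsub("[?]", "", b))
  for (i in seq_len(nrow(path))) {
    if (.normChrom(path$chrom[i]) == .normChrom(chrom) &&
        sp[2] >= path$lo[i] && sp[1] <= path$hi[i]) {
      return(i)
    }
  }
  stop("breakpoint ", chrom, b, " not found on the derivative")
}

# apply one reciprocal-translocation clause to a derivative path.
# The path is kept pter->qter-anchored along the primary chromosome, so the
# replaced side is the one away from the primary centromere.
.applyT <- function(path, map, primary, chroms, bands) {
  inPath <- vapply(chroms, function(c2) {
    any(.normChrom(path$chrom) == .normChrom(c2))
  }, logical(1))
  if (sum(inPath) == 0) stop("translocation t(", paste(chroms, collapse = ";"),
                             ") does not touch the derivative")
  residentIdx <- which(inPath)[1]
  if (sum(inPath) > 1) {
    # prefer the cited chromosome whose breakpoint lies on the current path
    for (k in which(inPath)) {
      ok <- tryCatch({
        .findInPath(path, map, chroms[k], bands[k])
        TRUE
      }, error = function(e) FALSE)
      if (ok) {
        residentIdx <- k
        break
      }
    }
  }
  res <- chroms[residentIdx]
  resBand <- bands[residentIdx]
  par <- chroms[-residentIdx][1]
  parBand <- bands[-residentIdx][1]
  i <- .findInPath(path, map, res, resBand)
  cen <- .cenOrdinals(map, primary)
  j <- NA_integer_
  for (k in seq_len(nrow(path))) {
    if (.normChrom(path$chrom[k]) == .normChrom(primary) &&
        path$lo[k] <= cen["p10"] && path$hi[k] >= cen["q10"]) {
      j <- k
      break
    }
  }
  if (is.na(j)) stop("derivative lost its ", primary, " centromere")
  bp <- mean(bandSpan(map, res, gsub("[?]", "", resBand)))
  replaceRight <- if (i != j) i > j else bp > mean(cen)
  parTel <- .armTelomere(parBand)
  if (replaceRight) {
    row <- .segRow(map, .normChrom(res), path$start[i], resBand)
    path <- rbind(path[seq_len(i - 1L), , drop = FALSE], row,
                  .segRow(map, .normChrom(par), parBand, parTel))
  } else {
    row <- .segRow(map, .normChrom(res), resBand, path$end[i])
    path <- rbind(.segRow(map, .normChrom(par), parTel, parBand), row,
                  path[seq(i + 1L, length.out = nrow(path) - i), , drop = FALSE])
  }
  path
}

#' Expand a short-form derivative to its segment list
#'
#' Applies ISCN derivative semantics to a short-form event written with
#' t()/breakpoint notation: the derivative keeps the centromeric portion of
#' the named chromosome and exchanges the portions distal to each breakpoint
#' for the translocation partners' telomeric tails.  Multiple t() clauses
#' are applied left to right.  Three-way translocations
#' (\code{der(N)t(a;N;c)} with two breakpoints on N) are expanded by cyclic
#' exchange semantics.  The result is canonicalized pter->qter along the
#' derivative.
#'
#' @param clause a short-form clause, e.g.
#'   \code{"der(1)t(1;15)(p36.3;q22.31)"}.
#' @param map a \linkS4class{CytobandMap}.
#' @return data.frame of ordered segments (see
#'   \linkS4class{StructuredChromosome}).
#' @export
expandShortForm <- function(clause, map = systemCytobandMap()) {
  ev <- .parseStructured(.normalizeIscn(clause), map, list())
  ev@segments
}

.expandDer <- function(units, map, cenChroms) {
  primary <- cenChroms[1]
  path <- .wholePath(map, primary)
  modifiers <- .emptyModifiers()
  for (u in units) {
    if (u$name == "t") {
      chroms <- gsub("\\?", "", strsplit(u$groups[1], ";")[[1]])
      bandGroups <- strsplit(u$groups[2], ";")[[1]]
      if (length(chroms) != length(bandGroups)) {
        stop("breakpoint arity mismatch in t(", u$groups[1], ")(",
             u$groups[2], ")")
      }
      if (length(chroms) == 2) {
        path <- .applyT(path, map, primary, chroms, bandGroups)
      } else if (length(chroms) == 3) {
        # cyclic three-way exchange; the named chromosome carries two
        # breakpoints written as a concatenated pair
        mid <- which(.normChrom(chroms) == .normChrom(primary))
        if (length(mid) != 1) {
          stop("three-way translocation must cite the derivative chromosome")
        }
        midBands <- .splitBandPair(bandGroups[mid])
        others <- setdiff(seq_along(chroms), mid)
        left <- others[1]
        right <- others[2]
        path <- rbind(
          .segRow(map, .normChrom(chroms[left]),
                  .armTelomere(bandGroups[left]), bandGroups[left]),
          .segRow(map, .normChrom(primary), midBands[1], midBands[2]),
          .segRow(map, .normChrom(chroms[right]), bandGroups[right],
                  .armTelomere(bandGroups[right])))
      } else {
        stop("unsupported construct: t() citing ", length(chroms),
             " chromosomes")
      }
    } else if (u$name %in% c("del", "amp", "dup")) {
      modifiers <- rbind(modifiers, .parseModifier(u, map))
    } else {
      stop("unsupported construct '", u$name, "' after der()")
    }
  }
  list(segments = path, modifiers = modifiers)
}

.parseModifier <- function(u, map) {
  chrom <- .normChrom(gsub("\\?", "", u$groups[1]))
  pr <- .splitBandPair(u$groups[2])
  iv <- .intervalSpan(map, chrom, pr[1], pr[2])
  data.frame(op = u$name, chrom = chrom, band1 = pr[1], band2 = pr[2],
             lo = iv$lo, hi = iv$hi, uncertain = iv$uncertain,
             stringsAsFactors = FALSE)
}

# whole-arm derivative: der(A;B)(x10;y10) keeps A from its x-arm telomere to
# the centromere and B from the centromere to its y-arm telomere
.wholeArmSegments <- function(map, cenChroms, args) {
  bands <- strsplit(args, ";")[[1]]
  if (length(bands) != 2 || length(cenChroms) != 2) {
    stop("whole-arm derivative needs two chromosomes and two arm breakpoints")
  }
  canon <- vapply(bands, function(b) gsub("\\?", "", b), character(1))
  if (!all(canon %in% c("p10", "q10"))) {
    stop("whole-arm derivative breakpoints must be p10/q10, got '",
         args, "'")
  }
  a <- cenChroms[1]
  b <- cenChroms[2]
  armA <- substr(canon[1], 1, 1)
  armB <- substr(canon[2], 1, 1)
  rbind(
    .segRow(map, .normChrom(a), paste0(armA, "ter"), canon[1]),
    .segRow(map, .normChrom(b), canon[2], paste0(armB, "ter")))
}

.parseStructured <- function(tok, map, prior) {
  gained <- startsWith(tok, "+")
  s <- sub("^\\+", "", tok)
  units <- .scanUnits(s)
  head <- units[[1]]
  kind <- switch(head$name,
                 der = "der", r = "r", psu_dic = "psu dic",
                 dup = "dup", del = "del",
                 stop("unsupported construct '", head$name, "' in '", s, "'"))
  if (!length(head$groups)) stop("missing chromosome list in '", s, "'")
  cenRaw <- strsplit(head$groups[1], ";")[[1]]
  cenChroms <- .normChrom(gsub("\\?", "", cenRaw))
  uncertain <- grepl("[?~]", s)
  ring <- FALSE
  modifiers <- .emptyModifiers()
  activeCen <- NA_character_
  rest <- units[-1]
  extraGroups <- head$groups[-1]

  if (kind == "psu dic") {
    if (length(extraGroups) != 1) stop("psu dic needs one breakpoint group")
    bands <- strsplit(extraGroups, ";")[[1]]
    if (length(bands) != 2) stop("psu dic needs two breakpoints")
    # first-cited chromosome keeps the active centromere (ISCN)
    activeCen <- cenChroms[1]
    b1 <- .resolveBandToken(map, cenChroms[1], bands[1])$canonical
    b2 <- .resolveBandToken(map, cenChroms[2], bands[2])$canonical
    far1 <- if (startsWith(b1, "p")) "qter" else "pter"
    far2 <- if (startsWith(b2, "p")) "qter" else "pter"
    segments <- rbind(
      .segRow(map, cenChroms[1], far1, bands[1]),
      .segRow(map, cenChroms[2], bands[2], far2))
    for (u in rest) {
      if (!u$name %in% c("del", "amp", "dup")) {
        stop("unsupported construct '", u$name, "' after psu dic")
      }
      modifiers <- rbind(modifiers, .parseModifier(u, map))
    }
  } else if (kind == "r") {
    if (length(extraGroups) == 1 && grepl("::|->", extraGroups)) {
      det <- .parseDetailed(extraGroups, map, cenChroms[1])
      segments <- det$segments
      ring <- TRUE
    } else if (!length(extraGroups) && !length(rest)) {
      # bare ring of one chromosome: pericentromeric content unknown;
      # modelled as the whole chromosome minus telomeres at band level
      segments <- .segRow(map, cenChroms[1], "p10", "q10")
      ring <- TRUE
    } else {
      stop("unsupported ring form in '", s, "'")
    }
  } else if (kind == "dup") {
    if (length(extraGroups) != 1) stop("dup needs a band range")
    pr <- .splitBandPair(extraGroups)
    # direct duplication: pter -> distal breakpoint :: proximal -> qter
    o1 <- mean(bandSpan(map, cenChroms[1], gsub("[?]", "", pr[1])))
    o2 <- mean(bandSpan(map, cenChroms[1], gsub("[?]", "", pr[2])))
    proximal <- if (o1 <= o2) pr[1] else pr[2]
    distal <- if (o1 <= o2) pr[2] else pr[1]
    segments <- rbind(
      .segRow(map, cenChroms[1], "pter", distal),
      .segRow(map, cenChroms[1], proximal, "qter"))
  } else if (kind == "del") {
    if (length(extraGroups) != 1) stop("del needs a band range")
    one <- regmatches(extraGroups,
                      regexpr(paste0("^", .BAND_RX, "$"), extraGroups,
                              perl = TRUE))
    if (length(one)) {
      # terminal deletion: everything distal to the breakpoint is lost
      if (startsWith(gsub("^[0-9XY]+", "", one), "q")) {
        segments <- .segRow(map, cenChroms[1], "pter", one)
      } else {
        segments <- .segRow(map, cenChroms[1], one, "qter")
      }
    } else {
      pr <- .splitBandPair(extraGroups)
      if (pr[1] == pr[2]) {
        # single-band interstitial deletion: band-level bookkeeping via a
        # del modifier over the full chromosome
        segments <- .segRow(map, cenChroms[1], "pter", "qter")
        modifiers <- rbind(modifiers, .parseModifier(
          list(name = "del", groups = c(cenChroms[1], extraGroups)), map))
      } else {
        o1 <- mean(bandSpan(map, cenChroms[1], gsub("[?]", "", pr[1])))
        o2 <- mean(bandSpan(map, cenChroms[1], gsub("[?]", "", pr[2])))
        proximal <- if (o1 <= o2) pr[1] else pr[2]
        distal <- if (o1 <= o2) pr[2] else pr[1]
        segments <- rbind(
          .segRow(map, cenChroms[1], "pter", proximal),
          .segRow(map, cenChroms[1], distal, "qter"))
      }
    }
  } else {  # der
    if (length(extraGroups) >= 1 && grepl("::|->", extraGroups[1])) {
      det <- .parseDetailed(extraGroups[1], map, cenChroms[1])
      segments <- det$segments
      ring <- det$ring
      for (u in rest) {
        if (!u$name %in% c("del", "amp", "dup")) {
          stop("unsupported construct '", u$name, "' after detailed der")
        }
        modifiers <- rbind(modifiers, .parseModifier(u, map))
      }
    } else if (length(extraGroups) >= 1 && grepl(";", extraGroups[1])) {
      segments <- .wholeArmSegments(map, cenChroms, extraGroups[1])
      for (u in rest) {
        if (!u$name %in% c("del", "amp", "dup")) {
          stop("unsupported construct '", u$name, "' after whole-arm der")
        }
        modifiers <- rbind(modifiers, .parseModifier(u, map))
      }
    } else if (!length(extraGroups) && !length(rest)) {
      # bare "der(A;B)" / "der(N)": an additional copy of a previously
      # defined derivative with the same cited chromosomes
      hit <- NULL
      for (p in prior) {
        if (is(p, "StructuredChromosome") && p@kind == "der" &&
            identical(p@cenChroms, cenChroms)) {
          hit <- p
          break
        }
      }
      if (is.null(hit)) {
        stop("bare der(", paste(cenRaw, collapse = ";"),
             ") has no previously defined derivative to copy")
      }
      segments <- hit@segments
      modifiers <- hit@modifiers
      ring <- hit@ring
    } else if (length(rest) && rest[[1]]$name == "t") {
      ex <- .expandDer(rest, map, cenChroms)
      segments <- ex$segments
      modifiers <- ex$modifiers
    } else {
      stop("unsupported der form in '", s, "'")
    }
  }
  label <- paste0(kind, "(", paste(cenRaw, collapse = ";"), ")")
  new("StructuredChromosome", kind = kind, cenChroms = cenChroms,
      gained = gained, ring = ring, segments = segments,
      modifiers = modifiers, activeCen = activeCen, freq = NA_integer_,
      text = gsub("psu_dic", "psu dic", s), label = label,
      uncertain = uncertain || any(segments$uncertain))
}

#' Parse an ISCN karyotype string
#'
#' Parses a single-clone ISCN 2013 karyotype (short-form and
#' detailed-system constructs; see the package vignette for the supported
#' dialect) into a \linkS4class{KaryotypeModel}.  Every comma-separated
#' token must be consumed; malformed or unsupported tokens raise an error
#' naming the offending substring and its character offset.
#'
#' @param text the karyotype string.
#' @param map a \linkS4class{CytobandMap} used to resolve band designators.
#' @return a \linkS4class{KaryotypeModel}.
#' @examples
#' m <- parseKaryotype("46,XY")
#' normalCount(m, "7")
#' @export
parseKaryotype <- function(text, map = systemCytobandMap()) {
  s <- .normalizeIscn(text)
  toks <- .splitTop(s, ",")
  offsets <- cumsum(c(0L, nchar(toks[-length(toks)]) + 1L))
  i <- 1L
  fail <- function(idx, msg) {
    stop("karyotype parse error at offset ", offsets[idx], " ('",
         toks[idx], "'): ", msg, call. = FALSE)
  }
  if (!grepl("^[0-9]+(~[0-9]+)?$", toks[i])) {
    fail(i, "expected chromosome count or count range")
  }
  cr <- as.numeric(strsplit(toks[i], "~", fixed = TRUE)[[1]])
  countRange <- if (length(cr) == 1) c(cr, cr) else cr
  i <- i + 1L
  ploidy <- 2L
  if (i <= length(toks) && grepl("^<[0-9]n>$", toks[i])) {
    ploidy <- as.integer(sub("^<([0-9])n>$", "\\1", toks[i]))
    i <- i + 1L
  }
  sex <- ""
  if (i <= length(toks) && grepl("^[XY]{1,5}$", toks[i])) {
    sex <- toks[i]
    i <- i + 1L
  }
  events <- list()
  # sex-chromosome gains/losses written directly after the sex designation
  # describe how the written complement differs from the ploidy reference;
  # the complement itself is already the observed count
  inSexRun <- nzchar(sex)
  while (i <= length(toks)) {
    tok <- toks[i]
    freq <- NA_integer_
    fm <- regexec("^(.*)\\[([0-9]+)\\]$", tok)
    g <- regmatches(tok, fm)[[1]]
    if (length(g)) {
      tok <- g[2]
      freq <- as.integer(g[3])
      if (freq < 1) fail(i, "clone frequency must be positive")
    }
    if (grepl("^[+-]([0-9]{1,2}|X|Y)$", tok)) {
      chrom <- .normChrom(substr(tok, 2, nchar(tok)))
      if (!chrom %in% unique(map@bands$chrom)) fail(i, "unknown chromosome")
      reflected <- inSexRun && chrom %in% c("X", "Y")
      events[[length(events) + 1L]] <- list(
        kind = "num", chrom = chrom,
        delta = if (startsWith(tok, "+")) 1L else -1L,
        freq = freq, reflected = reflected)
      if (!reflected) inSexRun <- FALSE
    } else {
      inSexRun <- FALSE
      ev <- tryCatch(.parseStructured(tok, map, events),
                     error = function(e) e)
      if (inherits(ev, "error")) fail(i, conditionMessage(ev))
      ev@freq <- freq
      events[[length(events) + 1L]] <- ev
    }
    i <- i + 1L
  }
  new("KaryotypeModel", countRange = countRange, ploidy = ploidy,
      sex = sex, events = events)
}

#' The bundled HEL (VCCS subline) karyotype
#'
#' Returns the near-triploid HEL cell line karyotype string bundled with the
#' package (VCCS subline, combined G-banding / M-FISH / M-BAND / SNP-array
#' determination), ready for \code{\link{parseKaryotype}}.
#'
#' @return a single karyotype string.
#' @export
helKaryotype <- function() {
  lines <- readLines(system.file("extdata", "hel_karyotype.txt",
                                 package = "karyorecon", mustWork = TRUE),
                     encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  lines[1]
}
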