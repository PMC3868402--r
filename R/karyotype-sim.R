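# Random karyotype generation over the supported ISCN dialect, used for
# round-trip property testing and as a source of synthetic truths.

#' Generate random ISCN karyotype strings
#'
#' Draws karyotypes from the supported dialect: numerical gains/losses,
#' short-form der with t() clauses, whole-arm der(A;B)(p10;q10),
#' detailed-system derivatives, rings, dup and del events, and
#' pseudodicentrics with amp modifiers, with optional clone frequencies.
#' Normal-homologue bookkeeping is respected so generated models never
#' consume more copies of a chromosome than the ploidy baseline provides.
#'
#' @param n number of karyotypes.
#' @param seed integer seed.
#' @param map a \linkS4class{CytobandMap}.
#' @return character vector of karyotype strings.
#' @export
randomKaryotypes <- function(n, seed, map = systemCytobandMap()) {
  subseeds <- .withSeed(seed, sample.int(.Machine$integer.max, n))
  vapply(seq_len(n), function(i) randomKaryotype(subseeds[i], map),
         character(1))
}

#' @rdname randomKaryotypes
#' @export
randomKaryotype <- function(seed, map = systemCytobandMap()) {
  .withSeed(seed, {
    chroms <- as.character(1:22)
    ploidy <- sample(2:3, 1)
    avail <- stats::setNames(rep(ploidy, length(chroms)), chroms)
    sex <- sample(c("XX", "XY"), 1)
    nev <- sample(2:6, 1)
    evs <- character(0)
    leafband <- function(ch, arm = NULL) {
      b <- leafBands(map, ch)
      if (!is.null(arm)) b <- b[b$arm == arm, ]
      sample(b$band, 1)
    }
    takeChrom <- function(k = 1) {
      ok <- names(avail)[avail > 0]
      if (length(ok) < k) return(NULL)
      sample(ok, k)
    }
    maybeFreq <- function() {
      if (stats::runif(1) < 0.3) paste0("[", sample(5:20, 1), "]") else ""
    }
    for (i in seq_len(nev)) {
      type <- sample(c("num", "dert", "wholearm", "detder", "ring", "dup",
                       "del", "psudic"), 1,
                     prob = c(0.25, 0.2, 0.1, 0.15, 0.08, 0.08, 0.08, 0.06))
      gained <- stats::runif(1) < 0.3
      ev <- NULL
      if (type == "num") {
        ch <- sample(chroms, 1)
        if (!gained && avail[ch] > 0) {
          avail[ch] <- avail[ch] - 1
          ev <- paste0("-", ch)
        } else {
          avail[ch] <- avail[ch] + 1
          ev <- paste0("+", ch)
        }
      } else if (type == "dert") {
        cs <- sample(chroms, 2)
        if (!gained) {
          if (avail[cs[1]] == 0) gained <- TRUE else avail[cs[1]] <- avail[cs[1]] - 1
        }
        ev <- paste0("der(", cs[1], ")t(", min(as.integer(cs)), ";",
                     max(as.integer(cs)), ")(",
                     if (as.integer(cs[1]) < as.integer(cs[2])) {
                       paste0(leafband(cs[1]), ";", leafband(cs[2]))
                     } else {
                       paste0(leafband(cs[2]), ";", leafband(cs[1]))
                     }, ")")
      } else if (type == "wholearm") {
        cs <- takeChrom(2)
        if (is.null(cs)) next
        if (!gained) {
          avail[cs[1]] <- avail[cs[1]] - 1
          avail[cs[2]] <- avail[cs[2]] - 1
        }
        arms <- sample(c("p10", "q10"), 2, replace = TRUE)
        ev <- paste0("der(", cs[1], ";", cs[2], ")(", arms[1], ";", arms[2], ")")
      } else if (type == "detder") {
        cs <- sample(chroms, 3)
        if (!gained) {
          if (avail[cs[1]] == 0) gained <- TRUE else avail[cs[1]] <- avail[cs[1]] - 1
        }
        b1 <- leafband(cs[1])
        b2 <- leafband(cs[1])
        ev <- paste0("der(", cs[1], ")(",
                     cs[2], "qter->", cs[2], leafband(cs[2], "q"), "::",
                     cs[1], b1, "->", cs[1], b2, "::",
                     cs[3], leafband(cs[3], "q"), "->", cs[3], "qter)")
      } else if (type == "ring") {
        ch <- sample(chroms, 1)
        if (!gained) {
          if (avail[ch] == 0) gained <- TRUE else avail[ch] <- avail[ch] - 1
        }
        ev <- paste0("r(", ch, ")(::", ch, leafband(ch, "p"), "->",
                     ch, leafband(ch, "q"), "::)")
      } else if (type == "dup") {
        ch <- sample(chroms, 1)
        if (!gained) {
          if (avail[ch] == 0) gained <- TRUE else avail[ch] <- avail[ch] - 1
        }
        b <- leafBands(map, ch)
        bq <- b$band[b$arm == "q"]
        ev <- paste0("dup(", ch, ")(", bq[1], sample(c("qter", bq[length(bq)]), 1),
                     ")")
      } else if (type == "del") {
        ch <- sample(chroms, 1)
        if (!gained) {
          if (avail[ch] == 0) gained <- TRUE else avail[ch] <- avail[ch] - 1
        }
        b <- leafBands(map, ch)
        bq <- b$band[b$arm == "q"]
        if (stats::runif(1) < 0.5 || length(bq) < 3) {
          ev <- paste0("del(", ch, ")(", bq[2], ")")
        } else {
          ev <- paste0("del(", ch, ")(", bq[2], bq[length(bq) - 1], ")")
        }
      } else {  # psudic
        cs <- takeChrom(2)
        if (is.null(cs)) next
        if (!gained) {
          avail[cs[1]] <- avail[cs[1]] - 1
          avail[cs[2]] <- avail[cs[2]] - 1
        }
        ev <- paste0("psu dic(", cs[1], ";", cs[2], ")(",
                     leafband(cs[1], "p"), ";", leafband(cs[2], "p"), ")")
        if (stats::runif(1) < 0.4) {
          ev <- paste0(ev, "amp(", cs[1], ")(", leafband(cs[1], "p"),
                       leafband(cs[1], "p"), ")")
        }
      }
      if (is.null(ev)) next
      evs <- c(evs, paste0(if (gained && type != "num") "+" else "", ev,
                           maybeFreq()))
    }
    count <- ploidy * 23 + sample(-4:4, 1)
    head <- if (stats::runif(1) < 0.3) {
      paste0(count, "~", count + sample(1:6, 1))
    } else {
      as.character(count)
    }
    paste(c(head, if (ploidy != 2) paste0("<", ploidy, "n>"), sex, evs),
          collapse = ",")
  })
}
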