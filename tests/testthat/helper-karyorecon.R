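# Shared fixtures and independent brute-force oracles.

kmap <- systemCytobandMap()
kloci <- bundledLoci()

helModel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- parseKaryotype(helKaryotype(), kmap)
    cache
  }
})

# toy truth: three derivative chromosomes over six chromosomes, suitable
# for exact inversion
toyKaryotype <- function() {
  paste0("48,XX,",
         "der(1)t(1;5)(p22.1;q23.1),",
         "der(3)t(3;8)(q21;q22.1),",
         "+der(11)t(11;20)(p11.2;q11.22)")
}
toyHk <- function() assignHomologues(parseKaryotype(toyKaryotype(), kmap), kmap)
toyChroms <- c("1", "3", "5", "8", "11", "20")

# ---- oracle: locus containment by explicit enumeration ------------------
# enumerate every band between the termini of an interval and check the
# locus band (or one of its sub-bands) is among them
oracleContains <- function(map, chrom, startBand, endBand,
                           locusChrom, locusBand) {
  if (locusChrom != chrom) return(FALSE)
  b <- map@bands[map@bands$chrom == chrom, ]
  matches <- function(leaf, tok) {
    leaf == tok || startsWith(leaf, paste0(tok, ".")) ||
      (grepl("\\.", tok) && startsWith(leaf, tok))
  }
  ordsOf <- function(tok) {
    if (tok == "pter") return(0)
    if (tok == "qter") return(max(b$ordinal) + 1)
    b$ordinal[vapply(b$band, matches, logical(1), tok = tok)]
  }
  s <- ordsOf(startBand)
  e <- ordsOf(endBand)
  between <- b$band[b$ordinal >= min(c(s, e)) & b$ordinal <= max(c(s, e))]
  any(vapply(between, matches, logical(1), tok = locusBand))
}

# ---- oracle: exhaustive segment assignment ------------------------------
# enumerate every mapping of segments to derivatives and keep those that
# satisfy the constraint predicate (re-stated naively here)
oracleAssign <- function(segments, paints) {
  obs <- paints@observations
  labels <- vapply(obs, `[[`, character(1), "label")
  nd <- length(obs)
  ns <- nrow(segments)
  sols <- list()
  grid <- rep(list(seq_len(nd)), ns)
  combos <- do.call(expand.grid, grid)
  for (r in seq_len(nrow(combos))) {
    asg <- as.integer(combos[r, ])
    ok <- TRUE
    for (d in seq_len(nd)) {
      mine <- segments[asg == d, , drop = FALSE]
      o <- obs[[d]]
      if (!setequal(unique(mine$chrom), o$sources)) { ok <- FALSE; break }
      nterm <- sum(mine$terminal)
      if (isTRUE(o$ring) && nterm > 0) { ok <- FALSE; break }
      if (!isTRUE(o$ring) && nterm > 2) { ok <- FALSE; break }
      for (ch in names(o$cenCounts)) {
        got <- sum(mine$spansCen & mine$chrom == ch)
        if (got != o$cenCounts[[ch]]) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) sols[[length(sols) + 1L]] <- setNames(labels[asg], segments$id)
  }
  sols
}

normalizeSolutions <- function(sols) {
  if (!length(sols)) return(character(0))
  sort(vapply(sols, function(s) {
    s <- s[order(names(s))]
    paste(names(s), s, sep = "->", collapse = ";")
  }, character(1)))
}

# ---- oracle: parsimony by exhaustive ancestral labelings ----------------
# score a nested-list rooted tree by brute force: enumerate all 0/1 state
# assignments to internal nodes (the founding clone sits on a stem above
# the root and is fixed at 0)
oracleParsimony <- function(tree, cm) {
  countInternal <- function(node) {
    if (is.character(node)) return(0L)
    1L + countInternal(node[[1]]) + countInternal(node[[2]])
  }
  nInt <- countInternal(tree)
  total <- 0
  for (i in seq_len(nrow(cm@states))) {
    irr <- cm@classes[i] == "LOH"
    obs <- setNames(cm@states[i, ], cm@taxa)
    best <- Inf
    for (mask in 0:(2^nInt - 1)) {
      states <- as.integer(intToBits(mask))[seq_len(nInt)]
      env <- new.env()
      env$k <- 0L
      env$cost <- 0
      walk <- function(node, parentState) {
        if (is.character(node)) {
          s <- obs[[node]]
          if (is.na(s)) s <- parentState  # "?" free
        } else {
          env$k <- env$k + 1L
          s <- states[env$k]
        }
        if (irr && parentState == 1 && s == 0) env$cost <- Inf
        if (s != parentState) env$cost <- env$cost + 1
        if (!is.character(node)) {
          walk(node[[1]], s)
          walk(node[[2]], s)
        }
      }
      # the founding clone (state 0) sits on a stem edge above the root
      walk(tree, 0L)
      best <- min(best, env$cost)
    }
    total <- total + best
  }
  total
}

# independent rooted-topology enumeration for the oracle, via phangorn
oracleTopologies <- function(taxa) {
  trees <- phangorn::allTrees(length(taxa), rooted = TRUE,
                              tip.label = taxa)
  lapply(trees, function(phy) {
    n <- length(phy$tip.label)
    build <- function(node) {
      if (node <= n) return(phy$tip.label[node])
      kids <- phy$edge[phy$edge[, 1] == node, 2]
      list(build(kids[1]), build(kids[2]))
    }
    build(n + 1L)
  })
}

# convert a LineageTree / phylo to the nested-list form (test-local copy)
.asNestedTest <- function(lt) {
  phy <- if (is(lt, "LineageTree")) lt@tree else lt
  n <- length(phy$tip.label)
  build <- function(node) {
    if (node <= n) return(phy$tip.label[node])
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    list(build(kids[1]), build(kids[2]))
  }
  build(n + 1L)
}

# canonical string form of a nested tree (order-insensitive)
treeKey <- function(tree) {
  if (is.character(tree)) return(tree)
  kids <- sort(c(treeKey(tree[[1]]), treeKey(tree[[2]])))
  paste0("(", kids[1], ",", kids[2], ")")
}

# ---- oracle: copy-number profile by fine position sampling --------------
oracleProfile <- function(structures, map, chrom, perBand = 200) {
  if (is(structures, "LinearChromosome")) structures <- list(structures)
  blocks <- do.call(rbind, lapply(structures, function(s) s@blocks))
  bb <- blocks[blocks$chrom == chrom, , drop = FALSE]
  K <- nrow(leafBands(map, chrom))
  vapply(seq_len(K), function(i) {
    xs <- (i - 1) + (seq_len(perBand) - 0.5) / perBand
    mean(vapply(xs, function(x) sum(bb$lo < x & x < bb$hi), numeric(1)))
  }, numeric(1))
}
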