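# Subline lineage inference from CNA/LOH characters with LOH
# irreversibility (Camin-Sokal-style asymmetric parsimony), and
# homologue-duplication event-order constraints.

#' Build / read a character matrix
#'
#' \code{characterMatrix} builds a \linkS4class{CharacterMatrix} from a
#' states matrix; \code{readCharacterMatrix} reads the CSV interchange form
#' (rows = characters; columns \code{name}, \code{class}, then one column
#' per taxon; "?" for unknown).  \code{helSublineCharacters} loads the
#' bundled HEL subline comparison (VCCS, DSMZ, ATCC, CGP).
#'
#' @param states matrix of 0/1/NA, characters in rows, taxa in columns.
#' @param classes per-character class: "CNA" (reversible) or "LOH"
#'   (irreversible).
#' @param taxa taxon names (default: column names of \code{states}).
#' @return a \linkS4class{CharacterMatrix}.
#' @export
characterMatrix <- function(states, classes, taxa = colnames(states)) {
  states <- as.matrix(states)
  mode(states) <- "integer"
  new("CharacterMatrix", taxa = taxa, states = states, classes = classes)
}

#' @rdname characterMatrix
#' @param path CSV path.
#' @export
readCharacterMatrix <- function(path) {
  x <- utils::read.csv(path, comment.char = "#", colClasses = "character",
                       check.names = FALSE)
  taxa <- setdiff(names(x), c("name", "class"))
  st <- as.matrix(x[, taxa])
  st[st == "?"] <- NA
  st <- matrix(as.integer(st), nrow = nrow(x),
               dimnames = list(x$name, taxa))
  characterMatrix(st, x$class, taxa)
}

#' @rdname characterMatrix
#' @export
helSublineCharacters <- function() {
  readCharacterMatrix(system.file("extdata", "hel_subline_characters.csv",
                                  package = "karyorecon", mustWork = TRUE))
}

# ---- rooted binary tree enumeration (nested-list representation) --------

.isLeaf <- function(tree) is.character(tree)

# all ways to insert `leaf` into `tree` (on every edge, or above the root)
.insertLeaf <- function(tree, leaf) {
  res <- list(list(tree, leaf))
  if (!.isLeaf(tree)) {
    for (side in 1:2) {
      for (sub in .insertLeaf(tree[[side]], leaf)) {
        t2 <- tree
        t2[[side]] <- sub
        res <- c(res, list(t2))
      }
    }
  }
  res
}

#' Enumerate all rooted binary topologies over a taxon set
#'
#' Leaf-insertion enumeration; each labelled rooted binary topology is
#' produced exactly once, in deterministic order ((2n-3)!! trees).
#'
#' @param taxa character vector (2 to 8 taxa).
#' @return list of nested-list trees (leaf = taxon name, internal node =
#'   list of two subtrees).
#' @export
enumerateRootedTrees <- function(taxa) {
  if (length(taxa) < 2) stop("need at least two taxa")
  if (length(taxa) > 8) {
    stop("exhaustive enumeration supports at most 8 taxa")
  }
  trees <- list(taxa[1])
  for (k in seq_along(taxa)[-1]) {
    trees <- unlist(lapply(trees, .insertLeaf, leaf = taxa[k]),
                    recursive = FALSE)
  }
  trees
}

.treeTaxa <- function(tree) {
  if (.isLeaf(tree)) tree else c(.treeTaxa(tree[[1]]), .treeTaxa(tree[[2]]))
}

.toNewick <- function(tree) {
  if (.isLeaf(tree)) tree
  else paste0("(", .toNewick(tree[[1]]), ",", .toNewick(tree[[2]]), ")")
}

# Sankoff costs for one character over states {0,1}; root fixed at state 0
# (the founding clone carries no derived aberrations).  Irreversible (LOH)
# characters forbid the 1 -> 0 transition.
.transCost <- function(irreversible) {
  m <- matrix(c(0, 1, 1, 0), 2, 2,
              dimnames = list(c("0", "1"), c("0", "1")))
  if (irreversible) m["1", "0"] <- Inf
  m  # m[parent, child]
}

.charCost <- function(tree, obs, trans) {
  # returns c(cost_if_node_state_0, cost_if_node_state_1)
  if (.isLeaf(tree)) {
    s <- obs[[tree]]
    if (is.na(s)) return(c(0, 0))
    return(if (s == 0) c(0, Inf) else c(Inf, 0))
  }
  l <- .charCost(tree[[1]], obs, trans)
  r <- .charCost(tree[[2]], obs, trans)
  vapply(1:2, function(s) {
    min(trans[s, 1] + l[1], trans[s, 2] + l[2]) +
      min(trans[s, 1] + r[1], trans[s, 2] + r[2])
  }, numeric(1))
}

#' Parsimony score of a rooted tree under LOH irreversibility
#'
#' Small-parsimony cost of a character matrix on a rooted binary tree with
#' the root fixed in the all-zero founding state.  Reversible (CNA)
#' characters count 0<->1 changes symmetrically; irreversible (LOH)
#' characters forbid 1->0, so a pattern that cannot be explained without a
#' reversal costs Inf (in practice extra independent gains are used
#' instead).  "?" states are free.
#'
#' @param tree a nested-list tree (see \code{\link{enumerateRootedTrees}}),
#'   a \linkS4class{LineageTree}, or an \code{ape::phylo}.
#' @param cm a \linkS4class{CharacterMatrix}.
#' @return numeric score (possibly Inf).
#' @export
parsimonyScore <- function(tree, cm) {
  tree <- .asNested(tree)
  if (!setequal(.treeTaxa(tree), cm@taxa)) {
    stop("tree taxa do not match the character matrix")
  }
  total <- 0
  for (i in seq_len(nrow(cm@states))) {
    obs <- as.list(stats::setNames(cm@states[i, ], cm@taxa))
    trans <- .transCost(cm@classes[i] == "LOH")
    cost <- .charCost(tree, obs, trans)
    # the founding clone (all-zero) sits on a stem edge above the taxa's
    # most recent common ancestor: a change shared by every subline costs
    # one change on the stem
    total <- total + min(trans[1, 1] + cost[1], trans[1, 2] + cost[2])
  }
  total
}

.asNested <- function(tree) {
  if (is(tree, "LineageTree")) tree <- tree@tree
  if (inherits(tree, "phylo")) return(.phyloToNested(tree))
  tree
}

.phyloToNested <- function(phy) {
  n <- length(phy$tip.label)
  build <- function(node) {
    if (node <= n) return(phy$tip.label[node])
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    if (length(kids) != 2) stop("tree must be binary")
    list(build(kids[1]), build(kids[2]))
  }
  build(n + 1L)
}

# top-down assignment of ancestral states for one character (ties resolved
# toward the parental state, then toward 0), recording changes per edge
.charChanges <- function(tree, obs, trans, name) {
  changes <- list()
  cost <- .charCost(tree, obs, trans)
  opts <- trans[1, ] + cost
  rootState <- if (opts[1] <= opts[2] + 1e-12) 0L else 1L
  if (rootState != 0L) {
    changes[[length(changes) + 1L]] <- data.frame(
      edge = "stem", character = name, from = 0L, to = rootState)
  }
  walk <- function(node, parentState) {
    if (.isLeaf(node)) {
      s <- obs[[node]]
      s <- if (is.na(s)) parentState else s
      if (s != parentState) {
        changes[[length(changes) + 1L]] <<- data.frame(
          edge = node, character = name, from = parentState, to = s)
      }
      return()
    }
    for (child in node) {
      cc <- .charCost(child, obs, trans)
      opts <- trans[parentState + 1L, ] + cc
      best <- which(opts <= min(opts) + 1e-12) - 1L
      s <- if (parentState %in% best) parentState else min(best)
      if (s != parentState) {
        changes[[length(changes) + 1L]] <<- data.frame(
          edge = paste(sort(.treeTaxa(child)), collapse = "+"),
          character = name, from = parentState, to = s)
      }
      walk(child, s)
    }
  }
  walk(tree, rootState)
  changes
}

#' All minimum-parsimony rooted trees
#'
#' Enumerates every rooted binary topology over the matrix's taxa (at most
#' 8), scores each with \code{\link{parsimonyScore}} and returns all
#' minimizers as \linkS4class{LineageTree} objects with their per-edge
#' character-state changes.
#'
#' @param cm a \linkS4class{CharacterMatrix}.
#' @return list of \linkS4class{LineageTree}.
#' @export
bestTree <- function(cm) {
  trees <- enumerateRootedTrees(cm@taxa)
  scores <- vapply(trees, parsimonyScore, numeric(1), cm = cm)
  smin <- min(scores)
  lapply(trees[scores == smin], function(tr) {
    chg <- list()
    for (i in seq_len(nrow(cm@states))) {
      obs <- as.list(stats::setNames(cm@states[i, ], cm@taxa))
      trans <- .transCost(cm@classes[i] == "LOH")
      chg <- c(chg, .charChanges(tr, obs, trans,
                                 rownames(cm@states)[i] %||% paste0("chr", i)))
    }
    changes <- if (length(chg)) {
      do.call(rbind, c(chg, list(make.row.names = FALSE)))
    } else {
      data.frame(edge = character(0), character = character(0),
                 from = integer(0), to = integer(0))
    }
    new("LineageTree", tree = ape::read.tree(text = paste0(.toNewick(tr), ";")),
        changes = changes, score = smin)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clades of a lineage tree
#'
#' Convenience accessor: the sets of taxa below each internal node.
#'
#' @param lt a \linkS4class{LineageTree} or nested-list tree.
#' @return list of character vectors (sorted taxa per clade).
#' @export
treeClades <- function(lt) {
  tree <- .asNested(lt)
  out <- list()
  walk <- function(node) {
    if (.isLeaf(node)) return(node)
    l <- walk(node[[1]])
    r <- walk(node[[2]])
    all <- sort(c(l, r))
    out[[length(out) + 1L]] <<- all
    all
  }
  walk(tree)
  out
}

#' Event-order constraints from homologue duplication logic
#'
#' In a polyploid genome, if one copy of a duplicated homologue carries a
#' rearrangement, the rearrangement must postdate the doubling of that
#' homologue; and a derivative present in two or more identical copies must
#' have formed before its duplication.  This function derives the implied
#' partial order: for each (chromosome, homologue) present in >= 2 copies
#' of which exactly one copy is rearranged, it emits
#' \code{doubling(chrom.homologue) < rearrangement(derivative)}; for
#' derivatives with >= 2 identical copies it emits
#' \code{formation(derivative) < duplication(derivative)}; explicitly
#' declared descents (child derivative evolved from parent) add
#' \code{formation(parent) < formation(child)}.  The result is checked for
#' cycles.
#'
#' @param hk a \linkS4class{HomologueAssignedKaryotype}.
#' @param descents optional named character vector: child derivative label
#'   -> parent derivative label.
#' @param map a \linkS4class{CytobandMap}.
#' @return list: \code{constraints} (data.frame from/to/rule),
#'   \code{consistent} (logical), \code{order} (a topological order of the
#'   events, NULL if cyclic).
#' @export
eventOrderConstraints <- function(hk, descents = NULL,
                                  map = systemCytobandMap()) {
  model <- hk@model
  evs <- structuredChromosomes(model, principalOnly = TRUE)
  labs <- vapply(evs, function(e) e@text, character(1))
  cons <- list()
  add <- function(from, to, rule) {
    cons[[length(cons) + 1L]] <<- data.frame(from = from, to = to,
                                             rule = rule)
  }
  # rearranged homologue copies per (chrom, homologue)
  chroms <- unique(unlist(lapply(evs, function(e) e@segments$chrom)))
  for (ch in chroms) {
    for (hom in c("A", "B")) {
      normals <- if (hom == "A") hk@normalA[[ch]] else hk@normalB[[ch]]
      carriers <- which(vapply(evs, function(e) {
        any(e@segments$chrom == ch & e@segments$homologue == hom)
      }, logical(1)))
      copies <- normals + length(carriers)
      if (copies >= 2 && length(carriers) == 1) {
        add(paste0("doubling(", ch, ".", hom, ")"),
            paste0("rearrangement(", labs[carriers], ")"),
            "rearranged copy of a duplicated homologue")
      }
    }
  }
  # identical derivatives present in multiple copies: compare content (a
  # bare "+der(A;B)" copy shares segments but not clause text)
  contentKey <- vapply(evs, function(e) {
    paste(e@kind, paste(e@cenChroms, collapse = ";"),
          paste(e@segments$chrom, e@segments$start, e@segments$end,
                collapse = "|"))
  }, character(1))
  dupNames <- character(0)
  for (ky in unique(contentKey[duplicated(contentKey)])) {
    lb <- labs[which(contentKey == ky)[1]]
    dupNames <- c(dupNames, lb)
    add(paste0("formation(", lb, ")"), paste0("duplication(", lb, ")"),
        "derivative present in identical copies")
  }
  if (!is.null(descents)) {
    for (child in names(descents)) {
      parent <- descents[[child]]
      if (parent %in% dupNames ||
          any(names(descents) != child & descents == parent)) {
        add(paste0("duplication(", parent, ")"),
            paste0("formation(", child, ")"), "descent from duplicated parent")
        add(paste0("formation(", parent, ")"),
            paste0("duplication(", parent, ")"),
            "derivative duplicated before remodelling")
      } else {
        add(paste0("formation(", parent, ")"),
            paste0("formation(", child, ")"), "descent")
      }
    }
  }
  constraints <- if (length(cons)) {
    unique(do.call(rbind, c(cons, list(make.row.names = FALSE))))
  } else {
    data.frame(from = character(0), to = character(0), rule = character(0))
  }
  # Kahn's algorithm for cycle detection / topological order
  nodes <- unique(c(constraints$from, constraints$to))
  order <- character(0)
  edges <- constraints[, c("from", "to")]
  while (length(nodes)) {
    free <- nodes[!nodes %in% edges$to]
    if (!length(free)) break
    order <- c(order, sort(free))
    nodes <- setdiff(nodes, free)
    edges <- edges[!edges$from %in% free, , drop = FALSE]
  }
  consistent <- !length(nodes)
  list(constraints = constraints, consistent = consistent,
       order = if (consistent) order else NULL)
}
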