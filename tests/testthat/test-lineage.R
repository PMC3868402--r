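test_that("parsimony scoring handles constant and irreversible characters", {
  taxa <- c("a", "b", "c", "d")
  same <- characterMatrix(
    matrix(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L), 3, 4,
           byrow = TRUE, dimnames = list(c("x", "y", "z"), taxa)),
    c("CNA", "CNA", "CNA"), taxa)
  anyTree <- list(list("a", "b"), list("c", "d"))
  # an all-shared character costs one change on the stem, an all-absent
  # character nothing, and a private character one change on its leaf edge
  expect_identical(parsimonyScore(anyTree, same), 2)

  irr <- characterMatrix(
    matrix(c(1L, 1L, 0L, 0L), 1, 4, dimnames = list("loh", taxa)),
    "LOH", taxa)
  grouped <- list(list("a", "b"), list("c", "d"))
  interleaved <- list(list("a", "c"), list("b", "d"))
  expect_identical(parsimonyScore(grouped, irr), 1)
  # reversal forbidden: the interleaved tree needs two independent gains
  expect_identical(parsimonyScore(interleaved, irr), 2)
  # the same pattern as a reversible character can also be explained by
  # one gain plus one loss, but that is no cheaper
  rev <- characterMatrix(irr@states, "CNA", taxa)
  expect_identical(parsimonyScore(interleaved, rev), 2)

  expect_error(parsimonyScore(grouped,
                              characterMatrix(irr@states, "LOH",
                                              c("a", "b", "c", "e"))),
               "taxa")
})

test_that("tree enumeration is exhaustive and non-redundant", {
  t3 <- enumerateRootedTrees(c("a", "b", "c"))
  expect_length(t3, 3)
  t4 <- enumerateRootedTrees(c("a", "b", "c", "d"))
  expect_length(t4, 15)
  expect_length(unique(vapply(t4, treeKey, character(1))), 15)
  expect_identical(sort(vapply(t4, treeKey, character(1))),
                   sort(vapply(oracleTopologies(c("a", "b", "c", "d")),
                               treeKey, character(1))))
  expect_error(enumerateRootedTrees(letters[1:9]), "8 taxa")
})

test_that("minimizer sets match the exhaustive labeling oracle", {
  taxa <- c("a", "b", "c", "d")
  set.seed(17)
  for (rep in 1:12) {
    st <- matrix(sample(c(0L, 1L, NA), 5 * 4, replace = TRUE,
                        prob = c(0.45, 0.45, 0.1)), 5, 4,
                 dimnames = list(paste0("k", 1:5), taxa))
    if (!any(apply(st, 1, function(r) length(unique(na.omit(r))) > 1))) next
    cls <- sample(c("CNA", "LOH"), 5, replace = TRUE)
    cm <- characterMatrix(st, cls, taxa)
    trees <- oracleTopologies(taxa)
    oscores <- vapply(trees, oracleParsimony, numeric(1), cm = cm)
    omin <- trees[oscores == min(oscores)]
    bt <- bestTree(cm)
    expect_equal(bt[[1]]@score, min(oscores))
    expect_identical(sort(vapply(bt, function(t) treeKey(.asNestedTest(t)),
                                 character(1))),
                     sort(vapply(omin, treeKey, character(1))))
  }
})

test_that("CNA-only scores agree with phangorn Fitch parsimony", {
  skip_if_not_installed("phangorn")
  cm <- helSublineCharacters()
  cna <- characterMatrix(cm@states[cm@classes == "CNA", , drop = FALSE],
                         rep("CNA", sum(cm@classes == "CNA")), cm@taxa)
  nested <- list(list(list("VCCS", "ATCC"), "DSMZ"), "CGP")
  mine <- parsimonyScore(nested, cna)
  # independent route: attach the all-zero founding clone as an outgroup
  # leaf and run symmetric parsimony
  nwk <- "((((VCCS,ATCC),DSMZ),CGP),founder);"
  phy <- ape::read.tree(text = nwk)
  st <- rbind(t(cna@states), founder = 0L)
  st[is.na(st)] <- "?"
  dat <- phangorn::phyDat(st, type = "USER", levels = c("0", "1"),
                          ambiguity = "?")
  expect_equal(mine, phangorn::parsimony(phy, dat))
})

test_that("the subline matrix recovers the published evolutionary pathway", {
  cm <- helSublineCharacters()
  bt <- bestTree(cm)
  expect_length(bt, 1)
  clades <- treeClades(bt[[1]])
  # (ATCC, VCCS) are the closest pair and CGP diverges first
  expect_true(any(vapply(clades, identical, logical(1),
                         y = c("ATCC", "VCCS"))))
  expect_true(any(vapply(clades, identical, logical(1),
                         y = c("ATCC", "DSMZ", "VCCS"))))
  # no LOH character is ever reversed, and each changes at most once
  ch <- bt[[1]]@changes
  loh <- rownames(cm@states)[cm@classes == "LOH"]
  expect_identical(sum(ch$character %in% loh & ch$from == 1 & ch$to == 0), 0L)
  expect_true(all(table(ch$character[ch$character %in% loh]) <= 1))
})

test_that("identical rows tie all topologies and constants change nothing", {
  taxa <- c("a", "b", "c", "d")
  st <- matrix(rep(c(1L, 1L, 0L, 1L), 3), 3, 4, byrow = TRUE,
               dimnames = list(paste0("k", 1:3), taxa))
  cm <- characterMatrix(st, rep("CNA", 3), taxa)
  bt <- bestTree(cm)
  # adding a constant character leaves the minimizer set unchanged
  cm2 <- characterMatrix(rbind(st, konst = c(1L, 1L, 1L, 1L)),
                         rep("CNA", 4), taxa)
  bt2 <- bestTree(cm2)
  key <- function(x) sort(vapply(x, function(t) treeKey(.asNestedTest(t)),
                                 character(1)))
  expect_identical(key(bt), key(bt2))
  # taxon-order permutation leaves the minimum cost unchanged
  perm <- c(3, 1, 4, 2)
  cm3 <- characterMatrix(st[, perm], rep("CNA", 3), taxa[perm])
  expect_identical(bestTree(cm3)[[1]]@score, bt[[1]]@score)
})

test_that("duplication logic yields the expected event order", {
  # a chromosome 6-like case: the homologue is present twice, once intact
  # and once inside a der(6)t(3;6) - doubling must precede the
  # rearrangement
  m <- parseKaryotype("47,XX,+6,der(6)t(3;6)(p14.3;q21)", kmap)
  hk <- assignHomologues(m, kmap)
  # put one intact copy on the rearranged homologue A
  hk@normalA[["6"]] <- 1L
  hk@normalB[["6"]] <- hk@normalB[["6"]] - 1L
  eo <- eventOrderConstraints(hk, map = kmap)
  expect_true(eo$consistent)
  expect_true(any(eo$constraints$from == "doubling(6.A)" &
                    grepl("t\\(3;6\\)", eo$constraints$to)))

  # a derivative present in two identical copies forms before it duplicates
  m2 <- parseKaryotype("47,XX,der(10;19)(p10;q10),+der(10;19)", kmap)
  hk2 <- assignHomologues(m2, kmap)
  eo2 <- eventOrderConstraints(hk2, map = kmap)
  expect_true(any(grepl("^formation", eo2$constraints$from) &
                    grepl("^duplication", eo2$constraints$to)))

  # declared descent from a duplicated parent: formation < duplication <
  # remodelling
  eo3 <- eventOrderConstraints(
    hk2, descents = c("der(4;20)" = "der(10;19)(p10;q10)"), map = kmap)
  expect_true(eo3$consistent)
  expect_true(any(eo3$constraints$from ==
                    "duplication(der(10;19)(p10;q10))" &
                    eo3$constraints$to == "formation(der(4;20))"))
  expect_identical(eo3$order[1], "formation(der(10;19)(p10;q10))")

  # a single-copy unrearranged homologue yields no constraints
  m3 <- parseKaryotype("46,XY", kmap)
  hk3 <- assignHomologues(m3, kmap)
  eo4 <- eventOrderConstraints(hk3, map = kmap)
  expect_identical(nrow(eo4$constraints), 0L)
})
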