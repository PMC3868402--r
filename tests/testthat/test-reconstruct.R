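test_that("a homogeneous noise-free region yields zero changepoints", {
  hk <- assignHomologues(parseKaryotype("46,XX", kmap), kmap)
  g <- probeGrid(kmap, chroms = "21", d = 10)
  a <- simulateArray(hk, g, 0, 0, seed = 1, map = kmap)
  cp <- segmentBafLrr(a)
  expect_identical(cp[["21"]]$changepoints, integer(0))
  expect_false(cp[["21"]]$flagged)
})

test_that("noise-free piecewise input recovers its breakpoints exactly", {
  hk <- toyHk()
  g <- probeGrid(kmap, chroms = "5", d = 20)
  a <- simulateArray(hk, g, 0, 0, seed = 2, map = kmap)
  cp <- segmentBafLrr(a)[["5"]]$changepoints
  # one true junction on chromosome 5, at the der(1) breakpoint band edge
  truth <- bandCopyTable(hk, kmap, chroms = "5")
  jump <- which(diff(truth$nA + truth$nB) != 0)
  expect_length(cp, length(jump))
  expect_identical(cp, jump * 20L)  # exact probe position of the band edge
})

test_that("too few probes yields no changepoints and a flag", {
  hk <- toyHk()
  g <- probeGrid(kmap, chroms = "5", d = 20)
  a <- simulateArray(hk, g, 0, 0, seed = 2, map = kmap)
  a@probes <- a@probes[1:12, ]
  cp <- segmentBafLrr(a, minProbes = 10)
  expect_true(cp[["5"]]$flagged)
  expect_identical(cp[["5"]]$changepoints, integer(0))
})

test_that("a (1,1)|(2,1) junction is localized within ten probes", {
  # simulation study: sigma_baf = 0.03, sigma_lrr = 0.15, 200 probes per
  # side, 50 seeds; at least 90% of seeds localize within +/- 10 probes
  hk <- toyHk()
  g <- probeGrid(kmap, chroms = "5", d = 20)
  truth <- bandCopyTable(hk, kmap, chroms = "5")
  trueCp <- which(diff(truth$nA + truth$nB) != 0) * 20L
  hits <- 0L
  for (seed in 1:50) {
    a <- simulateArray(hk, g, 0.15, 0.03, seed = seed, map = kmap)
    cp <- segmentBafLrr(a)[["5"]]$changepoints
    if (length(cp) >= 1 && min(abs(cp - trueCp)) <= 10) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.9)
})

test_that("allele-specific calls follow the folded-BAF geometry", {
  expect_identical(callAllelicCn(0, 0), c(nA = 1L, nB = 1L))
  expect_identical(callAllelicCn(log2(3 / 2), 1 / 6), c(nA = 2L, nB = 1L))
  # LOH with two copies: folded BAF at its maximum
  expect_identical(callAllelicCn(0, 0.5), c(nA = 2L, nB = 0L))
  # homozygous deletion
  expect_identical(callAllelicCn(-5, 0.5), c(nA = 0L, nB = 0L))
  # the call total is capped
  expect_identical(sum(callAllelicCn(3, 0, maxTotal = 8)), 8L)
  # ties break toward the more balanced pair
  expect_identical(callAllelicCn(1, 0.25), c(nA = 3L, nB = 1L))
})

test_that("segment assignment agrees with exhaustive enumeration", {
  paints <- new("PaintObservation", panel = c("1", "2", "5", "7"),
                observations = list(
                  list(label = "der(1)", sources = c("1", "5"),
                       cenCounts = c(`1` = 1L, `5` = 0L), norCount = 0L,
                       mband = list(), ring = FALSE),
                  list(label = "der(2)", sources = c("2", "7"),
                       cenCounts = c(`2` = 1L, `7` = 0L), norCount = 0L,
                       mband = list(), ring = FALSE)))
  segs <- data.frame(
    id = paste0("s", 1:4),
    chrom = c("1", "5", "2", "7"),
    terminal = c(TRUE, TRUE, TRUE, TRUE),
    spansCen = c(TRUE, FALSE, TRUE, FALSE),
    span = c(10, 4, 8, 3))
  res <- assignSegments(segs, paints)
  expect_true(res$feasible)
  expect_identical(normalizeSolutions(res$solutions),
                   normalizeSolutions(oracleAssign(segs, paints)))
  expect_length(res$solutions, 1)

  # randomized instances up to 10 segments agree with the oracle
  set.seed(31)
  for (rep in 1:20) {
    nd <- sample(2:3, 1)
    chroms <- as.character(sample(1:22, nd * 2))
    obs <- lapply(seq_len(nd), function(d) {
      src <- chroms[(2 * d - 1):(2 * d)]
      list(label = paste0("der", d), sources = src,
           cenCounts = setNames(c(1L, 0L), src), norCount = 0L,
           mband = list(), ring = sample(c(FALSE, FALSE, TRUE), 1))
    })
    paints <- new("PaintObservation", panel = chroms, observations = obs)
    ns <- sample(4:10, 1)
    segs <- data.frame(
      id = sprintf("s%02d", seq_len(ns)),
      chrom = sample(chroms, ns, replace = TRUE),
      terminal = sample(c(TRUE, FALSE), ns, replace = TRUE),
      spansCen = sample(c(TRUE, FALSE), ns, replace = TRUE),
      span = sample(1:20, ns, replace = TRUE))
    res <- assignSegments(segs, paints)
    expect_identical(normalizeSolutions(res$solutions),
                     normalizeSolutions(oracleAssign(segs, paints)))
  }
})

test_that("an unsatisfiable paint set is reported with its missing source", {
  paints <- new("PaintObservation", panel = c("11", "15", "19", "20"),
                observations = list(
                  list(label = "der(19)", sources = c("11", "15", "19", "20"),
                       cenCounts = c(`19` = 1L), norCount = 0L,
                       mband = list(), ring = FALSE)))
  segs <- data.frame(id = c("a", "b", "c"), chrom = c("11", "19", "20"),
                     terminal = FALSE, spansCen = c(FALSE, TRUE, FALSE),
                     span = c(5, 2, 3))
  res <- assignSegments(segs, paints)
  expect_false(res$feasible)
  expect_match(res$diagnostics, "chromosome 15")
})

test_that("rings accept no terminal segments", {
  paints <- new("PaintObservation", panel = c("3", "20"),
                observations = list(
                  list(label = "r(20)", sources = "20",
                       cenCounts = c(`20` = 1L), norCount = 0L,
                       mband = list(), ring = TRUE)))
  segs <- data.frame(id = "t1", chrom = "20", terminal = TRUE,
                     spansCen = TRUE, span = 3)
  res <- assignSegments(segs, paints)
  expect_false(res$feasible)
})

test_that("noise-free recovery inverts the forward model exactly", {
  hk <- toyHk()
  g <- probeGrid(kmap, chroms = toyChroms, d = 20)
  r <- recover(hk, g, 0, 0, seed = 8, panel = toyChroms, map = kmap)
  expect_identical(r$bandAccuracy, 1)
  expect_identical(r$compositionAccuracy, 1)
  # copy-mass conservation in the noise-free limit: per chromosome, summed
  # called copies over probes equal the truth's band-copy mass
  truth <- bandCopyTable(hk, kmap, chroms = toyChroms)
  for (ch in toyChroms) {
    tt <- truth[truth$chrom == ch, ]
    cc <- r$called[r$called$chrom == ch, ]
    expect_equal(sum(cc$t * cc$probes) / 20, sum(tt$nA + tt$nB))
  }
})

test_that("recovery is deterministic and accurate under noise", {
  hk <- toyHk()
  g <- probeGrid(kmap, chroms = toyChroms, d = 50)
  r1 <- recover(hk, g, 0.15, 0.03, seed = 5, map = kmap)
  r2 <- recover(hk, g, 0.15, 0.03, seed = 5, map = kmap)
  expect_identical(r1$called, r2$called)
  expect_gte(r1$bandAccuracy, 0.95)
})
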