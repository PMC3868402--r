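helDic <- function() dicentricChromosome(kmap, "9", "p24.3", "22", "p12")

test_that("a bridge break partitions the dicentric between its centromeres", {
  dic <- helDic()
  cp <- centromerePositions(dic, kmap)
  expect_identical(nrow(cp), 2L)
  set.seed(77)
  for (i in 1:25) {
    br <- bridgeBreak(dic, map = kmap)
    expect_gt(br$pos, min(cp$pos))
    expect_lt(br$pos, max(cp$pos))
    lc <- centromerePositions(br$left, kmap)
    rc <- centromerePositions(br$right, kmap)
    expect_identical(sum(lc$active), 1L)
    expect_identical(sum(rc$active), 1L)
    expect_identical(br$left@ends, c("telomere", "broken"))
    expect_identical(br$right@ends, c("broken", "telomere"))
    # conservation: the two products partition the parent's content
    tot <- function(x) {
      b <- x@blocks
      aggregate(hi - lo ~ chrom, data = b, sum)
    }
    parent <- tot(dic)
    both <- rbind(br$left@blocks, br$right@blocks)
    for (ch in parent$chrom) {
      expect_equal(sum(both$hi[both$chrom == ch] - both$lo[both$chrom == ch]),
                   parent[parent$chrom == ch, 2])
    }
  }
  expect_error(bridgeBreak(normalChromosome(kmap, "9"), map = kmap),
               "dicentric")
})

test_that("break positions are uniform over the inter-centromeric span", {
  dic <- helDic()
  cp <- centromerePositions(dic, kmap)
  set.seed(123)
  pos <- replicate(2000, bridgeBreak(dic, map = kmap)$pos)
  u <- (pos - min(cp$pos)) / diff(range(cp$pos))
  counts <- table(cut(u, breaks = seq(0, 1, by = 0.1)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("sister fusion mirrors the broken product into a palindrome", {
  dic <- helDic()
  br <- bridgeBreak(dic, pos = 35, map = kmap)
  fu <- sisterFusion(br$left)
  b <- fu@blocks
  n <- nrow(b)
  expect_identical(n, 2L * nrow(br$left@blocks))
  expect_identical(b$chrom, rev(b$chrom))
  expect_equal(b$lo, rev(b$lo))
  expect_equal(b$hi, rev(b$hi))
  expect_identical(b$orient, -rev(b$orient))
  expect_equal(attr(fu, "junction"), derivLength(br$left))
  # a monocentric input yields a new dicentric
  expect_identical(sum(fu@cens$active), 2L)
  expect_error(sisterFusion(dic), "broken end")
  # explicit mirror example: blocks [a+, b+] broken after b
  x <- new("LinearChromosome",
           blocks = rbind(.mk <- data.frame(chrom = "9", lo = 0, hi = 10,
                                            orient = 1L),
                          data.frame(chrom = "9", lo = 20, hi = 25,
                                     orient = 1L)),
           cens = data.frame(block = 1L, chrom = "9", active = TRUE),
           ends = c("telomere", "broken"), ring = FALSE)
  m <- sisterFusion(x)
  expect_identical(m@blocks$orient, c(1L, 1L, -1L, -1L))
  expect_equal(m@blocks$lo, c(0, 20, 20, 0))
})

test_that("zero cycles with no stabilization returns the input unchanged", {
  dic <- helDic()
  h <- runBfb(dic, cycles = 0, stabilization = "none", seed = 9, map = kmap)
  expect_identical(h@final, dic)
  expect_length(h@events, 0)
})

test_that("BFB histories replay to identical structures", {
  dic <- helDic()
  for (seed in c(3, 14, 159)) {
    h <- runBfb(dic, cycles = 4, stabilization = "none", seed = seed,
                map = kmap)
    expect_identical(replayHistory(h, map = kmap), h@final)
  }
})

test_that("copy-number profiles match a unit-position counting oracle", {
  dic <- helDic()
  for (seed in c(2, 21)) {
    h <- runBfb(dic, cycles = 3, stabilization = "none", seed = seed,
                map = kmap)
    prof <- cnProfile(h@final, kmap, chroms = c("9", "22"))
    for (ch in c("9", "22")) {
      got <- prof$count[prof$chrom == ch]
      want <- oracleProfile(h@final, kmap, ch, perBand = 400)
      expect_equal(got, want, tolerance = 0.02)
    }
  }
  # two normal homologues: every band at exactly 2
  two <- list(normalChromosome(kmap, "7"), normalChromosome(kmap, "7"))
  p7 <- cnProfile(two, kmap)
  expect_true(all(p7$count == 2))
})

test_that("amplification stays confined between the founding centromeres", {
  dic <- helDic()
  founding <- list(list(chrom = "9", arm = "p"), list(chrom = "22", arm = "p"))
  P9 <- sum(leafBands(kmap, "9")$arm == "p")
  P22 <- sum(leafBands(kmap, "22")$arm == "p")
  for (seed in 1:40) {
    cycles <- 1 + seed %% 6
    h <- runBfb(dic, cycles = cycles, stabilization = "none",
                seed = seed, map = kmap)
    prof <- cnProfile(h@final, kmap, chroms = c("9", "22"))
    # the q-arm tails (outside the centromeres) are carried whole: their
    # counts are constant, and any count above them is on the fused arms
    q9 <- prof$count[prof$chrom == "9" & prof$idx > P9]
    q22 <- prof$count[prof$chrom == "22" & prof$idx > P22]
    expect_true(length(unique(q9)) <= 1)
    expect_true(length(unique(q22)) <= 1)
    # the unimodal staircase is a few-cycle signature; confinement holds
    # for every history
    expect_true(bfbConsistent(prof, founding, kmap,
                              checkStaircase = cycles <= 3))
  }
})

test_that("profiles violating the between-centromere rule are rejected", {
  founding <- list(list(chrom = "9", arm = "p"), list(chrom = "22", arm = "p"))
  dic <- helDic()
  h <- runBfb(dic, cycles = 2, stabilization = "none", seed = 6, map = kmap)
  prof <- cnProfile(h@final, kmap)
  bad <- prof
  # plant amplification distal to the chromosome 9 centromere (on 9q)
  bad$count[bad$chrom == "9" & bad$idx == max(bad$idx[bad$chrom == "9"])] <-
    bad$count[bad$chrom == "9" & bad$idx == max(bad$idx[bad$chrom == "9"])] + 5
  res <- bfbConsistent(bad, founding, kmap)
  expect_false(res)
  expect_match(paste(attr(res, "diagnostics"), collapse = " "), "distal|constant")
})

test_that("a der(9)-like elevated-9p profile is BFB-consistent", {
  lb9 <- leafBands(kmap, "9")
  prof <- data.frame(chrom = "9", band = lb9$band, idx = seq_len(nrow(lb9)),
                     count = 1)
  # amplification of 9p24.3->9p21.2, stepping up toward the fusion side
  sp <- range(which(lb9$band %in% c("p24.3", "p21.2")))
  prof$count[prof$idx <= sp[2]] <- 2
  prof$count[prof$idx <= 3] <- 4
  expect_true(bfbConsistent(prof, list(list(chrom = "9", arm = "p")), kmap))
})

test_that("the dic(9;22) replay yields the pseudodicentric architecture", {
  sc <- system.file("extdata", "scenario_psu_dic_22_9.json",
                    package = "karyorecon")
  h <- replayScenario(sc, kmap)
  f <- h@final
  # both a chromosome 9 and a chromosome 22 centromere site, one inactive
  expect_setequal(f@cens$chrom, c("9", "22"))
  expect_identical(sum(f@cens$active), 1L)
  expect_identical(f@cens$chrom[!f@cens$active], "9")
  expect_identical(f@ends, c("telomere", "telomere"))
  P9 <- sum(leafBands(kmap, "9")$arm == "p")
  P22 <- sum(leafBands(kmap, "22")$arm == "p")
  # multiple 9p- and 22p-derived blocks
  expect_gte(sum(f@blocks$chrom == "9" & f@blocks$lo < P9), 2)
  expect_gte(sum(f@blocks$chrom == "22" & f@blocks$lo < P22), 2)
  prof <- cnProfile(f, kmap)
  # amplification on 9p and 22p only; single-copy q arms
  expect_gt(max(prof$count[prof$chrom == "9" & prof$idx <= P9]), 1)
  expect_gt(max(prof$count[prof$chrom == "22" & prof$idx <= P22]), 1)
  expect_true(all(prof$count[prof$chrom == "9" & prof$idx > P9] == 1))
  expect_true(all(prof$count[prof$chrom == "22" & prof$idx > P22] == 1))
  # every 9p band with content is at least as amplified as every 9q band
  expect_true(min(prof$count[prof$chrom == "9" & prof$idx <= 1]) >
                max(prof$count[prof$chrom == "9" & prof$idx > P9]))
})

test_that("ring excision releases a centromere-bearing pericentromeric ring", {
  sc <- system.file("extdata", "scenario_ring20_excision.json",
                    package = "karyorecon")
  h <- replayScenario(sc, kmap)
  ring <- h@final
  expect_true(ring@ring)
  expect_identical(ring@ends, c("none", "none"))
  expect_identical(sum(ring@cens$active), 1L)
  # all content is chromosome 20 pericentromeric material
  # (20p11.1-20q11.21), with no telomeric bands
  lb20 <- leafBands(kmap, "20")
  lo <- min(which(lb20$band == "p11.1")) - 1
  hi <- max(which(lb20$band == "q11.21"))
  expect_true(all(ring@blocks$chrom == "20"))
  expect_true(all(ring@blocks$lo >= lo & ring@blocks$hi <= hi))
  # the two acentric remnants are retained
  expect_gte(length(h@products), 2)
  # random ring excision from a seeded run also yields a 1-centromere ring
  h2 <- runBfb(helDic(), cycles = 2, stabilization = "ring_excision",
               seed = 42, map = kmap)
  expect_true(h2@final@ring)
  expect_identical(sum(h2@final@cens$active), 1L)
})

test_that("capture stabilization caps a broken end with donor material", {
  dic <- helDic()
  # acentric 18q telomeric tail as telomere donor
  telDonor <- terminalFragment(kmap, "18", "q12.1")
  h <- runBfb(dic, cycles = 2, stabilization = "telomere_capture",
              seed = 13, donor = telDonor, map = kmap)
  f <- h@final
  expect_identical(f@ends, c("telomere", "telomere"))
  expect_true("18" %in% f@blocks$chrom)
  # centromere-bearing donor fragment, then inactivation of the resident 9
  cenDonor <- terminalFragment(kmap, "18", "p11.22")
  h2 <- runBfb(dic, cycles = 2, stabilization = "centromere_capture",
               seed = 13, donor = cenDonor, inactivate = "9", map = kmap)
  expect_true("18" %in% h2@final@cens$chrom)
  expect_true(any(!h2@final@cens$active))
  expect_error(runBfb(dic, cycles = 1, stabilization = "telomere_capture",
                      seed = 1, map = kmap), "donor")
})
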