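test_that("the full HEL karyotype parses with every token consumed", {
  m <- helModel()
  sc <- structuredChromosomes(m)
  expect_length(sc, 21)
  expect_identical(m@countRange, c(56, 62))
  expect_identical(m@ploidy, 3L)
  expect_identical(m@sex, "X")
  # every structured event carries its clone frequency
  expect_true(all(!is.na(vapply(sc, function(e) e@freq, integer(1)))))
  # five abnormal chromosomes carry chromosome 20 material
  expect_length(chromCarriers(m, "20", kmap), 5)
  # of which three carry the chromosome 20 centromere
  expect_length(centromereCarriers(m, "20", kmap), 3)
})

test_that("malformed and unsupported constructs raise positioned errors", {
  expect_error(parseKaryotype("46,XY,inv(3)(p21q26)", kmap), "unsupported")
  expect_error(parseKaryotype("46,XY,der(1)t(1;15)(p36.3)", kmap), "arity")
  expect_error(parseKaryotype("46,XY,der(1)t(1;15)(p99;q22)", kmap), "p99")
  expect_error(parseKaryotype("46,XY,-33", kmap), "unknown chromosome")
  expect_error(parseKaryotype("XY,46", kmap), "count")
})

test_that("normal male karyotype yields a diploid baseline and no events", {
  m <- parseKaryotype("46,XY", kmap)
  expect_identical(m@ploidy, 2L)
  expect_length(m@events, 0)
  expect_identical(normalCount(m, "1"), 2L)
  expect_identical(normalCount(m, "X"), 1L)
  expect_identical(renderKaryotype(m), "46,XY")
})

test_that("short-form derivatives expand by ISCN derivative semantics", {
  e1 <- expandShortForm("der(1)t(1;15)(p36.3;q22.31)", kmap)
  expect_identical(paste(e1$chrom, e1$start, e1$end),
                   c("15 qter q22.31", "1 p36.3 qter"))
  e2 <- expandShortForm("der(5;17)(p10;q10)", kmap)
  expect_identical(paste(e2$chrom, e2$start, e2$end),
                   c("5 pter p10", "17 q10 qter"))
  e3 <- expandShortForm("der(10)t(10;18)(p12.1;q11.2)", kmap)
  expect_identical(paste(e3$chrom, e3$start, e3$end),
                   c("18 qter q11.2", "10 p12.1 qter"))
  # the derivative keeps the chromosome 10 centromere
  hit <- vapply(seq_len(nrow(e3)), function(i) {
    e3$chrom[i] == "10" && spansCentromere(kmap, "10", e3$start[i], e3$end[i])
  }, logical(1))
  expect_true(any(hit))
  # sequential t() clauses apply left to right
  e4 <- expandShortForm("der(10)t(10;18)(p12;q11.2)t(2;10)(q22;q24)", kmap)
  expect_identical(paste(e4$chrom, e4$start, e4$end),
                   c("18 qter q11.2", "10 p12 q24", "2 q22 qter"))
})

test_that("three-way translocation expands to the printed detailed form", {
  short <- expandShortForm("der(8)t(4;8;13)(q32.1;p12q22.1;q21.31)", kmap)
  detailed <- expandShortForm(
    "der(8)(4qter->4q32.1::8p12->8q22.1::13q21.31->13qter)", kmap)
  expect_identical(short[, c("chrom", "start", "end", "lo", "hi")],
                   detailed[, c("chrom", "start", "end", "lo", "hi")])
})

test_that("normal-homologue bookkeeping matches a hand count", {
  m <- helModel()
  # baseline 3 with one "-11": two normal 11s
  expect_identical(normalCount(m, "11"), 2L)
  # baseline 3 with one "-7"
  expect_identical(normalCount(m, "7"), 2L)
  # chromosome 9: "-9" plus der(9) and psu dic(22;9) consume all three
  expect_identical(normalCount(m, "9"), 0L)
  # chromosome 18: der(3;18) and der(18) consume two; the third homologue
  # is a ring (or lost) in the subclones - no normal 18 remains
  expect_identical(normalCount(m, "18"), 0L)
  expect_identical(normalCount(m, "20"), 1L)
  expect_true(all(vapply(as.character(1:22), function(ch) {
    normalCount(m, ch) >= 0
  }, logical(1))))
})

test_that("the detailed der(20) survives a render round trip unchanged", {
  m <- helModel()
  d20 <- Filter(function(e) e@label == "der(20)",
                structuredChromosomes(m))[[1]]
  m2 <- parseKaryotype(renderKaryotype(m), kmap)
  d20b <- Filter(function(e) e@label == "der(20)",
                 structuredChromosomes(m2))[[1]]
  expect_identical(d20@segments, d20b@segments)
  expect_identical(paste(d20@segments$chrom, d20@segments$start,
                         d20@segments$end),
                   c("15 qter q11.2", "20 q10 q11.1", "20 q13.33 q13.33",
                     "11 q23.2 qter"))
})

test_that("render-then-parse is a fixed point on the bundled corpus", {
  strings <- c(helKaryotype(), "46,XY", "46,XX",
               randomKaryotypes(200, 20260101, kmap))
  for (s in strings) {
    m <- parseKaryotype(s, kmap)
    r1 <- renderKaryotype(m)
    m2 <- parseKaryotype(r1, kmap)
    expect_identical(renderKaryotype(m2), r1)
    expect_true(sameKaryotype(m, m2))
  }
})

test_that("uncertain band tokens resolve to their widest consistent span", {
  m <- helModel()
  d9 <- Filter(function(e) e@label == "der(9)", structuredChromosomes(m))[[1]]
  s19 <- d9@segments[d9@segments$chrom == "19", ]
  expect_true(s19$uncertain)
  expect_identical(c(s19$lo, s19$hi), c(bandSpan(kmap, "19", "p13")))
  s22 <- d9@segments[d9@segments$chrom == "22", ]
  expect_true(s22$uncertain)
  # p11~2 -> p12~3 covers the p13..p11.1 leaf range at its widest
  expect_identical(c(s22$lo, s22$hi),
                   c(bandIndex(kmap, "22", "p13"),
                     bandSpan(kmap, "22", "p11")[2]))
})
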