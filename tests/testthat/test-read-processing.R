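ADAPTER <- "TGGAATTCTCGGGTGCCAAGGAACTCCAGT"

test_that("adapter trimming enforces the clean length window", {
  mk <- function(insert) paste0(insert, ADAPTER)
  set.seed(5)
  r17 <- mk(randDna(17)); r18 <- mk(randDna(18))
  r22 <- mk(randDna(22)); r30 <- mk(randDna(30)); r31 <- mk(randDna(31))
  out <- trimAndFilter(c(r17, r18, r22, r30, r31, ADAPTER), ADAPTER)
  expect_identical(unname(out$stats), c(6L, 3L))
  expect_identical(nchar(out$clean), c(18L, 22L, 30L))
  expect_identical(out$clean[2], substr(r22, 1, 22))
})

test_that("reads with no adapter hit are kept only when already in-window", {
  set.seed(6)
  short <- randDna(21)              # no adapter, 21 nt -> kept as-is
  long <- randDna(45)               # no adapter, 45 nt -> discarded
  out <- trimAndFilter(c(short, long), ADAPTER)
  expect_identical(out$clean, short)
})

test_that("inserts containing N are discarded", {
  withN <- paste0("ACGTN", randDna(17), ADAPTER)
  out <- trimAndFilter(withN, ADAPTER)
  expect_identical(unname(out$stats), c(1L, 0L))
})

test_that("malformed FASTQ is rejected with a line number", {
  p <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "r2-bad-header", "ACGT", "+", "IIII"), p)
  expect_error(readFastqSeqs(p), "line 5")
  writeLines(c("@r1", "ACGT", "+", "III"), p)   # quality too short
  expect_error(readFastqSeqs(p), "line 1.*length mismatch")
  writeLines(c("@r1", "ACGT", "+"), p)
  expect_error(readFastqSeqs(p), "multiple of 4")
})

test_that("tag collapsing is exact, symmetric and order-independent", {
  cs <- c(rep("AAACCCGGGTTTAAACCCGG", 3))
  empty <- character(0)
  t1 <- collapseTags(cs, empty)
  expect_identical(unname(tagCounts(t1)[1, ]), c(3L, 0L))

  set.seed(9)
  pool <- vapply(1:8, function(i) randDna(sample(18:30, 1)), character(1))
  a <- sample(pool, 200, replace = TRUE)
  b <- sample(pool, 150, replace = TRUE)
  tAB <- collapseTags(a, b)
  tBA <- collapseTags(b, a)
  expect_identical(tagCounts(tAB)[, "CS"], tagCounts(tBA)[, "TS"])
  expect_identical(tagCounts(tAB)[, "TS"], tagCounts(tBA)[, "CS"])
  tShuf <- collapseTags(sample(a), sample(b))
  expect_identical(tagCounts(tAB), tagCounts(tShuf))
  expect_identical(tagSequences(tAB), tagSequences(tShuf))
})

test_that("collapse then re-expand is a multiset identity on clean reads", {
  set.seed(10)
  pool <- vapply(1:12, function(i) randDna(sample(18:30, 1)), character(1))
  cs <- sample(pool, 300, replace = TRUE)
  ts <- sample(pool, 250, replace = TRUE)
  tg <- collapseTags(cs, ts)
  reCS <- rep(tagSequences(tg), tagCounts(tg)[, "CS"])
  reTS <- rep(tagSequences(tg), tagCounts(tg)[, "TS"])
  expect_identical(sort(reCS), sort(cs))
  expect_identical(sort(reTS), sort(ts))
})

test_that("length distribution histograms are exact and normalised", {
  tg <- collapseTags(rep(randDna(21), 10), character(0))
  ld <- lengthDistribution(tg)
  expect_identical(ld$length, 21L)
  expect_identical(ld$redundantCS, 10L)
  expect_identical(ld$uniqueCS, 1L)

  res <- defaultRun()
  ld <- lengthDistribution(res$tags)
  expect_lte(abs(sum(ld$pctRedundantCS) - 100), 0.05)
  expect_lte(abs(sum(ld$pctRedundantTS) - 100), 0.05)
  # the generator plants a 24-nt-dominant insert mix
  expect_identical(ld$length[which.max(ld$redundantCS)], 24L)
  expect_identical(ld$length[which.max(ld$redundantTS)], 24L)
})

test_that("simulated library tag counts equal the generator's oracle table", {
  res <- defaultRun()
  exp <- read.delim(file.path(defaultRunDir(), "expected_counts.tsv"),
                    comment.char = "#", stringsAsFactors = FALSE)
  got <- data.frame(sequence = tagSequences(res$tags),
                    countCS = tagCounts(res$tags)[, "CS"],
                    countTS = tagCounts(res$tags)[, "TS"],
                    stringsAsFactors = FALSE)
  got <- got[order(got$sequence), ]
  rownames(got) <- rownames(exp) <- NULL
  expect_identical(got$sequence, exp$sequence)
  expect_identical(as.integer(got$countCS), as.integer(exp$countCS))
  expect_identical(as.integer(got$countTS), as.integer(exp$countTS))
})
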