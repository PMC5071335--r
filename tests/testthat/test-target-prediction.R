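# Independent positional oracle for ungapped duplexes: miRNA position i
# pairs the window base at position L - i + 1; penalties 1 / 0.5 / 0 for
# mismatch / G:U / Watson-Crick, doubled at positions 2-13.
ungappedScore <- function(mirna, window) {
  m <- strsplit(mirna, "")[[1]]
  w <- strsplit(window, "")[[1]]
  L <- length(m)
  s <- 0
  for (i in seq_len(L)) {
    t <- w[L - i + 1L]
    pen <- if (paste0(m[i], t) %in% c("AT", "TA", "GC", "CG")) 0
           else if (paste0(m[i], t) %in% c("GT", "TG")) 0.5
           else 1
    s <- s + pen * if (i >= 2 && i <= 13) 2 else 1
  }
  s
}

test_that("perfect complement scores zero", {
  set.seed(51)
  for (i in 1:10) {
    m <- randDna(21)
    sc <- scoreSite(m, revComp(m))
    expect_identical(sc$S, 0)
    expect_identical(sc$nMismatch, 0L)
    expect_identical(sc$nGap, 0L)
  }
})

test_that("G:U wobble costs 0.5 and is doubled in the core", {
  m <- strrep("A", 21)
  site <- revComp(m)
  # wobble at miRNA position 1 (outside core): T:G pair via G at window end
  v <- strsplit(site, "")[[1]]
  m1 <- paste0("T", strrep("A", 20))
  v[21] <- "G"
  sc <- scoreSite(m1, paste(v, collapse = ""))
  expect_identical(sc$S, 0.5)
  expect_identical(sc$nGU, 1L)
  # same wobble at position 5 (core) doubles to 1.0
  m5 <- paste0(strrep("A", 4), "T", strrep("A", 16))
  v <- strsplit(site, "")[[1]]
  v[21 - 5 + 1] <- "G"
  sc <- scoreSite(m5, paste(v, collapse = ""))
  expect_identical(sc$S, 1)
})

test_that("a single gap costs 2 (4 in the core) and two gaps are impossible", {
  set.seed(52)
  m <- randDna(21)
  site <- revComp(m)
  # deleting a core window base forces a gap opposite a core miRNA position
  gapSite <- paste0(substr(site, 1, 10), substr(site, 12, 21))
  sc <- scoreSite(m, gapSite)
  expect_identical(sc$nGap, 1L)
  expect_gte(sc$S, 2)
  expect_error(scoreSite(m, substr(site, 1, 19)), "single gap")
})

test_that("scoring equals the exhaustive positional oracle on random pairs", {
  set.seed(53)
  for (i in 1:200) {
    m <- randDna(21)
    w <- randDna(21)
    expect_equal(scoreSite(m, w)$S, ungappedScore(m, w))
  }
})

test_that("positional rules reject cleavage-site and core violations", {
  set.seed(54)
  m <- randDna(21)
  perfect <- scoreSite(m, revComp(m))
  expect_true(schwabFilter(perfect))
  # target base guaranteed to mismatch the given miRNA base: neither its
  # Watson-Crick complement nor a G:U partner
  clash <- c(A = "C", C = "A", G = "A", T = "C")
  mismAt <- function(pos) {
    v <- strsplit(revComp(m), "")[[1]]
    v[21 - pos + 1] <- clash[[substr(m, pos, pos)]]
    scoreSite(m, paste(v, collapse = ""))
  }
  expect_false(schwabFilter(mismAt(10)))   # cleavage site
  expect_false(schwabFilter(mismAt(11)))
  oneCore <- mismAt(4)
  expect_true(schwabFilter(oneCore))       # one core mismatch allowed
  # more than two consecutive mismatches are rejected
  v <- strsplit(revComp(m), "")[[1]]
  for (pos in 15:17) v[21 - pos + 1] <- clash[[substr(m, pos, pos)]]
  run3 <- scoreSite(m, paste(v, collapse = ""))
  expect_false(schwabFilter(run3))
})

test_that("transcript scanning finds planted sites with exact cleavage coords", {
  set.seed(55)
  m <- randDna(21)
  site <- revComp(m)
  tx <- paste0(randDna(100), site, randDna(100))
  hits <- scanTargets(c(mirX = m), c(geneA = tx), allenMaxS = 4)
  pl <- hits[hits$S == 0, ]
  expect_identical(nrow(pl), 1L)
  expect_identical(pl$start, 100L)          # 0-based
  expect_true(pl$predicted)
  # cleavage position: transcript base paired to miRNA position 10
  expect_identical(pl$cleavagePos, 100L + 21L - 9L)
  # that base really pairs miRNA position 10
  expect_identical(substr(tx, pl$cleavagePos, pl$cleavagePos),
                   revComp(substr(m, 10, 10)))
})

test_that("cleavage validation needs a concentrated clone pileup", {
  site <- data.frame(cleavagePos = 101)
  conc <- mapCleavage(c(`101` = 7, `95` = 2, `103` = 1), site)
  expect_true(conc$validated)
  expect_equal(conc$canonicalFraction, 0.7)
  unif <- mapCleavage(setNames(rep(1, 10), as.character(96:105)), site)
  expect_false(unif$validated)
  few <- mapCleavage(c(`101` = 5), site)    # fraction 1 but < 10 clones
  expect_false(few$validated)
  expect_error(mapCleavage(integer(0), site), "at least one clone")
})

test_that("duplex rendering shows bars for pairs and circles for wobbles", {
  m <- paste0("T", strrep("A", 20))
  v <- strsplit(revComp(m), "")[[1]]
  v[21] <- "G"                               # wobble opposite position 1
  sc <- scoreSite(m, paste(v, collapse = ""))
  txt <- formatDuplex(sc)
  lines <- strsplit(txt, "\n")[[1]]
  expect_length(lines, 3)
  expect_match(lines[1], "^5' .* 3'")
  expect_match(lines[3], "^3' .* 5'")
  expect_identical(sum(strsplit(lines[2], "")[[1]] == "o"), 1L)
  expect_identical(sum(strsplit(lines[2], "")[[1]] == "|"), 20L)
})
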