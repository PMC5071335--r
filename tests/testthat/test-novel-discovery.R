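designedHairpin <- function(matureLen = 21, seed = 31) {
  set.seed(seed)
  mature <- randDna(matureLen)
  ext <- randDna(15)
  loop <- randDna(14)
  prec <- paste0(ext, mature, loop, revComp(mature), revComp(ext))
  list(mature = mature, precursor = prec,
       matureStart = nchar(ext) + 1L,
       matureEnd = nchar(ext) + matureLen)
}

test_that("a designed perfect hairpin passes the annotation criteria", {
  hp <- designedHairpin()
  f <- foldRNA(hp$precursor)
  ev <- evaluateHairpin(hp$precursor, f$structure, f$mfe,
                        hp$matureStart, hp$matureEnd)
  expect_true(ev$passes)
  expect_identical(ev$arm, "5p")
  expect_lte(ev$mfe, -18)
  expect_gte(ev$nPaired, 16)
  expect_lte(ev$nMismatch, 4)
  # inferred star: mature-sized window from the opposite arm of the stem
  expect_true(grepl(ev$star, hp$precursor, fixed = TRUE))
  expect_lte(abs(nchar(ev$star) - nchar(hp$mature)), 4)
})

test_that("a mature spanning the terminal loop is rejected", {
  hp <- designedHairpin()
  f <- foldRNA(hp$precursor)
  mid <- nchar(hp$precursor) %/% 2
  ev <- evaluateHairpin(hp$precursor, f$structure, f$mfe, mid - 10, mid + 10)
  expect_false(ev$passes)
  expect_true(ev$loopOverlap)
})

test_that("each criterion can individually fail a hairpin", {
  hp <- designedHairpin()
  f <- foldRNA(hp$precursor)
  strict <- function(...) {
    a <- list(maxDuplexMismatches = 4L, maxAsymmetricBulge = 2L,
              minPairedMature = 16L, mfeThreshold = -18)
    a[names(list(...))] <- list(...)
    HairpinCriteria(maxDuplexMismatches = a$maxDuplexMismatches,
                    maxAsymmetricBulge = a$maxAsymmetricBulge,
                    minPairedMature = a$minPairedMature,
                    mfeThreshold = a$mfeThreshold)
  }
  ev <- function(cr) evaluateHairpin(hp$precursor, f$structure, f$mfe,
                                     hp$matureStart, hp$matureEnd, cr)
  expect_true(ev(strict())$passes)
  expect_false(ev(strict(mfeThreshold = -1000))$passes)
  expect_false(ev(strict(minPairedMature = 22L))$passes)
})

test_that("candidate selection applies category, hit-count and length filters", {
  set.seed(33)
  seqs <- c(a = randDna(22), b = randDna(22), c = randDna(22),
            d = randDna(19), e = randDna(25), f = randDna(22))
  tg <- makeTags(unname(seqs), rep(1, 6), rep(1, 6))
  rd <- SummarizedExperiment::rowData(tg)
  ord <- match(tagSequences(tg), unname(seqs))   # tags are stored sorted
  rd$category <- c(a = "unknown", b = "unknown", c = "known_miRNA",
                   d = "unknown", e = "unknown", f = "unknown")[ord]
  rd$nHits <- c(a = 10L, b = 11L, c = 1L, d = 1L, e = 1L, f = 0L)[ord]
  SummarizedExperiment::rowData(tg) <- rd
  kept <- tagSequences(selectCandidates(tg))
  expect_identical(sort(kept), sort(unname(seqs["a"])))
  # boundary: exactly maxGenomeHits retained, one more removed
  expect_true(seqs[["a"]] %in% kept)    # 10 hits
  expect_false(seqs[["b"]] %in% kept)   # 11 hits
  expect_false(seqs[["d"]] %in% kept)   # 19 nt, below candidate window
  expect_false(seqs[["e"]] %in% kept)   # 25 nt, above candidate window
  expect_false(seqs[["f"]] %in% kept)   # unmapped
})

test_that("excision folds windows on both strands with the tag kept 5'->3'", {
  hp <- designedHairpin(seed = 35)
  set.seed(36)
  chrPlus <- paste0(randDna(250), hp$precursor, randDna(250))
  chrMinus <- paste0(randDna(250), revComp(hp$precursor), randDna(250))
  genome <- Biostrings::DNAStringSet(c(chr1 = chrPlus, chr2 = chrMinus))
  hits <- mapGenome(hp$mature, genome)
  # the mature hits its own locus and, as the star arm is its perfect
  # reverse complement, the star locus on the opposite strand: 4 hits
  expect_identical(sort(hits$strand), sort(c("+", "+", "-", "-")))
  folds <- exciseAndFold(hp$mature, hits, genome)
  expect_gt(nrow(folds), 0)
  # every excised window contains the mature at the reported coordinates
  for (k in seq_len(nrow(folds)))
    expect_identical(substr(folds$precursor[k], folds$matureStart[k],
                            folds$matureEnd[k]), hp$mature)
  evs <- vapply(seq_len(nrow(folds)), function(k)
    evaluateHairpin(folds$precursor[k], folds$structure[k], folds$mfe[k],
                    folds$matureStart[k], folds$matureEnd[k])$passes,
    logical(1))
  # the hairpin is recoverable from at least one window on each strand
  expect_true(any(evs[folds$strand == "+"]))
  expect_true(any(evs[folds$strand == "-"]))
})

test_that("family clustering tolerates 2 substitutions but not 3", {
  set.seed(37)
  known <- randDna(21)
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    for (p in seq_len(k)) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
    paste(v, collapse = "")
  }
  novel <- data.frame(mature = c(known, mut(known, 2), mut(known, 3)),
                      precursor = c(randDna(80), randDna(80), randDna(80)),
                      stringsAsFactors = FALSE)
  out <- clusterFamilies(novel, c(famX = known))
  expect_identical(out$family, c("famX", "famX", "species_specific"))
})

test_that("first-nucleotide bias is read-weighted and stratified by length", {
  novel <- data.frame(mature = c("CAAAAAAAAAAAAAAAAAAAA", "TAAAAAAAAAAAAAAAAAAAA",
                                 "GAAAAAAAAAAAAAAAAAAAAA"),
                      length = c(21L, 21L, 22L),
                      countCS = c(30L, 10L, 60L),
                      countTS = c(3L, 1L, 6L),
                      stringsAsFactors = FALSE)
  b <- firstNucleotideBias(novel)
  all21 <- b[b$length == "21", ]
  expect_identical(all21$countCS[all21$base == "C"], 30L)
  expect_identical(all21$pctCS[all21$base == "C"], 75)
  expect_identical(all21$pctCS[all21$base == "U"], 25)
  allAll <- b[b$length == "all", ]
  expect_identical(allAll$countCS[allAll$base == "G"], 60L)
  expect_identical(sum(allAll$countCS), 100L)
})
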