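smallConfig <- function(seed = 1) {
  SrnaSimConfig(seed = seed, nMirnas = 4, nKnown = 2, nNcrnas = 3,
                nGenes = 6, chromosomeLength = 20000,
                depthCS = 4000, depthTS = 4000,
                foldChange = list(mir_1 = 4, mir_2 = 0.25))
}

test_that("reference generation is deterministic in the seed", {
  t1 <- simulateReference(smallConfig(seed = 5))
  t2 <- simulateReference(smallConfig(seed = 5))
  expect_identical(as.character(t1@genome), as.character(t2@genome))
  expect_identical(t1@mirnas, t2@mirnas)
  expect_identical(t1@goMap, t2@goMap)
  t3 <- simulateReference(smallConfig(seed = 6))
  expect_false(identical(as.character(t1@genome), as.character(t3@genome)))
})

test_that("planted hairpins genuinely satisfy the discovery criteria", {
  truth <- simulateReference(smallConfig())
  crit <- HairpinCriteria()
  for (i in seq_len(nrow(truth@mirnas))) {
    m <- truth@mirnas[i, ]
    f <- foldRNA(m$precursor)
    mS <- regexpr(m$mature, m$precursor, fixed = TRUE)
    ev <- evaluateHairpin(m$precursor, f$structure, f$mfe,
                          mS, mS + nchar(m$mature) - 1L, crit)
    expect_true(ev$passes)
    expect_lte(f$mfe, crit@mfeThreshold - 7)   # designed stability margin
  }
})

test_that("planted features really sit in the genome at their coordinates", {
  truth <- simulateReference(smallConfig())
  for (i in seq_len(nrow(truth@mirnas))) {
    m <- truth@mirnas[i, ]
    sub <- as.character(Biostrings::subseq(truth@genome[[m$chrom]],
                                           m$start, m$end))
    expect_identical(if (m$strand == "+") sub else revComp(sub), m$precursor)
  }
  for (i in seq_len(nrow(truth@ncrnas))) {
    n <- truth@ncrnas[i, ]
    expect_identical(as.character(Biostrings::subseq(truth@genome[[n$chrom]],
                                                     n$start, n$end)), n$seq)
  }
})

test_that("planted target sites are perfect complements within transcripts", {
  truth <- simulateReference(SrnaSimConfig(seed = 1))
  expect_gt(nrow(truth@targets), 0)
  for (i in seq_len(nrow(truth@targets))) {
    tgt <- truth@targets[i, ]
    mat <- truth@mirnas$mature[truth@mirnas$id == tgt$mirna]
    tx <- truth@transcripts[[tgt$gene]]
    expect_true(grepl(revComp(mat), tx, fixed = TRUE))
  }
  # target sites exist only for known responsive miRNAs
  respKnown <- intersect(trueResponsive(truth),
                         truth@mirnas$id[truth@mirnas$known])
  expect_true(all(truth@targets$mirna %in% respKnown))
})

test_that("written reference files round-trip through standard parsers", {
  truth <- simulateReference(smallConfig())
  dir <- tempfile("synthref")
  files <- writeSyntheticData(truth, dir)
  expect_true(all(file.exists(files)))
  g <- Biostrings::readDNAStringSet(files[["genome"]])
  expect_identical(as.character(g), setNames(as.character(truth@genome),
                                             names(truth@genome)))
  gr <- rtracklayer::import(files[["gff3"]], format = "gff3")
  expect_identical(sum(gr$type == "gene"), nrow(truth@genes))
  expect_identical(sum(gr$type == "exon"), nrow(truth@exons))
  mat <- Biostrings::readDNAStringSet(files[["mature"]])
  expect_identical(length(mat), sum(truth@mirnas$known))
})

test_that("library simulation respects depth, fold direction and the adapter", {
  cfg <- smallConfig()
  truth <- simulateReference(cfg)
  dir <- tempfile("synthlib")
  lib <- simulateLibraries(cfg, truth, dir)
  reads <- readFastqSeqs(lib$fastqCS)
  expect_identical(length(reads), 4000L)
  expect_true(all(nchar(reads) == 50))
  # most reads carry the adapter (noise fraction is 5%)
  withAd <- grepl(substr(cfg@adapter, 1, 10), reads, fixed = TRUE)
  expect_gt(mean(withAd), 0.90)
  # fold changes point the right way in the expectation table
  me <- lib$meanExpected
  up <- me[me$id == "mir_1", ]
  dn <- me[me$id == "mir_2", ]
  expect_gt(up$meanTS / up$meanCS, 2)
  expect_lt(dn$meanTS / dn$meanCS, 0.5)
})

test_that("config validation catches impossible settings", {
  expect_error(SrnaSimConfig(noiseFraction = 1.2))
  expect_error(SrnaSimConfig(foldChange = list(mir_1 = -2)))
  expect_error(SrnaSimConfig(nMirnas = 500, nKnown = 10,
                             chromosomeLength = 3000, nChromosomes = 1))
})
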