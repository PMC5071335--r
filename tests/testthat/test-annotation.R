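library(Biostrings)
library(GenomicRanges)

test_that("ncRNA matching assigns classes by exact substring, both strands", {
  tagA <- "ACCGGTTACCGGTTACCGGT"
  tagB <- "TTGGCCAATTGGCCAATTGG"
  ref <- DNAStringSet(c(
    `rRNA|nc1` = paste0("GGGG", tagA, "CCCC"),
    `tRNA|nc2` = paste0("AAAA", revComp(tagB), "TTTT")))
  tg <- makeTags(c(tagA, tagB, "ACGTACGTACGTACGTACGT"), c(1, 1, 1), c(0, 0, 0))
  got <- matchNcrna(tg, ref)
  expect_identical(got, c("rRNA", "tRNA", NA))
})

test_that("genome mapping reports every perfect hit with exact coordinates", {
  set.seed(21)
  tag <- randDna(22)
  chr <- paste0(randDna(100), tag, randDna(100), revComp(tag), randDna(100))
  genome <- DNAStringSet(c(chr1 = chr))
  hits <- mapGenome(tag, genome)
  expect_identical(nrow(hits), 2L)
  plus <- hits[hits$strand == "+", ]
  minus <- hits[hits$strand == "-", ]
  expect_identical(plus$start, 100L)         # 0-based
  expect_identical(plus$end, 122L)
  expect_identical(minus$start, 222L)
  expect_identical(minus$end, 244L)
  # the genome substring really equals the tag (reverse-complemented for -)
  expect_identical(substr(chr, plus$start + 1, plus$end), tag)
  expect_identical(revComp(substr(chr, minus$start + 1, minus$end)), tag)
})

test_that("known miRNA identification handles exact matches and shifted isomiRs", {
  set.seed(22)
  mature <- randDna(21)
  hairpin <- paste0(randDna(15), mature, randDna(40))
  iso <- substr(hairpin, 15, 15 + 21)   # 1 nt 5' shift, 22 nt long
  far <- substr(hairpin, 5, 26)         # shifted by > 2 nt
  tg <- makeTags(c(mature, iso, far), c(5, 3, 2), c(1, 0, 0))
  kn <- identifyKnown(tg, DNAStringSet(c(mirK = mature)),
                      DNAStringSet(c(mirK = hairpin)))
  expect_identical(kn$assign, c("mirK", "mirK", NA))
  expect_identical(kn$counts$countCS, 8)
  expect_identical(kn$counts$countTS, 1)
})

test_that("a mature absent from its hairpin is a reference error", {
  tg <- makeTags("ACGTACGTACGTACGTACGTA", 1, 1)
  expect_error(
    identifyKnown(tg, DNAStringSet(c(m = "ACGTACGTACGTACGTACGTA")),
                  DNAStringSet(c(m = strrep("G", 60)))),
    "reference inconsistency")
})

test_that("cascade priority: ncRNA beats known miRNA beats exon beats intron", {
  set.seed(23)
  mature <- randDna(21)
  hairpin <- paste0(randDna(20), mature, randDna(20))
  exonic <- randDna(21)
  intronic <- randDna(21)
  anti <- randDna(21)
  lost <- randDna(21)
  # layout (1-based): hairpin 51-111, exonic 162-182, intronic 233-253,
  # revComp(anti) 304-324, lost 375-395
  chr <- paste0(randDna(50), hairpin,
                randDna(50), exonic,
                randDna(50), intronic,
                randDna(50), revComp(anti),
                randDna(50), lost, randDna(50))
  genome <- DNAStringSet(c(chr1 = chr))
  # gene1: exons 152-193 and 254-263, intron 194-253 (covers intronic tag);
  # gene2: single exon 294-334 (covers the antisense tag region)
  gr <- GRanges("chr1",
                IRanges::IRanges(start = c(152, 152, 254, 294, 294),
                                 end = c(263, 193, 263, 334, 334)),
                strand = "+",
                type = c("gene", "exon", "exon", "gene", "exon"))
  tg <- makeTags(c(mature, exonic, intronic, anti, lost),
                 c(4, 3, 2, 2, 1), c(1, 1, 1, 1, 0))
  ann <- annotateTags(tg, DNAStringSet(), genome,
                      DNAStringSet(c(mirK = mature)),
                      DNAStringSet(c(mirK = hairpin)), gr)
  cats <- tagCategories(ann)
  names(cats) <- tagSequences(ann)
  expect_identical(unname(cats[mature]), "known_miRNA")
  expect_identical(unname(cats[exonic]), "exon_sense")
  expect_identical(unname(cats[intronic]), "intron_sense")
  expect_identical(unname(cats[anti]), "exon_antisense")
  expect_identical(unname(cats[lost]), "unknown")

  # the same mature listed in the ncRNA reference outranks known_miRNA
  ann2 <- annotateTags(tg, DNAStringSet(c(`rRNA|r1` = paste0("AA", mature, "TT"))),
                       genome, DNAStringSet(c(mirK = mature)),
                       DNAStringSet(c(mirK = hairpin)), gr)
  expect_identical(unname(tagCategories(ann2)[match(mature, tagSequences(ann2))]),
                   "rRNA")
})

test_that("annotation categories partition clean reads exactly", {
  res <- defaultRun()
  s <- annotationSummary(res$tags)
  st <- S4Vectors::metadata(res$tags)$stats
  expect_identical(sum(s$redundantCS), unname(st$CS[["clean"]]))
  expect_identical(sum(s$redundantTS), unname(st$TS[["clean"]]))
  expect_identical(sum(s$uniqueCS), sum(tagCounts(res$tags)[, "CS"] > 0))
  expect_identical(sum(s$uniqueTS), sum(tagCounts(res$tags)[, "TS"] > 0))
})
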