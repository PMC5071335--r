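#' Run the full small RNA analysis pipeline on a synthetic dataset
#'
#' Executes every stage in cascade order inside `dir`: reference generation
#' and library simulation, adapter trimming and tag collapsing, the
#' annotation cascade, novel miRNA discovery, differential expression with
#' responsive-miRNA screening, target prediction for the responsive miRNAs,
#' regulatory network construction, GO enrichment, and the summary report.
#' All outputs are plain-text tables; a rerun with identical inputs produces
#' byte-identical files.
#'
#' @param config a [SrnaSimConfig-class].
#' @param dir working/output directory.
#' @param criteria a [HairpinCriteria-class].
#' @param fcThreshold,pThreshold responsive screening thresholds.
#' @param allenMaxS target-prediction score cutoff.
#' @param engine folding engine, see [foldRNA()].
#' @return invisibly, a list with all in-memory stage results: `truth`,
#'   `tags`, `novel`, `diffexp`, `targets`, `network`, `enrichment`,
#'   `report`.
#' @export
runPipeline <- function(config, dir, criteria = HairpinCriteria(),
                        fcThreshold = 1.0, pThreshold = 0.05,
                        allenMaxS = 4.0, engine = "internal") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(dir, f)

  # 1. synthetic data
  truth <- simulateReference(config, criteria)
  writeSyntheticData(truth, dir)
  simulateLibraries(config, truth, dir)

  # 2. read processing
  for (f in c("reads_cs.fastq", "reads_ts.fastq", "genome.fa", "ncrna.fa",
              "mirna_mature.fa", "mirna_hairpin.fa", "genes.gff3"))
    if (!file.exists(pth(f)))
      stop("missing input for read processing: ", pth(f))
  tags <- processReads(pth("reads_cs.fastq"), pth("reads_ts.fastq"),
                       adapter = config@adapter)
  writeTags(tags, pth("tags.tsv"))

  # 3. annotation cascade
  genome <- Biostrings::readDNAStringSet(pth("genome.fa"))
  tags <- annotateTags(tags, pth("ncrna.fa"), genome,
                       pth("mirna_mature.fa"), pth("mirna_hairpin.fa"),
                       pth("genes.gff3"))
  writeTags(tags, pth("tags.tsv"))
  .writeTsv(annotationSummary(tags), pth("annotation_summary.tsv"))
  knownCounts <- S4Vectors::metadata(tags)$knownCounts
  .writeTsv(knownCounts, pth("known_mirna_counts.tsv"))

  # 4. novel discovery
  novel <- discoverNovel(tags, genome, criteria, engine)
  matureRef <- Biostrings::readDNAStringSet(pth("mirna_mature.fa"))
  hairpinRef <- Biostrings::readDNAStringSet(pth("mirna_hairpin.fa"))
  if (nrow(novel) > 0L) {
    novel <- clusterFamilies(novel,
                             setNames(as.character(matureRef), names(matureRef)),
                             setNames(as.character(hairpinRef), names(hairpinRef)))
  } else novel$family <- character(0)
  .writeTsv(novel[, setdiff(colnames(novel), c("structure"))],
            pth("novel_mirnas.tsv"),
            comments = sprintf(
              "criteria: duplex mismatches <= %d, asymmetric bulge <= %d, paired mature >= %d, MFE <= %.1f, star distance <= %d, genome hits <= %d",
              criteria@maxDuplexMismatches, criteria@maxAsymmetricBulge,
              criteria@minPairedMature, criteria@mfeThreshold,
              criteria@maxStarDistance, criteria@maxGenomeHits))
  if (nrow(novel) > 0L) {
    .writeFasta(novel$precursor, novel$id, pth("hairpins.fa"))
    writeLines(as.vector(rbind(paste0(">", novel$id), novel$structure)),
               pth("hairpins.dotbracket"))
  }

  # 5. differential expression
  st <- S4Vectors::metadata(tags)$stats
  totalCS <- st$CS[["clean"]]; totalTS <- st$TS[["clean"]]
  knSeq <- setNames(as.character(matureRef), names(matureRef))
  deInput <- rbind(
    data.frame(id = knownCounts$id, sequence = unname(knSeq[knownCounts$id]),
               countCS = knownCounts$countCS, countTS = knownCounts$countTS,
               stringsAsFactors = FALSE),
    if (nrow(novel) > 0L)
      data.frame(id = novel$id, sequence = novel$mature,
                 countCS = novel$countCS, countTS = novel$countTS,
                 stringsAsFactors = FALSE))
  de <- diffExpression(deInput, totalCS, totalTS, fcThreshold, pThreshold)
  writeDiffexp(de, pth("diffexp.tsv"), fcThreshold, pThreshold)

  # 6. target prediction for responsive miRNAs
  resp <- de[de$responsive, , drop = FALSE]
  transcripts <- Biostrings::readDNAStringSet(pth("transcripts.fa"))
  respSeqs <- setNames(rnaToDna(resp$sequence), resp$id)
  sites <- scanTargets(respSeqs, transcripts, allenMaxS)
  pred <- intersectPredictions(sites)
  .writeTsv(sites, pth("targets.tsv"),
            comments = sprintf("penalty scheme: mismatch 1.0, G:U 0.5, gap 2.0, doubled at positions 2-13; max S = %.1f",
                               allenMaxS))

  # 7. network
  ppi <- .readTsv(pth("ppi.tsv"))
  tfList <- if (file.exists(pth("tf_list.txt"))) readLines(pth("tf_list.txt"))
            else character(0)
  net <- suppressWarnings(
    buildNetwork(resp, pred$sites, ppi, tfList))
  exportNetwork(net, pth("network.sif"), "sif")
  exportNetwork(net, pth("network.graphml"), "graphml")

  # 8. GO enrichment
  goMap <- .readTsv(pth("go_map.tsv"))
  background <- unique(c(goMap$gene, names(transcripts)))
  enr <- if (nrow(pred$sites) > 0L)
    goEnrichment(unique(pred$sites$gene), goMap, background)
  else
    goEnrichment(character(0), goMap, background)
  .writeTsv(enr, pth("enrichment.tsv"))

  # 9. report
  rpt <- summaryReport(tags, knownCounts, novel, de)
  .writeTsv(rpt, pth("report.tsv"))

  invisible(list(truth = truth, tags = tags, novel = novel, diffexp = de,
                 targets = pred, network = net, enrichment = enr,
                 report = rpt))
}

#' Headline bookkeeping report of a pipeline run
#'
#' Emits the study-level statistics a small RNA sequencing report prints:
#' raw and clean read counts with two-decimal percentages, unique tag counts
#' and mapped percentages, known/novel miRNA counts with the both-library
#' overlap percentage, read-abundance tiers for known miRNAs (>100, >1,000,
#' >10,000, >100,000 reads), the MFE range and mean of novel precursors, and
#' responsive up/down counts. Every percentage equals
#' `round(100 * numerator / denominator, 2)` (half away from zero) for
#' counts present in the same report, with a zero-division guard.
#'
#' @param tags an annotated [TagExperiment-class] (with read-processing
#'   stats in its metadata), or a list of precomputed library counts with
#'   elements `rawCS`, `cleanCS`, `uniqueCS`, `mappedUniqueCS` and the `TS`
#'   counterparts, so externally reported counts can be run through the
#'   exact report formulas.
#' @param knownCounts `data.frame` id/countCS/countTS of known miRNAs.
#' @param novel novel miRNA table from [discoverNovel()].
#' @param de differential table from [diffExpression()].
#' @return `data.frame` with columns `metric` and `value`.
#' @export
summaryReport <- function(tags, knownCounts, novel, de) {
  if (is(tags, "TagExperiment")) {
    st <- S4Vectors::metadata(tags)$stats
    cts <- tagCounts(tags)
    rd <- SummarizedExperiment::rowData(tags)
    mapped <- !is.na(rd$nHits) & rd$nHits > 0
    nums <- list()
    for (lib in c("CS", "TS")) {
      nums[[paste0("raw", lib)]] <- st[[lib]][["raw"]]
      nums[[paste0("clean", lib)]] <- st[[lib]][["clean"]]
      nums[[paste0("unique", lib)]] <- sum(cts[, lib] > 0)
      nums[[paste0("mappedUnique", lib)]] <- sum(cts[, lib] > 0 & mapped)
    }
  } else {
    nums <- tags
    need <- as.vector(outer(c("raw", "clean", "unique", "mappedUnique"),
                            c("CS", "TS"), paste0))
    if (!all(need %in% names(nums)))
      stop("precomputed counts must supply: ", paste(need, collapse = ", "))
  }

  kn <- knownCounts[knownCounts$countCS + knownCounts$countTS > 0, , drop = FALSE]
  knTotal <- kn$countCS + kn$countTS
  tiers <- c(100, 1000, 10000, 100000)

  add <- function(lst, metric, value) {
    lst[[length(lst) + 1L]] <- data.frame(metric = metric,
                                          value = as.character(value),
                                          stringsAsFactors = FALSE)
    lst
  }
  L <- list()
  for (lib in c("CS", "TS")) {
    raw <- nums[[paste0("raw", lib)]]; clean <- nums[[paste0("clean", lib)]]
    L <- add(L, paste0("rawReads", lib), raw)
    L <- add(L, paste0("cleanReads", lib), clean)
    L <- add(L, paste0("cleanPct", lib), formatPercent(clean, raw))
    uniq <- nums[[paste0("unique", lib)]]
    mappedU <- nums[[paste0("mappedUnique", lib)]]
    L <- add(L, paste0("uniqueTags", lib), uniq)
    L <- add(L, paste0("mappedUniqueTags", lib), mappedU)
    L <- add(L, paste0("mappedUniquePct", lib), formatPercent(mappedU, uniq))
  }
  nK <- nrow(kn)
  nBoth <- sum(kn$countCS > 0 & kn$countTS > 0)
  L <- add(L, "knownMirnasDetected", nK)
  L <- add(L, "knownMirnasCS", sum(kn$countCS > 0))
  L <- add(L, "knownMirnasTS", sum(kn$countTS > 0))
  L <- add(L, "knownBothLibraries", nBoth)
  L <- add(L, "knownBothPct", formatPercent(nBoth, nK))
  for (t in tiers) {
    nT <- sum(knTotal > t)
    L <- add(L, sprintf("knownOver%dReads", t), nT)
    L <- add(L, sprintf("knownOver%dPct", t), formatPercent(nT, nK))
  }
  L <- add(L, "novelMirnas", nrow(novel))
  if (nrow(novel) > 0L) {
    L <- add(L, "novelMfeMin", sprintf("%.2f", min(novel$mfe)))
    L <- add(L, "novelMfeMax", sprintf("%.2f", max(novel$mfe)))
    L <- add(L, "novelMfeMean", sprintf("%.2f", mean(novel$mfe)))
  }
  nUp <- sum(de$responsive & de$direction == "up", na.rm = TRUE)
  nDn <- sum(de$responsive & de$direction == "down", na.rm = TRUE)
  L <- add(L, "responsiveUp", nUp)
  L <- add(L, "responsiveDown", nDn)
  L <- add(L, "responsiveTotal", nUp + nDn)
  out <- do.call(rbind, L)
  rownames(out) <- NULL
  out
}
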