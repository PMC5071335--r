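#' @import S4Vectors
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom Biostrings DNAStringSet
NULL

# ---------------------------------------------------------------------------
# SrnaSimConfig
# ---------------------------------------------------------------------------

#' Configuration for the synthetic small RNA dataset
#'
#' Holds every knob of the synthetic-data generator: genome geometry, number
#' of planted miRNA hairpins and structured non-coding RNAs, gene models,
#' sequencing depths of the control (CS) and treated (TS) libraries,
#' per-miRNA linear fold changes (TS/CS; 1 means non-responsive), the 3'
#' adapter, the insert length window, and the fraction of random unmappable
#' noise reads.
#'
#' @slot seed integer RNG seed; a fixed seed yields a byte-identical dataset.
#' @slot nChromosomes number of toy chromosomes.
#' @slot chromosomeLength length of each chromosome (nt).
#' @slot nMirnas number of planted miRNA hairpin loci.
#' @slot nKnown how many planted miRNAs are labelled "known" (written to the
#'   mature/hairpin reference); the rest are left for novel discovery.
#' @slot nNcrnas number of planted structured non-coding RNAs
#'   (rRNA/tRNA/snRNA/snoRNA/scRNA, cycled).
#' @slot nGenes number of protein-coding gene models.
#' @slot depthCS,depthTS library depths (reads).
#' @slot foldChange named numeric vector of linear fold changes keyed by
#'   miRNA id (e.g. "mir_3"); miRNAs absent from the map default to 1.
#' @slot adapter 3' adapter sequence ligated onto every genuine insert.
#' @slot readLengthRange insert length window `c(min, max)` in nt.
#' @slot readLength total sequencer read length (insert + adapter fill).
#' @slot noiseFraction proportion of random, adapter-free noise reads.
#' @slot errorRate per-base sequencing error rate (default 0 so that exact
#'   genome matching remains meaningful).
#'
#' @seealso [simulateReference()], [simulateLibraries()]
#' @export
setClass("SrnaSimConfig",
  representation(
    seed = "integer",
    nChromosomes = "integer",
    chromosomeLength = "integer",
    nMirnas = "integer",
    nKnown = "integer",
    nNcrnas = "integer",
    nGenes = "integer",
    depthCS = "integer",
    depthTS = "integer",
    foldChange = "numeric",
    adapter = "character",
    readLengthRange = "integer",
    readLength = "integer",
    noiseFraction = "numeric",
    errorRate = "numeric"
  )
)

setValidity("SrnaSimConfig", function(object) {
  msg <- character(0)
  if (object@nChromosomes < 1L) msg <- c(msg, "need at least one chromosome")
  # rough capacity check: every planted locus (hairpin <= 400 nt, ncRNA <=
  # 150 nt, gene <= 2000 nt) must fit without overlap
  need <- object@nMirnas * 450 + object@nNcrnas * 200 + object@nGenes * 2200
  have <- object@nChromosomes * object@chromosomeLength
  if (need > have)
    msg <- c(msg, sprintf(
      "chromosomes too short to host all planted loci (need ~%d nt, have %d)",
      need, have))
  if (any(object@foldChange <= 0)) msg <- c(msg, "fold changes must be > 0")
  if (object@noiseFraction < 0 || object@noiseFraction >= 1)
    msg <- c(msg, "noiseFraction must be in [0, 1)")
  if (object@nKnown > object@nMirnas)
    msg <- c(msg, "nKnown cannot exceed nMirnas")
  if (nchar(object@adapter) < 6L) msg <- c(msg, "adapter must be >= 6 nt")
  if (length(object@readLengthRange) != 2L ||
      object@readLengthRange[1] > object@readLengthRange[2])
    msg <- c(msg, "readLengthRange must be c(min, max) with min <= max")
  if (object@errorRate < 0 || object@errorRate > 0.2)
    msg <- c(msg, "errorRate must be in [0, 0.2]")
  if (length(msg)) msg else TRUE
})

#' Construct a synthetic-dataset configuration
#'
#' Defaults define the package's reference study conditions: a 2 x 60 kb
#' genome, 30 planted miRNA hairpins of which 10 are labelled known, 10
#' structured ncRNAs, 30 gene models, and 50,000 reads per library with a set
#' of planted up- and down-regulated miRNAs.
#'
#' @param seed integer RNG seed.
#' @param nChromosomes,chromosomeLength genome geometry.
#' @param nMirnas,nKnown planted miRNA loci and how many are labelled known.
#' @param nNcrnas,nGenes planted ncRNA loci and gene models.
#' @param depthCS,depthTS library depths.
#' @param foldChange named numeric vector of linear TS/CS fold changes; `NULL`
#'   uses the default responsive set (see Details).
#' @param adapter 3' adapter sequence.
#' @param readLengthRange insert window `c(min, max)`.
#' @param readLength sequencer read length.
#' @param noiseFraction fraction of random unmappable reads.
#' @param errorRate per-base sequencing error rate.
#'
#' @details With `foldChange = NULL` twelve miRNAs are responsive: mir_1,
#' mir_4, mir_7, mir_11, mir_15, mir_19 up (folds 4-16) and mir_2, mir_8,
#' mir_12, mir_16, mir_22, mir_26 down (folds 1/4-1/16); all others are 1.
#' Entries for miRNA ids beyond `nMirnas` are ignored.
#'
#' @return a validated [SrnaSimConfig-class] object.
#' @examples
#' cfg <- SrnaSimConfig(seed = 1)
#' cfg
#' @export
SrnaSimConfig <- function(seed = 1L,
                          nChromosomes = 2L,
                          chromosomeLength = 60000L,
                          nMirnas = 30L,
                          nKnown = 10L,
                          nNcrnas = 10L,
                          nGenes = 30L,
                          depthCS = 50000L,
                          depthTS = 50000L,
                          foldChange = NULL,
                          adapter = "TGGAATTCTCGGGTGCCAAGGAACTCCAGT",
                          readLengthRange = c(18L, 30L),
                          readLength = 50L,
                          noiseFraction = 0.05,
                          errorRate = 0) {
  if (is.list(foldChange)) foldChange <- unlist(foldChange)
  if (is.null(foldChange)) {
    foldChange <- c(
      mir_1 = 4, mir_4 = 8, mir_7 = 4, mir_11 = 16, mir_15 = 4, mir_19 = 8,
      mir_2 = 0.25, mir_8 = 0.125, mir_12 = 0.25, mir_16 = 0.0625,
      mir_22 = 0.25, mir_26 = 0.125
    )
  }
  new("SrnaSimConfig",
    seed = as.integer(seed),
    nChromosomes = as.integer(nChromosomes),
    chromosomeLength = as.integer(chromosomeLength),
    nMirnas = as.integer(nMirnas),
    nKnown = as.integer(nKnown),
    nNcrnas = as.integer(nNcrnas),
    nGenes = as.integer(nGenes),
    depthCS = as.integer(depthCS),
    depthTS = as.integer(depthTS),
    foldChange = foldChange,
    adapter = toupper(adapter),
    readLengthRange = as.integer(readLengthRange),
    readLength = as.integer(readLength),
    noiseFraction = noiseFraction,
    errorRate = errorRate
  )
}

setMethod("show", "SrnaSimConfig", function(object) {
  cat("SrnaSimConfig\n")
  cat(sprintf("  genome: %d x %d nt | miRNAs: %d (%d known) | ncRNAs: %d | genes: %d\n",
              object@nChromosomes, object@chromosomeLength, object@nMirnas,
              object@nKnown, object@nNcrnas, object@nGenes))
  cat(sprintf("  depth CS/TS: %d/%d | noise: %.2f | seed: %d\n",
              object@depthCS, object@depthTS, object@noiseFraction,
              object@seed))
  resp <- names(object@foldChange)[abs(log2(object@foldChange)) >= 1]
  cat(sprintf("  responsive by design: %s\n", paste(resp, collapse = ", ")))
})

# ---------------------------------------------------------------------------
# HairpinCriteria
# ---------------------------------------------------------------------------

#' Criteria for accepting a candidate miRNA hairpin
#'
#' Thresholds applied when deciding whether an excised, folded genomic window
#' is a credible miRNA precursor, following standard plant miRNA annotation
#' practice: the mature must sit on one arm of the stem, the mature:star
#' duplex may carry only a few mismatched bases and no large asymmetric
#' bulge, most mature bases must be paired, and the fold must be stable.
#' Tags hitting the genome at too many loci are discarded before folding.
#'
#' @slot maxDuplexMismatches maximum mismatched bases in the mature:star
#'   duplex (default 4).
#' @slot maxAsymmetricBulge maximum asymmetric bulge within the duplex, nt
#'   (default 2).
#' @slot minPairedMature minimum number of paired mature bases (default 16).
#' @slot mfeThreshold maximum (i.e. least negative) acceptable minimum free
#'   energy, kcal/mol (default -18).
#' @slot maxStarDistance maximum space between the mature and its inferred
#'   star along the precursor, nt (default 35): the duplex must be local, a
#'   mature pairing a quasi-complementary region far across a long sloppy
#'   stem is not a credible Dicer substrate.
#' @slot maxGenomeHits tags with more genomic loci than this are removed
#'   (default 10; "more than 10 hits" are discarded, exactly 10 is kept).
#' @slot flankLong,flankShort excision window flanks around the tag, nt
#'   (defaults 200/30; both orientations are tried).
#' @slot maxPrecursorLength cap on the excised window, nt (default 400).
#' @slot candidateLengthRange mature length window for candidates (20-24 nt).
#' @export
setClass("HairpinCriteria",
  representation(
    maxDuplexMismatches = "integer",
    maxAsymmetricBulge = "integer",
    minPairedMature = "integer",
    mfeThreshold = "numeric",
    maxStarDistance = "integer",
    maxGenomeHits = "integer",
    flankLong = "integer",
    flankShort = "integer",
    maxPrecursorLength = "integer",
    candidateLengthRange = "integer"
  )
)

setValidity("HairpinCriteria", function(object) {
  msg <- character(0)
  if (object@maxGenomeHits < 1L) msg <- c(msg, "maxGenomeHits must be >= 1")
  if (!is.finite(object@mfeThreshold)) msg <- c(msg, "mfeThreshold must be finite")
  if (object@minPairedMature < 1L) msg <- c(msg, "minPairedMature must be >= 1")
  if (object@maxStarDistance < 1L) msg <- c(msg, "maxStarDistance must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname HairpinCriteria-class
#' @param maxDuplexMismatches,maxAsymmetricBulge,minPairedMature,mfeThreshold,maxStarDistance,maxGenomeHits,flankLong,flankShort,maxPrecursorLength,candidateLengthRange
#'   see the corresponding slots.
#' @return a validated [HairpinCriteria-class] object.
#' @examples
#' HairpinCriteria()
#' @export
HairpinCriteria <- function(maxDuplexMismatches = 4L,
                            maxAsymmetricBulge = 2L,
                            minPairedMature = 16L,
                            mfeThreshold = -18.0,
                            maxStarDistance = 35L,
                            maxGenomeHits = 10L,
                            flankLong = 200L,
                            flankShort = 30L,
                            maxPrecursorLength = 400L,
                            candidateLengthRange = c(20L, 24L)) {
  new("HairpinCriteria",
    maxDuplexMismatches = as.integer(maxDuplexMismatches),
    maxAsymmetricBulge = as.integer(maxAsymmetricBulge),
    minPairedMature = as.integer(minPairedMature),
    mfeThreshold = mfeThreshold,
    maxStarDistance = as.integer(maxStarDistance),
    maxGenomeHits = as.integer(maxGenomeHits),
    flankLong = as.integer(flankLong),
    flankShort = as.integer(flankShort),
    maxPrecursorLength = as.integer(maxPrecursorLength),
    candidateLengthRange = as.integer(candidateLengthRange)
  )
}

setMethod("show", "HairpinCriteria", function(object) {
  cat("HairpinCriteria\n")
  cat(sprintf("  duplex mismatches <= %d | asymmetric bulge <= %d nt | paired mature >= %d\n",
              object@maxDuplexMismatches, object@maxAsymmetricBulge,
              object@minPairedMature))
  cat(sprintf("  MFE <= %.1f kcal/mol | star distance <= %d nt | genome hits <= %d | window %d/%d nt (cap %d)\n",
              object@mfeThreshold, object@maxStarDistance,
              object@maxGenomeHits, object@flankShort,
              object@flankLong, object@maxPrecursorLength))
})

# ---------------------------------------------------------------------------
# TagExperiment
# ---------------------------------------------------------------------------

#' Collapsed unique small RNA tags with per-library counts
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' subclass whose rows are distinct clean-read sequences (unique tags) and
#' whose two columns are the control (CS) and treated (TS) libraries. The
#' `counts` assay holds per-library read counts; `rowData` carries the tag
#' sequence, the annotation category once the cascade has run, and the
#' number of perfect genomic hits once mapping has run. `metadata` stores the
#' raw/clean read bookkeeping of both libraries.
#'
#' @seealso [collapseTags()], [annotateTags()]
#' @export
setClass("TagExperiment", contains = "SummarizedExperiment")

setValidity("TagExperiment", function(object) {
  msg <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
    if (nrow(cts) > 0 && any(rowSums(cts) < 1))
      msg <- c(msg, "every tag needs at least one read across libraries")
  }
  if (!identical(colnames(object), c("CS", "TS")))
    msg <- c(msg, "columns must be CS and TS")
  if (!"sequence" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData column 'sequence' is required")
  if (length(msg)) msg else TRUE
})

#' Tag accessors
#'
#' `tagSequences()` returns the tag sequences, `tagCategories()` the cascade
#' categories (`NA` before annotation), and `tagCounts()` the counts matrix.
#'
#' @param x a [TagExperiment-class].
#' @return character vector, factor/character vector, or integer matrix.
#' @examples
#' te <- collapseTags(c("ACGTACGTACGTACGTAC"), character(0))
#' tagSequences(te)
#' tagCounts(te)
#' @export
tagSequences <- function(x) SummarizedExperiment::rowData(x)$sequence

#' @rdname tagSequences
#' @export
tagCategories <- function(x) SummarizedExperiment::rowData(x)$category

#' @rdname tagSequences
#' @export
tagCounts <- function(x) SummarizedExperiment::assay(x, "counts")

TAG_CATEGORIES <- c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA",
                    "known_miRNA", "exon_sense", "exon_antisense",
                    "intron_sense", "intron_antisense",
                    "novel_miRNA_candidate", "unknown")

setMethod("show", "TagExperiment", function(object) {
  cat(sprintf("TagExperiment: %d unique tags x %d libraries\n",
              nrow(object), ncol(object)))
  cts <- tagCounts(object)
  cat(sprintf("  reads CS/TS: %d/%d\n", sum(cts[, "CS"]), sum(cts[, "TS"])))
  cat_col <- tagCategories(object)
  if (!is.null(cat_col) && !all(is.na(cat_col))) {
    tb <- table(factor(cat_col, levels = TAG_CATEGORIES))
    tb <- tb[tb > 0]
    cat("  categories:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  } else {
    cat("  categories: not yet annotated\n")
  }
})

# ---------------------------------------------------------------------------
# RegulatoryNetwork
# ---------------------------------------------------------------------------

#' miRNA-mediated regulatory network
#'
#' A bipartite miRNA-to-target graph merged with protein-protein interaction
#' (PPI) edges. Nodes are miRNAs (with their log2 fold change) and proteins
#' (with a transcription-factor flag). Targeting edges are directed miRNA to
#' protein; PPI edges are undirected and stored with canonically ordered
#' endpoints.
#'
#' @slot nodes `DataFrame` with columns `id`, `type` ("miRNA"/"protein"),
#'   `log2fc` (NA for proteins), `isTF` (logical).
#' @slot edges `DataFrame` with columns `source`, `target`, `kind`
#'   ("targeting"/"ppi"), `score` (NA for targeting edges).
#' @seealso [buildNetwork()], [exportNetwork()]
#' @export
setClass("RegulatoryNetwork",
  representation(nodes = "DataFrame", edges = "DataFrame"))

setValidity("RegulatoryNetwork", function(object) {
  msg <- character(0)
  nd <- object@nodes; ed <- object@edges
  if (!all(c("id", "type", "log2fc", "isTF") %in% colnames(nd)))
    msg <- c(msg, "nodes need columns id, type, log2fc, isTF")
  if (!all(c("source", "target", "kind", "score") %in% colnames(ed)))
    msg <- c(msg, "edges need columns source, target, kind, score")
  if (nrow(ed) > 0) {
    if (!all(c(ed$source, ed$target) %in% nd$id))
      msg <- c(msg, "every edge endpoint must exist in nodes")
    tgt <- ed[ed$kind == "targeting", , drop = FALSE]
    if (nrow(tgt) > 0) {
      stype <- nd$type[match(tgt$source, nd$id)]
      ttype <- nd$type[match(tgt$target, nd$id)]
      if (!all(stype == "miRNA" & ttype == "protein"))
        msg <- c(msg, "targeting edges must run miRNA -> protein")
    }
    ppi <- ed[ed$kind == "ppi", , drop = FALSE]
    if (nrow(ppi) > 0 && !all(ppi$source <= ppi$target))
      msg <- c(msg, "ppi edges must be stored with ordered endpoints")
  }
  if (length(msg)) msg else TRUE
})

#' Network accessors
#'
#' @param x a [RegulatoryNetwork-class].
#' @return a `DataFrame` of nodes or edges.
#' @export
networkNodes <- function(x) x@nodes

#' @rdname networkNodes
#' @export
networkEdges <- function(x) x@edges

setMethod("show", "RegulatoryNetwork", function(object) {
  ed <- object@edges
  cat(sprintf("RegulatoryNetwork: %d nodes (%d miRNA, %d protein), %d edges (%d targeting, %d ppi)\n",
              nrow(object@nodes), sum(object@nodes$type == "miRNA"),
              sum(object@nodes$type == "protein"), nrow(ed),
              sum(ed$kind == "targeting"), sum(ed$kind == "ppi")))
})
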