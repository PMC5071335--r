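# Shared fixtures. The default pipeline run is expensive (~1 min), so it is
# computed once per test session and reused by every file that needs it.

.runCache <- new.env(parent = emptyenv())

defaultRun <- function() {
  if (is.null(.runCache$res)) {
    .runCache$dir <- file.path(tempdir(), "mircascade-default-run")
    .runCache$res <- runPipeline(SrnaSimConfig(seed = 1), .runCache$dir)
  }
  .runCache$res
}

defaultRunDir <- function() {
  defaultRun()
  .runCache$dir
}

# build a TagExperiment directly from sequence/count vectors
makeTags <- function(seqs, cs, ts, stats = NULL) {
  counts <- cbind(CS = as.numeric(cs), TS = as.numeric(ts))
  rownames(counts) <- seqs
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(sequence = seqs),
    colData = S4Vectors::DataFrame(row.names = c("CS", "TS")))
  tags <- methods::new("TagExperiment", se)
  if (!is.null(stats)) {
    md <- S4Vectors::metadata(tags)
    md$stats <- stats
    S4Vectors::metadata(tags) <- md
  }
  tags
}

# deterministic random DNA string
randDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

# write a temporary FASTQ file from read sequences (constant quality)
writeFastq <- function(reads, path) {
  if (length(reads) == 0L) {
    file.create(path)
    return(path)
  }
  recs <- rbind(paste0("@r", seq_along(reads)), reads, "+",
                vapply(nchar(reads), function(n)
                  paste(rep("I", n), collapse = ""), character(1)))
  writeLines(as.vector(recs), path)
  path
}
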