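#' Read a FASTQ file into a character vector of sequences
#'
#' Minimal strict Phred+33 FASTQ reader. Quality strings are retained only
#' for length validation; downstream filtering is sequence-based (an optional
#' mean-quality filter is available in [trimAndFilter()]).
#'
#' @param path FASTQ file path.
#' @return character vector of read sequences.
#' @export
readFastqSeqs <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop(sprintf("malformed FASTQ: %s has %d lines (not a multiple of 4)",
                 path, n))
  if (n == 0L) return(character(0))
  hdr <- seq(1L, n, by = 4L)
  plus <- seq(3L, n, by = 4L)
  badH <- which(substr(lines[hdr], 1L, 1L) != "@")
  if (length(badH))
    stop(sprintf("malformed FASTQ record at line %d: header must start with '@'",
                 hdr[badH[1]]))
  badP <- which(substr(lines[plus], 1L, 1L) != "+")
  if (length(badP))
    stop(sprintf("malformed FASTQ record at line %d: separator must start with '+'",
                 plus[badP[1]]))
  seqs <- lines[seq(2L, n, by = 4L)]
  quals <- lines[seq(4L, n, by = 4L)]
  badL <- which(nchar(seqs) != nchar(quals))
  if (length(badL))
    stop(sprintf("malformed FASTQ record at line %d: sequence/quality length mismatch",
                 hdr[badL[1]]))
  toupper(seqs)
}

#' Trim the 3' adapter and apply length filters
#'
#' The adapter is located as the longest prefix of the adapter sequence
#' matching a suffix of the read (leftmost hit; at least `minOverlap`
#' matching bases, `maxMismatch` substitutions allowed, default 0). The
#' insert 5' of the hit is kept when its length falls inside
#' `[minLen, maxLen]`. Reads without an adapter hit are kept as-is only if
#' already inside the length window; inserts containing N are discarded.
#'
#' @param reads character vector of read sequences (or a FASTQ path).
#' @param adapter 3' adapter sequence.
#' @param minLen,maxLen clean length window (defaults 18 and 30 nt).
#' @param minOverlap minimum adapter overlap (default 6 nt).
#' @param maxMismatch substitutions tolerated in the adapter match (default 0).
#' @param dropN discard inserts containing N (default TRUE).
#' @return a list with `clean` (character vector of clean inserts, one per
#'   surviving read) and `stats` (`raw`, `clean` read counts).
#' @examples
#' trimAndFilter(c(paste0(strrep("AC", 11), "TGGAATTCTCGG")),
#'               adapter = "TGGAATTCTCGGGTGCCAAGGAACTCCAGT")
#' @export
trimAndFilter <- function(reads, adapter, minLen = 18L, maxLen = 30L,
                          minOverlap = 6L, maxMismatch = 0L, dropN = TRUE) {
  if (length(reads) == 1L && file.exists(reads) &&
      grepl("\\.(fastq|fq)$", reads))
    reads <- readFastqSeqs(reads)
  stopifnot(nchar(adapter) > 0L, minLen <= maxLen)
  adapter <- toupper(adapter)
  raw <- length(reads)
  if (raw == 0L)
    return(list(clean = character(0), stats = c(raw = 0L, clean = 0L)))
  L <- nchar(reads)
  maxL <- max(L)
  hitPos <- rep(NA_integer_, raw)
  # leftmost start position where a prefix of the adapter matches the read
  # suffix; scanning positions in increasing order keeps the longest match
  for (p in 1:(maxL - minOverlap + 1L)) {
    open <- is.na(hitPos) & L >= p + minOverlap - 1L
    if (!any(open)) break
    mlen <- pmin(L - p + 1L, nchar(adapter))
    if (maxMismatch == 0L) {
      ok <- open & substr(reads, p, p + mlen - 1L) ==
        substr(rep.int(adapter, raw), 1L, mlen)
    } else {
      ok <- open
      idx <- which(open)
      for (i in idx) {
        a <- strsplit(substr(reads[i], p, p + mlen[i] - 1L), "")[[1]]
        b <- strsplit(substr(adapter, 1L, mlen[i]), "")[[1]]
        ok[i] <- sum(a != b) <= maxMismatch
      }
    }
    hitPos[ok & is.na(hitPos)] <- p
  }
  insert <- ifelse(is.na(hitPos), reads, substr(reads, 1L, hitPos - 1L))
  len <- nchar(insert)
  keep <- len >= minLen & len <= maxLen
  # no adapter hit: only acceptable when the whole read is already in-window
  keep[is.na(hitPos) & nchar(reads) > maxLen] <- FALSE
  if (dropN) keep <- keep & !grepl("N", insert, fixed = TRUE)
  clean <- insert[keep]
  list(clean = clean, stats = c(raw = raw, clean = length(clean)))
}

#' Collapse clean reads of both libraries into unique tags
#'
#' One tag per distinct sequence, with exact per-library counts. The result
#' is order-independent: permuting either input leaves the tag set and
#' counts unchanged.
#'
#' @param cleanCS,cleanTS character vectors of clean reads for the control
#'   and treated library.
#' @param stats optional named list with per-library raw/clean bookkeeping
#'   (stored in `metadata`).
#' @return a [TagExperiment-class].
#' @export
collapseTags <- function(cleanCS, cleanTS, stats = NULL) {
  tcs <- table(cleanCS)
  tts <- table(cleanTS)
  seqs <- sort(union(names(tcs), names(tts)))
  cts <- cbind(CS = as.integer(tcs[seqs]), TS = as.integer(tts[seqs]))
  cts[is.na(cts)] <- 0L
  rownames(cts) <- NULL
  rd <- S4Vectors::DataFrame(sequence = seqs,
                             category = rep(NA_character_, length(seqs)),
                             nHits = rep(NA_integer_, length(seqs)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cts),
    rowData = rd,
    colData = S4Vectors::DataFrame(library = c("CS", "TS"),
                                   row.names = c("CS", "TS")))
  md <- list(stats = stats)
  te <- methods::new("TagExperiment", se)
  S4Vectors::metadata(te) <- md
  te
}

#' Length distribution of unique tags
#'
#' Per-length redundant (count-weighted) and unique (tag-weighted)
#' histograms for both libraries, with percentages rounded to two decimals.
#'
#' @param tags a [TagExperiment-class].
#' @return `data.frame` with columns `length`, `redundantCS`, `uniqueCS`,
#'   `redundantTS`, `uniqueTS` and the matching `pct*` columns.
#' @export
lengthDistribution <- function(tags) {
  len <- nchar(tagSequences(tags))
  cts <- tagCounts(tags)
  lv <- sort(unique(len))
  agg <- function(w) vapply(lv, function(l) sum(w[len == l]), numeric(1))
  redCS <- agg(cts[, "CS"]); redTS <- agg(cts[, "TS"])
  uniCS <- agg(as.integer(cts[, "CS"] > 0))
  uniTS <- agg(as.integer(cts[, "TS"] > 0))
  data.frame(
    length = lv,
    redundantCS = as.integer(redCS), uniqueCS = as.integer(uniCS),
    redundantTS = as.integer(redTS), uniqueTS = as.integer(uniTS),
    pctRedundantCS = as.numeric(formatPercent(redCS, sum(redCS))),
    pctUniqueCS = as.numeric(formatPercent(uniCS, sum(uniCS))),
    pctRedundantTS = as.numeric(formatPercent(redTS, sum(redTS))),
    pctUniqueTS = as.numeric(formatPercent(uniTS, sum(uniTS))))
}

#' Process two FASTQ libraries into a collapsed tag set
#'
#' Runs [trimAndFilter()] on each library and [collapseTags()] on the
#' results; raw/clean bookkeeping lands in `metadata(result)$stats`.
#'
#' @param fastqCS,fastqTS FASTQ paths (control and treated libraries).
#' @param adapter 3' adapter sequence.
#' @param ... passed on to [trimAndFilter()].
#' @return a [TagExperiment-class].
#' @export
processReads <- function(fastqCS, fastqTS, adapter, ...) {
  cs <- trimAndFilter(readFastqSeqs(fastqCS), adapter, ...)
  ts <- trimAndFilter(readFastqSeqs(fastqTS), adapter, ...)
  collapseTags(cs$clean, ts$clean,
               stats = list(CS = cs$stats, TS = ts$stats))
}

#' Write unique tags to disk
#'
#' `writeTags()` emits a TSV (sequence, countCS, countTS, category, nHits);
#' `writeTagFasta()` emits the collapsed-read FASTA dialect
#' (`>tag_<i> x<count>`) for one library.
#'
#' @param tags a [TagExperiment-class].
#' @param path output file.
#' @param library which library's counts to embed in the FASTA headers.
#' @return invisibly, the path.
#' @export
writeTags <- function(tags, path) {
  rd <- SummarizedExperiment::rowData(tags)
  cts <- tagCounts(tags)
  .writeTsv(data.frame(sequence = rd$sequence,
                       countCS = cts[, "CS"], countTS = cts[, "TS"],
                       category = rd$category, nHits = rd$nHits), path)
}

#' @rdname writeTags
#' @export
writeTagFasta <- function(tags, path, library = c("CS", "TS")) {
  library <- match.arg(library)
  cts <- tagCounts(tags)[, library]
  sel <- cts > 0
  seqs <- tagSequences(tags)[sel]
  con <- file(path, "w")
  writeLines(as.vector(rbind(
    sprintf(">tag_%d x%d", seq_along(seqs), cts[sel]), seqs)), con)
  close(con)
  invisible(path)
}
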