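#' @importFrom GenomicRanges GRanges findOverlaps strand seqnames
#' @importFrom IRanges IRanges
NULL

.asDNAStringSet <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(Biostrings::readDNAStringSet(x))
  Biostrings::DNAStringSet(x)
}

# which tags (character vector) occur as exact substrings in each subject
# sequence (sense or antisense); returns list over subjects of tag indices
.substringHits <- function(tagSeqs, subjects) {
  hits <- vector("list", length(subjects))
  for (i in seq_along(hits)) hits[[i]] <- integer(0)
  if (length(tagSeqs) == 0L || length(subjects) == 0L) return(hits)
  both <- c(subjects, Biostrings::reverseComplement(subjects))
  for (w in sort(unique(nchar(tagSeqs)))) {
    idx <- which(nchar(tagSeqs) == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(tagSeqs[idx]))
    got <- Biostrings::vwhichPDict(pd, both)
    for (s in seq_along(subjects)) {
      found <- union(got[[s]], got[[s + length(subjects)]])
      if (length(found)) hits[[s]] <- c(hits[[s]], idx[found])
    }
  }
  hits
}

#' Assign tags to structured non-coding RNA classes
#'
#' A tag is assigned the class of the first reference sequence (file order)
#' that contains it as an exact substring, sense or antisense. Assigned tags
#' leave the cascade: they can never become miRNA candidates.
#'
#' @param tags a [TagExperiment-class].
#' @param ncrnaRef FASTA path or `DNAStringSet` whose names start with the
#'   ncRNA class (e.g. `"rRNA|..."`).
#' @return character vector of per-tag class assignments (`NA` = unassigned).
#' @export
matchNcrna <- function(tags, ncrnaRef) {
  ref <- .asDNAStringSet(ncrnaRef)
  seqs <- tagSequences(tags)
  assign <- rep(NA_character_, length(seqs))
  if (length(ref) == 0L) return(assign)
  cls <- sub("[|[:space:]].*$", "", names(ref))
  hits <- .substringHits(seqs, ref)
  for (i in seq_along(ref)) {     # file order = priority order
    todo <- hits[[i]][is.na(assign[hits[[i]]])]
    if (length(todo)) assign[todo] <- cls[i]
  }
  assign
}

#' Map tags to the genome by exact search on both strands
#'
#' Every perfect occurrence is reported; a tag matching the reverse
#' complement of the genome is a minus-strand hit over the same interval.
#'
#' @param tags a [TagExperiment-class] or character vector of sequences.
#' @param genome FASTA path or named `DNAStringSet`.
#' @return `data.frame` with columns `tag`, `chrom`, `start` (0-based),
#'   `end` (half-open), `strand`; the per-tag hit count is `nHits` via
#'   `table(hits$tag)`.
#' @export
mapGenome <- function(tags, genome) {
  genome <- .asDNAStringSet(genome)
  seqs <- if (is(tags, "TagExperiment")) tagSequences(tags) else tags
  out <- list()
  if (length(seqs) == 0L)
    return(data.frame(tag = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  for (w in sort(unique(nchar(seqs)))) {
    idx <- which(nchar(seqs) == w)
    fwd <- Biostrings::DNAStringSet(seqs[idx])
    rev <- Biostrings::reverseComplement(fwd)
    for (strand in c("+", "-")) {
      pd <- Biostrings::PDict(if (strand == "+") fwd else rev)
      for (ch in names(genome)) {
        m <- Biostrings::matchPDict(pd, genome[[ch]])
        cnt <- S4Vectors::elementNROWS(m)
        hit <- which(cnt > 0)
        for (k in hit) {
          st <- BiocGenerics::start(m[[k]])
          out[[length(out) + 1L]] <- data.frame(
            tag = seqs[idx[k]], chrom = ch, start = st - 1L,
            end = st - 1L + w, strand = strand, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(tag = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$tag, res$chrom, res$start, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Identify tags matching known mature miRNAs
#'
#' A tag is assigned to a known miRNA when it equals its mature sequence, or
#' matches it with at most `shift` nt of 5'/3' offset while remaining an
#' exact substring of that miRNA's hairpin (isomiR-style ends). Internal
#' mismatches are not tolerated by default.
#'
#' @param tags a [TagExperiment-class].
#' @param matureRef,hairpinRef FASTA paths or `DNAStringSet`s with matching
#'   names (mature absent from its hairpin is a reference-consistency error).
#' @param shift allowed 5'/3' end offset in nt (default 2).
#' @return list with `assign` (per-tag miRNA id or `NA`) and `counts`
#'   (`data.frame` id/countCS/countTS summed over assigned tags).
#' @export
identifyKnown <- function(tags, matureRef, hairpinRef, shift = 2L) {
  mat <- .asDNAStringSet(matureRef)
  hp <- .asDNAStringSet(hairpinRef)
  seqs <- tagSequences(tags)
  cts <- tagCounts(tags)
  assign <- rep(NA_character_, length(seqs))
  ids <- names(mat)
  if (length(mat) > 0L) {
    matc <- toupper(rnaToDna(as.character(mat)))
    hpc <- toupper(rnaToDna(as.character(hp)))[match(ids, names(hp))]
    for (j in seq_along(ids)) {
      mpos <- regexpr(matc[j], hpc[j], fixed = TRUE)
      if (is.na(hpc[j]) || mpos < 0)
        stop("reference inconsistency: mature of ", ids[j],
             " is not a substring of its hairpin")
      mS <- as.integer(mpos); mE <- mS + nchar(matc[j]) - 1L
      cand <- which(is.na(assign) &
                      abs(nchar(seqs) - nchar(matc[j])) <= 2L * shift)
      for (i in cand) {
        if (seqs[i] == matc[j]) { assign[i] <- ids[j]; next }
        tpos <- regexpr(seqs[i], hpc[j], fixed = TRUE)
        if (tpos > 0) {
          tS <- as.integer(tpos); tE <- tS + nchar(seqs[i]) - 1L
          if (abs(tS - mS) <= shift && abs(tE - mE) <= shift)
            assign[i] <- ids[j]
        }
      }
    }
  }
  counts <- data.frame(id = ids,
                       countCS = vapply(ids, function(j)
                         sum(cts[which(assign == j), "CS"]), numeric(1)),
                       countTS = vapply(ids, function(j)
                         sum(cts[which(assign == j), "TS"]), numeric(1)),
                       stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  list(assign = assign, counts = counts)
}

.loadGeneModels <- function(gff3) {
  if (is(gff3, "GRanges")) gr <- gff3
  else gr <- rtracklayer::import(gff3, format = "gff3")
  list(genes = gr[gr$type == "gene"], exons = gr[gr$type == "exon"])
}

#' Run the full annotation cascade
#'
#' Assigns each unique tag to exactly one category with a fixed priority:
#' structured ncRNA classes first, then known miRNAs, then exon/intron
#' sense/antisense by genomic overlap of the tag's hits (exon beats intron,
#' sense beats antisense, the highest-priority overlap among a multi-locus
#' tag's hits wins), and finally `unknown` for everything else, including
#' unmapped tags. Genome hits are computed for all tags and stored in
#' `metadata(result)$genomeHits`; known-miRNA per-id counts land in
#' `metadata(result)$knownCounts`.
#'
#' @param tags a [TagExperiment-class].
#' @param ncrnaRef,genome,matureRef,hairpinRef,gff3 reference inputs (paths
#'   or parsed objects).
#' @param shift end-offset tolerance for known miRNA matching.
#' @return the annotated [TagExperiment-class].
#' @export
annotateTags <- function(tags, ncrnaRef, genome, matureRef, hairpinRef, gff3,
                         shift = 2L) {
  seqs <- tagSequences(tags)
  ncr <- matchNcrna(tags, ncrnaRef)
  hits <- mapGenome(tags, genome)
  nHits <- integer(length(seqs))
  tb <- table(hits$tag)
  nHits[match(names(tb), seqs)] <- as.integer(tb)
  kn <- identifyKnown(tags, matureRef, hairpinRef, shift = shift)

  category <- rep(NA_character_, length(seqs))
  category[!is.na(ncr)] <- ncr[!is.na(ncr)]
  open <- is.na(category) & !is.na(kn$assign)
  category[open] <- "known_miRNA"

  gm <- .loadGeneModels(gff3)
  open <- which(is.na(category))
  if (length(open) > 0L && nrow(hits) > 0L) {
    oh <- hits[hits$tag %in% seqs[open], , drop = FALSE]
    if (nrow(oh) > 0L) {
      hg <- GenomicRanges::GRanges(oh$chrom,
                                   IRanges::IRanges(oh$start + 1L, oh$end),
                                   strand = oh$strand)
      prio <- c(exon_sense = 1L, exon_antisense = 2L,
                intron_sense = 3L, intron_antisense = 4L)
      lab <- rep(NA_character_, nrow(oh))
      for (feat in c("exon", "gene")) {
        fr <- gm[[if (feat == "exon") "exons" else "genes"]]
        ov <- GenomicRanges::findOverlaps(hg, fr, ignore.strand = TRUE)
        if (length(ov) == 0L) next
        sameStr <- as.character(GenomicRanges::strand(hg))[S4Vectors::queryHits(ov)] ==
          as.character(GenomicRanges::strand(fr))[S4Vectors::subjectHits(ov)]
        base <- if (feat == "exon") "exon" else "intron"
        cand <- ifelse(sameStr, paste0(base, "_sense"),
                       paste0(base, "_antisense"))
        for (k in seq_along(ov)) {
          q <- S4Vectors::queryHits(ov)[k]
          if (is.na(lab[q]) || prio[cand[k]] < prio[lab[q]])
            lab[q] <- cand[k]
        }
      }
      # per tag: highest-priority label over its hits
      byTag <- split(lab, oh$tag)
      for (tg in names(byTag)) {
        ls <- byTag[[tg]][!is.na(byTag[[tg]])]
        if (length(ls)) {
          best <- names(prio)[min(prio[ls])]
          category[match(tg, seqs)] <- best
        }
      }
    }
  }
  category[is.na(category)] <- "unknown"

  rd <- SummarizedExperiment::rowData(tags)
  rd$category <- category
  rd$nHits <- nHits
  rd$knownId <- kn$assign
  SummarizedExperiment::rowData(tags) <- rd
  md <- S4Vectors::metadata(tags)
  md$genomeHits <- hits
  md$knownCounts <- kn$counts
  S4Vectors::metadata(tags) <- md
  tags
}

#' Per-category annotation summary
#'
#' Redundant (read-weighted) and unique (tag-weighted) counts per category
#' and library. Categories partition the clean tags, so redundant counts sum
#' to the clean reads of each library.
#'
#' @param tags an annotated [TagExperiment-class].
#' @return `data.frame` with one row per category.
#' @export
annotationSummary <- function(tags) {
  cat_ <- tagCategories(tags)
  if (all(is.na(cat_))) stop("run annotateTags first")
  cts <- tagCounts(tags)
  lv <- TAG_CATEGORIES[TAG_CATEGORIES %in% unique(cat_)]
  rows <- lapply(lv, function(cc) {
    sel <- cat_ == cc
    data.frame(category = cc,
               redundantCS = sum(cts[sel, "CS"]),
               uniqueCS = sum(cts[sel, "CS"] > 0),
               redundantTS = sum(cts[sel, "TS"]),
               uniqueTS = sum(cts[sel, "TS"] > 0),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
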