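#' Evaluate whether a folded precursor window is a credible miRNA hairpin
#'
#' Applies the plant miRNA annotation criteria to one candidate precursor:
#' (a) the mature sequence must lie entirely on one arm of the stem (no
#' overlap with the terminal loop), (b) the mature:star duplex may contain at
#' most `maxDuplexMismatches` mismatched bases and no asymmetric bulge larger
#' than `maxAsymmetricBulge` nt, (c) at least `minPairedMature` mature bases
#' must be paired, (d) the minimum free energy must be at or below
#' `mfeThreshold`, and (e) the star region must lie within `maxStarDistance`
#' nt of the mature along the precursor, so the duplex closes a compact
#' stem-loop rather than bridging a long sloppy stem. The star sequence is
#' inferred from the structure with the canonical 2-nt 3' overhang.
#'
#' @param precursor precursor sequence (DNA or RNA alphabet).
#' @param structure dot-bracket string, same length as `precursor`.
#' @param mfe minimum free energy of `structure`, kcal/mol.
#' @param matureStart,matureEnd 1-based closed interval of the mature
#'   sequence within the precursor.
#' @param criteria a [HairpinCriteria-class].
#' @return a list with elements `passes` (logical), `arm` ("5p", "3p" or NA),
#'   `star` (inferred star sequence or NA), `nPaired`, `nMismatch`,
#'   `maxAsymmetricBulge`, `starDistance`, `loopOverlap`, and `mfe`.
#' @examples
#' hp <- "GGGCCCGGGCCCGGGCCCGGGAAAAACCCGGGCCCGGGCCCGGGCCC"
#' f <- foldRNA(hp)
#' evaluateHairpin(hp, f$structure, f$mfe, 1, 21, HairpinCriteria())
#' @export
evaluateHairpin <- function(precursor, structure, mfe, matureStart, matureEnd,
                            criteria = HairpinCriteria()) {
  n <- nchar(precursor)
  stopifnot(nchar(structure) == n,
            matureStart >= 1, matureEnd <= n, matureStart < matureEnd)
  p <- pairTable(structure)   # errors on unbalanced input
  ms <- as.integer(matureStart); me <- as.integer(matureEnd)
  lm <- me - ms + 1L
  pm <- p[ms:me]
  paired <- !is.na(pm)
  nPaired <- sum(paired)

  out <- list(passes = FALSE, arm = NA_character_, star = NA_character_,
              nPaired = nPaired, nMismatch = NA_integer_,
              maxAsymmetricBulge = NA_integer_, starDistance = NA_integer_,
              loopOverlap = FALSE, mfe = mfe)
  if (nPaired == 0L) return(out)

  # (a) one arm, no loop overlap: no partner may fall inside the mature, and
  # all partners must sit on the same side of it
  inside <- pm[paired] >= ms & pm[paired] <= me
  all3 <- all(pm[paired] > me)
  all5 <- all(pm[paired] < ms)
  if (any(inside) || (!all3 && !all5)) {
    out$loopOverlap <- TRUE
    return(out)
  }
  out$arm <- if (all3) "5p" else "3p"

  # (b) duplex mismatches + asymmetric bulges, walked along consecutive
  # paired mature positions; unpaired runs facing unpaired star bases count
  # min(run, facing) mismatches, the surplus is an asymmetric bulge
  idx <- which(paired)
  nm <- (idx[1] - 1L) + (lm - idx[length(idx)])  # unpaired mature ends
  maxAsym <- 0L
  if (length(idx) > 1L) {
    for (k in seq_len(length(idx) - 1L)) {
      gm <- idx[k + 1L] - idx[k] - 1L
      gs <- abs(pm[idx[k]] - pm[idx[k + 1L]]) - 1L
      nm <- nm + min(gm, gs)
      maxAsym <- max(maxAsym, abs(gm - gs))
    }
  }
  out$nMismatch <- nm
  out$maxAsymmetricBulge <- maxAsym

  # star with 2-nt 3' overhang, clipped to the precursor
  lo <- min(pm[paired]); hi <- max(pm[paired])
  if (out$arm == "5p") { slo <- lo + 2L; shi <- hi + 2L }
  else                 { slo <- lo - 2L; shi <- hi - 2L }
  slo <- max(1L, slo); shi <- min(n, shi)
  out$star <- substr(precursor, slo, shi)

  # (e) duplex locality: unpaired space between the mature and its star
  out$starDistance <- if (out$arm == "5p") lo - me - 1L else ms - hi - 1L

  out$passes <- (nPaired >= criteria@minPairedMature) &&
    (nm <= criteria@maxDuplexMismatches) &&
    (maxAsym <= criteria@maxAsymmetricBulge) &&
    (out$starDistance <= criteria@maxStarDistance) &&
    (mfe <= criteria@mfeThreshold)
  out
}

#' Select candidate tags for novel miRNA discovery
#'
#' From the annotated tag set, retains tags that survived the annotation
#' cascade unassigned (category "unknown"), map to the genome at between 1
#' and `maxGenomeHits` loci (tags with more hits are removed; a tag with
#' exactly `maxGenomeHits` is kept), and whose length is inside the
#' candidate window (default 20-24 nt).
#'
#' @param tags an annotated [TagExperiment-class] with `nHits` in `rowData`.
#' @param criteria a [HairpinCriteria-class].
#' @return the row-subset `TagExperiment` of candidate tags.
#' @export
selectCandidates <- function(tags, criteria = HairpinCriteria()) {
  rd <- SummarizedExperiment::rowData(tags)
  if (is.null(rd$category) || is.null(rd$nHits))
    stop("run the annotation cascade (annotateTags) before candidate selection")
  len <- nchar(rd$sequence)
  keep <- rd$category == "unknown" &
    rd$nHits >= 1L & rd$nHits <= criteria@maxGenomeHits &
    len >= criteria@candidateLengthRange[1] &
    len <= criteria@candidateLengthRange[2]
  tags[which(keep), ]
}

#' Excise genomic windows around a tag locus and fold them
#'
#' For each genomic hit of a candidate tag, two windows are excised: the tag
#' plus `flankShort` nt upstream and `flankLong` nt downstream, and the
#' mirror arrangement. Windows are clipped at chromosome ends and capped at
#' `maxPrecursorLength`; for minus-strand hits the reverse-complement window
#' is folded so the tag always reads 5' to 3'. Each window is folded by the
#' configured engine.
#'
#' @param tagSeq candidate tag sequence (DNA).
#' @param hits `data.frame` of genomic hits for this tag with columns
#'   `chrom`, `start` (0-based), `end`, `strand` (as from [mapGenome()]).
#' @param genome a named `DNAStringSet`.
#' @param criteria a [HairpinCriteria-class].
#' @param engine folding engine, see [foldRNA()].
#' @return a `data.frame` with one row per excised window: locus columns,
#'   `window` ("5p"/"3p" flank orientation), `precursor`, `structure`,
#'   `mfe`, `matureStart`, `matureEnd` (1-based within the precursor).
#'   Windows too short to evaluate (under tag length + 40 nt) are skipped.
#' @export
exciseAndFold <- function(tagSeq, hits, genome,
                          criteria = HairpinCriteria(), engine = "internal") {
  lt <- nchar(tagSeq)
  rows <- list()
  for (h in seq_len(nrow(hits))) {
    chrom <- hits$chrom[h]
    cl <- Biostrings::width(genome[chrom])
    s0 <- hits$start[h]; e0 <- hits$end[h]  # 0-based half-open
    for (orient in c("5p", "3p")) {
      if (orient == "5p") { up <- criteria@flankShort; dn <- criteria@flankLong }
      else                { up <- criteria@flankLong;  dn <- criteria@flankShort }
      if (hits$strand[h] == "-") { tmp <- up; up <- dn; dn <- tmp }
      ws <- max(0L, s0 - up); we <- min(cl, e0 + dn)
      if (we - ws > criteria@maxPrecursorLength) {
        # trim the long side to the cap
        if (orient == "5p") ws <- max(ws, we - criteria@maxPrecursorLength)
        we <- min(we, ws + criteria@maxPrecursorLength)
      }
      if (we - ws < lt + 40L) next
      win <- as.character(Biostrings::subseq(genome[[chrom]], ws + 1L, we))
      mS <- s0 - ws + 1L; mE <- mS + lt - 1L
      if (hits$strand[h] == "-") {
        win <- revComp(win)
        mS2 <- nchar(win) - mE + 1L
        mE <- nchar(win) - mS + 1L
        mS <- mS2
      }
      f <- foldRNA(win, engine = engine)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = ws, end = we, strand = hits$strand[h],
        window = orient, precursor = win, structure = f$structure,
        mfe = f$mfe, matureStart = mS, matureEnd = mE,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      window = character(0), precursor = character(0),
                      structure = character(0), mfe = numeric(0),
                      matureStart = integer(0), matureEnd = integer(0)))
  do.call(rbind, rows)
}

#' Discover novel miRNA candidates from annotated tags
#'
#' Runs the full discovery path: candidate selection (unannotated,
#' genome-mapped, length and multi-hit filters), precursor excision and
#' folding at every locus, and hairpin evaluation. A tag passing at any
#' window/locus is reported once, with the best-scoring (lowest MFE among
#' passing) precursor retained and all passing loci listed.
#'
#' @param tags an annotated [TagExperiment-class].
#' @param genome named `DNAStringSet`.
#' @param criteria a [HairpinCriteria-class].
#' @param engine folding engine, see [foldRNA()].
#' @return a `data.frame` with one row per passing tag: `id`, `mature`,
#'   `length`, `chrom`, `start`, `end`, `strand`, `precursor`, `structure`,
#'   `mfe`, `arm`, `star`, `countCS`, `countTS`, `nLoci`, `allLoci`.
#' @export
discoverNovel <- function(tags, genome, criteria = HairpinCriteria(),
                          engine = "internal") {
  cand <- selectCandidates(tags, criteria)
  hitTab <- S4Vectors::metadata(tags)$genomeHits
  if (is.null(hitTab))
    stop("annotated TagExperiment lacks genome hit table")
  cts <- tagCounts(cand)
  seqs <- tagSequences(cand)
  out <- list()
  for (i in seq_along(seqs)) {
    hits <- hitTab[hitTab$tag == seqs[i], , drop = FALSE]
    if (nrow(hits) == 0L) next
    folds <- exciseAndFold(seqs[i], hits, genome, criteria, engine)
    if (nrow(folds) == 0L) next
    ev <- lapply(seq_len(nrow(folds)), function(k)
      evaluateHairpin(folds$precursor[k], folds$structure[k], folds$mfe[k],
                      folds$matureStart[k], folds$matureEnd[k], criteria))
    ok <- vapply(ev, `[[`, logical(1), "passes")
    if (!any(ok)) next
    pass <- folds[ok, , drop = FALSE]
    evp <- ev[ok]
    best <- which.min(pass$mfe)
    loci <- unique(sprintf("%s:%d-%d(%s)", pass$chrom, pass$start + 1L,
                           pass$end, pass$strand))
    out[[length(out) + 1L]] <- data.frame(
      mature = seqs[i], length = nchar(seqs[i]),
      chrom = pass$chrom[best], start = pass$start[best],
      end = pass$end[best], strand = pass$strand[best],
      precursor = pass$precursor[best], structure = pass$structure[best],
      mfe = pass$mfe[best], arm = evp[[best]]$arm, star = evp[[best]]$star,
      countCS = cts[i, "CS"], countTS = cts[i, "TS"],
      nLoci = length(loci), allLoci = paste(loci, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(id = character(0), mature = character(0),
                      length = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), precursor = character(0),
                      structure = character(0), mfe = numeric(0),
                      arm = character(0), star = character(0),
                      countCS = integer(0), countTS = integer(0),
                      nLoci = integer(0), allLoci = character(0)))
  res <- do.call(rbind, out)
  # deterministic naming: order by locus
  res <- res[order(res$chrom, res$start, res$mature), , drop = FALSE]
  res <- cbind(id = sprintf("novel_mir_%d", seq_len(nrow(res))), res)
  rownames(res) <- NULL
  res
}

#' Cluster novel candidates into known miRNA families
#'
#' A candidate is assigned to a known family when its mature sequence matches
#' a known plant mature miRNA with at most `maxMismatch` substitutions (no
#' indels; for unequal lengths the shorter sequence is slid within the
#' longer), or when its precursor contains a known hairpin's mature sequence.
#' Everything else is labelled `species_specific`.
#'
#' @param novel `data.frame` from [discoverNovel()].
#' @param knownMatures named character vector (or `DNAStringSet`) of known
#'   plant mature miRNAs; names are family labels.
#' @param knownHairpins optional named character vector of known hairpins.
#' @param maxMismatch substitution tolerance (default 2).
#' @return `novel` with a `family` column added.
#' @export
clusterFamilies <- function(novel, knownMatures,
                            knownHairpins = NULL, maxMismatch = 2L) {
  km <- setNames(toupper(rnaToDna(as.character(knownMatures))),
                 names(knownMatures))
  fam <- rep("species_specific", nrow(novel))
  hamWithin <- function(a, b) {
    # min substitution distance of the shorter slid within the longer
    if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
    la <- nchar(a); lb <- nchar(b)
    av <- strsplit(a, "")[[1]]
    best <- Inf
    for (off in 0:(lb - la)) {
      bv <- strsplit(substr(b, off + 1L, off + la), "")[[1]]
      best <- min(best, sum(av != bv) + (lb - la))
    }
    best
  }
  for (i in seq_len(nrow(novel))) {
    m <- novel$mature[i]
    d <- vapply(km, function(k) {
      if (abs(nchar(k) - nchar(m)) > maxMismatch) Inf else hamWithin(m, k)
    }, numeric(1))
    if (length(d) && min(d) <= maxMismatch) {
      fam[i] <- names(km)[which.min(d)]
      next
    }
    if (!is.null(knownHairpins)) {
      kh <- setNames(toupper(rnaToDna(as.character(knownHairpins))),
                     names(knownHairpins))
      hit <- which(vapply(seq_along(kh), function(j) {
        matJ <- km[match(names(kh)[j], names(km))]
        (!is.na(matJ) && grepl(matJ, novel$precursor[i], fixed = TRUE)) ||
          grepl(novel$precursor[i], kh[j], fixed = TRUE) ||
          grepl(kh[j], novel$precursor[i], fixed = TRUE)
      }, logical(1)))
      if (length(hit)) fam[i] <- names(kh)[hit[1]]
    }
  }
  novel$family <- fam
  novel
}

#' First-nucleotide composition of novel miRNA candidates
#'
#' Read-weighted counts and percentages of A/C/G/U at the 5'-most position,
#' overall and stratified by mature length, per library.
#'
#' @param novel `data.frame` from [discoverNovel()] (needs `mature`,
#'   `countCS`, `countTS`).
#' @return `data.frame` with columns `length` ("all" or a number), `base`,
#'   `countCS`, `countTS`, `pctCS`, `pctTS`.
#' @export
firstNucleotideBias <- function(novel) {
  first <- dnaToRna(substr(novel$mature, 1, 1))
  strat <- c("all", sort(unique(as.character(novel$length))))
  rows <- lapply(strat, function(s) {
    sel <- if (s == "all") rep(TRUE, nrow(novel)) else novel$length == as.integer(s)
    cs <- tapply(novel$countCS[sel], factor(first[sel], levels = c("A", "C", "G", "U")), sum)
    ts <- tapply(novel$countTS[sel], factor(first[sel], levels = c("A", "C", "G", "U")), sum)
    cs[is.na(cs)] <- 0; ts[is.na(ts)] <- 0
    data.frame(length = s, base = c("A", "C", "G", "U"),
               countCS = as.integer(cs), countTS = as.integer(ts),
               pctCS = as.numeric(formatPercent(cs, sum(cs))),
               pctTS = as.numeric(formatPercent(ts, sum(ts))),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
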