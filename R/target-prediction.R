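.checkBases <- function(x, what) {
  if (grepl("[^ACGTUacgtu]", x))
    stop(what, " contains bases outside {A,C,G,T/U}")
}

#' Score a miRNA:target duplex with the plant complementarity penalty
#'
#' The miRNA (5' to 3') is aligned against the reverse complement of the
#' target window; per-position penalties are 1.0 for a mismatch, 0.5 for a
#' G:U wobble, 2.0 for a gap, and penalties at miRNA positions 2-13 are
#' doubled. At most one gap is allowed, so the window length may differ from
#' the miRNA length by at most 1; the minimum penalty over all alignments is
#' returned.
#'
#' @param mirna miRNA sequence, 5' to 3' (DNA or RNA alphabet).
#' @param window target site on the transcript, 5' to 3'.
#' @return a list: `S` (penalty score), `state` (per-miRNA-position code:
#'   0 Watson-Crick, 1 G:U, 2 mismatch, 3 gap), `nMismatch`, `nGU`, `nGap`,
#'   `gapKind` (0 none, 1 unpaired miRNA base, 2 bulged target base),
#'   `gapPos`, `mirna`, `window`.
#' @examples
#' scoreSite("ACGTACGTACGTACGTACGTA", revComp("ACGTACGTACGTACGTACGTA"))$S
#' @export
scoreSite <- function(mirna, window) {
  .checkBases(mirna, "miRNA")
  .checkBases(window, "target window")
  if (abs(nchar(window) - nchar(mirna)) > 1L)
    stop("window length must be within miRNA length +/- 1 (single gap)")
  res <- .score_duplex(rnaToDna(toupper(mirna)),
                       revComp(rnaToDna(toupper(window))))
  if (is.na(res$S[1])) stop("no admissible alignment")
  list(S = res$S,
       state = res$state,
       nMismatch = sum(res$state == 2L),
       nGU = sum(res$state == 1L),
       nGap = as.integer(res$gap_kind > 0L),
       gapKind = res$gap_kind,
       gapPos = res$gap_pos,
       mirna = toupper(rnaToDna(mirna)),
       window = toupper(rnaToDna(window)))
}

#' Positional filter on a scored duplex
#'
#' Empirical positional constraints for functional plant target sites:
#' no mismatch or gap at miRNA positions 10-11 (the cleavage site), at most
#' one mismatch within positions 2-12, at most two mismatches within
#' positions 12-21, and never more than two consecutive mismatches. G:U
#' wobbles are penalised by the score but do not count as mismatches here.
#'
#' @param site result of [scoreSite()].
#' @param maxCore,maxTail,maxRun the three thresholds (defaults 1, 2, 2).
#' @return logical.
#' @export
schwabFilter <- function(site, maxCore = 1L, maxTail = 2L, maxRun = 2L) {
  st <- site$state
  bad <- st >= 2L            # mismatch or gap
  n <- length(st)
  pos <- seq_len(n)
  if (any(bad[pos %in% 10:11])) return(FALSE)
  if (sum(bad[pos %in% 2:12]) > maxCore) return(FALSE)
  if (sum(bad[pos %in% 12:21]) > maxTail) return(FALSE)
  r <- rle(bad)
  if (any(r$lengths[r$values] > maxRun)) return(FALSE)
  TRUE
}

#' Scan a transcriptome for candidate miRNA target sites
#'
#' All windows of every transcript within one gap of the miRNA length are
#' scored; windows with `S <= allenMaxS` are candidate sites
#' (`passesAllen`). Each candidate is then put through [schwabFilter()];
#' sites passing both rule sets are the final predictions (`predicted`),
#' mirroring the intersection of two independent complementarity-rule
#' predictors. Overlapping windows of one miRNA on one transcript are
#' collapsed to the best-scoring one.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param transcripts named character vector (or `DNAStringSet`) of spliced
#'   transcripts, 5' to 3'.
#' @param allenMaxS maximum penalty score retained (default 4.0).
#' @return `data.frame`: `mirna`, `gene`, `transcript`, `start` (0-based),
#'   `width`, `S`, `passesAllen`, `passesSchwab`, `predicted`,
#'   `cleavagePos` (1-based transcript coordinate of the base paired to
#'   miRNA position 10).
#' @export
scanTargets <- function(mirnas, transcripts, allenMaxS = 4.0) {
  if (is(transcripts, "DNAStringSet"))
    transcripts <- setNames(as.character(transcripts), names(transcripts))
  out <- list()
  for (mid in names(mirnas)) {
    mseq <- rnaToDna(toupper(mirnas[[mid]]))
    for (gid in names(transcripts)) {
      hits <- .scan_transcript(mseq, transcripts[[gid]], allenMaxS)
      if (nrow(hits) == 0L) next
      hits <- hits[order(hits$S, hits$start), , drop = FALSE]
      kept <- logical(0); ivs <- list()
      for (k in seq_len(nrow(hits))) {
        iv <- c(hits$start[k], hits$start[k] + hits$width[k])
        overl <- any(vapply(ivs, function(z) iv[1] < z[2] && z[1] < iv[2],
                            logical(1)))
        kept[k] <- !overl
        if (!overl) ivs[[length(ivs) + 1L]] <- iv
      }
      hits <- hits[kept, , drop = FALSE]
      for (k in seq_len(nrow(hits))) {
        win <- substr(transcripts[[gid]], hits$start[k] + 1L,
                      hits$start[k] + hits$width[k])
        sc <- scoreSite(mseq, win)
        out[[length(out) + 1L]] <- data.frame(
          mirna = mid, gene = gid, transcript = paste0(gid, ".1"),
          start = hits$start[k], width = hits$width[k], S = sc$S,
          passesAllen = TRUE, passesSchwab = schwabFilter(sc),
          cleavagePos = hits$start[k] + hits$width[k] - 9L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(mirna = character(0), gene = character(0),
                      transcript = character(0), start = integer(0),
                      width = integer(0), S = numeric(0),
                      passesAllen = logical(0), passesSchwab = logical(0),
                      predicted = logical(0), cleavagePos = integer(0)))
  res <- do.call(rbind, out)
  res$predicted <- res$passesAllen & res$passesSchwab
  res <- res[order(res$mirna, res$gene, res$start), ]
  rownames(res) <- NULL
  res
}

#' Final predicted targets and per-miRNA summaries
#'
#' Keeps sites passing both rule sets and reports target-transcript and
#' target-gene counts per miRNA.
#'
#' @param sites output of [scanTargets()].
#' @return list with `sites` (predicted rows only) and `perMirna`
#'   (`data.frame` mirna / nTranscripts / nGenes).
#' @export
intersectPredictions <- function(sites) {
  pred <- sites[sites$predicted, , drop = FALSE]
  ids <- unique(pred$mirna)
  perMirna <- data.frame(
    mirna = ids,
    nTranscripts = vapply(ids, function(m)
      length(unique(pred$transcript[pred$mirna == m])), integer(1)),
    nGenes = vapply(ids, function(m)
      length(unique(pred$gene[pred$mirna == m])), integer(1)),
    stringsAsFactors = FALSE)
  rownames(perMirna) <- NULL
  list(sites = pred, perMirna = perMirna)
}

#' Validate a cleavage site from RACE-style 5' end evidence
#'
#' Clone 5' ends are compared with the canonical cleavage position of the
#' site, i.e. the transcript base paired to miRNA position 10 (the cut falls
#' between the bases opposite positions 10 and 11). The site is validated
#' when the canonical fraction reaches `minFraction` with at least
#' `minClones` clones.
#'
#' @param cloneEnds table of clone 5' ends: either a named integer vector
#'   (names = 1-based transcript positions) or a `data.frame` with `pos`
#'   and `count`.
#' @param site one row of [scanTargets()] output (needs `cleavagePos`).
#' @param minFraction canonical fraction required (default 0.5).
#' @param minClones minimum total clones (default 10).
#' @return list: `canonicalPos`, `canonicalFraction`, `totalClones`,
#'   `validated`.
#' @examples
#' site <- data.frame(cleavagePos = 101)
#' mapCleavage(c(`101` = 7, `95` = 2, `103` = 1), site)
#' @export
mapCleavage <- function(cloneEnds, site, minFraction = 0.5, minClones = 10L) {
  if (is.data.frame(cloneEnds))
    cloneEnds <- setNames(as.integer(cloneEnds$count),
                          as.character(cloneEnds$pos))
  tot <- sum(cloneEnds)
  if (tot < 1) stop("cleavage evidence requires at least one clone")
  canon <- as.integer(site$cleavagePos[1])
  atCanon <- sum(cloneEnds[names(cloneEnds) == as.character(canon)])
  frac <- atCanon / tot
  list(canonicalPos = canon, canonicalFraction = frac, totalClones = tot,
       validated = frac >= minFraction && tot >= minClones)
}

#' Pretty-print a scored duplex
#'
#' Three-line text rendering of the duplex: target site 5' to 3' on top,
#' a match line (vertical bars for Watson-Crick pairs, circles for G:U
#' wobbles, spaces for mismatches), and the miRNA 3' to 5' below.
#'
#' @param site result of [scoreSite()].
#' @return a single string with embedded newlines.
#' @export
formatDuplex <- function(site) {
  m <- strsplit(site$mirna, "")[[1]]
  w <- strsplit(site$window, "")[[1]]
  st <- site$state
  n <- length(m)
  # render on miRNA coordinates; the site is shown reverse-complement-wise
  rcw <- strsplit(revComp(site$window), "")[[1]]
  top <- chr <- bot <- character(0)
  wi <- 1L
  for (i in seq_len(n)) {
    if (st[i] == 3L) {            # unpaired miRNA base (gap in target)
      top <- c(top, "-"); chr <- c(chr, " "); bot <- c(bot, m[i])
      next
    }
    if (site$gapKind == 2L && i == site$gapPos) {  # bulged target base
      top <- c(top, rcw[wi]); chr <- c(chr, " "); bot <- c(bot, "-")
      wi <- wi + 1L
    }
    top <- c(top, rcw[wi])
    chr <- c(chr, c("|", "o", " ")[st[i] + 1L])
    bot <- c(bot, m[i])
    wi <- wi + 1L
  }
  paste0("5' ", dnaToRna(paste(rev(top), collapse = "")), " 3'  (target)\n",
         "   ", paste(rev(chr), collapse = ""), "\n",
         "3' ", dnaToRna(paste(rev(bot), collapse = "")), " 5'  (miRNA)")
}
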