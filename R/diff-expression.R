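#' TPM normalisation with zero-revision and low-expression exclusion
#'
#' Expression is normalised to transcripts per million of the library's
#' total clean reads: `tpm = count * 1e6 / N`. A per-library TPM of exactly
#' zero is revised to 0.01 before fold-change computation; records whose
#' adjusted TPM is below 1 in both libraries are marked excluded from
#' differential analysis.
#'
#' @param records `data.frame` with columns `id`, `x` (raw CS count) and
#'   `y` (raw TS count).
#' @param totalCS,totalTS total clean reads of the two libraries (N1, N2).
#' @return `records` with `tpmCS`, `tpmTS`, `tpmCSAdj`, `tpmTSAdj` and
#'   `excluded` columns added.
#' @examples
#' normalizeAndAdjust(data.frame(id = "m", x = 556771, y = 571620),
#'                    totalCS = 17811109, totalTS = 17708762)
#' @export
normalizeAndAdjust <- function(records, totalCS, totalTS) {
  stopifnot(totalCS > 0, totalTS > 0)
  if (any(records$x < 0) || any(records$y < 0))
    stop("counts must be non-negative")
  records$tpmCS <- records$x * 1e6 / totalCS
  records$tpmTS <- records$y * 1e6 / totalTS
  records$tpmCSAdj <- ifelse(records$tpmCS == 0, 0.01, records$tpmCS)
  records$tpmTSAdj <- ifelse(records$tpmTS == 0, 0.01, records$tpmTS)
  records$excluded <- records$tpmCSAdj < 1 & records$tpmTSAdj < 1
  records
}

#' Log2 fold change of adjusted TPM
#'
#' `log2fc = log2(tpmTSAdj / tpmCSAdj)`; excluded records get `NA`.
#'
#' @param records output of [normalizeAndAdjust()].
#' @return `records` with a `log2fc` column.
#' @export
log2FoldChange <- function(records) {
  records$log2fc <- ifelse(records$excluded, NA_real_,
                           log2(records$tpmTSAdj / records$tpmCSAdj))
  records
}

#' Exact tag-count significance between two libraries
#'
#' The Audic-Claverie statistic for digital expression data: given `x`
#' observations of a tag in a library of `totalCS` reads, the probability of
#' observing `y` in a second library of `totalTS` reads is
#' \deqn{p(y|x) = (N2/N1)^y \frac{(x+y)!}{x!\,y!\,(1+N2/N1)^{x+y+1}}}
#' computed in log-space via log-gamma. The reported p-value is the
#' two-sided tail `2 * min(P(K <= y), P(K >= y))` capped at 1; the point
#' probability is also available.
#'
#' @param x,y observed counts (vectors recycle).
#' @param totalCS,totalTS library totals N1, N2.
#' @param type `"two.sided"` (default) or `"point"`.
#' @return numeric vector of probabilities.
#' @examples
#' audicClaverie(0, 0, 1e6, 1e6, type = "point")   # 0.5
#' audicClaverie(5, 0, 1e6, 1e6, type = "point")   # 1/64
#' @export
audicClaverie <- function(x, y, totalCS, totalTS,
                          type = c("two.sided", "point")) {
  type <- match.arg(type)
  if (totalCS <= 0 || totalTS <= 0) stop("library totals must be positive")
  if (any(x < 0) || any(y < 0) || any(x != floor(x)) || any(y != floor(y)))
    stop("counts must be non-negative integers")
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  r <- totalTS / totalCS
  lr <- log(r); l1r <- log1p(r)
  lpoint <- function(x, k) {
    k * lr + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
      (x + k + 1) * l1r
  }
  if (type == "point") return(exp(lpoint(x, y)))
  vapply(seq_len(n), function(i) {
    xi <- x[i]; yi <- y[i]
    lp <- lpoint(xi, 0:yi)
    m <- max(lp)
    lower <- exp(m) * sum(exp(lp - m))          # P(K <= y)
    # P(K >= y) by forward summation (no 1-minus cancellation); the term
    # ratio tends to r/(1+r) < 1, so the series is eventually geometric
    upper <- 0; k <- yi; lt <- lpoint(xi, yi)
    repeat {
      tm <- exp(lt)
      upper <- upper + tm
      if (tm <= upper * 1e-18 || k - yi > 1e6) break
      k <- k + 1
      lt <- lt + lr + log(xi + k) - log(k) - l1r
    }
    min(1, 2 * min(lower, min(upper, 1)))
  }, numeric(1))
}

#' Screen stress-responsive miRNAs
#'
#' A record is responsive when it is not excluded, `|log2fc|` reaches
#' `fcThreshold` (default 1, i.e. two-fold) and the Audic-Claverie p-value
#' is at or below `pThreshold` (default 0.05). A Benjamini-Hochberg column
#' is added for transparency; the default screen does not threshold it.
#'
#' @param records output of [log2FoldChange()] with a `p` column.
#' @param fcThreshold minimum `|log2fc|`.
#' @param pThreshold maximum p-value.
#' @return `records` with `responsive` and `direction` ("up"/"down"/NA) and
#'   `fdrBH` columns, sorted by decreasing `log2fc` within direction.
#' @export
screenResponsive <- function(records, fcThreshold = 1.0, pThreshold = 0.05) {
  records$fdrBH <- p.adjust(records$p, method = "BH")
  records$responsive <- !records$excluded &
    !is.na(records$log2fc) &
    abs(records$log2fc) >= fcThreshold &
    records$p <= pThreshold
  records$direction <- ifelse(!records$responsive, NA_character_,
                              ifelse(records$log2fc > 0, "up", "down"))
  records[order(-records$responsive, records$log2fc * -1), ]
}

#' Differential expression of miRNAs between two libraries
#'
#' Driver: combines known and novel miRNA count tables, normalises to TPM,
#' applies the zero-revision and low-expression rules, computes log2 fold
#' change and the exact two-library p-value, and screens responsive miRNAs.
#'
#' @param counts `data.frame` with `id`, `countCS`, `countTS` (and
#'   optionally `sequence`).
#' @param totalCS,totalTS total clean reads per library.
#' @param fcThreshold,pThreshold screening thresholds, see
#'   [screenResponsive()].
#' @return `data.frame` with one row per miRNA, Table-style columns
#'   (`sequence` in the U alphabet when sequences are supplied).
#' @export
diffExpression <- function(counts, totalCS, totalTS,
                           fcThreshold = 1.0, pThreshold = 0.05) {
  rec <- data.frame(id = counts$id, x = counts$countCS, y = counts$countTS,
                    stringsAsFactors = FALSE)
  if (!is.null(counts$sequence)) rec$sequence <- dnaToRna(counts$sequence)
  rec <- normalizeAndAdjust(rec, totalCS, totalTS)
  rec <- log2FoldChange(rec)
  rec$p <- NA_real_
  ok <- !rec$excluded
  if (any(ok))
    rec$p[ok] <- audicClaverie(rec$x[ok], rec$y[ok], totalCS, totalTS)
  screenResponsive(rec, fcThreshold, pThreshold)
}

#' Write the differential expression table
#'
#' TSV mirroring the screened table layout (sequence, name, Log2(T/C),
#' p-value, responsive flag), with the active thresholds echoed in header
#' comments.
#'
#' @param records output of [diffExpression()].
#' @param path output file.
#' @param fcThreshold,pThreshold thresholds to echo.
#' @return invisibly, the path.
#' @export
writeDiffexp <- function(records, path, fcThreshold = 1.0, pThreshold = 0.05) {
  cols <- intersect(c("sequence", "id", "x", "y", "tpmCSAdj", "tpmTSAdj",
                      "log2fc", "p", "fdrBH", "excluded", "responsive",
                      "direction"), colnames(records))
  .writeTsv(records[, cols],
            path,
            comments = c(sprintf("fold-change threshold |log2fc| >= %g", fcThreshold),
                         sprintf("p-value threshold <= %g", pThreshold),
                         "p: two-sided Audic-Claverie tail; fdrBH: Benjamini-Hochberg"))
}
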