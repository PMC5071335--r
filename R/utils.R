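#' @useDynLib miRcascade, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rmultinom runif setNames p.adjust phyper
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA character vectors
#'
#' Thin character-vector wrapper used throughout the package; sequences are
#' stored as DNA (T, not U) internally.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @examples
#' revComp("ACGT")
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert between DNA and RNA alphabets
#'
#' @param x character vector of sequences.
#' @return character vector with T<->U swapped (case preserved).
#' @examples
#' dnaToRna("ACGT")
#' rnaToDna("ACGU")
#' @export
dnaToRna <- function(x) chartr("Tt", "Uu", x)

#' @rdname dnaToRna
#' @export
rnaToDna <- function(x) chartr("Uu", "Tt", x)

#' Round half away from zero
#'
#' Percentage bookkeeping in reports uses commercial rounding (0.5 always
#' rounds away from zero) rather than banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' roundHalfAway(0.125, 2)
#' @export
roundHalfAway <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Format a percentage the way sequencing reports print it
#'
#' Computes `100 * numerator / denominator`, rounded half away from zero to
#' two decimals. A zero denominator yields "0.00" rather than an error.
#'
#' @param num numerator count.
#' @param den denominator count.
#' @param digits decimal places (default 2).
#' @param suffix append a percent sign (default FALSE).
#' @return character vector of formatted percentages.
#' @examples
#' formatPercent(17811109, 18220106)  # "97.76"
#' @export
formatPercent <- function(num, den, digits = 2, suffix = FALSE) {
  n <- max(length(num), length(den))
  num <- rep_len(num, n)
  den <- rep_len(den, n)
  p <- ifelse(den == 0, 0, 100 * num / den)
  out <- sprintf(paste0("%.", digits, "f"), roundHalfAway(p, digits))
  if (suffix) out <- paste0(out, "%")
  out
}

#' Fold an RNA/DNA sequence into its minimum-free-energy secondary structure
#'
#' The default engine is the package's dynamic-programming folder over a
#' simplified nearest-neighbour energy model (Watson-Crick and G:U pairs,
#' stacking energies, tabulated hairpin/bulge/interior-loop penalties,
#' exterior-loop bifurcation). It is deterministic and returns nested
#' structures only. An external engine can be substituted via `engine`; it
#' must accept a single sequence and return `list(structure=, mfe=)` with a
#' balanced dot-bracket string of the same length.
#'
#' @param x character vector of sequences (DNA or RNA alphabet).
#' @param engine `"internal"` or a function implementing the engine contract.
#' @return for a single sequence, `list(structure, mfe)`; for several, a list
#'   of such lists.
#' @examples
#' foldRNA("GGGGGGAAAACCCCCC")
#' @export
foldRNA <- function(x, engine = "internal") {
  fold1 <- if (is.function(engine)) {
    engine
  } else if (identical(engine, "internal")) {
    function(s) .fold_rna(s)
  } else {
    stop("unknown folding engine: ", engine)
  }
  res <- lapply(as.character(x), function(s) {
    r <- fold1(s)
    stopifnot(nchar(r$structure) == nchar(s))
    r
  })
  if (length(res) == 1L) res[[1]] else res
}

#' Base-pair table from a dot-bracket string
#'
#' @param db dot-bracket string (balanced, nested).
#' @return integer vector `p` with `p[i]` the 1-based partner of base `i`,
#'   or `NA` if unpaired.
#' @examples
#' pairTable("((..))")
#' @export
pairTable <- function(db) {
  ch <- strsplit(db, "")[[1]]
  n <- length(ch)
  p <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[i] <- j
      p[j] <- i
    } else if (ch[i] != ".") {
      stop("invalid character in dot-bracket string: ", ch[i])
    }
  }
  if (length(stack) > 0L) stop("unbalanced dot-bracket string")
  p
}

# derive a 32-bit sub-seed deterministically from a base seed and a tag
.subSeed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

.writeTsv <- function(df, path, comments = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
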