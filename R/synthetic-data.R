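#' Ground truth of a synthetic small RNA study
#'
#' Container for everything the generator planted: the genome, miRNA
#' hairpins with their loci and per-miRNA fold changes, structured ncRNAs,
#' gene models and transcripts, multi-copy decoy tags, planted target sites,
#' the GO map and the PPI edge list.
#'
#' @slot config the [SrnaSimConfig-class] the truth was generated from.
#' @slot genome named `DNAStringSet` of toy chromosomes.
#' @slot mirnas planted miRNAs: id, mature, star, precursor, locus, arm,
#'   known flag, linear fold change, genomic mature coordinates.
#' @slot ncrnas planted structured ncRNAs (class, sequence, locus).
#' @slot genes,exons gene models (1-based closed genomic intervals).
#' @slot decoys multi-copy decoy tags (id, sequence, copies planted).
#' @slot targets planted perfect-complement target sites (miRNA, gene).
#' @slot goMap gene-to-GO-term map (long format).
#' @slot ppi protein-protein interaction edges (geneA, geneB, score).
#' @slot tfGenes genes flagged as transcription factors.
#' @slot transcripts named character vector of spliced transcripts (one per
#'   gene, 5' to 3').
#' @export
setClass("GroundTruth",
  representation(
    config = "SrnaSimConfig",
    genome = "DNAStringSet",
    mirnas = "data.frame",
    ncrnas = "data.frame",
    genes = "data.frame",
    exons = "data.frame",
    decoys = "data.frame",
    targets = "data.frame",
    goMap = "data.frame",
    ppi = "data.frame",
    tfGenes = "character",
    transcripts = "character"
  )
)

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth\n")
  cat(sprintf("  genome: %d chromosomes, %d nt total\n",
              length(object@genome), sum(Biostrings::width(object@genome))))
  cat(sprintf("  planted: %d miRNAs (%d known), %d ncRNAs, %d genes, %d target sites\n",
              nrow(object@mirnas), sum(object@mirnas$known),
              nrow(object@ncrnas), nrow(object@genes), nrow(object@targets)))
})

#' True responsive miRNA ids of a ground truth
#'
#' miRNAs whose planted linear fold change satisfies |log2 fold| >= 1.
#'
#' @param truth a [GroundTruth-class].
#' @return character vector of miRNA ids.
#' @export
trueResponsive <- function(truth) {
  m <- truth@mirnas
  m$id[abs(log2(m$fold)) >= 1]
}

# interval registry: place a feature of length len on a random chromosome
# without overlapping previously placed features (10 nt margin)
.makeRegistry <- function(chromLens) {
  env <- new.env(parent = emptyenv())
  env$occ <- lapply(chromLens, function(x) matrix(numeric(0), ncol = 2))
  env$lens <- chromLens
  env
}

.place <- function(reg, len, what, maxTry = 500L) {
  for (t in seq_len(maxTry)) {
    ch <- sample.int(length(reg$lens), 1L)
    if (reg$lens[ch] < len + 2L) next
    st <- sample.int(reg$lens[ch] - len + 1L, 1L)
    en <- st + len - 1L
    occ <- reg$occ[[ch]]
    if (nrow(occ) == 0L || all(en + 10 < occ[, 1] | st - 10 > occ[, 2])) {
      reg$occ[[ch]] <- rbind(occ, c(st, en))
      return(list(chrom = ch, start = st, end = en))
    }
  }
  stop(sprintf("planting collision after %d retries while placing %s (%d nt)",
               maxTry, what, len))
}

.randSeq <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

.mutate <- function(seq, k) {
  if (k == 0L) return(seq)
  v <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(v), k)
  for (p in pos) v[p] <- sample(setdiff(DNA_BASES, v[p]), 1L)
  paste(v, collapse = "")
}

# build one hairpin around a mature sequence; rejection-sample the loop /
# star mismatches until the designed precursor passes the evaluation
# criteria with an MFE margin, so that re-discovery from wider excised
# windows remains robust
.designHairpin <- function(mature, arm, criteria, maxTry = 60L) {
  for (t in seq_len(maxTry)) {
    ext <- .randSeq(sample(12:22, 1L))
    loop <- .randSeq(sample(12:18, 1L))
    star <- .mutate(revComp(mature), sample(0:2, 1L))
    prec <- if (arm == "5p") {
      paste0(ext, mature, loop, star, revComp(ext))
    } else {
      paste0(ext, star, loop, mature, revComp(ext))
    }
    mS <- if (arm == "5p") nchar(ext) + 1L
          else nchar(ext) + nchar(star) + nchar(loop) + 1L
    mE <- mS + nchar(mature) - 1L
    f <- foldRNA(prec)
    ev <- evaluateHairpin(prec, f$structure, f$mfe, mS, mE, criteria)
    if (ev$passes && f$mfe <= criteria@mfeThreshold - 7) {
      return(list(precursor = prec, star = ev$star, matureStart = mS,
                  matureEnd = mE, mfe = f$mfe))
    }
  }
  NULL
}

#' Generate the synthetic reference dataset
#'
#' Builds a self-consistent toy study with known ground truth: a random
#' genome into which miRNA hairpins (mature + loop + near-reverse-complement
#' star, rejection-sampled until the fold passes the default hairpin
#' criteria), structured ncRNAs, gene models, multi-copy decoy tags, and
#' perfect-complement miRNA target sites are planted at non-overlapping
#' loci. The first `nKnown` miRNAs are labelled "known" (they form the
#' mature/hairpin reference); the rest are left for novel discovery.
#' Deterministic for a fixed seed.
#'
#' @param config a [SrnaSimConfig-class].
#' @param criteria [HairpinCriteria-class] the planted hairpins must satisfy.
#' @return a [GroundTruth-class].
#' @examples
#' truth <- simulateReference(SrnaSimConfig(seed = 1, nMirnas = 4,
#'   nKnown = 2, nNcrnas = 2, nGenes = 4, chromosomeLength = 20000))
#' truth
#' @export
simulateReference <- function(config, criteria = HairpinCriteria()) {
  set.seed(config@seed)
  nChr <- config@nChromosomes
  chromLens <- rep(config@chromosomeLength, nChr)
  chromNames <- paste0("chr", seq_len(nChr))
  genome <- lapply(chromLens, function(L) sample(DNA_BASES, L, replace = TRUE))
  reg <- .makeRegistry(chromLens)

  plant <- function(seq, where) {
    v <- strsplit(seq, "")[[1]]
    genome[[where$chrom]][where$start:where$end] <<- v
  }

  # --- miRNA hairpins -----------------------------------------------------
  mirnas <- NULL
  if (config@nMirnas > 0L) {
    rows <- vector("list", config@nMirnas)
    for (i in seq_len(config@nMirnas)) {
      id <- paste0("mir_", i)
      matureLen <- sample(20:24, 1L, prob = c(.1, .5, .15, .1, .15))
      first <- sample(c("C", "T", "A", "G"), 1L, prob = c(.45, .3, .15, .1))
      mature <- paste0(first, .randSeq(matureLen - 1L))
      arm <- sample(c("5p", "3p"), 1L)
      hp <- NULL
      for (redo in 1:20) {
        hp <- .designHairpin(mature, arm, criteria)
        if (!is.null(hp)) break
        mature <- paste0(first, .randSeq(matureLen - 1L))
      }
      if (is.null(hp))
        stop("could not design a qualifying hairpin for ", id)
      loc <- .place(reg, nchar(hp$precursor), id)
      strand <- sample(c("+", "-"), 1L)
      plant(if (strand == "+") hp$precursor else revComp(hp$precursor), loc)
      if (strand == "+") {
        mS <- loc$start + hp$matureStart - 1L
        mE <- loc$start + hp$matureEnd - 1L
      } else {
        mS <- loc$end - hp$matureEnd + 1L
        mE <- loc$end - hp$matureStart + 1L
      }
      fold <- if (id %in% names(config@foldChange)) config@foldChange[[id]] else 1
      rows[[i]] <- data.frame(
        id = id, mature = mature, star = hp$star, precursor = hp$precursor,
        chrom = chromNames[loc$chrom], start = loc$start, end = loc$end,
        strand = strand, arm = arm, known = i <= config@nKnown, fold = fold,
        matureStart = mS, matureEnd = mE, mfe = hp$mfe,
        stringsAsFactors = FALSE)
    }
    mirnas <- do.call(rbind, rows)
  } else {
    mirnas <- data.frame(id = character(0), mature = character(0),
                         star = character(0), precursor = character(0),
                         chrom = character(0), start = integer(0),
                         end = integer(0), strand = character(0),
                         arm = character(0), known = logical(0),
                         fold = numeric(0), matureStart = integer(0),
                         matureEnd = integer(0), mfe = numeric(0),
                         stringsAsFactors = FALSE)
  }

  # --- structured ncRNAs --------------------------------------------------
  ncClasses <- c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA")
  ncrnas <- if (config@nNcrnas > 0L) {
    rows <- lapply(seq_len(config@nNcrnas), function(i) {
      cls <- ncClasses[(i - 1L) %% length(ncClasses) + 1L]
      seq <- .randSeq(sample(80:150, 1L))
      loc <- .place(reg, nchar(seq), paste0("ncrna_", i))
      plant(seq, loc)
      data.frame(id = sprintf("nc_%s_%d", cls, i), class = cls, seq = seq,
                 chrom = chromNames[loc$chrom], start = loc$start,
                 end = loc$end, strand = "+", stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  } else {
    data.frame(id = character(0), class = character(0), seq = character(0),
               chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), stringsAsFactors = FALSE)
  }

  # --- multi-copy decoy tags (one above, one at the multi-hit limit) ------
  decoys <- data.frame(id = character(0), seq = character(0),
                       copies = integer(0), stringsAsFactors = FALSE)
  if (config@nMirnas > 0L) {
    for (d in list(c("decoy_over", 12L), c("decoy_limit", 10L))) {
      seq <- .randSeq(22L)
      nc <- as.integer(d[2])
      for (k in seq_len(nc)) {
        loc <- .place(reg, 22L, d[1])
        plant(seq, loc)
      }
      decoys <- rbind(decoys, data.frame(id = d[1], seq = seq, copies = nc,
                                         stringsAsFactors = FALSE))
    }
  }

  # --- gene models --------------------------------------------------------
  genes <- exons <- NULL
  if (config@nGenes > 0L) {
    grows <- vector("list", config@nGenes)
    erows <- list()
    for (j in seq_len(config@nGenes)) {
      gid <- sprintf("gene%02d", j)
      nEx <- sample(2:3, 1L)
      exLens <- sample(200:400, nEx, replace = TRUE)
      inLens <- sample(100:200, nEx - 1L, replace = TRUE)
      span <- sum(exLens) + sum(inLens)
      loc <- .place(reg, span, gid)
      strand <- sample(c("+", "-"), 1L)
      pos <- loc$start
      for (e in seq_len(nEx)) {
        erows[[length(erows) + 1L]] <- data.frame(
          gene = gid, rank = e, chrom = chromNames[loc$chrom],
          start = pos, end = pos + exLens[e] - 1L, strand = strand,
          stringsAsFactors = FALSE)
        pos <- pos + exLens[e] + if (e < nEx) inLens[e] else 0L
      }
      grows[[j]] <- data.frame(gene = gid, chrom = chromNames[loc$chrom],
                               start = loc$start, end = loc$end,
                               strand = strand, stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, grows)
    exons <- do.call(rbind, erows)
  } else {
    genes <- data.frame(gene = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), stringsAsFactors = FALSE)
    exons <- data.frame(gene = character(0), rank = integer(0),
                        chrom = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        stringsAsFactors = FALSE)
  }

  # --- planted target sites (known responsive miRNAs only, so that novel
  # matures never acquire exonic loci that would outrank them in the
  # annotation cascade) ----------------------------------------------------
  targets <- data.frame(mirna = character(0), gene = character(0),
                        stringsAsFactors = FALSE)
  if (nrow(mirnas) > 0L && nrow(genes) > 0L) {
    respKnown <- mirnas$id[mirnas$known & abs(log2(mirnas$fold)) >= 1]
    pool <- genes$gene
    usedWindows <- list()
    for (mid in respKnown) {
      mat <- mirnas$mature[mirnas$id == mid]
      ngenes <- min(2L, length(pool))
      if (ngenes == 0L) break
      gsel <- sample(pool, ngenes)
      pool <- setdiff(pool, gsel)
      for (g in gsel) {
        ex <- exons[exons$gene == g, , drop = FALSE]
        ex <- ex[which.max(ex$end - ex$start), , drop = FALSE]
        wlen <- nchar(mat)
        st <- ex$start + sample.int(ex$end - ex$start - wlen - 20L, 1L) + 10L
        site <- if (ex$strand == "+") revComp(mat) else mat
        ch <- match(ex$chrom, chromNames)
        genome[[ch]][st:(st + wlen - 1L)] <- strsplit(site, "")[[1]]
        targets <- rbind(targets, data.frame(mirna = mid, gene = g,
                                             stringsAsFactors = FALSE))
      }
    }
  }

  # --- GO map and PPI -----------------------------------------------------
  goMap <- data.frame(gene = character(0), term = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(genes) > 0L) {
    terms <- sprintf("GO:%07d", 1:15)
    rows <- lapply(genes$gene, function(g) {
      data.frame(gene = g, term = sample(terms, sample(2:4, 1L)),
                 stringsAsFactors = FALSE)
    })
    goMap <- do.call(rbind, rows)
    if (nrow(targets) > 0L) {
      goMap <- rbind(goMap, data.frame(gene = unique(targets$gene),
                                       term = "GO:0099999",
                                       stringsAsFactors = FALSE))
    }
    goMap <- goMap[order(goMap$gene, goMap$term), ]
    rownames(goMap) <- NULL
  }

  ppi <- data.frame(geneA = character(0), geneB = character(0),
                    score = numeric(0), stringsAsFactors = FALSE)
  tfGenes <- character(0)
  if (nrow(genes) >= 2L) {
    hub <- if (nrow(targets) > 0L) targets$gene[1] else genes$gene[1]
    partners <- setdiff(genes$gene, hub)
    partners <- head(partners, 24L)
    ppi <- data.frame(geneA = rep(hub, length(partners)), geneB = partners,
                      score = roundHalfAway(runif(length(partners), .4, .99), 3),
                      stringsAsFactors = FALSE)
    extra <- 15L
    others <- setdiff(genes$gene, hub)
    if (length(others) >= 2L) {
      for (k in seq_len(extra)) {
        pr <- sort(sample(others, 2L))
        ppi <- rbind(ppi, data.frame(geneA = pr[1], geneB = pr[2],
                                     score = roundHalfAway(runif(1, .4, .99), 3),
                                     stringsAsFactors = FALSE))
      }
    }
    sw <- ppi$geneA > ppi$geneB
    tmp <- ppi$geneA[sw]; ppi$geneA[sw] <- ppi$geneB[sw]; ppi$geneB[sw] <- tmp
    ppi <- ppi[!duplicated(ppi[, 1:2]), ]
    rownames(ppi) <- NULL
    tfGenes <- head(unique(targets$gene), 4L)
  }

  genomeSet <- Biostrings::DNAStringSet(vapply(genome, paste,
                                               character(1), collapse = ""))
  names(genomeSet) <- chromNames

  # --- spliced transcripts (after all planting) ---------------------------
  transcripts <- character(0)
  if (nrow(genes) > 0L) {
    transcripts <- vapply(genes$gene, function(g) {
      ex <- exons[exons$gene == g, , drop = FALSE]
      ex <- ex[order(ex$rank), , drop = FALSE]
      seqs <- vapply(seq_len(nrow(ex)), function(e)
        as.character(Biostrings::subseq(genomeSet[[ex$chrom[e]]],
                                        ex$start[e], ex$end[e])),
        character(1))
      tx <- paste(seqs, collapse = "")
      if (ex$strand[1] == "-") tx <- revComp(tx)
      tx
    }, character(1))
    names(transcripts) <- genes$gene
  }

  new("GroundTruth", config = config, genome = genomeSet, mirnas = mirnas,
      ncrnas = ncrnas, genes = genes, exons = exons, decoys = decoys,
      targets = targets, goMap = goMap, ppi = ppi, tfGenes = tfGenes,
      transcripts = transcripts)
}

.writeFasta <- function(seqs, names, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names[i]), con)
    s <- seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write the synthetic reference files
#'
#' Emits the standard-format inputs the pipeline consumes: `genome.fa`,
#' `genes.gff3` (1-based closed intervals), `ncrna.fa`, `mirna_mature.fa`
#' and `mirna_hairpin.fa` (known subset only), `go_map.tsv`, `ppi.tsv`,
#' `tf_list.txt` and `truth.tsv`.
#'
#' @param truth a [GroundTruth-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
writeSyntheticData <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(dir, f)
  .writeFasta(as.character(truth@genome), names(truth@genome), pth("genome.fa"))
  nc <- truth@ncrnas
  .writeFasta(nc$seq, paste0(nc$class, "|", nc$id), pth("ncrna.fa"))
  kn <- truth@mirnas[truth@mirnas$known, , drop = FALSE]
  .writeFasta(kn$mature, kn$id, pth("mirna_mature.fa"))
  .writeFasta(kn$precursor, kn$id, pth("mirna_hairpin.fa"))

  # GFF3, written directly (1-based closed intervals)
  con <- file(pth("genes.gff3"), "w")
  writeLines("##gff-version 3", con)
  for (j in seq_len(nrow(truth@genes))) {
    g <- truth@genes[j, ]
    writeLines(sprintf("%s\tmiRcascade\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, g$start, g$end, g$strand, g$gene), con)
    writeLines(sprintf("%s\tmiRcascade\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
                       g$chrom, g$start, g$end, g$strand, g$gene, g$gene), con)
    ex <- truth@exons[truth@exons$gene == g$gene, , drop = FALSE]
    for (e in seq_len(nrow(ex))) {
      writeLines(sprintf("%s\tmiRcascade\texon\t%d\t%d\t.\t%s\t.\tID=%s.1.exon%d;Parent=%s.1",
                         ex$chrom[e], ex$start[e], ex$end[e], ex$strand[e],
                         g$gene, ex$rank[e], g$gene), con)
    }
  }
  close(con)

  .writeTsv(truth@goMap, pth("go_map.tsv"))
  .writeTsv(truth@ppi, pth("ppi.tsv"))
  writeLines(truth@tfGenes, pth("tf_list.txt"))
  tt <- truth@mirnas[, c("id", "mature", "chrom", "start", "end", "strand",
                         "arm", "known", "fold")]
  .writeTsv(tt, pth("truth.tsv"))
  .writeFasta(truth@transcripts, names(truth@transcripts), pth("transcripts.fa"))
  invisible(c(genome = pth("genome.fa"), gff3 = pth("genes.gff3"),
              ncrna = pth("ncrna.fa"), mature = pth("mirna_mature.fa"),
              hairpin = pth("mirna_hairpin.fa"), go = pth("go_map.tsv"),
              ppi = pth("ppi.tsv"), tf = pth("tf_list.txt"),
              truth = pth("truth.tsv"), transcripts = pth("transcripts.fa")))
}

# peaked insert length distribution: 24 nt dominant, then 21 nt
.fragLen <- function(n, range) {
  lens <- range[1]:range[2]
  w <- rep(1, length(lens))
  w[lens == 24] <- 10
  w[lens == 21] <- 4
  w[lens == 22] <- 2
  sample(lens, n, replace = TRUE, prob = w)
}

#' Simulate the two sequencing libraries
#'
#' Draws reads for the control (CS) and treated (TS) libraries from a shared
#' signal table: planted mature miRNAs (TS expectation = CS expectation times
#' the configured fold change), ncRNA fragments, degradation fragments from
#' genes and intergenic regions (24-nt dominant, then 21-nt), and the decoy
#' tags. Each genuine insert carries the 3' adapter and constant "I" quality;
#' a `noiseFraction` share of random adapter-free reads is appended. Library
#' counts are multinomial draws, so every non-noise read maps perfectly to
#' the genome when the error rate is 0. The realised per-sequence counts are
#' written alongside the FASTQ files as `expected_counts.tsv` for use as a
#' test oracle.
#'
#' @param config the [SrnaSimConfig-class] the truth was generated from.
#' @param truth the matching [GroundTruth-class].
#' @param dir output directory.
#' @return invisibly, a list with `expected` (data.frame sequence/countCS/
#'   countTS), `fastqCS`, `fastqTS` (paths), and `meanExpected` (the
#'   multinomial expectations used for the draw).
#' @export
simulateLibraries <- function(config, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(.subSeed(config@seed, 7L))
  sig <- .signalTable(config, truth)

  drawLib <- function(depth, weights) {
    nNoise <- as.integer(round(config@noiseFraction * depth))
    nSig <- depth - nNoise
    counts <- if (nSig > 0L && nrow(sig) > 0L)
      as.integer(rmultinom(1L, nSig, weights)) else integer(nrow(sig))
    list(counts = counts, nNoise = nNoise)
  }
  cs <- drawLib(config@depthCS, sig$wCS)
  ts <- drawLib(config@depthTS, sig$wTS)

  writeLib <- function(counts, nNoise, path) {
    inserts <- rep(sig$sequence, counts)
    L <- config@readLength
    reads <- vapply(inserts, function(s) {
      r <- paste0(s, config@adapter)
      if (nchar(r) >= L) substr(r, 1L, L)
      else paste0(r, paste(rep("A", L - nchar(r)), collapse = ""))
    }, character(1), USE.NAMES = FALSE)
    if (nNoise > 0L)
      reads <- c(reads, vapply(seq_len(nNoise), function(i) .randSeq(L),
                               character(1)))
    if (length(reads) > 1L) reads <- reads[sample.int(length(reads))]
    if (config@errorRate > 0 && length(reads) > 0L) {
      reads <- vapply(reads, function(r) {
        v <- strsplit(r, "")[[1]]
        hit <- runif(length(v)) < config@errorRate
        for (p in which(hit)) v[p] <- sample(setdiff(DNA_BASES, v[p]), 1L)
        paste(v, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    con <- file(path, "w")
    qual <- paste(rep("I", L), collapse = "")
    if (length(reads) > 0L) {
      recs <- rbind(paste0("@read_", seq_along(reads)), reads, "+", qual)
      writeLines(as.vector(recs), con)
    }
    close(con)
    path
  }
  fq1 <- writeLib(cs$counts, cs$nNoise, file.path(dir, "reads_cs.fastq"))
  fq2 <- writeLib(ts$counts, ts$nNoise, file.path(dir, "reads_ts.fastq"))

  expected <- data.frame(sequence = sig$sequence, countCS = cs$counts,
                         countTS = ts$counts, stringsAsFactors = FALSE)
  expected <- stats::aggregate(cbind(countCS, countTS) ~ sequence,
                               data = expected, FUN = sum)
  expected <- expected[expected$countCS + expected$countTS > 0, ]
  expected <- expected[order(expected$sequence), ]
  rownames(expected) <- NULL
  .writeTsv(expected, file.path(dir, "expected_counts.tsv"))

  nSigCS <- config@depthCS - as.integer(round(config@noiseFraction * config@depthCS))
  nSigTS <- config@depthTS - as.integer(round(config@noiseFraction * config@depthTS))
  meanExpected <- data.frame(
    sequence = sig$sequence, class = sig$class, id = sig$id,
    meanCS = nSigCS * sig$wCS / sum(sig$wCS),
    meanTS = nSigTS * sig$wTS / sum(sig$wTS),
    stringsAsFactors = FALSE)
  invisible(list(expected = expected, fastqCS = fq1, fastqTS = fq2,
                 meanExpected = meanExpected))
}

# the shared signal table: one row per distinct planted insert with
# per-library sampling weights
.signalTable <- function(config, truth) {
  rows <- list()
  m <- truth@mirnas
  if (nrow(m) > 0L) {
    base <- exp(runif(nrow(m), log(50), log(2000)))
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = m$mature, class = "miRNA", id = m$id,
      wCS = base, wTS = base * m$fold, stringsAsFactors = FALSE)
  }
  nc <- truth@ncrnas
  if (nrow(nc) > 0L) {
    frs <- lapply(seq_len(nrow(nc)), function(i) {
      k <- 3L
      lens <- .fragLen(k, config@readLengthRange)
      offs <- vapply(lens, function(l)
        sample.int(nchar(nc$seq[i]) - l + 1L, 1L), integer(1))
      w <- runif(k, 20, 200)
      data.frame(sequence = substring(nc$seq[i], offs, offs + lens - 1L),
                 class = nc$class[i], id = nc$id[i], wCS = w, wTS = w,
                 stringsAsFactors = FALSE)
    })
    rows[[length(rows) + 1L]] <- do.call(rbind, frs)
  }
  # degradation fragments: exons, introns and intergenic, both strands;
  # they carry enough weight that the 24-nt peak of the fragment length
  # distribution dominates the library over the (mostly 21-nt) miRNAs
  nFrag <- 400L
  if (length(truth@genome) > 0L && nFrag > 0L) {
    lens <- .fragLen(nFrag, config@readLengthRange)
    frs <- lapply(seq_len(nFrag), function(i) {
      l <- lens[i]
      src <- sample(c("exon", "intron", "intergenic"), 1L,
                    prob = c(.5, .25, .25))
      if (src == "exon" && nrow(truth@exons) > 0L) {
        e <- truth@exons[sample.int(nrow(truth@exons), 1L), ]
        st <- e$start + sample.int(max(1L, e$end - e$start - l), 1L) - 1L
        ch <- e$chrom
      } else if (src == "intron" && nrow(truth@genes) > 0L) {
        g <- truth@genes[sample.int(nrow(truth@genes), 1L), ]
        ex <- truth@exons[truth@exons$gene == g$gene, ]
        ex <- ex[order(ex$start), ]
        if (nrow(ex) > 1L) {
          k <- sample.int(nrow(ex) - 1L, 1L)
          ilo <- ex$end[k] + 1L; ihi <- ex$start[k + 1L] - 1L
          if (ihi - ilo + 1L >= l) {
            st <- ilo + sample.int(ihi - ilo - l + 2L, 1L) - 1L
            ch <- g$chrom
          } else { st <- NA }
        } else st <- NA
        if (is.na(st)) {
          ch <- names(truth@genome)[sample.int(length(truth@genome), 1L)]
          st <- sample.int(Biostrings::width(truth@genome[ch]) - l, 1L)
        }
      } else {
        ch <- names(truth@genome)[sample.int(length(truth@genome), 1L)]
        st <- sample.int(Biostrings::width(truth@genome[ch]) - l, 1L)
      }
      s <- as.character(Biostrings::subseq(truth@genome[[ch]], st, st + l - 1L))
      if (runif(1) < 0.5) s <- revComp(s)
      w <- runif(1, 50, 400)   # background, not treatment-responsive
      data.frame(sequence = s, class = "degradation", id = sprintf("frag_%d", i),
                 wCS = w, wTS = w,
                 stringsAsFactors = FALSE)
    })
    rows[[length(rows) + 1L]] <- do.call(rbind, frs)
  }
  if (nrow(truth@decoys) > 0L) {
    rows[[length(rows) + 1L]] <- data.frame(
      sequence = truth@decoys$seq, class = "decoy", id = truth@decoys$id,
      wCS = 30, wTS = 30, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(sequence = character(0), class = character(0),
                      id = character(0), wCS = numeric(0), wTS = numeric(0)))
  tab <- do.call(rbind, rows)
  # drop accidental duplicates of planted matures among fragments
  tab <- tab[!duplicated(tab$sequence) | tab$class == "miRNA", ]
  tab <- tab[!(duplicated(tab$sequence, fromLast = TRUE) & tab$class != "miRNA"), ]
  rownames(tab) <- NULL
  tab
}
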