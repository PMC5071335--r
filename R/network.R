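#' Build the miRNA-mediated regulatory network
#'
#' Nodes are the responsive miRNAs and the proteins encoded by their
#' predicted target genes; targeting edges come from the target table, and
#' PPI edges are kept only when both endpoints are in the node set (stored
#' with canonically ordered endpoints). PPI edges referencing genes outside
#' the node set are dropped (a count is recorded in the result's metadata
#' surrogate column behaviour; see `attr(net, "droppedPpi")`).
#'
#' @param responsive `data.frame` with `id` and `log2fc` of responsive
#'   miRNAs (e.g. the responsive rows of [diffExpression()] output).
#' @param targets `data.frame` with `mirna` and `gene` (predicted targets).
#' @param ppi `data.frame` with `geneA`, `geneB`, `score`.
#' @param tfList character vector of transcription-factor gene ids.
#' @return a [RegulatoryNetwork-class]; the number of dropped PPI edges is
#'   attached as attribute `droppedPpi`.
#' @export
buildNetwork <- function(responsive, targets, ppi = NULL, tfList = character(0)) {
  targets <- targets[targets$mirna %in% responsive$id, , drop = FALSE]
  mirIds <- unique(responsive$id)
  protIds <- unique(targets$gene)
  nodes <- S4Vectors::DataFrame(
    id = c(mirIds, protIds),
    type = c(rep("miRNA", length(mirIds)), rep("protein", length(protIds))),
    log2fc = c(responsive$log2fc[match(mirIds, responsive$id)],
               rep(NA_real_, length(protIds))),
    isTF = c(rep(FALSE, length(mirIds)), protIds %in% tfList))
  tEdges <- unique(targets[, c("mirna", "gene")])
  edges <- S4Vectors::DataFrame(
    source = tEdges$mirna, target = tEdges$gene,
    kind = rep("targeting", nrow(tEdges)), score = rep(NA_real_, nrow(tEdges)))
  dropped <- 0L
  if (!is.null(ppi) && nrow(ppi) > 0L) {
    a <- pmin(ppi$geneA, ppi$geneB)
    b <- pmax(ppi$geneA, ppi$geneB)
    keep <- a %in% protIds & b %in% protIds & a != b
    dropped <- sum(!keep)
    if (dropped > 0L)
      warning(dropped, " PPI edge(s) reference proteins outside the network and were dropped")
    pe <- unique(data.frame(source = a[keep], target = b[keep],
                            score = ppi$score[keep],
                            stringsAsFactors = FALSE))
    pe <- pe[!duplicated(pe[, c("source", "target")]), , drop = FALSE]
    if (nrow(pe) > 0L)
      edges <- rbind(edges, S4Vectors::DataFrame(
        source = pe$source, target = pe$target,
        kind = rep("ppi", nrow(pe)), score = pe$score))
  }
  net <- methods::new("RegulatoryNetwork", nodes = nodes, edges = edges)
  attr(net, "droppedPpi") <- dropped
  net
}

#' Degree summaries of the regulatory network
#'
#' Protein degree counts PPI edges only; miRNA out-degree counts targeting
#' edges. Both tables are sorted by decreasing degree.
#'
#' @param net a [RegulatoryNetwork-class].
#' @return list with `ppiDegree` (`data.frame` id/isTF/degree) and
#'   `mirnaOutDegree` (`data.frame` id/targets).
#' @export
degreeSummary <- function(net) {
  nd <- as.data.frame(networkNodes(net))
  ed <- as.data.frame(networkEdges(net))
  prot <- nd$id[nd$type == "protein"]
  ppi <- ed[ed$kind == "ppi", , drop = FALSE]
  deg <- vapply(prot, function(p)
    sum(ppi$source == p) + sum(ppi$target == p), integer(1))
  ppiDegree <- data.frame(id = prot, isTF = nd$isTF[match(prot, nd$id)],
                          degree = deg, stringsAsFactors = FALSE)
  ppiDegree <- ppiDegree[order(-ppiDegree$degree, ppiDegree$id), ]
  rownames(ppiDegree) <- NULL
  mir <- nd$id[nd$type == "miRNA"]
  tgt <- ed[ed$kind == "targeting", , drop = FALSE]
  out <- data.frame(id = mir,
                    targets = vapply(mir, function(m)
                      sum(tgt$source == m), integer(1)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$targets, out$id), ]
  rownames(out) <- NULL
  list(ppiDegree = ppiDegree, mirnaOutDegree = out)
}

#' GO term over-representation of a target gene set
#'
#' One-sided Fisher exact (hypergeometric upper tail) per GO term with at
#' least one target gene, against a background gene universe. Bonferroni
#' correction is applied over the tested terms and Benjamini-Hochberg FDR is
#' computed alongside; a term is significant when both adjusted values pass
#' their thresholds (default 0.01 each).
#'
#' @param targetGenes character vector of target gene ids.
#' @param goMap `data.frame` with `gene` and `term` (flat map; no ancestry
#'   propagation is performed).
#' @param background character vector of background gene ids (must contain
#'   all target genes).
#' @param pCut,fdrCut significance thresholds.
#' @return `data.frame`: `term`, `k` (targets in term), `n` (target-set
#'   size), `K` (background genes in term), `N` (background size), `pRaw`,
#'   `pBonferroni`, `fdrBH`, `significant`; sorted by `pRaw`.
#' @export
goEnrichment <- function(targetGenes, goMap, background,
                         pCut = 0.01, fdrCut = 0.01) {
  if (length(background) == 0L) stop("background gene set is empty")
  background <- unique(background)
  targetGenes <- unique(targetGenes)
  if (!all(targetGenes %in% background))
    stop("background must contain all target genes")
  goMap <- goMap[goMap$gene %in% background, , drop = FALSE]
  n <- length(targetGenes)
  N <- length(background)
  terms <- unique(goMap$term[goMap$gene %in% targetGenes])
  if (length(terms) == 0L)
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), pRaw = numeric(0),
                      pBonferroni = numeric(0), fdrBH = numeric(0),
                      significant = logical(0)))
  rows <- lapply(terms, function(tm) {
    inTerm <- unique(goMap$gene[goMap$term == tm])
    K <- length(inTerm)
    k <- sum(targetGenes %in% inTerm)
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, N = N, pRaw = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$pBonferroni <- pmin(1, res$pRaw * nrow(res))
  res$fdrBH <- p.adjust(res$pRaw, method = "BH")
  res$significant <- res$pBonferroni < pCut & res$fdrBH < fdrCut
  res <- res[order(res$pRaw, res$term), ]
  rownames(res) <- NULL
  res
}

.asIgraph <- function(net) {
  nd <- as.data.frame(networkNodes(net))
  ed <- as.data.frame(networkEdges(net))
  nd$log2fc[is.na(nd$log2fc)] <- NaN
  ed$score[is.na(ed$score)] <- NaN
  igraph::graph_from_data_frame(ed, directed = TRUE, vertices = nd)
}

#' Export / import a regulatory network
#'
#' `exportNetwork()` writes SIF (`source  kind  target`) or GraphML (via
#' igraph; node attributes `type`, `log2fc`, `isTF` and edge attributes
#' `kind`, `score` are preserved). `importNetwork()` reads a GraphML file
#' back into a [RegulatoryNetwork-class]; the round trip is lossless.
#'
#' @param net a [RegulatoryNetwork-class].
#' @param path output file.
#' @param format `"sif"` or `"graphml"`.
#' @return invisibly, the path (`exportNetwork`); a `RegulatoryNetwork`
#'   (`importNetwork`).
#' @export
exportNetwork <- function(net, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  ed <- as.data.frame(networkEdges(net))
  if (format == "sif") {
    con <- file(path, "w")
    nd <- as.data.frame(networkNodes(net))
    if (nrow(ed) > 0L)
      writeLines(sprintf("%s\t%s\t%s", ed$source, ed$kind, ed$target), con)
    iso <- setdiff(nd$id, c(ed$source, ed$target))
    if (length(iso)) writeLines(iso, con)
    close(con)
  } else {
    g <- .asIgraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname exportNetwork
#' @export
importNetwork <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nd <- igraph::as_data_frame(g, what = "vertices")
  ed <- igraph::as_data_frame(g, what = "edges")
  nodes <- S4Vectors::DataFrame(
    id = nd$name, type = nd$type,
    log2fc = ifelse(is.nan(nd$log2fc), NA_real_, nd$log2fc),
    isTF = as.logical(nd$isTF))
  edges <- S4Vectors::DataFrame(
    source = ed$from, target = ed$to, kind = ed$kind,
    score = ifelse(is.nan(ed$score), NA_real_, ed$score))
  methods::new("RegulatoryNetwork", nodes = nodes, edges = edges)
}
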