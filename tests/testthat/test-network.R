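# Independent hypergeometric tail oracle built from binomial coefficients
hyperTail <- function(k, n, K, N) {
  i <- k:min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

test_that("network construction restricts PPI edges to the node set", {
  responsive <- data.frame(id = c("mirA", "mirB"), log2fc = c(2.1, -1.4))
  targets <- data.frame(mirna = c("mirA", "mirA", "mirB"),
                        gene = c("g1", "g2", "g2"))
  ppi <- data.frame(geneA = c("g1", "g2", "g9"),
                    geneB = c("g2", "g3", "g1"),
                    score = c(0.9, 0.8, 0.7))
  expect_warning(net <- buildNetwork(responsive, targets, ppi, tfList = "g1"),
                 "dropped")
  nd <- as.data.frame(networkNodes(net))
  ed <- as.data.frame(networkEdges(net))
  expect_setequal(nd$id, c("mirA", "mirB", "g1", "g2"))
  expect_identical(sum(ed$kind == "targeting"), 3L)
  expect_identical(sum(ed$kind == "ppi"), 1L)      # only g1-g2 survives
  expect_identical(attr(net, "droppedPpi"), 2L)
  expect_true(nd$isTF[nd$id == "g1"])
  expect_equal(nd$log2fc[nd$id == "mirA"], 2.1)
  deg <- degreeSummary(net)
  expect_identical(deg$ppiDegree$degree[deg$ppiDegree$id == "g1"], 1L)
  expect_identical(deg$mirnaOutDegree$targets[deg$mirnaOutDegree$id == "mirA"], 2L)
})

test_that("an isolated target has PPI degree zero; the planted hub has 24", {
  res <- defaultRun()
  deg <- degreeSummary(res$network)
  # the planted hub is the most frequent endpoint of the PPI edge list
  ends <- c(res$truth@ppi$geneA, res$truth@ppi$geneB)
  hub <- names(sort(table(ends), decreasing = TRUE))[1]
  if (hub %in% deg$ppiDegree$id) {
    hubPartners <- sum((res$truth@ppi$geneA == hub | res$truth@ppi$geneB == hub) &
                       (res$truth@ppi$geneA %in% deg$ppiDegree$id) &
                       (res$truth@ppi$geneB %in% deg$ppiDegree$id))
    expect_identical(deg$ppiDegree$degree[deg$ppiDegree$id == hub], hubPartners)
  }
  # full-truth network: every planted partner present -> hub degree 24
  allGenes <- data.frame(mirna = "mirZ", gene = res$truth@genes$gene)
  netAll <- buildNetwork(data.frame(id = "mirZ", log2fc = 2),
                         allGenes, res$truth@ppi, res$truth@tfGenes)
  degAll <- degreeSummary(netAll)
  expect_identical(degAll$ppiDegree$degree[degAll$ppiDegree$id == hub], 24L)
})

test_that("GraphML round trip is lossless, including NA fold changes", {
  responsive <- data.frame(id = "mirA", log2fc = -3.25)
  targets <- data.frame(mirna = "mirA", gene = c("g1", "g2"))
  ppi <- data.frame(geneA = "g1", geneB = "g2", score = 0.91)
  net <- buildNetwork(responsive, targets, ppi, tfList = "g2")
  p <- tempfile(fileext = ".graphml")
  exportNetwork(net, p, "graphml")
  back <- importNetwork(p)
  ord <- function(df) {
    df <- as.data.frame(df)
    df[do.call(order, df), , drop = FALSE]
  }
  expect_equal(ord(networkNodes(back)), ord(networkNodes(net)),
               ignore_attr = TRUE)
  expect_equal(ord(networkEdges(back)), ord(networkEdges(net)),
               ignore_attr = TRUE)
  expect_equal(as.data.frame(networkNodes(back))$log2fc[
    as.data.frame(networkNodes(back))$id == "mirA"], -3.25)
})

test_that("SIF export lists every edge and isolated node", {
  responsive <- data.frame(id = "mirA", log2fc = 1.5)
  targets <- data.frame(mirna = "mirA", gene = "g1")
  net <- buildNetwork(responsive, targets)
  p <- tempfile(fileext = ".sif")
  exportNetwork(net, p, "sif")
  expect_identical(readLines(p), "mirA\ttargeting\tg1")
  expect_error(exportNetwork(net, p, "gexf"))
  # empty network -> valid empty file
  empty <- buildNetwork(data.frame(id = character(0), log2fc = numeric(0)),
                        data.frame(mirna = character(0), gene = character(0)))
  exportNetwork(empty, p, "sif")
  expect_identical(length(readLines(p)), 0L)
})

test_that("enrichment p-values match the binomial-coefficient oracle", {
  set.seed(61)
  N <- 1000
  background <- sprintf("g%04d", 1:N)
  goMap <- data.frame(gene = background[1:50], term = "GO:T1")
  targets <- c(background[1:5], background[101:115])   # k=5, n=20, K=50
  enr <- goEnrichment(targets, goMap, background)
  expect_equal(enr$pRaw[enr$term == "GO:T1"], hyperTail(5, 20, 50, 1000),
               tolerance = 1e-12)
  # random tables
  for (i in 1:25) {
    N <- sample(50:400, 1)
    K <- sample(5:(N - 5), 1)
    n <- sample(5:40, 1)
    bg <- sprintf("h%04d", 1:N)
    gm <- data.frame(gene = sample(bg, K), term = "GO:R")
    tg <- sample(bg, n)
    k <- sum(tg %in% gm$gene)
    if (k == 0) next
    e <- goEnrichment(tg, gm, bg)
    expect_equal(e$pRaw[e$term == "GO:R"], hyperTail(k, n, K, N),
                 tolerance = 1e-10)
  }
})

test_that("enrichment corrections and degenerate cases behave", {
  background <- sprintf("g%03d", 1:100)
  # term covering the whole background: no enrichment possible, p = 1
  goMap <- data.frame(gene = background, term = "GO:ALL")
  e <- goEnrichment(background[1:10], goMap, background)
  expect_equal(e$pRaw, 1)
  expect_gte(e$pBonferroni[1], e$pRaw[1])
  expect_error(goEnrichment("g001", goMap, character(0)), "empty")
  expect_error(goEnrichment("missing", goMap, background), "must contain")
})
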