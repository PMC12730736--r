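mitab_line <- function(a, b, taxa = c(9606, 9606), prov = "IM-1") {
  paste("uniprotkb:P1", "uniprotkb:P2", "-", "-",
        sprintf("uniprotkb:%s(gene name)", a),
        sprintf("uniprotkb:%s(gene name)", b),
        "-", "-", "-",
        sprintf("taxid:%d(human)", taxa[1]), sprintf("taxid:%d(mouse)", taxa[2]),
        "-", "-", paste0("imex:", prov), "-", sep = "\t")
}

test_that("MITAB reading keeps same-taxon pairs, dedupes and counts malformed lines", {
  f <- tempfile()
  writeLines(c(mitab_line("A", "B"),
               mitab_line("C", "D", taxa = c(9606, 10090))), f)
  e <- readMitab(f)
  expect_equal(nrow(e), 1)
  expect_setequal(c(e$source, e$target), c("A", "B"))

  writeLines(c(mitab_line("A", "B"), mitab_line("B", "A"),
               "garbage line"), f)
  expect_warning(e <- readMitab(f), "malformed")
  expect_equal(nrow(e), 1)
  expect_equal(attr(e, "n_malformed"), 1)

  # display_short fallback when no gene-name alias is present
  writeLines(paste("uniprotkb:P1", "uniprotkb:P2", "E(display_short)",
                   "F(display_short)", "-", "-", "-", "-", "-",
                   "taxid:9606(h)", "taxid:9606(h)", sep = "\t"), f)
  e <- readMitab(f)
  expect_equal(nrow(e), 1)
  expect_setequal(c(e$source, e$target), c("E", "F"))
})

test_that("a written interactome reads back with the same edge count", {
  edges <- simulateInteractome(120, seed = 4)
  f <- tempfile()
  writeMitab(edges, f)
  back <- readMitab(f)
  expect_equal(nrow(back), nrow(edges))
  k1 <- paste(pmin(edges$source, edges$target), pmax(edges$source, edges$target))
  k2 <- paste(pmin(back$source, back$target), pmax(back$source, back$target))
  expect_setequal(k1, k2)
})

test_that("a subject PPI network is the induced subgraph, singletons retained", {
  edges <- data.frame(source = c("A", "B"), target = c("B", "X"))
  net <- buildSubjectPPI(c("A", "B", "C"), edges)
  expect_setequal(nodeData(net)$gene, c("A", "B", "C"))
  expect_equal(numEdges(net), 1)
  expect_setequal(c(edgeData(net)$from, edgeData(net)$to), c("A", "B"))

  lonely <- buildSubjectPPI(c("Y", "Z"), edges)
  expect_equal(numEdges(lonely), 0)
  expect_equal(numNodes(lonely), 2)
  expect_error(buildSubjectPPI(character(), edges), "empty")
})

test_that("induced subgraph agrees with a brute-force pair loop and with build-then-prune", {
  db <- simulateInteractome(300, seed = 8)
  set.seed(1)
  genes <- sample(sprintf("GENE%05d", 1:300), 200)
  net <- buildSubjectPPI(genes, db)

  # brute force: loop over all unordered pairs of selected genes
  lookup <- new.env()
  for (i in seq_len(nrow(db))) {
    assign(paste(min(db$source[i], db$target[i]),
                 max(db$source[i], db$target[i])), TRUE, envir = lookup)
  }
  sg <- sort(genes)
  brute <- character()
  for (i in seq_along(sg)) {
    for (j in seq_len(i - 1L)) {
      k <- paste(sg[j], sg[i])
      if (!is.null(lookup[[k]])) brute <- c(brute, k)
    }
  }
  got <- paste(pmin(edgeData(net)$from, edgeData(net)$to),
               pmax(edgeData(net)$from, edgeData(net)$to))
  expect_setequal(got, brute)

  # first-degree network pruned to the input genes gives the same edges
  touched <- db[db$source %in% genes | db$target %in% genes, ]
  first_degree <- geneNetwork(unique(c(genes, touched$source, touched$target)),
                              data.frame(from = touched$source,
                                         to = touched$target))
  pruned_edges <- edgeData(first_degree)
  pruned_edges <- pruned_edges[pruned_edges$from %in% genes &
                               pruned_edges$to %in% genes, ]
  expect_setequal(paste(pmin(pruned_edges$from, pruned_edges$to),
                        pmax(pruned_edges$from, pruned_edges$to)), got)
  # no node outside the input set
  expect_true(all(nodeData(net)$gene %in% genes))
})

test_that("component decomposition bins sizes as giant/clusters/triads/pairs/singletons", {
  nodes <- c(paste0("p", 1:5), "q1", "q2", "r")
  edges <- data.frame(from = c(paste0("p", 1:4), "q1"),
                      to = c(paste0("p", 2:5), "q2"))
  d <- giantComponent(geneNetwork(nodes, edges))
  expect_equal(numNodes(giantNetwork(d)), 5)
  expect_equal(d@nPairs, 1L)
  expect_equal(d@nSingletons, 1L)
  expect_equal(d@nTriads, 0L)

  full <- geneNetwork(c("a", "b", "c"),
                      data.frame(from = c("a", "a", "b"), to = c("b", "c", "c")))
  expect_equal(numNodes(giantNetwork(giantComponent(full))), 3)
  empty <- giantComponent(geneNetwork(character()))
  expect_equal(numNodes(giantNetwork(empty)), 0)
  expect_equal(empty@nSingletons, 0L)
})

test_that("component sizes match a union-find oracle on random networks", {
  for (i in 1:25) {
    set.seed(i)
    n <- sample(10:40, 1)
    nodes <- paste0("n", seq_len(n))
    m <- sample(0:(2 * n), 1)
    ed <- data.frame(from = sample(nodes, m, TRUE), to = sample(nodes, m, TRUE))
    ed <- ed[ed$from != ed$to, ]
    d <- giantComponent(geneNetwork(nodes, ed))
    oracle <- uf_components(nodes, ed$from, ed$to)
    sizes <- sort(unname(vapply(oracle, length, integer(1))), decreasing = TRUE)
    expect_equal(numNodes(giantNetwork(d)), sizes[1])
    expect_equal(d@nSingletons, sum(sizes == 1) - (sizes[1] == 1))
    expect_equal(d@nPairs, as.integer(sum(sizes == 2) - (sizes[1] == 2)))
    expect_equal(d@nTriads, as.integer(sum(sizes == 3) - (sizes[1] == 3)))
    expect_equal(sum(d@membership$size[!duplicated(d@membership$component)]), n)
  }
})

test_that("decomposition is invariant under node relabeling", {
  set.seed(42)
  nodes <- paste0("x", 1:15)
  ed <- data.frame(from = sample(nodes, 18, TRUE), to = sample(nodes, 18, TRUE))
  ed <- ed[ed$from != ed$to, ]
  d1 <- giantComponent(geneNetwork(nodes, ed))
  perm <- setNames(paste0("y", sample(15)), nodes)
  d2 <- giantComponent(geneNetwork(unname(perm),
                                   data.frame(from = unname(perm[ed$from]),
                                              to = unname(perm[ed$to]))))
  sizes <- function(d) sort(table(d@membership$component))
  expect_equal(unname(as.vector(sizes(d1))), unname(as.vector(sizes(d2))))
})

test_that("linker genes connect disconnected DEGs and are flagged", {
  fi <- data.frame(source = c("A", "L"), target = c("L", "B"))
  net <- buildFINetwork(data.frame(gene = c("A", "B"), direction = c("up", "down")), fi)
  nd <- nodeData(net)
  expect_setequal(nd$gene, c("A", "B", "L"))
  expect_equal(nd$role[nd$gene == "L"], "linker")
  expect_equal(nd$direction[nd$gene == "A"], "up")
  expect_equal(nd$direction[nd$gene == "L"], "ns")
  expect_true(igraph::is_connected(asIgraph(net), mode = "weak"))

  # already-connected DEGs gain no linkers
  fi2 <- data.frame(source = c("A", "B", "C"), target = c("B", "C", "Z"))
  net2 <- buildFINetwork(data.frame(gene = c("A", "B", "C"),
                                    direction = "up"), fi2)
  expect_equal(sum(nodeData(net2)$role == "linker"), 0)
})

test_that("every added linker is adjacent to at least two input DEGs", {
  study <- small_study(seed = 10)
  degs <- data.frame(gene = sample(study$truth@deGenes$gene, 25),
                     direction = "up")
  net <- buildFINetwork(degs, study$fi_db)
  nd <- nodeData(net)
  fi <- study$fi_db
  input <- intersect(degs$gene, unique(c(fi$source, fi$target)))
  for (l in nd$gene[nd$role == "linker"]) {
    nbrs <- unique(c(fi$target[fi$source == l], fi$source[fi$target == l]))
    expect_gte(length(intersect(nbrs, input)), 2)
  }
})

test_that("topology counts match a brute-force edge scan and the published core table", {
  star <- geneNetwork(c("hub", paste0("leaf", 1:5)),
                      data.frame(from = "hub", to = paste0("leaf", 1:5)),
                      directed = TRUE)
  t <- nodeTopology(star)
  expect_equal(t$out_degree[t$gene == "hub"], 5)
  expect_equal(t$in_degree[t$gene == "hub"], 0)
  expect_equal(t$edge_count[t$gene == "hub"], 5)
  expect_equal(t$gene[1], "hub")

  core <- loadCoreGeneTable()
  expect_true(all(core$edge_count == core$in_degree + core$out_degree))
  expect_equal(core$gene_symbol[which.max(core$edge_count)], "EP300")

  set.seed(3)
  nodes <- paste0("v", 1:20)
  ed <- unique(data.frame(from = sample(nodes, 60, TRUE),
                          to = sample(nodes, 60, TRUE)))
  ed <- ed[ed$from != ed$to, ]
  net <- geneNetwork(nodes, ed, directed = TRUE)
  t <- nodeTopology(net)
  kept <- edgeData(net)
  for (g in nodes) {
    expect_equal(t$out_degree[t$gene == g], sum(kept$from == g))
    expect_equal(t$in_degree[t$gene == g], sum(kept$to == g))
  }
  expect_equal(sum(t$in_degree), numEdges(net))
  expect_equal(sum(t$out_degree), numEdges(net))
  expect_equal(nrow(topHubs(net, 7)), 7)
})

test_that("network intersection keeps shared nodes and source edges only", {
  a <- geneNetwork(c("A", "B", "C"), data.frame(from = "A", to = "B"))
  expect_identical(nodeData(intersectNetworks(a, a))$gene, nodeData(a)$gene)
  b <- geneNetwork(c("X", "Y"), data.frame(from = "X", to = "Y"))
  expect_warning(e <- intersectNetworks(a, b), "no nodes")
  expect_equal(numNodes(e), 0)

  for (i in 1:10) {
    set.seed(100 + i)
    na <- paste0("g", sample(30, 15)); nb <- paste0("g", sample(30, 15))
    ea <- data.frame(from = sample(na, 10, TRUE), to = sample(na, 10, TRUE))
    eb <- data.frame(from = sample(nb, 10, TRUE), to = sample(nb, 10, TRUE))
    ga <- geneNetwork(na, ea[ea$from != ea$to, ])
    gb <- geneNetwork(nb, eb[eb$from != eb$to, ])
    suppressWarnings({
      ab <- intersectNetworks(ga, gb, edge_source = "b")
      ba <- intersectNetworks(gb, ga, edge_source = "a")
    })
    expect_setequal(nodeData(ab)$gene, intersect(na, nb))
    expect_setequal(nodeData(ab)$gene, nodeData(ba)$gene)
    kb <- paste(pmin(edgeData(gb)$from, edgeData(gb)$to),
                pmax(edgeData(gb)$from, edgeData(gb)$to))
    got <- paste(pmin(edgeData(ab)$from, edgeData(ab)$to),
                 pmax(edgeData(ab)$from, edgeData(ab)$to))
    expect_true(all(got %in% kb))
  }
})

test_that("network export writes GraphML and SIF", {
  net <- geneNetwork(data.frame(gene = c("A", "B", "C"), role = "DEG"),
                     data.frame(from = "A", to = "B"), directed = TRUE)
  g <- tempfile(fileext = ".graphml"); s <- tempfile(fileext = ".sif")
  exportGraphML(net, g)
  exportSif(net, s)
  back <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::vcount(back), 3)
  expect_equal(igraph::ecount(back), 1)
  expect_length(readLines(s), 2)  # one edge line + one isolated node
})
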