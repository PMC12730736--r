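## Network construction, refinement and topology: subject PPI networks,
## functional-interaction networks with linker genes, component
## decomposition and hub metrics. igraph is the graph engine throughout.

#' Build a subject-specific PPI network
#'
#' Restricts an interactome to the genes of interest: the result is the
#' induced subgraph of the interactome on `genes` (mathematically equivalent
#' to building the first-neighbour network and then pruning interactors
#' outside the gene set — the equivalence is asserted in the test suite).
#' Input genes without any retained interaction stay in the network as
#' singleton nodes. Self-loops and duplicate edges are removed by the
#' [geneNetwork()] refinement.
#'
#' @param genes Non-empty character vector of gene symbols (e.g., genes
#'   carrying rare variants in this subject).
#' @param edges Interactome edge table with `source`/`target` columns, as
#'   returned by [readMitab()] or [simulateInteractome()].
#' @return An undirected [GeneNetwork-class] whose node set is exactly
#'   `genes`.
#' @examples
#' edges <- data.frame(source = c("A", "B"), target = c("B", "X"))
#' buildSubjectPPI(c("A", "B", "C"), edges)
#' @export
buildSubjectPPI <- function(genes, edges) {
  if (!length(genes)) stop("the gene set must not be empty")
  genes <- unique(as.character(genes))
  keep <- edges$source %in% genes & edges$target %in% genes
  ed <- data.frame(from = edges$source[keep], to = edges$target[keep])
  if ("provenance" %in% names(edges)) ed$provenance <- edges$provenance[keep]
  geneNetwork(genes, ed, directed = FALSE)
}

#' Decompose a network into giant component, clusters, triads, pairs and
#' singletons
#'
#' Connected components are computed on the undirected skeleton (weak
#' connectivity for directed networks) and binned by size: the largest
#' component is the giant (ties broken by the lexicographically smallest
#' member gene, for determinism), components of size >= 4 are secondary
#' clusters, size 3 are triads, size 2 pairs, size 1 singletons.
#'
#' @param n A [GeneNetwork-class].
#' @return A [ComponentDecomposition-class]. An empty network yields an
#'   all-zero decomposition.
#' @export
giantComponent <- function(n) {
  if (numNodes(n) == 0) {
    return(new("ComponentDecomposition",
               giant = geneNetwork(character()), secondaryClusters = list(),
               nTriads = 0L, nPairs = 0L, nSingletons = 0L,
               membership = data.frame(gene = character(),
                                       component = integer(),
                                       size = integer())))
  }
  g <- asIgraph(n)
  comp <- igraph::components(g, mode = "weak")
  genes <- nodeData(n)$gene
  member <- comp$membership[genes]
  sizes <- comp$csize
  ## deterministic giant: largest size, tie-broken by smallest member gene
  biggest <- which(sizes == max(sizes))
  if (length(biggest) > 1) {
    first_gene <- vapply(biggest, function(ci) min(genes[member == ci]), "")
    biggest <- biggest[order(first_gene)][1]
  } else {
    biggest <- biggest[1]
  }
  subnet <- function(ci) {
    keep <- genes[member == ci]
    nodes <- nodeData(n)[nodeData(n)$gene %in% keep, , drop = FALSE]
    ed <- edgeData(n)
    ed <- ed[ed$from %in% keep & ed$to %in% keep, , drop = FALSE]
    geneNetwork(nodes, ed, directed = n@directed)
  }
  secondary_ids <- setdiff(which(sizes >= 4), biggest)
  secondary_ids <- secondary_ids[order(-sizes[secondary_ids])]
  new("ComponentDecomposition",
      giant = subnet(biggest),
      secondaryClusters = lapply(secondary_ids, subnet),
      nTriads = as.integer(sum(sizes == 3) - (sizes[biggest] == 3)),
      nPairs = as.integer(sum(sizes == 2) - (sizes[biggest] == 2)),
      nSingletons = as.integer(sum(sizes == 1) - (sizes[biggest] == 1)),
      membership = data.frame(gene = genes, component = as.integer(member),
                              size = as.integer(sizes[member])))
}

#' Build a functional-interaction network from DEGs, adding linker genes
#'
#' Starts from the induced subgraph of the directed functional-interaction
#' database on the differentially expressed genes, then greedily adds
#' "linker" genes — non-input genes adjacent (in either direction) to at
#' least two input genes lying in different connected components of the
#' current network — in descending order of input-neighbour count
#' (lexicographic tie-break), until no candidate merges components any
#' further. Edges of the result are the induced edges of the database on the
#' final node set. Nodes are annotated with `role` (`DEG`/`linker`) and
#' `direction` (`up`/`down` from the DE table; `ns` for linkers).
#'
#' The linker rule is a documented heuristic for the pathway-database
#' "connect disconnected DEGs" behaviour; exact node counts are
#' database-dependent.
#'
#' @param degs `data.frame` with `gene` and `direction` columns, or a
#'   character vector (directions then default to `ns`).
#' @param fi_db Directed edge table with `source`/`target` columns.
#' @param add_linkers Logical; add linker genes?
#' @return A directed [GeneNetwork-class].
#' @export
buildFINetwork <- function(degs, fi_db, add_linkers = TRUE) {
  if (is.character(degs)) degs <- data.frame(gene = degs, direction = "ns")
  stopifnot(all(c("gene", "direction") %in% names(degs)))
  db_genes <- unique(c(fi_db$source, fi_db$target))
  input <- intersect(unique(degs$gene), db_genes)

  ## undirected adjacency for linker discovery
  nbr <- function(gene_set) {
    hits <- fi_db$source %in% gene_set | fi_db$target %in% gene_set
    unique(c(fi_db$source[hits], fi_db$target[hits]))
  }
  induced_edges <- function(nodes) {
    keep <- fi_db$source %in% nodes & fi_db$target %in% nodes
    data.frame(from = fi_db$source[keep], to = fi_db$target[keep])
  }

  nodes <- input
  linkers <- character()
  if (add_linkers && length(input) > 1) {
    ## candidate linkers: adjacent to >= 2 input genes
    cand <- setdiff(nbr(input), input)
    n_input_nbrs <- vapply(cand, function(x) {
      length(unique(c(fi_db$target[fi_db$source == x & fi_db$target %in% input],
                      fi_db$source[fi_db$target == x & fi_db$source %in% input])))
    }, integer(1))
    cand <- cand[n_input_nbrs >= 2]
    n_input_nbrs <- n_input_nbrs[cand]
    ord <- order(-n_input_nbrs, cand)
    cand <- cand[ord]

    comp_of <- function(nodes) {
      g <- igraph::graph_from_data_frame(induced_edges(nodes), directed = FALSE,
                                         vertices = data.frame(name = nodes))
      igraph::components(g)$membership[nodes]
    }
    member <- comp_of(nodes)
    for (x in cand) {
      if (length(unique(member[input])) <= 1) break
      adj_inputs <- unique(c(
        fi_db$target[fi_db$source == x & fi_db$target %in% input],
        fi_db$source[fi_db$target == x & fi_db$source %in% input]))
      if (length(unique(member[adj_inputs])) >= 2) {
        linkers <- c(linkers, x)
        nodes <- c(nodes, x)
        member <- comp_of(nodes)
      }
    }
  }
  node_df <- data.frame(gene = nodes,
                        role = ifelse(nodes %in% linkers, "linker", "DEG"),
                        stringsAsFactors = FALSE)
  dir_map <- stats::setNames(as.character(degs$direction), degs$gene)
  node_df$direction <- ifelse(node_df$role == "linker", "ns",
                              unname(dir_map[node_df$gene]))
  node_df$direction[is.na(node_df$direction)] <- "ns"
  geneNetwork(node_df, induced_edges(nodes), directed = TRUE)
}

#' Per-node topology table
#'
#' For a directed network, the in-degree and out-degree of every node and
#' the edge count (their sum); for an undirected network only the edge count
#' (degree) is reported. Rows are ranked by edge count descending with a
#' lexicographic tie-break on the gene symbol.
#'
#' @param n A [GeneNetwork-class].
#' @return A `data.frame` with `gene`, `edge_count` and (directed only)
#'   `in_degree`, `out_degree`, sorted by rank.
#' @export
nodeTopology <- function(n) {
  g <- asIgraph(n)
  genes <- nodeData(n)$gene
  if (n@directed) {
    din <- igraph::degree(g, mode = "in")[genes]
    dout <- igraph::degree(g, mode = "out")[genes]
    out <- data.frame(gene = genes, edge_count = as.integer(din + dout),
                      in_degree = as.integer(din),
                      out_degree = as.integer(dout))
  } else {
    out <- data.frame(gene = genes,
                      edge_count = as.integer(igraph::degree(g)[genes]))
  }
  out <- out[order(-out$edge_count, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top hub genes by edge count
#'
#' @param n A [GeneNetwork-class].
#' @param k Number of hubs to report.
#' @return The first `k` rows of [nodeTopology()].
#' @export
topHubs <- function(n, k = 7) {
  utils::head(nodeTopology(n), k)
}

#' Intersect two networks on their node sets
#'
#' Nodes of the result are the intersection of the two node sets; edges are
#' the edges of the chosen source network with both endpoints retained.
#' Node annotations are merged column-wise; on column collisions the values
#' of network `a` take precedence.
#'
#' @param a,b [GeneNetwork-class] objects over the same gene namespace.
#' @param edge_source `"a"` or `"b"`: whose edges to keep.
#' @return A [GeneNetwork-class]; empty (with a warning) when the node sets
#'   are disjoint.
#' @export
intersectNetworks <- function(a, b, edge_source = c("b", "a")) {
  edge_source <- match.arg(edge_source)
  shared <- intersect(nodeData(a)$gene, nodeData(b)$gene)
  if (!length(shared)) warning("the two networks share no nodes")
  src <- if (edge_source == "a") a else b
  ed <- edgeData(src)
  ed <- ed[ed$from %in% shared & ed$to %in% shared, , drop = FALSE]
  na <- nodeData(a)[match(shared, nodeData(a)$gene), , drop = FALSE]
  nb <- nodeData(b)[match(shared, nodeData(b)$gene), , drop = FALSE]
  extra <- setdiff(names(nb), names(na))
  nodes <- cbind(na, nb[, extra, drop = FALSE])
  geneNetwork(nodes, ed, directed = src@directed)
}
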