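#' @importFrom S4Vectors isSorted
NULL

## Columns every variant record table carries. Extra columns are allowed and
## preserved; these are required (NA permitted where noted in the class doc).
.VARIANT_COLUMNS <- c(
  "chrom", "pos", "ref", "alt", "gene_symbol", "biotype", "hgvsc", "hgvsp",
  "allele_frequency", "cadd_phred", "pli", "zygosity", "subject_id"
)

#' SubjectVariantSet: annotated variants of one subject
#'
#' Container for the annotated variant observations of a single subject. Each
#' row of `records` is one (variant allele, gene) annotation: the same allele
#' annotated to two genes contributes two rows. Required columns are `chrom`,
#' `pos` (1-based), `ref`, `alt`, `gene_symbol`, `biotype`, `hgvsc`, `hgvsp`,
#' `allele_frequency` (gnomAD fraction in \[0,1\] or `NA` when the allele is
#' unobserved in the reference population), `cadd_phred` (non-negative
#' PHRED-scaled CADD score), `pli` (probability of loss-of-function
#' intolerance, or `NA`), `zygosity` (`"het"` or `"hom"`), `subject_id`.
#'
#' Filters ([qcFilter()], [rareFilter()], [highImpactFilter()],
#' [pliPrioritize()]) return a new `SubjectVariantSet` and append an auditable
#' entry to [filterReport()].
#'
#' @slot subjectId Character label of the subject.
#' @slot records `data.frame` of variant records (see above).
#' @slot report List of per-stage filter reports.
#'
#' @export
setClass("SubjectVariantSet",
  slots = c(subjectId = "character", records = "data.frame", report = "list")
)

setValidity("SubjectVariantSet", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L) msg <- c(msg, "subjectId must be a single label")
  rec <- object@records
  missing_cols <- setdiff(.VARIANT_COLUMNS, names(rec))
  if (length(missing_cols)) {
    msg <- c(msg, paste("records lack columns:", paste(missing_cols, collapse = ", ")))
  } else if (nrow(rec)) {
    if (any(!is.na(rec$pos) & rec$pos < 1)) msg <- c(msg, "pos must be >= 1")
    af <- rec$allele_frequency
    if (any(!is.na(af) & (af < 0 | af > 1))) msg <- c(msg, "allele_frequency must lie in [0,1]")
    if (any(!is.na(rec$cadd_phred) & rec$cadd_phred < 0)) msg <- c(msg, "cadd_phred must be non-negative")
    if (any(!is.na(rec$pli) & (rec$pli < 0 | rec$pli > 1))) msg <- c(msg, "pli must lie in [0,1]")
    if (!all(rec$zygosity %in% c("het", "hom"))) msg <- c(msg, "zygosity must be 'het' or 'hom'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SubjectVariantSet
#'
#' @param records `data.frame` of variant records; missing required columns
#'   are added as `NA` except the genotype/identity columns, which must be
#'   present.
#' @param subjectId Subject label; defaults to the unique `subject_id` of
#'   `records` when present.
#' @param report Optional list of filter-report entries to carry over.
#' @return A [SubjectVariantSet-class] object.
#' @examples
#' rec <- data.frame(
#'   chrom = "1", pos = 100, ref = "A", alt = "G", gene_symbol = "GENE1",
#'   zygosity = "het", cadd_phred = 12, allele_frequency = 0.2
#' )
#' subjectVariantSet(rec, subjectId = "S1")
#' @export
subjectVariantSet <- function(records, subjectId = NULL, report = list()) {
  records <- as.data.frame(records)
  if (is.null(subjectId)) {
    sid <- unique(records$subject_id)
    subjectId <- if (length(sid) == 1L && !is.na(sid)) as.character(sid) else "subject"
  }
  for (col in .VARIANT_COLUMNS) {
    if (!col %in% names(records)) {
      records[[col]] <- rep(if (col == "subject_id") subjectId else NA,
                            nrow(records))
    }
  }
  records$subject_id <- as.character(records$subject_id)
  records$chrom <- as.character(records$chrom)
  records$gene_symbol <- as.character(records$gene_symbol)
  rownames(records) <- NULL
  new("SubjectVariantSet", subjectId = as.character(subjectId),
      records = records, report = report)
}

#' @rdname variantRecords
#' @export
setMethod("variantRecords", "SubjectVariantSet", function(x) x@records)

#' @rdname subjectId
#' @export
setMethod("subjectId", "SubjectVariantSet", function(x) x@subjectId)

#' @rdname geneIndex
#' @export
setMethod("geneIndex", "SubjectVariantSet", function(x) {
  rec <- x@records
  split(rec, factor(rec$gene_symbol, levels = unique(rec$gene_symbol)))
})

#' @rdname filterReport
#' @export
setMethod("filterReport", "SubjectVariantSet", function(x) x@report)

setMethod("show", "SubjectVariantSet", function(object) {
  cat("SubjectVariantSet for subject '", object@subjectId, "'\n", sep = "")
  cat("  ", nrow(object@records), " variant records in ",
      length(unique(object@records$gene_symbol)), " genes\n", sep = "")
  if (length(object@report)) {
    cat("  filter stages applied:",
        paste(vapply(object@report, `[[`, "", "stage"), collapse = " -> "), "\n")
  }
})

#' GeneNetwork: annotated gene-gene interaction network
#'
#' A directed or undirected network over gene symbols. `nodes` holds one row
#' per gene with arbitrary annotation columns (role, expression direction,
#' attached variants, ...); `edges` holds one row per interaction with `from`
#' and `to` columns plus optional provenance. After construction the network
#' is refined: self-loops removed, duplicate edges collapsed (unordered pairs
#' when undirected, ordered pairs when directed), endpoints restricted to the
#' node table.
#'
#' @slot nodes `data.frame` with a `gene` column first.
#' @slot edges `data.frame` with `from`/`to` columns.
#' @slot directed Single logical flag.
#'
#' @export
setClass("GeneNetwork",
  slots = c(nodes = "data.frame", edges = "data.frame", directed = "logical")
)

setValidity("GeneNetwork", function(object) {
  msg <- character()
  if (!"gene" %in% names(object@nodes)) msg <- c(msg, "nodes must have a 'gene' column")
  if (!all(c("from", "to") %in% names(object@edges))) {
    msg <- c(msg, "edges must have 'from' and 'to' columns")
  } else {
    ed <- object@edges
    if (nrow(ed)) {
      if (!all(c(ed$from, ed$to) %in% object@nodes$gene)) {
        msg <- c(msg, "edge endpoints must be nodes")
      }
      if (any(ed$from == ed$to)) msg <- c(msg, "self-loops are not allowed")
      key <- if (isTRUE(object@directed)) paste(ed$from, ed$to, sep = "\r") else
        paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to), sep = "\r")
      if (anyDuplicated(key)) msg <- c(msg, "duplicate edges are not allowed")
    }
  }
  if (anyDuplicated(object@nodes$gene)) msg <- c(msg, "duplicate nodes are not allowed")
  if (length(object@directed) != 1L) msg <- c(msg, "directed must be a single flag")
  if (length(msg)) msg else TRUE
})

#' Construct a refined GeneNetwork
#'
#' Applies the standard refinement: drop self-loops, collapse duplicate edges
#' (first occurrence wins), drop edges with endpoints outside the node set.
#'
#' @param nodes Character vector of gene symbols or a `data.frame` with a
#'   `gene` column.
#' @param edges `data.frame` with `from`/`to` columns (may be empty).
#' @param directed Logical; is the network directed?
#' @return A [GeneNetwork-class] object.
#' @examples
#' geneNetwork(c("A", "B", "C"), data.frame(from = "A", to = "B"))
#' @export
geneNetwork <- function(nodes, edges = NULL, directed = FALSE) {
  if (!is.data.frame(nodes)) nodes <- data.frame(gene = as.character(nodes))
  nodes$gene <- as.character(nodes$gene)
  nodes <- nodes[!duplicated(nodes$gene), , drop = FALSE]
  rownames(nodes) <- NULL
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(from = character(), to = character())
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  keep <- edges$from != edges$to &
    edges$from %in% nodes$gene & edges$to %in% nodes$gene
  edges <- edges[keep, , drop = FALSE]
  key <- if (directed) paste(edges$from, edges$to, sep = "\r") else
    paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to), sep = "\r")
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL
  new("GeneNetwork", nodes = nodes, edges = edges, directed = isTRUE(directed))
}

#' @rdname nodeData
#' @export
setMethod("nodeData", "GeneNetwork", function(x) x@nodes)

#' @rdname edgeData
#' @export
setMethod("edgeData", "GeneNetwork", function(x) x@edges)

#' @rdname numNodes
#' @export
setMethod("numNodes", "GeneNetwork", function(x) nrow(x@nodes))

#' @rdname numNodes
#' @export
setMethod("numEdges", "GeneNetwork", function(x) nrow(x@edges))

#' @rdname asIgraph
#' @export
setMethod("asIgraph", "GeneNetwork", function(x) {
  vertices <- x@nodes[, c("gene", setdiff(names(x@nodes), "gene")), drop = FALSE]
  atomic <- vapply(vertices, is.atomic, logical(1))
  igraph::graph_from_data_frame(x@edges, directed = x@directed,
                                vertices = vertices[, atomic, drop = FALSE])
})

setMethod("show", "GeneNetwork", function(object) {
  cat(if (object@directed) "Directed" else "Undirected",
      "GeneNetwork:", nrow(object@nodes), "nodes,", nrow(object@edges), "edges\n")
  ann <- setdiff(names(object@nodes), "gene")
  if (length(ann)) cat("  node annotations:", paste(ann, collapse = ", "), "\n")
})

#' ComponentDecomposition: connected components binned by size
#'
#' Result of [giantComponent()]: the largest connected component (the giant),
#' the secondary clusters (size >= 4 but not the giant), and counts of triads
#' (size 3), pairs (size 2) and singletons (size 1). Components are computed
#' on the undirected skeleton regardless of edge direction.
#'
#' @slot giant The giant component as a [GeneNetwork-class].
#' @slot secondaryClusters List of [GeneNetwork-class] objects.
#' @slot nTriads,nPairs,nSingletons Integer component counts.
#' @slot membership `data.frame` with `gene`, `component`, `size` columns.
#'
#' @export
setClass("ComponentDecomposition",
  slots = c(giant = "GeneNetwork", secondaryClusters = "list",
            nTriads = "integer", nPairs = "integer", nSingletons = "integer",
            membership = "data.frame")
)

setValidity("ComponentDecomposition", function(object) {
  n_binned <- numNodes(object@giant) +
    sum(vapply(object@secondaryClusters, numNodes, integer(1))) +
    3L * object@nTriads + 2L * object@nPairs + object@nSingletons
  if (nrow(object@membership) && n_binned != nrow(object@membership)) {
    return("component node counts do not sum to the parent node count")
  }
  TRUE
})

#' @rdname giantNetwork
#' @export
setMethod("giantNetwork", "ComponentDecomposition", function(x) x@giant)

setMethod("show", "ComponentDecomposition", function(object) {
  cat("ComponentDecomposition:\n")
  cat("  giant component: ", numNodes(object@giant), " nodes, ",
      numEdges(object@giant), " edges\n", sep = "")
  cat("  secondary clusters: ", length(object@secondaryClusters),
      "; triads: ", object@nTriads, "; pairs: ", object@nPairs,
      "; singletons: ", object@nSingletons, "\n", sep = "")
})

#' GeneCountMatrix: gene-by-sample counts with group labels
#'
#' A thin [SummarizedExperiment::SummarizedExperiment-class] subclass holding
#' the raw integer count matrix in the `counts` assay and the two-group design
#' in `colData(x)$group`. CPM and log2 CPM are derived on demand by [cpm()] so
#' that normalization always reflects the current (possibly filtered) counts.
#'
#' @export
setClass("GeneCountMatrix", contains = "SummarizedExperiment")

setValidity("GeneCountMatrix", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object)) {
    return("must carry a 'counts' assay")
  }
  k <- SummarizedExperiment::assay(object, "counts")
  if (any(k < 0)) msg <- c(msg, "counts must be non-negative")
  if (any(k != round(k))) msg <- c(msg, "counts must be integers")
  if (!"group" %in% names(SummarizedExperiment::colData(object))) {
    msg <- c(msg, "colData must have a 'group' column")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GeneCountMatrix
#'
#' @param counts Integer matrix, genes in rows (rownames = gene symbols),
#'   samples in columns.
#' @param group Per-sample group labels (coerced to factor).
#' @return A [GeneCountMatrix-class] object.
#' @examples
#' k <- matrix(rpois(12, 50), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' geneCountMatrix(k, rep(c("A", "B"), each = 2))
#' @export
geneCountMatrix <- function(counts, group) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "numeric"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(group = factor(group),
                                   row.names = colnames(counts))
  )
  new("GeneCountMatrix", se)
}

#' @rdname cpm
#' @export
setMethod("cpm", "GeneCountMatrix", function(x, log = FALSE, prior = 1) {
  k <- SummarizedExperiment::assay(x, "counts")
  lib <- colSums(k)
  out <- sweep(k, 2, lib, "/") * 1e6
  if (log) log2(out + prior) else out
})

#' @rdname sampleGroups
#' @export
setMethod("sampleGroups", "GeneCountMatrix", function(x) {
  SummarizedExperiment::colData(x)$group
})

#' SplsdaFit: sparse PLS-DA model
#'
#' Latent components extracted to maximize covariance between the (centered,
#' unit-scaled) expression matrix and the class-indicator response, with an
#' optional per-component cap on the number of nonzero loading weights.
#'
#' @slot loadings Gene-by-component matrix of unit-norm loading vectors.
#' @slot scores Sample-by-component matrix of X-variates.
#' @slot varianceExplained Per-component fraction of predictor variance.
#' @slot sparsity Number of nonzero loadings per component.
#' @slot genes Genes actually fitted (constant genes are dropped).
#'
#' @export
setClass("SplsdaFit",
  slots = c(loadings = "matrix", scores = "matrix",
            varianceExplained = "numeric", sparsity = "integer",
            genes = "character")
)

setValidity("SplsdaFit", function(object) {
  msg <- character()
  norms <- sqrt(colSums(object@loadings^2))
  if (any(abs(norms - 1) > 1e-6)) msg <- c(msg, "loading vectors must be unit-norm")
  ve <- object@varianceExplained
  if (any(ve < -1e-8 | ve > 1 + 1e-8)) msg <- c(msg, "varianceExplained must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SplsdaFit", function(object) {
  cat("SplsdaFit:", ncol(object@loadings), "component(s) over",
      nrow(object@loadings), "genes\n")
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * object@varianceExplained), collapse = ", "), "\n")
  cat("  nonzero loadings per component:",
      paste(object@sparsity, collapse = ", "), "\n")
})

#' RfeResult: recursive feature elimination trace
#'
#' @slot trace List of retained-gene character vectors, one per iteration
#'   (strictly decreasing in size; the first entry is the full starting set).
#' @slot finalGenes Genes retained at the end, exactly
#'   `floor(retainFraction * initial count)` of them.
#' @slot retainFraction Target fraction of genes to retain.
#'
#' @export
setClass("RfeResult",
  slots = c(trace = "list", finalGenes = "character", retainFraction = "numeric")
)

setValidity("RfeResult", function(object) {
  sizes <- vapply(object@trace, length, integer(1))
  msg <- character()
  if (length(sizes) > 1 && any(diff(sizes) >= 0)) {
    msg <- c(msg, "trace must be strictly decreasing in size")
  }
  expected <- floor(object@retainFraction * sizes[1])
  if (length(sizes) && length(object@finalGenes) != expected) {
    msg <- c(msg, "final size must equal floor(retainFraction * initial count)")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "RfeResult", function(object) {
  sizes <- vapply(object@trace, length, integer(1))
  cat("RfeResult:", sizes[1], "->", length(object@finalGenes), "genes in",
      length(sizes) - 1L, "elimination steps\n")
})

#' PhenotypePanel: virtual gene panel from phenotype-ontology terms
#'
#' The union of genes annotated to a set of phenotype (HPO) terms linked to a
#' disease entry, used as a disease-specific gene universe for network
#' intersection.
#'
#' @slot disease Disease label (e.g., an OMIM accession).
#' @slot terms `data.frame` with `term_id`, `term_name`, `n_genes`.
#' @slot annotations Long `data.frame` (`term_id`, `term_name`, `gene_symbol`).
#' @slot genes Deduplicated union of annotated genes.
#'
#' @export
setClass("PhenotypePanel",
  slots = c(disease = "character", terms = "data.frame",
            annotations = "data.frame", genes = "character")
)

setValidity("PhenotypePanel", function(object) {
  expected <- sort(unique(object@annotations$gene_symbol))
  if (!identical(sort(object@genes), expected)) {
    return("genes must equal the deduplicated union over terms")
  }
  TRUE
})

#' @rdname panelGenes
#' @export
setMethod("panelGenes", "PhenotypePanel", function(x) x@genes)

setMethod("show", "PhenotypePanel", function(object) {
  cat("PhenotypePanel '", object@disease, "': ", nrow(object@terms),
      " terms, ", length(object@genes), " unique genes\n", sep = "")
})

#' SimTruth: ground truth of a synthetic study
#'
#' Records what the synthetic-data generators planted, so recovery can be
#' scored: the modifier genes (subject-unique rare high-CADD variants), the
#' differentially expressed genes with their true log2 fold changes, the
#' phenotype-panel membership, and the seed that fully determines all outputs.
#'
#' @slot modifierGenes Character vector of planted modifier genes.
#' @slot deGenes `data.frame` with `gene` and `true_log2fc` columns.
#' @slot panelGenes Character vector of panel member genes.
#' @slot seed Integer seed.
#'
#' @export
setClass("SimTruth",
  slots = c(modifierGenes = "character", deGenes = "data.frame",
            panelGenes = "character", seed = "integer")
)

setValidity("SimTruth", function(object) {
  planted_universe <- union(object@deGenes$gene, object@panelGenes)
  ## only enforced once other layers have been planted: a variant-table-only
  ## truth legitimately has empty DE and panel slots
  if (length(object@modifierGenes) && length(planted_universe) &&
      !all(object@modifierGenes %in% planted_universe)) {
    return("modifier genes must be planted in the DE set or the panel")
  }
  TRUE
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth (seed ", object@seed, "): ", length(object@modifierGenes),
      " planted modifiers, ", nrow(object@deGenes), " DE genes, ",
      length(object@panelGenes), " panel genes\n", sep = "")
})
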