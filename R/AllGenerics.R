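#' @import methods
NULL

#' Variant records of a subject variant set
#'
#' @param x A [SubjectVariantSet-class] object.
#' @return A `data.frame` with one row per (variant, gene) annotation record.
#' @export
setGeneric("variantRecords", function(x) standardGeneric("variantRecords"))

#' Subject identifier
#'
#' @param x A [SubjectVariantSet-class] object.
#' @return A single character label.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' Per-gene index of variant records
#'
#' Partitions the records of a subject variant set by gene symbol.
#'
#' @param x A [SubjectVariantSet-class] object.
#' @return A named list of `data.frame`s, one per gene symbol.
#' @export
setGeneric("geneIndex", function(x) standardGeneric("geneIndex"))

#' Filter funnel report
#'
#' Every filter applied to a [SubjectVariantSet-class] appends an entry with
#' input/output record counts and per-reason removal counts, so the whole
#' filter cascade is auditable.
#'
#' @param x A [SubjectVariantSet-class] object.
#' @return A list of per-stage reports.
#' @export
setGeneric("filterReport", function(x) standardGeneric("filterReport"))

#' Node annotation table of a gene network
#'
#' @param x A [GeneNetwork-class] object.
#' @return A `data.frame` with a `gene` column plus annotation columns.
#' @export
setGeneric("nodeData", function(x) standardGeneric("nodeData"))

#' Edge table of a gene network
#'
#' @param x A [GeneNetwork-class] object.
#' @return A `data.frame` with `from` and `to` columns.
#' @export
setGeneric("edgeData", function(x) standardGeneric("edgeData"))

#' Convert a gene network to an igraph object
#'
#' @param x A [GeneNetwork-class] object.
#' @return An `igraph` graph with node annotations as vertex attributes.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' Number of nodes / edges in a gene network
#'
#' @param x A [GeneNetwork-class] object.
#' @return An integer count.
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname numNodes
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Counts-per-million matrix
#'
#' CPM is recomputed from the current counts, so each column always sums to
#' one million whatever filtering has been applied.
#'
#' @param x A [GeneCountMatrix-class] object.
#' @param log Logical; return `log2(CPM + prior)` instead of CPM.
#' @param prior Pseudo-count added before the log transform.
#' @return A numeric matrix, genes by samples.
#' @export
setGeneric("cpm", function(x, log = FALSE, prior = 1) standardGeneric("cpm"))

#' Sample group labels
#'
#' @param x A [GeneCountMatrix-class] object.
#' @return A factor of per-sample group labels.
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' Genes of a phenotype panel (union over terms)
#'
#' @param x A [PhenotypePanel-class] object.
#' @return A character vector of gene symbols.
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))

#' Giant component of a decomposition
#'
#' @param x A [ComponentDecomposition-class] object.
#' @return A [GeneNetwork-class] object (the largest connected component).
#' @export
setGeneric("giantNetwork", function(x) standardGeneric("giantNetwork"))
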