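## Phenotype-panel construction, variant overlay onto networks,
## CADD-threshold subnetworks and the final candidate-modifier shortlist.

#' Build a phenotype virtual gene panel
#'
#' Collects the genes annotated to the queried phenotype-ontology terms
#' into a disease-specific virtual panel (the union over terms).
#'
#' @param hpo_annotations Term-to-gene table with `term_id`, `term_name`,
#'   `gene_symbol` columns (see [readGenesToPhenotype()]).
#' @param query_terms Term ids to include; every id must be present in the
#'   annotation table, otherwise the call fails listing the offenders.
#' @param disease Disease label stored on the panel.
#' @return A [PhenotypePanel-class].
#' @export
buildPhenotypePanel <- function(hpo_annotations, query_terms = NULL,
                                disease = "disease") {
  if (is.null(query_terms)) query_terms <- unique(hpo_annotations$term_id)
  unknown <- setdiff(query_terms, hpo_annotations$term_id)
  if (length(unknown)) {
    stop("unknown phenotype term(s): ", paste(unknown, collapse = ", "))
  }
  ann <- hpo_annotations[hpo_annotations$term_id %in% query_terms, ,
                         drop = FALSE]
  ann <- ann[!duplicated(ann[, c("term_id", "gene_symbol")]), , drop = FALSE]
  per_term <- stats::aggregate(gene_symbol ~ term_id + term_name, ann, length)
  names(per_term)[3] <- "n_genes"
  new("PhenotypePanel", disease = disease,
      terms = per_term[order(per_term$term_id), ],
      annotations = ann[order(ann$term_id, ann$gene_symbol), ],
      genes = sort(unique(ann$gene_symbol)))
}

#' Overlay per-subject variant annotations onto a network
#'
#' Attaches to every node the (possibly empty) list of that gene's variant
#' records in each subject — allele frequency, CADD, zygosity, coding
#' annotation — without touching the topology: node and edge counts are
#' preserved exactly.
#'
#' @param n A [GeneNetwork-class].
#' @param a,b [SubjectVariantSet-class] objects for the two subjects.
#' @return The same network with list-columns `variants_a` and
#'   `variants_b` (per-node record `data.frame`s) and convenience columns
#'   `max_cadd_a`, `max_cadd_b`, `any_hom_a`, `any_hom_b`.
#' @export
overlayVariants <- function(n, a, b) {
  nodes <- nodeData(n)
  attach_cols <- c("hgvsc", "allele_frequency", "cadd_phred", "pli", "zygosity")
  per_gene <- function(s) {
    rec <- variantRecords(s)
    idx <- split(seq_len(nrow(rec)), rec$gene_symbol)
    lapply(stats::setNames(nodes$gene, nodes$gene), function(g) {
      rows <- idx[[g]]
      if (is.null(rows)) {
        rec[0, attach_cols, drop = FALSE]
      } else {
        rec[rows, attach_cols, drop = FALSE]
      }
    })
  }
  va <- per_gene(a)
  vb <- per_gene(b)
  max_or_na <- function(v) if (length(v) && any(!is.na(v))) max(v, na.rm = TRUE) else NA_real_
  nodes$variants_a <- unname(va)
  nodes$variants_b <- unname(vb)
  nodes$max_cadd_a <- vapply(va, function(d) max_or_na(d$cadd_phred), numeric(1))
  nodes$max_cadd_b <- vapply(vb, function(d) max_or_na(d$cadd_phred), numeric(1))
  nodes$any_hom_a <- vapply(va, function(d) any(d$zygosity == "hom"), logical(1))
  nodes$any_hom_b <- vapply(vb, function(d) any(d$zygosity == "hom"), logical(1))
  initialize(n, nodes = nodes)
}

#' Subject-specific CADD-threshold subnetwork
#'
#' Keeps the nodes carrying at least one variant with CADD at or above
#' `cadd_min` in the given subject (allele frequency is deliberately
#' ignored at this stage: common polymorphisms can act as genetic
#' modifiers), induces the edges, and decomposes the result into giant
#' component, secondary clusters, triads, pairs and singletons.
#'
#' @param n A variant-overlaid network from [overlayVariants()].
#' @param cadd_min CADD threshold (15 targets moderate-to-high impact).
#' @param subject `"a"` or `"b"`: which subject's variants to filter on.
#' @return A [ComponentDecomposition-class] of the induced subnetwork.
#' @export
caddSubnetwork <- function(n, cadd_min = 15, subject = c("a", "b")) {
  subject <- match.arg(subject)
  nodes <- nodeData(n)
  col <- paste0("variants_", subject)
  if (!col %in% names(nodes)) stop("run overlayVariants() first")
  qualifies <- vapply(nodes[[col]], function(d) {
    any(!is.na(d$cadd_phred) & d$cadd_phred >= cadd_min)
  }, logical(1))
  keep <- nodes$gene[qualifies]
  ed <- edgeData(n)
  ed <- ed[ed$from %in% keep & ed$to %in% keep, , drop = FALSE]
  sub <- geneNetwork(nodes[qualifies, , drop = FALSE], ed,
                     directed = n@directed)
  giantComponent(sub)
}

#' Shortlist candidate genetic modifiers
#'
#' Emits the genes of the giant component of a subject-specific
#' CADD-filtered subnetwork as candidate modifiers, each with its evidence
#' flags: `rare` (some qualifying variant with AF < `af_max` or
#' unannotated), `high_cadd` (CADD >= `cadd_min`), `homozygous_burden`
#' (some qualifying homozygous variant), `differentially_expressed`
#' (`padj < alpha` in the DE table), `phenotype_panel_member` and
#' `giant_component_member`. The three required flags — high CADD,
#' panel membership, giant-component membership — are conjunctive: genes
#' missing any of them are excluded. Candidates are sorted by number of
#' true flags (descending), then maximum CADD (descending), then gene.
#'
#' @param decomp A [ComponentDecomposition-class] from [caddSubnetwork()].
#' @param panel A [PhenotypePanel-class].
#' @param de A DE table from [nbWaldTest()].
#' @param subject `"a"` or `"b"`, matching the subject used in
#'   [caddSubnetwork()].
#' @param cadd_min,af_max,alpha Flag thresholds.
#' @return A `data.frame` of candidates with the evidence flags,
#'   `n_flags` and `max_cadd`; empty (with a warning) when the giant
#'   component is empty.
#' @export
shortlistCandidates <- function(decomp, panel, de, subject = c("a", "b"),
                                cadd_min = 15, af_max = 0.01, alpha = 0.05) {
  subject <- match.arg(subject)
  giant <- giantNetwork(decomp)
  nodes <- nodeData(giant)
  if (!nrow(nodes)) {
    warning("the giant component is empty; no candidates")
    return(data.frame(gene = character(), subject = character(),
                      rare = logical(), high_cadd = logical(),
                      homozygous_burden = logical(),
                      differentially_expressed = logical(),
                      phenotype_panel_member = logical(),
                      giant_component_member = logical(),
                      n_flags = integer(), max_cadd = numeric()))
  }
  col <- paste0("variants_", subject)
  if (!col %in% names(nodes)) stop("the decomposition must come from an overlaid network")
  qual <- lapply(nodes[[col]], function(d) {
    d[!is.na(d$cadd_phred) & d$cadd_phred >= cadd_min, , drop = FALSE]
  })
  sig_genes <- de$gene[!is.na(de$padj) & de$padj < alpha]
  out <- data.frame(
    gene = nodes$gene,
    subject = subject,
    rare = vapply(qual, function(d) {
      nrow(d) > 0 && any(is.na(d$allele_frequency) | d$allele_frequency < af_max)
    }, logical(1)),
    high_cadd = vapply(qual, function(d) nrow(d) > 0, logical(1)),
    homozygous_burden = vapply(qual, function(d) any(d$zygosity == "hom"),
                               logical(1)),
    differentially_expressed = nodes$gene %in% sig_genes,
    phenotype_panel_member = nodes$gene %in% panelGenes(panel),
    giant_component_member = TRUE,
    max_cadd = vapply(qual, function(d) {
      if (nrow(d)) max(d$cadd_phred) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  flag_cols <- c("rare", "high_cadd", "homozygous_burden",
                 "differentially_expressed", "phenotype_panel_member",
                 "giant_component_member")
  out$n_flags <- rowSums(out[, flag_cols])
  out <- out[out$high_cadd & out$phenotype_panel_member, , drop = FALSE]
  out <- out[order(-out$n_flags, -out$max_cadd, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
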