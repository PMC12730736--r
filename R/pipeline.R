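## Orchestration: run configuration, the three workflows (genomic,
## transcriptomic, integration) and run manifests. A 1-vs-1 analysis lives
## or dies by provenance, so every stage writes a manifest with input and
## output checksums and logs each filter's input/output counts; outputs
## contain no timestamps, so a rerun with the same config is byte-identical
## for the deterministic stages.

.THRESHOLD_RANGES <- list(
  af_max = c(0, 1), cadd_high = c(0, 99), cadd_mid = c(0, 99),
  pli_min = c(0, 1), cpm_min = c(0, Inf), min_samples = c(1, Inf),
  alpha = c(0, 1), retain_fraction = c(0, 1)
)

#' Construct a run configuration
#'
#' A plain named list (class `RunConfig`) holding input paths, the analysis
#' thresholds, the seed and the output directory. It round-trips through
#' [writeRunConfig()] / [readRunConfig()] identically.
#'
#' @param inputs Named list of input paths: `vcf1`, `ann1`, `vcf2`, `ann2`,
#'   `interactome` (PSI-MITAB), `fi_db` (directed TSV), `counts`,
#'   `phenotype` (genes_to_phenotype TSV), `gene_sets` (GMT).
#' @param out_dir Output directory.
#' @param seed Integer seed for the stochastic stages (GSEA permutations).
#' @param af_max,cadd_high,cadd_mid,pli_min,cpm_min,min_samples,alpha,retain_fraction
#'   Analysis thresholds (defaults: 0.01, 30, 15, 0.9, 0.5, 2, 0.05, 0.10).
#' @return A `RunConfig` list.
#' @export
runConfig <- function(inputs, out_dir, seed = 1, af_max = 0.01,
                      cadd_high = 30, cadd_mid = 15, pli_min = 0.9,
                      cpm_min = 0.5, min_samples = 2, alpha = 0.05,
                      retain_fraction = 0.10) {
  cfg <- list(inputs = lapply(inputs, as.character),
              out_dir = as.character(out_dir), seed = as.integer(seed),
              thresholds = list(af_max = af_max, cadd_high = cadd_high,
                                cadd_mid = cadd_mid, pli_min = pli_min,
                                cpm_min = cpm_min, min_samples = min_samples,
                                alpha = alpha,
                                retain_fraction = retain_fraction))
  class(cfg) <- c("RunConfig", "list")
  validateRunConfig(cfg)
  cfg
}

#' @rdname runConfig
#' @param cfg A `RunConfig`.
#' @export
validateRunConfig <- function(cfg) {
  stopifnot(is.list(cfg$inputs), length(cfg$out_dir) == 1)
  for (nm in names(.THRESHOLD_RANGES)) {
    v <- cfg$thresholds[[nm]]
    r <- .THRESHOLD_RANGES[[nm]]
    if (is.null(v) || !is.numeric(v) || v < r[1] || v > r[2]) {
      stop("threshold '", nm, "' missing or outside [", r[1], ", ", r[2], "]")
    }
  }
  invisible(cfg)
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file path.
#' @return `readRunConfig()` returns a validated `RunConfig`.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("RunConfig", "list")
  validateRunConfig(cfg)
  cfg
}

#' @rdname readRunConfig
#' @param cfg A `RunConfig`.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

.check_inputs <- function(cfg, needed) {
  paths <- unlist(cfg$inputs[needed])
  missing <- needed[!needed %in% names(cfg$inputs)]
  if (length(missing)) stop("config lacks input(s): ", paste(missing, collapse = ", "))
  absent <- paths[!file.exists(paths)]
  if (length(absent)) {
    stop("missing input file(s): ", paste(absent, collapse = ", "))
  }
  invisible(paths)
}

.write_manifest <- function(stage, cfg, inputs, outputs, dir) {
  manifest <- list(
    stage = stage, seed = cfg$seed, thresholds = cfg$thresholds,
    inputs = as.list(tools::md5sum(inputs)),
    outputs = as.list(tools::md5sum(unlist(outputs)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

.funnel <- function(label, set) {
  rep <- filterReport(set)
  for (e in rep) {
    message(sprintf("[%s] %s: %s -> %s records", label, e$stage,
                    if (!is.null(e$n_in)) e$n_in else "?", e$n_out))
  }
}

.read_subject <- function(cfg, which) {
  readAnnotatedVariants(cfg$inputs[[paste0("vcf", which)]],
                        cfg$inputs[[paste0("ann", which)]],
                        paste0("subject", which))
}

.decomp_summary <- function(d) {
  list(giant_nodes = numNodes(giantNetwork(d)),
       giant_edges = numEdges(giantNetwork(d)),
       secondary_clusters = length(d@secondaryClusters),
       triads = d@nTriads, pairs = d@nPairs, singletons = d@nSingletons)
}

#' Run the genomic workflow
#'
#' Parses both subjects' annotated variants, applies the QC and rare
#' filters, partitions variants and genes between the subjects, builds the
#' subject-specific PPI networks on the rare-variant genes, extracts their
#' giant components and runs over-representation analysis on the
#' giant-component genes. All artifacts plus a checksum manifest are
#' written under `out_dir/genomic/`.
#'
#' @param cfg A `RunConfig`.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
runGenomic <- function(cfg) {
  validateRunConfig(cfg)
  .check_inputs(cfg, c("vcf1", "ann1", "vcf2", "ann2", "interactome",
                       "gene_sets"))
  dir <- file.path(cfg$out_dir, "genomic")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  th <- cfg$thresholds

  s1 <- rareFilter(qcFilter(.read_subject(cfg, 1)), th$af_max)
  s2 <- rareFilter(qcFilter(.read_subject(cfg, 2)), th$af_max)
  .funnel("subject1", s1); .funnel("subject2", s2)
  venn <- partitionBySubject(s1, s2)

  edges <- readMitab(cfg$inputs$interactome)
  nets <- list(subject1 = buildSubjectPPI(unique(variantRecords(s1)$gene_symbol), edges),
               subject2 = buildSubjectPPI(unique(variantRecords(s2)$gene_symbol), edges))
  decomps <- lapply(nets, giantComponent)

  sets <- readGmt(cfg$inputs$gene_sets)
  universe <- unique(c(edges$source, edges$target,
                       variantRecords(s1)$gene_symbol,
                       variantRecords(s2)$gene_symbol))
  enrich <- lapply(decomps, function(d) {
    ora(nodeData(giantNetwork(d))$gene, sets, universe, alpha = th$alpha)
  })

  outputs <- list()
  for (nm in names(nets)) {
    v <- if (nm == "subject1") s1 else s2
    outputs[[paste0(nm, "_variants")]] <- file.path(dir, paste0(nm, "_rare_variants.tsv"))
    utils::write.table(variantRecords(v), outputs[[paste0(nm, "_variants")]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    outputs[[paste0(nm, "_report")]] <-
      writeFilterReport(v, file.path(dir, paste0(nm, "_filter_report.tsv")))
    outputs[[paste0(nm, "_network")]] <-
      exportGraphML(nets[[nm]], file.path(dir, paste0(nm, "_ppi.graphml")))
    outputs[[paste0(nm, "_ora")]] <- file.path(dir, paste0(nm, "_ora.tsv"))
    utils::write.table(enrich[[nm]], outputs[[paste0(nm, "_ora")]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  outputs$venn <- writeVennJson(venn, file.path(dir, "venn_summary.json"))
  outputs$components <- file.path(dir, "component_summary.json")
  jsonlite::write_json(lapply(decomps, .decomp_summary), outputs$components,
                       auto_unbox = TRUE, pretty = TRUE)
  manifest <- .write_manifest("genomic", cfg,
                              unlist(cfg$inputs[c("vcf1", "ann1", "vcf2",
                                                  "ann2", "interactome",
                                                  "gene_sets")]),
                              outputs, dir)
  invisible(list(subject1 = s1, subject2 = s2, venn = venn, networks = nets,
                 decompositions = decomps, enrichment = enrich,
                 manifest = manifest, outputs = outputs))
}

## shared transcriptomic core: filtering, DE, RFE, intersection, FI network
.transcriptomic_core <- function(cfg) {
  th <- cfg$thresholds
  m <- readCountsTsv(cfg$inputs$counts)
  m <- filterLowExpression(m, th$cpm_min, th$min_samples)
  m <- removeHLA(m)
  de <- nbWaldTest(m, alpha = th$alpha)
  rfe <- rfeSelect(m, retain_fraction = th$retain_fraction)
  degs <- intersectSelections(de, rfe, alpha = th$alpha)
  fi_db <- utils::read.delim(cfg$inputs$fi_db)
  fi_net <- buildFINetwork(degs, fi_db)
  list(counts = m, de = de, rfe = rfe, degs = degs, fi_db = fi_db,
       fi_network = fi_net)
}

#' Run the transcriptomic workflow
#'
#' Filters the count matrix (low expression, HLA genes), runs the NB Wald
#' test and sPLS-DA/RFE, intersects the two selections into the
#' high-confidence DEG list, builds the functional-interaction network with
#' linkers, computes node topology, and runs preranked GSEA on the log2
#' fold changes across all genes. Artifacts go to `out_dir/transcriptomic/`.
#'
#' @param cfg A `RunConfig`.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
runTranscriptomic <- function(cfg) {
  validateRunConfig(cfg)
  .check_inputs(cfg, c("counts", "fi_db", "gene_sets"))
  dir <- file.path(cfg$out_dir, "transcriptomic")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  th <- cfg$thresholds

  core <- .transcriptomic_core(cfg)
  message(sprintf("[transcriptomic] %d genes after filtering; %d DEGs; %d after RFE; %d intersected",
                  nrow(core$counts), sum(core$de$padj < th$alpha, na.rm = TRUE),
                  length(core$rfe@finalGenes), nrow(core$degs)))
  qc <- qcSummary(core$counts)
  topo <- nodeTopology(core$fi_network)
  ranking <- stats::setNames(core$de$log2fc, core$de$gene)
  sets <- readGmt(cfg$inputs$gene_sets)
  gsea <- gseaPreranked(ranking, sets, n_perm = 1000, seed = cfg$seed)

  outputs <- list(
    de = file.path(dir, "de_results.tsv"),
    degs = file.path(dir, "intersected_degs.tsv"),
    rfe = file.path(dir, "rfe_trace.json"),
    qc = file.path(dir, "qc_summary.json"),
    topology = file.path(dir, "fi_topology.tsv"),
    gsea = file.path(dir, "gsea_results.tsv"),
    fi_network = file.path(dir, "fi_network.graphml")
  )
  utils::write.table(core$de, outputs$de, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(core$degs, outputs$degs, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(sizes = vapply(core$rfe@trace, length, integer(1)),
                            final = core$rfe@finalGenes),
                       outputs$rfe, auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(qc, outputs$qc, auto_unbox = TRUE, pretty = TRUE,
                       digits = 10)
  utils::write.table(topo, outputs$topology, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gsea, outputs$gsea, sep = "\t", quote = FALSE, row.names = FALSE)
  exportGraphML(core$fi_network, outputs$fi_network)
  manifest <- .write_manifest("transcriptomic", cfg,
                              unlist(cfg$inputs[c("counts", "fi_db", "gene_sets")]),
                              outputs, dir)
  invisible(c(core, list(qc = qc, topology = topo, gsea = gsea,
                         manifest = manifest, outputs = outputs)))
}

#' Run the integration workflow
#'
#' Builds the phenotype virtual gene panel and its disease-phenotype
#' network, intersects the phenotype network's giant component with the
#' functional-interaction network (FI edges retained), overlays per-subject
#' variant annotations, extracts the subject-specific CADD-threshold
#' subnetworks, shortlists candidate modifiers and runs enrichment on the
#' giant-component genes. Artifacts go to `out_dir/integration/`.
#'
#' @param cfg A `RunConfig`.
#' @return Invisibly, a list with the in-memory stage results, including
#'   the per-subject candidate tables.
#' @export
runIntegration <- function(cfg) {
  validateRunConfig(cfg)
  .check_inputs(cfg, c("vcf1", "ann1", "vcf2", "ann2", "interactome",
                       "counts", "fi_db", "phenotype", "gene_sets"))
  dir <- file.path(cfg$out_dir, "integration")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  th <- cfg$thresholds

  ann <- readGenesToPhenotype(cfg$inputs$phenotype)
  panel <- buildPhenotypePanel(ann)
  edges <- readMitab(cfg$inputs$interactome)
  pheno_net <- buildSubjectPPI(panelGenes(panel), edges)
  pheno_giant <- giantNetwork(giantComponent(pheno_net))

  core <- .transcriptomic_core(cfg)
  inter <- intersectNetworks(pheno_giant, core$fi_network, edge_source = "b")

  s1 <- qcFilter(.read_subject(cfg, 1))
  s2 <- qcFilter(.read_subject(cfg, 2))
  overlaid <- overlayVariants(inter, s1, s2)

  decomp1 <- caddSubnetwork(overlaid, th$cadd_mid, "a")
  decomp2 <- caddSubnetwork(overlaid, th$cadd_mid, "b")
  cand1 <- shortlistCandidates(decomp1, panel, core$de, "a",
                               cadd_min = th$cadd_mid, af_max = th$af_max,
                               alpha = th$alpha)
  cand2 <- shortlistCandidates(decomp2, panel, core$de, "b",
                               cadd_min = th$cadd_mid, af_max = th$af_max,
                               alpha = th$alpha)
  message(sprintf("[integration] panel %d genes; intersected network %d nodes; candidates %d / %d",
                  length(panelGenes(panel)), numNodes(inter),
                  nrow(cand1), nrow(cand2)))

  sets <- readGmt(cfg$inputs$gene_sets)
  universe <- unique(c(edges$source, edges$target, core$de$gene))
  enrich <- list(
    subject1 = ora(nodeData(giantNetwork(decomp1))$gene, sets, universe,
                   alpha = th$alpha),
    subject2 = ora(nodeData(giantNetwork(decomp2))$gene, sets, universe,
                   alpha = th$alpha)
  )

  outputs <- list(
    panel = file.path(dir, "phenotype_panel.tsv"),
    network = file.path(dir, "integrated_network.graphml"),
    components = file.path(dir, "component_summary.json"),
    candidates1 = file.path(dir, "subject1_candidates.tsv"),
    candidates2 = file.path(dir, "subject2_candidates.tsv"),
    ora_long = file.path(dir, "enrichment_long.tsv")
  )
  utils::write.table(panel@annotations, outputs$panel, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  exportGraphML(inter, outputs$network)
  jsonlite::write_json(list(subject1 = .decomp_summary(decomp1),
                            subject2 = .decomp_summary(decomp2)),
                       outputs$components, auto_unbox = TRUE, pretty = TRUE)
  utils::write.table(cand1, outputs$candidates1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cand2, outputs$candidates2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(enrichmentLongFormat(enrich), outputs$ora_long,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- .write_manifest("integration", cfg,
                              unlist(cfg$inputs[c("vcf1", "ann1", "vcf2",
                                                  "ann2", "interactome",
                                                  "counts", "fi_db",
                                                  "phenotype", "gene_sets")]),
                              outputs, dir)
  invisible(list(panel = panel, phenotype_giant = pheno_giant,
                 intersected = inter, overlaid = overlaid,
                 decompositions = list(subject1 = decomp1, subject2 = decomp2),
                 candidates = list(subject1 = cand1, subject2 = cand2),
                 enrichment = enrich, manifest = manifest, outputs = outputs))
}

#' Run all three workflows
#'
#' @param cfg A `RunConfig`.
#' @return Invisibly, a list with the three stage results.
#' @export
runAll <- function(cfg) {
  invisible(list(genomic = runGenomic(cfg),
                 transcriptomic = runTranscriptomic(cfg),
                 integration = runIntegration(cfg)))
}

#' Write a markdown run report
#'
#' Summarizes the funnel counts and candidate tables of a completed run in
#' a single human-readable markdown file.
#'
#' @param results The list returned by [runAll()].
#' @param path Output markdown path.
#' @return Invisibly, `path`.
#' @export
reportRun <- function(results, path) {
  lines <- c("# Modifier-prioritization run report", "")
  g <- results$genomic
  if (!is.null(g)) {
    lines <- c(lines, "## Genomic", "",
               sprintf("- subject1 rare variants: %d", nrow(variantRecords(g$subject1))),
               sprintf("- subject2 rare variants: %d", nrow(variantRecords(g$subject2))),
               sprintf("- shared variant keys: %d", g$venn$variant$counts[["shared"]]),
               "")
  }
  t <- results$transcriptomic
  if (!is.null(t)) {
    lines <- c(lines, "## Transcriptomic", "",
               sprintf("- genes tested: %d", nrow(t$de)),
               sprintf("- univariate DEGs: %d", sum(t$de$padj < 0.05, na.rm = TRUE)),
               sprintf("- RFE-retained genes: %d", length(t$rfe@finalGenes)),
               sprintf("- intersected DEGs: %d", nrow(t$degs)),
               "")
  }
  i <- results$integration
  if (!is.null(i)) {
    lines <- c(lines, "## Integration", "",
               sprintf("- panel genes: %d", length(panelGenes(i$panel))),
               sprintf("- candidates subject1: %s",
                       paste(i$candidates$subject1$gene, collapse = ", ")),
               sprintf("- candidates subject2: %s",
                       paste(i$candidates$subject2$gene, collapse = ", ")),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}
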