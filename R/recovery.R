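## End-to-end recovery of planted modifiers on a synthetic study: the
## scoring harness for the pipeline's headline property — that genes
## planted as subject-1-unique rare high-CADD variants, differentially
## expressed and phenotype-annotated end up on the candidate shortlist.

#' Run the full analysis chain on an in-memory synthetic study
#'
#' Executes the complete modifier-prioritization chain — expression
#' filtering, NB Wald test, sPLS-DA/RFE, DEG intersection, FI network with
#' linkers, phenotype panel, network intersection, variant overlay,
#' CADD-threshold subnetworks and candidate shortlisting — on a
#' [simulateStudy()] bundle, without touching the file system.
#'
#' @param study A list from [simulateStudy()].
#' @param af_max,cadd_mid,alpha,retain_fraction Analysis thresholds.
#' @return A list with the intermediate results (`de`, `rfe`, `degs`,
#'   `fi_network`, `panel`, `intersected`, `decompositions`) and the
#'   per-subject `candidates` tables.
#' @export
runSyntheticStudy <- function(study, af_max = 0.01, cadd_mid = 15,
                              alpha = 0.05, retain_fraction = 0.10) {
  m <- removeHLA(filterLowExpression(study$counts))
  de <- nbWaldTest(m, alpha = alpha)
  rfe <- rfeSelect(m, retain_fraction = retain_fraction)
  degs <- intersectSelections(de, rfe, alpha = alpha)
  fi_net <- buildFINetwork(degs, study$fi_db)
  panel <- buildPhenotypePanel(study$panel)
  pheno_net <- buildSubjectPPI(panelGenes(panel), study$interactome)
  pheno_giant <- giantNetwork(giantComponent(pheno_net))
  inter <- intersectNetworks(pheno_giant, fi_net, edge_source = "b")
  overlaid <- overlayVariants(inter, qcFilter(study$subject1),
                              qcFilter(study$subject2))
  decomp <- list(subject1 = caddSubnetwork(overlaid, cadd_mid, "a"),
                 subject2 = caddSubnetwork(overlaid, cadd_mid, "b"))
  cand <- list(
    subject1 = shortlistCandidates(decomp$subject1, panel, de, "a",
                                   cadd_min = cadd_mid, af_max = af_max,
                                   alpha = alpha),
    subject2 = shortlistCandidates(decomp$subject2, panel, de, "b",
                                   cadd_min = cadd_mid, af_max = af_max,
                                   alpha = alpha)
  )
  list(de = de, rfe = rfe, degs = degs, fi_network = fi_net, panel = panel,
       intersected = inter, overlaid = overlaid, decompositions = decomp,
       candidates = cand)
}

#' Score recovery of planted modifiers
#'
#' Simulates a study under the given settings, runs the full chain and
#' reports how many of the planted modifier genes appear on subject 1's
#' candidate shortlist.
#'
#' @param seed Integer seed for the simulated study.
#' @param ... Passed to [simulateStudy()].
#' @return A list with `recovered` (genes), `n_planted`, `n_recovered`,
#'   `fraction` and the full `result`.
#' @export
recoverPlantedModifiers <- function(seed, ...) {
  study <- simulateStudy(seed = seed, ...)
  res <- runSyntheticStudy(study)
  planted <- study$truth@modifierGenes
  recovered <- intersect(planted, res$candidates$subject1$gene)
  list(recovered = recovered, n_planted = length(planted),
       n_recovered = length(recovered),
       fraction = length(recovered) / max(length(planted), 1),
       result = res, truth = study$truth)
}
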