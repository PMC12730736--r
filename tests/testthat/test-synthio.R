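test_that("variant tables share exactly n_shared keys and plant modifiers in subject 1", {
  sim <- simulateVariantTables(100, 50, 10, n_planted = 2, seed = 1)
  key <- function(s) {
    r <- variantRecords(s)
    unique(paste(r$chrom, r$pos, r$ref, r$alt, sep = ":"))
  }
  k1 <- key(sim$subject1); k2 <- key(sim$subject2)
  expect_length(intersect(k1, k2), 50)
  expect_length(k1, 60)
  expect_length(k2, 60)

  r1 <- variantRecords(sim$subject1)
  planted <- r1[r1$gene_symbol %in% sim$truth@modifierGenes &
                r1$cadd_phred >= 30, ]
  expect_equal(nrow(planted), 2)
  expect_true(all(is.na(planted$allele_frequency) |
                  planted$allele_frequency < 0.01))
  expect_true(all(planted$zygosity == "hom"))
  # planted keys are absent from subject 2
  pk <- paste(planted$chrom, planted$pos, planted$ref, planted$alt, sep = ":")
  expect_length(intersect(pk, k2), 0)
})

test_that("the same seed reproduces variant tables byte-identically", {
  a <- simulateVariantTables(100, 50, 10, n_planted = 2, seed = 1)
  b <- simulateVariantTables(100, 50, 10, n_planted = 2, seed = 1)
  expect_identical(variantRecords(a$subject1), variantRecords(b$subject1))
  expect_identical(variantRecords(a$subject2), variantRecords(b$subject2))
  c <- simulateVariantTables(100, 50, 10, n_planted = 2, seed = 2)
  expect_false(identical(variantRecords(a$subject1), variantRecords(c$subject1)))
})

test_that("with nothing planted, the filter cascade matches a brute-force row scan", {
  sim <- simulateVariantTables(200, 100, 30, n_planted = 0, seed = 3)
  filtered <- highImpactFilter(rareFilter(sim$subject1), 30)
  r <- variantRecords(sim$subject1)
  brute <- sum((is.na(r$allele_frequency) | r$allele_frequency < 0.01) &
               !is.na(r$cadd_phred) & r$cadd_phred >= 30)
  expect_equal(nrow(variantRecords(filtered)), brute)
  # background CADD is bounded by 25, so nothing survives
  expect_equal(brute, 0)
})

test_that("variant generator rejects impossible requests", {
  expect_error(simulateVariantTables(0, 10, 5, seed = 1), "positive")
  expect_error(simulateVariantTables(100, 50, 10, n_planted = 11, seed = 1),
               "n_planted")
  expect_error(simulateVariantTables(2, 1e5, 1e5, seed = 1), "capacity")
})

test_that("interactome has the promised structure", {
  expect_equal(nrow(simulateInteractome(2, seed = 1)), 1)
  e <- simulateInteractome(500, seed = 7)
  expect_equal(sum(e$source == e$target), 0)
  key <- paste(pmin(e$source, e$target), pmax(e$source, e$target))
  expect_equal(anyDuplicated(key), 0)
  expect_true(all(e$taxon_a == 9606 & e$taxon_b == 9606))
  expect_error(simulateInteractome(10, degree_model = 0.5), ">= 1")
})

test_that("interactome giant-component fraction matches a BFS oracle", {
  e <- simulateInteractome(500, seed = 7)
  nodes <- sprintf("GENE%05d", 1:500)
  net <- geneNetwork(nodes, data.frame(from = e$source, to = e$target))
  giant_frac <- numNodes(giantNetwork(giantComponent(net))) / 500
  adj <- adjacency_list(nodes, e$source, e$target)
  best <- 0
  remaining <- nodes
  while (length(remaining)) {
    comp <- bfs_component(remaining[1], adj)
    best <- max(best, length(comp))
    remaining <- setdiff(remaining, comp)
  }
  expect_equal(giant_frac, best / 500)
  expect_gte(giant_frac, 0.8)
})

test_that("null counts have near-zero mean log-ratio and DE-free truth", {
  sim <- simulateCounts(5000, de_fraction = 0, seed = 11)
  k <- cpm(sim$counts)   # depth-normalized: library sizes vary by design
  g <- sampleGroups(sim$counts) == "group1"
  ratio <- log2((rowMeans(k[, g]) + 0.5) / (rowMeans(k[, !g]) + 0.5))
  expect_lt(abs(mean(ratio)), 0.05)
  expect_equal(nrow(sim$truth@deGenes), 0)
})

test_that("in the Poisson large-count limit the DE ratio approaches 2^lfc", {
  sim <- simulateCounts(300, de_fraction = 0.2, effect_log2fc = 2,
                        dispersion = 0, libsize_mean = 5e6,
                        libsize_sigma = 0, seed = 12)
  k <- SummarizedExperiment::assay(sim$counts, "counts")
  g <- sampleGroups(sim$counts) == "group1"
  tr <- sim$truth@deGenes
  up <- tr$gene[tr$true_log2fc > 0]
  obs <- rowMeans(k[up, g]) / rowMeans(k[up, !g])
  expect_equal(median(obs), 4, tolerance = 0.1)
  expect_identical(
    SummarizedExperiment::assay(simulateCounts(50, seed = 4)$counts, "counts"),
    SummarizedExperiment::assay(simulateCounts(50, seed = 4)$counts, "counts"))
  expect_error(simulateCounts(50, dispersion = -1), "dispersion")
  expect_error(simulateCounts(50, n_reps = 1), "n_reps")
})

test_that("phenotype panel covers the include set and round-trips through the reader", {
  genes <- paste0("G", 1:50)
  inc <- c("G1", "G2", "G3")
  tab <- simulatePhenotypePanel(genes, n_terms = 4, genes_per_term = c(5, 10),
                                include = inc, seed = 2)
  expect_true(all(inc %in% tab$gene_symbol))
  one <- simulatePhenotypePanel(genes, n_terms = 1, genes_per_term = c(7, 7),
                                seed = 3)
  expect_equal(length(unique(one$gene_symbol)),
               sum(one$term_id == one$term_id[1]))
  f1 <- tempfile(); f2 <- tempfile()
  writeGenesToPhenotype(tab, f1)
  writeGenesToPhenotype(simulatePhenotypePanel(genes, n_terms = 4,
                                               genes_per_term = c(5, 10),
                                               include = inc, seed = 2), f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- readGenesToPhenotype(f1)
  expect_setequal(back$gene_symbol, tab$gene_symbol)
  expect_setequal(back$term_id, tab$term_id)
  expect_error(simulatePhenotypePanel(character(), n_terms = 1), "empty")
})

test_that("simulated study tables parse losslessly through the package readers", {
  study <- small_study(seed = 6)
  dir <- withr::local_tempdir()
  paths <- writeStudyFiles(study, dir)

  s1 <- readAnnotatedVariants(paths$vcf1, paths$ann1, "subject1")
  expect_equal(nrow(variantRecords(s1)), nrow(variantRecords(study$subject1)))
  edges <- readMitab(paths$interactome)
  expect_equal(nrow(edges), nrow(study$interactome))
  m <- readCountsTsv(paths$counts)
  expect_identical(SummarizedExperiment::assay(m, "counts"),
                   SummarizedExperiment::assay(study$counts, "counts"))
  expect_identical(as.character(sampleGroups(m)),
                   as.character(sampleGroups(study$counts)))
  ann <- readGenesToPhenotype(paths$phenotype)
  expect_setequal(unique(ann$gene_symbol), unique(study$panel$gene_symbol))
  sets <- readGmt(paths$gene_sets)
  expect_identical(lapply(sets, sort), lapply(study$gene_sets, sort))
})

test_that("the study truth links modifiers to both the DE set and the panel", {
  study <- small_study(seed = 9)
  tr <- study$truth
  expect_true(all(tr@modifierGenes %in% tr@deGenes$gene))
  expect_true(all(tr@modifierGenes %in% tr@panelGenes))
  expect_true(all(abs(tr@deGenes$true_log2fc) == 2))
})
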