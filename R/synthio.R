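## Synthetic-data generators.
##
## Every generator is fully determined by its `seed` argument and emits the
## same tabular formats the corresponding readers consume, so the whole
## pipeline is testable without any external download. Ground truth (planted
## modifier genes, DE genes, panel membership) is returned as a SimTruth.

.default_gene_names <- function(n) sprintf("GENE%05d", seq_len(n))

#' Simulate annotated variant tables for two subjects
#'
#' Emulates the exome comparison of two related subjects: a large body of
#' shared variants plus subject-unique variants, with `n_planted` "modifier"
#' variants planted only in subject 1 — rare (gnomAD AF < 0.01 or missing),
#' highly deleterious (CADD in \[30, 50\]) and homozygous, so the downstream
#' rare/high-impact filter cascade can recover them.
#'
#' Background allele frequencies follow a Beta(0.2, 5) mixture with a stated
#' fraction of records missing AF (emulating alleles absent from the
#' reference population); background CADD scores are Uniform(0, 25);
#' background zygosity is Bernoulli(0.1) homozygous.
#'
#' @param n_genes Size of the gene universe.
#' @param n_shared Number of variant keys present in both subjects.
#' @param n_unique_per_subject Number of subject-unique variant keys each.
#' @param n_planted Number of planted modifier variants (subject 1 only);
#'   must not exceed `n_unique_per_subject`.
#' @param seed Integer seed; fully determines the output.
#' @param gene_names Optional gene universe (length `n_genes`).
#' @param modifier_genes Optional genes to plant the modifiers in (sampled
#'   from the universe when `NULL`).
#' @param af_missing_rate Fraction of background records with missing AF.
#' @param hom_rate Background homozygosity rate.
#' @return A list with elements `subject1` and `subject2`
#'   ([SubjectVariantSet-class]) and `truth` ([SimTruth-class]).
#' @examples
#' sim <- simulateVariantTables(100, 50, 10, n_planted = 2, seed = 1)
#' sim$truth
#' @export
simulateVariantTables <- function(n_genes, n_shared, n_unique_per_subject,
                                  n_planted = 0, seed = 1,
                                  gene_names = NULL, modifier_genes = NULL,
                                  af_missing_rate = 0.1, hom_rate = 0.1) {
  if (n_genes <= 0 || n_shared < 0 || n_unique_per_subject <= 0) {
    stop("variant counts must be positive")
  }
  if (n_planted > n_unique_per_subject) {
    stop("n_planted must not exceed n_unique_per_subject")
  }
  n_total <- n_shared + 2L * n_unique_per_subject
  ## each gene owns a 10 kb window of candidate positions
  if (n_total > n_genes * 10000) {
    stop("requested variant count exceeds the positional capacity of the gene universe")
  }
  if (is.null(gene_names)) gene_names <- .default_gene_names(n_genes)
  stopifnot(length(gene_names) == n_genes)
  set.seed(seed)

  if (is.null(modifier_genes)) {
    modifier_genes <- sample(gene_names, n_planted)
  }
  stopifnot(length(modifier_genes) == n_planted, all(modifier_genes %in% gene_names))

  gene_chrom <- sample(as.character(1:22), n_genes, replace = TRUE)
  names(gene_chrom) <- gene_names

  ## assign genes: planted variants go to the modifier genes, the rest uniform
  n_background <- n_total - n_planted
  genes <- c(sample(gene_names, n_background, replace = TRUE), modifier_genes)
  ## unique positions inside each gene's window
  pos <- integer(n_total)
  for (g in unique(genes)) {
    idx <- which(genes == g)
    offset <- (match(g, gene_names) - 1L) * 10000L
    pos[idx] <- offset + sample.int(10000L, length(idx))
  }
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, n_total, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1), "")

  af <- stats::rbeta(n_total, 0.2, 5)
  af[stats::runif(n_total) < af_missing_rate] <- NA_real_
  cadd <- stats::runif(n_total, 0, 25)
  pli <- ifelse(stats::runif(n_total) < 0.15, stats::runif(n_total), 0)
  pli[stats::runif(n_total) < 0.1] <- NA_real_

  planted_idx <- if (n_planted) (n_background + 1L):n_total else integer()
  if (n_planted) {
    af[planted_idx] <- stats::runif(n_planted, 0, 0.009)
    af[planted_idx][stats::runif(n_planted) < 0.3] <- NA_real_
    cadd[planted_idx] <- stats::runif(n_planted, 30, 50)
  }

  base <- data.frame(
    chrom = gene_chrom[genes], pos = pos, ref = ref, alt = alt,
    gene_symbol = genes, biotype = "protein_coding",
    hgvsc = paste0("c.", pos %% 10000L, ref, ">", alt),
    hgvsp = NA_character_,
    allele_frequency = af, cadd_phred = cadd, pli = pli,
    stringsAsFactors = FALSE
  )
  rownames(base) <- NULL

  shared_idx <- seq_len(n_shared)
  uniq1_idx <- c(n_shared + seq_len(n_unique_per_subject - n_planted), planted_idx)
  uniq2_idx <- n_shared + (n_unique_per_subject - n_planted) +
    seq_len(n_unique_per_subject)

  draw_zyg <- function(n) ifelse(stats::runif(n) < hom_rate, "hom", "het")
  tab1 <- base[c(shared_idx, uniq1_idx), , drop = FALSE]
  tab1$zygosity <- draw_zyg(nrow(tab1))
  tab1$zygosity[tab1$pos %in% base$pos[planted_idx] &
                tab1$gene_symbol %in% modifier_genes &
                tab1$cadd_phred >= 30] <- "hom"
  tab1$subject_id <- "subject1"
  tab2 <- base[c(shared_idx, uniq2_idx), , drop = FALSE]
  tab2$zygosity <- draw_zyg(nrow(tab2))
  tab2$subject_id <- "subject2"

  truth <- new("SimTruth", modifierGenes = as.character(modifier_genes),
               deGenes = data.frame(gene = character(), true_log2fc = numeric()),
               panelGenes = character(), seed = as.integer(seed))
  list(subject1 = subjectVariantSet(tab1, "subject1"),
       subject2 = subjectVariantSet(tab2, "subject2"),
       truth = truth)
}

#' Simulate an undirected protein-protein interactome
#'
#' Generates a scale-free (preferential attachment) interactome over the gene
#' universe, optionally densified inside pathway-like modules with
#' Erdos-Renyi within-module edges — real interaction databases are locally
#' dense around pathways, and downstream induced subgraphs inherit that
#' structure. The result is connected by construction of the preferential
#' attachment backbone (every new node attaches to an existing one), so the
#' giant component always covers all nodes.
#'
#' @param n_nodes Number of genes (>= 2).
#' @param degree_model Preferential-attachment parameter: edges added per new
#'   node (>= 1).
#' @param taxon NCBI taxonomy identifier recorded on both interactors.
#' @param seed Integer seed.
#' @param gene_names Optional node names (length `n_nodes`).
#' @param modules Optional list of character vectors (gene modules) to
#'   densify with within-module edges.
#' @param module_p Within-module edge probability when `modules` is given.
#' @return A `data.frame` of undirected edges with columns `source`,
#'   `target`, `taxon_a`, `taxon_b`, `provenance` (no self-loops, no
#'   duplicate unordered pairs).
#' @examples
#' edges <- simulateInteractome(50, seed = 7)
#' nrow(edges)
#' @export
simulateInteractome <- function(n_nodes, degree_model = 2, taxon = 9606,
                                seed = 1, gene_names = NULL,
                                modules = NULL, module_p = 0.25) {
  if (n_nodes < 2) stop("n_nodes must be at least 2")
  if (degree_model < 1) stop("degree_model (edges per new node) must be >= 1")
  if (is.null(gene_names)) gene_names <- .default_gene_names(n_nodes)
  stopifnot(length(gene_names) == n_nodes)
  set.seed(seed)
  g <- igraph::sample_pa(n_nodes, power = 1, m = degree_model,
                         directed = FALSE, algo = "psumtree")
  el <- igraph::as_edgelist(g, names = FALSE)
  from <- gene_names[el[, 1]]
  to <- gene_names[el[, 2]]
  if (!is.null(modules)) {
    for (mod in modules) {
      mod <- intersect(mod, gene_names)
      if (length(mod) < 2) next
      pairs <- utils::combn(sort(mod), 2)
      keep <- stats::runif(ncol(pairs)) < module_p
      from <- c(from, pairs[1, keep])
      to <- c(to, pairs[2, keep])
    }
  }
  key <- paste(pmin(from, to), pmax(from, to), sep = "\r")
  dup <- duplicated(key) | from == to
  from <- from[!dup]; to <- to[!dup]
  data.frame(source = from, target = to,
             taxon_a = as.integer(taxon), taxon_b = as.integer(taxon),
             provenance = sprintf("SIM-%06d", seq_along(from)),
             stringsAsFactors = FALSE)
}

#' Simulate a directed functional-interaction database
#'
#' Same topology model as [simulateInteractome()] (scale-free backbone plus
#' optional dense pathway modules), but each edge is given a random direction,
#' emulating a curated functional-interaction database with signalling
#' direction flags.
#'
#' @inheritParams simulateInteractome
#' @return A `data.frame` with columns `source`, `target`, `direction`
#'   (always `"->"`), `annotation`.
#' @export
simulateFiDatabase <- function(n_nodes, degree_model = 3, seed = 1,
                               gene_names = NULL, modules = NULL,
                               module_p = 0.3) {
  edges <- simulateInteractome(n_nodes, degree_model = degree_model,
                               seed = seed, gene_names = gene_names,
                               modules = modules, module_p = module_p)
  flip <- stats::runif(nrow(edges)) < 0.5
  src <- ifelse(flip, edges$target, edges$source)
  tgt <- ifelse(flip, edges$source, edges$target)
  data.frame(source = src, target = tgt, direction = "->",
             annotation = "simulated functional interaction",
             stringsAsFactors = FALSE)
}

#' Simulate a two-group negative-binomial count matrix
#'
#' Draws integer counts \eqn{K_{ij} \sim NB(\mu_{ij}, \alpha)} with
#' \eqn{\mu_{ij} = L_j \, p_i \, 2^{\pm \log_2\!FC/2}} — the fold change is
#' split symmetrically across the two groups, so a DE gene's expected
#' between-group count ratio is exactly \eqn{2^{\log_2 FC}}. Library sizes
#' \eqn{L_j} are log-normal with sigma 0.2 (so median-of-ratios
#' normalization is exercised nontrivially), and baseline proportions
#' \eqn{p_i} are log-normal.
#'
#' @param n_genes Number of genes.
#' @param n_reps Replicates per group (>= 2); the design is 2 x `n_reps`.
#' @param de_fraction Fraction of genes that are differentially expressed
#'   (ignored when `de_genes` is supplied).
#' @param effect_log2fc Absolute log2 fold change of DE genes; each planted
#'   gene gets a random sign. May be negative (sign is folded into the draw);
#'   `dispersion` must be positive (0 is treated as the Poisson limit).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param libsize_mean,libsize_sigma Log-normal library-size model.
#' @param seed Integer seed.
#' @param gene_names Optional gene names.
#' @param de_genes Optional character vector of genes to plant as DE.
#' @return A list with `counts` ([GeneCountMatrix-class]) and `truth`
#'   ([SimTruth-class]) whose `deGenes` table carries the signed true log2
#'   fold changes.
#' @examples
#' sim <- simulateCounts(100, de_fraction = 0.1, effect_log2fc = 2,
#'                       dispersion = 0.05, seed = 1)
#' sim$truth
#' @export
simulateCounts <- function(n_genes, n_reps = 3, de_fraction = 0.1,
                           effect_log2fc = 2, dispersion = 0.05,
                           libsize_mean = 1e6, libsize_sigma = 0.2,
                           seed = 1, gene_names = NULL, de_genes = NULL) {
  if (n_reps < 2) stop("n_reps must be at least 2")
  if (dispersion < 0) stop("dispersion must be non-negative")
  if (de_fraction < 0 || de_fraction > 1) stop("de_fraction must lie in [0,1]")
  if (is.null(gene_names)) gene_names <- .default_gene_names(n_genes)
  stopifnot(length(gene_names) == n_genes)
  set.seed(seed)

  if (is.null(de_genes)) {
    n_de <- round(de_fraction * n_genes)
    de_genes <- sample(gene_names, n_de)
  } else {
    stopifnot(all(de_genes %in% gene_names))
  }
  lfc <- numeric(n_genes)
  names(lfc) <- gene_names
  lfc[de_genes] <- abs(effect_log2fc) * sample(c(-1, 1), length(de_genes), replace = TRUE)

  baseline <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1.2)
  p <- baseline / sum(baseline)
  libsize <- stats::rlnorm(2 * n_reps, meanlog = log(libsize_mean), sdlog = libsize_sigma)
  group <- rep(c("group1", "group2"), each = n_reps)
  half <- ifelse(group == "group1", 1, -1)

  mu <- outer(p, libsize) * 2^(outer(lfc / 2, half))
  counts <- if (dispersion < 1e-12) {
    matrix(stats::rpois(length(mu), lambda = mu), nrow = n_genes)
  } else {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion), nrow = n_genes)
  }
  dimnames(counts) <- list(gene_names,
                           paste0(rep(c("s1_rep", "s2_rep"), each = n_reps),
                                  rep(seq_len(n_reps), 2)))
  truth <- new("SimTruth", modifierGenes = character(),
               deGenes = data.frame(gene = de_genes,
                                    true_log2fc = unname(lfc[de_genes])),
               panelGenes = character(), seed = as.integer(seed))
  list(counts = geneCountMatrix(counts, group), truth = truth)
}

#' Simulate a phenotype-ontology annotation table
#'
#' Builds an HPO-style term-to-gene table: `n_terms` synthetic phenotype
#' terms, each annotated with a random draw of genes from the universe, with
#' every gene in `include` guaranteed to be annotated to at least one term.
#' The table round-trips through [readGenesToPhenotype()].
#'
#' @param genes Gene universe to draw annotations from.
#' @param n_terms Number of phenotype terms.
#' @param genes_per_term Length-2 range of genes per term.
#' @param include Genes that must be annotated to at least one term.
#' @param seed Integer seed.
#' @return A `data.frame` with `term_id`, `term_name`, `gene_symbol`.
#' @examples
#' simulatePhenotypePanel(paste0("G", 1:20), n_terms = 3,
#'                        genes_per_term = c(3, 6), seed = 1)
#' @export
simulatePhenotypePanel <- function(genes, n_terms = 10,
                                   genes_per_term = c(10, 30),
                                   include = character(), seed = 1) {
  if (!length(genes)) stop("the gene universe must not be empty")
  stopifnot(all(include %in% genes))
  set.seed(seed)
  sizes <- sample(genes_per_term[1]:genes_per_term[2], n_terms, replace = TRUE)
  sizes <- pmin(sizes, length(genes))
  rows <- lapply(seq_len(n_terms), function(k) {
    data.frame(term_id = sprintf("HP:%07d", 9000000 + k),
               term_name = sprintf("Synthetic phenotype %d", k),
               gene_symbol = sample(genes, sizes[k]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  for (g in include) {
    if (!g %in% tab$gene_symbol) {
      k <- sample.int(n_terms, 1)
      tab <- rbind(tab, data.frame(term_id = sprintf("HP:%07d", 9000000 + k),
                                   term_name = sprintf("Synthetic phenotype %d", k),
                                   gene_symbol = g))
    }
  }
  tab <- tab[!duplicated(tab[, c("term_id", "gene_symbol")]), ]
  tab <- tab[order(tab$term_id, tab$gene_symbol), ]
  rownames(tab) <- NULL
  tab
}

#' Simulate a complete synthetic modifier study
#'
#' Composes the individual generators into one coherent "study": a gene
#' universe partitioned into pathway-like modules, a module-structured
#' interactome and functional-interaction database, two subject variant
#' tables with planted subject-1 modifiers, a 2 x `n_reps` NB count matrix in
#' which the modifiers are differentially expressed, and a phenotype panel
#' covering the disease modules (and therefore the modifiers). The planted
#' modifiers live in the first disease module, DE genes are concentrated in
#' the disease modules, and panel terms annotate disease-module genes — the
#' statistical structure the integration pipeline assumes.
#'
#' @param n_genes Gene universe size.
#' @param n_modules Number of equally sized pathway modules.
#' @param n_disease_modules Leading modules treated as disease-related.
#' @param n_planted Number of planted modifier genes (all in module 1).
#' @param n_shared,n_unique Variant-table sizes (see
#'   [simulateVariantTables()]).
#' @param de_fraction,effect_log2fc,dispersion,n_reps Count-model settings
#'   (see [simulateCounts()]).
#' @param n_panel_terms Number of phenotype-panel terms.
#' @param seed Integer seed; fully determines the study.
#' @return A list: `subject1`, `subject2` (variant sets), `interactome`,
#'   `fi_db` (edge tables), `counts`, `panel` (annotation table),
#'   `gene_sets` (module gene sets, GMT-ready), `modules`, `truth`.
#' @export
simulateStudy <- function(n_genes = 2000, n_modules = 40,
                          n_disease_modules = 6, n_planted = 5,
                          n_shared = 4000, n_unique = 1000,
                          de_fraction = 0.075, effect_log2fc = 2,
                          dispersion = 0.05, n_reps = 3,
                          n_panel_terms = 12, seed = 1) {
  set.seed(seed)
  genes <- .default_gene_names(n_genes)
  module_id <- rep(seq_len(n_modules), length.out = n_genes)
  module_id <- sort(module_id)
  modules <- split(genes, module_id)
  names(modules) <- sprintf("MODULE_%02d", seq_len(n_modules))

  disease_genes <- unlist(modules[seq_len(n_disease_modules)], use.names = FALSE)
  modifiers <- sample(modules[[1]], n_planted)

  ## DE genes: most in the disease modules (where the panel looks), the rest
  ## anywhere; modifiers are always DE.
  n_de <- round(de_fraction * n_genes)
  n_disease_de <- round(0.6 * n_de)
  de_genes <- unique(c(
    modifiers,
    sample(disease_genes, min(n_disease_de, length(disease_genes))),
    sample(setdiff(genes, disease_genes), n_de - n_disease_de)
  ))

  counts <- simulateCounts(n_genes, n_reps = n_reps,
                           effect_log2fc = effect_log2fc,
                           dispersion = dispersion,
                           seed = seed + 1L, gene_names = genes,
                           de_genes = de_genes)
  vars <- simulateVariantTables(n_genes, n_shared = n_shared,
                                n_unique_per_subject = n_unique,
                                n_planted = n_planted, seed = seed + 2L,
                                gene_names = genes,
                                modifier_genes = modifiers)
  interactome <- simulateInteractome(n_genes, degree_model = 2,
                                     seed = seed + 3L, gene_names = genes,
                                     modules = modules, module_p = 0.25)
  fi_db <- simulateFiDatabase(n_genes, degree_model = 3, seed = seed + 4L,
                              gene_names = genes, modules = modules,
                              module_p = 0.3)
  panel <- simulatePhenotypePanel(disease_genes, n_terms = n_panel_terms,
                                  genes_per_term = c(25, 50),
                                  include = modifiers, seed = seed + 5L)

  truth <- new("SimTruth", modifierGenes = modifiers,
               deGenes = counts$truth@deGenes,
               panelGenes = sort(unique(panel$gene_symbol)),
               seed = as.integer(seed))
  list(subject1 = vars$subject1, subject2 = vars$subject2,
       interactome = interactome, fi_db = fi_db,
       counts = counts$counts, panel = panel,
       gene_sets = modules, modules = modules, truth = truth)
}
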