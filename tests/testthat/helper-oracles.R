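# Independent oracles used across the suite. Each is deliberately written
# with a different algorithm than the implementation it checks.

# union-find connected components; edges as a two-column character matrix
uf_components <- function(nodes, from, to) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_along(from)) {
    ra <- find(from[i]); rb <- find(to[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, "")
  split(nodes, roots)
}

# breadth-first search component containing `start`
bfs_component <- function(start, adj) {
  seen <- start
  queue <- start
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    nb <- setdiff(adj[[x]], seen)
    seen <- c(seen, nb)
    queue <- c(queue, nb)
  }
  seen
}

adjacency_list <- function(nodes, from, to) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(from)) {
    adj[[from[i]]] <- c(adj[[from[i]]], to[i])
    adj[[to[i]]] <- c(adj[[to[i]]], from[i])
  }
  adj
}

# reference BH step-up: p * m / rank with running minimum from the top
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# exact hypergeometric upper tail by term-wise summation with explicit
# binomial coefficients (independent of phyper)
hyper_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# classical unweighted KS enrichment score by walking the full ranking
ks_es_unweighted <- function(ranked_genes, set) {
  N <- length(ranked_genes)
  inset <- ranked_genes %in% set
  k <- sum(inset)
  run <- cumsum(ifelse(inset, 1 / k, -1 / (N - k)))
  run[which.max(abs(run))]
}

# a small fast study for pipeline-level tests
small_study <- function(seed = 5) {
  simulateStudy(n_genes = 400, n_modules = 8, n_disease_modules = 6,
                n_planted = 3, n_shared = 800, n_unique = 200,
                n_panel_terms = 8, seed = seed)
}

make_variant_records <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    chrom = sample(as.character(1:5), n, TRUE),
    pos = sample.int(1e5, n), ref = "A", alt = "G",
    gene_symbol = paste0("G", sample.int(max(2, n %/% 2), n, TRUE)),
    biotype = "protein_coding", hgvsc = NA, hgvsp = NA,
    allele_frequency = ifelse(runif(n) < 0.2, NA, runif(n)),
    cadd_phred = runif(n, 0, 50),
    pli = ifelse(runif(n) < 0.3, NA, runif(n)),
    zygosity = sample(c("het", "hom"), n, TRUE),
    subject_id = "s", stringsAsFactors = FALSE
  )
}
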