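## Over-representation analysis, redundancy reduction by weighted set
## cover, and preranked GSEA with a weighted Kolmogorov-Smirnov running
## sum. BH adjustment is applied per gene-set collection (database).

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of
#' observing at least the attained overlap between the query and the set,
#' against the supplied reference universe (typically the protein-coding
#' genome). Query genes outside the universe are dropped with a warning;
#' set members outside the universe do not count toward the set size.
#' P-values are Benjamini-Hochberg adjusted across all terms of the
#' collection.
#'
#' @param query Character vector of genes of interest.
#' @param collection Named list of gene sets (e.g., from [readGmt()]).
#' @param universe Reference gene universe.
#' @param alpha FDR threshold used for the `significant` flag.
#' @param min_overlap Minimum overlap for a term to be reported.
#' @return A `data.frame` with one row per term: `term`, `overlap`,
#'   `set_size`, `expected`, `enrichment_ratio`, `pvalue`, `fdr`,
#'   `significant`, `members` (overlap genes, `/`-separated), sorted by
#'   p-value.
#' @export
ora <- function(query, collection, universe, alpha = 0.05, min_overlap = 0) {
  if (!length(universe)) stop("the reference universe must not be empty")
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe were dropped")
    query <- intersect(query, universe)
  }
  n <- length(query)
  N <- length(universe)
  rows <- lapply(names(collection), function(term) {
    set <- intersect(unique(collection[[term]]), universe)
    K <- length(set)
    members <- intersect(query, set)
    k <- length(members)
    expected <- n * K / N
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, overlap = k, set_size = K, expected = expected,
               enrichment_ratio = if (expected > 0) k / expected else NA_real_,
               pvalue = p,
               members = paste(sort(members), collapse = "/"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$overlap >= min_overlap, , drop = FALSE]
  out$fdr <- stats::p.adjust(out$pvalue, method = "BH")
  out$significant <- out$fdr < alpha
  out <- out[order(out$pvalue, out$term),
             c("term", "overlap", "set_size", "expected", "enrichment_ratio",
               "pvalue", "fdr", "significant", "members")]
  rownames(out) <- NULL
  out
}

#' Reduce enriched terms by weighted set cover
#'
#' Greedy redundancy reduction: repeatedly select the term maximizing
#' (newly covered member genes) / weight, with weight
#' `1 / (-log10(fdr) + eps)` — i.e., more significant terms are cheaper —
#' until every gene covered by any input term is covered, or `top_k` terms
#' have been chosen. Ties break deterministically by fdr, then term name.
#'
#' @param significant An [ora()] result (or any `data.frame` with `term`,
#'   `fdr` and `/`-separated `members` columns), typically pre-filtered to
#'   the significant terms.
#' @param top_k Maximum number of terms to select (`Inf` for no cap).
#' @param eps Guard against division by zero at fdr = 1.
#' @return The selected rows, in selection order, with a `new_genes`
#'   column counting the genes each term added.
#' @export
weightedSetCover <- function(significant, top_k = Inf, eps = 1e-300) {
  if (!nrow(significant)) return(cbind(significant, new_genes = integer()))
  members <- strsplit(significant$members, "/", fixed = TRUE)
  weight <- 1 / (-log10(pmax(significant$fdr, 1e-300)) + eps)
  uncovered <- unique(unlist(members))
  chosen <- integer()
  gained <- integer()
  while (length(uncovered) && length(chosen) < top_k) {
    newly <- vapply(members, function(mm) length(intersect(mm, uncovered)),
                    integer(1))
    newly[chosen] <- 0L
    score <- newly / weight
    if (all(score <= 0)) break
    best <- which(score == max(score))
    if (length(best) > 1) {
      best <- best[order(significant$fdr[best], significant$term[best])][1]
    }
    chosen <- c(chosen, best)
    gained <- c(gained, newly[best])
    uncovered <- setdiff(uncovered, members[[best]])
  }
  out <- significant[chosen, , drop = FALSE]
  out$new_genes <- gained
  rownames(out) <- NULL
  out
}

## signed running-sum enrichment score from the sorted hit positions.
## pos: positions of the set genes in the ranking (sorted increasing);
## w: |ranking metric|^p at those positions; N: total genes.
.es_from_positions <- function(pos, w, N) {
  k <- length(pos)
  nr <- sum(w)
  if (nr == 0) w <- rep(1, k) / k else w <- w
  hit <- cumsum(w) / sum(w)
  miss_after <- (pos - seq_len(k)) / (N - k)
  dev_top <- hit - miss_after                 # just after each hit
  dev_bottom <- c(0, hit[-k]) - miss_after    # just before each hit
  hi <- max(dev_top)
  lo <- min(dev_bottom)
  if (hi >= -lo) hi else lo
}

#' Preranked gene set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment scores on a ranked
#' gene list (e.g., log2 fold changes across all genes), with a null built
#' by gene-label permutation: at 3+3 replicates sample permutation is
#' degenerate, so the preranked gene-permutation convention is used.
#' The p-value compares the observed score with null scores of matching
#' sign; NES divides the score by the mean absolute null score of that
#' sign; FDR is a BH adjustment over terms.
#'
#' @param ranking Named numeric vector (gene -> ranking metric), no
#'   duplicated names.
#' @param collection Named list of gene sets.
#' @param n_perm Number of gene-label permutations (>= 100).
#' @param weight_p Weighting exponent on the ranking metric (1 is the
#'   standard weighted statistic; 0 recovers the classical unweighted KS).
#' @param min_size Terms with fewer ranked genes are skipped with a warning.
#' @param seed Integer seed for the permutations.
#' @return A `data.frame` with `term`, `size`, `es`, `nes`, `pvalue`,
#'   `fdr`, sorted by p-value.
#' @export
gseaPreranked <- function(ranking, collection, n_perm = 1000, weight_p = 1,
                          min_size = 3, seed = 1) {
  if (anyDuplicated(names(ranking))) stop("ranking has duplicated genes")
  if (n_perm < 100) stop("n_perm must be at least 100")
  ord <- order(-ranking, names(ranking))
  ranked_genes <- names(ranking)[ord]
  metric <- abs(ranking[ord])^weight_p
  N <- length(ranking)
  set.seed(seed)

  sizes <- vapply(collection, function(s) length(intersect(s, ranked_genes)),
                  integer(1))
  skipped <- names(collection)[sizes < min_size]
  if (length(skipped)) {
    warning(length(skipped), " term(s) with fewer than ", min_size,
            " ranked genes were skipped")
  }
  collection <- collection[sizes >= min_size]
  rows <- lapply(names(collection), function(term) {
    pos <- sort(match(intersect(collection[[term]], ranked_genes),
                      ranked_genes))
    k <- length(pos)
    es <- .es_from_positions(pos, metric[pos], N)
    null_es <- vapply(seq_len(n_perm), function(i) {
      p <- sort(sample.int(N, k))
      .es_from_positions(p, metric[p], N)
    }, numeric(1))
    same_sign <- null_es[sign(null_es) == sign(es)]
    pvalue <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))
    denom <- mean(abs(same_sign))
    nes <- if (is.finite(denom) && denom > 0) es / denom else NA_real_
    data.frame(term = term, size = k, es = es, nes = nes, pvalue = pvalue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(), size = integer(), es = numeric(),
                      nes = numeric(), pvalue = numeric(), fdr = numeric()))
  }
  out$fdr <- stats::p.adjust(out$pvalue, method = "BH")
  out <- out[order(out$pvalue, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Long-format export of enrichment results for bubble plots
#'
#' One row per (term, subject) with the gene count and FDR — the layout
#' used for cross-subject enrichment bubble charts.
#'
#' @param results Named list of [ora()] tables, one per subject.
#' @param significant_only Keep only FDR-significant terms.
#' @return A `data.frame` with `term`, `subject`, `gene_count`, `fdr`.
#' @export
enrichmentLongFormat <- function(results, significant_only = TRUE) {
  rows <- lapply(names(results), function(subj) {
    r <- results[[subj]]
    if (significant_only) r <- r[r$significant, , drop = FALSE]
    if (!nrow(r)) return(NULL)
    data.frame(term = r$term, subject = subj, gene_count = r$overlap,
               fdr = r$fdr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(), subject = character(),
                      gene_count = integer(), fdr = numeric())
  }
  rownames(out) <- NULL
  out
}
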