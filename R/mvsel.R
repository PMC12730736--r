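## Sparse PLS-DA with recursive feature elimination, and the
## univariate-multivariate intersection selector. In a 1-vs-1 subject
## comparison (3+3 replicates) cross-validation is degenerate, so model
## size is fixed (one component, no CV) and sparsity enters through the
## RFE schedule rather than a tuned keep parameter.

.splsda_matrix <- function(m, groups) {
  if (is(m, "GeneCountMatrix")) {
    x <- t(cpm(m, log = TRUE))
    if (is.null(groups)) groups <- sampleGroups(m)
  } else {
    x <- t(as.matrix(m))
  }
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  if (any(table(groups) < 2)) stop("each group needs at least two samples")
  list(x = x, groups = groups)
}

#' Fit a sparse PLS-DA model
#'
#' Encodes class membership as a centered +/-1 indicator and extracts
#' latent components that maximize the covariance between predictor scores
#' and the response. Predictors (genes) are centered and unit-scaled;
#' constant genes are dropped. Sparsity is imposed by hard-thresholding
#' each loading vector to its `keep` largest-magnitude entries before
#' renormalization; the predictor matrix is deflated between components.
#'
#' @param m A [GeneCountMatrix-class] (log2 CPM is used) or a
#'   genes-by-samples numeric matrix.
#' @param groups Two-level sample labels (taken from `m` when it is a
#'   [GeneCountMatrix-class]).
#' @param n_components Number of latent components.
#' @param keep Number of nonzero loadings per component (recycled);
#'   `NULL` keeps all genes (dense PLS-DA).
#' @return An [SplsdaFit-class].
#' @export
splsdaFit <- function(m, groups = NULL, n_components = 1, keep = NULL) {
  inp <- .splsda_matrix(m, groups)
  x <- inp$x
  groups <- inp$groups
  sds <- apply(x, 2, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  genes <- colnames(x)
  if (!length(genes)) stop("no non-constant genes to fit")
  if (!is.null(keep) && any(keep > length(genes))) {
    stop("keep exceeds the number of (non-constant) genes")
  }
  keep <- if (is.null(keep)) rep(length(genes), n_components) else
    rep_len(keep, n_components)

  x <- scale(x, center = TRUE, scale = TRUE)
  y <- ifelse(groups == levels(groups)[1], 1, -1)
  y <- y - mean(y)
  total_var <- sum(x^2)

  loadings <- matrix(0, length(genes), n_components,
                     dimnames = list(genes, paste0("comp", seq_len(n_components))))
  scores <- matrix(0, nrow(x), n_components,
                   dimnames = list(rownames(x), colnames(loadings)))
  varexp <- numeric(n_components)
  xd <- x
  yd <- y
  for (h in seq_len(n_components)) {
    w <- drop(crossprod(xd, yd))
    if (keep[h] < length(w)) {
      ## hard-threshold to the keep largest |w|; lexicographic tie-break
      ord <- order(-abs(w), genes)
      w[-ord[seq_len(keep[h])]] <- 0
    }
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_h <- drop(xd %*% w)
    tt <- sum(t_h^2)
    p_h <- drop(crossprod(xd, t_h)) / tt
    c_h <- sum(yd * t_h) / tt
    loadings[, h] <- w
    scores[, h] <- t_h
    varexp[h] <- tt * sum(p_h^2) / total_var
    xd <- xd - tcrossprod(t_h, p_h)
    yd <- yd - t_h * c_h
  }
  new("SplsdaFit", loadings = loadings, scores = scores,
      varianceExplained = varexp,
      sparsity = as.integer(colSums(loadings != 0)),
      genes = genes)
}

#' Recursive feature elimination under sPLS-DA ranking
#'
#' Iteratively refits a one-component PLS-DA on the surviving genes, ranks
#' genes by the absolute first-component loading (lexicographic gene-symbol
#' tie-break), and drops the bottom `step_fraction`, until the retained set
#' reaches the target size `floor(retain_fraction * initial count)` — the
#' last step truncates exactly to the target. Deterministic for fixed
#' inputs and invariant to the input order of genes.
#'
#' @param m,groups As in [splsdaFit()].
#' @param retain_fraction Target fraction of genes to retain, in (0, 1).
#' @param step_fraction Fraction of surviving genes dropped per iteration.
#' @return An [RfeResult-class] whose `trace` starts at the full gene set.
#' @export
rfeSelect <- function(m, groups = NULL, retain_fraction = 0.10,
                      step_fraction = 0.2) {
  if (retain_fraction <= 0 || retain_fraction >= 1) {
    stop("retain_fraction must lie strictly between 0 and 1")
  }
  inp <- .splsda_matrix(m, groups)
  x_all <- inp$x
  groups <- inp$groups
  genes <- sort(colnames(x_all))
  target <- floor(retain_fraction * length(genes))
  if (target < 1) stop("retain_fraction leaves no genes")

  current <- genes
  trace <- list(current)
  while (length(current) > target) {
    fit <- splsdaFit(t(x_all[, current, drop = FALSE]), groups,
                     n_components = 1)
    w <- abs(fit@loadings[, 1])
    ranked <- fit@genes[order(-w, fit@genes)]
    ## genes dropped as constant rank below everything
    ranked <- c(ranked, setdiff(current, ranked))
    next_n <- max(target, floor(length(current) * (1 - step_fraction)))
    if (next_n >= length(current)) next_n <- length(current) - 1L
    current <- sort(ranked[seq_len(next_n)])
    trace <- c(trace, list(current))
  }
  new("RfeResult", trace = trace, finalGenes = current,
      retainFraction = retain_fraction)
}

#' Intersect univariate and multivariate gene selections
#'
#' The high-confidence DEG list: genes significant in the NB Wald test
#' (`padj < alpha`) that also survive recursive feature elimination.
#' Directions are carried from the univariate result.
#'
#' @param univariate A DE table from [nbWaldTest()].
#' @param multivariate An [RfeResult-class].
#' @param alpha Adjusted-p significance threshold.
#' @return A `data.frame` with `gene`, `log2fc`, `padj`, `direction`,
#'   sorted by gene.
#' @export
intersectSelections <- function(univariate, multivariate, alpha = 0.05) {
  sig <- univariate[!is.na(univariate$padj) & univariate$padj < alpha, ,
                    drop = FALSE]
  keep <- intersect(sig$gene, multivariate@finalGenes)
  out <- sig[match(sort(keep), sig$gene),
             c("gene", "log2fc", "padj", "direction"), drop = FALSE]
  rownames(out) <- NULL
  out
}
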