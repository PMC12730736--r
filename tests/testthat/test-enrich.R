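test_that("ORA reproduces the closed-form hypergeometric tail", {
  universe <- paste0("u", 1:20)
  set <- universe[1:5]
  res <- ora(set, list(S = set), universe)
  expect_equal(res$pvalue, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$overlap, 5)
  expect_equal(res$enrichment_ratio, 5 / (5 * 5 / 20))

  # query == universe: every overlap equals the set size and p = 1
  coll <- list(A = universe[1:7], B = universe[4:20])
  res <- ora(universe, coll, universe)
  expect_equal(res$overlap[match(c("A", "B"), res$term)], c(7, 17))
  expect_true(all(res$pvalue == 1))
  expect_error(ora(set, coll, character()), "empty")
  expect_warning(ora(c(set, "absent"), coll, universe), "outside")
})

test_that("ORA p-values agree with explicit tail enumeration on random instances", {
  for (i in 1:30) {
    set.seed(i)
    N <- sample(10:30, 1)
    universe <- paste0("g", 1:N)
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    coll <- list(T = sample(universe, K))
    query <- sample(universe, n)
    res <- ora(query, coll, universe)
    k <- length(intersect(query, coll$T))
    expect_equal(res$pvalue, hyper_tail(k, K, N, n), tolerance = 1e-10)
  }
})

test_that("ORA is invariant under a relabeling of genes", {
  set.seed(99)
  universe <- paste0("g", 1:50)
  coll <- list(T = sample(universe, 12))
  query <- sample(universe, 15)
  p1 <- ora(query, coll, universe)$pvalue
  relab <- setNames(paste0("h", sample(50)), universe)
  p2 <- ora(unname(relab[query]), list(T = unname(relab[coll$T])),
            unname(relab))$pvalue
  expect_equal(p1, p2)
})

test_that("weighted set cover keeps disjoint terms and drops nested duplicates", {
  tab <- data.frame(term = c("A", "B", "C"), fdr = c(0.01, 0.01, 0.01),
                    members = c("a/b/c", "d/e", "f"))
  got <- weightedSetCover(tab)
  expect_setequal(got$term, c("A", "B", "C"))
  expect_equal(got$term[1], "A")  # largest new coverage first

  nested <- data.frame(term = c("A", "B"), fdr = c(0.01, 0.01),
                       members = c("a/b/c/d", "b/c"))
  expect_equal(weightedSetCover(nested)$term, "A")
  expect_equal(nrow(weightedSetCover(tab[0, ])), 0)
})

test_that("unbounded set cover covers everything and stays within the greedy bound", {
  for (i in 1:15) {
    set.seed(i)
    n_terms <- sample(4:8, 1)
    genes <- paste0("x", 1:12)
    members <- lapply(seq_len(n_terms), function(j)
      sort(sample(genes, sample(2:6, 1))))
    tab <- data.frame(term = paste0("T", seq_len(n_terms)),
                      fdr = round(runif(n_terms, 1e-6, 0.05), 6),
                      members = vapply(members, paste, "", collapse = "/"))
    got <- weightedSetCover(tab, top_k = Inf)
    expect_setequal(unlist(strsplit(got$members, "/")), unique(unlist(members)))

    # exhaustive optimum over all covering subsets (weights as implemented)
    w <- 1 / (-log10(tab$fdr) + 1e-300)
    target <- unique(unlist(members))
    best <- Inf
    for (mask in 1:(2^n_terms - 1)) {
      idx <- which(bitwAnd(mask, 2^(seq_len(n_terms) - 1)) > 0)
      if (setequal(intersect(unlist(members[idx]), target), target)) {
        best <- min(best, sum(w[idx]))
      }
    }
    greedy_cost <- sum(w[match(got$term, tab$term)])
    H <- sum(1 / seq_len(length(target)))
    expect_lte(greedy_cost, H * best + 1e-12)
  }
})

test_that("a set at the top of the ranking approaches the maximal enrichment score", {
  genes <- paste0("g", 1:200)
  ranking <- setNames(seq(10, -10, length.out = 200), genes)
  res <- gseaPreranked(ranking, list(top = genes[1:15]), n_perm = 200, seed = 1)
  expect_gt(res$es, 0.9)
  expect_lte(abs(res$es), 1)
  expect_lt(res$pvalue, 0.05)
  expect_equal(sign(res$nes), sign(res$es))
})

test_that("the unweighted statistic equals a direct running-sum implementation", {
  for (i in 1:20) {
    set.seed(200 + i)
    genes <- paste0("g", 1:80)
    ranking <- setNames(rnorm(80), genes)
    set <- sample(genes, 10)
    res <- gseaPreranked(ranking, list(S = set), n_perm = 100, weight_p = 0,
                         seed = i)
    ranked <- genes[order(-ranking, genes)]
    expect_equal(res$es, ks_es_unweighted(ranked, set), tolerance = 1e-10)
  }
})

test_that("the weighted statistic agrees with the reference GSEA implementation", {
  set.seed(42)
  genes <- paste0("g", 1:150)
  ranking <- setNames(rnorm(150), genes)
  set <- sample(genes, 12)
  res <- gseaPreranked(ranking, list(S = set), n_perm = 100, seed = 1)
  ord <- order(-ranking, names(ranking))
  ref <- fgsea::calcGseaStat(ranking[ord],
                             selectedStats = match(set, names(ranking)[ord]))
  expect_equal(res$es, ref, tolerance = 1e-8)
})

test_that("GSEA input contracts are enforced", {
  genes <- paste0("g", 1:50)
  r <- setNames(rnorm(50), genes)
  expect_error(gseaPreranked(setNames(1:2, c("a", "a")), list(S = "a")),
               "duplicated")
  expect_error(gseaPreranked(r, list(S = genes[1:5]), n_perm = 10), "100")
  expect_warning(gseaPreranked(r, list(tiny = genes[1:2], ok = genes[1:10]),
                               n_perm = 100, seed = 1), "skipped")
  r1 <- gseaPreranked(r, list(S = genes[1:10]), n_perm = 200, seed = 7)
  r2 <- gseaPreranked(r, list(S = genes[1:10]), n_perm = 200, seed = 7)
  expect_identical(r1, r2)
})

test_that("long-format export pivots per-subject enrichment tables", {
  universe <- paste0("u", 1:30)
  res <- list(s1 = ora(universe[1:6], list(T = universe[1:6]), universe),
              s2 = ora(universe[7:9], list(T = universe[1:6]), universe))
  long <- enrichmentLongFormat(res, significant_only = FALSE)
  expect_equal(nrow(long), 2)
  expect_setequal(long$subject, c("s1", "s2"))
})
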