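write_toy_vcf <- function(path, gts = c("0/1", "1/1", "0/1"),
                          alts = c("G", "T", "C")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    vapply(seq_along(gts), function(i) {
      paste("1", 100 + i, ".", "A", alts[i], ".", "PASS", ".", "GT", gts[i],
            sep = "\t")
    }, "")
  )
  writeLines(lines, path)
  path
}

toy_annotation <- function(path, pos, alts, genes) {
  df <- data.frame(variant_key = paste("1", pos, "A", alts, sep = ":"),
                   gene_symbol = genes, biotype = "protein_coding",
                   hgvsc = NA, hgvsp = NA, allele_frequency = 0.001,
                   cadd_phred = 20, pli = NA)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("zygosity is derived from the genotype field", {
  vcf <- write_toy_vcf(tempfile(fileext = ".vcf"))
  ann <- toy_annotation(tempfile(), 101:103, c("G", "T", "C"),
                        c("GA", "GB", "GC"))
  s <- readAnnotatedVariants(vcf, ann, "S1")
  r <- variantRecords(s)
  expect_equal(nrow(r), 3)
  expect_equal(r$zygosity[order(r$pos)], c("het", "hom", "het"))
  expect_equal(subjectId(s), "S1")
})

test_that("multi-allelic sites split into biallelic records", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    paste("1", "500", ".", "A", "G,T", ".", "PASS", ".", "GT", "1/2", sep = "\t")
  ), vcf)
  ann <- toy_annotation(tempfile(), c(500, 500), c("G", "T"), c("GX", "GX"))
  r <- variantRecords(readAnnotatedVariants(vcf, ann, "S1"))
  expect_equal(nrow(r), 2)
  expect_setequal(r$alt, c("G", "T"))
  expect_true(all(r$zygosity == "het"))
})

test_that("an empty annotation table yields an empty set and reports every VCF allele unjoined", {
  vcf <- write_toy_vcf(tempfile(fileext = ".vcf"))
  ann <- tempfile()
  writeLines(paste("variant_key", "gene_symbol", sep = "\t"), ann)
  expect_warning(s <- readAnnotatedVariants(vcf, ann, "S1"), "3 VCF allele")
  expect_equal(nrow(variantRecords(s)), 0)
  expect_equal(filterReport(s)[[1]]$n_unjoined_vcf, 3)
})

test_that("unjoinable annotation rows are collected, not dropped silently", {
  vcf <- write_toy_vcf(tempfile(fileext = ".vcf"))
  ann <- toy_annotation(tempfile(), c(101, 102, 103, 999),
                        c("G", "T", "C", "A"), c("GA", "GB", "GC", "GZ"))
  expect_warning(s <- readAnnotatedVariants(vcf, ann, "S1"),
                 "did not join")
  expect_equal(nrow(filterReport(s)[[1]]$unjoined_annotation), 1)
  expect_equal(nrow(variantRecords(s)), 3)
})

test_that("parsed record count matches the generator's emitted rows", {
  sim <- simulateVariantTables(80, 40, 10, n_planted = 1, seed = 1)
  vcf <- tempfile(fileext = ".vcf"); ann <- tempfile()
  writeSubjectVcf(sim$subject1, vcf, ann)
  s <- readAnnotatedVariants(vcf, ann, "subject1")
  expect_equal(nrow(variantRecords(s)), nrow(variantRecords(sim$subject1)))
})

test_that("QC removes long ALTs at the documented boundary and blank fields", {
  rec <- make_variant_records(6, seed = 2)
  rec$alt[1] <- strrep("A", 26)   # removed
  rec$alt[2] <- strrep("A", 25)   # retained
  rec$gene_symbol[3] <- ""
  rec$chrom[4] <- NA
  rec$biotype[5] <- "lncRNA"
  s <- qcFilter(subjectVariantSet(rec))
  kept <- variantRecords(s)
  expect_equal(nrow(kept), 2)
  expect_true(strrep("A", 25) %in% kept$alt)
  rep <- filterReport(s)[[1]]
  expect_equal(rep$n_in, rep$n_out + sum(rep$removed))
  expect_setequal(names(rep$removed),
                  c("alt_longer_than_25bp", "missing_gene_symbol",
                    "missing_chromosome", "non_protein_coding"))
  # all-clean input is untouched
  clean <- subjectVariantSet(make_variant_records(10, seed = 3))
  expect_identical(variantRecords(qcFilter(clean)), variantRecords(clean))
})

test_that("the rare filter is strict at the threshold and keeps missing AF", {
  rec <- make_variant_records(3, seed = 4)
  rec$allele_frequency <- c(0.01, 0.0099, NA)
  s <- rareFilter(subjectVariantSet(rec))
  expect_equal(variantRecords(s)$allele_frequency, c(0.0099, NA))
  rec$allele_frequency <- 0.5
  expect_equal(nrow(variantRecords(rareFilter(subjectVariantSet(rec)))), 0)
  expect_error(rareFilter(s, af_max = 0), "af_max")
  expect_error(rareFilter(s, af_max = 1.5), "af_max")
})

test_that("the published variant table passes the rare filter intact and thresholds behave", {
  fix <- loadRareVariantSet()
  expect_equal(nrow(variantRecords(fix)), 48)
  expect_equal(nrow(variantRecords(rareFilter(fix))), 48)
  expect_equal(nrow(variantRecords(highImpactFilter(fix, 30))), 48)
  expect_equal(nrow(variantRecords(highImpactFilter(fix, 50))), 0)
  expect_identical(variantRecords(highImpactFilter(fix, 0)),
                   variantRecords(fix))
})

test_that("pLI prioritization selects the constrained genes of the published table", {
  fix <- loadRareVariantSet()
  pri <- pliPrioritize(fix)
  expect_setequal(unique(variantRecords(pri)$gene_symbol),
                  c("CUX1", "KCNJ12", "PABPC1", "PAX7", "RANBP3"))
  # records with missing pLI never pass
  rec <- make_variant_records(5, seed = 5)
  rec$pli <- NA
  expect_equal(nrow(variantRecords(pliPrioritize(subjectVariantSet(rec)))), 0)
})

test_that("filters commute, are idempotent and conserve row counts", {
  sim <- simulateVariantTables(150, 80, 30, n_planted = 3, seed = 6)
  s <- sim$subject1
  a <- variantRecords(highImpactFilter(rareFilter(s), 10))
  b <- variantRecords(rareFilter(highImpactFilter(s, 10)))
  expect_setequal(do.call(paste, a), do.call(paste, b))
  for (f in list(function(x) rareFilter(x),
                 function(x) highImpactFilter(x, 10),
                 function(x) qcFilter(x),
                 function(x) pliPrioritize(x))) {
    once <- f(s)
    expect_identical(variantRecords(f(once)), variantRecords(once))
    rep <- utils::tail(filterReport(once), 1)[[1]]
    expect_equal(rep$n_in, rep$n_out + sum(rep$removed))
  }
})

test_that("subject partition is a disjoint cover at variant and gene level", {
  sim <- simulateVariantTables(120, 60, 20, n_planted = 2, seed = 7)
  v <- partitionBySubject(sim$subject1, sim$subject2)
  expect_equal(v$variant$counts[["shared"]], 60)
  expect_length(intersect(v$variant$shared, v$variant$unique_a), 0)
  expect_length(intersect(v$variant$unique_a, v$variant$unique_b), 0)
  r1 <- variantRecords(sim$subject1)
  all_keys <- union(v$variant$shared, union(v$variant$unique_a, v$variant$unique_b))
  expect_length(all_keys, 100)

  same <- partitionBySubject(sim$subject1, sim$subject1)
  expect_equal(unname(same$variant$counts[c("unique_a", "unique_b")]), c(0L, 0L))
  disjoint <- partitionBySubject(
    subjectVariantSet(make_variant_records(5, seed = 1), "x"),
    subjectVariantSet(make_variant_records(5, seed = 99), "y"))
  expect_equal(disjoint$variant$counts[["shared"]], 0)
  f <- tempfile(fileext = ".json")
  writeVennJson(v, f)
  expect_equal(jsonlite::read_json(f)$variant$counts$shared, 60)
})
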