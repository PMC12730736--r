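## Variant parsing and the rare/high-impact filter cascade.

.add_report <- function(x, stage, n_in, n_out, removed = integer()) {
  entry <- list(stage = stage, n_in = n_in, n_out = n_out,
                removed = removed)
  initialize(x, report = c(x@report, list(entry)))
}

#' Parse a single-sample VCF plus a VEP-style annotation table
#'
#' Joins a VCF 4.2 file (GT field required) with a tab-delimited annotation
#' table into a [SubjectVariantSet-class], one record per (variant, gene)
#' annotation row. Multi-allelic sites are split into biallelic records;
#' zygosity is derived from the genotype: two copies of the ALT allele
#' (e.g., `1/1`, `1|1`) map to `hom`, one copy to `het`, zero copies drop
#' the allele for this subject.
#'
#' Annotation rows join by a `variant_key` column (`chrom:pos:ref:alt`) when
#' present, otherwise by explicit `chrom`/`pos`/`ref`/`alt` columns
#' (remappable via `column_map`). Annotation rows that fail to join are not
#' silently dropped: they are collected in the parse report together with
#' the count of VCF alleles that received no annotation.
#'
#' @param vcf_path Path to the VCF file.
#' @param annotation_path Path to the annotation TSV.
#' @param subject_id Subject label stamped on every record.
#' @param column_map Named character vector remapping annotation column
#'   names, e.g. `c(gene_symbol = "SYMBOL", cadd_phred = "CADD_PHRED")`.
#' @return A [SubjectVariantSet-class]; its [filterReport()] holds a `parse`
#'   entry with `n_vcf_alleles`, `n_unjoined_vcf` and the unjoined
#'   annotation rows.
#' @export
readAnnotatedVariants <- function(vcf_path, annotation_path, subject_id,
                                  column_map = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) stop("VCF contains no records: ", vcf_path)
  if (ncol(vcf@gt) < 2) stop("VCF must contain a genotype column: ", vcf_path)
  fmt <- strsplit(vcf@gt[, 1], ":", fixed = TRUE)
  gt_idx <- vapply(fmt, function(f) match("GT", f), integer(1))
  if (anyNA(gt_idx)) stop("VCF FORMAT lacks the GT field")
  gt <- mapply(function(cell, i) strsplit(cell, ":", fixed = TRUE)[[1]][i],
               vcf@gt[, 2], gt_idx, USE.NAMES = FALSE)

  ## split multi-allelic sites into biallelic allele observations
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    alleles <- strsplit(gt[i], "[/|]")[[1]]
    out <- lapply(seq_along(alts), function(a) {
      n_alt <- sum(alleles == as.character(a))
      if (n_alt == 0) return(NULL)
      data.frame(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
                 ref = fix$REF[i], alt = alts[a],
                 zygosity = if (n_alt >= 2) "hom" else "het",
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  alleles <- do.call(rbind, rows)
  alleles$variant_key <- .variant_key(alleles$chrom, alleles$pos,
                                      alleles$ref, alleles$alt)

  ann <- utils::read.delim(annotation_path, check.names = FALSE,
                           na.strings = c("NA", ""))
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      names(ann)[names(ann) == column_map[[std]]] <- std
    }
  }
  if (!"variant_key" %in% names(ann)) {
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(ann))) {
      stop("annotation table needs a variant_key or chrom/pos/ref/alt columns")
    }
    ann$variant_key <- .variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  }

  hit <- match(ann$variant_key, alleles$variant_key)
  unjoined_ann <- ann[is.na(hit), , drop = FALSE]
  joined <- ann[!is.na(hit), , drop = FALSE]
  allele_part <- alleles[hit[!is.na(hit)], c("chrom", "pos", "ref", "alt", "zygosity")]
  rec <- cbind(allele_part,
               joined[, setdiff(names(joined),
                                c("chrom", "pos", "ref", "alt", "variant_key")),
                      drop = FALSE])
  rec$subject_id <- rep(subject_id, nrow(rec))
  n_unjoined_vcf <- sum(!alleles$variant_key %in% ann$variant_key)
  if (n_unjoined_vcf > 0) {
    warning(n_unjoined_vcf, " VCF allele(s) had no annotation row")
  }
  if (nrow(unjoined_ann) > 0) {
    warning(nrow(unjoined_ann), " annotation row(s) did not join to the VCF")
  }
  out <- subjectVariantSet(rec, subjectId = subject_id)
  out@report <- list(list(stage = "parse",
                          n_vcf_alleles = nrow(alleles),
                          n_unjoined_vcf = n_unjoined_vcf,
                          unjoined_annotation = unjoined_ann,
                          n_out = nrow(rec)))
  out
}

#' Variant quality-control filter
#'
#' Removes records lacking a chromosome annotation or a gene symbol, records
#' whose ALT allele exceeds 25 bp (sequencing-artifact heuristic; a 25 bp
#' ALT is kept), and records in non-protein-coding biotypes (a missing
#' biotype is treated as protein-coding). Per-reason removal counts are
#' appended to [filterReport()]; the counts always reconcile:
#' input = output + sum(removed).
#'
#' @param s A [SubjectVariantSet-class].
#' @return The filtered [SubjectVariantSet-class].
#' @export
qcFilter <- function(s) {
  rec <- variantRecords(s)
  reason <- rep(NA_character_, nrow(rec))
  bad_chrom <- is.na(rec$chrom) | rec$chrom == ""
  bad_gene <- is.na(rec$gene_symbol) | rec$gene_symbol == ""
  long_alt <- !is.na(rec$alt) & nchar(rec$alt) > 25
  bad_biotype <- !is.na(rec$biotype) & rec$biotype != "protein_coding"
  reason[bad_biotype] <- "non_protein_coding"
  reason[long_alt] <- "alt_longer_than_25bp"
  reason[bad_gene] <- "missing_gene_symbol"
  reason[bad_chrom] <- "missing_chromosome"
  keep <- is.na(reason)
  removed <- table(reason[!keep])
  out <- initialize(s, records = rec[keep, , drop = FALSE])
  .add_report(out, "qc_filter", nrow(rec), sum(keep),
              stats::setNames(as.integer(removed), names(removed)))
}

#' Rare-variant filter
#'
#' Retains records whose population allele frequency is strictly below
#' `af_max`, or absent altogether (an allele unobserved in the reference
#' population is treated as rare). The comparison is strict: AF exactly
#' equal to the threshold is removed.
#'
#' @param s A [SubjectVariantSet-class].
#' @param af_max Allele-frequency threshold in (0, 1].
#' @return The filtered [SubjectVariantSet-class].
#' @export
rareFilter <- function(s, af_max = 0.01) {
  if (!is.numeric(af_max) || af_max <= 0 || af_max > 1) {
    stop("af_max must lie in (0, 1]")
  }
  rec <- variantRecords(s)
  keep <- is.na(rec$allele_frequency) | rec$allele_frequency < af_max
  out <- initialize(s, records = rec[keep, , drop = FALSE])
  .add_report(out, "rare_filter", nrow(rec), sum(keep),
              c(common = sum(!keep)))
}

#' High-impact (CADD) filter
#'
#' Retains records with PHRED-scaled CADD score at or above `cadd_min`
#' (inclusive). A missing CADD score counts as 0.
#'
#' @param s A [SubjectVariantSet-class].
#' @param cadd_min Non-negative CADD threshold; 30 targets the top 0.1\% of
#'   possible variants, 15 approximately the top 3.2\%.
#' @return The filtered [SubjectVariantSet-class].
#' @export
highImpactFilter <- function(s, cadd_min) {
  if (cadd_min < 0) stop("cadd_min must be non-negative")
  rec <- variantRecords(s)
  cadd <- ifelse(is.na(rec$cadd_phred), 0, rec$cadd_phred)
  keep <- cadd >= cadd_min
  out <- initialize(s, records = rec[keep, , drop = FALSE])
  .add_report(out, "high_impact_filter", nrow(rec), sum(keep),
              c(low_cadd = sum(!keep)))
}

#' Loss-of-function intolerance prioritization
#'
#' Retains records in genes with pLI at or above `pli_min`. A missing pLI
#' fails the prioritization (pLI is a prioritization criterion, not a QC
#' one: missingness carries no evidence of intolerance).
#'
#' @param s A [SubjectVariantSet-class].
#' @param pli_min pLI threshold; 0.9 is the conventional "intolerant" cutoff.
#' @return The filtered [SubjectVariantSet-class].
#' @export
pliPrioritize <- function(s, pli_min = 0.9) {
  rec <- variantRecords(s)
  keep <- !is.na(rec$pli) & rec$pli >= pli_min
  out <- initialize(s, records = rec[keep, , drop = FALSE])
  .add_report(out, "pli_prioritize", nrow(rec), sum(keep),
              c(low_or_missing_pli = sum(!keep)))
}

#' Partition two subjects' variants into shared and unique sets
#'
#' Computes the Venn partition of two subject variant sets, both at the
#' variant-key level (key = chrom:pos:ref:alt; multiple gene annotations of
#' one allele count once) and at the gene level (a gene is "present" in a
#' subject if it carries at least one record).
#'
#' @param a,b [SubjectVariantSet-class] objects with consistent variant keys.
#' @return A list of class `VennSummary` with `variant` and `gene` elements,
#'   each holding `shared`, `unique_a`, `unique_b` vectors and a `counts`
#'   vector.
#' @export
partitionBySubject <- function(a, b) {
  ra <- variantRecords(a); rb <- variantRecords(b)
  keys_a <- unique(.variant_key(ra$chrom, ra$pos, ra$ref, ra$alt))
  keys_b <- unique(.variant_key(rb$chrom, rb$pos, rb$ref, rb$alt))
  genes_a <- unique(ra$gene_symbol); genes_b <- unique(rb$gene_symbol)
  venn <- function(x, y) {
    shared <- intersect(x, y)
    list(shared = shared, unique_a = setdiff(x, y), unique_b = setdiff(y, x),
         counts = c(shared = length(shared),
                    unique_a = length(setdiff(x, y)),
                    unique_b = length(setdiff(y, x))))
  }
  out <- list(subject_a = subjectId(a), subject_b = subjectId(b),
              variant = venn(keys_a, keys_b), gene = venn(genes_a, genes_b))
  class(out) <- c("VennSummary", "list")
  out
}

#' @export
print.VennSummary <- function(x, ...) {
  cat("VennSummary:", x$subject_a, "vs", x$subject_b, "\n")
  cat("  variants: shared", x$variant$counts["shared"],
      "| unique", x$variant$counts["unique_a"], "/",
      x$variant$counts["unique_b"], "\n")
  cat("  genes:    shared", x$gene$counts["shared"],
      "| unique", x$gene$counts["unique_a"], "/",
      x$gene$counts["unique_b"], "\n")
  invisible(x)
}

#' Write a Venn summary as JSON
#'
#' @param x A `VennSummary` from [partitionBySubject()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeVennJson <- function(x, path) {
  out <- unclass(x)
  out$variant$counts <- as.list(out$variant$counts)
  out$gene$counts <- as.list(out$gene$counts)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write a filter funnel report as TSV
#'
#' One row per filter stage with input/output counts and the per-reason
#' removal counts flattened to `reason=count` pairs.
#'
#' @param s A [SubjectVariantSet-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeFilterReport <- function(s, path) {
  rep <- filterReport(s)
  rows <- lapply(rep, function(e) {
    data.frame(stage = e$stage,
               n_in = if (!is.null(e$n_in)) e$n_in else NA,
               n_out = e$n_out,
               removed = if (!is.null(e$removed) && length(e$removed)) {
                 paste(names(e$removed), e$removed, sep = "=", collapse = ";")
               } else "")
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
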