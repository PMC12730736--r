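## Loaders for the bundled reference tables: the published list of rare
## high-CADD variants in the two siblings, the core genes of the functional
## interaction network, and the potentially impactful variants mapped onto
## the personalized integrated networks. Those tables print no genomic
## coordinates, so loaders synthesize placeholder variant keys (sequential
## positions on a pseudo-chromosome) — sufficient for filtering and
## integration, which operate on gene symbol, AF, CADD, pLI and zygosity.

.extdata <- function(file) {
  system.file("extdata", file, package = "ModifierNet", mustWork = TRUE)
}

#' Load the bundled rare high-CADD variant table
#'
#' The published table of rare (gnomAD AF < 0.01 or unannotated), highly
#' deleterious (CADD >= 30) variants found in the two siblings. A row with
#' subject `1-2` is expanded into a record for each subject. Zygosity is not
#' printed in the source table and is set to `het` throughout.
#'
#' @return A list with `subject1` and `subject2`
#'   ([SubjectVariantSet-class]) and the raw `table`.
#' @export
loadRareVariantTable <- function() {
  tab <- utils::read.delim(.extdata("sibling_rare_variants.tsv"),
                           na.strings = c("NA", ""))
  expand <- function(subject_label, subject_id) {
    rows <- tab[tab$subject %in% c(subject_label, "1-2"), , drop = FALSE]
    data.frame(chrom = "1", pos = as.integer(rownames(rows)),
               ref = "N", alt = "N",
               gene_symbol = rows$gene_symbol, biotype = "protein_coding",
               hgvsc = rows$hgvsc, hgvsp = rows$hgvsp,
               allele_frequency = rows$allele_frequency,
               cadd_phred = rows$cadd_phred, pli = rows$pli,
               zygosity = "het", subject_id = subject_id,
               stringsAsFactors = FALSE)
  }
  list(subject1 = subjectVariantSet(expand("1", "subject1")),
       subject2 = subjectVariantSet(expand("2", "subject2")),
       table = tab)
}

#' Load the bundled rare variant table as a single merged set
#'
#' All 48 records regardless of subject, as one [SubjectVariantSet-class];
#' a `1-2` row contributes a single record flagged `shared`.
#'
#' @return A [SubjectVariantSet-class].
#' @export
loadRareVariantSet <- function() {
  tab <- utils::read.delim(.extdata("sibling_rare_variants.tsv"),
                           na.strings = c("NA", ""))
  rec <- data.frame(chrom = "1", pos = seq_len(nrow(tab)), ref = "N", alt = "N",
                    gene_symbol = tab$gene_symbol, biotype = "protein_coding",
                    hgvsc = tab$hgvsc, hgvsp = tab$hgvsp,
                    allele_frequency = tab$allele_frequency,
                    cadd_phred = tab$cadd_phred, pli = tab$pli,
                    zygosity = "het", subject_id = tab$subject,
                    stringsAsFactors = FALSE)
  subjectVariantSet(rec, subjectId = "both")
}

#' Load the bundled core-gene topology table
#'
#' The seven highly connected genes at the core of the published functional
#' interaction network, with their edge counts and in-/out-degrees.
#'
#' @return A `data.frame`.
#' @export
loadCoreGeneTable <- function() {
  utils::read.delim(.extdata("fi_core_genes.tsv"))
}

#' Load the bundled integrated-network variant table
#'
#' Variants with CADD >= 15 mapped to genes in the giant components of the
#' two personalized integrated networks, with per-subject presence and
#' zygosity. Returned both as the raw wide table and as per-subject
#' [SubjectVariantSet-class] objects.
#'
#' @return A list with `table`, `subject1`, `subject2`.
#' @export
loadIntegratedVariantTable <- function() {
  tab <- utils::read.delim(.extdata("integrated_network_variants.tsv"),
                           na.strings = c("NA", ""))
  expand <- function(present, zygosity, subject_id) {
    rows <- which(tab[[present]] == 1)
    data.frame(chrom = "1", pos = rows, ref = "N", alt = "N",
               gene_symbol = tab$gene_symbol[rows], biotype = "protein_coding",
               hgvsc = tab$hgvsc[rows], hgvsp = tab$hgvsp[rows],
               allele_frequency = tab$allele_frequency[rows],
               cadd_phred = tab$cadd_phred[rows], pli = NA_real_,
               zygosity = tab[[zygosity]][rows],
               subject_id = subject_id,
               expression = ifelse(is.na(tab$expression[rows]), "ns",
                                   tab$expression[rows]),
               giant_component = tab$giant_component[rows],
               stringsAsFactors = FALSE)
  }
  list(table = tab,
       subject1 = subjectVariantSet(expand("subject1", "zygosity1", "subject1")),
       subject2 = subjectVariantSet(expand("subject2", "zygosity2", "subject2")))
}
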