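## Readers and writers for the standard interchange formats the pipeline
## consumes and (for the synthetic generators) emits: VCF 4.2 + annotation
## TSV, PSI-MITAB 2.7, counts TSV, genes_to_phenotype-style TSV, GMT,
## GraphML/SIF network export.

.variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Write a subject variant set as VCF 4.2 plus an annotation TSV
#'
#' The VCF carries one record per distinct variant key (chrom, pos, ref, alt)
#' with a single-sample GT field derived from zygosity (`hom` -> `1/1`,
#' `het` -> `0/1`); per-gene annotations (one row per (variant, gene) pair)
#' go to the companion tab-delimited table, keyed by `variant_key`. This is
#' the inverse of [readAnnotatedVariants()].
#'
#' @param x A [SubjectVariantSet-class] object.
#' @param vcf_path,annotation_path Output file paths.
#' @return Invisibly, a list with the two paths.
#' @export
writeSubjectVcf <- function(x, vcf_path, annotation_path) {
  rec <- variantRecords(x)
  key <- .variant_key(rec$chrom, rec$pos, rec$ref, rec$alt)
  first <- !duplicated(key)
  vrec <- rec[first, , drop = FALSE]
  vkey <- key[first]
  ord <- order(suppressWarnings(as.integer(vrec$chrom)), vrec$chrom, vrec$pos)
  vrec <- vrec[ord, , drop = FALSE]
  vkey <- vkey[ord]
  gt <- ifelse(vrec$zygosity == "hom", "1/1", "0/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ModifierNet-simulator",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", subjectId(x), sep = "\t")
  )
  body <- paste(vrec$chrom, vrec$pos, vkey, vrec$ref, vrec$alt, ".", "PASS",
                ".", "GT", gt, sep = "\t")
  writeLines(c(header, body), vcf_path)

  ann <- rec
  ann$variant_key <- key
  cols <- c("variant_key", "gene_symbol", "biotype", "hgvsc", "hgvsp",
            "allele_frequency", "cadd_phred", "pli")
  utils::write.table(ann[, cols], annotation_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(vcf = vcf_path, annotation = annotation_path))
}

#' Write interaction edges as PSI-MITAB 2.7
#'
#' Gene symbols are encoded in the alias columns with the
#' `uniprotkb:SYMBOL(gene name)` convention and taxa in the
#' `taxid:NNNN(species)` convention, which is what [readMitab()] resolves.
#'
#' @param edges `data.frame` with `source`, `target` and optionally
#'   `taxon_a`, `taxon_b`, `provenance` columns.
#' @param path Output path.
#' @param taxon Default taxon when the edge table has none.
#' @return Invisibly, `path`.
#' @export
writeMitab <- function(edges, path, taxon = 9606) {
  ta <- if ("taxon_a" %in% names(edges)) edges$taxon_a else taxon
  tb <- if ("taxon_b" %in% names(edges)) edges$taxon_b else taxon
  prov <- if ("provenance" %in% names(edges)) edges$provenance else
    sprintf("SIM-%06d", seq_len(nrow(edges)))
  lines <- paste(
    paste0("uniprotkb:P", sprintf("%05d", seq_len(nrow(edges)))),
    paste0("uniprotkb:Q", sprintf("%05d", seq_len(nrow(edges)))),
    "-", "-",
    paste0("uniprotkb:", edges$source, "(gene name)"),
    paste0("uniprotkb:", edges$target, "(gene name)"),
    "-", "-", "-",
    paste0("taxid:", ta, "(species)"),
    paste0("taxid:", tb, "(species)"),
    "-", "-",
    paste0("imex:", prov),
    "-",
    sep = "\t"
  )
  writeLines(c(paste0("#ID(s) interactor A\tID(s) interactor B\t",
                      "Alt. ID(s) A\tAlt. ID(s) B\tAlias(es) A\tAlias(es) B\t",
                      "Detection method(s)\tFirst author\tPublication(s)\t",
                      "Taxid A\tTaxid B\tInteraction type(s)\tSource db\t",
                      "Interaction id(s)\tConfidence"), lines), path)
  invisible(path)
}

#' Read a PSI-MITAB 2.5/2.7 interaction file
#'
#' Parses the tab-delimited MITAB dialect used by IMEx exports and returns an
#' undirected edge table restricted to interactions where both interactors
#' carry the requested taxon. Gene symbols are resolved from the alias
#' columns with a documented precedence: the `uniprotkb:SYMBOL(gene name)`
#' alias first, then a `display_short` label, otherwise the interactor is
#' unresolvable and the line is dropped (counted). Malformed lines (fewer
#' than 11 columns) are skipped with a count; if more than `warn_fraction` of
#' lines are malformed a warning is raised.
#'
#' @param path MITAB file path.
#' @param taxon_filter NCBI taxon both interactors must carry (default 9606).
#' @param warn_fraction Malformed-line fraction that triggers a warning.
#' @return A `data.frame` of undirected edges (`source`, `target`,
#'   `taxon_a`, `taxon_b`, `provenance`), deduplicated on the unordered pair,
#'   with attributes `n_malformed` and `n_unresolved`.
#' @export
readMitab <- function(path, taxon_filter = 9606, warn_fraction = 0.1) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, integer(1)) >= 11L
  n_malformed <- sum(!ok)
  if (length(lines) && n_malformed / length(lines) > warn_fraction) {
    warning(n_malformed, " of ", length(lines), " MITAB lines are malformed")
  }
  fields <- fields[ok]
  resolve <- function(alias, altid) {
    m <- regmatches(alias, regexec("uniprotkb:([^|(]+)\\(gene name\\)", alias))[[1]]
    if (length(m) == 2) return(m[2])
    m <- regmatches(alias, regexec("([^|:(]+)\\(display_short\\)", alias))[[1]]
    if (length(m) == 2) return(m[2])
    m <- regmatches(altid, regexec("([^|:(]+)\\(display_short\\)", altid))[[1]]
    if (length(m) == 2) return(m[2])
    NA_character_
  }
  taxid <- function(s) {
    m <- regmatches(s, regexec("taxid:(-?[0-9]+)", s))[[1]]
    if (length(m) == 2) as.integer(m[2]) else NA_integer_
  }
  parsed <- lapply(fields, function(f) {
    data.frame(source = resolve(f[5], f[3]), target = resolve(f[6], f[4]),
               taxon_a = taxid(f[10]), taxon_b = taxid(f[11]),
               provenance = if (length(f) >= 14) sub("^imex:", "", f[14]) else NA,
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, c(parsed, list(make.row.names = FALSE)))
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        taxon_a = integer(), taxon_b = integer(),
                        provenance = character())
  }
  n_unresolved <- sum(is.na(edges$source) | is.na(edges$target))
  edges <- edges[!is.na(edges$source) & !is.na(edges$target), , drop = FALSE]
  edges <- edges[!is.na(edges$taxon_a) & !is.na(edges$taxon_b) &
                 edges$taxon_a == taxon_filter & edges$taxon_b == taxon_filter, ,
                 drop = FALSE]
  key <- paste(pmin(edges$source, edges$target),
               pmax(edges$source, edges$target), sep = "\r")
  edges <- edges[!duplicated(key) & edges$source != edges$target, , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "n_malformed") <- n_malformed
  attr(edges, "n_unresolved") <- n_unresolved
  edges
}

#' Write / read a gene-by-sample counts table
#'
#' Plain TSV with a `gene_id` column followed by one column per sample; the
#' group of each sample is stored in a `#group:` comment line so the design
#' round-trips.
#'
#' @param x A [GeneCountMatrix-class] object.
#' @param path File path.
#' @return `writeCountsTsv()` invisibly returns `path`;
#'   `readCountsTsv()` returns a [GeneCountMatrix-class].
#' @export
writeCountsTsv <- function(x, path) {
  k <- SummarizedExperiment::assay(x, "counts")
  df <- data.frame(gene_id = rownames(k), k, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#group:\t", paste(as.character(sampleGroups(x)), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCountsTsv
#' @param group Optional group labels, overriding the `#group:` comment line.
#' @export
readCountsTsv <- function(path, group = NULL) {
  first <- readLines(path, n = 1)
  if (is.null(group) && startsWith(first, "#group:")) {
    group <- strsplit(first, "\t", fixed = TRUE)[[1]][-1]
  }
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  k <- as.matrix(df[, -1, drop = FALSE])
  rownames(k) <- df$gene_id
  if (is.null(group)) stop("no group labels found or supplied")
  geneCountMatrix(k, group)
}

#' Read a genes_to_phenotype-style annotation table
#'
#' Tab-delimited with configurable column names, following the HPO
#' `genes_to_phenotype.txt` dialect (one row per gene-term annotation).
#'
#' @param path File path.
#' @param term_col,name_col,gene_col Column names holding the term id, term
#'   name and gene symbol.
#' @return A `data.frame` with `term_id`, `term_name`, `gene_symbol`.
#' @export
readGenesToPhenotype <- function(path, term_col = "hpo_id",
                                 name_col = "hpo_name",
                                 gene_col = "gene_symbol") {
  df <- utils::read.delim(path, check.names = FALSE)
  missing <- setdiff(c(term_col, name_col, gene_col), names(df))
  if (length(missing)) {
    stop("annotation table lacks columns: ", paste(missing, collapse = ", "))
  }
  out <- data.frame(term_id = as.character(df[[term_col]]),
                    term_name = as.character(df[[name_col]]),
                    gene_symbol = as.character(df[[gene_col]]),
                    stringsAsFactors = FALSE)
  out[!duplicated(out[, c("term_id", "gene_symbol")]), , drop = FALSE]
}

#' @rdname readGenesToPhenotype
#' @param annotations A `data.frame` with `term_id`, `term_name`,
#'   `gene_symbol` columns, as produced by [simulatePhenotypePanel()].
#' @export
writeGenesToPhenotype <- function(annotations, path) {
  out <- data.frame(ncbi_gene_id = NA_integer_,
                    gene_symbol = annotations$gene_symbol,
                    hpo_id = annotations$term_id,
                    hpo_name = annotations$term_name)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write GMT gene-set files
#'
#' Reading is delegated to [fgsea::gmtPathways()]; writing emits the
#' standard three-plus columns (name, description, genes).
#'
#' @param path File path.
#' @return `readGmt()` returns a named list of character vectors.
#' @export
readGmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname readGmt
#' @param sets Named list of character vectors.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Export a gene network as GraphML or SIF
#'
#' GraphML export (via igraph) carries the atomic node annotation columns as
#' vertex attributes; SIF is the minimal `source relation target` text
#' format, with isolated nodes emitted as single-column lines.
#'
#' @param x A [GeneNetwork-class] object.
#' @param path Output path.
#' @param relation Interaction label used in the SIF body.
#' @return Invisibly, `path`.
#' @export
exportGraphML <- function(x, path) {
  igraph::write_graph(asIgraph(x), path, format = "graphml")
  invisible(path)
}

#' @rdname exportGraphML
#' @export
exportSif <- function(x, path, relation = "interacts") {
  ed <- edgeData(x)
  isolated <- setdiff(nodeData(x)$gene, c(ed$from, ed$to))
  writeLines(c(paste(ed$from, relation, ed$to), isolated), path)
  invisible(path)
}

#' Write every file of a simulated study to a directory
#'
#' Materializes a [simulateStudy()] bundle in the on-disk formats the
#' pipeline readers consume: per-subject VCF + annotation TSV, PSI-MITAB
#' interactome, functional-interaction TSV, counts TSV, phenotype annotation
#' TSV and a GMT of the pathway modules.
#'
#' @param study A list from [simulateStudy()].
#' @param dir Output directory (created if needed).
#' @return A named list of file paths.
#' @export
writeStudyFiles <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf1 = file.path(dir, "subject1.vcf"),
    ann1 = file.path(dir, "subject1_annotation.tsv"),
    vcf2 = file.path(dir, "subject2.vcf"),
    ann2 = file.path(dir, "subject2_annotation.tsv"),
    interactome = file.path(dir, "interactome.mitab"),
    fi_db = file.path(dir, "fi_database.tsv"),
    counts = file.path(dir, "counts.tsv"),
    phenotype = file.path(dir, "genes_to_phenotype.tsv"),
    gene_sets = file.path(dir, "pathways.gmt")
  )
  writeSubjectVcf(study$subject1, paths$vcf1, paths$ann1)
  writeSubjectVcf(study$subject2, paths$vcf2, paths$ann2)
  writeMitab(study$interactome, paths$interactome)
  utils::write.table(study$fi_db, paths$fi_db, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeCountsTsv(study$counts, paths$counts)
  writeGenesToPhenotype(study$panel, paths$phenotype)
  writeGmt(study$gene_sets, paths$gene_sets)
  paths
}
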