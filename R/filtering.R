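#' Is a variant functionally important?
#'
#' A functionally important variant is a nonsynonymous, splicing, stopgain
#' or stoploss variant: `TRUE` iff the region annotation includes
#' `splicing`, or the exonic function is one of nonsynonymous, stopgain,
#' stoploss. This is the unit the inheritance-model filters count.
#'
#' @param variants A `variant_table` (or ranked rows).
#' @return Logical vector.
#' @export
#' @examples
#' v <- variant_table(chrom = c("1", "1"), pos = c(10L, 20L),
#'                    ref = "G", alt = "A", region = c("exonic", "intronic"),
#'                    exonic_func = c("nonsynonymous", NA))
#' is_functional(v)
is_functional <- function(variants) {
  spl <- vapply(region_tokens(variants$region),
                function(t) "splicing" %in% t, logical(1))
  ef <- normalize_exonic_func(variants$exonic_func)
  spl | (!is.na(ef) & ef %in% .FUNCTIONAL_EXONIC)
}

# Canonical exonic-function tokens: ANNOVAR writes e.g.
# "nonsynonymous SNV", "stopgain", "stoploss", "synonymous SNV".
normalize_exonic_func <- function(x) {
  x <- tolower(blank_to_na(as.character(x)))
  x <- sub("[ _]snv$", "", x)
  x <- sub("^stop[ _-]?gain$", "stopgain", x)
  x <- sub("^stop[ _-]?loss$", "stoploss", x)
  x
}

#' Filter a ranked table by an inheritance model
#'
#' Gene-level Mendelian model filters over functionally important variants
#' (nonsynonymous, splicing, stopgain/stoploss):
#' * `dominant` keeps genes carrying at least one functionally important
#'   variant;
#' * `recessive` keeps genes carrying two or more;
#' * `x_recessive` keeps genes on chromosome X carrying at least one.
#'
#' The filter operates at gene granularity but returns variants: every
#' variant of a qualifying gene is retained (so the output remains a
#' rankable table) unless `functional_only = TRUE`, which additionally
#' drops the qualifying genes' non-functional variants. Non-genic variants
#' are always removed. Ranks are recomputed on the surviving set.
#'
#' @param ranked A `ranked_table`.
#' @param model `"dominant"`, `"recessive"` or `"x_recessive"`
#'   (`"autosomal_dominant"`/`"autosomal_recessive"` accepted).
#' @param functional_only Drop non-functional variants of qualifying genes.
#' @return A filtered, re-ranked `ranked_table`.
#' @export
apply_model <- function(ranked, model, functional_only = FALSE) {
  stopifnot(inherits(ranked, "ranked_table"))
  model <- normalize_model(model)
  rows <- genic_rows(ranked$rows)
  if (!nrow(rows)) return(rerank(ranked, rows))

  fun <- is_functional(rows)
  genes <- gene_tokens(rows$gene)
  idx <- rep(seq_len(nrow(rows)), lengths(genes))
  long <- data.table(gene = unlist(genes), fun = fun[idx],
                     chrom = rows$chrom[idx])
  per_gene <- long[, .(n_functional = sum(fun), on_x = any(chrom == "X")),
                   by = gene]
  keep_genes <- switch(model,
    dominant    = per_gene[n_functional >= 1L]$gene,
    recessive   = per_gene[n_functional >= 2L]$gene,
    x_recessive = per_gene[n_functional >= 1L & (on_x)]$gene)

  in_gene <- vapply(genes, function(g) any(g %in% keep_genes), logical(1))
  keep <- if (functional_only) in_gene & fun else in_gene
  if (model == "x_recessive") keep <- keep & rows$chrom == "X"
  rerank(ranked, rows[keep])
}

normalize_model <- function(model) {
  m <- tolower(gsub("[ -]", "_", as.character(model)[1]))
  m <- sub("^autosomal_", "", m)
  m <- sub("^x(_linked)?_recessive$|^xrecessive$", "x_recessive", m)
  if (!m %in% c("dominant", "recessive", "x_recessive"))
    stop("unknown inheritance model: ", model)
  m
}

#' Build a filter specification
#'
#' A conjunction of criteria applied by [apply_filterspec()]:
#' a MAF ceiling over selected population databases (a variant passes iff
#' every selected database's AF, missing treated as 0 so novel variants
#' are never discarded, is at most `maf_threshold`); a functional-class
#' criterion ([is_functional()]); a clinical criterion (ClinVar or
#' GWAS-catalog membership); a minimum count of functionally important
#' variants per gene; and an inheritance model. At least one criterion
#' must be set.
#'
#' @param maf_threshold Maximum allele frequency in \[0,1\], or `NULL`.
#' @param maf_databases Databases the MAF criterion inspects: subset of
#'   `"1000g"`, `"esp6500"`, `"exac"`.
#' @param functional_only Keep only functionally important variants.
#' @param clinical_only Keep only ClinVar/GWAS-catalog variants.
#' @param min_mutations_per_gene Keep variants of genes with at least this
#'   many functionally important variants, or `NULL`.
#' @param model Inheritance model (see [apply_model()]), or `NULL`.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(maf_threshold = NULL,
                        maf_databases = c("1000g", "esp6500", "exac"),
                        functional_only = FALSE, clinical_only = FALSE,
                        min_mutations_per_gene = NULL, model = NULL) {
  if (is.null(maf_threshold) && !isTRUE(functional_only) &&
      !isTRUE(clinical_only) && is.null(min_mutations_per_gene) &&
      is.null(model))
    stop("empty filter specification: set at least one criterion")
  if (!is.null(maf_threshold) &&
      (maf_threshold < 0 || maf_threshold > 1))
    stop("maf_threshold must lie in [0,1]")
  maf_databases <- normalize_af_db(maf_databases)
  if (!is.null(min_mutations_per_gene)) {
    min_mutations_per_gene <- as.integer(min_mutations_per_gene)
    if (min_mutations_per_gene < 1L)
      stop("min_mutations_per_gene must be a positive integer")
  }
  if (!is.null(model)) model <- normalize_model(model)
  structure(list(maf_threshold = maf_threshold,
                 maf_databases = maf_databases,
                 functional_only = isTRUE(functional_only),
                 clinical_only = isTRUE(clinical_only),
                 min_mutations_per_gene = min_mutations_per_gene,
                 model = model),
            class = "filter_spec")
}

normalize_af_db <- function(db) {
  key <- tolower(gsub("[^a-z0-9]", "", tolower(db)))
  map <- c("1000g" = "af_1000g", "1000genomes" = "af_1000g",
           "af1000g" = "af_1000g",
           "esp6500" = "af_esp6500", "esp" = "af_esp6500",
           "esp600" = "af_esp6500", "afesp6500" = "af_esp6500",
           "exac" = "af_exac", "afexac" = "af_exac")
  out <- map[key]
  if (anyNA(out))
    stop("unknown population database(s): ",
         paste(db[is.na(out)], collapse = ", "))
  unique(unname(out))
}

#' Apply a filter specification to a ranked table
#'
#' Applies the conjunction of all criteria set in the [filter_spec()];
#' ranks are recomputed on the surviving rows. Chaining single-criterion
#' specs gives the same result as one combined spec.
#'
#' @param ranked A `ranked_table`.
#' @param spec A `filter_spec`.
#' @return A filtered, re-ranked `ranked_table`.
#' @export
apply_filterspec <- function(ranked, spec) {
  stopifnot(inherits(ranked, "ranked_table"), inherits(spec, "filter_spec"))
  out <- ranked
  rows <- out$rows
  keep <- rep(TRUE, nrow(rows))
  if (!is.null(spec$maf_threshold)) {
    for (db in spec$maf_databases) {
      af <- rows[[db]]
      af[is.na(af)] <- 0
      keep <- keep & af <= spec$maf_threshold
    }
  }
  if (spec$functional_only) keep <- keep & is_functional(rows)
  if (spec$clinical_only) keep <- keep & (rows$clinvar | rows$gwas)
  out <- rerank(out, rows[keep])
  if (!is.null(spec$min_mutations_per_gene))
    out <- keep_genes_by_functional_count(out, spec$min_mutations_per_gene)
  if (!is.null(spec$model)) out <- apply_model(out, spec$model)
  out
}

# Keep variants of genes whose functional-variant count meets the bound.
keep_genes_by_functional_count <- function(ranked, bound) {
  rows <- genic_rows(ranked$rows)
  if (!nrow(rows)) return(rerank(ranked, rows))
  fun <- is_functional(rows)
  genes <- gene_tokens(rows$gene)
  idx <- rep(seq_len(nrow(rows)), lengths(genes))
  long <- data.table(gene = unlist(genes), fun = fun[idx])
  ok <- long[, .(n_functional = sum(fun)), by = gene][n_functional >= bound]$gene
  keep <- vapply(genes, function(g) any(g %in% ok), logical(1))
  rerank(ranked, rows[keep])
}
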