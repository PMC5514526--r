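#' Construct a variant table
#'
#' The central container of the package: a `data.table` with one row per
#' annotated variant and a fixed set of canonical columns. All readers
#' produce it and all scoring, ranking and filtering functions consume it.
#'
#' Canonical columns: `chrom`, `pos`, `ref`, `alt`, `variant_class`
#' (`"SNV"`, `"INDEL"` or `"OTHER"`, derived from the alleles), `region`
#' (`";"`-separated region classes), `exonic_func`, `gene` (`";"`-separated
#' symbols), `dbsnp_id`, per-database allele frequencies (`af_1000g`,
#' `af_esp6500`, `af_exac`), per-algorithm prediction calls (`sift`,
#' `polyphen2`, `lrt`, `mutationtaster`, `mutationassessor`, `fathmm`,
#' `metasvm`, `metalr`), conservation scores (`gerp`, `phylop`,
#' `phastcons`, `siphy`), regulatory-overlap flags (`encode_element`,
#' `encode_tfbs`, `encode_conserved`), `clinvar`, `gwas`, `cadd`, and an
#' optional `genotypes` list column of named per-sample calls
#' (`hom_ref`, `het`, `hom_alt`, `hap_ref`, `hap_alt`, `missing`).
#'
#' @param chrom Chromosome labels ("1".."22", "X", "Y", "MT"); a "chr"
#'   prefix is stripped and labels are upper-cased.
#' @param pos 1-based positions (positive integers).
#' @param ref,alt Allele strings.
#' @param ... Any further canonical columns as named vectors (recycled to
#'   length); unspecified annotation columns are filled with missing values.
#' @param extras Optional named list of additional (opaque) columns carried
#'   through unchanged.
#' @return A `variant_table` (also a `data.table`).
#' @export
#' @examples
#' variant_table(chrom = "1", pos = 155271258L, ref = "G", alt = "A",
#'               region = "exonic", gene = "PKLR")
variant_table <- function(chrom = character(), pos = integer(),
                          ref = character(), alt = character(), ...,
                          extras = NULL) {
  dt <- data.table(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt))
  dots <- list(...)
  if (length(dots) && is.null(names(dots)))
    stop("additional variant columns must be named")
  for (nm in names(dots)) set(dt, j = nm, value = dots[[nm]])
  if (!is.null(extras))
    for (nm in names(extras)) set(dt, j = nm, value = extras[[nm]])
  as_variant_table(dt)
}

#' Coerce a data frame to a variant table
#'
#' Normalizes chromosome labels, derives `variant_class` from the alleles,
#' fills absent annotation columns with missing values, and validates the
#' container invariants (positive positions, `ref != alt`, frequencies in
#' \[0,1\]).
#'
#' @param x A data frame with at least `chrom`, `pos`, `ref`, `alt`.
#' @return A `variant_table`.
#' @export
as_variant_table <- function(x) {
  dt <- as.data.table(x)
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  dt[, chrom := normalize_chrom(chrom)]
  dt[, pos := as.integer(pos)]
  dt[, ref := toupper(as.character(ref))]
  dt[, alt := toupper(as.character(alt))]
  dt[, variant_class := classify_alleles(ref, alt)]

  chr_cols <- c("region", "exonic_func", "gene", "dbsnp_id", .PRED_ALGOS)
  num_cols <- c(.AF_DBS, .CONS_ALGOS, "cadd")
  lgl_cols <- c(.ENCODE_FLAGS, "clinvar", "gwas")
  for (cc in chr_cols) {
    if (!cc %in% names(dt)) set(dt, j = cc, value = NA_character_)
    else set(dt, j = cc, value = blank_to_na(as.character(dt[[cc]])))
  }
  for (nc in num_cols) {
    if (!nc %in% names(dt)) set(dt, j = nc, value = NA_real_)
    else set(dt, j = nc, value = suppressWarnings(as.numeric(dt[[nc]])))
  }
  for (lc in lgl_cols) {
    if (!lc %in% names(dt)) set(dt, j = lc, value = FALSE)
    else set(dt, j = lc, value = isTRUE_vec(dt[[lc]]))
  }

  if (nrow(dt)) {
    if (anyNA(dt$pos) || any(dt$pos < 1L))
      stop("variant positions must be positive 1-based integers")
    if (any(!nzchar(dt$ref)) || any(!nzchar(dt$alt)))
      stop("ref and alt alleles must be non-empty")
    if (any(dt$ref == dt$alt))
      stop("ref and alt alleles must differ")
    for (db in .AF_DBS) {
      bad <- !is.na(dt[[db]]) & (dt[[db]] < 0 | dt[[db]] > 1)
      if (any(bad))
        stop("allele frequencies in '", db, "' outside [0,1]")
    }
  }
  lead <- c(need, "variant_class", "region", "exonic_func", "gene",
            "dbsnp_id", .AF_DBS, .PRED_ALGOS, .CONS_ALGOS,
            .ENCODE_FLAGS, "clinvar", "gwas", "cadd")
  setcolorder(dt, c(lead, setdiff(names(dt), lead)))
  setattr(dt, "class", unique(c("variant_table", class(dt))))
  dt[]
}

#' @method print variant_table
#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("<variant_table> %d variant(s)\n", nrow(x)))
  NextMethod()
}

# "chr1" -> "1", "chrM"/"M" -> "MT"; case-insensitive.
normalize_chrom <- function(chrom) {
  ch <- toupper(sub("^chr", "", as.character(chrom), ignore.case = TRUE))
  ch[ch == "M"] <- "MT"
  ch
}

# SNV iff both alleles are single ACGT bases; length mismatch or the
# ANNOVAR "-" placeholder means INDEL; anything else (MNPs etc.) OTHER.
classify_alleles <- function(ref, alt) {
  snv <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %chin% c("A", "C", "G", "T") & alt %chin% c("A", "C", "G", "T")
  indel <- !snv & (nchar(ref) != nchar(alt) | ref == "-" | alt == "-")
  fifelse(snv, "SNV", fifelse(indel, "INDEL", "OTHER"))
}

blank_to_na <- function(x) {
  x[!is.na(x) & (x == "" | x == ".")] <- NA_character_
  x
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) return(fifelse(is.na(x), FALSE, x))
  if (is.numeric(x)) return(!is.na(x) & x != 0)
  x <- tolower(as.character(x))
  !is.na(x) & x %in% c("true", "t", "1", "yes", "y")
}

# Split a ";"-separated region string into canonical class tokens.
# ANNOVAR's ncRNA_exonic / ncRNA_intronic / ncRNA_splicing collapse to
# ncRNA; unknown tokens are preserved (the encoder warns and treats them
# as the intergenic tier).
region_tokens <- function(region) {
  toks <- strsplit(as.character(region), ";", fixed = TRUE)
  lapply(toks, function(t) {
    t <- t[!is.na(t) & nzchar(t) & t != "."]
    t <- sub("^ncRNA_.*$", "ncRNA", t)
    unique(t)
  })
}

# Split ";"-separated gene annotations into unique symbols.
gene_tokens <- function(gene) {
  lapply(strsplit(as.character(gene), "[;,]"), function(g) {
    g <- unique(g[!is.na(g) & nzchar(g) & g != "."])
    g
  })
}
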