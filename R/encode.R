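#' Encode region class annotations into a weight
#'
#' Follows the ANNOVAR annotation precedence order
#' exonic = splicing > ncRNA > UTR5/UTR3 > intronic >
#' upstream/downstream > intergenic with weights 1, 5/6, 4/6, 3/6, 2/6 and
#' 1/6. A variant annotated to several classes (e.g. `"exonic;splicing"`)
#' receives the weight of the highest-precedence class present; the result
#' does not depend on token order. Unknown tokens are treated as the
#' intergenic tier with a warning; a missing region annotation is scored
#' at the intergenic tier silently.
#'
#' @param region Character vector of `";"`-separated region annotations.
#' @return Numeric vector of encoded weights in \[0,1\].
#' @export
#' @examples
#' encode_region(c("exonic", "intronic", "intronic;splicing"))
encode_region <- function(region) {
  toks <- region_tokens(region)
  unknown <- setdiff(unique(unlist(toks)), .REGION_CLASSES)
  if (length(unknown))
    warning("unknown region class(es) treated as intergenic: ",
            paste(unknown, collapse = ", "))
  vapply(toks, function(t) {
    if (!length(t)) return(.REGION_WEIGHTS[["intergenic"]])
    w <- .REGION_WEIGHTS[t]
    w[is.na(w)] <- .REGION_WEIGHTS[["intergenic"]]
    max(w)
  }, numeric(1))
}

#' Encode a deleteriousness prediction call into a weight
#'
#' PolyPhen2 uses the three-level map D (damaging) = 1,
#' P (possibly damaging) = 0.5, B (benign) = 0. The remaining seven
#' algorithms (SIFT, LRT, MutationTaster, MutationAssessor, FATHMM,
#' MetaSVM, MetaLR) are binary: deleterious = 1, tolerated = 0. Call codes
#' follow the dbNSFP letter conventions (e.g. MutationTaster A/D
#' deleterious, N/P tolerated; MutationAssessor H/M deleterious, L/N
#' tolerated). A missing call contributes 0.
#'
#' @param algorithm One of `"sift"`, `"polyphen2"`, `"lrt"`,
#'   `"mutationtaster"`, `"mutationassessor"`, `"fathmm"`, `"metasvm"`,
#'   `"metalr"` (case-insensitive).
#' @param call Character vector of categorical calls (NA/`"."` = missing).
#' @return Numeric vector of weights in \{0, 0.5, 1\}.
#' @export
#' @examples
#' encode_prediction("polyphen2", c("D", "P", "B", NA))
#' encode_prediction("sift", c("D", "T"))
encode_prediction <- function(algorithm, call) {
  algorithm <- tolower(algorithm)
  if (!algorithm %in% .PRED_ALGOS)
    stop("unknown prediction algorithm: ", algorithm)
  call <- blank_to_na(as.character(call))
  w <- as.numeric(!is.na(call) & call %in% .DELETERIOUS_CALLS[[algorithm]])
  if (algorithm == "polyphen2")
    w[!is.na(call) & call == "P"] <- 0.5
  w
}

#' Encode a conservation score into a weight
#'
#' A variant scores 1 when its conservation score strictly exceeds the
#' algorithm's cutoff (highly conserved), otherwise 0; the GERP++ cutoff
#' is 2. Missing scores contribute 0.
#'
#' @param algorithm One of `"gerp"`, `"phylop"`, `"phastcons"`, `"siphy"`.
#' @param score Numeric vector of raw conservation scores.
#' @param cutoffs Named cutoff vector, as in [weight_config()].
#' @return Numeric 0/1 vector.
#' @export
#' @examples
#' encode_conservation("gerp", c(3.1, 2.0, -1.4, NA))
encode_conservation <- function(algorithm, score,
                                cutoffs = weight_config()$cutoffs) {
  algorithm <- tolower(algorithm)
  if (!algorithm %in% .CONS_ALGOS)
    stop("unknown conservation algorithm: ", algorithm)
  as.numeric(!is.na(score) & score > cutoffs[[algorithm]])
}

#' Encode an allele frequency into a rarity weight
#'
#' The weight is `1 - AF`, giving more weight to rare alleles. A variant
#' absent from a population database (missing AF) is treated as maximally
#' rare and receives weight 1.
#'
#' @param af Numeric vector of allele frequencies in \[0,1\] (NA = absent).
#' @return Numeric vector of weights in \[0,1\].
#' @export
#' @examples
#' encode_frequency(c(0, 0.25, NA))
encode_frequency <- function(af) {
  if (any(!is.na(af) & (af < 0 | af > 1)))
    stop("allele frequencies must lie in [0,1]")
  fifelse(is.na(af), 1, 1 - af)
}

#' Encode the binary annotation flags of a variant table
#'
#' Binary (0/1) weights for: novelty (1 iff the variant has no dbSNP id),
#' ClinVar membership, GWAS-catalog membership, and ENCODE overlap (1 iff
#' the variant carries an ENCODE element, a transcription-factor binding
#' site or a conserved site; `per_flag = TRUE` keeps the three flags
#' separate).
#'
#' @param variants A `variant_table`.
#' @param per_flag Keep the three regulatory flags as separate columns.
#' @return A `data.table` of 0/1 columns `novelty`, `clinvar`, `gwas` and
#'   `encode` (or `encode_element`/`encode_tfbs`/`encode_conserved`).
#' @export
encode_binary_flags <- function(variants, per_flag = FALSE) {
  out <- data.table(
    novelty = as.numeric(is.na(variants$dbsnp_id)),
    clinvar = as.numeric(variants$clinvar),
    gwas    = as.numeric(variants$gwas))
  if (per_flag) {
    for (fl in .ENCODE_FLAGS)
      set(out, j = fl, value = as.numeric(variants[[fl]]))
  } else {
    out[, encode := as.numeric(variants$encode_element |
                                 variants$encode_tfbs |
                                 variants$encode_conserved)]
  }
  out[]
}

#' Score variants: encoded weights and total rank score
#'
#' Encodes every enabled annotation source of each SNV into a weight in
#' \[0,1\] and sums the user-weighted encoded values into the rank score:
#' `score = sum_s w_s * e_s` over enabled sources `s`. INDELs are never
#' scored; passing any non-SNV row is an error (partition first, as
#' [rank_variants()] does).
#'
#' @param variants A `variant_table` of SNVs.
#' @param config A [weight_config()].
#' @return A `data.table` with one encoded-weight column `w_<source>` per
#'   enabled source and a `score` column; rows align with `variants`.
#' @export
#' @examples
#' v <- variant_table(chrom = "1", pos = 100L, ref = "G", alt = "A",
#'                    region = "exonic", sift = "D", gerp = 3.5)
#' score_variants(v, weight_config())
score_variants <- function(variants, config = weight_config()) {
  stopifnot(inherits(config, "weight_config"))
  variants <- as_variant_table(variants)
  if (nrow(variants) && any(variants$variant_class != "SNV"))
    stop("score_variants() only scores SNVs; partition INDELs out first ",
         "(see rank_variants())")

  enc <- data.table(region = encode_region(variants$region))
  for (alg in .PRED_ALGOS)
    set(enc, j = alg, value = encode_prediction(alg, variants[[alg]]))
  for (alg in .CONS_ALGOS)
    set(enc, j = alg,
        value = encode_conservation(alg, variants[[alg]], config$cutoffs))
  if (config$freq_mode == "per_db") {
    for (db in .AF_DBS)
      set(enc, j = db, value = encode_frequency(variants[[db]]))
  } else {
    afm <- do.call(pmax, c(unname(as.list(variants[, .AF_DBS, with = FALSE])),
                           list(na.rm = TRUE)))
    set(enc, j = "frequency", value = encode_frequency(afm))
  }
  flags <- encode_binary_flags(variants,
                               per_flag = config$encode_mode == "per_flag")
  for (nm in names(flags)) set(enc, j = nm, value = flags[[nm]])

  keep <- enabled_sources(config)
  enc <- enc[, keep, with = FALSE]
  if (nrow(enc)) {
    total <- as.vector(as.matrix(enc) %*% config$weights[keep])
  } else {
    total <- numeric(0)
  }
  setnames(enc, keep, paste0("w_", keep))
  enc[, score := total]
  enc[]
}
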