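#' Tally genotypes in case and control groups
#'
#' For each variant, counts homozygous-ALT carriers, heterozygous
#' carriers, and the total number of called alleles separately in the case
#' and control sample groups. Homozygous-reference calls contribute to the
#' allele total but not to the hom/het tallies (a hom-ref carrier carries
#' no signal at a variant site). Missing genotypes — including half-missing
#' diploid calls — contribute nothing; haploid calls (e.g. chrX in males)
#' contribute one allele.
#'
#' @param variants A `variant_table` with a `genotypes` list column
#'   (named per-sample calls, as produced by [read_vcf()]).
#' @param cases,controls Disjoint character vectors of sample ids; every
#'   id must be present in each variant's genotype map.
#' @return A `data.table`, one row per variant, with columns
#'   `n_hom_cases`, `n_het_cases`, `n_alleles_cases`, `n_hom_controls`,
#'   `n_het_controls`, `n_alleles_controls`, `n_alt_cases`,
#'   `n_alt_controls` (alt-allele counts, convenience for predicates).
#' @export
count_genotypes <- function(variants, cases, controls) {
  cases <- as.character(cases); controls <- as.character(controls)
  both <- intersect(cases, controls)
  if (length(both))
    stop("case and control groups overlap: ", paste(both, collapse = ", "))
  if (!"genotypes" %in% names(variants))
    stop("variants carry no genotypes; read them from a multi-sample VCF")

  tally <- function(gt, ids) {
    missing_ids <- setdiff(ids, names(gt))
    if (length(missing_ids))
      stop("unknown sample id(s): ", paste(missing_ids, collapse = ", "))
    g <- gt[ids]
    n_dip <- sum(g %in% c("hom_ref", "het", "hom_alt"))
    n_hap <- sum(g %in% c("hap_ref", "hap_alt"))
    c(hom = sum(g == "hom_alt"),
      het = sum(g == "het"),
      alleles = 2L * n_dip + n_hap,
      alt = 2L * sum(g == "hom_alt") + sum(g == "het") + sum(g == "hap_alt"))
  }
  ca <- vapply(variants$genotypes, tally, integer(4), ids = cases)
  co <- vapply(variants$genotypes, tally, integer(4), ids = controls)
  data.table(
    n_hom_cases = ca["hom", ], n_het_cases = ca["het", ],
    n_alleles_cases = ca["alleles", ],
    n_hom_controls = co["hom", ], n_het_controls = co["het", ],
    n_alleles_controls = co["alleles", ],
    n_alt_cases = ca["alt", ], n_alt_controls = co["alt", ])
}

#' Filter variants by a case/control genotype contrast
#'
#' Computes [count_genotypes()] tallies and keeps the variants whose
#' contrast satisfies the predicate. Built-in predicates:
#' * `"cases_only"`: the alternate allele is present in at least one case
#'   and in zero control alleles;
#' * `"controls_only"`: the converse;
#' * `list(k = , m = )` (or the string `"thresholds:k,m"`): at least `k`
#'   alternate alleles among cases and at most `m` among controls.
#'
#' Surviving variants carry their tallies as extra columns, so the result
#' feeds directly into [rank_variants()].
#'
#' @param variants A `variant_table` with genotypes.
#' @param cases,controls Disjoint character vectors of sample ids.
#' @param predicate `"cases_only"`, `"controls_only"`, a
#'   `list(k =, m =)`, or `"thresholds:k,m"`.
#' @return The surviving rows as a `variant_table` with appended tally
#'   columns.
#' @export
casecontrol_filter <- function(variants, cases, controls,
                               predicate = "cases_only") {
  cnt <- count_genotypes(variants, cases, controls)
  pred <- parse_predicate(predicate)
  keep <- switch(pred$kind,
    cases_only    = cnt$n_alt_cases >= 1L & cnt$n_alt_controls == 0L,
    controls_only = cnt$n_alt_controls >= 1L & cnt$n_alt_cases == 0L,
    thresholds    = cnt$n_alt_cases >= pred$k & cnt$n_alt_controls <= pred$m)
  out <- cbind(as.data.table(variants), cnt)[keep]
  as_variant_table(out)
}

parse_predicate <- function(predicate) {
  if (is.list(predicate)) {
    if (!all(c("k", "m") %in% names(predicate)))
      stop("threshold predicate needs elements 'k' and 'm'")
    return(list(kind = "thresholds",
                k = as.integer(predicate$k), m = as.integer(predicate$m)))
  }
  p <- as.character(predicate)[1]
  if (p %in% c("cases_only", "controls_only")) return(list(kind = p))
  if (grepl("^thresholds:", p)) {
    km <- as.integer(strsplit(sub("^thresholds:", "", p), ",")[[1]])
    if (length(km) != 2L || anyNA(km))
      stop("malformed threshold predicate: ", p)
    return(list(kind = "thresholds", k = km[1], m = km[2]))
  }
  stop("unknown case-control predicate: ", p)
}

# Normalize a diploid/haploid GT string ("0/1", "1|1", "0", "./1", ...)
# to a genotype call. Any missing allele makes the whole call missing.
gt_to_call <- function(gt) {
  gt <- as.character(gt)
  out <- rep("missing", length(gt))
  al <- strsplit(gt, "[/|]")
  for (i in seq_along(al)) {
    a <- al[[i]]
    if (is.na(gt[i]) || !length(a) || anyNA(a) || any(a == ".")) next
    if (length(a) == 1L) {
      out[i] <- if (a == "0") "hap_ref" else "hap_alt"
    } else if (all(a == "0")) {
      out[i] <- "hom_ref"
    } else if (all(a != "0")) {
      out[i] <- "hom_alt"
    } else {
      out[i] <- "het"
    }
  }
  out
}
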