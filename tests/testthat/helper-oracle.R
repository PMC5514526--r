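# Independent brute-force re-computation of the rank score: a literal,
# per-variant transcription of the encoding rules, deliberately written
# without reusing any of the package's encoder code paths. Used to verify
# score_variants() by dual-route comparison.

oracle_region_weight <- function(region) {
  tiers <- list(exonic = 1, splicing = 1,
                ncRNA = 5 / 6,
                UTR5 = 4 / 6, UTR3 = 4 / 6,
                intronic = 3 / 6,
                upstream = 2 / 6, downstream = 2 / 6,
                intergenic = 1 / 6)
  if (is.na(region) || region == "") return(1 / 6)
  best <- 0
  for (tok in strsplit(region, ";")[[1]]) {
    if (grepl("^ncRNA", tok)) tok <- "ncRNA"
    w <- if (tok %in% names(tiers)) tiers[[tok]] else 1 / 6
    if (w > best) best <- w
  }
  best
}

oracle_pred_weight <- function(alg, call) {
  if (is.na(call)) return(0)
  if (alg == "polyphen2") {
    if (call == "D") return(1)
    if (call == "P") return(0.5)
    return(0)
  }
  del <- list(sift = "D", lrt = "D", mutationtaster = c("A", "D"),
              mutationassessor = c("H", "M"), fathmm = "D",
              metasvm = "D", metalr = "D")
  if (call %in% del[[alg]]) 1 else 0
}

oracle_cons_weight <- function(score, cutoff) {
  if (is.na(score)) return(0)
  if (score > cutoff) 1 else 0
}

oracle_freq_weight <- function(af) {
  if (is.na(af)) return(1)
  1 - af
}

# One variant (a plain list/row) -> total score under the given config.
oracle_total <- function(row, config) {
  e <- list()
  e$region <- oracle_region_weight(row$region)
  e$novelty <- if (is.na(row$dbsnp_id)) 1 else 0
  for (alg in c("sift", "polyphen2", "lrt", "mutationtaster",
                "mutationassessor", "fathmm", "metasvm", "metalr"))
    e[[alg]] <- oracle_pred_weight(alg, row[[alg]])
  for (alg in c("gerp", "phylop", "phastcons", "siphy"))
    e[[alg]] <- oracle_cons_weight(row[[alg]], config$cutoffs[[alg]])
  if (config$freq_mode == "per_db") {
    for (db in c("af_1000g", "af_esp6500", "af_exac"))
      e[[db]] <- oracle_freq_weight(row[[db]])
  } else {
    afs <- c(row$af_1000g, row$af_esp6500, row$af_exac)
    e$frequency <- if (all(is.na(afs))) 1 else 1 - max(afs, na.rm = TRUE)
  }
  if (config$encode_mode == "combined") {
    e$encode <- if (isTRUE(row$encode_element) || isTRUE(row$encode_tfbs) ||
                    isTRUE(row$encode_conserved)) 1 else 0
  } else {
    e$encode_element <- if (isTRUE(row$encode_element)) 1 else 0
    e$encode_tfbs <- if (isTRUE(row$encode_tfbs)) 1 else 0
    e$encode_conserved <- if (isTRUE(row$encode_conserved)) 1 else 0
  }
  e$clinvar <- if (isTRUE(row$clinvar)) 1 else 0
  e$gwas <- if (isTRUE(row$gwas)) 1 else 0

  total <- 0
  for (s in names(config$weights))
    if (config$enabled[[s]])
      total <- total + config$weights[[s]] * e[[s]]
  total
}

oracle_totals <- function(variants, config) {
  vapply(seq_len(nrow(variants)),
         function(i) oracle_total(as.list(variants[i, ]), config),
         numeric(1))
}
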