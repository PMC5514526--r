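#' Specify a causal-gene spike-in
#'
#' Describes the variants to supplement into a synthetic background exome
#' so that ranking + model filtering can be benchmarked on recovering the
#' spiked gene: one variant for a dominant-style design, two for a
#' recessive-style design.
#'
#' @param gene Gene symbol to spike.
#' @param n_variants Number of variants to insert (>= 1).
#' @param make_functional Make them exonic nonsynonymous SNVs.
#' @param make_rare Leave them absent from every population database.
#' @param make_deleterious Give deleterious calls from all eight
#'   prediction algorithms and high conservation (GERP++ 5.0).
#' @param chrom Chromosome for the spiked variants; `NULL` picks a random
#'   autosome (use `"X"` for X-linked designs).
#' @return A `spike_spec` object.
#' @export
spike_spec <- function(gene, n_variants = 1L, make_functional = TRUE,
                       make_rare = TRUE, make_deleterious = TRUE,
                       chrom = NULL) {
  n_variants <- as.integer(n_variants)
  if (is.na(n_variants) || n_variants < 1L)
    stop("n_variants must be a positive integer")
  structure(list(gene = as.character(gene), n_variants = n_variants,
                 make_functional = isTRUE(make_functional),
                 make_rare = isTRUE(make_rare),
                 make_deleterious = isTRUE(make_deleterious),
                 chrom = if (!is.null(chrom)) normalize_chrom(chrom)),
            class = "spike_spec")
}

#' Generate a synthetic background exome
#'
#' Draws `n` annotated variants with the broad statistical structure of a
#' "normal" annotated exome: region classes mostly intronic/intergenic
#' with a minority exonic; allele frequencies mostly common (Beta
#' spectrum); ~95% of variants carrying dbSNP ids; deleteriousness
#' predictions mostly tolerated; conservation scores mostly below their
#' cutoffs. A small fraction of INDELs is included so the SNV/INDEL
#' partition is exercised. Output is deterministic for a fixed seed.
#'
#' This is deliberately a minimal-sufficient background — category
#' proportions and an AF spectrum, no linkage, no site-frequency realism —
#' adequate for spike-in contrast experiments, not population-genetic
#' simulation.
#'
#' @param n Number of variants (>= 0).
#' @param seed Integer RNG seed.
#' @param af_spectrum List with Beta parameters `shape1`, `shape2` of the
#'   allele-frequency spectrum and `p_missing`, the probability that a
#'   known variant is absent from a given database.
#' @param p_indel Fraction of INDEL records.
#' @param n_samples If > 0, attach per-sample genotypes for samples
#'   `S1..Sn` (alt-allele dosage drawn from the variant's AF).
#' @return A `variant_table`.
#' @export
#' @examples
#' bg <- generate_background(100, seed = 7)
#' table(bg$variant_class)
generate_background <- function(n, seed,
                                af_spectrum = list(shape1 = 2, shape2 = 1,
                                                   p_missing = 0.05),
                                p_indel = 0.02, n_samples = 0L) {
  n <- as.integer(n)
  stopifnot(n >= 0L)
  if (n == 0L) return(variant_table())
  with_seed(seed, {
    regions <- c("exonic", "splicing", "ncRNA", "UTR5", "UTR3", "intronic",
                 "upstream", "downstream", "intergenic")
    rprob <- c(0.10, 0.004, 0.03, 0.02, 0.05, 0.55, 0.02, 0.02, 0.206)
    region <- sample(regions, n, replace = TRUE, prob = rprob)
    # occasional multi-valued annotation, as ANNOVAR emits
    two <- runif(n) < 0.01 & region %in% c("exonic", "intronic")
    region[two] <- paste(region[two], "splicing", sep = ";")

    chrom <- sample(c(as.character(1:22), "X"), n, replace = TRUE,
                    prob = c(rep(1, 22), 0.5))
    pos <- sample.int(2.4e8, n, replace = TRUE)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    is_indel <- runif(n) < p_indel
    alt[is_indel] <- paste0(alt[is_indel], "A")

    n_genes <- max(1L, n %/% 3L)
    gene <- sprintf("GENE%05d", sample.int(n_genes, n, replace = TRUE))
    gene[grepl("intergenic", region)] <- NA_character_

    known <- runif(n) < 0.95
    dbsnp_id <- ifelse(known, sprintf("rs%08d", sample.int(9e7, n)), NA)

    af1 <- function() {
      af <- rbeta(n, af_spectrum$shape1, af_spectrum$shape2)
      af[!known | runif(n) < af_spectrum$p_missing] <- NA
      round(af, 4)
    }
    exonic <- grepl("exonic", region) & !is_indel

    ef <- rep(NA_character_, n)
    ef[exonic] <- sample(c("nonsynonymous", "synonymous", "stopgain",
                           "stoploss", "unknown"),
                         sum(exonic), replace = TRUE,
                         prob = c(0.45, 0.45, 0.02, 0.005, 0.075))

    pred_call <- function(del, tol, p_del = 0.05) {
      out <- rep(NA_character_, n)
      out[exonic] <- ifelse(runif(sum(exonic)) < p_del,
                            sample(del, sum(exonic), replace = TRUE),
                            sample(tol, sum(exonic), replace = TRUE))
      out
    }
    pp2 <- rep(NA_character_, n)
    pp2[exonic] <- sample(c("D", "P", "B"), sum(exonic), replace = TRUE,
                          prob = c(0.05, 0.05, 0.90))

    dt <- data.table(
      chrom = chrom, pos = pos, ref = unname(ref), alt = alt,
      region = region, exonic_func = ef, gene = gene, dbsnp_id = dbsnp_id,
      af_1000g = af1(), af_esp6500 = af1(), af_exac = af1(),
      sift = pred_call("D", "T"),
      polyphen2 = pp2,
      lrt = pred_call("D", c("N", "U")),
      mutationtaster = pred_call(c("A", "D"), c("N", "P")),
      mutationassessor = pred_call(c("H", "M"), c("L", "N")),
      fathmm = pred_call("D", "T"),
      metasvm = pred_call("D", "T"),
      metalr = pred_call("D", "T"),
      gerp = round(rnorm(n, -1, 2), 3),
      phylop = round(rnorm(n, 0, 1.2), 3),
      phastcons = round(rbeta(n, 0.5, 1.5), 3),
      siphy = round(rnorm(n, 6, 3), 3),
      encode_element = runif(n) < 0.08,
      encode_tfbs = runif(n) < 0.03,
      encode_conserved = runif(n) < 0.05,
      clinvar = runif(n) < 0.001,
      gwas = runif(n) < 0.005,
      cadd = round(runif(n, 0, 30), 2))
    # keep loci unique so tie-breaks and VCF round-trips are unambiguous
    dt <- unique(dt, by = c("chrom", "pos"))

    if (n_samples > 0L) {
      samples <- sprintf("S%d", seq_len(n_samples))
      af_gt <- fifelse(is.na(dt$af_1000g), 0.01, pmax(dt$af_1000g, 0.01))
      dt[, genotypes := lapply(seq_len(.N), function(i) {
        dose <- rbinom(n_samples, 2L, af_gt[i])
        setNames(c("hom_ref", "het", "hom_alt")[dose + 1L], samples)
      })]
    }
    as_variant_table(dt)
  })
}

#' Supplement spiked causal variants into a background
#'
#' Appends `n_variants` novel (no dbSNP id), functional, rare,
#' fully-deleterious SNVs attributed to the spiked gene, emulating
#' supplementing known causal mutations into a normal exome. With all
#' defaults the spiked variants attain the maximal encoded weight on every
#' enabled deleteriousness, conservation, rarity and novelty source.
#'
#' @param background A `variant_table` (see [generate_background()]).
#' @param spec A [spike_spec()].
#' @param seed Integer RNG seed (placement of the spiked loci).
#' @return A `variant_table` of `nrow(background) + n_variants` rows.
#' @export
spike <- function(background, spec, seed = 1L) {
  stopifnot(inherits(spec, "spike_spec"))
  background <- as_variant_table(background)
  with_seed(seed, {
    k <- spec$n_variants
    chrom <- spec$chrom %||% sample(as.character(1:22), 1)
    taken <- background$pos[background$chrom == chrom]
    pos <- sample.int(2.4e8, k)
    while (anyDuplicated(c(pos, taken)))
      pos <- sample.int(2.4e8, k)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, k, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    sp <- data.table(
      chrom = chrom, pos = pos, ref = unname(ref), alt = alt,
      region = if (spec$make_functional) "exonic" else "intronic",
      exonic_func = if (spec$make_functional) "nonsynonymous" else NA_character_,
      gene = spec$gene, dbsnp_id = NA_character_,
      cadd = 35)
    if (spec$make_deleterious) {
      for (alg in .PRED_ALGOS) set(sp, j = alg, value = "D")
      sp[, mutationtaster := "A"][, mutationassessor := "H"]
      sp[, c("gerp", "phylop", "phastcons", "siphy") :=
           .(5.0, 5.0, 0.99, 20.0)]
    }
    if (!spec$make_rare)
      sp[, c("af_1000g", "af_esp6500", "af_exac") := .(0.2, 0.2, 0.2)]
    if ("genotypes" %in% names(background)) {
      samples <- names(background$genotypes[[1]])
      sp[, genotypes := lapply(seq_len(.N), function(i)
        setNames(c("het", rep("hom_ref", length(samples) - 1L)), samples))]
    }
    out <- rbind(background, sp, fill = TRUE)
    as_variant_table(out)
  })
}

#' Write a variant table as an ANNOVAR-style multianno file
#'
#' Emits the tab-delimited dialect [read_annovar_table()] consumes, using
#' the first header name of [default_column_map()] for each annotation
#' column; missing values become `"."`, presence-style flags become
#' `"Present"`/`"."`.
#'
#' @param variants A `variant_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annovar_table <- function(variants, path) {
  variants <- as_variant_table(variants)
  map <- default_column_map()
  end <- variants$pos + nchar(variants$ref) - 1L
  out <- data.table(Chr = variants$chrom, Start = variants$pos, End = end,
                    Ref = variants$ref, Alt = variants$alt)
  presence_cols <- c(.ENCODE_FLAGS, "clinvar", "gwas")
  for (field in names(map)) {
    header <- map[[field]][1]
    v <- variants[[field]]
    if (field %in% presence_cols) v <- ifelse(isTRUE_vec(v), "Present", NA)
    set(out, j = header, value = v)
  }
  write_tsv_full(out, path)
}

#' Write a variant table as a single- or multi-sample VCF
#'
#' Emits a minimal VCFv4.2 file carrying the annotations as INFO keys
#' named after the default multianno headers (`";"` in values escaped as
#' `\\x3b`, the ANNOVAR convention) and, when a `genotypes` column is
#' present, FORMAT/GT sample columns. Readable by [read_vcf()] and by
#' standard VCF tooling.
#'
#' @param variants A `variant_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  variants <- as_variant_table(variants)
  map <- default_column_map()
  presence_cols <- c(.ENCODE_FLAGS, "clinvar", "gwas")

  meta <- c("##fileformat=VCFv4.2",
            "##source=rankvar-synthetic",
            sprintf(paste0("##INFO=<ID=%s,Number=%s,Type=%s,",
                           "Description=\"%s annotation\">"),
                    vapply(map, `[`, character(1), 1L),
                    ifelse(names(map) %in% presence_cols, "0", "1"),
                    ifelse(names(map) %in% presence_cols, "Flag", "String"),
                    names(map)),
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")

  info <- vapply(seq_len(nrow(variants)), function(i) {
    parts <- character(0)
    for (field in names(map)) {
      v <- variants[[field]][i]
      if (field %in% presence_cols) {
        if (isTRUE(v)) parts <- c(parts, map[[field]][1])
      } else if (!is.na(v)) {
        parts <- c(parts, sprintf("%s=%s", map[[field]][1],
                                  gsub(";", "\\x3b", as.character(v),
                                       fixed = TRUE)))
      }
    }
    if (length(parts)) paste(parts, collapse = ";") else "."
  }, character(1))

  body <- data.table(CHROM = variants$chrom, POS = variants$pos,
                     ID = fifelse(is.na(variants$dbsnp_id), ".",
                                  variants$dbsnp_id),
                     REF = variants$ref, ALT = variants$alt,
                     QUAL = ".", FILTER = "PASS", INFO = info)
  header <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if ("genotypes" %in% names(variants) && nrow(variants)) {
    samples <- names(variants$genotypes[[1]])
    body[, FORMAT := "GT"]
    gt_string <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                   hap_ref = "0", hap_alt = "1", missing = "./.")
    for (s in samples)
      set(body, j = s,
          value = vapply(variants$genotypes, function(g)
            gt_string[[g[[s]]]], character(1)))
    header <- c(header, "FORMAT", samples)
  }
  # genomic order, as VCF requires
  setorder(body, CHROM, POS)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines(paste(header, collapse = "\t"), con)
  if (nrow(body))
    writeLines(do.call(paste, c(as.list(body), sep = "\t")), con)
  invisible(path)
}

# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}
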