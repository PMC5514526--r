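# Small hand-built variant tables used across the unit tests.

av <- function(..., n = 1L) {
  defaults <- list(chrom = rep("1", n), pos = seq_len(n) * 100L,
                   ref = rep("G", n), alt = rep("A", n))
  args <- utils::modifyList(defaults, list(...))
  do.call(variant_table, args)
}

# A compact multi-gene table with known structure: scores differ by
# construction through region/novelty/prediction contrasts.
toy_table <- function() {
  variant_table(
    chrom = c("1", "1", "2", "7", "X", "X", "3"),
    pos = c(100L, 200L, 300L, 400L, 500L, 600L, 700L),
    ref = c("G", "C", "T", "A", "G", "C", "A"),
    alt = c("A", "T", "C", "G", "T", "G", "C"),
    region = c("exonic", "exonic", "intronic", "exonic", "exonic",
               "splicing", "intergenic"),
    exonic_func = c("nonsynonymous", "synonymous", NA, "nonsynonymous",
                    "stopgain", NA, NA),
    gene = c("GENEA", "GENEA", "GENEB", "GENEC", "GENEX", "GENEX", NA),
    dbsnp_id = c(NA, "rs1", "rs2", NA, NA, "rs3", "rs4"),
    sift = c("D", "T", NA, "D", "D", NA, NA),
    gerp = c(4.1, 0.2, 1.0, 3.0, 5.0, 2.5, NA),
    af_exac = c(NA, 0.2, 0.5, 0.001, NA, 0.0005, 0.4))
}

write_mini_vcf <- function(path, records,
                           samples = NULL,
                           header = TRUE) {
  meta <- c("##fileformat=VCFv4.2",
            "##INFO=<ID=Gene.refGene,Number=1,Type=String,Description=\"g\">",
            "##INFO=<ID=Func.refGene,Number=1,Type=String,Description=\"f\">",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">")
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(samples)) cols <- c(cols, "FORMAT", samples)
  lines <- c(if (header) meta, paste(cols, collapse = "\t"), records)
  writeLines(lines, path)
  path
}
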