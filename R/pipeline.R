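#' Run the command-line pipeline
#'
#' Single entry point wiring readers, encoder, ranker, filters and writers;
#' this is what the installed `exec/rankvar` script calls. Subcommands:
#'
#' * `rank --input <tsv|vcf> [--format annovar|vcf|auto] [--config <yaml>]
#'   --out-prefix <p>` — writes `<p>.ranked.tsv`, `<p>.indels.tsv`,
#'   `<p>.genes.tsv` and `<p>.report.json`.
#' * `filter --input <p>.ranked.tsv [--model dominant|recessive|x_recessive]
#'   [--maf <f>] [--maf-db 1000g,esp6500,exac] [--functional-only]
#'   [--clinical-only] [--min-per-gene <n>] --out-prefix <p2>` — re-filters
#'   a previously ranked table.
#' * `casecontrol --vcf <f> --cases <file> --controls <file>
#'   [--predicate cases_only|controls_only|thresholds:k,m] --out <tsv>` —
#'   genotype-contrast filtering; sample lists are newline-delimited ids.
#' * `simulate --n <int> --seed <int> [--spike GENE:k:dominant|recessive]
#'   [--format annovar|vcf] [--samples <int>] --out <path>` — synthetic
#'   exome generation.
#'
#' All diagnostics go to stderr; a JSON run report reconciling the counts
#' of every stage is written next to the outputs.
#'
#' @param args Character vector of command-line arguments (subcommand
#'   first), e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return Exit status, invisibly (0 on success).
#' @export
run_pipeline <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args))
      stop("usage: rankvar <rank|filter|casecontrol|simulate> [options]")
    cmd <- args[1]
    rest <- args[-1]
    switch(cmd,
      rank = cmd_rank(rest),
      filter = cmd_filter(rest),
      casecontrol = cmd_casecontrol(rest),
      simulate = cmd_simulate(rest),
      "--version" = { cat(as.character(packageVersion("rankvar")), "\n"); 0L },
      stop("unknown subcommand: ", cmd))
    0L
  }, error = function(e) {
    message("ERROR: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli <- function(args, option_list, usage) {
  parser <- optparse::OptionParser(option_list = option_list, usage = usage)
  optparse::parse_args(parser, args = args)
}

load_config <- function(path) {
  if (is.null(path)) weight_config() else read_weight_config(path)
}

cmd_rank <- function(args) {
  opt <- parse_cli(args, list(
    optparse::make_option("--input", type = "character"),
    optparse::make_option("--format", type = "character", default = "auto"),
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--out-prefix", type = "character",
                          dest = "out_prefix")),
    "rankvar rank --input FILE --out-prefix PREFIX")
  if (is.null(opt$input) || is.null(opt$out_prefix))
    stop("rank: --input and --out-prefix are required")
  config <- load_config(opt$config)
  fmt <- opt$format
  if (fmt == "auto")
    fmt <- if (grepl("\\.vcf(\\.gz)?$", opt$input)) "vcf" else "annovar"
  variants <- switch(fmt,
    annovar = read_annovar_table(opt$input),
    vcf = read_vcf(opt$input),
    stop("unknown input format: ", fmt))

  ranked <- rank_variants(variants, config)
  genes <- summarize_genes(ranked)
  p <- opt$out_prefix
  write_ranked_table(ranked, paste0(p, ".ranked.tsv"))
  write_tsv(ranked$indels, paste0(p, ".indels.tsv"))
  write_tsv(genes, paste0(p, ".genes.tsv"))
  report <- run_report(
    stage = "rank",
    input = list(path = opt$input, format = fmt,
                 total = nrow(variants) +
                   (attr(variants, "n_skipped") %||% 0L) +
                   (attr(variants, "n_multiallelic") %||% 0L),
                 parsed = nrow(variants),
                 snv = sum(variants$variant_class == "SNV"),
                 indel = sum(variants$variant_class == "INDEL"),
                 other = sum(variants$variant_class == "OTHER"),
                 malformed_skipped = attr(variants, "n_skipped") %||% 0L,
                 multiallelic_dropped =
                   attr(variants, "n_multiallelic") %||% 0L),
    output = list(ranked_rows = nrow(ranked$rows),
                  indel_rows = nrow(ranked$indels),
                  gene_rows = nrow(genes),
                  chrom_counts = as.list(ranked$chrom_counts)),
    config = config)
  jsonlite::write_json(report, paste0(p, ".report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("rank: %d SNV(s) ranked, %d INDEL(s) set aside",
                  nrow(ranked$rows), nrow(ranked$indels)))
  0L
}

cmd_filter <- function(args) {
  opt <- parse_cli(args, list(
    optparse::make_option("--input", type = "character"),
    optparse::make_option("--model", type = "character", default = NULL),
    optparse::make_option("--maf", type = "double", default = NULL),
    optparse::make_option("--maf-db", type = "character",
                          default = "1000g,esp6500,exac", dest = "maf_db"),
    optparse::make_option("--functional-only", action = "store_true",
                          default = FALSE, dest = "functional_only"),
    optparse::make_option("--clinical-only", action = "store_true",
                          default = FALSE, dest = "clinical_only"),
    optparse::make_option("--min-per-gene", type = "integer",
                          default = NULL, dest = "min_per_gene"),
    optparse::make_option("--out-prefix", type = "character",
                          dest = "out_prefix")),
    "rankvar filter --input RANKED.tsv [criteria] --out-prefix PREFIX")
  if (is.null(opt$input) || is.null(opt$out_prefix))
    stop("filter: --input and --out-prefix are required")
  rows <- read_ranked_table(opt$input)
  ranked <- structure(list(rows = rows, indels = data.table(),
                           chrom_counts = integer(0),
                           config = weight_config()),
                      class = "ranked_table")
  spec <- filter_spec(maf_threshold = opt$maf,
                      maf_databases = strsplit(opt$maf_db, ",")[[1]],
                      functional_only = opt$functional_only,
                      clinical_only = opt$clinical_only,
                      min_mutations_per_gene = opt$min_per_gene,
                      model = opt$model)
  out <- apply_filterspec(ranked, spec)
  genes <- summarize_genes(out)
  p <- opt$out_prefix
  write_ranked_table(out, paste0(p, ".ranked.tsv"))
  write_tsv(genes, paste0(p, ".genes.tsv"))
  report <- run_report(
    stage = "filter",
    input = list(path = opt$input, total = nrow(rows)),
    filter = spec_as_list(spec),
    output = list(kept = nrow(out$rows),
                  removed = nrow(rows) - nrow(out$rows),
                  gene_rows = nrow(genes)))
  jsonlite::write_json(report, paste0(p, ".report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("filter: %d of %d row(s) kept", nrow(out$rows), nrow(rows)))
  0L
}

cmd_casecontrol <- function(args) {
  opt <- parse_cli(args, list(
    optparse::make_option("--vcf", type = "character"),
    optparse::make_option("--cases", type = "character"),
    optparse::make_option("--controls", type = "character"),
    optparse::make_option("--predicate", type = "character",
                          default = "cases_only"),
    optparse::make_option("--out", type = "character")),
    "rankvar casecontrol --vcf F --cases F --controls F --out F")
  if (is.null(opt$vcf) || is.null(opt$cases) || is.null(opt$controls) ||
      is.null(opt$out))
    stop("casecontrol: --vcf, --cases, --controls and --out are required")
  cases <- readLines(opt$cases)
  controls <- readLines(opt$controls)
  cases <- cases[nzchar(cases)]; controls <- controls[nzchar(controls)]
  variants <- read_vcf(opt$vcf)
  kept <- casecontrol_filter(variants, cases, controls, opt$predicate)
  write_tsv(kept, opt$out)
  report <- run_report(
    stage = "casecontrol",
    input = list(path = opt$vcf, total = nrow(variants),
                 multiallelic_dropped = attr(variants, "n_multiallelic") %||% 0L,
                 n_cases = length(cases), n_controls = length(controls),
                 predicate = opt$predicate),
    output = list(kept = nrow(kept),
                  removed = nrow(variants) - nrow(kept)))
  jsonlite::write_json(report, paste0(opt$out, ".report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("casecontrol: %d of %d variant(s) kept",
                  nrow(kept), nrow(variants)))
  0L
}

cmd_simulate <- function(args) {
  opt <- parse_cli(args, list(
    optparse::make_option("--n", type = "integer", default = 1000L),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--spike", type = "character", default = NULL),
    optparse::make_option("--format", type = "character", default = "annovar"),
    optparse::make_option("--samples", type = "integer", default = 0L),
    optparse::make_option("--out", type = "character")),
    "rankvar simulate --n N --seed S [--spike GENE:k:model] --out F")
  if (is.null(opt$out)) stop("simulate: --out is required")
  v <- generate_background(opt$n, seed = opt$seed, n_samples = opt$samples)
  if (!is.null(opt$spike)) {
    parts <- strsplit(opt$spike, ":", fixed = TRUE)[[1]]
    if (length(parts) < 2L)
      stop("malformed --spike (expected GENE:k[:model]): ", opt$spike)
    model <- if (length(parts) >= 3L) parts[3] else "dominant"
    sp <- spike_spec(parts[1], n_variants = as.integer(parts[2]),
                     chrom = if (normalize_model(model) == "x_recessive") "X")
    v <- spike(v, sp, seed = opt$seed + 1L)
  }
  switch(opt$format,
         annovar = write_annovar_table(v, opt$out),
         vcf = write_vcf(v, opt$out),
         stop("unknown output format: ", opt$format))
  message(sprintf("simulate: %d variant(s) written to %s", nrow(v), opt$out))
  0L
}

run_report <- function(stage, ..., config = NULL) {
  rep <- c(list(tool = "rankvar",
                version = as.character(packageVersion("rankvar")),
                stage = stage), list(...))
  if (!is.null(config))
    rep$settings <- list(weights = as.list(config$weights),
                         enabled = as.list(config$enabled),
                         cutoffs = as.list(config$cutoffs),
                         freq_mode = config$freq_mode,
                         encode_mode = config$encode_mode,
                         gene_score = config$gene_score)
  rep
}

spec_as_list <- function(spec) {
  Filter(Negate(is.null), unclass(spec))
}
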