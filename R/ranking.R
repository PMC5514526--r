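#' Rank variants by total score
#'
#' Partitions the input into SNVs and INDELs (INDELs are annotated but
#' never scored; they are reported separately), scores every SNV with
#' [score_variants()], sorts by score descending and assigns dense ranks:
#' tied scores share a rank and the next distinct score takes the next
#' integer. Within a tie, rows are ordered by chromosome, position, ref,
#' alt (lexicographic) so output is byte-stable and independent of input
#' order.
#'
#' @param variants A `variant_table` (SNVs, INDELs and others mixed).
#' @param config A [weight_config()].
#' @return A `ranked_table`: list with `rows` (a `data.table` of `rank`,
#'   `score`, the variant columns and the `w_<source>` encoded weights),
#'   `indels` (unranked `variant_table`), `chrom_counts` (named integer,
#'   SNVs per chromosome) and the `config` used.
#' @export
#' @examples
#' v <- generate_background(50, seed = 1)
#' rk <- rank_variants(v)
#' head(rk$rows[, .(rank, score, chrom, pos, gene)])
rank_variants <- function(variants, config = weight_config()) {
  variants <- as_variant_table(variants)
  is_snv <- variants$variant_class == "SNV"
  indels <- variants[variants$variant_class == "INDEL"]
  snvs <- variants[is_snv]

  brk <- score_variants(snvs, config)
  rows <- cbind(data.table(score = brk$score), snvs,
                brk[, setdiff(names(brk), "score"), with = FALSE])
  setorder(rows, -score, chrom, pos, ref, alt)
  rows[, rank := if (.N) frank(-score, ties.method = "dense") else integer(0)]
  setcolorder(rows, c("rank", "score"))

  cc <- if (nrow(rows)) {
    tab <- rows[, .N, by = chrom]
    setNames(tab$N, tab$chrom)
  } else setNames(integer(0), character(0))

  structure(list(rows = rows[], indels = indels, chrom_counts = cc,
                 config = config),
            class = "ranked_table")
}

#' @method print ranked_table
#' @export
print.ranked_table <- function(x, n = 6L, ...) {
  cat(sprintf("<ranked_table> %d ranked SNV(s), %d INDEL(s) set aside, %d chromosome(s)\n",
              nrow(x$rows), nrow(x$indels), length(x$chrom_counts)))
  if (nrow(x$rows)) {
    cols <- intersect(c("rank", "score", "chrom", "pos", "ref", "alt",
                        "gene", "region"), names(x$rows))
    print(utils::head(x$rows[, cols, with = FALSE], n))
  }
  invisible(x)
}

# Re-sort and re-assign dense ranks after a filter removed rows.
rerank <- function(ranked, rows) {
  setorder(rows, -score, chrom, pos, ref, alt)
  rows[, rank := if (.N) frank(-score, ties.method = "dense") else integer(0)]
  cc <- if (nrow(rows)) {
    tab <- rows[, .N, by = chrom]
    setNames(tab$N, tab$chrom)
  } else setNames(integer(0), character(0))
  structure(list(rows = rows[], indels = ranked$indels, chrom_counts = cc,
                 config = ranked$config),
            class = "ranked_table")
}

#' Summarize ranked variants per gene
#'
#' One summary row per gene symbol among genic SNVs: the gene's best (or,
#' with `mode = "sum"`, summed) rank score, its best CADD value and its
#' mutation count. Variants in non-genic regions (intergenic, upstream,
#' downstream) are excluded; a variant annotated to several
#' `";"`-separated genes counts once for each symbol. Genes are ordered by
#' `best_score` descending (ties broken by symbol) and given dense
#' `gene_rank`s.
#'
#' @param ranked A `ranked_table`.
#' @param mode `"max"` (representative-variant score, default) or `"sum"`;
#'   defaults to the ranked table's config.
#' @return A `data.table` with columns `gene_rank`, `gene`, `best_score`,
#'   `best_cadd`, `mutation_count`.
#' @export
summarize_genes <- function(ranked, mode = NULL) {
  stopifnot(inherits(ranked, "ranked_table"))
  mode <- mode %||% ranked$config$gene_score
  mode <- match.arg(mode, c("max", "sum"))
  rows <- genic_rows(ranked$rows)
  if (!nrow(rows))
    return(data.table(gene_rank = integer(), gene = character(),
                      best_score = numeric(), best_cadd = numeric(),
                      mutation_count = integer()))
  genes <- gene_tokens(rows$gene)
  idx <- rep(seq_len(nrow(rows)), lengths(genes))
  long <- data.table(gene = unlist(genes),
                     score = rows$score[idx], cadd = rows$cadd[idx])
  out <- long[, .(
    best_score = if (mode == "max") max(score) else sum(score),
    best_cadd = if (all(is.na(cadd))) NA_real_ else max(cadd, na.rm = TRUE),
    mutation_count = .N), by = gene]
  setorder(out, -best_score, gene)
  out[, gene_rank := frank(-best_score, ties.method = "dense")]
  setcolorder(out, "gene_rank")
  out[]
}

# Genic rows: a gene symbol present and the region not purely
# intergenic/upstream/downstream.
genic_rows <- function(rows) {
  if (!nrow(rows)) return(rows)
  has_gene <- lengths(gene_tokens(rows$gene)) > 0L
  genic <- vapply(region_tokens(rows$region), function(t) {
    length(t) > 0L && any(!t %in% .NONGENIC)
  }, logical(1))
  rows[has_gene & genic]
}
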