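#' Weight configuration for the ranking score
#'
#' Holds the user weight in \[0,1\] for every annotation source, an
#' enabled/disabled flag per source, and the conservation cutoffs. The rank
#' score of a variant is the sum over enabled sources of
#' `user_weight * encoded_weight`, so disabling a source is equivalent to
#' giving it user weight 0. Default user weights are 1 for every source.
#'
#' Sources: `region`, `novelty`, the eight prediction algorithms (`sift`,
#' `polyphen2`, `lrt`, `mutationtaster`, `mutationassessor`, `fathmm`,
#' `metasvm`, `metalr`), the four conservation tracks (`gerp`, `phylop`,
#' `phastcons`, `siphy`), one frequency source per population database
#' (`af_1000g`, `af_esp6500`, `af_exac`; or a single `frequency` source
#' when `freq_mode = "max"`), `encode` (or the three individual flags when
#' `encode_mode = "per_flag"`), `clinvar` and `gwas`.
#'
#' Conservation cutoffs are strict (`score > cutoff` scores 1): GERP++
#' defaults to 2; the PhyloP (2), phastCons (0.6) and SiPhy (12) defaults
#' follow common dbNSFP-style practice and are configurable.
#'
#' @param weights Named numeric vector of user weights in \[0,1\];
#'   unnamed sources keep the default of 1.
#' @param enabled Named logical vector; unnamed sources stay enabled. A
#'   character vector is interpreted as the set of sources to *disable*.
#' @param cutoffs Named numeric vector overriding conservation cutoffs
#'   (`gerp`, `phylop`, `phastcons`, `siphy`).
#' @param freq_mode `"per_db"` (default): each population database
#'   contributes its own `1 - AF` term. `"max"`: a single term uses the
#'   maximum AF observed across databases.
#' @param encode_mode `"combined"` (default): one binary source that is 1
#'   if any regulatory flag is set. `"per_flag"`: three separate binary
#'   sources.
#' @param gene_score `"max"` (default) or `"sum"`: how per-gene summary
#'   scores aggregate the gene's variant scores.
#' @return A `weight_config` object.
#' @export
#' @examples
#' cfg <- weight_config(weights = c(gwas = 0.5), enabled = c(clinvar = FALSE))
#' cfg$weights[["gwas"]]
weight_config <- function(weights = NULL, enabled = NULL, cutoffs = NULL,
                          freq_mode = c("per_db", "max"),
                          encode_mode = c("combined", "per_flag"),
                          gene_score = c("max", "sum")) {
  freq_mode <- match.arg(freq_mode)
  encode_mode <- match.arg(encode_mode)
  gene_score <- match.arg(gene_score)

  sources <- config_sources(freq_mode, encode_mode)
  w <- setNames(rep(1, length(sources)), sources)
  e <- setNames(rep(TRUE, length(sources)), sources)
  k <- c(gerp = 2, phylop = 2, phastcons = 0.6, siphy = 12)

  if (!is.null(weights)) {
    bad <- setdiff(names(weights), sources)
    if (length(bad))
      stop("unknown weight source(s): ", paste(bad, collapse = ", "))
    if (any(is.na(weights)) || any(weights < 0 | weights > 1))
      stop("user weights must lie in [0,1]")
    w[names(weights)] <- weights
  }
  if (!is.null(enabled)) {
    if (is.character(enabled))
      enabled <- setNames(rep(FALSE, length(enabled)), enabled)
    bad <- setdiff(names(enabled), sources)
    if (length(bad))
      stop("unknown source(s) in 'enabled': ", paste(bad, collapse = ", "))
    e[names(enabled)] <- as.logical(enabled)
  }
  if (!is.null(cutoffs)) {
    bad <- setdiff(names(cutoffs), names(k))
    if (length(bad))
      stop("unknown conservation cutoff(s): ", paste(bad, collapse = ", "))
    k[names(cutoffs)] <- cutoffs
  }

  structure(list(weights = w, enabled = e, cutoffs = k,
                 freq_mode = freq_mode, encode_mode = encode_mode,
                 gene_score = gene_score),
            class = "weight_config")
}

config_sources <- function(freq_mode, encode_mode) {
  c("region", "novelty", .PRED_ALGOS, .CONS_ALGOS,
    if (freq_mode == "per_db") .AF_DBS else "frequency",
    if (encode_mode == "combined") "encode" else .ENCODE_FLAGS,
    "clinvar", "gwas")
}

# Sources that are both enabled and carry nonzero machinery in scoring.
enabled_sources <- function(config) {
  names(config$enabled)[config$enabled]
}

#' @method print weight_config
#' @export
print.weight_config <- function(x, ...) {
  cat("<weight_config>\n")
  off <- names(x$enabled)[!x$enabled]
  nondef <- names(x$weights)[x$weights != 1]
  cat(sprintf("  sources: %d (%s disabled)\n", length(x$weights),
              if (length(off)) paste(off, collapse = ", ") else "none"))
  if (length(nondef))
    cat("  non-default weights:",
        paste(sprintf("%s=%g", nondef, x$weights[nondef]), collapse = ", "),
        "\n")
  cat(sprintf("  cutoffs: %s\n",
              paste(sprintf("%s>%g", names(x$cutoffs), x$cutoffs),
                    collapse = ", ")))
  cat(sprintf("  freq_mode=%s encode_mode=%s gene_score=%s\n",
              x$freq_mode, x$encode_mode, x$gene_score))
  invisible(x)
}

#' Read / write a weight configuration file
#'
#' The on-disk format is flat YAML with `weights:`, `enabled:` and
#' `cutoffs:` mappings plus the three mode keys; omitted entries take the
#' defaults of [weight_config()].
#'
#' @param path File path.
#' @return `read_weight_config()` returns a `weight_config`.
#' @export
read_weight_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  weight_config(
    weights = if (!is.null(y$weights)) unlist(y$weights),
    enabled = if (!is.null(y$enabled)) unlist(y$enabled),
    cutoffs = if (!is.null(y$cutoffs)) unlist(y$cutoffs),
    freq_mode = y$freq_mode %||% "per_db",
    encode_mode = y$encode_mode %||% "combined",
    gene_score = y$gene_score %||% "max")
}

#' @rdname read_weight_config
#' @param config A `weight_config`.
#' @export
write_weight_config <- function(config, path) {
  stopifnot(inherits(config, "weight_config"))
  yaml::write_yaml(list(
    weights = as.list(config$weights),
    enabled = as.list(config$enabled),
    cutoffs = as.list(config$cutoffs),
    freq_mode = config$freq_mode,
    encode_mode = config$encode_mode,
    gene_score = config$gene_score), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
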