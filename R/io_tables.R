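#' Default ANNOVAR multianno column map
#'
#' Maps each canonical annotation field to the header names it may carry
#' in an ANNOVAR "multianno" table (several database releases are listed
#' per field; the first header present wins). Pass a modified copy — or a
#' named list of `canonical_field = "HeaderName"` overrides — as
#' `column_map` to [read_annovar_table()]/[read_vcf()] to handle other
#' header dialects.
#'
#' @return Named list: canonical field -> character vector of candidate
#'   header names.
#' @export
default_column_map <- function() {
  list(
    region           = c("Func.refGene", "Func.ensGene", "Func.knownGene", "Func"),
    gene             = c("Gene.refGene", "Gene.ensGene", "Gene.knownGene", "Gene"),
    exonic_func      = c("ExonicFunc.refGene", "ExonicFunc.ensGene",
                         "ExonicFunc.knownGene", "ExonicFunc"),
    dbsnp_id         = c("avsnp150", "avsnp147", "avsnp144", "snp138",
                         "snp137", "dbSNP"),
    af_1000g         = c("1000g2015aug_all", "1000g2014oct_all", "1000G_ALL"),
    af_esp6500       = c("esp6500siv2_all", "esp6500_all"),
    af_exac          = c("ExAC_ALL", "exac03"),
    sift             = "SIFT_pred",
    polyphen2        = c("Polyphen2_HDIV_pred", "Polyphen2_HVAR_pred"),
    lrt              = "LRT_pred",
    mutationtaster   = "MutationTaster_pred",
    mutationassessor = "MutationAssessor_pred",
    fathmm           = "FATHMM_pred",
    metasvm          = "MetaSVM_pred",
    metalr           = "MetaLR_pred",
    gerp             = c("GERP++_RS", "GERP.._RS"),
    phylop           = c("phyloP100way_vertebrate", "phyloP46way_placental",
                         "phyloP20way_mammalian"),
    phastcons        = c("phastCons100way_vertebrate",
                         "phastCons46way_placental"),
    siphy            = "SiPhy_29way_logOdds",
    encode_element   = c("wgEncodeRegDnaseClustered", "encodeElement"),
    encode_tfbs      = c("tfbsConsSites", "wgEncodeRegTfbsClustered"),
    encode_conserved = c("phastConsElements46way", "conservedElements"),
    clinvar          = c("CLNSIG", "CLINSIG", "clinvar_20150629", "clinvar"),
    gwas             = c("gwasCatalog", "gwascatalog"),
    cadd             = c("CADD_phred", "CADD13_PHRED", "CADD")
  )
}

merge_column_map <- function(column_map) {
  map <- default_column_map()
  if (!is.null(column_map))
    for (nm in names(column_map)) map[[nm]] <- column_map[[nm]]
  map
}

#' Read an ANNOVAR-style annotated variant table
#'
#' Reads a tab-delimited multianno table (header row; first five columns
#' Chr, Start, End, Ref, Alt; 1-based coordinates) into a
#' [variant_table()]. Remaining columns are matched to the canonical
#' annotation schema by name through [default_column_map()] (overridable
#' via `column_map`); unrecognized columns are preserved as opaque extra
#' columns. `"."` and empty strings mean missing. Rows whose mandatory
#' fields do not parse (non-positive position, empty alleles,
#' `ref == alt`) are skipped and counted in the `n_skipped` attribute.
#'
#' Presence-style annotation columns (ClinVar, GWAS catalog, the three
#' ENCODE tracks) become `TRUE` whenever the cell is non-missing.
#'
#' @param path Path to the table.
#' @param column_map Optional named list overriding the default map.
#' @return A `variant_table`; attribute `n_skipped` counts dropped rows.
#' @export
read_annovar_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  raw <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
               na.strings = NULL, quote = "")
  if (!nrow(raw) || !ncol(raw)) stop("empty input table: ", path)
  lead_want <- c("Chr", "Start", "End", "Ref", "Alt")
  have <- tolower(names(raw))
  lead_idx <- match(tolower(lead_want), have)
  if (anyNA(lead_idx))
    stop("missing mandatory column(s): ",
         paste(lead_want[is.na(lead_idx)], collapse = ", "))

  # End column ignored: Start suffices for 1-bp variants
  map <- merge_column_map(column_map)
  dt <- data.table(chrom = raw[[lead_idx[1]]],
                   pos = raw[[lead_idx[2]]],
                   ref = raw[[lead_idx[4]]],
                   alt = raw[[lead_idx[5]]])

  used <- lead_idx
  presence_cols <- c(.ENCODE_FLAGS, "clinvar", "gwas")
  for (field in names(map)) {
    j <- match(tolower(map[[field]]), have)
    j <- j[!is.na(j)][1]
    if (is.na(j)) next
    used <- c(used, j)
    val <- blank_to_na(raw[[j]])
    if (field %in% presence_cols) {
      # presence-style: any non-missing cell counts, except explicit
      # negatives in ClinVar-style significance fields
      hit <- !is.na(val)
      if (field == "clinvar")
        hit <- hit & !grepl("^(benign|likely benign|non-pathogenic)$",
                            val, ignore.case = TRUE)
      set(dt, j = field, value = hit)
    } else {
      set(dt, j = field, value = val)
    }
  }
  for (j in setdiff(seq_len(ncol(raw)), used))
    set(dt, j = names(raw)[j], value = raw[[j]])

  pos_num <- suppressWarnings(as.numeric(dt$pos))
  ok <- !is.na(pos_num) & pos_num >= 1 & pos_num == floor(pos_num) &
    !is.na(dt$chrom) & nzchar(dt$chrom) &
    !is.na(dt$ref) & nzchar(dt$ref) & dt$ref != "." &
    !is.na(dt$alt) & nzchar(dt$alt) & dt$alt != "." &
    toupper(dt$ref) != toupper(dt$alt)
  n_skipped <- sum(!ok)
  if (n_skipped)
    warning(n_skipped, " row(s) with unparseable mandatory fields skipped")
  out <- as_variant_table(dt[ok])
  setattr(out, "n_skipped", n_skipped)
  out
}

#' Read variants from a VCF file
#'
#' Reads a VCFv4.x file (plain or bgzip) into a [variant_table()].
#' Annotations, if present, are taken from INFO keys bearing the same
#' names as the table headers of [default_column_map()]; `";"` characters
#' escaped as `\\x3b` (the ANNOVAR convention) are decoded. Genotypes are
#' decoded from FORMAT/GT into a `genotypes` list column. The ranking
#' algorithm focuses on biallelic variants: multi-allelic records are
#' dropped with a warning and counted in the `n_multiallelic` attribute.
#'
#' @param path Path to the VCF.
#' @param column_map Optional named list overriding the default map.
#' @return A `variant_table`; attribute `n_multiallelic` counts dropped
#'   multi-allelic records.
#' @export
read_vcf <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (!any(grepl("^##fileformat=VCF", v@meta)))
    stop("malformed VCF header (no ##fileformat line): ", path)
  fix <- v@fix
  alt <- fix[, "ALT"]
  multi <- !is.na(alt) & grepl(",", alt, fixed = TRUE)
  n_multi <- sum(multi)
  if (n_multi)
    warning(n_multi, " multi-allelic record(s) dropped ",
            "(only biallelic variants are ranked)")
  keep <- !multi & !is.na(alt) & alt != "."

  dt <- data.table(chrom = fix[keep, "CHROM"],
                   pos = fix[keep, "POS"],
                   ref = fix[keep, "REF"],
                   alt = alt[keep],
                   dbsnp_id = blank_to_na(fix[keep, "ID"]))

  info <- fix[keep, "INFO"]
  map <- merge_column_map(column_map)
  presence_cols <- c(.ENCODE_FLAGS, "clinvar", "gwas")
  if (any(!is.na(info))) {
    for (field in names(map)) {
      val <- NULL
      for (key in map[[field]]) {
        got <- info_value(info, key)
        if (any(!is.na(got))) { val <- got; break }
      }
      if (is.null(val)) next
      if (field == "dbsnp_id") {
        dt[is.na(dbsnp_id), dbsnp_id := val[is.na(dt$dbsnp_id)]]
      } else if (field %in% presence_cols) {
        set(dt, j = field, value = !is.na(val))
      } else {
        set(dt, j = field, value = val)
      }
    }
  }

  if (ncol(v@gt) > 1L) {
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[keep, , drop = FALSE]
    samples <- colnames(gt)
    dt[, genotypes := lapply(seq_len(.N), function(i)
      setNames(gt_to_call(gt[i, ]), samples))]
  }
  out <- as_variant_table(dt)
  setattr(out, "n_multiallelic", n_multi)
  out
}

# Extract "key=value" from raw INFO strings, decoding ANNOVAR's \x3b
# escapes; flag-style keys (present without "=") return "TRUE".
info_value <- function(info, key) {
  out <- rep(NA_character_, length(info))
  ok <- which(!is.na(info))
  if (!length(ok)) return(out)
  pat <- paste0("(?:^|;)", gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1", key),
                "(?:=([^;]*))?(?=;|$)")
  m <- regexpr(pat, info[ok], perl = TRUE)
  hit <- m > 0L
  if (any(hit)) {
    matched <- regmatches(info[ok], m)
    val <- sub(pat, "\\1", matched, perl = TRUE)
    val[val == ""] <- "TRUE"
    out[ok[hit]] <- val
  }
  out <- gsub("\\x3b", ";", out, fixed = TRUE)
  blank_to_na(out)
}

#' Write / read a ranked variant table
#'
#' Writes the rows of a `ranked_table` as a tab-delimited file with a
#' deterministic column order (rank, score, locus, alleles, annotations,
#' encoded weights, CADD); missing values are written as `"."`. Numeric
#' columns are serialized with full precision so that
#' `read_ranked_table(write_ranked_table(x))` reproduces every ranked
#' field bit-for-bit. The per-sample `genotypes` column, if present, is
#' serialized as `sample=call` pairs.
#'
#' @param ranked A `ranked_table` (or its `rows`).
#' @param path Output path.
#' @return `write_ranked_table()` returns `path` invisibly;
#'   `read_ranked_table()` returns the rows as a `data.table`.
#' @export
write_ranked_table <- function(ranked, path) {
  rows <- if (inherits(ranked, "ranked_table")) ranked$rows else
    as.data.table(ranked)
  write_tsv_full(flatten_genotypes(rows), path)
}

#' @rdname write_ranked_table
#' @export
read_ranked_table <- function(path) {
  if (!file.exists(path)) stop("ranked table not found: ", path)
  hdr <- names(fread(path, sep = "\t", header = TRUE, nrows = 0L))
  char_cols <- intersect(c("chrom", "ref", "alt", "variant_class", "region",
                           "exonic_func", "gene", "dbsnp_id", "genotypes",
                           .PRED_ALGOS), hdr)
  dbl_cols <- intersect(c("score", .AF_DBS, .CONS_ALGOS, "cadd",
                          grep("^w_", hdr, value = TRUE)), hdr)
  cls <- c(setNames(rep("character", length(char_cols)), char_cols),
           setNames(rep("double", length(dbl_cols)), dbl_cols))
  dt <- fread(path, sep = "\t", header = TRUE, na.strings = ".",
              colClasses = cls)
  if ("genotypes" %in% names(dt))
    dt[, genotypes := lapply(genotypes, unflatten_genotypes1)]
  dt[]
}

#' Write the INDEL side table or a gene summary
#'
#' Plain tab-delimited writers used by the pipeline for the unranked
#' INDEL table and the per-gene summary.
#'
#' @param x A `data.table`.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) write_tsv_full(flatten_genotypes(x), path)

# fwrite with doubles forced through %.17g so values survive the
# round-trip exactly.
write_tsv_full <- function(dt, path) {
  dt <- copy(as.data.table(dt))
  for (j in names(dt))
    if (is.double(dt[[j]]))
      set(dt, j = j, value = fifelse(is.na(dt[[j]]), NA_character_,
                                     sprintf("%.17g", dt[[j]])))
  ok <- tryCatch({
    fwrite(dt, path, sep = "\t", na = ".", quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write table to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

flatten_genotypes <- function(dt) {
  dt <- copy(as.data.table(dt))
  if ("genotypes" %in% names(dt))
    dt[, genotypes := vapply(genotypes, function(g)
      paste(sprintf("%s=%s", names(g), g), collapse = ","),
      character(1))]
  dt[]
}

unflatten_genotypes1 <- function(s) {
  if (is.na(s) || !nzchar(s)) return(setNames(character(0), character(0)))
  kv <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
  setNames(vapply(kv, `[`, character(1), 2L),
           vapply(kv, `[`, character(1), 1L))
}
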