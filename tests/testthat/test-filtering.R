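test_that("functional importance: nonsynonymous, splicing, stopgain/stoploss", {
  v <- variant_table(
    chrom = "1", pos = c(10L, 20L, 30L, 40L, 50L, 60L),
    ref = "G", alt = "A",
    region = c("exonic", "exonic", "intronic;splicing", "exonic", "exonic",
               "intronic"),
    exonic_func = c("nonsynonymous", "synonymous", NA, "stopgain",
                    "stoploss", NA))
  expect_identical(is_functional(v), c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE))
  # ANNOVAR spelling variants normalize
  v2 <- av(region = "exonic", exonic_func = "nonsynonymous SNV")
  expect_true(is_functional(v2))
})

test_that("dominant keeps >=1-functional genes, recessive >=2, X on chrX", {
  rk <- rank_variants(toy_table())
  # GENEA: 1 functional (nonsyn) + 1 synonymous; GENEC: 1 functional;
  # GENEX (chrX): stopgain + splicing = 2 functional; GENEB: none
  dom <- apply_model(rk, "dominant")
  expect_setequal(unique(dom$rows$gene), c("GENEA", "GENEC", "GENEX"))
  # all variants of a qualifying gene are retained, including synonymous
  expect_identical(sum(dom$rows$gene == "GENEA"), 2L)
  rec <- apply_model(rk, "recessive")
  expect_setequal(unique(rec$rows$gene), "GENEX")
  xr <- apply_model(rk, "x_recessive")
  expect_setequal(unique(xr$rows$gene), "GENEX")
  expect_true(all(xr$rows$chrom == "X"))
  # a chr7-style autosomal gene never passes x_recessive
  expect_false("GENEC" %in% xr$rows$gene)
  # functional-only additionally drops non-functional variants
  domf <- apply_model(rk, "dominant", functional_only = TRUE)
  expect_identical(sum(domf$rows$gene == "GENEA"), 1L)
  expect_error(apply_model(rk, "codominant"), "unknown inheritance model")
})

test_that("model filters accept the paper-style aliases and recompute ranks", {
  rk <- rank_variants(toy_table())
  expect_identical(apply_model(rk, "autosomal_dominant")$rows,
                   apply_model(rk, "dominant")$rows)
  rec <- apply_model(rk, "autosomal_recessive")
  expect_identical(rec$rows$rank,
                   data.table::frank(-rec$rows$score, ties.method = "dense"))
  expect_identical(sum(rec$chrom_counts), nrow(rec$rows))
})

test_that("filter spec: MAF with missing-as-zero, clinical, composition", {
  rk <- rank_variants(toy_table())
  # maf on exac: 0.001 and missing pass a 0.01 ceiling; 0.2/0.4/0.5 fail
  kept <- apply_filterspec(rk, filter_spec(maf_threshold = 0.01,
                                           maf_databases = "exac"))
  expect_true(all(data.table::fifelse(is.na(kept$rows$af_exac), 0,
                                      kept$rows$af_exac) <= 0.01))
  expect_true(any(is.na(kept$rows$af_exac)))  # novel variants survive
  # clinical_only with no flags set removes everything in the toy table
  clin <- apply_filterspec(rk, filter_spec(clinical_only = TRUE))
  expect_identical(nrow(clin$rows), 0L)
  # chained single-criterion specs equal the combined spec
  combined <- apply_filterspec(rk, filter_spec(maf_threshold = 0.01,
                                               functional_only = TRUE))
  chained <- apply_filterspec(
    apply_filterspec(rk, filter_spec(functional_only = TRUE)),
    filter_spec(maf_threshold = 0.01))
  expect_equal(combined$rows, chained$rows)
  expect_error(filter_spec(), "at least one criterion")
  expect_error(filter_spec(maf_threshold = 2), "\\[0,1\\]")
  expect_error(filter_spec(maf_threshold = 0.1, maf_databases = "hapmap"),
               "unknown population database")
})

test_that("min mutations per gene counts functional variants", {
  rk <- rank_variants(toy_table())
  one <- apply_filterspec(rk, filter_spec(min_mutations_per_gene = 2))
  expect_setequal(unique(one$rows$gene), "GENEX")
})

test_that("filters are subset operations, idempotent, and nested", {
  for (seed in 1:4) {
    v <- generate_background(250, seed = seed)
    rk <- rank_variants(v)
    key <- function(t) paste(t$rows$chrom, t$rows$pos, t$rows$alt)
    dom <- apply_model(rk, "dominant")
    rec <- apply_model(rk, "recessive")
    # subset
    expect_true(all(key(dom) %in% key(rk)))
    expect_true(all(key(rec) %in% key(rk)))
    # recessive genes nest within dominant genes
    expect_true(all(unique(unlist(strsplit(rec$rows$gene, ";"))) %in%
                    unique(unlist(strsplit(dom$rows$gene, ";")))))
    expect_true(all(key(rec) %in% key(dom)))
    # idempotence
    expect_equal(apply_model(dom, "dominant")$rows, dom$rows)
    spec <- filter_spec(maf_threshold = 0.3, functional_only = TRUE)
    once <- apply_filterspec(rk, spec)
    expect_equal(apply_filterspec(once, spec)$rows, once$rows)
  }
})

test_that("relative score order survives filtering before re-ranking", {
  rk <- rank_variants(generate_background(300, seed = 41))
  f <- apply_filterspec(rk, filter_spec(maf_threshold = 0.5))
  expect_true(all(diff(f$rows$score) <= 1e-12))
  expect_identical(f$rows$rank,
                   data.table::frank(-f$rows$score, ties.method = "dense"))
})
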