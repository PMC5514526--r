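test_that("region precedence encoding reproduces the tier weights", {
  expect_identical(encode_region("exonic"), 1)
  expect_identical(encode_region("splicing"), 1)
  expect_identical(encode_region("ncRNA"), 5 / 6)
  expect_identical(encode_region("ncRNA_exonic"), 5 / 6)
  expect_identical(encode_region("UTR5"), 4 / 6)
  expect_identical(encode_region("UTR3"), 4 / 6)
  expect_identical(encode_region("intronic"), 3 / 6)
  expect_identical(encode_region("upstream"), 2 / 6)
  expect_identical(encode_region("downstream"), 2 / 6)
  expect_identical(encode_region("intergenic"), 1 / 6)
})

test_that("multi-valued regions take the highest-precedence class, any order", {
  expect_identical(encode_region("intronic;splicing"), 1)
  expect_identical(encode_region("splicing;intronic"), 1)
  expect_identical(encode_region("UTR5;intergenic"), 4 / 6)
  expect_identical(encode_region("exonic;splicing"), 1)
})

test_that("unknown region tokens fall to the intergenic tier with a warning", {
  expect_warning(w <- encode_region("weird_class"), "intergenic")
  expect_identical(w, 1 / 6)
})

test_that("prediction encoding: PolyPhen2 three-level, others binary", {
  expect_identical(encode_prediction("polyphen2", c("D", "P", "B")),
                   c(1, 0.5, 0))
  for (alg in c("sift", "fathmm", "metasvm", "metalr", "lrt"))
    expect_identical(encode_prediction(alg, c("D", "T")), c(1, 0))
  expect_identical(encode_prediction("mutationtaster", c("A", "D", "N", "P")),
                   c(1, 1, 0, 0))
  expect_identical(encode_prediction("mutationassessor", c("H", "M", "L", "N")),
                   c(1, 1, 0, 0))
  # missing calls contribute nothing
  expect_identical(encode_prediction("mutationtaster", c(NA, ".", "")),
                   c(0, 0, 0))
  expect_error(encode_prediction("cadd", "D"), "unknown prediction")
})

test_that("conservation encoding is strict at the cutoff", {
  expect_identical(encode_conservation("gerp", c(3.1, 2.0, -1.4, NA)),
                   c(1, 0, 0, 0))
  # configurable cutoffs
  k <- weight_config(cutoffs = c(phylop = 1))$cutoffs
  expect_identical(encode_conservation("phylop", c(1.5, 0.9), k), c(1, 0))
  expect_error(encode_conservation("cadd", 1), "unknown conservation")
})

test_that("frequency encoding is 1 - AF with missing treated as novel", {
  expect_identical(encode_frequency(0), 1)
  expect_identical(encode_frequency(0.25), 0.75)
  expect_identical(encode_frequency(NA_real_), 1)
  expect_identical(encode_frequency(1), 0)
  expect_error(encode_frequency(1.2), "\\[0,1\\]")
})

test_that("binary flags: novelty, clinvar, gwas and collapsed ENCODE", {
  v <- av(n = 3L,
          dbsnp_id = c(NA, "rs1129738", "rs2"),
          clinvar = c(FALSE, TRUE, FALSE),
          encode_tfbs = c(FALSE, FALSE, TRUE))
  fl <- encode_binary_flags(v)
  expect_identical(fl$novelty, c(1, 0, 0))
  expect_identical(fl$clinvar, c(0, 1, 0))
  expect_identical(fl$gwas, c(0, 0, 0))
  expect_identical(fl$encode, c(0, 0, 1))
  pf <- encode_binary_flags(v, per_flag = TRUE)
  expect_identical(pf$encode_tfbs, c(0, 0, 1))
})

test_that("score is the user-weighted sum of encoded weights", {
  cfg0 <- weight_config()
  # only region annotated: every other source contributes 0 except
  # novelty and the three (missing = rare) frequency terms
  v <- av(region = "exonic", dbsnp_id = "rs1",
          af_1000g = 1, af_esp6500 = 1, af_exac = 1)
  b <- score_variants(v, cfg0)
  expect_equal(b$score, 1)
  # all user weights zero -> zero total
  z <- weight_config(weights = setNames(rep(0, length(cfg0$weights)),
                                        names(cfg0$weights)))
  expect_equal(score_variants(toy_table()[variant_class == "SNV"], z)$score,
               rep(0, 7))
  # fully annotated maximally deleterious novel variant hits the upper
  # bound: one unit per enabled source
  vmax <- av(region = "exonic", dbsnp_id = NULL,
             sift = "D", polyphen2 = "D", lrt = "D", mutationtaster = "A",
             mutationassessor = "H", fathmm = "D", metasvm = "D",
             metalr = "D", gerp = 10, phylop = 10, phastcons = 1, siphy = 30,
             encode_element = TRUE, clinvar = TRUE, gwas = TRUE)
  expect_equal(score_variants(vmax, cfg0)$score, sum(cfg0$weights))
})

test_that("INDELs are never scored", {
  v <- av(ref = "G", alt = "GA")
  expect_error(score_variants(v), "SNV")
})

test_that("score_variants matches the brute-force oracle on random variants", {
  n <- 1000L
  v <- generate_background(n, seed = 11)
  v <- v[v$variant_class == "SNV"]
  for (cfg in list(weight_config(),
                   weight_config(weights = c(region = 0.3, sift = 0.7,
                                             af_exac = 0.25),
                                 enabled = c(gwas = FALSE),
                                 cutoffs = c(gerp = 3)),
                   weight_config(freq_mode = "max",
                                 encode_mode = "per_flag"))) {
    got <- score_variants(v, cfg)$score
    want <- oracle_totals(v, cfg)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("monotonicity: rarer, more deleterious, or novel never lowers the score", {
  v <- generate_background(200, seed = 5)
  v <- v[v$variant_class == "SNV"]
  cfg <- weight_config()
  base <- score_variants(v, cfg)$score
  rarer <- data.table::copy(v)
  rarer$af_exac <- pmax(rarer$af_exac - 0.3, 0)
  expect_true(all(score_variants(rarer, cfg)$score >= base - 1e-12))
  deadlier <- data.table::copy(v)
  deadlier$sift <- "D"
  expect_true(all(score_variants(deadlier, cfg)$score >= base - 1e-12))
  denovo <- data.table::copy(v)
  denovo$dbsnp_id <- NA_character_
  expect_true(all(score_variants(denovo, cfg)$score >= base - 1e-12))
})

test_that("disabling a source equals setting its user weight to zero", {
  v <- generate_background(300, seed = 9)
  v <- v[v$variant_class == "SNV"]
  for (src in c("region", "sift", "af_1000g", "encode", "novelty")) {
    off <- weight_config(enabled = setNames(FALSE, src))
    zero <- weight_config(weights = setNames(0, src))
    expect_equal(score_variants(v, off)$score,
                 score_variants(v, zero)$score, tolerance = 1e-12)
  }
})

test_that("every encoded weight lies in [0,1] and totals are bounded", {
  v <- generate_background(500, seed = 13)
  v <- v[v$variant_class == "SNV"]
  cfg <- weight_config()
  b <- score_variants(v, cfg)
  wcols <- grep("^w_", names(b), value = TRUE)
  for (col in wcols) {
    expect_true(all(b[[col]] >= 0 & b[[col]] <= 1))
  }
  expect_true(all(b$score >= 0 & b$score <= sum(cfg$weights) + 1e-12))
})

test_that("weight config round-trips through YAML and validates inputs", {
  cfg <- weight_config(weights = c(gerp = 0.5), enabled = c(gwas = FALSE),
                       cutoffs = c(siphy = 10), freq_mode = "max")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_weight_config(cfg, path)
  expect_equal(read_weight_config(path), cfg)
  expect_error(weight_config(weights = c(region = 1.5)), "\\[0,1\\]")
  expect_error(weight_config(weights = c(bogus = 1)), "unknown weight")
})
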