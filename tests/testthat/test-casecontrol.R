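gt_table <- function(gts) {
  # gts: list of named call vectors, one per variant
  n <- length(gts)
  v <- variant_table(chrom = rep("1", n), pos = seq_len(n) * 10L,
                     ref = rep("G", n), alt = rep("A", n))
  v[, genotypes := gts]
  v
}

test_that("hand-counted genotype tallies", {
  v <- gt_table(list(c(S1 = "hom_alt", S2 = "het", S3 = "hom_ref")))
  cnt <- count_genotypes(v, cases = c("S1", "S2"), controls = "S3")
  expect_identical(cnt$n_hom_cases, 1L)
  expect_identical(cnt$n_het_cases, 1L)
  expect_identical(cnt$n_alleles_cases, 4L)
  expect_identical(cnt$n_hom_controls, 0L)
  expect_identical(cnt$n_het_controls, 0L)
  expect_identical(cnt$n_alleles_controls, 2L)
})

test_that("missing genotypes contribute nothing; hom-ref only adds alleles", {
  v <- gt_table(list(
    setNames(rep("missing", 4), paste0("S", 1:4)),
    setNames(rep("hom_ref", 4), paste0("S", 1:4))))
  cnt <- count_genotypes(v, cases = paste0("S", 1:2),
                         controls = paste0("S", 3:4))
  expect_identical(unlist(cnt[1]), setNames(rep(0L, 8), names(cnt)))
  expect_identical(cnt$n_alleles_cases[2], 4L)
  expect_identical(cnt$n_hom_cases[2], 0L)
  # 5 hom-ref cases -> 10 case alleles
  v5 <- gt_table(list(setNames(rep("hom_ref", 6), paste0("S", 1:6))))
  cnt5 <- count_genotypes(v5, cases = paste0("S", 1:5), controls = "S6")
  expect_identical(cnt5$n_alleles_cases, 10L)
})

test_that("haploid calls count one allele", {
  v <- gt_table(list(c(S1 = "hap_alt", S2 = "hap_ref", S3 = "het")))
  cnt <- count_genotypes(v, cases = c("S1", "S2"), controls = "S3")
  expect_identical(cnt$n_alleles_cases, 2L)
  expect_identical(cnt$n_alt_cases, 1L)
})

test_that("group hygiene: overlap and unknown sample ids are fatal", {
  v <- gt_table(list(c(S1 = "het", S2 = "hom_ref")))
  expect_error(count_genotypes(v, cases = "S1", controls = c("S1", "S2")),
               "overlap")
  expect_error(count_genotypes(v, cases = "S9", controls = "S2"), "S9")
})

test_that("invariants: alt-allele bound and even diploid allele totals", {
  set.seed(77)
  calls <- c("hom_ref", "het", "hom_alt", "missing")
  gts <- replicate(200, setNames(sample(calls, 8, replace = TRUE),
                                 paste0("S", 1:8)), simplify = FALSE)
  v <- gt_table(gts)
  cnt <- count_genotypes(v, cases = paste0("S", 1:4),
                         controls = paste0("S", 5:8))
  expect_true(all(2L * cnt$n_hom_cases + cnt$n_het_cases <=
                    cnt$n_alleles_cases))
  expect_true(all(2L * cnt$n_hom_controls + cnt$n_het_controls <=
                    cnt$n_alleles_controls))
  expect_true(all(cnt$n_alleles_cases %% 2L == 0L))
  # brute-force per-sample recount
  for (i in sample(200, 25)) {
    g <- gts[[i]][paste0("S", 1:4)]
    expect_identical(cnt$n_hom_cases[i], sum(g == "hom_alt"))
    expect_identical(cnt$n_het_cases[i], sum(g == "het"))
    expect_identical(cnt$n_alleles_cases[i], 2L * sum(g != "missing"))
  }
  # counts invariant to sample order within groups
  cnt2 <- count_genotypes(v, cases = paste0("S", 4:1),
                          controls = paste0("S", 8:5))
  expect_identical(cnt, cnt2)
})

test_that("predicate truth table and case/control label-swap symmetry", {
  gts <- list(
    c(S1 = "het", S2 = "hom_ref", S3 = "hom_ref", S4 = "hom_ref"),  # case only
    c(S1 = "het", S2 = "hom_ref", S3 = "het", S4 = "hom_ref"),      # both
    c(S1 = "hom_ref", S2 = "hom_ref", S3 = "hom_alt", S4 = "het"),  # ctrl only
    c(S1 = "hom_alt", S2 = "hom_ref", S3 = "hom_ref", S4 = "hom_ref"))
  v <- gt_table(gts)
  cases <- c("S1", "S2"); controls <- c("S3", "S4")
  co <- casecontrol_filter(v, cases, controls, "cases_only")
  expect_identical(co$pos, c(10L, 40L))
  expect_true(all(c("n_alt_cases", "n_hom_controls") %in% names(co)))
  # thresholds: k alt alleles in cases, at most m in controls
  th <- casecontrol_filter(v, cases, controls, "thresholds:2,0")
  expect_identical(th$pos, 40L)  # hom_alt case = 2 alt alleles
  th2 <- casecontrol_filter(v, cases, controls, list(k = 1, m = 2))
  expect_identical(nrow(th2), 3L)
  # swapping the labels maps cases_only onto controls_only exactly
  swapped <- casecontrol_filter(v, controls, cases, "controls_only")
  expect_identical(swapped$pos, co$pos)
  expect_error(casecontrol_filter(v, cases, controls, "weird"), "predicate")
})

test_that("label-swap symmetry holds on random genotype tables", {
  set.seed(123)
  calls <- c("hom_ref", "het", "hom_alt", "missing")
  gts <- replicate(200, setNames(sample(calls, 6, replace = TRUE,
                                        prob = c(0.6, 0.2, 0.1, 0.1)),
                                 paste0("S", 1:6)), simplify = FALSE)
  v <- gt_table(gts)
  a <- paste0("S", 1:3); b <- paste0("S", 4:6)
  expect_identical(casecontrol_filter(v, a, b, "cases_only")$pos,
                   casecontrol_filter(v, b, a, "controls_only")$pos)
})

test_that("case-control survivors feed straight into ranking", {
  bg <- generate_background(300, seed = 19, n_samples = 6)
  kept <- casecontrol_filter(bg, paste0("S", 1:3), paste0("S", 4:6),
                             list(k = 1, m = 6))
  rk <- rank_variants(kept)
  expect_identical(nrow(rk$rows), sum(kept$variant_class == "SNV"))
  expect_true("n_alt_cases" %in% names(rk$rows))
})
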