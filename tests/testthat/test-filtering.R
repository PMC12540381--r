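expr_fixture <- function() {
  tibble::tibble(gene_id = c("GENE_A", "GENE_B", "GENE_C"),
                 gene_symbol = c("GENE_A", "GENE_B", "GENE_C"),
                 tpm = c(2.5, 0.5, 12), rpkm = NA_real_)
}

one_variant <- function(...) {
  base <- tibble::tibble(
    chrom = "chr1", pos = 1000L, ref_allele = "A", alt_allele = "G",
    variant_class = "SNV", tumor_dp = 60L, tumor_ad_alt = 6L,
    normal_dp = 35L, normal_ad_ref = 10L, base_quality = 30,
    sor = 3.0, vaf = 0.10
  )
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

test_that("compute_vaf matches direct division on random valid pairs", {
  expect_equal(compute_vaf(5, 50), 0.10)
  expect_equal(compute_vaf(0, 100), 0)
  withr::with_seed(42, {
    dp <- sample(1:500, 1000, TRUE)
    ad <- vapply(dp, function(d) sample(0:d, 1), integer(1))
  })
  expect_equal(compute_vaf(ad, dp), ad / dp)
  expect_error(compute_vaf(1, 0), "dp = 0")
  expect_error(compute_vaf(10, 5), "ad_alt")
})

test_that("single-rule violations produce the matching reason code", {
  ex <- expr_fixture()
  v_ok <- one_variant()
  verdict <- apply_filters(v_ok, ex, "GENE_A")
  expect_true(verdict$passed)
  expect_equal(verdict$failed_rules[[1]], character(0))

  low_vaf <- apply_filters(one_variant(vaf = 0.04), ex, "GENE_A")
  expect_false(low_vaf$passed)
  expect_equal(low_vaf$failed_rules[[1]], "VAF")

  low_tpm <- apply_filters(v_ok, ex, "GENE_B")
  expect_equal(low_tpm$failed_rules[[1]], "TPM")

  no_expr <- apply_filters(v_ok, ex, "GENE_ZZ")
  expect_equal(no_expr$failed_rules[[1]], "NO_EXPRESSION")
})

test_that("boundary values pass inclusively on every threshold", {
  boundary <- one_variant(tumor_dp = 50L, tumor_ad_alt = 5L, normal_dp = 30L,
                          normal_ad_ref = 3L, base_quality = 20, sor = 5.0,
                          vaf = 0.05)
  ex <- tibble::tibble(gene_id = "G", gene_symbol = "G", tpm = 1.0)
  verdict <- apply_filters(boundary, ex, "G")
  expect_true(verdict$passed)
  # one unit below each minimum (or above the maximum) must fail
  expect_false(apply_filters(one_variant(tumor_dp = 49L), ex, "G")$passed)
  expect_false(apply_filters(one_variant(sor = 5.01), ex, "G")$passed)
  expect_false(apply_filters(one_variant(vaf = 0.0499), ex, "G")$passed)
})

test_that("all rules are evaluated without short-circuiting", {
  v <- one_variant(tumor_dp = 10L, tumor_ad_alt = 2L, vaf = 0.2,
                   base_quality = 10, sor = 8)
  verdict <- apply_filters(v, expr_fixture(), "GENE_B")
  expect_setequal(verdict$failed_rules[[1]],
                  c("TUMOR_DP", "TUMOR_AD", "BASEQ", "SOR", "TPM"))
})

test_that("tumor-only mode skips normal-sample rules with provenance", {
  v <- one_variant(normal_dp = NA_integer_, normal_ad_ref = NA_integer_)
  verdict <- apply_filters(v, expr_fixture(), "GENE_A")
  expect_true(verdict$passed)
  expect_true(attr(verdict, "tumor_only"))
})

test_that("the alternative normal-AD interpretation rejects germline alt support", {
  th <- filter_thresholds(normal_ad_interpretation = "alt_at_most")
  v <- one_variant()
  v$normal_ad_alt <- 10L
  verdict <- apply_filters(v, expr_fixture(), "GENE_A", th)
  expect_equal(verdict$failed_rules[[1]], "NORMAL_AD")
  v$normal_ad_alt <- 0L
  expect_true(apply_filters(v, expr_fixture(), "GENE_A", th)$passed)
})

test_that("apply_filters agrees with a straight-line oracle on random cohorts", {
  v <- random_variants(300, seed = 99)
  genes <- withr::with_seed(100, sample(paste0("G", 1:40), 300, TRUE))
  tpm <- withr::with_seed(101,
    setNames(round(rlnorm(35, 0, 1.5), 3), paste0("G", 1:35)))  # G36-40 unexpressed
  ex <- tibble::tibble(gene_id = names(tpm), gene_symbol = names(tpm),
                       tpm = unname(tpm))
  verdicts <- apply_filters(v, ex, genes)
  oracle <- filter_oracle(v, as.list(tpm), genes)
  expect_equal(verdicts$failed_rules, oracle, ignore_attr = TRUE)
  expect_equal(verdicts$passed, lengths(oracle) == 0)
})

test_that("relaxing any single threshold never decreases the pass count", {
  v <- random_variants(200, seed = 7)
  genes <- withr::with_seed(8, sample(paste0("G", 1:20), 200, TRUE))
  ex <- tibble::tibble(gene_id = paste0("G", 1:20),
                       gene_symbol = paste0("G", 1:20),
                       tpm = withr::with_seed(9, round(rlnorm(20, 0, 1.5), 3)))
  base <- filter_thresholds()
  base_pass <- sum(apply_filters(v, ex, genes, base)$passed)
  relaxed <- list(
    filter_thresholds(tumor_dp_min = 20),
    filter_thresholds(normal_dp_min = 10),
    filter_thresholds(tumor_ad_min = 1),
    filter_thresholds(normal_ad_min = 0),
    filter_thresholds(base_quality_min = 5),
    filter_thresholds(sor_max = 20),
    filter_thresholds(vaf_min = 0),
    filter_thresholds(tpm_min = 0)
  )
  for (th in relaxed) {
    expect_gte(sum(apply_filters(v, ex, genes, th)$passed), base_pass)
  }
})

test_that("verdicts are deterministic and order-preserving", {
  v <- random_variants(50, seed = 3)
  genes <- rep("G1", 50)
  ex <- tibble::tibble(gene_id = "G1", gene_symbol = "G1", tpm = 5)
  a <- apply_filters(v, ex, genes)
  b <- apply_filters(v, ex, genes)
  expect_identical(a$variant_key, b$variant_key)
  expect_identical(a$failed_rules, b$failed_rules)
})

test_that("filtering summaries count per-rule failures and passes consistently", {
  empty <- apply_filters(one_variant()[0, ], expr_fixture(), character(0))
  s0 <- summarize_filtering(empty)
  expect_equal(s0$n_total, 0)
  expect_equal(sum(tidy(s0)$n_failed), 0)

  v <- dplyr::bind_rows(
    one_variant(), one_variant(vaf = 0.01), one_variant(vaf = 0.02),
    one_variant(vaf = 0.03), dplyr::bind_rows(replicate(6, one_variant(),
                                                        simplify = FALSE))
  )
  verd <- apply_filters(v, expr_fixture(), rep("GENE_A", 10))
  s <- summarize_filtering(verd)
  expect_equal(s$n_pass, 7)
  expect_equal(tidy(s)$n_failed[tidy(s)$rule == "VAF"], 3)
  g <- glance(s)
  expect_equal(g$n_total, 10)
  expect_equal(g$n_pass + g$n_fail, g$n_total)
})
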