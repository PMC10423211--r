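test_that("the dual VAF window classifies CH, germline and sub-clonal calls", {
  # blood VAF 0.14, tumor VAF 0.18 -> CH in TII
  maf <- make_maf(1, t_ref = 82, t_alt = 18, n_ref = 86, n_alt = 14)
  out <- classify_ch(maf)
  expect_true(out$is_ch_in_tii)
  expect_equal(out$reason, "pass")
  expect_equal(out$tumor_vaf, 0.18)
  expect_equal(out$blood_vaf, 0.14)

  # heterozygous germline: VAF 0.5 in both samples
  maf <- make_maf(1, t_ref = 50, t_alt = 50, n_ref = 50, n_alt = 50)
  out <- classify_ch(maf)
  expect_false(out$is_ch_in_tii)
  expect_match(out$reason, "germline_range")

  # strict boundaries: exactly 2% fails, exactly 25% fails
  maf <- make_maf(1, t_ref = 90, t_alt = 10, n_ref = 98, n_alt = 2)
  out <- classify_ch(maf)
  expect_false(out$is_ch_in_tii)
  expect_equal(out$reason, "below_lower_blood")
  maf <- make_maf(1, t_ref = 75, t_alt = 25, n_ref = 90, n_alt = 10)
  out <- classify_ch(maf)
  expect_false(out$is_ch_in_tii)
  expect_equal(out$reason, "germline_range_tumor")
})

test_that("classification refuses zero-depth calls", {
  maf <- make_maf(1)
  maf$t_ref_count <- 0
  maf$t_alt_count <- 0
  expect_error(classify_ch(maf), "zero total depth")
})

test_that("widening the VAF window never shrinks the passing set", {
  co <- simulate_cohort(small_config(seed = 6))
  base <- classify_ch(co$maf, ch_call_config(0.02, 0.25))
  for (delta in c(0.005, 0.01, 0.015)) {
    wide <- classify_ch(co$maf, ch_call_config(0.02 - delta, 0.25 + delta))
    expect_true(all(wide$is_ch_in_tii[base$is_ch_in_tii]))
  }
})

test_that("classification on true VAFs is exact and improves with depth", {
  # true VAFs: planted inside the window, germline at 0.5, noise below 2% --
  # on the true values the window makes no errors
  co <- simulate_cohort(small_config(seed = 8))
  tv <- co$truth$true_vaf
  inside <- tv$blood_vaf > 0.02 & tv$blood_vaf < 0.25 &
    tv$tumor_vaf > 0.02 & tv$tumor_vaf < 0.25
  expect_true(all(inside[tv$label == "planted_ch"]))
  expect_true(all(!inside[tv$label %in% c("germline", "noise")]))

  # with sampled read counts, planted-carrier misclassification shrinks
  # as depth grows
  err_rate <- function(depth) {
    co <- simulate_cohort(small_config(seed = 13, depth_mean = depth,
                                       blood_vaf_range = c(0.04, 0.08),
                                       tumor_vaf_range = c(0.04, 0.08)))
    planted <- names(co$truth$labels)[co$truth$labels == "planted_ch"]
    calls <- classify_ch(co$maf)
    sub <- calls[calls$variant_id %in% planted, ]
    mean(!sub$is_ch_in_tii)
  }
  expect_lte(err_rate(500), err_rate(50))
})

test_that("Wilson intervals match the closed form and behave at boundaries", {
  # frozen against the closed-form Wilson formula at z = qnorm(0.975)
  ci <- binomial_ci(14, 100, 0.95)
  z <- qnorm(0.975)
  denom <- 1 + z^2 / 100
  center <- (0.14 + z^2 / 200) / denom
  half <- (z / denom) * sqrt(0.14 * 0.86 / 100 + z^2 / (4 * 100^2))
  expect_equal(ci, c(center - half, center + half), tolerance = 1e-9)

  expect_equal(binomial_ci(0, 100)[1], 0)
  ci <- binomial_ci(50, 100)
  expect_equal(ci[1] + ci[2], 1, tolerance = 1e-12)  # symmetric about 0.5

  # interval always contains the point estimate
  for (alt in c(0, 1, 7, 50, 99, 100)) {
    ci <- binomial_ci(alt, 100)
    expect_true(ci[1] <= alt / 100 && alt / 100 <= ci[2])
  }
  expect_error(binomial_ci(5, 0), "depth")
  expect_error(binomial_ci(5, 4), "alt_count")
})

test_that("alternative interval methods are available and sane", {
  wald <- binomial_ci(14, 100, method = "wald")
  expect_equal(mean(wald), 0.14, tolerance = 1e-12)
  cp <- binomial_ci(14, 100, method = "clopper-pearson")
  # Clopper-Pearson matches the exact binomial test interval
  bt <- binom.test(14, 100)$conf.int
  expect_equal(cp, as.numeric(bt), tolerance = 1e-9)
})

test_that("variant summaries use cohort fraction and carrier-only moments", {
  # 75 passing samples of a 1,064-sample cohort -> sample fraction 0.0705
  calls <- data.frame(
    sample_id = sprintf("S%04d", 1:80),
    variant_id = "7:1000:A:G", gene = "C1GALT1C1",
    protein_change = "p.V276G", consequence = "missense",
    tumor_vaf = 0.18, blood_vaf = 0.14,
    is_ch_in_tii = c(rep(TRUE, 75), rep(FALSE, 5)),
    stringsAsFactors = FALSE
  )
  s <- summarize_variants(calls, 1064)
  expect_equal(s$n_pass, 75)
  expect_equal(round(s$sample_fraction, 4), 0.0705)

  # two passing samples with tumor VAFs 0.10 and 0.20: mean 0.15, sample SD
  calls <- data.frame(
    sample_id = c("A", "B"), variant_id = "v", gene = "G",
    protein_change = "p", consequence = "missense",
    tumor_vaf = c(0.10, 0.20), blood_vaf = c(0.1, 0.1),
    is_ch_in_tii = TRUE, stringsAsFactors = FALSE
  )
  s <- summarize_variants(calls, 10)
  expect_equal(s$tumor_vaf_mean, 0.15)
  expect_equal(s$tumor_vaf_sd, 0.0707, tolerance = 1e-3)
  expect_equal(s$tumor_vaf_sd, sd(c(0.1, 0.2)))

  # zero passing samples: fraction 0, moments absent
  calls$is_ch_in_tii <- FALSE
  s <- summarize_variants(calls, 10)
  expect_equal(s$sample_fraction, 0)
  expect_true(is.na(s$tumor_vaf_mean))
  expect_true(is.na(s$tumor_vaf_sd))
})
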