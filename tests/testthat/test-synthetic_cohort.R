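test_that("invalid configurations are rejected with the offending field named", {
  expect_error(simulation_config(n_samples = -1), "n_samples")
  expect_error(simulation_config(blood_vaf_range = c(0.2, 0.1)),
               "blood_vaf_range")
  expect_error(simulation_config(blood_vaf_range = c(0.01, 0.2)),
               "blood_vaf_range")  # must sit inside the (2%, 25%) window
  expect_error(simulation_config(tumor_vaf_range = c(0.05, 0.30)),
               "tumor_vaf_range")
  expect_error(simulation_config(n_genes = 2, n_planted_ch = 5),
               "n_genes")
  expect_error(simulation_config(qc_fail_fraction = 1.5), "qc_fail_fraction")
})

test_that("a fixed seed gives byte-identical fixture bundles", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture_bundle(simulate_cohort(small_config(seed = 1)), d1)
  write_fixture_bundle(simulate_cohort(small_config(seed = 1)), d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("checksum of", f))
  }
})

test_that("planted CH variants land inside the VAF window at depth 200", {
  co <- simulate_cohort(small_config(seed = 1, n_planted_ch = 5,
                                     depth_mean = 200))
  planted <- names(co$truth$labels)[co$truth$labels == "planted_ch"]
  maf <- co$maf
  for (v in planted) {
    sub <- maf[maf$variant_id == v, ]
    bv <- compute_vaf(sub$n_ref_count, sub$n_alt_count)
    tv <- compute_vaf(sub$t_ref_count, sub$t_alt_count)
    inside <- bv > 0.02 & bv < 0.25 & tv > 0.02 & tv < 0.25
    expect_gte(mean(inside), 0.95)
  }
})

test_that("germline variants concentrate at VAF 0.5", {
  co <- simulate_cohort(small_config(seed = 3, n_germline = 3,
                                     depth_mean = 200))
  germ <- names(co$truth$labels)[co$truth$labels == "germline"]
  maf <- co$maf
  for (v in germ) {
    sub <- maf[maf$variant_id == v, ]
    bv <- compute_vaf(sub$n_ref_count, sub$n_alt_count)
    # overwhelming majority in the germline range at depth ~200
    expect_gte(mean(bv >= 0.25), 0.95)
    # mean within 3 binomial standard errors of 0.5
    depth <- sub$n_ref_count + sub$n_alt_count
    se <- sqrt(mean(0.5 * 0.5 / depth) / nrow(sub))
    expect_lt(abs(mean(bv) - 0.5), 3 * se)
  }
})

test_that("depths stay inside the observed 16-725 range", {
  co <- simulate_cohort(small_config(seed = 5, depth_mean = 20))
  depths <- c(co$maf$t_ref_count + co$maf$t_alt_count,
              co$maf$n_ref_count + co$maf$n_alt_count)
  expect_true(all(depths >= 16 & depths <= 725))
})

test_that("MAF row count equals the sum of per-variant carrier counts", {
  co <- simulate_cohort(small_config(seed = 2))
  expected <- sum(lengths(co$truth$carriers))
  expect_equal(nrow(co$maf), expected)
  d <- withr::local_tempdir()
  manifest <- write_fixture_bundle(co, d)
  expect_equal(manifest$n[grepl("variants.maf", manifest$file)], expected)
})

test_that("an all-zero configuration writes valid headers-only files", {
  cfg <- simulation_config(n_samples = 0, n_genes = 0, n_planted_ch = 0,
                           n_germline = 0, n_noise = 0,
                           n_passenger_somatic = 0, n_cells = 0)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$maf), 0)
  d <- withr::local_tempdir()
  write_fixture_bundle(co, d)
  back <- read_fixture_bundle(d)
  expect_equal(nrow(back$maf), 0)
  expect_equal(nrow(back$annotations), 0)
  expect_equal(length(back$cells$barcodes), 0)
})

test_that("fixture bundles round-trip through the readers", {
  co <- simulate_cohort(small_config(seed = 9))
  d <- withr::local_tempdir()
  write_fixture_bundle(co, d)
  back <- read_fixture_bundle(d)
  expect_equal(back$maf[MAF_REQUIRED_COLUMNS], co$maf[MAF_REQUIRED_COLUMNS])
  expect_equal(back$annotations, co$annotations)
  expect_equal(back$gene_meta, co$gene_meta)
  expect_equal(back$pathway_map, co$pathway_map)
  expect_equal(back$bulk, co$bulk, tolerance = 1e-12)
  expect_equal(as.matrix(back$cells$counts), as.matrix(co$cells$counts),
               ignore_attr = TRUE)
  expect_equal(back$cells$cell_type, co$cells$cell_type)
})

test_that("passenger variants carry the deviation their name promises", {
  co <- simulate_cohort(small_config(seed = 4))
  lab <- co$truth$labels
  ann <- co$annotations
  # gnomad passenger is common in the population
  v <- names(lab)[lab == "passenger:gnomad"]
  expect_gte(ann$population_freq[ann$variant_id == v], 1e-4)
  # deleterious passenger is tolerated/benign by both predictors
  v <- names(lab)[lab == "passenger:deleterious"]
  expect_equal(ann$sift[ann$variant_id == v], "tolerated")
  expect_equal(ann$polyphen[ann$variant_id == v], "benign")
  # hypermutable passenger sits in a flagged gene
  v <- names(lab)[lab == "passenger:hypermutable"]
  g <- co$truth$true_vaf$gene[co$truth$true_vaf$variant_id == v]
  expect_true(co$gene_meta$hypermutable[co$gene_meta$gene == g])
  # expression passenger's gene has zero immune-cell counts
  v <- names(lab)[lab == "passenger:expression"]
  g <- co$truth$true_vaf$gene[co$truth$true_vaf$variant_id == v]
  s <- summarize_gene_expression(co$cells, g)
  expect_equal(s$n_immune_cells_expressing, 0)
  # sample_fraction passenger is carried by ~2% of samples
  v <- names(lab)[lab == "passenger:sample_fraction"]
  cf <- length(co$truth$carriers[[v]]) / length(co$samples)
  expect_lt(cf, 0.05)
})
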