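test_that("report_percent reproduces printed funnel arithmetic", {
  expect_equal(report_percent(47255, 558470, 1), 8.5)
  expect_equal(report_percent(567, 1710, 1), 33.2)
  expect_equal(report_percent(0, 10, 1), 0.0)
  expect_equal(report_percent(558470, 4579609, 1), 12.2)
  expect_equal(report_percent(558470, 4579609, 0), 12)
  expect_error(report_percent(5, 0), "denominator")
})

test_that("candidate rows format as VAF +/- SD, fraction, frequency, expression", {
  s <- list(tumor_vaf_mean = 0.18, tumor_vaf_sd = 0.03,
            blood_vaf_mean = 0.14, blood_vaf_sd = 0.05,
            sample_fraction = 75 / 1064)
  ann <- list(population_freq = 2 / 105263)
  es <- structure(list(gene = "C1GALT1C1",
                       n_cells_expressing = 12075,
                       n_immune_cells_expressing = 2810,
                       immune_fraction = 2810 / 12075),
                  class = "gene_expression_summary")
  expect_equal(format_candidate_row(s, ann, es),
               "0.18 ± 0.03 | 0.14 ± 0.05 | 0.0705 | 2E-5 | 23% (2,810/12,075)")

  # single-carrier candidate: no SD term
  s1 <- list(tumor_vaf_mean = 0.1, tumor_vaf_sd = NA_real_,
             blood_vaf_mean = 0.1, blood_vaf_sd = NA_real_,
             sample_fraction = 1 / 1064)
  expect_equal(format_candidate_row(s1), "0.10 | 0.10 | 0.0009")
  # zero population frequency prints as 0
  expect_equal(format_candidate_row(s, list(population_freq = 0)),
               "0.18 ± 0.03 | 0.14 ± 0.05 | 0.0705 | 0")
})

test_that("the funnel is monotone and deterministic", {
  co <- simulate_cohort(small_config(seed = 12))
  cfg <- ch_pipeline_config(n_cohort = length(co$samples))
  r1 <- suppressMessages(run_ch_pipeline(co$maf, co$annotations, co$gene_meta,
                                         co$cells, co$bulk, co$pathway_map,
                                         cfg))
  expect_true(all(r1$funnel$output <= r1$funnel$input))
  # variant-level stages chain: each stage's input is the previous output
  v <- r1$funnel[-(1:2), ]
  expect_equal(v$input[-1], v$output[-nrow(v)])

  r2 <- suppressMessages(run_ch_pipeline(co$maf, co$annotations, co$gene_meta,
                                         co$cells, co$bulk, co$pathway_map,
                                         cfg))
  expect_equal(r1$funnel, r2$funnel)
  expect_equal(r1$candidates, r2$candidates)
  expect_equal(r1$pathway_counts, r2$pathway_counts)
})

test_that("an all-noise cohort yields a valid zero-candidate funnel", {
  cfg <- simulation_config(n_samples = 80, n_genes = 20, n_planted_ch = 0,
                           n_germline = 0, n_noise = 15,
                           n_passenger_somatic = 0, n_cells = 200, seed = 5)
  co <- simulate_cohort(cfg)
  r <- suppressMessages(run_ch_pipeline(co$maf, co$annotations, co$gene_meta,
                                        co$cells, co$bulk, co$pathway_map,
                                        ch_pipeline_config(n_cohort = 80)))
  expect_equal(nrow(r$candidates), 0)
  expect_true(all(r$funnel$output <= r$funnel$input))
  expect_equal(length(r$de), 0)
})

test_that("pipeline accepts file paths and matches the in-memory run", {
  co <- simulate_cohort(small_config(seed = 19))
  d <- withr::local_tempdir()
  write_fixture_bundle(co, d)
  cfg <- ch_pipeline_config(n_cohort = length(co$samples))
  r_mem <- suppressMessages(run_ch_pipeline(co$maf, co$annotations,
                                            co$gene_meta, co$cells, co$bulk,
                                            co$pathway_map, cfg))
  r_file <- suppressMessages(run_ch_pipeline(
    file.path(d, "variants.maf.tsv"),
    file.path(d, "annotations.tsv"),
    file.path(d, "gene_meta.tsv"),
    file.path(d, "scrna"),
    file.path(d, "bulk_expression.tsv"),
    file.path(d, "pathway_map.tsv"),
    cfg))
  expect_equal(r_file$funnel, r_mem$funnel)
  expect_equal(r_file$candidates$variant_id, r_mem$candidates$variant_id)
  expect_equal(r_file$pathway_counts, r_mem$pathway_counts)
})

test_that("pathway counts cover SDE genes of every tested candidate", {
  co <- simulate_cohort(small_config(seed = 12))
  r <- suppressMessages(run_ch_pipeline(co$maf, co$annotations, co$gene_meta,
                                        co$cells, co$bulk, co$pathway_map,
                                        ch_pipeline_config(
                                          n_cohort = length(co$samples))))
  expect_gt(length(r$de), 0)
  for (v in names(r$de)) {
    sde <- r$de[[v]]$gene[r$de[[v]]$sde]
    # each SDE gene contributes once per mapped pathway
    expected <- sum(co$pathway_map$gene %in% sde)
    expect_equal(sum(r$pathway_counts[, v]), expected +
                   sum(!sde %in% co$pathway_map$gene))
  }
})

test_that("print and summary render without error", {
  co <- simulate_cohort(small_config(seed = 12))
  r <- suppressMessages(run_ch_pipeline(co$maf, co$annotations, co$gene_meta,
                                        co$cells, co$bulk, co$pathway_map,
                                        ch_pipeline_config(
                                          n_cohort = length(co$samples))))
  expect_output(print(r), "funnel")
  expect_output(summary(r), "Candidate table")
  ct <- candidate_table(r, co$annotations)
  expect_true(all(c("sample_fraction", "population_freq",
                    "n_immune_expressing") %in% names(ct)))
})
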