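# End-to-end orchestration of the four-stage funnel:
#   (1) call-quality gate and protein-altering selection,
#   (2) CH-in-TII classification by the dual VAF window,
#   (3) candidate filters (cohort frequency, population rarity,
#       hypermutable-gene exclusion, deleteriousness consensus, immune-cell
#       expression),
#   (4) differential expression of carriers vs non-carriers with top-level
#       pathway tabulation.
# Per-sample rows collapse to one funnel unit per distinct variant
# (chrom:pos:ref:alt) from the distinct-variant tally onward.

#' Pipeline configuration
#'
#' Gathers every threshold of the funnel with its default: the call-quality
#' gate (LOD >= 4.0, base quality >= 10), the dual VAF window (2% < VAF < 25%
#' in both samples), the cohort-frequency threshold (> 5% of samples), the
#' population-rarity threshold (gnomAD-style frequency < 1e-4), and the DE
#' FDR threshold (< 0.05).
#'
#' @param min_lod,min_base_quality call-quality gate thresholds.
#' @param vaf_lower,vaf_upper strict VAF window bounds.
#' @param ci_level,ci_method VAF confidence-interval settings.
#' @param min_sample_fraction strict cohort-frequency threshold.
#' @param max_population_freq strict population-rarity threshold.
#' @param fdr strict FDR threshold for SDE genes.
#' @param n_cohort cohort size for sample fractions; `NULL` means the number
#'   of distinct samples seen in the variant table.
#' @return a list of class `"ch_pipeline_config"`.
#' @export
ch_pipeline_config <- function(min_lod = 4.0, min_base_quality = 10,
                               vaf_lower = 0.02, vaf_upper = 0.25,
                               ci_level = 0.95, ci_method = "wilson",
                               min_sample_fraction = 0.05,
                               max_population_freq = 1e-4,
                               fdr = 0.05, n_cohort = NULL) {
  structure(list(
    min_lod = min_lod, min_base_quality = min_base_quality,
    ch = ch_call_config(vaf_lower, vaf_upper, ci_level, ci_method),
    filters = filter_config(min_sample_fraction, max_population_freq),
    fdr = fdr, n_cohort = n_cohort
  ), class = "ch_pipeline_config")
}

#' Percentage of a count over a denominator
#'
#' `100 * numerator / denominator`, rounded half-to-even to the requested
#' number of decimals (R's default rounding).
#'
#' @param numerator,denominator counts; `denominator` must be positive.
#' @param decimals decimal places (default 1).
#' @return numeric percentage.
#' @export
#' @examples
#' report_percent(47255, 558470, 1)  # 8.5
report_percent <- function(numerator, denominator, decimals = 1) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  round(100 * numerator / denominator, decimals)
}

# one funnel stage record
.stage <- function(name, input, output, total) {
  data.frame(
    stage = name, input = input, output = output,
    percent_of_previous = if (input > 0) report_percent(output, input, 1)
                          else NA_real_,
    percent_of_total = if (!is.na(total) && total > 0) {
      report_percent(output, total, 1)
    } else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Run the four-stage CH-in-TII funnel
#'
#' Executes the full pipeline over in-memory tables or file paths: quality
#' gate, distinct-variant tally, protein-altering selection, CH-in-TII
#' classification, cohort-frequency / rarity / hypermutable / deleteriousness
#' filters, immune-expression check, then per-candidate differential
#' expression and pathway tabulation. All stage counts are recorded in the
#' funnel report; the run is deterministic given its inputs.
#'
#' @param maf a variant table (from [read_maf()] or [simulate_cohort()]), or
#'   a path to a MAF-dialect file.
#' @param annotations annotation table or TSV path (`variant_id`,
#'   `population_freq`, `sift`, `polyphen`).
#' @param gene_meta gene metadata table or TSV path (`gene`, `hypermutable`).
#' @param cells a [cell_matrix()], a directory containing the MTX bundle, or
#'   `NULL` to skip the expression stage.
#' @param bulk gene-by-sample expression matrix, TSV path, or `NULL` to skip
#'   the DE stage.
#' @param pathway_map pathway map table or TSV path, or `NULL`.
#' @param config a [ch_pipeline_config()].
#' @return an object of class `"ch_pipeline_result"`: `funnel` (stage count
#'   table), `candidates` (per-variant candidate summaries), `ch_calls`
#'   (per-sample CH classifications), `de` (named list of per-candidate DE
#'   tables), `pathway_counts` (pathways x candidates matrix), `config`,
#'   `n_cohort`.
#' @export
run_ch_pipeline <- function(maf, annotations, gene_meta = NULL, cells = NULL,
                            bulk = NULL, pathway_map = NULL,
                            config = ch_pipeline_config()) {
  stopifnot(inherits(config, "ch_pipeline_config"))
  if (is.character(maf)) maf <- read_maf(maf)
  if (is.character(annotations)) {
    annotations <- utils::read.delim(annotations, stringsAsFactors = FALSE)
  }
  if (is.character(gene_meta)) {
    gene_meta <- utils::read.delim(gene_meta, stringsAsFactors = FALSE)
  }
  if (is.character(cells)) {
    cells <- read_cell_matrix(file.path(cells, "matrix.mtx"),
                              file.path(cells, "barcodes.tsv"),
                              file.path(cells, "genes.tsv"),
                              file.path(cells, "celltypes.tsv"))
  }
  if (is.character(bulk)) bulk <- read_bulk_expression(bulk)
  if (is.character(pathway_map)) pathway_map <- read_pathway_map(pathway_map)

  n_cohort <- if (!is.null(config$n_cohort)) config$n_cohort else {
    length(unique(maf$Tumor_Sample_Barcode))
  }

  stages <- list()
  # stage: quality gate (row level)
  gated <- quality_gate(maf, config$min_lod, config$min_base_quality)
  stages[[1]] <- .stage("quality_gate (calls)", nrow(maf), nrow(gated), NA)

  # distinct-variant tally
  n_distinct <- length(unique(gated$variant_id))
  total <- n_distinct
  stages[[2]] <- .stage("distinct_variants", nrow(gated), n_distinct, total)

  # protein-altering selection (variant level)
  pa <- select_protein_altering(gated)
  n_pa <- length(unique(pa$variant_id))
  stages[[3]] <- .stage("protein_altering", n_distinct, n_pa, total)

  # CH-in-TII classification
  calls <- classify_ch(pa, config$ch)
  summaries <- summarize_variants(calls, max(n_cohort, 1))
  ch_set <- summaries[summaries$n_pass > 0, , drop = FALSE]
  stages[[4]] <- .stage("ch_in_tii", n_pa, nrow(ch_set), total)

  # candidate filters, in the reported order
  s1 <- filter_sample_fraction(ch_set, config$filters)
  stages[[5]] <- .stage("sample_fraction", nrow(ch_set), nrow(s1), total)
  s2 <- filter_rare(s1, annotations, config$filters)
  stages[[6]] <- .stage("population_rarity", nrow(s1), nrow(s2), total)
  s3 <- if (!is.null(gene_meta)) filter_hypermutable(s2, gene_meta) else s2
  stages[[7]] <- .stage("hypermutable_exclusion", nrow(s2), nrow(s3), total)
  s4 <- filter_deleterious(s3, annotations)
  stages[[8]] <- .stage("deleteriousness", nrow(s3), nrow(s4), total)

  expr_summaries <- NULL
  if (!is.null(cells) && nrow(s4) > 0) {
    expr_summaries <- lapply(unique(s4$gene), function(g) {
      summarize_gene_expression(cells, g)
    })
    names(expr_summaries) <- unique(s4$gene)
    s5 <- filter_expressed_in_immune(expr_summaries, s4)
  } else {
    s5 <- s4
  }
  stages[[9]] <- .stage("immune_expression", nrow(s4), nrow(s5), total)

  candidates <- s5
  # carrier sets for the surviving candidates
  carrier_sets <- lapply(candidates$variant_id, function(v) {
    unique(calls$sample_id[calls$variant_id == v & calls$is_ch_in_tii])
  })
  names(carrier_sets) <- candidates$variant_id

  # stage 4: differential expression + pathway tabulation per candidate
  de <- list()
  pathway_counts <- NULL
  if (!is.null(bulk) && nrow(candidates) > 0) {
    n_samp <- ncol(bulk)
    for (v in candidates$variant_id) {
      carr <- intersect(carrier_sets[[v]], colnames(bulk))
      if (length(carr) >= 2 && length(carr) <= n_samp - 2) {
        de[[v]] <- run_de(bulk, carr, config$fdr)
      }
    }
    if (!is.null(pathway_map) && length(de) > 0) {
      vocab <- sort(unique(pathway_map$pathway))
      pathway_counts <- matrix(0L, nrow = length(vocab) + 1,
                               ncol = length(de),
                               dimnames = list(c(vocab, "unmapped"),
                                               names(de)))
      for (v in names(de)) {
        sde <- de[[v]]$gene[de[[v]]$sde]
        tab <- tabulate_pathways(sde, pathway_map)
        pathway_counts[names(tab), v] <- as.integer(tab)
      }
    }
  }

  funnel <- do.call(rbind, stages)
  rownames(funnel) <- NULL
  structure(list(
    funnel = funnel, candidates = candidates, ch_calls = calls,
    summaries = summaries, expr_summaries = expr_summaries,
    carrier_sets = carrier_sets, de = de, pathway_counts = pathway_counts,
    config = config, n_cohort = n_cohort, timestamp = format(Sys.time())
  ), class = "ch_pipeline_result")
}

#' @export
#' @method print ch_pipeline_result
print.ch_pipeline_result <- function(x, ...) {
  cat("CH-in-TII funnel over", x$n_cohort, "samples\n\n")
  f <- x$funnel
  for (i in seq_len(nrow(f))) {
    pct <- if (is.na(f$percent_of_previous[i])) "" else {
      sprintf(" (%.1f%% of previous)", f$percent_of_previous[i])
    }
    cat(sprintf("  %-28s %8d -> %8d%s\n", f$stage[i], f$input[i],
                f$output[i], pct))
  }
  cat("\nCandidates:", nrow(x$candidates), "\n")
  if (nrow(x$candidates) > 0) {
    cat(paste0("  ", x$candidates$gene, " ", x$candidates$protein_change,
               " (sample fraction ",
               sprintf("%.4f", x$candidates$sample_fraction), ")\n"),
        sep = "")
  }
  invisible(x)
}

#' @export
#' @method summary ch_pipeline_result
summary.ch_pipeline_result <- function(object, ...) {
  cand <- candidate_table(object)
  cat("Funnel stages:\n")
  print(object$funnel, row.names = FALSE)
  cat("\nCandidate table:\n")
  if (nrow(cand) > 0) print(cand, row.names = FALSE) else cat("  (none)\n")
  if (length(object$de) > 0) {
    n_sde <- vapply(object$de, function(d) sum(d$sde), numeric(1))
    cat("\nSDE genes per candidate (FDR <", object$config$fdr, "):\n")
    for (v in names(n_sde)) cat("  ", v, ":", n_sde[[v]], "\n")
  }
  invisible(cand)
}

#' Candidate table in reporting shape
#'
#' One row per surviving candidate with the funnel's reporting columns:
#' VAF mean +/- SD for tumor and blood, cohort sample fraction, and (when the
#' expression stage ran) the immune expression counts.
#'
#' @param result a `"ch_pipeline_result"`.
#' @param annotations optional annotation table for the population-frequency
#'   column.
#' @return a `data.frame`.
#' @export
candidate_table <- function(result, annotations = NULL) {
  cand <- result$candidates
  if (nrow(cand) == 0) return(cand)
  out <- cand[, c("variant_id", "gene", "protein_change", "n_pass",
                  "sample_fraction", "tumor_vaf_mean", "tumor_vaf_sd",
                  "blood_vaf_mean", "blood_vaf_sd")]
  if (!is.null(annotations)) {
    out$population_freq <- annotations$population_freq[
      match(out$variant_id, annotations$variant_id)]
  }
  if (!is.null(result$expr_summaries)) {
    out$n_immune_expressing <- vapply(out$gene, function(g) {
      s <- result$expr_summaries[[g]]
      if (is.null(s)) NA_real_ else s$n_immune_cells_expressing
    }, numeric(1))
    out$n_cells_expressing <- vapply(out$gene, function(g) {
      s <- result$expr_summaries[[g]]
      if (is.null(s)) NA_real_ else s$n_cells_expressing
    }, numeric(1))
  }
  rownames(out) <- NULL
  out
}

# "2E-5"-style population-frequency formatting (one significant digit)
.format_popfreq <- function(freq) {
  vapply(freq, function(f) {
    if (is.na(f)) return("NA")
    if (f == 0) return("0")
    e <- floor(log10(f))
    m <- round(f / 10^e)
    if (m == 10) { m <- 1; e <- e + 1 }
    paste0(m, "E", e)
  }, character(1))
}

#' Format one candidate row for display
#'
#' Renders the per-candidate reporting string: tumor and blood VAF to 2
#' decimals with +/- SD (the SD term is suppressed for single-carrier
#' candidates, which have none), the cohort sample fraction to 4 decimals,
#' the population frequency in compact scientific notation, and the immune
#' expression as "P% (immune/total)" with thousands separators.
#'
#' @param summary one-row candidate summary (see [summarize_variants()]).
#' @param annotation one-row annotation (`population_freq`), or `NULL`.
#' @param expression_summary a `"gene_expression_summary"`, or `NULL`.
#' @return a single formatted string.
#' @export
format_candidate_row <- function(summary, annotation = NULL,
                                 expression_summary = NULL) {
  fmt_vaf <- function(mean, sd) {
    if (is.na(sd)) sprintf("%.2f", mean)
    else sprintf("%.2f ± %.2f", mean, sd)
  }
  parts <- c(
    fmt_vaf(summary$tumor_vaf_mean, summary$tumor_vaf_sd),
    fmt_vaf(summary$blood_vaf_mean, summary$blood_vaf_sd),
    sprintf("%.4f", summary$sample_fraction)
  )
  if (!is.null(annotation)) {
    parts <- c(parts, .format_popfreq(annotation$population_freq))
  }
  if (!is.null(expression_summary)) {
    s <- expression_summary
    pct <- round(100 * s$immune_fraction)
    parts <- c(parts, sprintf(
      "%d%% (%s/%s)", pct,
      formatC(s$n_immune_cells_expressing, big.mark = ",", format = "d"),
      formatC(s$n_cells_expressing, big.mark = ",", format = "d")))
  }
  paste(parts, collapse = " | ")
}
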