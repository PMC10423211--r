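# Clonally expanded somatic (CH) mutation classification in TII cells.
#
# A variant observed in a sample is called a CH mutation in tumor-infiltrating
# immune cells when its VAF lies strictly inside the (2%, 25%) window in BOTH
# the blood and the tumor sample: the lower bound excludes sequencing noise and
# circulating tumor/cell-free DNA, the upper bound excludes heterozygous
# germline variants (VAF ~ 50%).

#' Configuration for CH-in-TII classification
#'
#' @param vaf_lower lower VAF bound (strict; default 0.02). Values at or below
#'   are treated as sub-clonal noise.
#' @param vaf_upper upper VAF bound (strict; default 0.25). Values at or above
#'   are treated as germline range.
#' @param ci_level confidence level for binomial VAF intervals (default 0.95).
#' @param ci_method interval type: `"wilson"` (default), `"wald"` or
#'   `"clopper-pearson"`.
#' @return a list of class `"ch_call_config"`.
#' @export
ch_call_config <- function(vaf_lower = 0.02, vaf_upper = 0.25,
                           ci_level = 0.95, ci_method = "wilson") {
  if (!(vaf_lower >= 0 && vaf_lower < vaf_upper && vaf_upper <= 1)) {
    stop("require 0 <= vaf_lower < vaf_upper <= 1")
  }
  if (!(ci_level > 0 && ci_level < 1)) stop("ci_level must be in (0, 1)")
  ci_method <- match.arg(ci_method, c("wilson", "wald", "clopper-pearson"))
  structure(list(vaf_lower = vaf_lower, vaf_upper = vaf_upper,
                 ci_level = ci_level, ci_method = ci_method),
            class = "ch_call_config")
}

#' Binomial proportion confidence interval
#'
#' Computes a confidence interval for the proportion `alt_count / depth`.
#' The default is the Wilson score interval, which behaves sensibly at
#' boundary counts (0 or `depth` alternate reads); Wald and Clopper-Pearson
#' (exact) intervals are available for comparison.
#'
#' @param alt_count number of alternate-allele reads (successes).
#' @param depth total reads (trials); must be positive.
#' @param level confidence level in (0, 1); default 0.95.
#' @param method `"wilson"` (default), `"wald"` or `"clopper-pearson"`.
#' @return numeric vector `c(lower, upper)`, clamped to \[0, 1\]; for
#'   vector input, a two-column matrix.
#' @export
#' @examples
#' binomial_ci(14, 100)
binomial_ci <- function(alt_count, depth, level = 0.95, method = "wilson") {
  if (any(depth <= 0)) stop("depth must be positive")
  if (any(alt_count < 0) || any(alt_count > depth)) {
    stop("alt_count must be in [0, depth]")
  }
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  method <- match.arg(method, c("wilson", "wald", "clopper-pearson"))
  p_hat <- alt_count / depth
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "wilson") {
    denom <- 1 + z^2 / depth
    center <- (p_hat + z^2 / (2 * depth)) / denom
    half <- (z / denom) * sqrt(p_hat * (1 - p_hat) / depth +
                                 z^2 / (4 * depth^2))
    lo <- center - half
    hi <- center + half
  } else if (method == "wald") {
    half <- z * sqrt(p_hat * (1 - p_hat) / depth)
    lo <- p_hat - half
    hi <- p_hat + half
  } else {
    alpha <- 1 - level
    lo <- ifelse(alt_count == 0, 0,
                 stats::qbeta(alpha / 2, alt_count, depth - alt_count + 1))
    hi <- ifelse(alt_count == depth, 1,
                 stats::qbeta(1 - alpha / 2, alt_count + 1, depth - alt_count))
  }
  lo <- pmax(0, lo)
  hi <- pmin(1, hi)
  if (length(p_hat) == 1) c(lo, hi) else cbind(lower = lo, upper = hi)
}

#' Classify variant calls as CH mutations in TII cells
#'
#' Applies the dual VAF window: a call passes iff
#' `vaf_lower < VAF < vaf_upper` (strict at both bounds) in both the blood and
#' the tumor sample. Failing calls carry a reason code: `below_lower_blood`,
#' `below_lower_tumor` (sub-clonal), `germline_range_blood`,
#' `germline_range_tumor` (heterozygous germline range). Binomial confidence
#' intervals for both VAFs are attached.
#'
#' @param table a variant table (see [read_maf()]); both tumor and blood
#'   depths must be positive for every row.
#' @param config a [ch_call_config()].
#' @return a `data.frame` with one row per input call: `sample_id`,
#'   `variant_id`, `gene`, `protein_change`, `consequence`, `tumor_vaf`,
#'   `blood_vaf`, depths, CI bounds, `is_ch_in_tii`, `reason`.
#' @export
classify_ch <- function(table, config = ch_call_config()) {
  stopifnot(inherits(config, "ch_call_config"))
  t_depth <- table$t_ref_count + table$t_alt_count
  n_depth <- table$n_ref_count + table$n_alt_count
  if (nrow(table) > 0 && (any(t_depth == 0) || any(n_depth == 0))) {
    stop("zero total depth in tumor or blood: VAF undefined")
  }
  tumor_vaf <- if (nrow(table) > 0) {
    compute_vaf(table$t_ref_count, table$t_alt_count)
  } else numeric(0)
  blood_vaf <- if (nrow(table) > 0) {
    compute_vaf(table$n_ref_count, table$n_alt_count)
  } else numeric(0)

  lo <- config$vaf_lower
  hi <- config$vaf_upper
  pass <- blood_vaf > lo & blood_vaf < hi & tumor_vaf > lo & tumor_vaf < hi
  reason <- rep("pass", length(pass))
  reason[tumor_vaf >= hi] <- "germline_range_tumor"
  reason[blood_vaf >= hi] <- "germline_range_blood"
  reason[tumor_vaf <= lo] <- "below_lower_tumor"
  reason[blood_vaf <= lo] <- "below_lower_blood"

  t_ci <- binomial_ci(table$t_alt_count, pmax(t_depth, 1),
                      config$ci_level, config$ci_method)
  n_ci <- binomial_ci(table$n_alt_count, pmax(n_depth, 1),
                      config$ci_level, config$ci_method)
  if (is.null(dim(t_ci))) t_ci <- matrix(t_ci, ncol = 2)
  if (is.null(dim(n_ci))) n_ci <- matrix(n_ci, ncol = 2)

  data.frame(
    sample_id = if (nrow(table)) table$Tumor_Sample_Barcode else character(0),
    variant_id = if (nrow(table)) table$variant_id else character(0),
    gene = if (nrow(table)) table$Hugo_Symbol else character(0),
    protein_change = if (nrow(table)) table$Protein_Change else character(0),
    consequence = if (nrow(table)) table$consequence else character(0),
    tumor_vaf = tumor_vaf, blood_vaf = blood_vaf,
    tumor_depth = as.numeric(t_depth), blood_depth = as.numeric(n_depth),
    tumor_ci_lo = t_ci[, 1], tumor_ci_hi = t_ci[, 2],
    blood_ci_lo = n_ci[, 1], blood_ci_hi = n_ci[, 2],
    is_ch_in_tii = pass, reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Per-variant cohort summary of CH calls
#'
#' Aggregates per-sample CH calls to one row per distinct variant. The sample
#' fraction is the number of samples in which the call passes the dual VAF
#' window divided by the cohort size. VAF means and sample standard deviations
#' (n - 1 denominator) are computed over the passing samples only — the
#' samples in which the variant is detected as a CH mutation; with a single
#' passing sample the SD is `NA`, and with none the VAF moments are absent
#' (`NA`).
#'
#' @param calls output of [classify_ch()].
#' @param n_cohort total number of patients in the cohort (may exceed the
#'   number of samples with calls).
#' @return a `data.frame` with one row per variant: `variant_id`, `gene`,
#'   `protein_change`, `consequence`, `n_pass`, `sample_fraction`,
#'   `tumor_vaf_mean`, `tumor_vaf_sd`, `blood_vaf_mean`, `blood_vaf_sd`.
#' @export
summarize_variants <- function(calls, n_cohort) {
  stopifnot(n_cohort >= length(unique(calls$sample_id)))
  if (nrow(calls) == 0) {
    return(data.frame(variant_id = character(0), gene = character(0),
                      protein_change = character(0), consequence = character(0),
                      n_pass = integer(0), sample_fraction = numeric(0),
                      tumor_vaf_mean = numeric(0), tumor_vaf_sd = numeric(0),
                      blood_vaf_mean = numeric(0), blood_vaf_sd = numeric(0),
                      stringsAsFactors = FALSE))
  }
  ids <- unique(calls$variant_id)
  rows <- lapply(ids, function(v) {
    sub <- calls[calls$variant_id == v, , drop = FALSE]
    ok <- sub[sub$is_ch_in_tii, , drop = FALSE]
    n_pass <- length(unique(ok$sample_id))
    data.frame(
      variant_id = v,
      gene = sub$gene[1],
      protein_change = sub$protein_change[1],
      consequence = sub$consequence[1],
      n_pass = n_pass,
      sample_fraction = n_pass / n_cohort,
      tumor_vaf_mean = if (n_pass > 0) mean(ok$tumor_vaf) else NA_real_,
      tumor_vaf_sd = if (n_pass > 1) stats::sd(ok$tumor_vaf) else NA_real_,
      blood_vaf_mean = if (n_pass > 0) mean(ok$blood_vaf) else NA_real_,
      blood_vaf_sd = if (n_pass > 1) stats::sd(ok$blood_vaf) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
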