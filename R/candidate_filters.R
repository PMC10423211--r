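# Stage-3 candidate filters: cohort frequency, population rarity,
# hypermutable-gene exclusion, and deleteriousness consensus. Each filter is a
# subset operation on the per-variant summary table (output rows are a subset
# of input rows, unmodified), and the per-variant filters commute.

#' Filter thresholds for candidate selection
#'
#' @param min_sample_fraction minimum cohort sample fraction (strict `>`;
#'   default 0.05, i.e. the variant must occur in more than 5% of samples).
#' @param max_population_freq maximum population allele frequency (strict `<`;
#'   default 1e-4, i.e. gnomAD-rare).
#' @return a list of class `"filter_config"`.
#' @export
filter_config <- function(min_sample_fraction = 0.05,
                          max_population_freq = 1e-4) {
  if (!(min_sample_fraction >= 0 && min_sample_fraction <= 1)) {
    stop("min_sample_fraction must be in [0, 1]")
  }
  if (!(max_population_freq >= 0 && max_population_freq <= 1)) {
    stop("max_population_freq must be in [0, 1]")
  }
  structure(list(min_sample_fraction = min_sample_fraction,
                 max_population_freq = max_population_freq),
            class = "filter_config")
}

#' Keep variants that occur frequently in the cohort
#'
#' Rare population variants that nonetheless recur in more than 5% of cohort
#' blood samples are unlikely to be passenger mutations, since non-tumor
#' immune cells lack the defective DNA repair that scatters passengers across
#' tumor genomes. Retains `sample_fraction > min_sample_fraction` (strict).
#'
#' @param summaries per-variant summary table (see [summarize_variants()]).
#' @param config a [filter_config()].
#' @return the surviving subset of `summaries`.
#' @export
filter_sample_fraction <- function(summaries, config = filter_config()) {
  out <- summaries[summaries$sample_fraction > config$min_sample_fraction, ,
                   drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep variants that are rare in the population
#'
#' Retains variants with population allele frequency strictly below
#' `max_population_freq` (default 1e-4). A variant with no annotation row is
#' treated conservatively as failing the filter (and counted in the
#' `"missing_annotation"` attribute), mirroring the exclusion-biased design of
#' the candidate selection.
#'
#' @param summaries per-variant summary table.
#' @param annotations annotation table with columns `variant_id`,
#'   `population_freq`, `sift`, `polyphen`.
#' @param config a [filter_config()].
#' @return the surviving subset of `summaries`.
#' @export
filter_rare <- function(summaries, annotations, config = filter_config()) {
  freq <- annotations$population_freq[match(summaries$variant_id,
                                            annotations$variant_id)]
  missing <- is.na(freq)
  if (any(missing)) {
    message(sum(missing),
            " variant(s) without annotation treated as failing the rarity filter")
  }
  keep <- !missing & freq < config$max_population_freq
  out <- summaries[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "missing_annotation") <- sum(missing)
  out
}

#' Exclude variants in hypermutable gene families
#'
#' Immunoglobulin, immunoglobulin-like receptor, histocompatibility antigen
#' and T-cell receptor loci hypermutate or vary extremely as part of the
#' normal immune response; variants there are excluded. Hypermutable status is
#' supplied as data (`gene_meta`), not inferred from symbols — see
#' [default_hypermutable()] for a convenience symbol-prefix rule.
#'
#' @param summaries per-variant summary table.
#' @param gene_meta table with columns `gene` and `hypermutable` (logical);
#'   must cover every gene appearing in `summaries`.
#' @return the surviving subset of `summaries`.
#' @export
filter_hypermutable <- function(summaries, gene_meta) {
  idx <- match(summaries$gene, gene_meta$gene)
  if (anyNA(idx)) {
    miss <- unique(summaries$gene[is.na(idx)])
    stop("gene(s) missing from gene metadata: ", paste(miss, collapse = ", "))
  }
  hyper <- as.logical(gene_meta$hypermutable[idx])
  out <- summaries[!hyper, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default hypermutable-family call from gene-symbol prefixes
#'
#' Convenience helper flagging immunoglobulin (IGH/IGK/IGL), killer-cell and
#' leukocyte Ig-like receptor (KIR/LILR), histocompatibility antigen (HLA) and
#' T-cell receptor (TRA/TRB/TRG/TRD) symbols. Authoritative status should be
#' supplied as data; this mirrors the common symbol conventions only.
#'
#' @param genes character vector of gene symbols.
#' @return logical vector, `TRUE` for symbols matching a hypermutable-family
#'   prefix.
#' @export
default_hypermutable <- function(genes) {
  grepl("^(IGH|IGK|IGL|TRA|TRB|TRG|TRD|HLA|KIR|LILR)", genes)
}

#' Deleteriousness consensus call
#'
#' A variant is considered deleterious when it is truncating or frame-shifting
#' (nonsense, frame-shift insertion/deletion, or splice-site — classes that
#' SIFT/PolyPhen do not score), or when both predictors agree: SIFT calls it
#' `deleterious` and PolyPhen calls it damaging. By default both PolyPhen
#' grades (`probably_damaging`, `possibly_damaging`) count as damaging.
#'
#' @param consequence consequence class vector.
#' @param sift SIFT call: `deleterious`, `tolerated` or `unknown`.
#' @param polyphen PolyPhen call: `probably_damaging`, `possibly_damaging`,
#'   `benign` or `unknown`.
#' @param damaging_polyphen PolyPhen grades counted as damaging.
#' @param auto_deleterious consequence classes deleterious regardless of
#'   predictor calls.
#' @return logical vector.
#' @export
is_deleterious <- function(consequence, sift, polyphen,
                           damaging_polyphen = c("probably_damaging",
                                                 "possibly_damaging"),
                           auto_deleterious = c("nonsense", "frameshift_ins",
                                                "frameshift_del",
                                                "splice_site")) {
  consequence %in% auto_deleterious |
    (sift == "deleterious" & polyphen %in% damaging_polyphen)
}

#' Keep variants predicted deleterious
#'
#' Applies [is_deleterious()] to each summarized variant using its annotation
#' row. Variants without an annotation row are treated as having `unknown`
#' predictor calls (so only truncating/frame-shift/splice classes survive).
#'
#' @param summaries per-variant summary table (with a `consequence` column).
#' @param annotations annotation table (`variant_id`, `sift`, `polyphen`).
#' @param ... passed to [is_deleterious()].
#' @return the surviving subset of `summaries`.
#' @export
filter_deleterious <- function(summaries, annotations, ...) {
  idx <- match(summaries$variant_id, annotations$variant_id)
  sift <- ifelse(is.na(idx), "unknown", annotations$sift[idx])
  polyphen <- ifelse(is.na(idx), "unknown", annotations$polyphen[idx])
  keep <- is_deleterious(summaries$consequence, sift, polyphen, ...)
  out <- summaries[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
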