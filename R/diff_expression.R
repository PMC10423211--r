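# Differential expression between mutation-carrier and non-carrier samples:
# per-gene two-sided Welch t test with Satterthwaite degrees of freedom,
# Benjamini-Hochberg FDR control across tested genes, and tabulation of the
# top-level pathways touched by the significant genes.

#' Welch two-sample t test with Satterthwaite degrees of freedom
#'
#' For independent samples with unequal standard deviations:
#' `t = (mean(x) - mean(y)) / sqrt(sx^2/nx + sy^2/ny)` with effective
#' degrees of freedom
#' `df = (sx^2/nx + sy^2/ny)^2 / ((sx^2/nx)^2/(nx-1) + (sy^2/ny)^2/(ny-1))`
#' and a two-sided p value from the Student t distribution with that df.
#'
#' @param x,y numeric vectors (each of length >= 2; at least one group must
#'   have nonzero variance).
#' @return a list with `t_stat`, `df`, `p_value`.
#' @export
#' @examples
#' welch_t(c(1, 2, 3, 4), c(2, 4, 6, 8))
welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each group must have at least 2 observations")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) stop("both groups have zero variance")
  se2x <- vx / nx
  se2y <- vy / ny
  t_stat <- (mean(x) - mean(y)) / sqrt(se2x + se2y)
  df <- (se2x + se2y)^2 / (se2x^2 / (nx - 1) + se2y^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t_stat = t_stat, df = df, p_value = p)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Standard step-up procedure: with p values sorted ascending,
#' `q(i) = min_{j >= i} p(j) * m / j`, capped at 1. Output order matches
#' input order; tied p values share their adjusted value.
#'
#' @param p_values numeric vector of p values in \[0, 1\].
#' @return numeric vector of BH-adjusted q values, same order as input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p values must lie in [0, 1]")
  }
  m <- length(p_values)
  o <- order(p_values)
  scaled <- p_values[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(scaled)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Differential expression between carrier and non-carrier samples
#'
#' Runs a per-gene two-sided Welch t test comparing mutation-carrier samples
#' against all remaining samples, then applies Benjamini-Hochberg correction
#' across the tested genes. Genes with zero variance in both groups are
#' untestable: they are skipped (counted in the `n_skipped` attribute) and do
#' not enter the multiple-testing correction. A gene is flagged significantly
#' differentially expressed (SDE) iff its q value is strictly below `fdr`.
#'
#' @param expr numeric matrix, genes in rows (rownames = symbols), samples in
#'   columns (colnames = sample ids).
#' @param carriers character vector of carrier sample ids; must be a strict
#'   subset of the columns with at least 2 carriers and 2 non-carriers.
#' @param fdr FDR threshold (default 0.05, strict `<`).
#' @return a `data.frame` with one row per tested gene: `gene`,
#'   `mean_carrier`, `mean_noncarrier`, `t_stat`, `df`, `p_value`, `q_value`,
#'   `sde`; attribute `n_skipped` counts untestable genes.
#' @export
run_de <- function(expr, carriers, fdr = 0.05) {
  samples <- colnames(expr)
  if (is.null(samples)) stop("expression matrix must have sample ids as colnames")
  if (!all(carriers %in% samples)) {
    stop("carrier id(s) not present in expression matrix")
  }
  n_car <- length(unique(carriers))
  if (n_car < 2 || n_car > length(samples) - 2) {
    stop("need at least 2 carriers and 2 non-carriers")
  }
  in_car <- samples %in% carriers
  rows <- vector("list", nrow(expr))
  n_skipped <- 0L
  for (i in seq_len(nrow(expr))) {
    x <- expr[i, in_car]
    y <- expr[i, !in_car]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    w <- welch_t(x, y)
    rows[[i]] <- data.frame(gene = rownames(expr)[i],
                            mean_carrier = mean(x), mean_noncarrier = mean(y),
                            t_stat = w$t_stat, df = w$df, p_value = w$p_value,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- data.frame(gene = character(0), mean_carrier = numeric(0),
                      mean_noncarrier = numeric(0), t_stat = numeric(0),
                      df = numeric(0), p_value = numeric(0),
                      q_value = numeric(0), sde = logical(0),
                      stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out$sde <- out$q_value < fdr
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a gene -> top-level pathway map
#'
#' @param path TSV with header columns `gene` and `pathway`; a gene may map
#'   to several pathways (one row each).
#' @return a `data.frame` with columns `gene`, `pathway`.
#' @export
read_pathway_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("gene", "pathway") %in% names(df))) {
    stop("pathway map must have columns 'gene' and 'pathway'")
  }
  df
}

#' Tabulate top-level pathways touched by SDE genes
#'
#' Counts significantly differentially expressed genes per top-level pathway.
#' A gene mapping to k pathways contributes 1 to each; genes absent from the
#' map are counted under the explicit `"unmapped"` bucket.
#'
#' @param sde_genes character vector of SDE gene symbols.
#' @param map pathway map (`gene`, `pathway`), see [read_pathway_map()].
#' @return named integer vector: pathway -> SDE gene count (plus `"unmapped"`
#'   when applicable).
#' @export
tabulate_pathways <- function(sde_genes, map) {
  sde_genes <- unique(sde_genes)
  hits <- map[map$gene %in% sde_genes, , drop = FALSE]
  counts <- if (nrow(hits) > 0) {
    tab <- table(hits$pathway)
    stats::setNames(as.integer(tab), names(tab))
  } else {
    stats::setNames(integer(0), character(0))
  }
  unmapped <- setdiff(sde_genes, map$gene)
  if (length(unmapped) > 0) {
    counts <- c(counts, unmapped = length(unmapped))
  }
  counts
}

#' Read a bulk gene-by-sample expression table
#'
#' @param path TSV with a `gene` column followed by one column per sample.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
read_bulk_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene" %in% names(df)) stop("bulk expression table must have a 'gene' column")
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  if (length(m) == 0) storage.mode(m) <- "double"
  if (!is.numeric(m)) stop("bulk expression values must be numeric")
  if (any(!is.finite(m))) stop("bulk expression values must be finite")
  rownames(m) <- df$gene
  m
}
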