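# Consequence vocabulary ------------------------------------------------------

#' Consequence classes treated as protein altering
#'
#' Nonsense, missense, in-frame and frame-shift insertions/deletions, and
#' splice-site variants. Synonymous, intronic, intergenic and UTR variants are
#' excluded because they are far less likely to be pathogenic.
#'
#' @export
PROTEIN_ALTERING_CLASSES <- c(
  "missense", "nonsense", "frameshift_ins", "frameshift_del",
  "inframe_ins", "inframe_del", "splice_site"
)

#' All recognised consequence classes
#' @export
CONSEQUENCE_CLASSES <- c(
  PROTEIN_ALTERING_CLASSES,
  "synonymous", "intron", "intergenic", "utr", "other"
)

# Mapping from standard MAF Variant_Classification strings to the internal
# consequence vocabulary. Anything unrecognised maps to "other".
.maf_class_map <- c(
  Missense_Mutation = "missense",
  Nonsense_Mutation = "nonsense",
  Frame_Shift_Ins   = "frameshift_ins",
  Frame_Shift_Del   = "frameshift_del",
  In_Frame_Ins      = "inframe_ins",
  In_Frame_Del      = "inframe_del",
  Splice_Site       = "splice_site",
  Silent            = "synonymous",
  Intron            = "intron",
  IGR               = "intergenic",
  "3'UTR"           = "utr",
  "5'UTR"           = "utr"
)

#' Map MAF Variant_Classification strings to consequence classes
#'
#' Accepts either standard MAF classification strings (e.g.
#' `Missense_Mutation`) or the internal lower-case vocabulary; anything else
#' maps to `"other"`.
#'
#' @param x character vector of classification strings.
#' @return character vector of consequence classes.
#' @export
map_consequence <- function(x) {
  x <- as.character(x)
  out <- unname(.maf_class_map[x])
  direct <- x %in% CONSEQUENCE_CLASSES
  out[direct] <- x[direct]
  out[is.na(out)] <- "other"
  out
}

# Required MAF columns (bit-exact names) --------------------------------------

MAF_REQUIRED_COLUMNS <- c(
  "Hugo_Symbol", "Chromosome", "Start_Position", "Reference_Allele",
  "Tumor_Seq_Allele2", "Variant_Classification", "Protein_Change",
  "Tumor_Sample_Barcode", "t_ref_count", "t_alt_count",
  "n_ref_count", "n_alt_count", "lod", "base_quality"
)

#' Read a MAF-dialect variant table
#'
#' Reads a tab-delimited variant table with a named-column header (a minimal
#' faithful MAF subset) holding per-sample tumor and matched-blood allele
#' depths, a caller log-odds (LOD) score, and a base quality score. Rows with
#' zero total depth in either the tumor or the blood sample are dropped; the
#' number of dropped rows is recorded in the `"dropped"` attribute and
#' reported via [message()].
#'
#' Coordinates are 1-based inclusive (MAF convention). A `variant_id` column
#' is derived as `chrom:pos:ref:alt` and identifies the distinct variant
#' across samples; `consequence` holds the mapped consequence class.
#'
#' @param path path to a tab-delimited MAF-dialect file.
#' @return a `data.frame` with one row per variant call, carrying the original
#'   columns plus `variant_id` and `consequence`, and attributes `dropped`
#'   (count of zero-depth rows removed).
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) {
    stop("MAF file not found: ", path)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = NA, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  missing <- setdiff(MAF_REQUIRED_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("MAF file is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  num_cols <- c("Start_Position", "t_ref_count", "t_alt_count",
                "n_ref_count", "n_alt_count", "lod", "base_quality")
  for (cl in num_cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0) {
        stop("non-numeric value in column '", cl, "' at data line ", bad[1])
      }
      df[[cl]] <- vn
    }
  }
  df <- as_variant_table(df)
  df
}

#' Coerce a data frame to the internal variant-call table layout
#'
#' Validates required columns, derives `variant_id` and `consequence`, and
#' drops rows whose tumor or blood total depth is zero (recorded in the
#' `dropped` attribute).
#'
#' @param df a data frame with the required MAF columns.
#' @return the validated variant table.
#' @export
as_variant_table <- function(df) {
  missing <- setdiff(MAF_REQUIRED_COLUMNS, names(df))
  if (length(missing) > 0) {
    stop("variant table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) > 0 && any(df$Start_Position < 1)) {
    stop("Start_Position must be >= 1 (1-based MAF coordinates)")
  }
  counts <- c("t_ref_count", "t_alt_count", "n_ref_count", "n_alt_count")
  if (nrow(df) > 0 && any(unlist(df[counts]) < 0)) {
    stop("read counts must be non-negative")
  }
  df$Chromosome <- as.character(df$Chromosome)
  zero_depth <- (df$t_ref_count + df$t_alt_count) == 0 |
    (df$n_ref_count + df$n_alt_count) == 0
  n_drop <- sum(zero_depth)
  if (n_drop > 0) {
    message("dropped ", n_drop, " row(s) with zero total depth in tumor or blood")
    df <- df[!zero_depth, , drop = FALSE]
  }
  df$variant_id <- variant_id(df$Chromosome, df$Start_Position,
                              df$Reference_Allele, df$Tumor_Seq_Allele2)
  df$consequence <- map_consequence(df$Variant_Classification)
  rownames(df) <- NULL
  attr(df, "dropped") <- n_drop
  df
}

#' Construct variant identifiers from coordinates and alleles
#'
#' @param chrom,pos,ref,alt vectors of chromosome, 1-based position,
#'   reference and alternate alleles.
#' @return character vector `chrom:pos:ref:alt`.
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Write a variant table in the same MAF dialect read_maf() consumes
#'
#' @param table a variant table (the required MAF columns; derived columns are
#'   not written).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(table, path) {
  out <- table[, intersect(MAF_REQUIRED_COLUMNS, names(table)), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Variant allele fraction from per-allele read counts
#'
#' VAF = alt / (ref + alt), the fraction of reads supporting the alternate
#' allele. The denominator is the sum of the two allele counts (not total
#' site depth), so the value is an exact ratio of two integers.
#'
#' @param ref_count,alt_count reference- and alternate-allele read counts
#'   (vectors of equal length).
#' @return numeric vector of fractions in \[0, 1\].
#' @export
#' @examples
#' compute_vaf(86, 14)   # 0.14
compute_vaf <- function(ref_count, alt_count) {
  if (any(ref_count < 0) || any(alt_count < 0)) {
    stop("read counts must be non-negative")
  }
  depth <- ref_count + alt_count
  if (any(depth == 0)) {
    stop("zero total depth: VAF undefined")
  }
  alt_count / depth
}

#' Call-quality gate on LOD and base quality
#'
#' Retains rows whose caller log-odds score and base quality both meet the
#' minimum thresholds (inclusive: a "minimum" of 4.0 passes a row at exactly
#' 4.0). Row order is preserved and the operation is idempotent.
#'
#' @param table a variant table.
#' @param min_lod minimum log-odds score (default 4.0, a 10^4:1 odds of a
#'   correct call).
#' @param min_base_quality minimum Phred-scaled base quality (default 10).
#' @return the filtered table.
#' @export
quality_gate <- function(table, min_lod = 4.0, min_base_quality = 10) {
  stopifnot(min_lod >= 0, min_base_quality >= 0)
  keep <- table$lod >= min_lod & table$base_quality >= min_base_quality
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict a variant table to protein-altering consequence classes
#'
#' Retains missense, nonsense, frame-shift and in-frame insertions/deletions,
#' and splice-site variants; removes synonymous, intronic, intergenic, UTR
#' and unclassified rows.
#'
#' @param table a variant table with a `consequence` column (see [read_maf()]).
#' @return the filtered table.
#' @export
select_protein_altering <- function(table) {
  if (is.null(table$consequence)) {
    table$consequence <- map_consequence(table$Variant_Classification)
  }
  out <- table[table$consequence %in% PROTEIN_ALTERING_CLASSES, , drop = FALSE]
  rownames(out) <- NULL
  out
}
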