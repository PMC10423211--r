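# Shared fixture builders. Everything is generated in code at test time.

# scaled-down default cohort for fast tests
small_config <- function(seed = 42, ...) {
  args <- list(n_samples = 120, n_genes = 40, n_planted_ch = 4,
               n_germline = 6, n_noise = 10, n_passenger_somatic = 5,
               n_cells = 600, seed = seed)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

# well-separated regime: true VAFs centred at 0.12, carrier fraction ~ 0.08,
# depth 500 — planted variants should be recovered exactly
well_separated_config <- function(seed = 11) {
  simulation_config(n_samples = 150, n_genes = 40, n_planted_ch = 5,
                    n_germline = 6, n_noise = 8, n_passenger_somatic = 5,
                    depth_mean = 500,
                    blood_vaf_range = c(0.115, 0.125),
                    tumor_vaf_range = c(0.115, 0.125),
                    carrier_fraction_range = c(0.075, 0.085),
                    n_cells = 600, seed = seed)
}

# hand-built variant-call rows with sensible defaults
make_maf <- function(n = 1, gene = "GENEA", chrom = "1",
                     pos = seq_len(n), ref = "A", alt = "G",
                     classification = "missense", protein = "p.V276G",
                     sample = sprintf("S%03d", seq_len(n)),
                     t_ref = 82, t_alt = 18, n_ref = 86, n_alt = 14,
                     lod = 30, bq = 30) {
  df <- data.frame(
    Hugo_Symbol = gene, Chromosome = chrom, Start_Position = pos,
    Reference_Allele = ref, Tumor_Seq_Allele2 = alt,
    Variant_Classification = classification, Protein_Change = protein,
    Tumor_Sample_Barcode = sample,
    t_ref_count = t_ref, t_alt_count = t_alt,
    n_ref_count = n_ref, n_alt_count = n_alt,
    lod = lod, base_quality = bq,
    stringsAsFactors = FALSE
  )
  suppressMessages(as_variant_table(df))
}

# minimal per-variant summary rows for filter tests
make_summaries <- function(variant_id, gene = paste0("G", seq_along(variant_id)),
                           sample_fraction = 0.08, consequence = "missense",
                           n_pass = 10) {
  data.frame(variant_id = variant_id, gene = gene,
             protein_change = "p.A1V", consequence = consequence,
             n_pass = n_pass, sample_fraction = sample_fraction,
             tumor_vaf_mean = 0.12, tumor_vaf_sd = 0.03,
             blood_vaf_mean = 0.1, blood_vaf_sd = 0.03,
             stringsAsFactors = FALSE)
}

# toy labelled cell matrix built from a dense matrix (genes x cells)
make_cells <- function(counts, cell_type,
                       genes = paste0("G", seq_len(nrow(counts))),
                       barcodes = paste0("C", seq_len(ncol(counts)))) {
  cell_matrix(Matrix::Matrix(counts, sparse = TRUE), genes, barcodes,
              cell_type)
}
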