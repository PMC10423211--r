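# Synthetic cohort generator with planted ground truth.
#
# Emulates the statistical structure of a matched tumor/normal-blood exome
# cohort with tumor-infiltrating immune cells: true CH-in-TII variants whose
# blood and tumor VAFs sit inside the (2%, 25%) window, heterozygous germline
# variants (true VAF 0.5), sub-threshold noise variants, and passenger
# somatic variants each constructed to fail exactly one downstream filter.
# Read depths are Poisson around `depth_mean`, floored at 16 and capped at
# 725 (the observed depth range of deep matched exome cohorts); alternate
# read counts are Binomial(depth, true VAF).

PASSENGER_FILTERS <- c("sample_fraction", "gnomad", "hypermutable",
                       "deleterious", "expression")

#' Simulation configuration
#'
#' Defaults describe a scaled-down but structurally faithful cohort: planted
#' CH variants with true VAFs centred in the CH band (8-18%) carried by
#' 7-15% of samples (comfortably above the 5% cohort-frequency threshold,
#' like real candidates whose sample fractions ran 7-12%), germline variants
#' at VAF 0.5, sub-2% noise variants, and one passenger variant per
#' downstream filter.
#'
#' @param n_samples number of patients (matched tumor/blood pairs).
#' @param n_genes number of genes; must be at least `n_planted_ch +
#'   n_passenger_somatic`.
#' @param n_planted_ch number of true CH-in-TII variants, one per gene.
#' @param n_germline number of heterozygous germline variants (true VAF 0.5).
#' @param n_noise number of sub-threshold variants (true VAF < 2%).
#' @param n_passenger_somatic number of passenger variants; each cycles
#'   through the named filters `r paste(PASSENGER_FILTERS, collapse=", ")`
#'   and is built to fail exactly that one.
#' @param depth_mean mean sequencing depth in reads (Poisson, clipped to
#'   \[16, 725\]).
#' @param blood_vaf_range,tumor_vaf_range true-VAF ranges for planted
#'   variants; must lie inside (0.02, 0.25).
#' @param carrier_fraction_range range of the fraction of samples carrying
#'   each planted variant; the generator pairs this with the fixed 0.02
#'   carrier fraction of the `passenger:sample_fraction` variant so the
#'   cohort straddles the 5% cohort-frequency threshold.
#' @param qc_fail_fraction fraction of noise-variant calls emitted with LOD
#'   or base quality below the pass thresholds.
#' @param n_cells number of cells in the single-cell matrix.
#' @param de_genes_per_variant number of bulk-expression genes shifted in the
#'   carriers of each planted variant.
#' @param de_effect_size log-scale expression shift attached to planted
#'   variants (in units of the within-group SD, which is 1).
#' @param seed master integer RNG seed; one stream per output table is
#'   derived from it, so adding variants to one table does not perturb
#'   another.
#' @return a validated list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_samples = 200,
                              n_genes = 120,
                              n_planted_ch = 8,
                              n_germline = 15,
                              n_noise = 25,
                              n_passenger_somatic = 5,
                              depth_mean = 150,
                              blood_vaf_range = c(0.08, 0.18),
                              tumor_vaf_range = c(0.08, 0.18),
                              carrier_fraction_range = c(0.07, 0.15),
                              qc_fail_fraction = 0.5,
                              n_cells = 2000,
                              de_genes_per_variant = 10,
                              de_effect_size = 1.0,
                              seed = 1L) {
  cfg <- list(n_samples = n_samples, n_genes = n_genes,
              n_planted_ch = n_planted_ch, n_germline = n_germline,
              n_noise = n_noise, n_passenger_somatic = n_passenger_somatic,
              depth_mean = depth_mean, blood_vaf_range = blood_vaf_range,
              tumor_vaf_range = tumor_vaf_range,
              carrier_fraction_range = carrier_fraction_range,
              qc_fail_fraction = qc_fail_fraction, n_cells = n_cells,
              de_genes_per_variant = de_genes_per_variant,
              de_effect_size = de_effect_size, seed = as.integer(seed))
  for (fld in c("n_samples", "n_genes", "n_planted_ch", "n_germline",
                "n_noise", "n_passenger_somatic", "n_cells",
                "de_genes_per_variant")) {
    v <- cfg[[fld]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      stop("invalid configuration field '", fld, "': must be a count >= 0")
    }
  }
  if (!is.numeric(depth_mean) || depth_mean <= 0) {
    stop("invalid configuration field 'depth_mean': must be positive")
  }
  for (fld in c("blood_vaf_range", "tumor_vaf_range",
                "carrier_fraction_range")) {
    r <- cfg[[fld]]
    if (length(r) != 2 || any(r < 0) || any(r > 1) || r[1] >= r[2]) {
      stop("invalid configuration field '", fld,
           "': must be a pair in [0, 1] with low < high")
    }
  }
  for (fld in c("blood_vaf_range", "tumor_vaf_range")) {
    r <- cfg[[fld]]
    if (r[1] <= 0.02 || r[2] >= 0.25) {
      stop("invalid configuration field '", fld,
           "': planted true VAFs must lie strictly inside (0.02, 0.25)")
    }
  }
  if (qc_fail_fraction < 0 || qc_fail_fraction > 1) {
    stop("invalid configuration field 'qc_fail_fraction': must be in [0, 1]")
  }
  need_genes <- n_planted_ch + n_passenger_somatic
  if (n_genes < need_genes ||
      (n_genes == 0 && (n_germline > 0 || n_noise > 0))) {
    stop("invalid configuration field 'n_genes': need at least ",
         max(need_genes, 1), " genes for the requested variants")
  }
  if (is.na(cfg$seed)) stop("invalid configuration field 'seed'")
  structure(cfg, class = "simulation_config")
}

# Independent deterministic RNG stream per output table.
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

.clip_depth <- function(d) pmin(pmax(d, 16), 725)

# Variant blueprint: one row per distinct variant with its true parameters.
.plan_variants <- function(config) {
  n_total <- config$n_planted_ch + config$n_germline + config$n_noise +
    config$n_passenger_somatic
  if (n_total == 0) {
    return(data.frame(variant_id = character(0), gene = character(0),
                      label = character(0), consequence = character(0),
                      protein_change = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0), alt = character(0),
                      blood_vaf = numeric(0), tumor_vaf = numeric(0),
                      carrier_fraction = numeric(0),
                      stringsAsFactors = FALSE))
  }
  genes <- sprintf("SYNG%03d", seq_len(max(config$n_genes, 1)))
  # dedicated genes for planted and passenger variants; the hypermutable
  # passenger sits in an immunoglobulin-prefixed symbol
  labels <- c(rep("planted_ch", config$n_planted_ch),
              rep("germline", config$n_germline),
              rep("noise", config$n_noise),
              if (config$n_passenger_somatic > 0) {
                paste0("passenger:",
                       PASSENGER_FILTERS[(seq_len(config$n_passenger_somatic) - 1)
                                         %% length(PASSENGER_FILTERS) + 1])
              })
  n_dedicated <- config$n_planted_ch + config$n_passenger_somatic
  dedicated <- genes[seq_len(n_dedicated)]
  pool <- if (config$n_genes > n_dedicated) {
    genes[(n_dedicated + 1):config$n_genes]
  } else genes

  gene_of <- character(n_total)
  d <- 0L
  for (i in seq_len(n_total)) {
    if (labels[i] == "planted_ch" || startsWith(labels[i], "passenger:")) {
      d <- d + 1L
      gene_of[i] <- dedicated[d]
    } else {
      gene_of[i] <- sample(pool, 1)
    }
  }
  hyper_idx <- which(labels == "passenger:hypermutable")
  if (length(hyper_idx) > 0) {
    gene_of[hyper_idx] <- sub("^SYNG", "IGHV", gene_of[hyper_idx])
  }

  bvaf <- tvaf <- cf <- numeric(n_total)
  consequence <- character(n_total)
  for (i in seq_len(n_total)) {
    lab <- labels[i]
    if (lab == "germline") {
      bvaf[i] <- 0.5; tvaf[i] <- 0.5
      cf[i] <- stats::runif(1, 0.2, 0.6)
      consequence[i] <- "missense"
    } else if (lab == "noise") {
      bvaf[i] <- stats::runif(1, 0.003, 0.015)
      tvaf[i] <- stats::runif(1, 0.003, 0.015)
      cf[i] <- stats::runif(1, 0.01, 0.04)
      consequence[i] <- sample(c("missense", "synonymous", "intron"), 1,
                               prob = c(0.6, 0.2, 0.2))
    } else {
      bvaf[i] <- stats::runif(1, config$blood_vaf_range[1],
                              config$blood_vaf_range[2])
      tvaf[i] <- stats::runif(1, config$tumor_vaf_range[1],
                              config$tumor_vaf_range[2])
      cf[i] <- if (lab == "passenger:sample_fraction") 0.02 else {
        stats::runif(1, config$carrier_fraction_range[1],
                     config$carrier_fraction_range[2])
      }
      consequence[i] <- "missense"
    }
  }
  chrom <- as.character(sample(1:22, n_total, replace = TRUE))
  pos <- sample.int(5e7, n_total)  # unique positions: distinct variant ids
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_total, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  protein_change <- paste0("p.", sample(aa, n_total, replace = TRUE),
                           sample.int(600, n_total, replace = TRUE),
                           sample(aa, n_total, replace = TRUE))
  data.frame(
    variant_id = variant_id(chrom, pos, ref, alt),
    gene = gene_of, label = labels, consequence = consequence,
    protein_change = protein_change, chrom = chrom, pos = pos,
    ref = ref, alt = alt, blood_vaf = bvaf, tumor_vaf = tvaf,
    carrier_fraction = cf, stringsAsFactors = FALSE
  )
}

#' Simulate a synthetic cohort with planted ground truth
#'
#' Generates all six inputs the pipeline consumes — the MAF-dialect variant
#' table, variant annotations, gene metadata, a labelled single-cell count
#' matrix, a bulk expression table, and a gene-to-pathway map — together with
#' the ground truth of every planted variant. Planted CH variants satisfy
#' every downstream filter by construction; each `passenger:<filter>` variant
#' fails exactly its named filter; germline variants sit at true VAF 0.5 and
#' noise variants below 2%.
#'
#' @param config a [simulation_config()].
#' @return a list of class `"ch_cohort"`: `maf` (variant table),
#'   `annotations`, `gene_meta`, `cells` (a [cell_matrix()]), `bulk`
#'   (gene-by-sample matrix), `pathway_map`, `truth` (labels, carrier sets,
#'   true VAFs, DE target genes), `samples`, `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  samples <- if (config$n_samples > 0) {
    sprintf("S%04d", seq_len(config$n_samples))
  } else character(0)

  set.seed(.sub_seed(config$seed, 1))
  plan <- .plan_variants(config)

  # carrier sets (at least one carrier per variant when samples exist)
  carriers <- list()
  if (nrow(plan) > 0 && length(samples) > 0) {
    for (i in seq_len(nrow(plan))) {
      k <- max(1L, round(plan$carrier_fraction[i] * length(samples)))
      carriers[[plan$variant_id[i]]] <- sort(sample(samples, k))
    }
  }

  # MAF rows: one per variant per carrier sample
  set.seed(.sub_seed(config$seed, 2))
  maf_rows <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    carr <- carriers[[plan$variant_id[i]]]
    if (is.null(carr) || length(carr) == 0) next
    m <- length(carr)
    t_depth <- .clip_depth(stats::rpois(m, config$depth_mean))
    n_depth <- .clip_depth(stats::rpois(m, config$depth_mean))
    t_alt <- stats::rbinom(m, t_depth, plan$tumor_vaf[i])
    n_alt <- stats::rbinom(m, n_depth, plan$blood_vaf[i])
    lod <- stats::runif(m, 4.01, 75.10)
    bq <- stats::runif(m, 10, 40)
    if (plan$label[i] == "noise" && config$qc_fail_fraction > 0) {
      fail <- stats::runif(m) < config$qc_fail_fraction
      which_field <- stats::runif(m) < 0.5
      lod[fail & which_field] <- stats::runif(sum(fail & which_field), 0.5, 3.9)
      bq[fail & !which_field] <- stats::runif(sum(fail & !which_field), 1, 9.9)
    }
    maf_rows[[i]] <- data.frame(
      Hugo_Symbol = plan$gene[i], Chromosome = plan$chrom[i],
      Start_Position = plan$pos[i], Reference_Allele = plan$ref[i],
      Tumor_Seq_Allele2 = plan$alt[i],
      Variant_Classification = plan$consequence[i],
      Protein_Change = plan$protein_change[i],
      Tumor_Sample_Barcode = carr,
      t_ref_count = t_depth - t_alt, t_alt_count = t_alt,
      n_ref_count = n_depth - n_alt, n_alt_count = n_alt,
      lod = round(lod, 2), base_quality = round(bq, 1),
      stringsAsFactors = FALSE
    )
  }
  maf_rows <- maf_rows[!vapply(maf_rows, is.null, logical(1))]
  maf <- if (length(maf_rows) > 0) do.call(rbind, maf_rows) else {
    data.frame(Hugo_Symbol = character(0), Chromosome = character(0),
               Start_Position = integer(0), Reference_Allele = character(0),
               Tumor_Seq_Allele2 = character(0),
               Variant_Classification = character(0),
               Protein_Change = character(0),
               Tumor_Sample_Barcode = character(0),
               t_ref_count = integer(0), t_alt_count = integer(0),
               n_ref_count = integer(0), n_alt_count = integer(0),
               lod = numeric(0), base_quality = numeric(0),
               stringsAsFactors = FALSE)
  }
  maf <- suppressMessages(as_variant_table(maf))

  # annotations (stream 3)
  set.seed(.sub_seed(config$seed, 3))
  ann <- if (nrow(plan) > 0) {
    freq <- numeric(nrow(plan))
    sift <- polyphen <- character(nrow(plan))
    for (i in seq_len(nrow(plan))) {
      lab <- plan$label[i]
      if (lab == "germline") {
        freq[i] <- stats::runif(1, 0.01, 0.3)
        sift[i] <- "tolerated"; polyphen[i] <- "benign"
      } else if (lab == "noise") {
        freq[i] <- sample(c(0, stats::runif(1, 1e-6, 5e-5)), 1)
        sift[i] <- "unknown"; polyphen[i] <- "unknown"
      } else if (lab == "passenger:gnomad") {
        freq[i] <- 0.05
        sift[i] <- "deleterious"; polyphen[i] <- "probably_damaging"
      } else if (lab == "passenger:deleterious") {
        freq[i] <- sample(c(0, stats::runif(1, 1e-6, 5e-5)), 1)
        sift[i] <- "tolerated"; polyphen[i] <- "benign"
      } else {
        # planted and remaining passengers: rare and damaging by consensus
        freq[i] <- sample(c(0, stats::runif(1, 1e-6, 5e-5)), 1)
        sift[i] <- "deleterious"
        polyphen[i] <- sample(c("probably_damaging", "possibly_damaging"), 1,
                              prob = c(0.8, 0.2))
      }
    }
    data.frame(variant_id = plan$variant_id, population_freq = freq,
               sift = sift, polyphen = polyphen, stringsAsFactors = FALSE)
  } else {
    data.frame(variant_id = character(0), population_freq = numeric(0),
               sift = character(0), polyphen = character(0),
               stringsAsFactors = FALSE)
  }

  # gene metadata: every gene appearing anywhere, hypermutable iff Ig-prefixed
  all_genes <- unique(c(sprintf("SYNG%03d", seq_len(config$n_genes)),
                        plan$gene))
  all_genes <- all_genes[order(all_genes)]
  gene_meta <- data.frame(gene = all_genes,
                          hypermutable = default_hypermutable(all_genes),
                          stringsAsFactors = FALSE)

  # single-cell matrix (stream 4)
  set.seed(.sub_seed(config$seed, 4))
  cells <- .simulate_cells(config, all_genes, plan)

  # bulk expression (stream 5)
  set.seed(.sub_seed(config$seed, 5))
  bulk <- NULL
  de_genes <- list()
  if (length(all_genes) > 0 && length(samples) > 0) {
    baseline <- stats::runif(length(all_genes), 4, 8)
    bulk <- matrix(stats::rnorm(length(all_genes) * length(samples),
                                mean = baseline, sd = 1),
                   nrow = length(all_genes), ncol = length(samples),
                   dimnames = list(all_genes, samples))
    planted_ids <- plan$variant_id[plan$label == "planted_ch"]
    for (v in planted_ids) {
      targets <- sample(all_genes, min(config$de_genes_per_variant,
                                       length(all_genes)))
      de_genes[[v]] <- targets
      carr <- carriers[[v]]
      bulk[targets, carr] <- bulk[targets, carr] + config$de_effect_size
    }
  } else {
    bulk <- matrix(numeric(0), nrow = length(all_genes), ncol = 0,
                   dimnames = list(all_genes, NULL))
  }

  # pathway map (stream 6): each gene in 1-2 top-level pathways
  set.seed(.sub_seed(config$seed, 6))
  vocab <- c("Immune system", "Signal transduction", "Metabolism",
             "Gene expression", "Metabolism of proteins",
             "Developmental Biology", "Disease", "Vesicle-mediated transport",
             "Cell cycle", "Homeostasis", "Cellular response to stress",
             "Programmed cell death")
  pathway_map <- if (length(all_genes) > 0) {
    rows <- lapply(all_genes, function(g) {
      k <- sample(1:2, 1)
      data.frame(gene = g, pathway = sample(vocab, k),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  } else {
    data.frame(gene = character(0), pathway = character(0),
               stringsAsFactors = FALSE)
  }

  truth <- list(
    labels = stats::setNames(plan$label, plan$variant_id),
    carriers = carriers,
    true_vaf = plan[, c("variant_id", "gene", "label", "blood_vaf",
                        "tumor_vaf", "carrier_fraction")],
    de_genes = de_genes
  )
  structure(list(maf = maf, annotations = ann, gene_meta = gene_meta,
                 cells = cells, bulk = bulk, pathway_map = pathway_map,
                 truth = truth, samples = samples, config = config),
            class = "ch_cohort")
}

# Sparse cell x gene simulation: per-gene expressing-cell probability, counts
# Poisson(1)+1 in expressing cells. Genes hosting planted or passenger
# variants (other than passenger:expression) are guaranteed at least one
# immune expressing cell; the passenger:expression gene is expressed only in
# non-immune cells.
.simulate_cells <- function(config, all_genes, plan) {
  n_cells <- config$n_cells
  if (n_cells == 0 || length(all_genes) == 0) {
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(length(all_genes), n_cells))
    return(cell_matrix(m, all_genes,
                       if (n_cells > 0) sprintf("CELL%05d", seq_len(n_cells))
                       else character(0),
                       character(n_cells)))
  }
  comp <- c("T-cells" = 0.33, "Myeloid" = 0.20, "B-cells" = 0.08,
            "Plasmablasts" = 0.02, "Cancer Epithelial" = 0.20,
            "Normal Epithelial" = 0.05, "CAFs" = 0.06,
            "Endothelial" = 0.04, "PVL" = 0.02)
  cell_type <- sample(names(comp), n_cells, replace = TRUE, prob = comp)
  barcodes <- sprintf("CELL%05d", seq_len(n_cells))
  immune <- unname(default_immune_labels()[cell_type])
  immune[is.na(immune)] <- FALSE

  silent_gene <- plan$gene[plan$label == "passenger:expression"]
  variant_genes <- setdiff(plan$gene[plan$label == "planted_ch" |
                                       startsWith(plan$label, "passenger:")],
                           silent_gene)
  ii <- jj <- integer(0)
  xx <- numeric(0)
  for (g in seq_along(all_genes)) {
    gname <- all_genes[g]
    p_expr <- stats::runif(1, 0.05, 0.30)
    if (gname %in% silent_gene) {
      pool <- which(!immune)
    } else {
      pool <- seq_len(n_cells)
    }
    k <- stats::rbinom(1, length(pool), p_expr)
    if (k == 0 && !(gname %in% silent_gene) && gname %in% variant_genes) k <- 1
    if (k == 0) next
    cols <- sample(pool, k)
    if (gname %in% variant_genes && !any(immune[cols]) && any(immune)) {
      cols <- c(cols, sample(which(immune), 1))
    }
    ii <- c(ii, rep(g, length(cols)))
    jj <- c(jj, cols)
    xx <- c(xx, stats::rpois(length(cols), 1) + 1)
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(all_genes), n_cells))
  cell_matrix(m, all_genes, barcodes, cell_type)
}

#' Write a cohort to a fixture bundle on disk
#'
#' Emits the MAF-dialect TSV, annotation TSV, gene-metadata TSV, the
#' MatrixMarket single-cell triplet with cell-type labels, the bulk
#' expression TSV, the pathway-map TSV, and the ground truth as JSON.
#'
#' @param cohort a `"ch_cohort"` from [simulate_cohort()].
#' @param directory output directory (created if needed).
#' @return manifest `data.frame` with columns `file` and `n` (data rows, or
#'   cells for the single-cell matrix), invisibly returned paths attached.
#' @export
write_fixture_bundle <- function(cohort, directory) {
  stopifnot(inherits(cohort, "ch_cohort"))
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE)
  if (!ok || file.access(directory, 2) != 0) {
    stop("directory not writable: ", directory)
  }
  scdir <- file.path(directory, "scrna")
  dir.create(scdir, showWarnings = FALSE)

  p_maf <- file.path(directory, "variants.maf.tsv")
  write_maf(cohort$maf, p_maf)

  p_ann <- file.path(directory, "annotations.tsv")
  utils::write.table(cohort$annotations, p_ann, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p_gm <- file.path(directory, "gene_meta.tsv")
  utils::write.table(cohort$gene_meta, p_gm, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  p_mtx <- file.path(scdir, "matrix.mtx")
  Matrix::writeMM(cohort$cells$counts, p_mtx)
  p_genes <- file.path(scdir, "genes.tsv")
  writeLines(cohort$cells$genes, p_genes)
  p_bc <- file.path(scdir, "barcodes.tsv")
  writeLines(cohort$cells$barcodes, p_bc)
  p_ct <- file.path(scdir, "celltypes.tsv")
  utils::write.table(
    data.frame(barcode = cohort$cells$barcodes,
               cell_type = cohort$cells$cell_type,
               stringsAsFactors = FALSE),
    p_ct, sep = "\t", quote = FALSE, row.names = FALSE)

  p_bulk <- file.path(directory, "bulk_expression.tsv")
  gnames <- rownames(cohort$bulk)
  bulk_df <- data.frame(gene = if (is.null(gnames)) character(0) else gnames,
                        stringsAsFactors = FALSE)
  if (ncol(cohort$bulk) > 0) {
    bulk_df <- cbind(bulk_df, as.data.frame(cohort$bulk,
                                            check.names = FALSE))
  }
  utils::write.table(bulk_df, p_bulk, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  p_pw <- file.path(directory, "pathway_map.tsv")
  utils::write.table(cohort$pathway_map, p_pw, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  p_truth <- file.path(directory, "ground_truth.json")
  jsonlite::write_json(
    list(labels = as.list(cohort$truth$labels),
         carriers = cohort$truth$carriers,
         true_vaf = cohort$truth$true_vaf,
         de_genes = cohort$truth$de_genes,
         samples = cohort$samples),
    p_truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- data.frame(
    file = c("variants.maf.tsv", "annotations.tsv", "gene_meta.tsv",
             "scrna/matrix.mtx", "scrna/genes.tsv", "scrna/barcodes.tsv",
             "scrna/celltypes.tsv", "bulk_expression.tsv", "pathway_map.tsv",
             "ground_truth.json"),
    n = c(nrow(cohort$maf), nrow(cohort$annotations), nrow(cohort$gene_meta),
          ncol(cohort$cells$counts), length(cohort$cells$genes),
          length(cohort$cells$barcodes), length(cohort$cells$barcodes),
          nrow(cohort$bulk), nrow(cohort$pathway_map), length(cohort$truth$labels)),
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(directory, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}

#' Read a fixture bundle written by [write_fixture_bundle()]
#'
#' @param directory bundle directory.
#' @return a list with `maf`, `annotations`, `gene_meta`, `cells`, `bulk`,
#'   `pathway_map`, `truth`, `samples`.
#' @export
read_fixture_bundle <- function(directory) {
  scdir <- file.path(directory, "scrna")
  truth <- jsonlite::fromJSON(file.path(directory, "ground_truth.json"))
  list(
    maf = read_maf(file.path(directory, "variants.maf.tsv")),
    annotations = utils::read.delim(file.path(directory, "annotations.tsv"),
                                    stringsAsFactors = FALSE),
    gene_meta = utils::read.delim(file.path(directory, "gene_meta.tsv"),
                                  stringsAsFactors = FALSE),
    cells = read_cell_matrix(file.path(scdir, "matrix.mtx"),
                             file.path(scdir, "barcodes.tsv"),
                             file.path(scdir, "genes.tsv"),
                             file.path(scdir, "celltypes.tsv")),
    bulk = read_bulk_expression(file.path(directory, "bulk_expression.tsv")),
    pathway_map = read_pathway_map(file.path(directory, "pathway_map.tsv")),
    truth = truth,
    samples = truth$samples
  )
}
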