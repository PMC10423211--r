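---
title: "Identifying clonal hematopoietic mutations in tumor-infiltrating immune cells"
author: "chtii"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying clonal hematopoietic mutations in tumor-infiltrating immune cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chtii)
```

## The model

Normal hematopoiesis constantly replaces immune cells from stem cells, so
somatic mutations rarely accumulate in a meaningful fraction of a person's
immune compartment. Clonal hematopoiesis breaks that assumption: a mutation
conferring a self-renewal advantage on a hematopoietic stem or progenitor
cell expands into a clone that can make up several percent of peripheral
blood. Secondary mutations arising inside that clone are then carried by a
substantial fraction of circulating — and tumor-infiltrating — immune cells.
A secondary mutation that damages an immune-response gene cannot *drive*
tumor growth (it is not in the tumor), but it can *facilitate* it by blunting
the anti-tumor response of the infiltrate.

The observable signature in a matched tumor/blood exome pair is a variant
present at low-but-clonal allele fraction in **both** samples. With
VAF = alt/(ref + alt):

* **VAF > 2% in blood** marks clonal expansion. Below 2%, sequencing error
  and trace circulating tumor / cell-free DNA (up to ~1% of blood DNA) can
  explain the signal.
* **VAF < 25% in both samples** excludes heterozygous germline variants,
  which cluster at 50% (and at 100% when homozygous).
* Requiring the window **in both samples** ties the tumor-sample signal to
  the infiltrating immune cells: the same variant arising independently in
  blood and tumor tissue is highly improbable, so a shared low-fraction
  variant was acquired in blood and carried into the tumor by TII cells.

Both inequalities are strict (`>` 2%, `<` 25%): the thresholds themselves
are excluded, matching the wording of the criteria the window encodes.

The funnel around this core classification is exclusion-biased by design —
it prefers losing genuine immunosuppressive mutations over admitting
passengers. A candidate must additionally:

1. be **protein altering** (missense, nonsense, frame-shift or in-frame
   indel, splice site) — synonymous, intronic, intergenic and UTR variants
   are far less likely to be pathogenic;
2. recur in **more than 5% of cohort samples**. Immune cells are not
   hypermutating tumor cells; a population-rare variant that independently
   recurs in many patients' blood is unlikely to be a neutral passenger;
3. be **rare in the population** (allele frequency < 10⁻⁴ in a
   gnomAD-style reference) — common variants are tolerated by selection;
4. not sit in a **hypermutable family** (immunoglobulin, Ig-like receptor,
   histocompatibility antigen, T-cell receptor loci), which vary naturally
   during immune response;
5. be **predicted deleterious**: called *deleterious* by SIFT **and**
   *damaging* by PolyPhen, or be truncating/frame-shift/splice (classes the
   predictors do not score);
6. lie in a gene **expressed in immune cells** of the tumor
   microenvironment, established from a labelled single-cell count matrix;
7. show **expression consequences**: genes significantly differentially
   expressed (Benjamini–Hochberg q < 0.05, two-sided Welch *t*) between
   carrier and non-carrier samples, tabulated by top-level pathway.

The final published-evidence curation step (which in the motivating study
narrowed 95 computational candidates to 8) is a literature review and is not
computable; the pipeline therefore ends at the computable stages and accepts
an optional user-supplied allowlist instead of pretending to automate it.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `min_lod` | 4.0 | log₁₀ odds | caller confidence ≥ 10⁴:1; "minimum" is inclusive, so exactly 4.0 passes |
| `min_base_quality` | 10 | Phred | standard low-quality cutoff, inclusive |
| `vaf_lower` | 0.02 | fraction | clonal-hematopoiesis convention; also clears cfDNA contamination (strict) |
| `vaf_upper` | 0.25 | fraction | germline exclusion with margin below 0.5 (strict) |
| `min_sample_fraction` | 0.05 | fraction of cohort | strict `>`; recurrence threshold for non-passengers |
| `max_population_freq` | 1e-4 | allele fraction | strict `<`; gnomAD-style rarity |
| `ci_level` / `ci_method` | 0.95 / wilson | — | VAF interval; wald and clopper-pearson available |
| `fdr` | 0.05 | — | strict `<` on BH q values |

## Numerical and design choices

* **VAF denominator** is ref + alt of the variant's two alleles, not total
  site depth. The MAF dialect carries per-allele counts, and this makes the
  VAF an exact ratio of two integers. The alternative (total depth) would
  differ only at multi-allelic sites, which are out of scope.
* **Wilson rather than Wald** intervals by default: at the boundary counts
  that matter here (few alt reads at the 2% edge) Wald collapses to
  degenerate intervals while Wilson stays inside (0, 1) and keeps close to
  nominal coverage. The method is configurable (`wald`,
  `clopper-pearson`) because only "a binomial proportion interval" is
  specified by the procedure this implements, not which one.
* **VAF moments over detected samples only.** The per-variant mean ± SD is
  computed over the samples in which the variant passes the window (sample
  SD, n − 1); a single-carrier variant reports no SD rather than 0.
* **Missing annotation fails the rarity filter** (conservative, logged):
  exclusion-biased, consistent with the funnel's purpose.
* **PolyPhen "possibly damaging" counts as damaging**; the consensus rule
  names "damaging" without distinguishing grades. Configurable.
* **Splice-site variants are auto-deleterious** alongside truncating and
  frame-shift classes, because SIFT/PolyPhen do not score them. Configurable.
* **"Expressed" means raw count > 0** in the single-cell matrix — the
  reported quantities are integer cell counts, implying presence/absence on
  raw counts, so no normalization is applied.
* **Immune fraction denominator**: the reported ratio style
  "23% (2,810/12,075)" divides immune-expressing cells by *all* expressing
  cells. The summary also reports the fraction of immune cells expressing
  the gene (`fraction_of_immune_cells`) since the prose description of such
  tables is ambiguous; the ratio-of-expressing-cells version is the one the
  printed arithmetic pins down, and it is what `format_candidate_row()`
  prints.
* **Untestable genes** (zero variance in both groups) are excluded from the
  BH correction denominator m — an untestable hypothesis should not dilute
  the correction. They are counted and reported.
* **Funnel bookkeeping**: per-sample calls collapse to one unit per distinct
  variant (chrom, pos, ref, alt) from the distinct-variant tally onward.
  Stage percentages are computed from the actual counts with round-half-even
  at the requested precision; a published cascade whose printed percentage
  disagrees with its own counts is not special-cased.
* **Reason-code precedence**: when a call fails the window in both samples
  on different sides, the below-lower code wins over the germline-range code
  (deterministic; no ordering was prescribed).
* **Filter order**: sample fraction → rarity → hypermutable →
  deleteriousness → immune expression, following the narrative order of the
  funnel this reproduces. The per-variant filters commute (tested), so the
  order affects only the per-stage counts in the report, never the final
  candidate set.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` produces all six pipeline inputs with known ground
truth. Its defaults are a scaled-down statement of the regime the method is
meant for:

* 200 matched tumor/blood pairs (a desk-scale stand-in for cohorts of ~1,000);
* 8 planted CH-in-TII variants — the number of candidates the motivating
  analysis ended with — with true VAFs uniform on (0.08, 0.18) in both
  samples (printed candidate VAF means ran 0.05–0.18) and carrier fractions
  uniform on (0.07, 0.15) (printed sample fractions: 7.05–11.56%);
* 15 germline variants at true VAF 0.5 and 25 noise variants below 2%, the
  latter with half their calls failing the LOD/base-quality gate;
* 5 passenger variants, one per stage-3 filter, each constructed to fail
  exactly its named filter (e.g. population frequency 0.05 for the rarity
  passenger, carrier fraction 0.02 for the cohort-frequency passenger, a
  gene silent in immune cells for the expression passenger);
* read depth Poisson(150), clipped to [16, 725] — the depth range observed
  in deep matched exome data; alt reads Binomial(depth, true VAF);
* 2,000 cells with a breast-tumor-microenvironment-like composition
  (T-cells 33%, myeloid 20%, B-cells 8%, plasmablasts 2%, the rest
  epithelial/stromal/endothelial);
* bulk expression Gaussian on a log-like scale (per-gene baseline
  U(4, 8), SD 1), with a 1-SD shift in carriers for 10 target genes per
  planted variant — so the Welch-*t* assumptions hold by construction.

One RNG stream per output table is derived from the master seed, so adding
variants to one table does not perturb the others; a fixed seed yields
byte-identical bundles.

The generator deliberately does **not** model: read-level artifacts (no
FASTQ/BAM), mapping bias, multi-allelic sites, clonal phylogenies,
CHIP-driver versus secondary mutations as distinct processes, per-variant
depth heterogeneity beyond Poisson (the true depth distribution of exome
cohorts is only known to range 16–725 here; Poisson is a documented
stand-in), count-distributed bulk expression, or cell-type misannotation.
A green recovery test therefore establishes that the funnel's logic and
thresholds behave as specified on data satisfying its assumptions — not that
the method is robust to caller artifacts or annotation error in real
cohorts.

## Recovery behaviour

On a well-separated configuration (true VAFs ≈ 0.12, carrier fraction
≈ 0.08, depth 500) the pipeline recovers exactly the planted variant set —
precision and recall 1.0 — and each passenger is eliminated at, and only at,
its named stage. At the default depth of 150 the same holds for the default
VAF ranges; misclassification of individual carrier calls appears when true
VAFs approach the window edges (e.g. 0.04–0.08 at depth 50) and shrinks with
depth, as the binomial sampling variance of the empirical VAF contracts.

## Known limitations

* Sample fractions require the true cohort size (`n_cohort`); when it is
  not supplied the number of distinct samples in the variant table is used,
  which under-counts cohorts containing samples with no calls.
* The DE stage needs at least two carriers and two non-carriers with bulk
  expression; candidates outside that range are reported without DE results.
* Annotation (population frequency, SIFT, PolyPhen) and cell-type labels
  are consumed as given; the package neither recomputes population
  frequencies nor runs effect predictors, and label quality bounds the
  expression filter.
* The pathway tabulation is a count of SDE genes per supplied top-level
  pathway label, not an over-representation statistic: no enrichment p value
  is attached, by scope.
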