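# clonotrack

Single-cell T cell receptor (TCR) clonotype tracking and repertoire
analysis in R.

## The problem

In transplantation immunology, the T cell clones that drive
graft-versus-host disease (GVHD) can be identified *in vitro*: in a
mixed lymphocyte reaction (MLR), responder T cells that proliferate
against donor-mismatched stimulators dilute a division-tracking dye, and
the highly-proliferated (CTV-Low) sorted fraction is enriched for
alloreactive clones. Single-cell V(D)J sequencing gives each T cell a
clonal barcode — the CDR3 junction of its TCR — so those same clones can
be re-identified later among T cells infiltrating GVHD target organs
(spleen, liver) and their transcriptional program examined. For
organisms without a vendor-curated V(D)J reference (such as rhesus
macaque), this additionally requires building and quality-controlling a
custom segment reference and the enrichment primers that target the TCR
constant regions.

`clonotrack` implements this downstream analysis end to end:

* **V(D)J reference QC** — parse pipe-delimited segment FASTA
  references, scan segments for premature stop codons (TAA/TAG/TGA in
  frame, terminal stop exempt), frameshift-incompatible lengths,
  ambiguous bases; audit nested-PCR primers against constant regions
  (Hamming matching, 3′-to-3′ nested distances, Wallace-rule Tm).
* **10x-style IO** — `filtered_contig_annotations` CSV tables and
  MatrixMarket expression triplets; per-sample chain reconstruction
  rates; VDJ-to-expression barcode matching.
* **Clonotyping** — cells grouped by CDR3 nucleotide identity (alpha,
  beta, or paired mode), cross-sample occurrence matrices, clone
  tracking, and MLR+/MLR− tagging of tissue cells against an
  allo-proliferating clonotype set.
* **Repertoire statistics** — Shannon diversity
  `H = -Σ pᵢ ln pᵢ` with the analytic variance
  `var H = (Σ pᵢ ln² pᵢ − H²)/N + (S−1)/(2N²)`, the Hutcheson t-test
  `t = (H₁−H₂)/√(v₁+v₂)` with Welch-style degrees of freedom, and the
  classical Morisita overlap
  `MI = 2 Σ xᵢyᵢ / ((λₓ+λ_y) Nₓ N_y)`, `λₓ = Σ xᵢ(xᵢ−1)/(Nₓ(Nₓ−1))`
  (Horn variant available).
* **Expression pipeline** — QC filtering (500–6,000 genes, 1,800–40,000
  transcripts, mito fraction < 5%, genes in ≥ 5 cells), log-CP10K
  normalization (Pearson-residual option), per-gene Wilcoxon rank-sum
  differential expression with Bonferroni adjustment, and signed
  gene-signature scoring from GMT files.
* **Synthetic data** — a deterministic generator for repertoires, MLR
  sorted fractions with planted alloreactive expansion, tissue samples,
  contig tables with chain dropout, and negative-binomial expression
  with planted effects, all with ground truth.

## Worked example

Simulate one donor's MLR at the default study conditions, compute
diversity and overlap, and tag a simulated liver sample:

```r
library(clonotrack)

cfg <- sim_config(seed = 7)          # 30k clones, 5k cells/fraction,
rep <- sample_repertoire(cfg)        # 1% alloreactive, expansion 1/5/50
mlr <- simulate_mlr(rep, cfg)

contigs <- lapply(names(mlr$samples), function(s)
  emit_contig_csv(mlr$samples[[s]], rep, cfg, sample_id = s))

chain_summary(contigs[[1]])
#>   sample_id n_cells pct_cdr3_alpha pct_cdr3_beta pct_productive_pair
#> 1     blood    4795       63.04484      93.78519            56.83003

occ <- occurrence_matrix(lapply(contigs, assign_clonotypes, mode = "alpha_nt"))
for (s in colnames(occ$counts)) {
  d <- shannon_index(clonotype_counts(occ, s))
  cat(sprintf("%-9s H = %.3f (S = %d)\n", s, d$H, d$S))
}
#> blood     H = 7.895 (S = 2773)
#> ctv_high  H = 7.883 (S = 2742)
#> ctv_mid   H = 7.861 (S = 2698)
#> ctv_low   H = 7.349 (S = 2101)

hutcheson_test(clonotype_counts(occ, "ctv_low"),
               clonotype_counts(occ, "ctv_high"))
#> 	Hutcheson t-test for two Shannon diversity indices
#> t = -21.954, df = 5198.6, p-value < 2.2e-16

round(pairwise_overlap(occ)["blood", ], 3)
#>    blood ctv_high  ctv_mid  ctv_low
#>    6.514    0.969    0.834    0.131
```

The diversity ordering (CTV-Low < CTV-Mid < CTV-High) reflects the
planted clonal expansion in the proliferated fraction, and blood
overlaps the non-proliferated CTV-High fraction most — exactly the
structure such experiments show. (Classical Morisita self-similarity on
singleton-rich repertoires exceeds 1; the off-diagonal comparisons are
the meaningful entries.)

Tagging a tissue sample against the planted alloreactive clone set
recovers it exactly, because synthetic CDR3s are unique by construction:

```r
keys   <- clone_keys(rep, mlr$truth$allo_clones, mode = "paired_nt")
tissue <- simulate_tissue(rep, mlr$truth$allo_clones, n_cells = 2000,
                          n_allo_cells = 60, seed = 8)
tags   <- tag_alloreactive(
  emit_contig_csv(tissue, rep, sim_config(seed = 7, p_alpha = 1, p_beta = 1),
                  "liver"), keys, mode = "paired_nt")
attr(tags, "label_counts")
#>   MLR_plus  MLR_minus unassigned
#>         60       1940          0
```

Real references can be audited directly; the nine constant-region
segments shipped in `inst/extdata` give:

```r
ref <- parse_imgt_fasta(system.file("extdata",
         "rhesus_cregion_segments.fasta", package = "clonotrack"))
filter_reference(ref)$kept$records$allele
#> [1] "TRAC*02" "TRAC*03" "TRAC*04" "TRAC*05" "TRAC*06"
```

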