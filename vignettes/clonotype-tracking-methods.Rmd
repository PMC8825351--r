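---
title: "Methods: single-cell TCR clonotype tracking and repertoire statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell TCR clonotype tracking and repertoire statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonotrack)
```

## Scope and model of the data

`clonotrack` implements the downstream analysis of a single-cell TCR
(scTCR-Seq) experiment built on a custom V(D)J reference, of the kind used
to identify alloreactive T cell clonotypes in a mixed lymphocyte reaction
(MLR) and re-identify them in graft-versus-host disease (GVHD) target
organs. The package covers five analysis stages plus a synthetic-data
generator:

1. **Reference construction and QC** — parsing pipe-delimited V(D)J
   segment FASTA files, screening segments for premature stop codons,
   frameshift-incompatible lengths, ambiguous bases and short sequences,
   and auditing nested-PCR enrichment primers against constant regions.
2. **10x-style IO** — contig annotation tables (one assembled chain per
   row) and MatrixMarket expression triplets, with per-sample chain
   reconstruction summaries and VDJ-to-expression barcode matching.
3. **Clonotyping** — cells grouped by the exact CDR3 nucleotide sequence
   of the alpha chain, the beta chain, or both; cross-sample occurrence
   matrices; clone tracking; MLR+/MLR− tissue-cell tagging.
4. **Repertoire statistics** — Shannon diversity with an analytic
   variance, the Hutcheson t-test for comparing two diversities, and
   Morisita repertoire overlap.
5. **Expression pipeline** — QC filtering, library-size normalization,
   per-gene Wilcoxon differential expression between MLR+ and MLR−
   cells, and signed gene-signature scoring.

Upstream read alignment and contig assembly (the job of the vendor
pipeline), graph clustering, dimensionality reduction, and latent-space
signature frameworks are deliberately out of scope; synthetic expression
data are pre-gated to T cells. The package's interface is its exported
functions together with `scripts/acceptance.R`; the operations are
scriptable directly from R, so no separate command-line wrapper is
shipped.

## Reference QC

A segment reference uses an 8-field pipe-delimited FASTA header
(`record id | allele + source note | gene | region | chain type | chain |
isotype | allele number`). `qc_segment()` walks complete codons from a
configurable frame offset and flags internal TAA/TAG/TGA codons; a stop
in the final complete codon is treated as the natural terminal stop of a
constant region and not flagged. Constant regions whose length minus the
frame offset is not a multiple of 3 receive a `FRAME_LENGTH` flag
(frameshift relative to the annotated length) unless declared partial.
`filter_reference()` removes, by default, segments flagged
`PREMATURE_STOP` or `FRAME_LENGTH` — the two error classes that break
downstream translation — while ambiguous bases and short segments only
warn.

The reading frame of a constant region is implied by the upstream J
junction and is not recorded in the header; the default frame offset is
0 with a per-region override. On the nine constant-region records
bundled in `inst/extdata` (six TRAC alleles, three TRBC alleles), the
frame-0 policy keeps five segments; notably the longest TRAC allele is
clean only in frame 2, and two TRBC alleles carry an apparent single-base
deletion relative to the first, so they fail both the stop scan and the
length check. The package reports these QC verdicts as computed rather
than forcing any published total, since the full published reference
(hundreds of V/J segments) is not shipped.

Primer audits use Hamming-only matching (`find_primer_sites()`, backed
by `Biostrings::matchPattern`) on both strands; indel-tolerant matching
was rejected so the naive sliding-window oracle used in the tests stays
exact. Coordinates are 0-based half-open on the segment's sense strand;
a reverse primer is a strand flag (`antisense`), never a negative
coordinate. `nested_distance()` measures between primer 3′ ends (the
biologically meaningful endpoints for nested PCR): on the printed TRAC
constant region the v1 alpha outer/inner pair sits 249 bp apart, which
the package reports as computed — the protocol's printed 297 bp does not
state its measurement endpoints, and the inner primer itself matches the
printed sequence only at Hamming distance 2 (both beta outer primers
have no match at all within the printed constant regions, consistent
with binding across an exon junction). `primer_properties()` implements
the Wallace rule (`2(A+T) + 4(G+C)` °C) and GC fraction, the two quick
screens used when matching custom primers to a kit's forward primers;
thermodynamic nearest-neighbour Tm is a non-goal.

## Clonotyping rules

A cell is assigned to a clonotype iff it has the chain(s) the mode
requires with a CDR3 nucleotide call. With multiple contigs of one
chain, the highest-UMI contig wins, ties broken by lexicographically
smallest contig id — this makes assignment invariant to input row order,
which is asserted as a property test. Cells carrying extra same-chain
contigs are counted (`multi_chain_cells`) as a doublet indicator but not
removed. Single-chain modes intentionally allow clonotype keys to be
shared across donors: cross-donor sharing is exactly what the Morisita
specificity analysis measures, and vendor default clonotype calls (which
forbid cross-donor sharing) cannot express it.

For MLR+/MLR− tagging the default mode is `paired_nt` (both CDR3s must
match), with single-chain modes available. The allo-proliferating set
can be defined two ways: from ground truth in simulations
(`clone_keys()`), or operationally as every clonotype with at least
`min_cells` cells in the highly-proliferated fraction
(`alloreactive_keys()`, default 2 — a singleton is weak evidence of
proliferation, and no published threshold exists). The three labels
(`MLR_plus`, `MLR_minus`, `unassigned`) always partition the cells.

## Diversity and overlap statistics

All logarithms are natural; diversities are in nats. For a count vector
with proportions $p_i$, $N$ cells and $S$ observed clonotypes:

$$H = -\sum_i p_i \ln p_i, \qquad
\widehat{\mathrm{var}}\,H = \frac{\sum_i p_i \ln^2 p_i - H^2}{N}
 + \frac{S-1}{2N^2}.$$

The Hutcheson t-test compares two Shannon indices using these variances,
$t = (H_1 - H_2)/\sqrt{v_1 + v_2}$, with Welch-style effective degrees
of freedom $(v_1+v_2)^2 / (v_1^2/N_1 + v_2^2/N_2)$, floored at 1, and a
two-sided p-value. Two identical zero-variance samples are defined as
$t = 0$, $p = 1$ rather than an error.

Repertoire overlap uses the classical Morisita index on integer cell
counts,

$$MI = \frac{2\sum_i x_i y_i}{(\lambda_x + \lambda_y) N_x N_y}, \qquad
\lambda_x = \frac{\sum_i x_i (x_i - 1)}{N_x (N_x - 1)},$$

which is 0 for disjoint repertoires and ≈ 1 (it can slightly exceed 1)
for identical ones. When both samples are all singletons the classical
denominator vanishes and the Horn variant
($\lambda = \sum_i (x_i/N_x)^2$) is substituted, flagged in the result;
the Horn variant can also be requested directly. Raw cell counts (not
UMI-weighted) are used, matching how clonotype tables are built. The
implementation is checked against a brute-force double-sum oracle to
1e-12 and, where the index is ≤ 1, against `vegan`'s Morisita
dissimilarity (vegan clamps similarity at 1, so values above 1 — e.g.
$MI((2,2),(2,2)) = 1.5$ — are outside its range by design).

## Expression pipeline

`qc_filter()` applies the study thresholds: genes present in fewer than
5 cells removed first; then cells retained with 500–6,000 genes detected
and 1,800–40,000 transcripts (both read as closed intervals) and a
mitochondrial fraction strictly below 5% ("less than 5%"). Mitochondrial
genes are identified by a configurable name-prefix list, since
annotations for non-model organisms vary. The filter is idempotent on
the cell dimension; gene filtering can cascade once after cells are
removed, so idempotence is asserted after two applications.

The default normalization is log counts-per-10k ($\log(1+x)$ after
scaling each cell to 10,000 counts), with per-gene Pearson residuals
under a fixed-dispersion negative-binomial null as a recorded
alternative. A variance-stabilizing regression normalization is
deliberately not re-implemented: the downstream tests are rank-based
(Wilcoxon) and therefore robust to the normalization family, and the
variant used is recorded in the output metadata.

Differential expression is a per-gene two-sided Wilcoxon rank-sum test
(normal approximation with tie correction, via `stats::wilcox.test`),
with fold changes computed on de-logged means with $\varepsilon =
10^{-9}$, Bonferroni adjustment by default (Benjamini–Hochberg
available) and significance at adjusted $p < 0.05$. Signature scores are
signed means of per-gene z-scored normalized expression,
$(\sum_{g \in \mathrm{pos}} z_{gc} - \sum_{g \in \mathrm{neg}} z_{gc}) /
n_\mathrm{present}$; zero-variance genes contribute 0, and genes absent
from the matrix are dropped and counted, which makes the score invariant
to adding absent genes. Group comparisons of scores are again Wilcoxon
tests.

## The synthetic-data generator

The generator encodes the study design so every stage is testable with
known ground truth and no downloads. Its defaults are the conditions
under which the package's acceptance properties are evaluated, chosen
once and documented here:

- **Repertoire**: 30,000 clones with lognormal frequencies
  ($\sigma = 0.8$; a Dirichlet model is available). This was calibrated
  once so that the Shannon diversity of a 5,000-cell sorted-fraction
  sample lands at the 7.5–9 nats scale reported for such fractions;
  heavier tails or fewer clones push sampled diversity well below that
  range. Each clone gets globally unique alpha and beta CDR3 junctions
  (random non-stop codons between the canonical cysteine codon and a
  fixed terminal codon, 10–16 aa). Junctions are generated, not
  recombination-modeled: uniqueness by construction is what the
  exact-recovery tagging tests require.
- **MLR fractions**: 5,000 cells per fraction; 1% of clones flagged
  alloreactive; expansion multipliers High/Mid/Low = 1/5/50 applied to
  alloreactive clone frequencies before renormalizing and drawing cells
  multinomially. This yields the observed qualitative structure:
  diversity ordered Low < Mid < High, blood most similar to the
  non-proliferated fraction, and a Hutcheson Low-vs-High p-value far
  below 0.01.
- **Chain dropout**: alpha detected with probability 0.6 and beta 0.9,
  independently per cell — the midpoints of reported per-sample
  reconstruction ranges (50–67% alpha, 83–94% beta). A correlation knob
  between chains is deferred. Dropout never deletes a cell from the
  sample, only its contig rows.
- **Expression**: negative-binomial counts (dispersion size = 2) over
  1,000 genes with lognormal gene means and lognormal cell size factors;
  a planted cytotoxic DE gene (named `GZMB`) at 2.5× in MLR+ cells; a
  20-gene planted signature at 1.12× — calibrated once so the
  signature-score shift between groups is about half a pooled standard
  deviation, the planted-shift magnitude the detection tests are run
  at; 10 `MT-`-prefixed genes carrying ~2% of counts. Optional outlier
  cells each violate exactly one QC threshold (high mito, low counts,
  high counts, low genes) to exercise the filter.

Determinism: every generator function derives its RNG stream from the
config seed (with fixed per-stage offsets), so identical configs give
byte-identical CSV/MTX outputs; this is asserted in the tests.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: V(D)J recombination biology
(segment usage biases, junctional indels, convergent recombination that
could break CDR3 uniqueness), transcriptome-wide co-expression and
cell-state structure, ambient RNA, doublets beyond a corrupt-contig
knob, and batch effects. Exact-recovery results (tagging sensitivity and
specificity of 1) are properties of the unique-CDR3 construction, not
claims about real repertoires, where single-chain matching can collide.

## Numerical choices and degenerate inputs

- Diversity requires $N \ge 1$ (all-zero vectors are errors); the
  Hutcheson test and Morisita require $N \ge 2$ per sample.
- Ranking ties in clone tracking and contig selection break
  lexicographically, making reports deterministic.
- `morisita` aligns named vectors on the union of labels; unnamed
  vectors must be position-aligned.
- Wilcoxon p-values use the normal approximation throughout (group
  sizes in this setting are hundreds of cells); constant genes get
  $p = 1$.
- QC with every cell removed raises an error carrying the per-criterion
  tally rather than returning an empty matrix.
- Problem sizes in the test-suite simulations (5,000 cells per fraction,
  20 replicate seeds for ordering/type-I properties, 500 + 500 cells and
  200–1,000 genes for expression designs) were chosen as the smallest
  sizes at which the targeted effects are unambiguous.

## Known limitations

- The reading frame of constant regions is a policy, not an annotation;
  QC verdicts for segments whose true frame differs from the configured
  one must be interpreted accordingly.
- Single-chain clonotype modes can in principle merge distinct clones
  sharing one CDR3; paired mode is the default for tagging for this
  reason.
- The Morisita heatmap uses raw cell counts; UMI weighting is not
  implemented.
- Signature gene symbols are matched verbatim against the matrix's gene
  namespace; no ortholog mapping is attempted.
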