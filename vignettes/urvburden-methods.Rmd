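---
title: "Methods: ultra-rare variant collapsing and gene-set burden analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ultra-rare variant collapsing and gene-set burden analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `urvburden`, the
assumptions it makes, the tunable parameters and their defaults, what the
synthetic cohort generator does and does not emulate, and the numerical and
design choices that were genuinely open.

## The model

The pipeline targets the regime of **small case-control exome cohorts**
(tens of samples per arm) and **ultra-rare variants** — variants absent
from, or extremely rare in, a large population frequency resource such as
gnomAD. In this regime per-variant association is powerless, so evidence is
aggregated at two levels.

**Gene level (collapsing analysis).** For each gene, each subject is coded
1 if they carry at least one qualifying variant anywhere in the gene and 0
otherwise; any number of variants collapses to "carrier". The carrier counts
form a 2×2 table (cases/controls × carrier/non-carrier) tested with the
exact conditional test: under the null of equal carrier probability and
conditioning on both margins, the case-carrier count is hypergeometric, and
the two-sided p-value sums the probabilities of all tables as or less
probable than the observed one (the minimum-likelihood rule). This
convention matters: a one-sided test would miss control-enriched genes
entirely, and the minimum-likelihood rule is what R's standard
implementation uses, so published values computed there reproduce exactly.
No multiple-testing correction is applied at this level — with n ≈ 35 + 38
no single gene can reach exome-wide significance, and the nominal hits are
not reported as associations but fed forward as a ranked set (a Bonferroni
column is emitted for reference).

**Set level (burden and over-representation).** Two questions are asked of
gene sets. First, does an *a priori* curated list of disease-relevant genes
preferentially appear among the nominal collapsing hits? With `N` testable
genes (the universe: analyzable genes carrying at least one qualifying
variant), `K` curated genes inside that universe, `n` nominal hits and `k`
overlapping genes, the p-value is the upper tail `P(X >= k)` of
`Hypergeometric(N, K, n)`, inclusive of the observed overlap. Curated genes
outside the universe were never testable, so they reduce `K` rather than
diluting the test. Second, which annotated gene sets are over-represented
among genes carrying strict-tier ultra-rare variants? Each term is tested
with the same hypergeometric tail against an explicit universe, adjusted by
Benjamini–Hochberg *within its category* (molecular-function terms compete
with molecular-function terms, pathways with pathways). Enrichment is
declared *exclusive* when a term is significant for case protein-altering
variants but neither for controls nor for the case-synonymous comparator
stream — the pattern expected of a real protein-level signal rather than of
cohort-specific artefacts (batch effects inflate synonymous lists just as
well as missense lists).

**Coverage harmonization.** Burden tests compare carrier frequencies, so a
gene sequenced more deeply in cases than controls yields spurious signal
through differential callability alone. Before any testing, samples failing
cohort-wide depth bounds are excluded, and a gene is retained only if (i)
its cohort mean depth exceeds `min_gene_mean_depth`, (ii) its cohort mean
fraction of bases at ≥ 10× reaches `min_frac_ge10x`, (iii) *every* passing
sample covers less than `max_frac_lt20x_per_sample` of its bases below 20×,
and (iv) case and control group mean depths agree within
`max_rel_mean_diff`. Each excluded gene is reported with the first rule it
fails, in that order.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| permissive-tier MAF bound | 0.01 (inclusive) | allele fraction | collapsing tier; inclusive because boundary variants are still "rare" at any defensible rounding; configurable |
| strict-tier AF rule | absent from resource | — | enrichment tier; a recorded frequency of exactly 0 is also treated as absent (a 0 printed by an annotation pipeline means "not observed") |
| strict-tier CADD bound | 20 | PHRED | top 1% predicted deleteriousness; unscored variants *fail* a CADD-thresholded tier (conservative) |
| consequence classes | missense, splice acceptor/donor, stop gained/lost | — | the protein-altering set; stop-loss is included deliberately |
| `min_gene_mean_depth` | 50 | × | strict inequality (a 50.0× gene is excluded) |
| `min_frac_ge10x` | 0.95 | fraction | inclusive (0.95 passes) |
| `max_frac_lt20x_per_sample` | 0.20 | fraction | strict, enforced per sample |
| `max_rel_mean_diff` | 0.10 | fraction | relative to the larger group mean; see below |
| per-sample bounds | mean ≥ 50×, frac < 20× ≤ 0.20 | — | cohort-wide per-sample QC |
| `alpha` | 0.05 | — | nominal level used for hits, BH significance and exclusivity |

## Design choices that were open

- **"Differ by more than 10% in mean coverage"** can be read as absolute or
  relative. The default is relative with the larger group mean as
  denominator, because a relative rule is scale-free across capture kits and
  sequencing batches; an absolute mode is available
  (`coverage_thresholds(mean_diff_mode = "absolute")`).
- **MAF bound inclusivity.** Descriptions of this design vary between
  "< 0.01" and "≤ 0.01"; the bound is implemented inclusively and is
  configurable. No variant in the package's fixtures sits exactly on the
  boundary, so the choice is documented rather than consequential.
- **Hypergeometric tail convention.** The burden p-value includes the
  observed overlap (`P(X ≥ k)`, not `P(X > k)`); the exclusive tail would
  understate the evidence and, at `k = 0`, the inclusive tail correctly
  returns 1.
- **Hit rule.** The default nominal-hit set is {case-enriched, p < α}. A
  published hit list may differ from what its own printed per-gene counts
  imply (rows can be dropped for reasons outside the counts table), so
  `run_burden_test(..., hits = ...)` accepts an explicit override for exact
  replication; the override is intersected with the universe.
- **Gene assignment.** One symbol per variant (canonical transcript). When
  an annotation source lists several symbols, the first is kept and the
  discard is logged; how multi-gene variants should be counted is genuinely
  underdetermined, and counting once avoids double-dipping the universe.
- **Unpaired rank test for the homozygous-burden comparison.** The
  comparison of per-sample homozygous ultra-rare counts between two
  subpopulation strata of unequal size is an unpaired problem; the
  Wilcoxon rank-sum (Mann–Whitney) test is used. A signed-rank test is
  undefined without pairing.
- **BH is not idempotent.** Re-applying the step-up adjustment to already
  adjusted values inflates them (every non-maximal order statistic is
  multiplied by m/j > 1), so the property suite asserts monotonicity,
  pointwise dominance and hand-computed cases, and fixed-point behaviour
  only where it truly holds (constant vectors).
- **Missing genotypes** (`./.`) count as non-carrier, with the count logged:
  at these sample sizes treating missingness as carrier evidence would
  manufacture burden out of callability.

## The synthetic cohort generator

`simulation_config()` defaults describe the study conditions the package is
built around: 37 enrolled cases (30 + 7 across two subpopulations, the
smaller one consanguineous with a doubled homozygote rate), of which 2 are
planted to fail per-sample coverage QC leaving 35; 38 controls; 7,500 genes;
protein-altering consequence proportions 96.9% missense / 2.1% stop / 1.0%
splice; 10 planted risk genes with case carrier probability 0.25 against a
background of 0.01; 20 planted uneven-coverage genes, five per
harmonization rule; a planted case-only gene set and a planted
both-groups set (carrier probability 0.15 in both arms, chosen lower than
the risk-gene effect so the case-only set dominates the enrichment ranking
while the shared set still clears significance in both streams); and a
curated list of the 10 risk genes plus 15 background decoys, giving the
25-gene list size the burden test is exercised at.

Two structural decisions keep the generator honest:

1. **Carrier events are primary.** Qualifying carrier events are drawn
   per gene × sample at exactly the configured probabilities and then
   dressed with variant-level annotations that are guaranteed to pass the
   permissive tier. Decoy variants (non-PASS or common-frequency) and the
   synonymous comparator stream are layered on *independently*, so they
   exercise the rejection paths without perturbing carrier status. As a
   result `expected_power()` — an exact enumeration over case and control
   binomial carrier counts of the probability that the Fisher p-value beats
   α — is exact for planted genes, and observed hit rates can be held to it
   within binomial error.
2. **Coordinates are synthetic.** Variants live on one artificial contig
   with non-overlapping 10 kb per-gene intervals; nothing requires a
   reference genome.

What the generator does **not** emulate: linkage disequilibrium and
haplotype sharing, relatedness, recurrent (shared) variants, sex
chromosomes, indels, site-specific sequencing error, or real runs of
homozygosity (the consanguineous stratum only scales the homozygote rate).
Passing tests therefore demonstrate that the statistical machinery recovers
truth under the model the analysis itself assumes — they do not certify
behaviour under population structure or batch artefacts, which is precisely
why the coverage-harmonization and exclusivity layers exist for real data.

## Numerical choices

- Both exact tests work on log-probabilities (`dhyper(log = TRUE)` plus
  log-sum-exp) and are validated against brute-force combinatorial oracles
  to 1e-12 on all margins up to 60 and universes up to 25.
- Tie handling in the Fisher tail uses a relative tolerance of 1e-7 when
  comparing table probabilities, so tables tied with the observed one up to
  floating-point noise are included — without this, equality of real-number
  probabilities computed by different factorizations is untestable.
- Ranking ties (equal p) break by descending case-carrier count, then
  symbol, making output order fully deterministic; TSV outputs fix
  scientific notation at six significant digits so repeated runs are
  byte-identical.
- Degenerate inputs: genes with zero carriers are dropped before testing
  (they carry no information; the universe still counts every gene with at
  least one qualifying variant); a rank test between two identical constant
  count vectors returns p = 1; an empty enrichment query warns and
  proceeds.

## Problem sizes

The shipped test suite simulates at 400–800 genes for unit-level checks and
at the full default (7,500 genes, 75 samples) for the end-to-end
truth-recovery check; the complete suite runs in well under a minute on one
core. These sizes were chosen because every planted effect is already
resolvable at them; nothing in the implementation caps cohort or gene
counts.

## Known limitations

- Carrier coding discards dosage and allele count beyond presence/absence;
  recessive architectures are only visible through the separate
  homozygous-burden comparison.
- No covariate adjustment (ancestry, sex, batch): the design compensates
  with coverage harmonization, the exclusivity comparison, and optional
  subpopulation restriction of the enrichment queries, not with regression.
- Over-representation analysis treats gene sets as flat symbol lists — no
  ontology-graph propagation, no annotation-database weighting — so its
  p-values are not comparable to web services that use richer statistics
  or their own backgrounds.
- Male X-chromosome hemizygosity is not modelled; dosage-2 calls are taken
  at face value.
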