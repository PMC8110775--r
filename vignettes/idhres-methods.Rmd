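---
title: "Methods: models, thresholds and design choices in idhres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, thresholds and design choices in idhres}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind each component of
`idhres`, the tunable parameters with their defaults and units, the
numerical conventions, and what a passing test does and does not
establish. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Variant filtering and confidence tiers

The pipeline deterministically reproduces a targeted-panel somatic
filtering cascade. All thresholds are stated as *removal* conditions and
their complements are kept, which pins down the boundaries:

| rule | removal condition | boundary behavior |
|---|---|---|
| coverage | tumor depth < 15× | depth = 15 kept |
| tumor VAF | < 5% | VAF = 5% kept |
| normal contamination | SNV: normal VAF ≥ 1%; indel: normal VAF ≠ 0 | SNV normal = 0.9% kept |
| coding | consequence not protein-altering | splice-site counts as altering |
| polymorphism | population frequency ≥ 0.14% | freq = 0.14% removed |

"Protein-altering" is operationalized as a fixed whitelist (missense,
nonsense/stop-gain, stop-loss, frameshift, in-frame indel,
splice-site). Confidence tiers are assigned in strict hierarchical
order — exact catalog match, loss-of-function in a tumor-suppressor
gene, same-codon match, near-codon (≤ 3 residues) plus damaging
prediction — so adding an exact catalog record can only lower a
variant's tier number. Variants lacking a protein position skip the
position-based rules rather than erroring. The historical manual-review
step is replaced by the deterministic tier output plus an audit log
that names the failed rule(s) for every removal. Annotation lookups are
total: a variant absent from the population-frequency table has
frequency 0; one absent from the damaging table is not damaging.

## Cancer cell fractions and clonal dynamics

No copy-number data are modeled, so CCF uses the diploid, copy-neutral,
heterozygous assumption CCF = min(1, 2·VAF). This is stated prominently
because it is both the analysis model and the generator's ground truth;
amplified or LOH loci would violate it. Relative timing compares each
gene's mean CCF with the IDH CCF using a tie band τ = 0.1 (CCF units):
`later` below IDH − τ, `earlier` above IDH + τ, `co-occurring` inside.

IDH clearance uses the *minimum* on-treatment VAF (the best response
achieved), not the VAF at a fixed visit — the source analyses are
ambiguous on this point and the minimum is the more conservative
measure of residual disease. The ≥ 75% decrease boundary is inclusive.

Relapse events: `emergent` means the allele was absent from the
post-filter baseline table, i.e. "not detectable above the 5% VAF
floor", deliberately matching the filter so that sub-floor baseline
clones are still called emergent, as they would be in practice.
`selected` requires a relapse VAF at least 2× baseline; the 2× fold is
this package's choice (the source describes "selection" only
qualitatively) and is configurable. Pathway grouping ships as an
editable TSV (`inst/extdata/pathway_map.tsv`) covering hematopoietic
TFs, RAS-RTK, chromatin, DNA methylation, cohesin and splicing genes,
with an explicit `other` fallback.

Clone independence on single-cell genotype matrices excludes missing
genotypes pairwise, requires ≥ 50 informative cells (below that the
verdict is `ambiguous` with a warning), and compares the observed
double-mutant count with its independence expectation using the exact
Fisher p-value; `mutually-exclusive` and `co-occurring` both require
p < α = 0.05.

## Consensus clustering of promoter methylation

After removing SNP-related and chrX/Y probes, per-probe variance is
computed on the full filtered matrix and the top 1% most variable
probes are intersected with promoter-flagged probes. Consensus k-means
parameters (unstated in the source analyses) default to 1000 resamples
at 80% sample subsampling; tests use 100 resamples, which is sufficient
for stable consensus at the planted effect sizes. k-means uses
Euclidean distance on beta values, k-means++ seeding, 10 restarts with
lowest-inertia tie-break; the final partition is a k-means clustering
of the consensus-matrix rows. The pipeline preset fixes k = 2 (the
analysis target is a two-cluster structure) while `k_range` lets users
inspect the stability curve (mean within-cluster minus between-cluster
consensus). Cluster labels are ordered by grand-mean beta so "cluster
2" is always the relatively hypermethylated group; this makes labels
deterministic given the data.

DMP testing replaces a moderated-t pipeline with a per-probe two-sided
Welch t-test on beta values plus Benjamini–Hochberg correction. With
dozens of samples per group the moderation has little effect; the
preserved analysis target is the DMP *set* at a BH FDR, and the same
engine backs differential expression on log2 values. Degenerate
(zero-variance) probes get t = 0, p = 1 rather than NaN. In the
longitudinal analysis, delta is baseline − post so demethylation is
positive; when a uniform shift leaves the per-probe deltas constant,
cross-group concordance is defined as 1 if the two groups' deltas are
numerically equal (Pearson correlation is undefined at zero variance).

## LSC17 and enrichment

The LSC17 score is the published weighted sum of 17 log2 expression
values; the coefficients are hard-coded and unit-tested gene by gene.
Because the upstream normalization is not reproduced here, the absolute
score scale (and hence any specific AUROC on real data) is
normalization-dependent and is not an acceptance surface; only relative
comparisons within one normalized dataset are meaningful. Legacy
signature symbols are resolved through an editable alias table
(FAM30A→KIAA0125, BEX3→NGFRAP1, ADGRG1→GPR56). A missing signature gene
is an error naming the gene; `impute_missing = TRUE` substitutes 0.

The preranked enrichment statistic is a weighted running sum (weight =
|statistic|, exponent 1): the ES is the maximum deviation, its sign the
direction, and the p-value comes from random same-size gene-label
permutations with the +1 correction, so p ≥ 1/(n_permutations + 1). No
multi-collection FDR is computed; gene sets are user-supplied.

## Association statistics

The two-sided Fisher p uses the minimum-likelihood convention (sum of
hypergeometric probabilities ≤ the observed table's, with a 1e-7
relative tolerance for floating-point ties), which matches
`fisher.test`'s convention and the exhaustive enumeration oracle. The
odds ratio is reported uncorrected (ad/bc, possibly 0 or ∞); the Woolf
logit 95% CI applies the Haldane–Anscombe 0.5 correction only when a
cell is zero and only for the CI. AUROC is the tie-corrected
Mann–Whitney construction (midranks; ties count ½), with an optional
auto-orientation that reports which direction was used. Logistic
regression is IRLS to tolerance 1e-8 (max 50 iterations) with Wald
errors; separation is flagged (diverging coefficients or degenerate
fitted probabilities) and suppresses estimates rather than reporting
unstable ones. The log-rank comparison delegates to the `survival`
package (infrastructure, not contribution).

## Evolution patterns

Thresholds are package choices, reported with every call: 2HG is
"suppressed" at relapse if ≤ (1 − r)·baseline with r = 0.5 (relative
units; 2HG spans orders of magnitude so a 50% cut separates sustained
suppression from rebound cleanly); methylation has "rebounded" if the
relapse mean beta is within δ = 0.01 of baseline (beta units; the
treatment effect on the mean is ~0.045 in the generator's world, so
δ = 0.01 splits the two regimes with margin). Pattern 3 additionally
*requires* an emergent mutation in the homologous IDH gene — the rule
invariant "no pattern 3 without a homolog switch" is enforced
structurally, and everything else (e.g. 2HG rebound without a switch)
is `unclassified` with the evidence retained. Nonresponder trajectories
are summarized but never force-fitted to patterns 1–3.

## The synthetic cohort: what it emulates, and what it does not

Defaults state the emulated world: 60 patients, 50% responders (30/60),
30% in hypermethylated cluster 2, IDH2:IDH1 ≈ 63:37, co-occurring
driver frequencies anchored to the observed landscape (DNMT3A/SRSF2
0.44, ASXL1 0.37, RUNX1 0.31, a lower-frequency tail), early drivers
clonal (CCF 1.0), RAS-pathway drivers subclonal (CCF 0.2–0.4, kept
above the 5% VAF detection floor so planted truth is recoverable),
depth negative-binomial around 300× (≈ the reported panel depth),
two-thirds of responders relapsing, 29% of responders clearing their
IDH mutation, and evolution patterns 1/2/3 in proportions 0.4/0.4/0.2
(mirroring the 2/2/1 case split in the source material, with each
pattern guaranteed present when ≥ 3 patients relapse). Cluster-2
patients are down-weighted 0.35:1 when responders are drawn, planting
the cluster-2 nonresponse bias; DNMT3A is enriched in hypomethylated
cluster 1 (0.55 vs 0.20). Methylation: fixed per-probe means,
discriminating promoter probes shifted +0.15 in cluster 2, a fixed 30%
demethylation probe set reduced by 0.15 beta on treatment (rebounding
at relapse only in pattern-2/3 patients), Gaussian noise sd 0.02.
Expression: fixed gene means, the 17 signature genes plus a 50-gene
planted LSC set shifted +1 log2 in cluster 2 at all timepoints
(stemness is not reversed by therapy). VAFs are binomial draws at
CCF/2 plus Gaussian measurement noise (sd 0.01).

Deliberately *not* emulated: genome coordinates with real structure,
probe–probe linkage, batch effects, copy-number events, doublets in
single-cell data, and count-level expression noise. A green end-to-end
test therefore establishes that the pipeline recovers planted structure
of realistic magnitude under idealized noise — not that it reproduces
any real cohort's printed estimates, which depend on patient-level data
not available at desk scale.

## Acceptance interpretation notes

The acceptance criteria are property-based. One interpretation choice
is worth recording: "coefficients recovered within 2 SE in ≥ 95% of
simulated cohorts" is checked per coefficient (nominal coverage of a
±2 SE Wald interval is 95.45% for one parameter), because joint
coverage of two parameters at ±2 SE has expected rate ≈ 91% and would
make the criterion unattainable in expectation. Tests use fixed seeds
throughout; simulation sizes inside multi-cohort loops use reduced
probe/gene counts (500–2000 probes) purely for runtime, with effect
sizes unchanged.
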