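---
title: "Consensus differential methylation calling on beta-value arrays"
author: "methcall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus differential methylation calling on beta-value arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

CpG methylation microarrays report, per interrogated CpG site and sample, a
beta value $\beta = M/(M+U+\alpha) \in [0,1]$ — 0 for completely
unmethylated, 1 for completely methylated cytosines. In a tumor series such
as neuroblastic tumors (neuroblastoma against ganglioneuroma,
ganglioneuroblastoma and normal fetal brain / adrenal gland references),
the analytical task is to find CpGs — and through them genes — that gain
(hyperM) or lose (hypoM) methylation in the tumors relative to every
reference tissue, under two hard constraints of real studies:

* reference tissues are precious and tiny (single samples are common), and
* tumor cohorts are epigenetically heterogeneous — a real signal may be
  carried by only a subset of cases.

Because there is no single agreed statistic for "differentially
methylated", `methcall` implements a stringent *consensus* definition:
three different criteria must agree before a probe is called.

## The three criteria

For one comparison of case samples against one reference set, per probe:

**A — threshold rule.** Hypermethylated when *every individual reference
value* is below `low_beta` (default 0.25) while at least `case_fraction`
(default 10%, inclusive) of the non-missing case values exceed `high_beta`
(default 0.75); hypomethylated with the sides swapped. "All reference
samples" is read as a strict consensus over individual values, not their
mean — the mean-based view is deliberately left to criterion B, which keeps
the two criteria non-redundant.

**B — mean shift.** $|\overline{\beta}_{case} - \overline{\beta}_{ref}| >$
`mean_diff` (default 0.25), strictly; the sign of the difference fixes the
direction and must agree with criterion A.

**C — permutation t test.** An unpaired pooled-variance t statistic per
probe (Welch selectable), adjusted two ways computed jointly over all
probes: the Westfall–Young free step-down maxT permutation adjustment for
family-wise error, and Benjamini–Hochberg FDR on the raw permutation
p-values. The criterion itself is `q < fdr_alpha` (default 0.05) on the BH
q-value. Two-sided testing via $|t|$ throughout: both directions of change
are of interest.

A probe's direction is non-`none` only when all *applicable* criteria pass
with a consistent direction. When either group is smaller than
`min_group_for_ttest` (default 3) a t test is not meaningful; criterion C
is then marked *not applicable* — not failed — the call is annotated
test-skipped, and the consensus reduces to A ∧ B. This pathway is not an
edge case: two of the three reference tissues in the motivating design
(fetal brain, adrenal gland) are single samples.

### The maxT step-down procedure

For features ordered by decreasing $|t|$, each feature's null distribution
is the successive maximum of permuted $|t|$ over itself and all less
significant features; monotonicity is enforced by a running maximum down
the ordering. When the number of distinct two-group relabelings
$\binom{n}{n_a}$ is at most `exhaustive_limit` (default 20,000) all are
enumerated, p-values are exact permutation fractions, and the observed
labeling is part of the enumeration so $p > 0$ by construction. Otherwise
`n_perm` random relabelings are drawn and the add-one estimator
$p = (1 + \#\{perm \ge obs\})/(1 + B)$ is used. Permutations are processed
in blocks so memory stays bounded regardless of $B$.

Numerical conventions: a zero-variance feature gets $t = 0$ (uninformative,
never significant) rather than NaN; zero pooled variance with a nonzero
mean difference is guarded to a large finite sentinel whose p-value comes
from the permutation distribution, never from the t distribution;
permutation comparisons use an absolute tie guard of $10^{-12}$ so exact
ties count as exceedances on both sides of the comparison.

### Power of criterion C at intermediate carrier fractions

A property worth understanding before interpreting consensus output: when a
signal is carried by only part of the case group, the case distribution at
that probe is bimodal, which both inflates the within-case variance and —
more fundamentally — creates many relabelings (for example, all reference
slots drawn from the carrier mode) whose $|t|$ equals or exceeds the
observed one. Against a 3-sample reference, a probe shifted by
$\Delta\beta = 0.6$ in 50% of 20 cases has an exhaustive permutation
p-value around 0.1–0.2 regardless of how large the shift is; after BH
correction over thousands of probes such a probe can never reach
`q < 0.05`. Only near-fully-penetrant signals reach the attainable floor
$1/\binom{n}{n_a}$ and survive. The consequence is that the full
three-criteria consensus is conservative by design: against small reference
sets it detects signals carried by (nearly) all cases, while
partial-penetrance signals are detected by the A ∧ B pathway when the
reference set is too small for the t test to apply. The package's
calibration utilities (`null_calibration()`, `parameter_recovery()`)
quantify exactly this on generated data, and the acceptance suite records
the resulting operating characteristics rather than hiding them.

## From probes to genes, and across references

Genes are called by the any-probe rule: a gene is differentially methylated
when at least one of its probes is, with the direction shared by its called
probes; genes whose called probes disagree are flagged ambiguous and
excluded from ranked lists. The 27K-style design has roughly two probes per
gene, so more elaborate aggregation has little to work with.

Case-specific genes are the direction-aware intersection of gene calls
across all reference comparisons (the Venn intersection over supervised
analyses against distinct reference tissues); a gene called hyper against
one reference and hypo against another is excluded outright. Ranking of the
final list uses the fraction of case samples shifted (descending), then the
maximum absolute mean beta difference (descending), then the gene symbol —
the last key only to make output fully deterministic.

Clinical-subgroup contrasts (high vs low risk, stage 4 vs 4S, MYCN
amplified vs non-amplified, age cut-offs at 18 months / 5 years) reuse the
same machinery between two tumor subsets; optionally a three-way
consistency flag additionally requires the threshold criterion's
reference-side condition to hold in the normal reference tissues.

## Quality control

Before analysis: gonosomal (chrX/chrY) probes are removed — "gender
specific" is read as chromosomal annotation, not empirical sex association
— along with probes failing detection (p > 0.01) in more than 5% of
samples and probes missing more than 20% of values; samples failing more
than 1% of probes are removed. The detection p cut-off and both fail
fractions follow common array practice and are fully config-exposed: the
exclusion *mechanism* is the reproducible content, not the constants.
Exclusion reports account for every input probe and sample. Missing beta
values are excluded pairwise from means and tests, never imputed — except
in the PCA/clustering views, where probe means are imputed for the view
only.

## Enrichment and annotation

Called gene sets are characterized by hypergeometric upper-tail tests
(`enrich_category()`): chromosome and cytoband distribution, promoter
CpG-content classes (HCP/ICP/LCP/mixed), Polycomb-target status, and any
user-supplied term→gene map (a local stand-in for web-service GO analysis).
The background universe is the set of genes surviving QC on the array, not
the genome: array content makes background rates platform-relative. Raw
hypergeometric probabilities are reported at a 0.05 cut-off by default,
with optional BH adjustment across categories.

Promoter class can also be computed from sequence: 500-bp windows slid at
1-bp steps across the −700..+200 region around the TSS; HCP when some
window has GC ≥ 0.55 and CpG observed/expected ≥ 0.75, LCP when no window
reaches o/e 0.48, ICP otherwise, with
$o/e = \#CpG \cdot L / (\#C \cdot \#G)$ and N bases excluded from counts.
The classifier is a convenience; curated annotation remains the source of
truth for promoter class and Polycomb status.

## Expression concordance

Expression matrices are z-score transformed per gene over a named
standardization population; the default is all samples, with a
references-only alternative. The choice matters more than it looks: for a
gene shifted in a fraction $f$ of the standardization population, the
attainable z of the shifted samples is bounded by $\sqrt{(1-f)/f}$ no
matter how large the shift, so when tumors dominate the series the
all-sample default caps tumor z-scores below 1 and the prevalence rule
below can never fire. Recovery analyses on generated data therefore
standardize over the references.

A gene is differentially expressed when the permutation t test (same maxT +
BH machinery) is significant at 0.01 — applied to the adjusted value by
default, raw p optional — *and* its z exceeds 1 in strictly more than 50%
of case samples (symmetrically below −1 for down-regulation). Concordance
summaries count hyperM-with-down and hypoM-with-up genes among those with
expression data; percentages are exact counts truncated (not rounded) to
one decimal, matching how such rates are conventionally printed
(5/13 → 38.4%, 10/136 → 7.3%).

## Sample-structure views

PCA treats samples as observations over probe-centered, unscaled beta
values (beta is already bounded and comparable across probes) via SVD, with
a deterministic sign convention (the largest-magnitude loading of each
component is positive). Hierarchical clustering defaults to average linkage
on Euclidean distances, serialized as Newick with merge-height branch
lengths. Both are reproducible stand-ins for vendor-tool displays whose
parameters are undocumented — defaults are config-exposed and no bit-match
is claimed.

## The synthetic generator

`synthetic_dataset()` emulates the statistical structure of a small tumor
methylation study with a planted-truth registry for scoring:

* per-probe bimodal baselines — unmethylated (mean 0.10), methylated
  (0.85) and intermediate (0.50) states mixed 45/35/20, with beta noise
  parameterized by mean and concentration (default 50, i.e. sd ≈ 0.05 at
  mean 0.85) because that maps directly onto the bimodal beta landscape of
  27K-style arrays;
* ~2 probes per gene, matching the array's gene coverage;
* 20 tumor cases against reference tissues of sizes 1/1/3 (the third
  mixed-neuroblastic set carries a GNB label) so the test-skipped pathway
  is exercised exactly as a real design forces;
* planted hyper/hypo genes (defaults 10/30 — hypomethylation dominating,
  as in neuroblastic tumors) shifted by `effect_delta` (0.6) in a
  configurable carrier fraction of cases (0.5), carriers shared across a
  gene's probes;
* clinical covariates (INSS stage, MYCN status, age) in study-like
  proportions, subgroup-planted signals keyed to those fields;
* detection p-values ~ U(0, 0.005) with plantable bad samples/probes; and
* an expression matrix whose responsive genes move opposite to
  hypermethylation and with hypomethylation in carrier samples only.

What it does *not* emulate: probe cross-hybridization, SNP-affected
probes, copy-number contamination of beta, batch structure, or any
correlation between neighboring probes beyond shared gene membership.
Passing recovery tests therefore demonstrate the caller's arithmetic and
operating characteristics, not robustness to those artifacts.

A deterministic single-gene fixture (`make_ccnd1_fixture()`) encodes a
harder qualitative pattern: a 17-probe gene with an unmethylated promoter,
a gene body heterogeneous in the references (lower tumor values that must
*not* be called, because the strict reference condition fails), and two
3'-UTR probes methylated above 0.90 in every reference with 17 of 21 tumors
low — under default parameters exactly those two probes are called.

## Calibration results and problem sizes

`null_calibration()` (200 generated datasets of 2,000 probes, 20 cases,
1/1/3 references, no planted signal) measures spurious consensus calls and
the family-wise error of the maxT criterion at 0.05;
`parameter_recovery()` (25 replicates, 1,500 probes, 30 hypo + 10 hyper
planted genes at Δβ 0.6 in half the cases) measures gene-level sensitivity
and precision. These sizes keep each experiment within a few minutes on one
CPU while leaving binomial uncertainty on a 5% rate at about ±2 percentage
points. Both are run, from scratch, by the test suite and by
`scripts/acceptance.R`; given the power analysis above, the recovery
experiment at 50% carriers documents the conservatism of the full
three-criteria consensus rather than a high sensitivity.

## Known limitations

* The consensus is deliberately stringent; its t criterion has essentially
  no power for partial-penetrance signals against small references (see
  above), and the threshold criterion collapses for probes whose reference
  values straddle the 0.25/0.75 cuts.
* Beta values are consumed as given: no IDAT processing, normalization, or
  batch correction.
* The array cannot distinguish 5-methylcytosine from
  5-hydroxymethylcytosine, and neither can anything downstream of it.
* Gene-level calls inherit the array's probe placement; a "gene" call may
  rest on a single CpG far from the promoter.
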