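---
title: "Signature reversal scoring and combination synergy: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature reversal scoring and combination synergy: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revsig)
```

revsig implements a transcriptome-driven drug-repositioning workflow for
castration-resistant prostate cancer (CRPC) and comparable settings: a
disease expression signature is derived by meta-analysis across
tumor/normal microarray studies, drug-induced landmark-gene profiles are
scored for their ability to *reverse* that signature, compound activity
(IC50/AUC) is used to stratify and validate the reversal scores, genes
consistently reversed by active compounds are identified, and a
target-inhibition model ranks drug combinations. This vignette documents
the statistical models, the tunable parameters, and the design choices
behind each stage, together with what the bundled synthetic cohort can
and cannot demonstrate.

## The disease meta-signature

Each study is a probe-level log2 expression matrix with tumor and normal
samples. When several probes measure one gene, the probe with the largest
interquartile range across samples is kept (exact ties go to the
lexicographically smallest probe id, so the operation is deterministic).
Only genes present on all platforms enter the meta-analysis.

Per study, differential expression uses a two-sample moderated
t-statistic: the pooled per-gene variance \(s_g^2\) (on \(d_g\) degrees
of freedom) is shrunk toward a prior \(s_0^2\) with prior degrees of
freedom \(d_0\),

\[
\tilde{s}_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}, \qquad
t_g = \frac{\bar{x}_{g,\mathrm{tumor}} - \bar{x}_{g,\mathrm{normal}}}
           {\sqrt{\tilde{s}_g^2 (1/n_1 + 1/n_2)}},
\]

with p-values from a t distribution on \(d_g + d_0\) degrees of freedom.
\((d_0, s_0^2)\) are estimated by the method of moments on
\(\log s_g^2\): the excess variance of
\(\log s_g^2 - \psi(d_g/2) + \log(d_g/2)\) over \(\psi'(d_g/2)\) is
inverted through the trigamma function (Newton iteration) to give
\(d_0\). Setting `prior_df = 0` recovers the ordinary pooled t exactly;
`prior_df = Inf` replaces every variance by \(s_0^2\). When the moment
estimate of the excess variance is non-positive the prior df is taken as
infinite, which is the natural limit.

Studies are combined by a fixed-effect model on the effect sizes: with
per-study sampling variances \(v_i = \tilde{s}^2 (1/n_1 + 1/n_2)\) and
weights \(w_i = 1/v_i\),

\[
\hat\beta = \frac{\sum_i w_i \,\mathrm{fc}_i}{\sum_i w_i}, \qquad
\mathrm{Var}(\hat\beta) = \frac{1}{\sum_i w_i},
\]

with a normal reference for the combined z and Benjamini–Hochberg
adjustment across genes. A deliberate design choice: the effect-size
fixed-effect model is used rather than Fisher-style p-value combination,
because signature selection needs a combined log2 fold-change for the
\(|\mathrm{log2FC}| > 1.5\) cut as well as an adjusted p-value for the
\(q < 0.001\) cut, and a single coherent model supplies both. Whether an
effect-size or p-combination model better matches any particular
published analysis is usually not decidable from the publication; the
choice here is recorded, not asserted as universal.

Signature thresholds default to adjusted p `q_deg = 0.001` and
`lfc = 1.5` log2 units, the values used for the CRPC signature this
workflow targets (53 up- and 42 down-regulated genes out of a 978-gene
landmark universe).

## Reversal scoring (RGES and sRGES)

A drug profile is a differential-expression vector over the landmark
genes. It is ranked descending (rank 1 = most up-regulated; value ties
break by gene id). For a gene set occupying sorted positions
\(p_{(1)} < \dots < p_{(t)}\) in a list of length \(n\), the
Connectivity-Map Kolmogorov–Smirnov enrichment statistic is

\[
a = \max_j \left(\tfrac{j}{t} - \tfrac{p_{(j)}}{n}\right), \quad
b = \max_j \left(\tfrac{p_{(j)}}{n} - \tfrac{j-1}{t}\right), \quad
\mathrm{ES} = \begin{cases} a & a > b \\ -b & \text{otherwise.} \end{cases}
\]

The reverse gene expression score of a profile is
\(\mathrm{RGES} = \mathrm{ES}_{up} - \mathrm{ES}_{down}\) when the two
enrichment scores have opposite signs and 0 otherwise (the standard
same-sign zeroing of the Connectivity-Map family; the rule is isolated in
`compute_rges()` so it can be revisited). RGES lies in \([-2, 2]\);
strongly negative values mean the drug pushes disease-up genes down and
disease-down genes up. A degenerate edge worth knowing: for a gene set
equal to the whole universe the formula gives \(-1/n\), not exactly 0 —
the package keeps the literal formula rather than special-casing.

Profiles flagged non-gold (low quality) are excluded before scoring.
Because one compound is profiled at several doses, durations and cell
lines, per-profile RGES values are summarized to one sRGES per compound
relative to the reference condition of 10 µM and 24 h: global offsets

* `dose_offset` = mean RGES at dose < 10 µM minus mean RGES at ≥ 10 µM,
* `duration_offset` = likewise for < 24 h vs ≥ 24 h,

are estimated within compounds observed on both sides of each split and
averaged across such compounds; each off-reference record is adjusted by
subtracting the applicable offsets, and sRGES is the equal-weight mean of
the adjusted values. The summarization is therefore exact for compounds
profiled only at the reference condition (sRGES = mean RGES) and
order-invariant in the records. This two-offset additive scheme is the
simplest defensible reading of "summarize relative to a reference
condition"; published weighting formulas for this step are typically not
printed in full, so the scheme is a package design decision and is fully
covered by tests.

Condition contrasts (`condition_contrast()`) compare RGES between dose
and duration groups, and compare per-compound RGES standard deviations
across cell lines versus across same-cell-line replicates. These are
unpaired two-sample comparisons, so an unpaired exact Wilcoxon rank-sum
test is used even where a signed-rank test is sometimes named for such
contrasts in the literature; a signed-rank test requires paired
observations that these groupings do not provide.

## Activity integration

IC50 records (µM) vary across cell lines and assays; the per-compound
median is used, with the even-count median taken as the mean of the
middle pair. Compounds are active when the median IC50 is strictly below
10 µM and inactive at or above it — the usual primary-screening cutoff.
AUC records are handled by the same aggregation but never mixed with
IC50s in one call. The link between reversal strength and activity is
quantified by the Spearman correlation between sRGES and median activity
over the compound intersection. Tumor–cell-line expression similarity
restricts to the 5,000 most variable shared genes (IQR across cell
lines) before computing per-pair Spearman correlations; `top_k` is
clipped with a warning when fewer genes are shared.

## Reversal-gene discovery

For each compound, gold profiles are collapsed to one ranking by the
per-gene median differential value; a gene's normalized position is
rank/n ∈ (0, 1], small at the top. A disease-up gene is *reversed* when
active compounds place it lower (larger position) than inactive
compounds; disease-down genes mirror this. The per-gene test is a
one-sided Wilcoxon rank-sum in the reversing direction. Leave-one-
compound-out (LOCO) cross-validation removes one compound at a time,
recomputes every gene's one-sided p on the remaining compounds,
BH-adjusts across genes within the trial, and calls a gene reversed only
if its adjusted p stays below `q_reversal = 0.25` in *every* trial and
its rank shift points the right way in every trial. Inside the LOCO loop
the rank-sum p-value uses a vectorized normal approximation with tie and
continuity corrections (the user-facing `test_reversal()` uses the exact
test when sample sizes permit); at the screen's typical group sizes
(dozens of compounds per class) the approximation is accurate to the
third decimal.

A property of this design worth stating plainly: BH at a lenient
threshold of 0.25 *is* a false-discovery-rate guarantee, not a
false-positive-count guarantee. With a handful of true reversal genes,
roughly `0.25 / 0.75 × (number of true calls)` false calls are expected,
and the all-trials LOCO intersection removes few of them because
leave-one-out p-values are strongly correlated across trials. On the
bundled screening scenario (95 signature genes, 4 planted reversal
genes, 50 active / 48 inactive compounds, rank shift 0.3) the screen
recovers all 4 planted genes in every tested seed while averaging about
one false call per run. Users wanting fewer false calls should lower
`q_reversal`; the 0.25 default reproduces the lenient screening cutoff
this workflow is modeled on.

## Combination synergy (target-inhibition averaging)

Drug sensitivities are taken as bounded values in [0, 1]; sRGES is
mapped by min-max rescaling so the strongest reverser gets 1
(`rges_to_sensitivity()`). Given a binary drug-target matrix, the
sensitivity of inhibiting a target set \(T\) is predicted by
maximization/minimization averaging: a lower bound \(L(T)\) is the
largest observed sensitivity among drugs whose target sets lie inside
\(T\) (0 if none), an upper bound \(U(T)\) the smallest among drugs
whose target sets contain \(T\) (1 if none); drugs with exactly the
target set \(T\) fix the prediction at the mean of their sensitivities,
otherwise \(\hat{y}(T) = (L + U)/2\). Under sensitivities consistent
with a monotone truth this prediction is monotone in \(T\) and brackets
the truth within \((U - L)/2\); with arbitrary inconsistent inputs only
the \((L+U)/2\) rule retains the monotonicity guarantee, which is why
the structural tests draw sensitivities from a planted monotone model.

Synergy of a drug pair is scored per target pair (i from drug 1, j from
drug 2, shared targets skipped — a drug pair consisting of two copies of
the same single-target drug has no valid pair and errors):

* additive: \(S_a = y(i,j) - (y(i) + y(j))\)
* multiplicative: \(S_m = y(i,j) - y(i)\,y(j)\)
* highest single agent: \(S_l = y(i,j) - \max(y(i), y(j))\)

where \(y(i)\), \(y(j)\), \(y(i,j)\) are model predictions for the
singleton and pair target sets, averaged over all valid pairs. The
predicted combination sensitivity is *expectation + synergy*, clipped to
[0, 1]. "Expectation" is not universally defined in this family of
methods; the package takes it as the model prediction for the union of
the two drugs' target sets, keeping the whole quantity inside one model,
and offers the independence-style null \(1 - (1 - y_1)(1 - y_2)\) behind
`expectation_kind = "independence"`. The index set of the synergy
average is read as target pairs rather than, say, drug pairs, because
the score formulas are functions of single-target sensitivities.

## The synthetic cohort

`simulation_config()` pins the cohort to the dimensions of the study
this workflow reproduces: 978 landmark genes; four studies totalling 64
tumors and 114 normal or benign samples (allocated 16/16/16/16 and
29/29/28/28 — per-study sizes are a package choice since only the totals
are fixed); 53 up- and 42 down-regulated DEGs planted at 2.0 log2 units;
172 compounds of which 30% truly reverse the signature; doses {5, 10} µM
and durations {6, 24} h including the reference condition; a 20-target
drug-target matrix.

Generator mechanics, all seeded from one root seed through named
substreams so every artifact is reproducible bit for bit:

* **Expression**: per-gene baseline means ~ N(7, 1) on the log2 scale
  with unit-variance sample noise, matching typical normalized
  microarray ranges and keeping the moderated-t model well specified.
  Planted DEGs shift tumors by ±`deg_log2fc`. Each platform measures
  ~12% of genes with two probes (probe-specific offsets, sd 0.3) so
  probe collapsing is exercised.
* **Profiles**: background differential expression is i.i.d. N(0, 1).
  Reversers subtract a shift from planted up-genes and add it to planted
  down-genes before ranking; the shift is `6 × reversal_strength × u_c`
  with a per-compound grade `u_c ~ U(0.65, 1)`, attenuated ×0.6 away
  from the reference condition and modulated by a per-(compound, cell
  line) factor so cell-line variation exceeds replicate noise. At
  `reversal_strength = 1` every reverser's reference-condition RGES
  falls below −1.5; at the 0.8 default, reference RGES sits around −1.5
  to −1.9.
* **Activity**: `log10(IC50) = 2.25 + 1.4 × score + ε`,
  `ε ~ N(0, ic50_noise_sd)` with the 0.3 log10-µM default, where the
  score is the planted per-compound reversal score; noise is added on
  the log scale so IC50s are strictly positive, and the intercept/slope
  place the reverser population astride the 10 µM threshold so both
  activity classes are populated. The `scores` argument lets a caller
  drive the link with externally computed sRGES values, which is how the
  noise-free "Spearman rho exactly 1" property is exercised.
* **Drug targets**: 1–3 targets per drug; true combination sensitivity
  is `1 - exp(-Σ target weights)`, monotone in the target set by
  construction, so the target-inhibition model's central assumption
  holds in the planted truth.

What the generator does *not* emulate: platform-specific probe
chemistry, batch and lab effects, correlated gene-gene structure,
dose-response curve shapes, or the identifier-mapping pain of real
LINCS/ChEMBL/CCLE integration. Passing the recovery tests therefore
shows the statistical machinery is correct and calibrated under its own
assumptions — it does not show that any particular real compound or
gene would be recovered from the real databases.

In the default cohort the reverser compounds shift the *entire* planted
signature, so the reversal-gene screen legitimately calls most signature
genes reversed there; the focused `simulate_reversal_screen()` scenario
(only 4 of 95 signature genes planted with a 0.3 rank shift, 50 active /
48 inactive compounds) is the discriminating test of that stage. Its
value shift is calibrated analytically: a shift of
`sqrt(2) × qnorm(0.5 + δ)` in a standard-normal field moves a gene's
expected normalized position by δ.

## Numerical and degenerate-input conventions

* Ranking ties break by gene id ascending; probe-IQR ties by probe id —
  all orderings in the package are total, so equal seeds give
  byte-identical files.
* Same-sign RGES is exactly 0; enrichment scores of saturated sets are
  −1/n (literal formula, no special case).
* `p.adjust(method = "BH")` supplies the step-up adjustment; tests pin
  it against an independent brute-force implementation.
* Constant vectors: correlation-based similarity returns NA with a
  warning (cosine is still defined); rank-based potency evaluation and
  sensitivity rescaling refuse constant input.
* All-zero within-group variance aborts the moderated t (degenerate
  input); single genes with zero variance are handled by shrinkage.
* Predicted combination sensitivities are clipped to [0, 1]; the clip is
  the only nonlinearity applied after the additive
  expectation + synergy decomposition.
* Pipeline stages abort with the stage name and cause and leave a
  `FAILED_<stage>` marker next to any partial outputs.

## Problem sizes used by the test suite

The suite exercises the full 978-gene, 178-sample, 172-compound cohort
where the claim depends on those dimensions (signature recovery over 20
seeds, potency recovery over 100 seeds, the end-to-end determinism
check) and smaller instances (150 genes, 2 studies, 24 compounds;
rank-test oracles at n ≤ 50; target-inhibition enumeration at ≤ 10
targets) where the property is size-independent. These sizes are the
package's own choice of a thorough-but-quick default; all of them are
plain parameters that scale up without code changes.
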