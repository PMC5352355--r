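---
title: "Calling ALK rearrangements from qPCR: models, simulators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling ALK rearrangements from qPCR: models, simulators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alkscreen)
```

## The problem

About 5% of non-small-cell lung cancers carry a rearrangement fusing the 3′
(kinase-domain) portion of the *ALK* gene to a partner such as *EML4* or
*KIF5B*. These patients respond to ALK inhibitors, so determining
rearrangement status quickly matters, but the reference assays — break-apart
FISH and ALK immunohistochemistry — are slow and resource-intensive.
`alkscreen` implements a PCR-first screening route: a non-coding RNA marker
discovered on expression arrays, combined with the 5′/3′ transcript
imbalance that a fusion leaves behind, plus a multiplex panel of
fusion-junction primer pairs.

The package covers three linked pieces: the **microarray screen** that finds
the marker, the **three-level qPCR caller**, and **simulators** for the
cohort and for the confirmatory assays, so that every stage can be exercised
and tested without any external data.

## The microarray screen

Probe-level intensities are quantile-normalized (each array is forced onto
the across-array mean of sorted values, ties receiving the mean of the
reference values at the tied ranks) and summarized per probe set by Tukey
median polish: the probes × samples block is decomposed into overall + probe
+ sample effects by alternating median sweeps, and the reported log2
expression is overall + sample effect. This is the summarization used by
RMA. The convolution background-correction step of full RMA is deliberately
omitted: it requires raw scanner-scale data and does not change which
computations carry the screen; the omission is the one systematic
simplification of the preprocessing path, and it is why desk-scale fold
changes run a few percent low of their generating values (see below).

Differential expression uses the SAM relative difference

$$ d_i = \frac{\bar x_{i,\text{ALK}} - \bar x_{i,\text{rest}}}{s_i + s_0}, $$

with $s_i$ the pooled two-sample standard-error term and the fudge factor
$s_0$ chosen by the percentile rule: over candidate percentiles of the
$s_i$ distribution, pick the value minimizing the coefficient of variation
of the median $|d|$ across equal-count windows of $s_i$. False-discovery
q-values come from class-label permutations: for each observed $|d_i|$ the
median, across permutations, of the number of permuted $|d|$ values at or
above it, divided by the number of probe sets called at that threshold, made
monotone in rank and capped at 1. When fewer distinct label splits exist
than requested permutations the enumeration is exhaustive, which is what
makes small fixtures exactly checkable against a brute-force oracle. No
$\pi_0$ correction is applied, so the estimate is conservative. Ties in
$|d|$ are broken lexicographically by probe-set id for a deterministic
ranking. The screening defaults are 1000 permutations and an FDR threshold
of 0.05.

Fold change is defined as $2^{\Delta}$ of the difference of mean log2
expression — the standard convention for RMA-scale data. Probe-to-transcript
matching is an ungapped Hamming search (both strands, at most one mismatch
by default, 0-based half-open coordinates) in which `N` matches nothing,
implemented over `Biostrings` with a recount filter enforcing the `N` rule.

## The three-level caller

All scores are on the Ct (cycle) scale; one cycle is a twofold template
difference at perfect efficiency, and **lower scores mean rearrangement**.

1. **Marker ΔCt** — marker Ct minus the arithmetic mean of the HPRT1 and
   ESD reference-gene Cts. The arithmetic mean on the Ct scale is the
   geometric mean of abundances under equal efficiencies; references with
   equal weight is conventional ΔCt practice.
2. **Imbalance ΔCt** — ALK 3′ Ct minus ALK 5′ Ct. Any per-sample constant
   (loading, global efficiency) cancels by construction; negative values
   mean the kinase-domain side is overexpressed.
3. **Combined score** — their sum, which separates the classes at least as
   well as either component and governs the status call.

Censoring is explicit throughout: a reaction that has not crossed threshold
by `max_ct` (default 40 cycles, the assay's cycle count) is recorded as
`NA`, never as a number. A censored marker or one censored imbalance side is
scored at the `max_ct` sentinel and flagged — absence of amplification is
informative for negatives. A censored reference gene is a QC failure: the
sample is indeterminate, not guessed.

Because no established cutoff exists for these scores, cutoffs are derived
from labelled training data: the midpoint between the classes when they
separate, otherwise the threshold maximizing Youden's J with ties broken
toward higher specificity (a screening assay should not over-call), with a
median fallback when no threshold beats chance. Separate cutoffs are kept
for the marker, the imbalance and the combined score; the combined-score
cutoff decides status, the component cutoffs set per-level evidence flags.

The subtype panel declares one expected melt temperature per primer pair; a
pair is detected when its amplicon Ct is at most `ct_detect` (default 35
cycles) *and* its melt temperature is within `tm_tol` (default 0.5 °C) —
both conventional qPCR practice, as the source protocol does not state
values. Among multiple detections the lowest Ct wins (ties by lexicographic
variant id, with a multi-detection flag); a winning pair covering several
junction variants returns the covering set with an ambiguity flag rather
than pretending to resolve it.

A detected subtype forces a positive call even when the combined score is
above cutoff; the call is then annotated as discordant. This is deliberate:
it is exactly the signature of a specimen with very few
rearrangement-positive cells, where dilution pushes the expression scores
toward the negative class while the junction amplicon — which has no
background competition — still amplifies.

## What the simulators emulate

The cohort generator is the package's study-conditions definition, not a
tuning surface.

* **Truth**: subgroups ALK-translocated / EGFR / KRAS / triple-negative /
  adjacent-normal. The default is a scaled-down 16 ALK+ / 40 negative
  cohort for fast iteration; `preset = "e_geod_31210"` gives the E-GEOD-31210
  246-array composition (11/127/20/68 tumors + 20 normals). Positives draw
  a fusion variant uniformly from a 27-variant catalogue over 8 partners;
  tumor-cell fraction is uniform on \[0.2, 0.9\] by default (the source
  reports no distribution; resected specimens with substantial tumor
  content are the realistic setting, and the interesting low-fraction
  regime is exercised explicitly in tests).
* **Arrays**: log2 intensity = probe-set baseline + probe affinity offset +
  group effect + Gaussian noise (SD 0.8). Baselines are right-skewed
  (shifted exponential, mean 8, SD 2): real array intensity distributions
  have a long high tail, and without it quantile normalization clips probe
  sets elevated only in a minority class — a property of the normalization,
  not of the screen. The marker probe set (242964_at analogue) is elevated
  by log2(37.4) in positives and the ALK probe set (208212_s_at analogue)
  by log2(29.8), the fold changes the screen is designed to detect.
* **qPCR**: per target, template abundance mixes positive-cell and
  background levels linearly by tumor fraction for fusion-derived targets
  (marker, ALK 3′, the covering subtype amplicon); ALK 5′ and the reference
  genes ignore the fraction. Then
  $Ct = \text{intercept} - \log_e(a)/\log_e(\text{efficiency}) + \epsilon$,
  efficiency 2 by default (ΔCt arithmetic presumes it), noise SD 0.5
  cycles, censored above 40. Default abundances give a >100-fold
  marker difference and a >5-cycle imbalance between classes — the
  magnitudes the assay targets.
* **FISH**: each of 50 scored cells is positive independently with
  probability equal to the tumor fraction; the specimen is positive when
  strictly more than 15% are (≥ 8 cells; 7/50 = 14% fails — the strict
  reading of "more than 15%", pinned in tests). The two microscopy-positive
  patterns (split signals, isolated red) are collapsed into one per-cell
  event since the decision rule depends only on the count. At a 3% fraction
  the positive-call probability is the exact binomial tail
  1 − F(7; 50, 0.03) ≈ 1.1 × 10⁻⁴, which is the quantitative mechanism of
  PCR-positive / FISH-negative discordance.
* **IHC**: scores 0–3 from a configurable per-status distribution
  (deterministic by default — the source gives rules, not error rates),
  capped at 1 when the tumor fraction is ≤ 10% (staining must appear in
  more than 10% of tumor cells), binarized positive at 2+.

What passing tests on these simulations do **not** show: robustness to
array batch effects, to RNA degradation in fixed tissue, to qPCR efficiency
drift between targets, or to fusion variants absent from the panel. The
generator is exchangeable across non-ALK subgroups, so subgroup-specific
expression structure is not modelled either.

## Numerical choices and degenerate inputs

* Median polish sweeps rows before columns, recenters via medians, and
  stops on relative change of the residual L1 norm (tolerance 1e-9, at most
  100 sweeps; past that the last iterate is used — the sample effects
  settle long before the strict stopping rule fires). Single-probe sets
  pass through unchanged.
* SAM defines $d = 0$ whenever the mean difference is exactly zero, so
  zero-variance null fixtures yield $d = 0$, $q = 1$ rather than 0/0.
* Permutation sampling is without replacement; the identity split is
  included when enumeration is exhaustive.
* `choose_cutoff` candidates are midpoints of adjacent distinct scores plus
  sentinels beyond the range; empirical J is piecewise constant between
  scores, so this grid attains the global maximum exactly.
* All randomness flows from one configured seed; each pipeline stage uses a
  deterministic sub-stream, so partial reruns reproduce and fixed seeds
  give byte-identical output files.
* Problem sizes used by the shipped tests and the acceptance script — a
  500-probe-set array, 56-sample default cohorts, 20–30 replicate seeds,
  60–1000 permutations — were chosen as the smallest sizes at which the
  sampling error of each checked quantity is well inside its assertion
  band.

## Known limitations

* The fold changes recovered through the full desk-scale preprocessing path
  run a few percent below their generating values (≈ −4% at the default
  cohort, ≈ −8% at the 11/246 composition): quantile normalization over a
  500-probe-set simulated array compresses the minority-class tail more
  than it would on a real 54k-probe-set chip, and no background correction
  is applied. The tests' tolerances account for this documented bias.
* The q-value estimator is conservative (no $\pi_0$), which costs power at
  small permutation counts.
* The ΔCt(3′/5′) convention — 3′ minus 5′, references cancelling — is an
  interpretation; the source never defines the quantity algebraically. The
  sign convention (positives low) is fixed throughout and tested.
* Cutoffs are derived by resubstitution on the training cohort;
  cross-validated cutoff uncertainty is out of scope.
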