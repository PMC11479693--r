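---
title: "Methods: variant classification, calcium scoring and outcome statistics in fertscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant classification, calcium scoring and outcome statistics in fertscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fertscreen)
```

`fertscreen` implements the computational core of a diagnostic workup for men
whose ICSI cycles repeatedly end in total or low fertilization: Bayesian
classification of candidate variants in the sperm-borne oocyte-activation
genes (*PLCZ1*, *ACTL7A*, *ACTL9*), scoring of the calcium-release capacity of
their sperm in oocyte-injection assays, and exact contingency analysis of
clinical outcomes before and after assisted oocyte activation (AOA). This
vignette documents the models, the tunable parameters, the numerical
conventions, and what the synthetic-data generators do and do not emulate.

## The Bayesian point framework for ACMG/AMP classification

Each ACMG/AMP criterion applied to a variant is an evidence item with a
direction (pathogenic or benign) and a strength. Strengths carry points on the
naturally scaled exponent scheme — supporting 1, moderate 2, strong 4, very
strong 8 — positive for pathogenic and negative for benign evidence. For a net
total $N$ the combined odds of pathogenicity are

$$O = O_{VS}^{\,N/8}, \qquad
  \Pr(\text{pathogenic} \mid \text{evidence}) =
  \frac{O\,\pi}{(O-1)\,\pi + 1},$$

with prior $\pi = 0.10$ and very-strong odds $O_{VS} = 350$ by default. Both
are configurable through `bayes_params()`; the defaults are the framework's
canonical constants and are corroborated internally by the package's golden
tests: the eleven distinct posterior values that the classifier prints for
integer point totals $\{0,1,2,3,4,5,6,7,9,10,11\}$ agree, at 3-decimal
rounding, with the posteriors the study tables report, and a zero-evidence
variant scores exactly the prior ($P = 0.1$).

Categories follow the point bounds $\ge 10$ pathogenic (P), $6$–$9$ likely
pathogenic (LP), $0$–$5$ uncertain (VUS), $-6$–$-1$ likely benign (LB),
$\le -7$ benign (B); a stand-alone benign criterion (BA1) forces B regardless
of points. VUS are sub-graded by temperature from the same point total
(5 hot, 4 warm, 3 tepid, 2 cool, 1 cold, 0 ice cold). We considered assigning
tiers from posterior ranges instead, but the published labels attach two
different tiers to the same posterior (0.188), so ranges cannot reproduce
them; point-based tiers match every label except that single
self-contradictory pair, which we record and do not attempt to resolve.

Posteriors are kept at full precision internally; rounding (half-up, three
decimals) happens only at presentation. `invert_posterior()` recovers the
integer point total nearest a printed posterior — ties broken toward zero —
and is how the packaged variant table carries point totals: the per-criterion
evidence sets behind the published classifications are not public, so the
fixture stores the totals recovered from the printed posteriors and flags
them as derived. Functional evidence (calcium-release testing and the sperm
phenotype assays) enters as additional items via `update_with_functional()`,
which simply re-classifies the concatenated evidence; a modified-strength
criterion (e.g. a strong code applied at supporting level) is expressed by
the `strength` field, deliberately decoupled from the criterion code.

## Variant screening rules

Candidate tables are filtered on gnomAD allele frequency with a strict
`< 0.05` cut — the threshold is deliberately permissive because the condition
is rare and penetrance unknown — and a missing frequency (a novel variant)
passes, since novelty cannot argue commonness. REVEL flags pathogenicity
strictly above 0.5. AlphaMissense scores are binned `[0, 0.34)` likely
benign, `[0.34, 0.564)` uncertain, `[0.564, 1]` likely pathogenic; the
published ranges do not state a boundary convention, so we use half-open
intervals with the top bin closed, which partitions $[0,1]$ exactly.

Carrier frequencies use per-gene denominators from the screening roster:
cohort 1 (28 patients) was screened for *PLCZ1* only, cohort 2 (27 patients)
for all three genes, so *PLCZ1* rates are out of 55 and *ACTL7A*/*ACTL9*
rates out of 27. Compound heterozygosity is flagged per gene when a patient
carries two or more distinct heterozygous variants in it.

## Calcium-trace scoring

A Fura-2 ratio trace is reduced to spikes in three steps: a rolling-median
baseline (default span 300 s — long against a single spike, short against
slow drift), a robust noise estimate (MAD of the residual), and strict local
maxima of the residual exceeding
$\max(k\,\hat\sigma, \text{min\_amplitude})$ with $k = 4$ by default.
Candidate peaks are accepted largest-first subject to a refractory spacing
(default 30 s), which makes the procedure deterministic; amplitude is peak
minus local baseline, so scores are invariant to constant offsets of the
whole trace. The upstream study analysed its traces in a commercial tool
whose settings are unpublished; this detector is the package's own design,
chosen for determinism and robustness to drift, with every parameter exposed
in `detector_params()`.

An oocyte's score is $A$ (mean spike amplitude, AU), $F$ (spikes per hour)
and their product $A{\times}F$, the total-calcium-released statistic. The
source material never states $F$'s units; we define it per hour, and the
recording span is taken as $n \cdot \Delta t$ so that a 2 h recording
sampled on $[0, 7200)$ s scores against exactly 2 h. Because absolute
$A{\times}F$ values depend on detector settings and the raw traces are not
available, the published per-patient AU values are not reproduction targets;
correctness is established property-wise instead (exact recovery of injected
spikes in noiseless synthetic traces, 10%-accurate $A{\times}F$ recovery at
signal-to-noise 20 across 50 seeded replicates). Spike counts over the full
recording map to frequency categories: 0 spikes "0", 1–2 "+", 3–9 "++",
10–20 "+++", more than 20 "++++".

Fertilization-competence thresholds are strict: mean $A{\times}F > 9$ AU
(mouse assay, 2 h) and $> 0.6$ AU (human assay, 10 h) count as the normal
range, equality as deficient — consistent with the deficient side being
described as $\le 9$ and $\le 0.6$. Patient–control comparisons gate the
two-sample t-test on Shapiro–Wilk normality of both samples at the same
$\alpha$ (default 0.05) and otherwise fall back to the two-sided
Mann–Whitney U test; constant samples, on which Shapiro–Wilk is undefined,
go to the rank test with a warning.

## Cycle accounting and exact tests

Clinical rates are pooled count ratios: fertilization $\sum 2PN / \sum MII$,
blastocyst $\sum \text{blastocysts} / \sum 2PN$ restricted to cycles where
blastocyst culture was performed (rows with an absent blastocyst count are
excluded from numerator and denominator), and positive-hCG and live-birth
rates per cycle. All rates are kept as integer count pairs until display
(2-decimal, half-up percentages), so rounding can never hide a count
discrepancy. The packaged cycle table stores one pooled row per patient and
arm, exactly as the source table prints them, with an `n_cycles` column; the
per-cycle splits were never published, and because counts are additive every
aggregate is identical to what per-cycle rows would give. A positive-hCG
count may exceed the cycle count of its row (fresh plus frozen transfers
from one cycle), which is why hCG is modelled as a count, not a flag.

The inclusion rule — at least one conventional ICSI cycle with $\ge 4$ MII
oocytes and fertilization $\le 33.33\%$ — is evaluated in integer arithmetic
(`3 * two_pn <= mii`), so a rate of exactly one third is eligible and
0.3334 is not, with no decimal-rounding artifacts. MOAT groups partition the
activation-rate axis at $\le 20\%$ (group 1) and $\ge 85\%$ (group 3); the
published definition leaves the interval (84%, 85%) unassigned, and we close
it conservatively into group 2.

The two-sided Fisher test is the conditional probability-mass definition:
summing hypergeometric probabilities of all tables with the observed margins
whose probability does not exceed the observed table's, with a relative
tolerance of $10^{-7}$ on the comparison. It is implemented directly (a
dozen lines over `dhyper`) and is cross-checked in the test suite against
both `stats::fisher.test` and a from-first-principles binomial-coefficient
enumeration over every 2×2 table with margins up to 12. Degenerate column
margins (all successes or all failures) yield $p = 1$; empty groups are
errors.

Sperm-phenotype rates reuse the same machinery: acrosome detachment is called
at $\ge 50\%$ of the acrosome length (or folding with $> 50\%$ detached),
rates are computed over intact-acrosome cells with an analysis floor of 20
cells (fewer triggers a flag, not a refusal), and immunofluorescence
expression classes split background-corrected intensity at user-supplied
invisible/obvious thresholds — the source protocol publishes no numeric
defaults, so these are configuration, with the expression proportion defined
as weak-plus-obvious over intact cells and a 50-cell floor.

## Synthetic data: what it emulates and what it does not

`simulate_trace()` generates baseline + linear drift + Poisson-timed spikes
(instantaneous rise, exponential decay, truncated-normal amplitudes) +
i.i.d. Gaussian noise, returning the ground-truth spike train for recovery
tests. Real Fura-2 noise is structured (photobleaching, movement, shot
noise) and real transients have finite rise times; the generator
deliberately ignores both, because the tests only need a controllable
signal-to-noise knob, and passing them therefore demonstrates detector
correctness on idealized traces, not performance on real recordings. Spike
decay tails overlap when events fall close together, so amplitude recovery
is exact (to $10^{-6}$) only on well-separated schedules; on Poisson
schedules the tests allow 3%.

`simulate_cohort()` draws per-cycle fertilization as
$\text{Binomial}(MII, p_{\text{arm}})$ with Bernoulli hCG and live-birth
outcomes; its default arm rates (0.11 vs 0.62 fertilization, 0.11 vs 0.60
hCG) mirror the magnitude of the effect the workup is meant to detect.
`simulate_evidence()` draws random criteria sets with known net points for
classifier round-trips. All generators are deterministic given their seed.

Problem sizes used by the test suite were chosen to keep the full run around
a minute on one core while leaving Monte-Carlo margins comfortable: 50
replicate traces of 2 h at 1 Hz for detector recovery, 500 simulated null
cohorts (10 patients, 2–4 cycles, 8–16 oocytes per cycle) for the type-I
error check of the arm comparison (expected rejection $0.05 \pm 0.03$), and
exhaustive Fisher enumeration over margins $\le 12$.

## Known limitations

* ACMG criteria arrive pre-asserted; the package does not derive PVS1/PM2
  logic from raw annotations, and no HGVS normalization or liftover is done.
* The spike detector has no notion of multi-phasic or plateau transients;
  strongly overlapping oscillations will be merged by the refractory rule.
* Published per-patient $A{\times}F$ values cannot be reproduced without the
  raw traces; only the scoring rules and thresholds are testable.
* Per-transfer (as opposed to per-cycle) pregnancy accounting is out of
  scope; outcomes are attributed to the cycle row that produced them.

## A worked pass over the packaged tables

```{r report}
report <- run_paper_report()
report
```

```{r classify-example}
pre <- classify(evidence_for_points(5))
pre
update_with_functional(pre, evidence_for_points(1))
```
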