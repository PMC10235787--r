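---
title: "Methods and design notes for mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

# Scope and model

`mrmediate` implements a two-sample summary-data Mendelian randomisation
pipeline: instrument selection and harmonisation, univariable causal
estimation with sensitivity estimators, a multivariable-MR (MVMR)
mediation decomposition, and pathway over-representation of the genes
whose expression is driven by the instruments. The causal diagram is

exposure → mediator → outcome, plus a direct exposure → outcome path,

with a binary outcome handled throughout on the log-odds scale. All
estimation uses only per-variant effect/SE pairs from non-overlapping
GWAS; no individual-level data enter anywhere.

Three assumptions underpin every estimate: instruments are robustly
associated with the exposure; independent of confounders; and affect the
outcome only through the exposure. The sensitivity estimators probe the
third assumption under different pleiotropy models, and the synthetic
generator (below) reproduces exactly those violation modes so each
estimator can be checked against a known truth.

# Instrument handling

**Selection and clumping.** Variants with exposure $p < 5\times10^{-8}$
are greedily clumped: repeatedly keep the smallest-p variant and discard
everything in LD with it at $r^2 \ge 0.001$. Ties in p are broken by
ascending variant identifier so results are reproducible; missing LD pairs
mean $r^2 = 0$ (the sparse output convention of reference-panel tools).
For MVMR the union of variants significant for either exposure is pooled
and clumped the same way, ranked by each variant's minimum p across the
pooled exposures — the rank statistic is a package choice (recorded in
output) since only "pooled and clumped" is specified in standard
descriptions of the approach.

**Harmonisation.** The first table defines the reference effect allele.
Matching allele pairs keep their sign, swapped pairs negate beta and
complement the frequency, anything else is dropped and counted.
Palindromic (A/T, C/G) variants are aligned by allele letters like any
other variant — deliberately no frequency-based orientation check, and no
proxy substitution for missing variants. Harmonisation is idempotent and
sign-consistent, and both properties are asserted in the test suite.

**Strength.** Per-variant $F = (\beta/\sigma)^2$ — the single-variant
summary-data approximation, chosen because no individual-level data are
available. Variance explained uses $2p(1-p)\beta^2$ (valid for a
variance-standardised trait) with fallback $F/(F+n-2)$ when the effect
allele frequency is missing; the formula used is named in the output.
Instruments with $F \le 10$ are flagged, never silently dropped.

# Estimators and numerical choices

* **IVW** uses first-order Wald-ratio weights, so it coincides exactly
  with weighted least squares of outcome on exposure betas through the
  origin (asserted to 1e-10 against an independent `lm()` oracle). The
  random-effects flavour is multiplicative with the inflation floored at
  1; additive random effects are not implemented.
* **Weighted median** interpolates the cumulative weight function at 0.5.
  Its SE comes from a parametric bootstrap (default 1000 replicates) that
  resamples both exposure and outcome betas; the seed is a required
  argument because no default replicate count/seed convention exists.
* **MR-Egger** orients all exposure betas non-negative before fitting.
  SEs for slope and intercept are inflated by
  $\max(1, \sqrt{RSS/(J-2)})$; p-values are two-sided normal.
* **MR-PRESSO** simulates the no-pleiotropy null by redrawing betas from
  their sampling distributions around leave-one-out fits. Empirical
  p-values are computed as $(1+\#\{\text{sim} \ge \text{obs}\})/(n_{sim}+1)$,
  so the smallest attainable outlier p is $1/(n_{sim}+1)$: with the
  Bonferroni flagging threshold $0.05/J$, the default 1000 simulations
  cannot flag anything once $J \ge 50$. The package warns in that regime;
  calibration runs here use $n_{sim} = 2500$ at $J = 100$. The distortion
  test compares the observed raw-vs-corrected shift against shifts from
  excluding equally many randomly chosen unflagged variants.
* **MVMR** is weighted least squares with the intercept fixed to zero and
  outcome-precision weights, taken literally from the standard
  summary-data formulation; cross-trait sampling covariances are not
  modelled. Coefficient SEs are inflated by $\max(1, \sqrt{RSS/(J-k)})$.
  The conditional F diagnostic projects each exposure's betas on the
  others' and standardises the residual by that exposure's SEs — a
  summary-data approximation reported for information, not a gate. An
  exposure column that is entirely zero is excluded with a warning (its
  direct effect is unidentifiable) rather than reported as a collinear
  design; genuinely collinear designs raise an error naming the worst
  pair.

**Mediation decomposition.** `indirect = total − direct` with
$SE^2_{ind} = SE^2_{tot} + SE^2_{dir}$; the proportion mediated is
`indirect/total` with a ratio delta-method SE. The covariance between
total and direct is set to zero even though both involve the same outcome
GWAS: the two estimates use different instrument sets (the exposure's own
clumped instruments for the total; pooled-and-clumped for the direct), and
zero covariance is the convention of the difference method for summary
data. It makes the indirect-effect SE conservative, which shows up as
above-nominal CI coverage of the mediated proportion in calibration runs.
Confidence intervals are symmetric normal on the log-odds scale, so a
proportion CI can legitimately extend outside [0, 1]. Unit rescaling
(e.g. per-10-mmHg reporting) multiplies effect and SE before
exponentiation and provably leaves the proportion unchanged. A total
effect below 1e-10 in magnitude makes the proportion undefined and raises
an error rather than returning an unstable ratio.

# Enrichment

Instrument variants map to genes through a cis-eQTL table at q < 0.05,
pooling evidence across tissues by default (a per-tissue restriction is
available; the pooled rule can only ever add genes). Over-representation
is the one-sided hypergeometric tail — identical to one-sided Fisher's
exact, asserted against `fisher.test` — with Benjamini-Hochberg control at
FDR 5%. The background universe is all genes annotated to at least one
pathway in the supplied GMT, not the genome: the choice is recorded in the
output columns (`N`). Pathway hierarchy is ignored (flat gene sets). Drugs
are joined only onto FDR-significant pathways and grouped by ATC class.
Live database queries are deliberately out of scope; small synthetic
fixture tables under `inst/extdata/` (named `synthetic_*`) emulate the
qualitative published finding that immune-signalling pathways behind
blood-pressure instruments carry JAK-inhibitor and PD-1/PD-L1 drugs.

# The synthetic generator: what it emulates, and what not

`truth_config()`/`simulate_study()` generate three summary-statistics
tables (exposure, mediator, binary outcome) under a known mediation DAG:

* exposure instruments with effects $\gamma_j$, mediator-specific
  instruments with effects $\delta_j$ (the mediator column would be
  perfectly collinear with the exposure column without them — this field
  is a necessary extension of the configured DAG for MVMR
  identifiability);
* true mediator effect $\theta_{XM}\gamma_j + \delta_j$, true outcome
  effect $\theta_{dir}\gamma_j + \theta_{MY} b_{Mj} + \alpha_j$;
* observed betas = truth + independent normal noise per study
  (non-overlapping samples are modelled as independent noise draws), with
  $\sigma = 1/\sqrt{2p(1-p)n}$ — the standard approximation, also for the
  binary outcome (no liability-threshold simulation);
* pleiotropy $\alpha_j$: none, balanced (zero-mean), directional
  (mean-shifted, independent of $\gamma$ — InSIDE holds), or correlated
  ($\alpha_j \propto \gamma_j$ plus noise — InSIDE violated); planted
  outliers add a fixed offset in outcome-SE units;
* optional LD blocks: tags carry the lead's truth scaled by $r$ and share
  its noise with correlation $r$, $r^2$ as configured.

Defaults are chosen once to mirror the consortium setting the pipeline
targets: exposure/mediator studies of 700k, outcome effective n of 240k
(≈62k cases / 1.2M controls), minor allele frequencies in [0.1, 0.4], and
instrument magnitudes uniform in [0.02, 0.045] SD. The magnitude floor
makes every instrument genome-wide significant by construction — the
generator states a world of *selected* instruments, so p-value selection
introduces no winner's curse into calibration runs — and J = 100 such
instruments explain ≈4–5% of a standardised exposure with all F well
above 10, matching the totals printed for real blood-pressure and
adiposity GWAS. The `weak_instruments` scenario switches to small normal
effects (mean F < 10 by construction). `scenario_suite()` ships nine
named configurations spanning these regimes.

What the generator does **not** emulate: realistic allele-frequency
spectra and polygenic backgrounds, sample overlap, population
stratification, liability-scale case-control subtleties, and genome-scale
numbers of null variants. A green calibration test therefore establishes
that the estimators are correct *under their stated assumptions and
violation modes*, not that any real-data result is reproduced; the
published real-data odds ratios require the original consortium downloads
(see the README's external-data section).

# Calibration results asserted by the suite

The acceptance tests (and `scripts/acceptance.R`) recompute, seeded:
IVW type-I error at $\alpha = 0.05$ within [0.03, 0.07] under the null
scenario (500 replicates, J = 50) and 95% CI coverage within [0.92, 0.98]
under the causal scenario; mean estimated mediated proportion within 0.05
of the implied 0.5 with ≥90% CI coverage (200 replicates, J = 100); a
10-SE planted outlier flagged in ≥95% of 100 replicates with the corrected
CI covering the truth in ≥90%; and exact agreement of estimators and
over-representation p-values with independent oracles. The worked
mediation examples from published odds ratios reproduce the printed
65.21% and 53.15% proportions to within the rounding of two-decimal ORs.

# Known limitations

Single-mediator models only (no network decomposition, no MVMR-Egger);
first-order Wald-ratio SEs; multiplicative random effects only; no Steiger
filtering or bidirectional analysis; LD is consumed, never computed, and
proxy lookup is out of scope. Bayesian genome-wide sensitivity methods
(e.g. CAUSE-style model comparison) are reported in the literature this
pipeline accompanies but are defined elsewhere and intentionally excluded;
the result schema's free-text `method` field lets externally computed
estimates be merged into the same report tables.
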