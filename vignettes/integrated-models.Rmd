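---
title: "Integrating two SGE screens: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating two SGE screens: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: what
each model assumes, which parameters matter and why their defaults are
what they are, what the synthetic-data generator does and does not
emulate, and where the design was genuinely open.

## Data model

The unit of data is one raw functional score for a (variant, assay,
replicate) triple, with the variant's exon as its batch label. Two assays
are integrated: a reference assay with three or more replicates
(HAP1-like) and a second assay with two (ES-cell-like). Throughout the
package, *lower scores mean depletion*, i.e. loss of function: cells
carrying a non-functional BRCA2 variant drop out of the screen. That
direction convention is stated once here and used consistently —
harmonization rejects a negative rescaling slope rather than silently
flipping a discordant assay.

## Harmonization

The second assay is mapped onto the reference scale by the unique affine
transform that sends its synonymous-control and nonsense-control score
medians onto the reference assay's. Medians, not means, because the
measurement model assumes heavy tails; pooled over replicates, because
replicate-level differences are precisely what the hierarchical model's
batch random effects are for. Rescaling with two anchors is exact on the
anchors, idempotent, and rank-preserving.

The anchor medians are estimated from a finite set of control variants,
so the fitted slope and intercept carry sampling noise that acts as a
small *common* shift on every rescaled score. This shift does not average
away as the variant count grows; it is the dominant uncertainty in
component-mean recovery on simulated data and is a known limitation of
two-anchor harmonization generally.

## The integrated VarCall model

A Bayesian hierarchical two-component mixture over all harmonized
replicate scores:

* `z_v` — pathogenicity indicator. Fixed at 0 for synonymous variants and
  1 for nonsense variants (their status is treated as known);
  `Bernoulli(pi)` for everything else. The default prior `pi = 0.2`
  reflects the predicted 22.7% pathogenic fraction among missense
  variants in the BRCA2 DNA-binding domain; `pi = 0.1` is the standard
  sensitivity alternative, and `prior_sensitivity()` reports the fraction
  of variants whose seven-level category is unchanged between the two.
* `theta_v | z_v ~ Normal(mu_{z_v}, sigma_{z_v})` — the latent effect,
  with the non-functional mean constrained below the functional mean.
* `y = b[e,r] + exp(g[e,r]) * theta_v + eps`, `eps ~ t_nu(0, tau)` —
  the measurement model. Location (`b`) and log-scale (`g`) random
  effects per replicate-by-exon batch absorb batching; generating and
  fitting the scale effect on the log scale keeps multiplicative scales
  positive without truncation. The t errors absorb outliers.

The model is specified in the JAGS language and fit by MCMC through
`rjags`; each chain receives a deterministic RNG stream derived from the
spec seed, so fits are reproducible.

Hyperpriors are not dictated by the model's provenance, so the package
uses weakly informative, scale-aware defaults: Normal priors on `mu_F`
and on the positive gap `delta = mu_F - mu_N` centred at the control
medians and their difference, with SD twice the overall score SD;
half-Normal(overall SD) priors on `sigma_F`, `sigma_N`, `tau` and the
batch location SD; half-Normal(0.5) on the log-scale-effect SD; and
`Gamma(2, 0.1)` truncated to `nu > 2` on the t degrees of freedom.
Parameterizing `mu_N = mu_F - delta` with `delta > 0` enforces the
ordering by construction and prevents label switching.

Convergence is declared when every free hyperparameter has potential
scale reduction factor at most 1.05 and chain-pooled effective sample
size at least 400; otherwise the fit carries a `converged = FALSE` flag.
The flag is deliberately strict: at the default two chains of 2000
retained draws the component-mean chains often sit below the effective
sample size bar even when their estimates are stable to the third
decimal, and the fit is flagged rather than the bar lowered.

### From posterior probability to evidence strength

`PP_v` is the posterior mean of `z_v`. Controls have `PP` exactly 0 or 1
by construction, so before converting to odds the probability is clamped
to `[1/(S+1), S/(S+1)]` with `S` the total number of posterior draws:
controls get finite, maximal-strength Bayes factors and the ordering of
all interior variants is untouched. The Bayes factor (posterior odds over
prior odds) is compared to the fractional powers of the canonical
odds-of-pathogenicity constant 350 — `350^(1/2)`, `350^(1/4)`,
`350^(1/8)` and their reciprocals — to assign the seven categories.
Thresholds are inclusive on the boundary and the constant is a
configurable argument with this default.

## The integrated GMM model

Each variant is summarised by the mean of its harmonized replicate scores
(configurable to the median), and a two-component univariate Gaussian
mixture is fit by EM: 10 restarts (the first anchored at the control
medians, the rest random), convergence when the log-likelihood gain drops
below 1e-8 or at 500 iterations, a variance floor of 1e-6 against
collapsing components, and the best restart by log-likelihood kept. The
log-likelihood is non-decreasing across iterations by construction and
the fit records its trace.

Component labels come from control calibration — the component with the
higher mean responsibility among nonsense controls is non-functional —
rather than from the means, though on any sane fit the two coincide. The
per-variant evidence is the component density ratio `LR = f_N(y)/f_F(y)`,
computed on the log scale to survive underflow; the probability of impact
on function is `PIF = LR * pi / (LR * pi + 1 - pi)`. The fitted mixture
weight is deliberately *not* used as the prior: keeping the evidence (LR)
separable from the prior is what lets both integrated models share one
strength scale, and the LR is compared against the same thresholds as the
VarCall Bayes factor.

Degenerate inputs (all summary scores essentially identical) are refused
with an error rather than fitted.

## Concordance and evaluation

Concordance between two category sources is decided at the *side* level —
any pathogenic strength in both, any benign strength in both, or
Uncertain in both — because that is the membership rule expert panels
apply; exact seven-level agreement is reported separately. No partial
credit is given for adjacent strengths.

Sensitivity and specificity against standards come in two definitions:
conservative (sensitivity from Pathogenic_Strong calls only, specificity
from Benign_Strong/Moderate) and all-categories (any side membership).
A standard with an Uncertain call counts in the denominator of either
definition but is not listed as discrepant: "discrepant" is reserved for
opposite-side calls, and only those trigger the VUS(discordant) override
downstream. A polarity with no standards yields an absent metric, never a
zero.

The pooled burden test reports the sample odds ratio `ad/bc` with a
Haldane +0.5 correction when any cell is zero, a two-sided Fisher exact
p-value, and a Wald interval on the log odds ratio; a zero row or column
makes the odds ratio undefined (reported absent).

## Points-based classification

Evidence codes carry fixed integer weights (+8/+4/+2/+1 pathogenic,
-8/-4/-2/-1 benign) and the total maps to bands: B at -7 and below, LB
-6 to -2, VUS -1 to +5, LP +6 to +9, P at +10 and above — the bands
partition the integers, and there is no rounding anywhere. Functional
evidence enters as PS3/BS3 at the strength of the seven-level category,
structurally capped at +/-4. Frequency evidence treats absence from the
population resource (missing or zero filter allele frequency) and
sub-threshold presence as mutually exclusive states: PM2_Supporting for
absence, BA1/BS1/BS1_Supporting above the 0.001 / 0.0001 / 0.00002
thresholds, nothing in between. In-silico evidence uses BayesDel at or
above 0.3 for moderate pathogenic support and a benign cutoff of 0.15 for
BP4; the benign cutoff is an externally sourced expert-panel value, kept
as a flagged configurable default. PVS1 defaults to +8 for nonsense and
canonical-splice variants; expert-panel decision-tree modulation, and all
codes whose derivation needs clinical or literature data (PS1, PM3, PM5,
PP4, BP5, BS2, BP7), arrive as preassigned inputs that the engine
validates and sums. Mutually exclusive code families (PS3/BS3; the
frequency family including PM2; PP3/BP4) raise an error naming the clash.

Every variant is classified twice — with and without the functional code
— and the VUS(discordant) override applies only to the "with" run: a
functional call on the opposite side of a ClinVar or HDR standard
withholds the variant from P/B classification regardless of its points.
VUS(discordant) is a distinct class value but counts as VUS in
classified-fraction summaries.

## The synthetic-data generator

`simulate_screen()` draws variants with a realistic consequence mix
(20% synonymous, 5% nonsense, 70% missense, 5% canonical-splice),
missense pathogenicity at 22.7%, latent effects from the two-component
mixture, and observations through exactly the measurement model the
VarCall fit assumes: exon-by-replicate location and log-scale batch
effects, scaled t noise, an affine distortion on the second assay, and
completely-at-random dropout. Default score scale: functional mean 0,
non-functional mean -1, component SDs 0.15 (about 6.7 SDs of
separation, so control-dependent tests are stable), batch SDs 0.05,
residual t(5) scale 0.10, second-assay distortion `y -> 0.3 + 1.25 y`,
2% missingness. The spec of the generating model needs a residual noise
scale alongside the t degrees of freedom; `residual_scale` is that field.

What it does *not* emulate: sequencing read counts and their
overdispersion, gRNA-level structure, time-course dropout kinetics,
informative missingness, position-specific (per-residue) effect
correlation, and real functional-score distributions' asymmetries. Tests
passing on this generator therefore demonstrate correctness of the
inference machinery under the model's own assumptions — parameter
recovery, closed-form agreement, calibration — not performance on real
screens, where model misspecification is the dominant risk.

## Problem sizes and numerical checks

The package's own validation runs at desk scale, chosen to keep the full
suite in minutes: the default screen has 500 variants (about 2450
observations), fit with 2 chains x 2000 retained draws; the closed-form
cross-check uses a 50-variant batch-free instance with hyperparameters
fixed at truth, where the MCMC posterior must match the analytic
two-component responsibility within 0.02 for every variant; the EM fit
must reach within 0.1 log-likelihood of an exhaustive 0.05-resolution
grid search on a 25-variant instance; and small fixtures use a
control-enriched consequence mix so both anchor classes exist at that
size. Component-mean recovery is judged against a standard error that
includes both component sampling and the harmonization anchor shift
described above, computed from generator constants.

## Known limitations

* One MCMC backend (JAGS). The sampler contract is a thin function
  boundary, but no alternative backend ships.
* Two-anchor median rescaling is exactly identified and robust, but its
  anchor noise becomes a common shift on the rescaled assay; with few
  controls this is the accuracy floor for component means.
* The GMM reduces replicates to one summary score and ignores batch
  structure; that is its design, and the VarCall model is the primary
  model for exactly that reason.
* Variants observed in a single assay are retained and flagged, but all
  bundled analyses run on the common set.
* The burden test is the pooled 2x2 path only; covariate-adjusted
  regression on individual-level cohort data is out of scope.
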