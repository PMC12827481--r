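---
title: "Transcriptomic DILI risk scoring: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptomic DILI risk scoring: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aegisr)
```

## The problem and the model

Intrinsic drug-induced liver injury (DILI) is dose-dependent: as exposure
rises, hepatotoxic compounds perturb the transcriptional programmes of
apoptosis-regulating transcription factors (TFs) before overt cytotoxicity.
`aegisr` quantifies that perturbation from a treatment-versus-control
expression experiment and turns it into a bounded risk score that can be
compared across compounds, doses (expressed as multiples of the clinical
C~max~) and platforms.

The pipeline has four stages.

**1. Per-gene linear model.** For each gene, expression (log2 scale) is
regressed on a treatment indicator plus, when several donors are present,
additive donor fixed effects. The design is orthogonally transformed (QR)
so that the treatment contrast occupies a single coordinate and the
residuals the remaining $d$ coordinates. This transform is not just a
computational convenience: the rotation test below resamples *within* that
residual space, so the coordinates are part of the model's contract
(`fit_contrast()` keeps them).

**2. Empirical-Bayes variance moderation.** With few replicates the
per-gene variance $s_g^2$ is noisy. We assume the classical hierarchical
model $s_g^2 \mid \sigma_g^2 \sim \sigma_g^2 \chi^2_d / d$ with a scaled
inverse-chi-square prior $\sigma_g^2 \sim s_0^2 d_0 / \chi^2_{d_0}$, so the
marginal of $s_g^2$ is a scaled F distribution. $(d_0, s_0^2)$ are
estimated by the method of moments on $\log s_g^2$ (digamma/trigamma
inversion; the trigamma inverse is solved by Newton iteration). The
posterior variance $\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$ yields
a moderated $t_g$ on $d_0 + d$ degrees of freedom, converted to its normal
equivalent $z_g = \Phi^{-1}(F_t(t_g))$. With `trend = TRUE`, $s_0^2$
follows a locally weighted regression (lowess, span 0.5, one robustifying
iteration) of $\log s_g^2$ on average log-expression, which is appropriate
for log-CPM count data whose variance depends on abundance.

**3. Rotation gene-set test.** The signature (eight apoptosis-regulating TF
regulons — ATF3, E2F3, FOXA1, FOXO3, JUN, PPARG, REST, TFAP4 — and their
combined union) is tested *self-contained*: is the set perturbed at all,
regardless of the rest of the transcriptome? Each gene contributes the
$(d+1)$-vector of its contrast and residual coordinates; a resample draws
ONE unit vector uniformly on the $d$-sphere and applies it to every gene.
Because the rotation is shared, inter-gene correlation is preserved and the
test remains exact under correlated nulls — the property that breaks naive
gene-sampling tests (our test suite demonstrates the contrast: a latent
factor shared by set genes leaves the rotation test at nominal type-I error
while inflating a gene-permutation oracle several-fold). Rotated data are
re-moderated with the prior estimated once from the observed data; this is
the standard computational shortcut, and the prior is a smooth functional
of thousands of genes, so a single rotation of a small set barely moves it.

The floormean set statistics summarise the set's moderated $z$ scores:
$S_{up} = \mathrm{mean}(\max(z_g, 0))$,
$S_{down} = \mathrm{mean}(\max(-z_g, 0))$, and the mixed statistic
$S_{mixed} = \mathrm{mean}(\max(|z_g|, q))$ with floor
$q = \Phi^{-1}(0.75) \approx 0.674$, the median of $|N(0,1)|$. Flooring at
the null median stops a mass of tiny $|z|$ from diluting the signal of a
genuinely perturbed minority. The floor is exposed (`mixed_floor` in
`rotation_config()`); setting it to 0 gives the plain mean of $|z|$.
P-values are $(b + 1)/(n_{rot} + 1)$ with a $\ge$ comparison (conservative,
never zero), the two-sided p is $2\min(p_{up}, p_{down})$ capped at 1, and
the mixed p-values are Benjamini–Hochberg adjusted across the tested sets.

**4. The DILI score.** With the "active" threshold $\sqrt 2$ on $z$,
PropUp and PropDown are the fractions of set genes active in each
direction, and

$$\text{raw} = (\text{PropUp} + \text{PropDown}) \cdot
  (-\log_{10} \text{FDR}_{mixed}), \qquad
  \text{score} = \min\!\left(1, \max\!\left(0, \frac{\text{raw} - 0}{4 - 0}\right)\right).$$

The min–max constants are not arbitrary: with the default 9999 rotations
the smallest attainable p-value is $10^{-4}$, so
$-\log_{10}$FDR $\le 4$ and, with proportions summing to at most 1, the raw
score is bounded by exactly 4. The normalised score therefore spans
$[0, 1]$ with 1 attainable, and scores are comparable across experiments
run at the same rotation count.

## Confidence by noise injection

Each treatment can be re-scored (default 50 times) after adding Gaussian
noise with per-gene SD equal to the gene's sample SD across *all* samples
of the experiment. The mean and SD over iterations give a stability
summary, and a 10,000-point normal sample of that mean/SD supports ridge
plots. Two properties deserve emphasis:

* All iterations share one rotation stream with the base run, so with zero
  injected noise every iteration reproduces the base score exactly, and
  differences between iterations isolate the effect of the noise.
* The injected noise *inflates* per-gene variance — the cross-sample SD
  includes between-group effect variance — so the iterated mean sits at or
  below the no-noise score unless the score is saturated. The mean of the
  iterations (the score of record in the output tables) is therefore a
  conservative estimate; it is reproducible across independent noise
  streams within Monte-Carlo error, which is what the test suite asserts.

## Calibration, panel statistics and dose–response

`threshold_sweep()` walks every observed score (plus 0 and 1) as a cutoff
(prediction positive iff score $\ge$ threshold), reporting specificity
TN/(TN+FP), sensitivity TP/(TP+FN), precision TP/(TP+FP) and the Matthews
correlation coefficient; the MCC-optimal threshold defines the high-risk
zone. Zero-denominator metrics propagate as `NA`, never silently as 0, and
MCC is 0 when a marginal is empty. `precision_trend()` is the Spearman
correlation of threshold versus precision — a calibrated score should show
a positive trend (precision ties at 1 cap the correlation below 1 even for
perfectly separated panels). Fisher's exact test (conditional-MLE odds
ratio with exact CI, via `stats::fisher.test`) summarises a binary panel,
and `pair_delta()` ranks structurally similar compound pairs with a
two-sided one-sample t-test on the score differences. Thresholds are
dataset- and platform-specific (sequencing depth changes how many
differentially expressed genes are detectable), which is why the package
reproduces the calibration *procedure* rather than shipping fixed
thresholds.

`fit_loglogistic()` fits
$f(x) = c + (d - c) / (1 + e^{b(\ln x - \ln e)})$ by Levenberg–Marquardt in
$(b, \ln e, c, d)$: negative $b$ means the response rises with dose, $e$ is
the EC50 in dose-multiple units. Starts come from the response range, the
half-range crossing and a logit-linear slope, plus five jittered restarts
(fixed internal jitter seed, so fits are deterministic); the best SSE wins.
The default four-parameter fit bounds both asymptotes in $[0, 1]$, the
scale of normalised scores; two- and three-parameter variants pin $c$ and
$d$. Flat responses are flagged non-identifiable (slope p-value 1) rather
than silently fit, and non-convergence is reported, never guessed.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `nrot` | 9999 | rotations; sets the p-value floor $1/(n_{rot}+1)$ and hence the score cap |
| `active_z_threshold` | $\sqrt 2$ | $z$ cutoff for an "active" gene in PropUp/PropDown |
| `mixed_floor` | $\Phi^{-1}(0.75)$ | floor on $|z|$ in the mixed floormean statistic |
| `trend` | off for log-intensity input, on for log-CPM counts | abundance-dependent prior variance |
| `norm_min`, `norm_max` | 0, 4 | min–max normalisation constants (matched to `nrot = 9999`) |
| `n_noise_iter` | 50 | noise-injection iterations |
| `ridge_points` | 10000 | size of the visualisation sample |
| `prior_count` | 0.5 | log-CPM pseudo-count |

## The synthetic generator

`simulate_experiment()` produces the structure the score assumes: per-gene
Gaussian baselines on the log2 scale, an optional shared latent factor
(inter-gene correlation), and a log2 shift applied to a configurable
fraction of signature genes in treated samples, scaled across doses by a
log-logistic factor. Defaults describe a realistic hepatocyte screen: a
241-gene signature over 8 regulons in a 2000-gene background, 3 replicates
per group, doses 0.1/1/10 × C~max~, Hill slope −0.7 with midpoint at
1 × C~max~, log2 effect size 1 on half the signature genes (half up, half
down) and residual SD 0.5. A Poisson-lognormal count mode is available
through `log_cpm()` to exercise the count path. What the generator does
*not* emulate — plate effects, library-size artefacts of shallow 3′
protocols, donor disease biology, and compound-specific pathway structure —
bounds what green tests mean: they certify the statistical machinery, not
biological validity on any particular real dataset.

`simulate_compound_panel()` builds labelled panels (positives with the
configured effect, negatives with zero effect) for exercising calibration
end-to-end; each compound draws an independent substream of the master
seed, so panels are reproducible and order-independent.

## Numerical choices and degenerate inputs

* Random rotations are normalised standard-normal vectors — exactly
  uniform on the sphere, and cheap.
* $z$ from $t$ uses `pt(..., log.p = TRUE)` tails, so $|t| > 37$ does not
  saturate to `Inf`.
* $d_0$ estimates above $10^6$ are reported as `Inf`; with no excess
  dispersion the prior variance falls back to the mean of the observed
  variances.
* Exact within-group replicates leave residual variances at the rounding
  error of the orthogonal transform; a relative zero-guard treats them as
  zero, and an experiment where *every* gene is exact is rejected as
  degenerate (no variance-based test is meaningful there).
* Probe collapse keeps the highest-mean probe verbatim; ties keep the
  probe first in input order (deterministic, measure-zero on real data).
* Ortholog mapping keeps only one-to-one pairs: ambiguous mappings are
  dropped and counted, never aggregated into invented expression values.
* Sets are intersected with measured genes (losses logged); a set with
  fewer than two measured genes is skipped with a warning, an empty
  intersection is an error naming the set.
* Paired score deltas that are constant to machine precision are treated
  as degenerate (p = 1 at zero, p = 0 flagged otherwise) instead of
  feeding a zero-variance t-test.

## Problem sizes used by the test suite

The suite validates the statistics at sizes chosen to give tight checks in
seconds: type-I error over 500 null simulations (200 genes × 6 samples,
999 rotations), oracle agreement against $10^6$ brute-force rotations on a
4-gene set, prior recovery from 2000 simulated variances over 20 seeds,
correlation-robustness over 300 simulations, and EC50 recovery over 50
noisy fits. Production-scale runs (e.g. 9999 rotations × 50 noise
iterations on a 241-gene signature) scale linearly in rotations ×
iterations × set size.

## Known limitations

* The score is sign-agnostic at the set level; a regulon driven half up
  and half down scores like one driven uniformly up. The per-TF breakdown
  (`regulon_breakdown()`) is the tool for direction-aware follow-up.
* Compounds with weak transcriptomic responses produce low scores
  regardless of their clinical risk; the score measures transcriptional
  perturbation, not toxicity per se.
* Calibrated thresholds do not transfer across platforms or depths; they
  must be re-derived per dataset with `threshold_sweep()`.
* The noise-injection mean is conservative (biased low) near the decision
  boundary, as discussed above.
* The bundled signature file is a synthetic stand-in with the canonical
  *structure* (8 regulons, 241 distinct targets, JUN the largest with 53);
  analyses of real data should supply the genuine regulon table or
  signature GMT.
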