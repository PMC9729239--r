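---
title: "Methods: summary-statistic MVMR mediation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-statistic MVMR mediation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## Model and assumptions

`mrmediate` dissects the causal effect of a molecular exposure $E$ (e.g. DNA
methylation at a CpG probe) on an outcome $Y$ into a direct part and a part
mediated by $k$ cis molecular mediators $M_1,\dots,M_k$ (e.g. transcript
levels), using only per-variant summary statistics and an LD reference. The
genetic instruments must satisfy the usual MR assumptions (associated with
the trait they instrument; independent of confounders; no pathway to $Y$
other than through the instrumented traits), and the mediation decomposition
additionally assumes a forward causal chain $E \to M_k \to Y$ in which the
direct and indirect effects are additive:

$$\theta_T = \theta_D + \sum_k \alpha_{EM,k}\,\alpha_{MY,k}.$$

All inputs are standardized to the per-SD scale, $\beta = z/\sqrt{n}$ and
$\mathrm{se} = 1/\sqrt{n}$, so that $\mathrm{var}(\beta) = 1/n$ exactly; this
single variance convention is used everywhere downstream
(`standardize_effects()`). For binary outcomes supplied as log-odds ratios
the estimates should be read on the liability scale.

The total effect uses the correlated-instrument IVW estimator
(`ivw_correlated()`),
$\hat\theta_T = (\beta_E' C^{-1}\beta_E)^{-1}\beta_E' C^{-1}\beta_Y$, and the
direct effect its multivariable analogue (`mvmr_correlated()`) with the
instrument-effect matrix $B$ (exposure in column 1). Accounting for the LD
matrix $C$ lets the instrument set be only mildly pruned ($r^2<0.05$), which
matters because the MVMR fit needs more instruments than mediators.

## Instrument and mediator selection

* Exposure instruments: cis ($<1$ Mb), $P<10^{-6}$, greedy $r^2<0.05$
  pruning in ascending p-value order; at least 5 must survive for a pair to
  enter the screen.
* Steiger directionality filter: an instrument is kept for use against a
  downstream trait only if
  $t = (|\beta_{up}| - |\beta_{down}|)/\sqrt{\mathrm{var}(\beta_{up}) +
  \mathrm{var}(\beta_{down})} > t_{rev} = -2$, a one-sided normal test at
  $p = 0.023$. It is applied to exposure instruments against the outcome and
  against every retained mediator, and to mediator instruments against the
  outcome. After all filters at least 3 exposure instruments must remain.
* Mediator candidacy: transcripts with TSS within $\pm 500$ kb of the probe
  whose exposure-to-mediator IVW p-value passes $P_{EM} < 0.01$ (the default;
  the threshold is exposed because both too-lenient and too-stringent values
  bias the MP downward — see the simulations below).
* Pooled instruments: mediator instruments are prioritized by a rank score
  (sum over mediators of the instrument's p-value rank; an instrument absent
  from a mediator's list receives that mediator's worst rank plus one — the
  construction is only specified up to this convention, and ties are broken
  by minimum p-value then position) and clumped greedily against the
  already-kept exposure instruments, which are never displaced: exposure
  instrument strength is the binding constraint.
* Unreported effects: QTL tables publish only significant rows, so effects
  absent from a table enter $B$ as exact zeros rather than as noisy
  near-zero estimates; this deliberately reduces regression dilution.

## Standard errors, heterogeneity and instrument strength

The Delta-method SE sandwiches a diagonal $\Sigma$ with
$\Sigma_{ii} = \max(s^2, \mathrm{var}(\beta_{Y_i}))$ between
$C^{-1/2}$-decorrelated design vectors. Two conventions are deliberate:

* $s^2$, the regression variance, is the $C^{-1}$-weighted residual variance
  with $m-1$ (univariable) or $m-(k+1)$ (MVMR, floored at 1) degrees of
  freedom; for a single instrument $s^2 := \mathrm{var}(\beta_{Y_1})$.
* $C^{-1/2}$ is the symmetric eigendecomposition root (not Cholesky), so
  estimates and Q statistics are invariant to instrument order.

Heterogeneity Q is computed on the decorrelated residuals,
$Q = \sum_i u_i^2/\Sigma_{ii}$ with $u = C^{-1/2}(\beta_Y - B\hat\theta)$,
with $m-1$ df in the univariable fit and $m-k$ df in the MVMR fit (the
printed convention; note it is not $m-(k+1)$). When $C=I$ this reduces to
the familiar IVW Cochran's Q. Because $\Sigma$ uses
$\max(s^2,\mathrm{var}(\beta_{Y_i}))$, Q is conservative in strongly
heterogeneous sets relative to a fixed-effect-weighted Q.

The conditional F-statistic of the exposure given the mediators follows the
Sanderson construction: regress the exposure's instrument-effect column on
the mediator columns ($C^{-1}$-weighted), then

$$F_{cond} = \frac{n_E\,\delta' C^{-1} \delta}{m\,\sigma_v^2},\qquad
\sigma_v^2 = \sigma_E^2 - 2 g'\sigma_{EM} + g'\Sigma_{MM} g,$$

with $\delta$ the residual vector, $g$ the regression coefficients and the
$\sigma$ terms from the phenotypic correlation matrix of (exposure,
mediators). Individual-level mediator correlations are usually unavailable,
so the identity matrix is the default ($\sigma_v^2 = 1 + g'g$); a supplied
correlation matrix switches on the adjusted variant. With no mediators the
statistic reduces to the mean per-instrument F ($n_E\sum\beta_{E_i}^2/m$),
and an exactly collinear mediator drives it to 0. Values $\le 10$ flag
weak-instrument risk.

## Mediation proportions

For a set of pairs, the unmediated proportion is the no-intercept slope
$\hat\gamma = \sum\hat\theta_D\hat\theta_T/\sum\hat\theta_T^2$. The regressor
is noisy, so the slope is attenuated; the dilution correction divides by
$\sqrt{1 - \sum \mathrm{SE}^2(\hat\theta_T)/\sum\hat\theta_T^2}$ and
$\widehat{MP} = 1 - \hat\gamma_{cor}$. The SE of $\hat\gamma$ uses the
classical homoskedastic no-intercept formula and is scaled by the same
denominator (the correction's own uncertainty is ignored, consistent with
symmetric reported CIs). Group MPs come only from this slope, never from
averaging per-pair MPs; per-pair MPs ($1-\hat\theta_D/\hat\theta_T$) are
reported unclamped and without variance. Pairs in which no cis transcript
passes $P_{EM}$ are "non-detectable" ($\hat\theta_D := \hat\theta_T$);
including them gives the *overall* MP, excluding them the *detectable* MP,
and pairs with no cis transcript at all are excluded from both. Two MP
estimates are compared with a z-test on the corrected slopes assuming
independence, which is lenient when the pair sets overlap.

## Simulation engine

`simulate_dataset()` draws, per replicate: exposure instrument effects
rescaled to exactly $h^2_E$; per-mediator direct effects rescaled to
$h^2_{M,direct}$; causal pairs $(\alpha_{EM}, \alpha_{MY})$ from a bivariate
normal (variances `var_alpha_*`, correlation $\rho$) for the $N_{med}$
relevant mediators and zero for the rest; and
$\theta_D = \theta_M(1/MP - 1)$. Observed summary statistics add independent
noise with variance $1/N$ per dataset — the sampling variance of a
standardized effect estimate — and exposure effects at mediator-instrument
positions are re-zeroed to mimic reporting thresholds. Instruments are
mutually independent ($C=I$), and only the relevant mediators carry own
instruments (the instrument grid has $m_E + N_{med}\,m_M$ positions); a null
mediator that slips past selection therefore contributes a pure-noise
column, which is exactly the weak-instrument mechanism a too-lenient
$P_{EM}$ exposes. No Steiger filtering is applied in the simulated chain:
the generative model is strictly forward-causal and instruments are strong.

Defaults ($m_E = m_M = 10$, $h^2_E = h^2_{M,direct} = 0.1$,
`var_alpha` $= 0.05$, $\rho = 0$, $N = 30{,}000$, true MP $0.35$, 2 of 12
mediators relevant, 500 replicates) were calibrated once so that conditional
F-statistics (~100) and mediator-selection behaviour sit in the regimes
observed in real cis-QTL applications; all are config-exposed. Under these
conditions the estimator shows a small downward bias (mean
$\widehat{MP} \approx 34\%$), driven mostly by incomplete mediator selection
(~1.7 of 2 detected); cutting the mediator sample size to 3,000 deflates
the MP further (~13% relative) with only ~1.0 of 2 relevant mediators
detected. `N_med_sig` counts *relevant* mediators passing $P_{EM}$; the
total selected count (including false positives) is recorded separately.
Per-replicate random streams are derived from the master seed and the
replicate index, so scenarios are bit-reproducible.

## Pleiotropy null simulation

To ask whether an observed exposure–transcript association could arise from
chance LD between nearby QTL signals, the transcript's multivariable eQTL
effects $\beta_{multi} = C_M^{-1}\beta_M$ are reassigned to random instrument
sets drawn from a leniently pruned pool ($r^2<0.5$, position-ordered greedy
pruning — the ordering is a convention), the implied marginal effects at the
exposure instruments are $C_{E,M_j}\beta_{multi}$, and the exposure-to-
hypothetical-transcript MR p-value is recorded;
$P_{sim} = \#(P_{EM,j} < P_{EM})/N_{sim}$. The default $N_{sim}$ is 1,000
(desk scale); production analyses should raise it. The pool defaults to the
pair's own region, with a panel-wide option.

## Synthetic data generator

`region_blueprint()`/`generate_region()` emulate the file-level inputs: an
AR(1) LD panel ($r_{ij} = \phi^{|i-j|}$ — chosen for analytic positive
definiteness; block structures can be built by concatenation), causal QTL
blocks for the exposure and each transcript separated so cross-signal LD is
negligible, marginal effects $C\beta_{causal}$ observed with $1/n$ noise,
shared allele frequencies (with an optional perturbation to exercise the AF
filter), and per-table reporting thresholds ($P<10^{-6}$ mQTL-style,
$P<1.8\times10^{-5}$ eQTL-style, complete GWAS). Defaults mirror large
consortium sample sizes (32,851 exposure; 31,684 mediator; 300,000 outcome).

What the generator does **not** emulate — hence what passing tests do not
show about real data: realistic block-wise LD and allele-coding quirks;
sample overlap between datasets; a dominant top QTL (synthetic instruments
have comparable strength, so e.g. the leave-top-IV variant does not
necessarily lower conditional F here, while in real data it does);
non-additive or reverse-causal architectures; and multi-allelic variants,
which the harmonizer drops.

Harmonization inside the screen is anchored on the outcome GWAS (assumed
complete): each molecular table is aligned pairwise against it, keeping its
own reported variants, because requiring every variant in every table would
contradict the reporting-threshold design. Synthetic panels are generated
allele-aligned; for external panels with allele annotations the harmonizer
sign-aligns the correlations, otherwise the panel is assumed aligned to the
first table's effect alleles.

## Numerical choices and degenerate inputs

* LD matrices are regularized by clipping eigenvalues below $10^{-8}$ before
  any inversion or square root, uniformly.
* Mediator columns making $B$ numerically rank deficient (relative singular
  value $<10^{-10}$, assessed sequentially with column 1 always kept) are
  dropped and recorded; an all-zero or duplicated mediator column therefore
  never changes $\hat\theta_D$.
* Distance-clumping ties (equal $p_T$) break by position; rank-score ties by
  minimum p-value then position.
* $\hat\alpha_{MY,k}$ is replaced by the univariable mediator-to-outcome IVW
  estimate when the mediator has $\ge 3$ own instruments, which disentangles
  correlated mediators better than joint coefficients.
* Dilution correction is undefined when
  $\sum\mathrm{SE}^2 \ge \sum\hat\theta_T^2$; the group is skipped with a
  diagnostic. Groups need $\ge 10$ pairs by default.
* Duplicate variant IDs (multi-allelics) are dropped on read; mismatching
  allele pairs (neither match nor swap) are dropped with a warning.

## Problem sizes used in the tests

The shipped test suite and acceptance script run 500-replicate scenarios
(the study's convention), 30-region synthetic cohorts, and 100-instance
oracle comparisons; everything completes in well under a minute on one CPU.
Scaling the simulation engine up (more mediators, more instruments, larger
panels) is linear in replicates and cubic only in the per-fit instrument
count, which stays small by design.

## Known limitations

Per-pair MP estimates carry no variance (individual-level data would be
required). The MP comparison z-test assumes independent estimates. The
conditional-F default ignores phenotypic correlations among mediators
(identity matrix), which is conservative in spirit but not guaranteed
conservative in magnitude. MVMR heterogeneity uses the printed $m-k$ df
convention. The framework assumes the forward chain $E \to M \to Y$; Steiger
filtering reduces, but cannot eliminate, reverse-causation and horizontal
pleiotropy.
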