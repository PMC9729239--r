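# mrmediate

Three-sample multivariable Mendelian randomization (MVMR) mediation analysis
from summary statistics.

## The problem

DNA methylation (DNAm) at CpG sites causally influences complex traits, but
how much of that influence travels through gene expression? Given only
summary statistics — mQTLs for a DNAm probe (the exposure *E*), cis-eQTLs for
nearby transcripts (candidate mediators *M₁…M_k*), a GWAS for the outcome
trait *Y*, and an LD reference panel — `mrmediate` estimates the **mediation
proportion (MP)**: the fraction of the exposure's total causal effect on the
outcome that is propagated through the assayed mediators. The same machinery
applies to any molecular exposure/mediator layers with cis QTL data.

## The model

All effects are standardized (`β = z/√n`, so `var(β) = 1/n`). With
instrument effects **β**_E on the exposure, **β**_Y on the outcome and LD
matrix **C** between instruments, the total effect is the
correlated-instrument IVW estimate

    θ̂_T = (β_E' C⁻¹ β_E)⁻¹ β_E' C⁻¹ β_Y

with a Delta-method standard error using Σ_ii = max(s², var(β_Yi)). The
direct effect conditional on the mediators comes from the multivariable
analogue

    θ̂_D = (B' C⁻¹ B)⁻¹ B' C⁻¹ β_Y   (first element)

where **B** stacks instrument effects on the exposure (column 1) and each
mediator; effects below a QTL dataset's reporting threshold enter as exact
zeros. Instruments are cis-significant (P < 1e-6), LD-pruned (r² < 0.05),
Steiger-filtered against downstream traits (t_rev = −2, one-sided p = 0.023),
and pooled across mediators by rank-score clumping. Mediators are transcripts
within ±500 kb whose exposure→mediator MR passes P_EM < 0.01.

Across a set of exposure–outcome pairs, the unmediated proportion is the
no-intercept slope γ̂ of θ̂_D on θ̂_T, corrected for regression dilution:

    γ̂_cor = γ̂ / √(1 − ΣSE²(θ̂_T)/Σθ̂_T²),   MP̂ = 1 − γ̂_cor

Diagnostics include Sanderson-style conditional F-statistics (weak
instruments), Cochran-type heterogeneity Q (univariable df m−1, MVMR df m−k),
a leave-top-IV variant, mediator decorrelation (R_med clumping), and a
by-chance-LD horizontal-pleiotropy null simulation (random instrument sets
assigned the real transcript's multivariable eQTL effects via
β_multi = C_M⁻¹β_M, marginalized back through cross-LD).

A generative simulation engine (`sim_config()` / `run_scenario()`) and a
synthetic region/cohort generator (`region_blueprint()` /
`generate_region_cohort()`) make every stage testable without external data.

## Worked example

Simulation: bias of the MP estimator under the default study conditions
(true MP 0.35, 2 relevant of 12 potential mediators, P_EM = 0.01,
n = 30,000, 500 replicates):

```r
library(mrmediate)
run_scenario(sim_config(reps = 500, seed = 1))
#> Scenario: true MP = 0.35 -> MP_hat = 34.2% (95% CI: [33.7%-34.7%]);
#>   mean N_med_sig = 1.68; mean F_cond = 95.6
```

The estimator is mildly downward-biased (34.2% vs the generative 35%),
mostly because on average only 1.68 of the 2 relevant mediators pass the
selection threshold.

Per-pair mediation on a synthetic cis region with two true mediators
(true θ_T = 0.3575, true MP = 0.664):

```r
tr <- data.frame(id = c("TX1", "TX2"), tss_offset = c(4e4, 9e4),
                 alpha_EM = c(-0.5, 0.35), alpha_MY = c(-0.3, 0.25),
                 h2_direct = 0.05, n_qtls = 5)
bp  <- region_blueprint(region_id = "demo", transcripts = tr, theta_D = 0.12)
reg <- generate_region(bp, seed = 8)
pair <- mediate_pair(reg$exposure, reg$transcripts, reg$outcome, reg$ld)
pair
#> <pair_result> demo_probe:outcome [full] status=ok
#>   theta_T = 0.3388 (SE 0.01491), theta_D = 0.1441, MP = 0.575, n_med = 2
pair$mediators[, c("mediator_id", "alpha_EM", "p_EM", "alpha_MY")]
#>   mediator_id alpha_EM     p_EM alpha_MY
#> 1         TX1   -0.452 1.31e-09   -0.364
#> 2         TX2    0.266 5.70e-07    0.324
```

Both transcripts are recovered as mediators with the correct effect signs;
the per-pair MP̂ of 0.575 approximates the generative 0.664 (per-pair MPs
carry no variance estimate and are aggregated across pairs via the
dilution-corrected slope, `estimate_mp()`). The exposure's conditional
F-statistic is 68.5, well above the weak-instrument threshold of 10, and the
product-of-coefficients indirect effect (0.251) agrees with the difference
method (0.339 − 0.144 = 0.195) within estimation error.

A cohort-level screen over many regions, with stage counts, sensitivity
variants and grouped MP estimates, runs through `run_screen()`; a thin CLI
(`inst/cli/mrmediate`) exposes `simulate`, `sweep`, `fixtures`, `screen`,
`scan` and `pleiosim` subcommands.

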