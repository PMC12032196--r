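# restoremeta

Response-ratio meta-analysis of ecosystem recovery experiments: does passive
**ecological restoration** (fencing, land abandonment, natural succession) or
actively assisted **ecological rehabilitation** (fertilization, soil
amendment, afforestation) better recover plant diversity, soil microbial
diversity, and soil phosphorus?

The package is written for synthesists working with long-format compilations
of field experiments — one row per treatment/control comparison per study —
and implements the full analysis chain such a synthesis needs: data
preparation with explicit dispersion-handling rules, effect-size computation
with within-study weight adjustment, random-effects pooling with subgroup
contrasts, publication-bias diagnostics, response-ratio regressions, and
covariance-based path analysis. A synthetic-data generator with known ground
truth makes every step testable end to end.

## The model

Each observation compares a treatment mean `X̄t` (after recovery) with a
control mean `X̄c`, both strictly positive. The effect size is the log
response ratio with its large-sample variance:

```
lnRR = ln(X̄t) − ln(X̄c)
v    = s_t² / (n_t X̄t²) + s_c² / (n_c X̄c²)
```

SEs reported instead of SDs are converted by `SD = SE·√n`; SDs missing
entirely are imputed as one tenth of the group mean. The initial weight is
`w = 1/v`; when one study contributes `n` observations of the same variable,
each observation's weight is adjusted to `w′ = w/n` so the study's total
influence does not grow with how finely it sliced its measurements. Pooling
is the adjusted-weight mean, back-transformed to a percentage change:

```
lnRR′̄ = Σᵢ lnRRᵢ·w′ᵢ / Σᵢ w′ᵢ        %change = (exp(lnRR′̄) − 1) × 100
```

Between-study variance τ² is estimated by DerSimonian–Laird or REML on
study-level collapsed effects (optionally shared across the subgroup cells
of a variable, the assumption a moderator-style multilevel fit makes), and
the pooled standard error carries it at the study level, since observations
within a study share its true effect. An effect is significant when its 95%
CI excludes zero; recovery types are compared per variable by a two-sided
z-test on the difference of pooled effects.

Publication bias: Egger's regression of `lnRR/se` on `1/se` (intercept =
asymmetry), and Duval–Tweedie trim-and-fill (`L0`/`R0` estimators) for
variables that fail the Egger screen; bias is declared immaterial when the
original pooled effect lies inside the 95% CI of the filled-set estimate.

Relationships among response ratios (soil P vs. biomass/diversity) are
unweighted OLS fits on study-level paired lnRRs. The path model
(MAT/MAP → biomass & diversity → STP/SAP) is fit by minimising the
maximum-likelihood covariance discrepancy
`F = ln|Σ(θ)| + tr(SΣ⁻¹) − ln|S| − p`; a model is accepted when
RMSEA < 0.08, χ²/df ∈ [0, 2], and NFI, CFI or IFI exceeds 0.9.

## Worked example

```r
library(restoremeta)

sim <- generate_meta_dataset(meta_sim_config(seed = 42))   # 72 studies
tab <- assign_subgroups(prepare_observations(sim$table, strict = FALSE))
tab
#> <study_table> 563 observations from 72 studies (source: <in-memory>)
#>   prep: 368 SE->SD conversions, 132 SD imputations, 0 rows dropped
#>   subgroups assigned (ecosystem, duration_bin)

eff <- compute_effects(tab)                 # lnRR, v, w, w' per observation
sm  <- recovery_type_summary(eff)           # forest-plot-style summary
sm[sm$variable %in% c("AGB", "STP"), c("variable", "recovery_type", "k",
   "lnrr_bar", "ci_low", "ci_high", "pct_change", "contrast_p", "stars")]
#>  variable  recovery_type  k lnrr_bar ci_low ci_high pct_change contrast_p stars
#>       AGB rehabilitation 31    0.368 0.2464   0.489       44.5     0.0546    ns
#>       AGB    restoration 32    0.522 0.4222   0.622       68.6     0.0546    ns
#>       STP rehabilitation 24    0.145 0.0157   0.274       15.6     0.7306    ns
#>       STP    restoration 77    0.171 0.0938   0.249       18.7     0.7306    ns
```

Read: aboveground biomass rose 68.6% under passive restoration (k = 32
observations, CI excludes zero) versus 44.5% under rehabilitation; the
z-contrast between the two recovery types is not significant at α = 0.05
(p ≈ 0.055). Soil total phosphorus rose modestly and similarly under both.
These numbers are simulated — the generating truths are `lnRR = 0.5` (AGB)
and `0.15` (STP) for both recovery types — which is exactly what makes the
example verifiable.

One-command orchestration, writing `effects.csv`, `pooled_summary.csv`,
`bias_reports.csv`, per-panel relationship CSVs, `sem_fits.json` and a
`run_manifest.json` that reproduces the run bit for bit:

```r
run_full_analysis(run_config(input = "observations.csv", out_dir = "out"))
# or: run_full_analysis(run_config(simulate = TRUE, out_dir = "out", seed = 1))
```

A thin command-line wrapper lives at `inst/cli/restoremeta.R`
(`Rscript restoremeta.R simulate --out outdir --seed 1`).

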