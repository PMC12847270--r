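# paddysoilq

Desk-scale analysis pipeline for long-term rice–eel co-culture
fertilization experiments — for soil scientists and agronomists comparing
fertilization regimes (conventional chemical control RT; eel co-culture
variants IRT, I70, and the straw/organic substitution treatments IS, IO)
across soil depths in a randomized block design.

The package computes, from tidy per-plot tables:

* **Water-stable aggregate indices** from wet-sieve fraction masses over
  six size classes: the macroaggregate share `R0.25 = M(>0.25mm) / M_T`,
  the mean weight diameter `MWD = Σ Xᵢ Wᵢ`, and the geometric mean diameter
  `GMD = exp(Σ Wᵢ ln Xᵢ / Σ Wᵢ)` (always ≤ MWD).
* **Alpha diversity** per sample: Gini–Simpson `1 − Σ pᵢ²`, Shannon
  entropy, and Pielou evenness `H / ln S`.
* **Treatment-effect summaries**: percent change versus the control,
  one-way ANOVA with Tukey HSD compact letter displays, and Pearson
  correlation matrices with p-values.
* **Grey relational analysis (GRA)** to rank treatments over a
  treatments × indices matrix: mean normalization `y = X/X̄`, relational
  coefficients `ε = (Δmin + ρ Δmax)/(Δ + ρ Δmax)` (Deng's construction,
  default, plus a literal textbook variant), grey relational degree
  `β = mean(ε)`, and a ranking with tie flags.
* A **seeded synthetic-data generator** emulating the 5-treatment ×
  2-depth × 3-replicate design with multiplicative treatment effects,
  lognormal measurement noise, Dirichlet sieve compositions, and
  Dirichlet-multinomial taxon counts — calibrated by default to the
  reference study's published gene-copy means and percent-change
  statements (`default_calibration()`).

See the methods vignette (`vignettes/soil-quality-gra.Rmd`) for the models,
conventions and limitations.

## Worked example

```r
library(paddysoilq)

# percent change of topsoil bacterial gene copies vs the RT control,
# from the published treatment means the package ships
tab <- gene_copy_table()
b <- subset(tab, variable == "bacterial_copies" & depth == "D0_20")
data.frame(treatment = b$treatment,
           pct = round(percent_change(b$mean, b$mean[b$treatment == "RT"]), 2))
#>   treatment   pct
#> 1        RT  0.00
#> 2       IRT 15.05
#> 3       I70 13.12
#> 4        IS 26.36
#> 5        IO 78.96

# full pipeline on calibrated synthetic data
res <- run_pipeline(list(simulate = TRUE, seed = 1, out_dir = "psq-out"))
res$gra
#> Grey relational analysis (deng_standard mode, 5 treatments x 20 indices)
#> Ranking: IO > IS > IRT > I70 > RT
#>   treatment    grd rank
#> 1        IO 0.9337    1
#> 2        IS 0.8442    2
#> 3       IRT 0.7296    3
#> 4       I70 0.6735    4
#> 5        RT 0.6647    5
```

The percent changes are the effect sizes the study design is about (IS
+26%, IO +79% bacterial abundance in topsoil); the GRA ranking says organic
fertilizer substitution (IO) improves the combined soil-quality battery
most and the eel-free control (RT) least. `run_pipeline()` writes
`aggregates.csv`, `diversity.csv`, `effects.csv`, `gra.csv`, a Markdown
report with the same numbers, a provenance `config.json`, and a run log;
reruns with the same seed are byte-identical.

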