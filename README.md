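# modvelo: modular Bayesian RNA velocity

RNA velocity infers the direction and speed of cellular differentiation from
the ratio of unspliced to spliced mRNA counts in single-cell RNA-seq. Classic
velocity models assume each gene switches once between a fixed ON and OFF
transcription rate, which breaks down for trajectories with transcriptional
boosts, weak signals in mature cell types, or multiple overlapping programs.

`modvelo` implements a modular velocity model for R users: the gene-level
transcription rate is expanded into a sum of *modules*, independently
switching transcriptional programs with simple linear kinetics,

```
d(alpha_mg)/dt = lambda_mi (alphahat_mgi - alpha_mg)      (target rate: alphahat, 0 when OFF)
d(u_mg)/dt     = alpha_mg - beta_g u_mg                   (splicing rate beta)
d(s_mg)/dt     = beta_g u_mg - gamma_g s_mg               (degradation rate gamma)
```

with module switch-on/off times `T_m,ON < T_m,OFF` and per-cell latent times
`T_c` shared across genes. Every module ODE — and by linearity their sum —
is solved in closed form (numerically stable divided-difference expressions,
no ODE integrator in the model), so the expected unspliced/spliced counts and
the RNA velocity `ds/dt = sum_m (beta u_m - gamma s_m)` are exact analytic
functions of the parameters. Observed raw counts are modeled as negative
binomial (mean–concentration convention, `Var = mu + mu^2/a`) around
measurement expectations that include per-cell detection efficiency, a
spliced/unspliced modality factor, ambient RNA per batch, and per-gene
overdispersion. Modules double as an interpretable, mechanistic analog of
factor analysis: each has marker genes, an activation level per cell, a
kinetic state (OFF / induction / ON / repression) and a steady-state
expression signature usable as a reference for spatial deconvolution.

Inference is fully Bayesian with two backends behind one `mv_fit()` surface:
a fast MAP + Laplace approximation (compiled analytic gradients of the joint
posterior; good point estimates for rate recovery) and mean-field stochastic
variational inference (reparameterization gradients + Adam; calibrated
posterior uncertainty, e.g. for the posterior-time coefficient of variation
used as a dataset-level quality control). A forward simulator with complete
ground truth, the cross-boundary directional correctness (CBDir) benchmark
metric, and a small CLI round out the package.

## Worked example

```r
library(modvelo)

# simulate 300 cells x 100 genes from the generative model (2 modules)
sim <- simulate_counts(n_cells = 300, n_genes = 100, n_modules = 2, seed = 11)

# fit; n_samples = 30 joint posterior draws via the Laplace approximation
fit <- mv_fit(sim$data, n_modules = 2, seed = 1)
fit
#> <mv_fit> 300 cells x 100 genes, 2 modules, 30 posterior samples
#>   final log posterior: -67705.18 (566 evaluations)

# how well are the kinetic rates recovered?
recovery_score(sim, fit)
#> # A tibble: 2 x 3
#>   parameter        spearman pearson
#>   <chr>               <dbl>   <dbl>
#> 1 splicing_rate       0.916   0.901
#> 2 degradation_rate    0.931   0.936

# module analytics
module_markers(fit, k = 3)          # genes ranked by explained rate fraction
module_states(fit)                  # OFF / induction / ON / repression per cell
steady_state_reference(fit)         # g_mg = alphahat_mg / gamma_g signatures

# posterior-averaged velocity graph and trajectory-direction benchmark
vg <- velocity_graph(fit, n_samples = 30)
ve <- embed_velocity(vg, sim$data$embedding)
cbdir(sim$data$embedding, ve, sim$data$clusters,
      data.frame(source = c("stage1", "stage2"),
                 target = c("stage2", "stage3")))
#> # A tibble: 2 x 4
#>   source target n_boundary cbdir
#>   <chr>  <chr>       <int> <dbl>
#> 1 stage1 stage2         36 0.459
#> 2 stage2 stage3         29 0.687
```

The Spearman correlations above say that the per-gene splicing and
degradation rates — the quantities velocity is a function of — are recovered
to rank correlation ≈ 0.92-0.93 from raw counts alone; the positive CBDir
values say the inferred velocity flow crosses both cluster boundaries in the
simulated ground-truth direction.

A command-line tool mirrors this workflow
(`inst/cli/modvelo simulate|fit|analyze|benchmark`).

## Vignette

`vignettes/modular-velocity.Rmd` documents the model, priors, inference
backends, simulator design and known limitations.
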