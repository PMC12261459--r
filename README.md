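# rvinn

Time-varying mRNA kinetics from unspliced/spliced time courses, inferred
with physics-informed neural networks.

## The problem

Time-course RNA-seq measures, per gene, an intronic signal (a proxy for
unspliced pre-mRNA, *U*) and an exonic signal (mature spliced mRNA, *S*).
The mRNA lifecycle couples them:

```
dU/dt = α(t) − β(t)·U        (transcription in, splicing out)
dS/dt = β(t)·U − γ(t)·S      (splicing in, degradation out)
```

Resolving the time-varying transcription rate α(t), splicing rate β(t) and
degradation rate γ(t) from a handful of noisy time points is an ill-posed
ODE inverse problem: classical approaches force the rates into rigid
parametric families. `rvinn` instead represents the state and all three
rates with small tanh neural networks and trains them jointly against a
loss that combines the data misfit, the ODE residual at dense collocation
times (evaluated via exact analytic differentiation of the networks), and
a soft constraint that splicing efficiency changes slowly:

```
L(θ, λ1, λ2) = L_data + λ1·L_ode + λ2·L_aux ,   min over θ, max over λ
```

The adaptive weights λ grow (gradient ascent, gated on a decreasing total
loss) so early training fits the observed patterns and late training
enforces the physics — the self-adaptive weighting that stabilizes PINN
inverse problems. Each gene gets an ensemble of random restarts (Adam, then
L-BFGS refinement) whose estimated trajectories are averaged.

The package is for computational biologists who want genome-wide,
per-gene, smoothly time-resolved kinetic estimates from ordinary bulk
time-course RNA-seq — no metabolic labeling, no live imaging — plus the
downstream analyses this enables: transcriptional synchrony along the
genome, enhancer-proximity effects, dynamic transcriptional buffering, and
RNA-binding-protein target enrichment.

## Worked example

Simulate one regulated gene at the hardest benchmark design (9 time points,
sampling interval 180 min, triplicates, 30% noise), fit it, and compare the
recovered kinetics with the retained ground truth:

```r
library(rvinn)

spec  <- scenario_spec("steady_to_steady", n_genes = 1, seed = 42)
gene  <- simulate_scenario(spec, sampling_interval = 180, noise_frac = 0.3)[[1]]
fit   <- train_ensemble(gene$observations,
                        train_cfg = train_config(adam_max_iter = 1500,
                                                 lbfgs_max_iter = 1500,
                                                 n_restarts = 3, seed = 7))
evaluate_gene(fit, gene$truth_grid)
#>        gene_id  cc_alpha  cc_gamma rel_l1_beta
#> 1 sim_gene_001 0.9975564 0.9674401   0.4469689

head(predict_dense(fit), 3)
#>   time    U_fit    S_fit    alpha      beta      gamma
#> 1    0 13.10672 45.37954 1.891288 0.1402116 0.03989306
#> 2    1 13.11629 45.38861 1.891745 0.1402116 0.03992263
#> 3    2 13.12580 45.39746 1.892198 0.1402115 0.03995226
```

`cc_alpha` and `cc_gamma` are lag-0 Pearson cross-correlations between the
estimated and true transcription/degradation trajectories on a 1-min grid
over the 24-h window (1 = shapes recovered perfectly); `rel_l1_beta` is the
relative L1-error of the splicing-rate trajectory (0 = exact). Here the
transcription program is recovered almost perfectly, the degradation
dynamics closely, and the splicing rate — the parameter these data
constrain least (its scale is only weakly identified; see the vignette) —
to within ~45%. `predict_dense(fit)` returns the fitted state and all
three rate trajectories minute-by-minute (rates per minute, abundances in
the input units); `classify_buffered(fit)` turns a fit into a
dynamic-buffering call.

A command-line front end for array-job-scale runs ships in
`inst/cli/rvinn.R` with subcommands `simulate`, `preprocess`, `train`
(shardable via `--shard k/N`), `evaluate` and `analyze`.

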