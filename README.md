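# tnseascape

Time-resolved fitness analysis for longitudinal RB-TnSeq experiments.

Pooled, randomly barcoded transposon (RB-TnSeq) libraries measure
genome-wide knockout fitness, but a single endpoint readout cannot see
effects that reverse sign as a batch culture moves through growth,
stationary phase, death phase, and long-term stationary phase.
`tnseascape` takes poolcount-style barcode count tables sampled at several
days, derives per-barcode **selection rates** (days⁻¹ — the per-day change in
log abundance relative to an empirically neutral gene set), and infers
gene-level rates for each sampling interval with a hierarchical Bayesian
model. On top of the interval estimates it fits a one-dimensional Fisher's
geometric **seascape**: every mutant gets a latent phenotypic coordinate
*z*, every interval a quadratic fitness landscape, and the moving optimum is
tied through time by a discretized Ornstein–Uhlenbeck process.

The package is aimed at microbial functional genomicists running pooled
fitness assays in temporally structured environments (starvation, feast /
famine cycling, stress sequences).

## The models in brief

**Longitudinal model.** Barcode-level rates in interval *d* (intervals
0→1, 1→4, 4→10 days) are

> rate(b, r, d) ~ Normal(β_d + u_{g(b),d}, σ_d)

with gene effects (u_{g,1}, u_{g,2}, u_{g,3}) — parameterized as an
interval-1 intercept plus two slope contrasts — drawn from a multivariate
normal with half-Student-t scale priors and an LKJ(2) correlation prior.
Posteriors come from a blocked Gibbs/Metropolis sampler with conjugate
gene- and population-effect updates, gated on split-chain convergence
(Rhat < 1.01 for ≥ 99 % of parameters). The net rate is the
duration-weighted average `snet = 0.1·s1 + 0.3·s2 + 0.6·s3`; genes are
called beneficial/deleterious at posterior tail probability ≥ 0.9, and
interval tables are summarized by the skew (B − D)/(B + D).

**Seascape model.** Gene-level posterior summaries (median, sd) are treated
as noisy observations of

> s_{g,d} = α_d − ½ κ_d (z_g − θ_d)²

with per-interval peak α_d, curvature κ_d ≥ 0, and optimum θ_d;
θ follows a discretized OU process over interval midpoints. The
time-weighted integrated landscape has the closed-form optimum
`z* = Σ w_d κ_d θ_d / Σ w_d κ_d`, and regulator coordinates can be compared
against signed sums of their regulons' coordinates.

**Benchmark simulator.** `simulate_tnseq()` generates barcode trajectories
with three explicit noise channels (intragenic rate variation, per-observation
measurement error, per-replicate-sample batch offsets, each at sd 0 / 0.1 / 1
days⁻¹), and `run_benchmark_grid()` scores the Bayesian model against a
BarSeq-style t-interval baseline by RMSE and 90 %-interval coverage over the
27-condition grid, with bootstrap confidence intervals.

## Worked example

The packaged toy fixture has 30 barcodes in 10 genes (3 of them neutral
references) over days 0/1/4/10 with three replicates per day:

```r
library(tnseascape)
md <- read.delim(system.file("extdata", "toy_metadata.tsv", package = "tnseascape"))
md$replicate <- as.character(md$replicate)
pc <- read_poolcount(system.file("extdata", "toy_poolcount.tsv",
                                 package = "tnseascape"), md)
pc <- positional_correction(filter_day0(pc), window = 11)
ab <- clr_transform(pc, readLines(system.file("extdata", "toy_neutral.txt",
                                              package = "tnseascape")))
rates <- compute_selection_rates(ab)
fit <- fit_longitudinal(rates, model_spec(seed = 1))
summary(fit)
```

```
tnfit: 10 genes, 4000 draws (4 chains x 1000), seed 1
convergence: passed (100.0% of parameters with Rhat < 1.01, max Rhat 1.007)

classification at threshold 0.900:
 quantity B D total       skew
       s1 5 2     7  0.4285714
       s2 2 5     7 -0.4285714
       s3 3 6     9 -0.3333333
     snet 4 6    10 -0.2000000
```

Five gene disruptions are confidently beneficial in the first day and two
deleterious (skew +0.43); the balance reverses in the death-phase interval
(−0.43). `coef(fit)` returns the posterior-median rate matrix, e.g.

```
          s1     s2     s3   snet
b0005  0.030 -0.090  0.544  0.302
b0009 -0.150 -0.792 -0.227 -0.389
```

so disrupting `b0005` is near-neutral early but strongly beneficial late
(net +0.30 days⁻¹ — a ~20-fold abundance gain over 10 days), while `b0009`
is deleterious throughout. Downstream, `fit_seascape()` consumes
`fit$summaries`, `cluster_trajectories()`/`pca_trajectories()` group the
median trajectories, and `regulon_enrichment_null()` /
`mutation_count_permutation()` provide permutation nulls. `run_pipeline()`
orchestrates all stages from a YAML config and writes TSV artifacts plus a
hashed manifest.

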