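# ssglv

Bayesian inference of microbial interaction networks from abundance
time series, built around the discrete-time stochastic generalized
Lotka-Volterra (gLV) model and spike-and-slab variable selection.

## The problem

Synthetic microbial consortia — here a four-member gut community of
*E. coli* (Ec), *S.* Typhimurium (ST), *B. thetaiotaomicron* (BT) and
*B. fragilis* (BF) — are characterized by growing all members together
while perturbing the starting inoculum of one member at a time
(10-fold "knockdowns") and quantifying every strain over a 27-h batch
culture. The question is which microbe-microbe interactions (antagonism,
cross-feeding) shape the community: that is a network-inference problem
over noisy, short, multi-condition time series.

`ssglv` provides the full desk pipeline: a measurement-realistic
simulator for the five-condition knockdown design, the Bayesian
network-inference machinery, and the ecological summaries (Pielou
evenness, log-fold knockdown ratios, EC50 growth-requirement fits) used
to describe consortium behavior. Since the real qPCR trajectory tables
for this design are not publicly deposited, the simulator doubles as
the test bed: every inference claim is validated against synthetic data
with known ground truth.

## The model

Abundances x_{k,i} (CFU/ml, species i at time point k) follow the
discrete-time stochastic gLV update

    x_{k+1,i} = x_{k,i} + x_{k,i} ( r_i + Σ_j a_{i,j} z_{i,j} x_{k,j} ) Δ_k + w_{k,i}

with growth rates r_i, interaction coefficients a_{i,j} (effect of
species j on species i), binary edge indicators z_{i,j}, time steps
Δ_k, and Brownian process-noise increments w_{k,i} with variance
v_i^w Δ_k. Priors: z_{i,j} ~ Bernoulli(0.5) on the off-diagonal edges
(diagonal self-limitation always in the model), r_i | v^r ~ N(0, v^r),
a_{i,j} | v^a ~ N(0, v^a), and diffuse scaled inverse-chi-squared
priors on the variances: Inv-χ²(0.1, 0.01) for v^r, Inv-χ²(0.1, 1e-14)
for v^a, Inv-χ²(0.1, 1e4) for each v_i^w.

Posterior sampling is a partially collapsed Gibbs sweep (5,000
iterations, 1,000 burn-in by default): each edge indicator is updated
with its coefficient integrated out analytically, coefficients are then
drawn from their conjugate Gaussian full conditional, and variances
from their conjugate scaled-inverse-chi-squared conditionals. Edge
evidence is reported as a Bayes factor — posterior odds of inclusion
over prior odds — with the conventional reading: BF in [3, 10] is
substantial evidence, BF > 10 strong; an edge included in every
retained draw has infinite BF (flagged). An optional extension adds
3rd- and 4th-order interaction terms (products of the other species'
abundances) with their own indicators.

## Worked example

Simulate the wild-type-like preset (all-antagonistic truth, 7 of 12
candidate edges present) under the five-condition knockdown design and
infer its network:

```r
library(ssglv)

params <- preset_wt_network(1)
design <- make_knockdown_design(params$species)   # C1 + four knockdowns
gd  <- generate_dataset(params, design, noise_model(measurement_cv = 0),
                        seed = 20260919)
res <- infer_network(gd$dataset, config = mcmc_config(seed = 20260919))
subset(res$summary, bayes_factor > 10)
```

```
   source target inclusion_prob bayes_factor evidence mean_strength sign
1      Ec     ST              1          Inf   strong     -1.10e-10   -1
2      Ec     BT              1          Inf   strong     -8.13e-11   -1
4      ST     Ec              1          Inf   strong     -1.18e-10   -1
5      ST     BT              1          Inf   strong     -1.19e-10   -1
7      BT     Ec              1          Inf   strong     -9.00e-11   -1
...                    (7 strong edges, all negative, matching truth)
```

All 7 true edges are recovered with infinite Bayes factors (included in
every retained draw), the 5 absent edges get BF ≈ 0, and every inferred
sign is negative, matching the antagonistic ground truth. The same run
on the engineered-like preset recovers exactly its two positive
cross-feeding edges (BF→Ec, BF→ST) plus its two negative edges.

Ecological summaries:

```r
tr <- glv_simulate(params, design$conditions$C1, design$sampling_times)
apply(tr$abundances, 1, pielou_evenness)   # 1.000 ... 0.950 at 27 h
pielou_evenness(c(0.25, 0.25, 0.25, 0.25)) # 1: perfectly even
pielou_evenness(c(1, 0, 0, 0))             # 0: complete dominance
```

The numbered scripts under `analysis/` run the whole workflow —
`01_simulate.R`, `02_infer_networks.R`, `03_evaluate_recovery.R`
(including a measurement-noise robustness sweep and the higher-order
null check), `04_ecology_metrics.R` — writing their tables under
`results/`.

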