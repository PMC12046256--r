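---
title: "Generating and auditing artificial patient cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and auditing artificial patient cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

synthcohort builds artificial patient cohorts from small, high-dimensional
clinical tables — the high-dimension, low-sample-size (HDLSS) regime where a
few hundred patients carry close to a hundred mixed-type features — and
audits the result along three axes: statistical fidelity, confidentiality,
and plausibility. This vignette is the package's account of the science: the
models, the knobs that matter, what the synthetic test fixture does and does
not establish, and the numerical choices made where the design was open.

## The pipeline

```{r}
library(synthcohort)

schema <- fixture_schema()
cohort <- simulate_cohort(fixture_config(seed = 1))   # stands in for real data
encoded <- fit_transform(cohort, schema)              # 521 x 103 design matrix
fit <- rhvae(encoded, rhvae_config(epochs = 300, seed = 7))
artificial <- generate_cohort(fit, 5000, seed = 11)
report <- audit_cohorts(cohort, artificial, schema, encoded = encoded)
glance(report)
```

## Encoding mixed-type clinical tables

A `cohort_schema()` types every column as numerical (with a clinical range
and an integer flag), binary (two levels), or categorical (three or more
levels). `fit_transform()` maps a conforming table to a fully numeric design
matrix: numerics min-max scaled to [0, 1] on the observed range, binaries to
a single 0/1 column, categoricals to one-hot blocks. Binary columns
deliberately occupy one column rather than a two-column one-hot: it is the
minimal faithful width, and it is what makes an 85-feature cohort with 19
numerical, 60 binary and 6 four-level categorical columns encode to exactly
19 + 60 + 24 = 103 columns. Decoding inverts every step — unscale, clip to
the schema range, round integer-valued numerics half away from zero,
threshold binaries at 0.5, argmax one-hot blocks with ties broken toward the
lowest-index level — so any real matrix in encoding space becomes a
schema-valid patient table. Missing cells are imputed before encoding
(median for numerics, mode for discrete columns) and counted in a coercion
log; the audit statistics make no allowance for missingness, so imputation
must happen upstream of everything else.

## The generative model

The generator is a variational autoencoder with a learned Riemannian metric
over its latent space. Encoder and decoder are small tanh multilayer
perceptrons (defaults: 103 → 64 → 32 → 10 and its mirror image); the
posterior is diagonal Gaussian; training minimizes the negative ELBO with
Adam at the default schedule — 1000 epochs, batch size 32, learning rate
0.001 — with no scheduler and no early stopping. Scaled-down runs in
the examples and tests use 300 epochs, which on the fixture is past the
point where the loss curve flattens. All gradients are analytic and are
checked against finite differences in the test suite.

**Observation model.** Reconstruction is role-aware: Bernoulli likelihood
for binary columns, categorical (softmax) likelihood within each one-hot
block, and — the one place the package departs from the obvious choice — a
*censored* Gaussian (Tobit) likelihood on [0, 1] for scaled numerics, with a
learned noise scale per coordinate. Min-max scaling of a clinical variable
with a bounded range clips values at the bounds, so a scaled value of
exactly 0 or 1 is a censoring event, not an exact observation: a variable
like pack-years has a large atom at zero, and a plain Gaussian likelihood
both misfits that atom and biases the noise scale downward. Continuous
densities confined to [0, 1] (for instance the continuous Bernoulli, which
is log-linear and therefore monotone) cannot represent concentrated unimodal
clinical marginals at all. The censored Gaussian matches the generative
step exactly — generation draws `mean + noise` and clips — so boundary
atoms, interior shape and noise calibration are all estimated consistently.
Decoder outputs remain in (0, 1) (sigmoid means, softmax blocks) as the
bounded-activation contract requires.

**The learned metric.** The latent metric is parameterized as
$G^{-1}(z) = \sum_i M_i \exp(-\lVert z - c_i \rVert^2 / T^2) + \lambda I$
with centroids $c_i$, positive semi-definite $M_i = L_i L_i^\top$
(lower-triangular $L_i$), temperature $T$ (default 0.8) and regularization
floor $\lambda$ (default $10^{-3}$), which guarantees symmetric positive
definiteness everywhere and $G^{-1} \to \lambda I$ far from the data. The
package learns the metric from the encoder: centroids track the posterior
means of a fixed training subsample (capped at 400 points) by exponential
moving average, and the factors are diagonal, tracking the corresponding
inverse posterior variances — the local precision the encoder itself
reports. The general triangular form is supported throughout
(`metric_inverse()`, `leapfrog_integrate()`); the learned metric simply
happens to be diagonal, and the fast batched diagonal path is cross-checked
against the generic path in the tests.

**Hamiltonian refinement.** After a 10-epoch warm-up, each minibatch's
posterior draw is refined by a few generalized-leapfrog steps (default 3
steps of size 0.01) under the Hamiltonian
$H(z,p) = U(z) + \tfrac12 p^\top G^{-1}(z) p + \tfrac12 \log\det G(z)$ with
$U$ the reconstruction energy plus the prior. The implicit updates are
solved by fixed-point iteration to tolerance $10^{-10}$, which keeps the
integrator reversible and second-order accurate (both properties are
asserted numerically in the tests). Backpropagation through the implicit
flow is approximated by gradient pass-through: the refined point feeds the
decoder, while the encoder receives the reparameterization gradient at the
unrefined draw. With zero leapfrog steps the engine is *exactly* a vanilla
VAE, and the test suite holds it to an independent ELBO implementation at
$10^{-5}$ on a fixed batch. A `kl_warmup_epochs` option can additionally
ramp the KL weight from 0 to 1 to counteract early posterior collapse; it
defaults to off.

## Sampling artificial patients

Generation samples latent points, decodes them, draws each encoded
coordinate from its decoded distribution (censored Gaussian for numerics,
Bernoulli for binaries, categorical per block), and inverse-transforms the
matrix into a schema-valid table. Sampling each coordinate rather than
emitting decoder means is essential for distributional fidelity: means alone
under-disperse every marginal.

The default `"metric-walk"` latent sampler is a Metropolis random walk over
the metric's *local volume measure*: the equal-weight Gaussian mixture in
which centroid $i$ spreads its mass with covariance equal to the local
metric tensor $G(c_i) = (M_i + \lambda I)^{-1}$. Two design points deserve
a record. First, the naive alternative — a density proportional to
$\sqrt{\det G^{-1}(z)}$ of the *summed* kernel metric — looks natural but is
badly mode-seeking in more than a few dimensions: where kernels overlap, the
determinant raises their sum to the $d_z/2$ power, so the measure collapses
onto the densest point of the centroid cloud (we verified the collapse
empirically before discarding it; equilibrated chains under-dispersed every
informative latent direction by 25% and more). The per-centroid mixture
keeps the volume weighting — each component's mass is its local volume
element — while spreading exactly as the learned geometry says the manifold
extends locally. Second, the mixture has an exact sampler, so each walk
starts *in its stationary distribution*; the subsequent Metropolis steps
(default 30, proposal scale half the typical local standard deviation)
explore without any convergence transient, and results cannot depend on
chain length in distribution. Every sample derives its own counter-based
sub-seed from the request seed, so generating 10,000 patients in chunks of
1,000 — or any other chunking — reproduces the unchunked result exactly.
The `"prior-gaussian"` sampler (standard normal draws) is retained as an
ablation baseline; which latent scheme a given study used is generally not
recoverable from its outputs, so both are first-class.

## The audit statistics

**Fidelity** is scored on a 0–100 scale per component and averaged:

- *numerical stability*: per numerical variable, a two-sample
  Kolmogorov–Smirnov test at $\alpha = 0.05$ with asymptotic p-values and no
  multiplicity correction; the score is 100 times the fraction of variables
  not rejected. A test-based definition makes a perfect 100 attainable,
  which a distance-based definition would not.
- *categorical stability*: per binary/categorical variable, 100 times one
  minus the total variation distance between level-frequency vectors,
  averaged over variables.
- *correlation stability*: 100 times one minus the mean absolute
  off-diagonal difference between the Pearson correlation matrices of the
  numerical variables.

The composite is reported to one decimal, rounding half away from zero.
Binary variables are audited as categorical, never numerical. Undefined
components (e.g. a schema with no numerics) are dropped from the mean with
a warning rather than silently scored.

**Confidentiality.** The filter similarity score is the percentage of
artificial records that are not exact duplicates of any real record on all
decoded fields; an optional `epsilon` mode additionally flags artificial
records within a Euclidean threshold in encoded space (off by default,
since "similar" is otherwise undefined). The degree of anonymization
compares each artificial record's nearest-neighbour distance to the real
cohort against each real record's leave-one-out nearest-neighbour distance,
both computed in the min-max-scaled encoded space so that no wide-range
numeric dominates; the cohort is flagged anonymized when the median
artificial-to-real distance reaches the median real-to-real spacing.

A limitation worth stating plainly: a *well-calibrated* generator tends to
sit at an anonymization ratio just below 1. An artificial record differs
from its nearest real neighbour by roughly one draw of observation noise,
while two real records differ by two independent draws; only model bias
pushes artificial records further out. On the synthetic fixture this
package's ratio is reproducibly about 0.98–0.99 — artificial patients are
as far from real patients as real patients are from each other, but not
farther. A pipeline with a smoother (lower-fidelity) decoder clears the
ratio-above-1 bar more easily; ours favors fidelity and reports the flag
honestly. The filter similarity score on the fixture is 100: no generated
record duplicates a training record.

**Plausibility.** For blinded expert categorization tasks,
`categorization_sheet()` samples a balanced set of real and artificial
patients (default 100, i.e. 50 + 50), shuffles them under a seed, and
separates the blinded sheet from the hidden key. `cohen_kappa()` scores a
completed sheet against the key: $\kappa = (p_o - p_e)/(1 - p_e)$ with the
asymptotic Fleiss–Cohen–Everitt standard error for the 95% CI, each rater
scored against ground truth (matching a design that reports one coefficient
per expert). Agreement below 0.2 is interpreted as the rater being unable
to distinguish artificial from real patients; the CI method is a package
choice, validated by a 10,000-task coverage simulation in the tests
(≈95% coverage, mean $|\kappa| < 0.02$ under random guessing).

## What the synthetic fixture is, and is not

Real cohorts of the shape this package targets — a few hundred
pre-anesthesia assessments with 85 mixed-type features — are rarely
shareable, so the package ships a seeded generator of *synthetic* cohorts
of exactly that shape: 19 numerical vitals/labs, 60 binary comorbidity and
medication flags, 6 four-level categorical assessments, encoding to 103
columns. Patients are driven by 4 standard-normal latent factors with
block-structured loadings (cardiometabolic, frailty, inflammation/renal,
lifestyle), so the cohort carries genuine correlation structure for the
correlation-stability audit to preserve; BMI is derived from weight and
height (within 0.5 units); binaries follow prevalence-calibrated logistic
models on the factors; categoricals follow graded softmax responses. Ranges
and prevalences are clinically plausible inventions.

Passing the audit on the fixture therefore shows that the pipeline can
learn and reproduce a factor-driven mixed-type cohort of exactly this
shape; it does not show anything about any particular real cohort's feature
list, marginals, or correlation pattern, and real clinical data bring
pathologies the fixture deliberately lacks (informative missingness,
measurement artifacts, rare-category explosions, longitudinal structure).

## Numerical choices and scales

Scaled-down runs used throughout the package's examples, tests and
acceptance script: 300 training epochs on the 521-patient fixture and
5,000 generated patients — sizes chosen so a complete
train/generate/audit cycle runs in a few minutes on one CPU while remaining
past the loss plateau. Other defaults: latent dimension 10 and hidden
widths (64, 32), sized for HDLSS tabular data; metric temperature 0.8 and
regularization $10^{-3}$; 400 metric centroids at most (EMA rate 0.1);
leapfrog fixed-point tolerance $10^{-10}$ with a 20-iteration cap in
training and $10^{-13}$/100 in the generic integrator; observation noise
scales clamped to $e^{-5}$–$e^{2}$; posterior log-variances clamped to
±8. Degenerate inputs are handled explicitly: constant numerics encode as
flagged zeros and decode back to their constant; empty tables validate to
zero rows but cannot fit a processor; argmax ties break to the lowest index;
all-missing columns are errors.

## Command line

A thin CLI over the exported functions ships in
`inst/scripts/synthcohort-cli` with subcommands `fixture`, `train`,
`generate`, `audit`, `sheet` and `kappa`, JSON-lines logging, and nonzero
exits on any error. The R functions remain the primary interface; the CLI
adds nothing the functions do not have.
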