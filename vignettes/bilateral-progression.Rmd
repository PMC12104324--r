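---
title: "Modelling bilateral lymphatic progression of oropharyngeal tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bilateral lymphatic progression of oropharyngeal tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(bilymph)
```

## The clinical problem

In oropharyngeal squamous cell carcinoma (OPSCC), radiotherapy target
volumes electively include lymph node levels (LNLs) that may harbor occult
microscopic metastases undetectable by imaging. Current guidelines assign
these volumes from population-level prevalence, so a patient with a small
lateralized tumor and a clinically negative contralateral neck receives much
the same contralateral irradiation as a patient with an advanced tumor
crossing the mid-sagittal plane. `bilymph` implements a probabilistic model
of how nodal disease spreads through the cervical lymphatic system over
time, on both sides of the neck, so that the risk of occult disease in any
level can be computed for an individual patient's presentation: T-category,
tumor lateralization, and the pattern of clinically detected involvement.

## The hidden Markov model of one neck side

Each LNL (I, II, III, IV, V, VII) is a binary hidden variable: healthy or
involved. Disease starts with all levels healthy and progresses over
abstract discrete time steps. Spread follows a directed acyclic graph: the
primary tumor can seed each level directly (per-step probability specific to
the level), and an involved level can seed its efferent neighbour along the
chain I→II→III→IV→V. During one step, a healthy level `v` with per-step
tumor-spread probability $b_v$ and involved parents $r$ with arc
probabilities $t_{rv}$ stays healthy with probability
$(1-b_v)\prod_r(1-t_{rv})$; events across levels are conditionally
independent given the current state, and involved levels never revert
(*no self-healing*). This yields a $2^V \times 2^V$ row-stochastic
transition matrix over involvement patterns in which every entry that would
clear a level is zero and the all-involved pattern is absorbing.

States are enumerated by binary counting with the first level as the most
significant bit; this ordering is arbitrary but frozen, so that serialized
matrices and stored draws are comparable across runs.

The number of progression steps between disease onset and diagnosis is not
observed. It is marginalized against a binomial prior over $0,\dots,10$
steps whose success probability depends on the T-group: fixed at 0.3 for
early (T1/T2) tumors — diagnosis after three steps on average — and a free
parameter for advanced (T3/T4) tumors, fitted near 0.45 (about 4.5 steps).
T-category thus acts as a surrogate for how long the disease has progressed.

Observation is imperfect: a diagnostic modality relates the hidden state of
each level to a reported finding via its sensitivity and specificity,
factorizing over levels into an observation matrix. The bundled modality
table treats pathology and the cohort consensus as perfect, imaging
(CT/MRI/PET-CT) as 0.81 sensitive / 0.76 specific, and fine needle
aspiration as 0.80 / 0.98. During *training*, the consensus involvement
recorded in a cohort is treated as the true hidden state (an identity
observation); the imaging and FNA confusion values are used at *prediction*
time only.

## The bilateral extension

No major lymph vessels cross the mid-sagittal plane, so the model assumes no
direct drainage from ipsilateral to contralateral levels: given the
diagnosis time, the two sides evolve independently, and the joint
distribution over both necks is the product of the two per-time state
distributions mixed over the shared time prior. This shared clock is what
couples the sides: severe contralateral involvement is unlikely at early
times, when limited ipsilateral involvement is also the rule, which
reproduces the observed correlation between ipsi- and contralateral disease
without any dedicated coupling parameter.

Parameters are shared where anatomy is symmetric: the arc probabilities
$t_{rv}$ are identical on both sides. Tumor-spread probabilities are not:
ipsilateral rates $b^i_v$ are free, contralateral rates for a lateralized
tumor $b^c_v$ are free (and much smaller), and once the tumor extends over
the midline the contralateral rates become the linear mix
$\alpha\, b^i_v + (1-\alpha)\, b^c_v$ with one global mixing weight
$\alpha$.

Midline extension itself is dynamic: a tumor starts lateralized and crosses
the midline with a per-step probability $p_\epsilon$, so
$P(\epsilon = \text{True} \mid t) = 1 - (1-p_\epsilon)^t$ — crossing is more
likely for tumors diagnosed late, which is exactly the observed association
between advanced T-category and midline extension. The contralateral state
distribution is therefore tracked jointly with the crossing flag: the
lateralized branch decays geometrically while evolving under the lateralized
matrix, and the crossed branch accumulates mass by the recursion in which
the newly crossing mass is already propagated with the mixed-rate matrix in
the crossing step. `midline_evolution()` implements this recursion and its
conservation laws are property-tested (the two branches' row sums add to
one, and the crossed branch reproduces the closed geometric form to 1e-12).

For the default six-level graph the free parameter vector has 19 entries:
six ipsilateral rates, six lateralized contralateral rates, the mixing
weight, four arc probabilities, the advanced-T time parameter, and the
crossing probability. The early-T time parameter (0.3) and the horizon of
10 steps are fixed constants.

## Likelihood

A cohort record contributes the probability of its consensus involvement
pattern under the joint distribution for its T-group and midline status.
Levels without a finding are marginalized by masking their observation
factor (equivalent to summing over completions, without enumerating them);
records with unknown midline status are marginalized exactly over both
crossing branches rather than imputed. The cohort log-likelihood is the sum
over patients; since its cost is dominated by the $64\times64$ matrix
products, patients are grouped by their distinct (T-group, midline flag,
pattern) combination and each distinct pattern is touched once per
parameter evaluation. Zero-probability records are floored at $-10^{10}$
so the sampler always sees finite rejection values.

## Inference

The posterior over the 19 free parameters under a uniform prior on the unit
cube is explored with an affine-invariant ensemble sampler using
differential-evolution moves: each walker proposes a jump along the
difference of two walkers from the complementary half of the ensemble,
scaled by $2.38/\sqrt{2d}$ with a small jitter, with a 10% chance of an
unscaled mode-hopping jump, accepted by Metropolis–Hastings. Twelve walkers
per dimension is the default.

Convergence of the burn-in is monitored through the integrated
autocorrelation time, estimated by FFT with Sokal's self-consistent window,
averaged over walkers and then over parameters (the per-parameter times are
similar here; averaging gives a single robust statistic). The chain is
declared converged once the relative change between successive estimates
falls below 0.05 *and* the estimate is below one fiftieth of the chain
length — early estimates are biased low and are not trusted. After
convergence, the sampler runs 10 × `thin` further steps and retains every
10th ensemble state, i.e. ten draws per walker.

Two practical choices deserve note:

* **Initialization.** Drawing every walker uniformly from the prior cube is
  supported (`init = "cube"`), but with cohorts of thousands of patients the
  posterior occupies a tiny fraction of the cube and a dispersed ensemble
  takes many thousands of steps to collapse onto it — differential-evolution
  proposals scale with the ensemble spread, so almost all are rejected
  during that transient. The default (`init = "map_ball"`) therefore first
  locates the posterior mode with a short bounded quasi-Newton search and
  scatters the walkers in a tight Gaussian ball (sd 0.005) around it, the
  standard recommendation for ensemble samplers. The burn-in then only
  needs to expand the ensemble to the posterior scale, which the
  convergence criteria still verify.
* **Retention.** "Ten draws spaced ten steps apart" is read as: run 100
  further ensemble steps post-convergence and keep every 10th full ensemble
  state. With hundreds of walkers this yields thousands of draws.

Walker acceptance fractions are reported with the fit (healthy mixing sits
near 25–35%); they are logged, not asserted.

## Risk prediction

Given a clinical presentation — T-group, midline status, and per-level
findings, each with its modality — the posterior over the true bilateral
involvement follows from Bayes' rule: per-level observation factors (from
each level's sensitivity/specificity) weight the model's joint prior for
that T-group and midline status, normalized over all $2^V \times 2^V$ state
pairs. The occult-disease risk of a level is the marginal of this posterior
over all state pairs in which that level is involved. Scenario conventions
follow clinical reporting: levels not explicitly mentioned are assumed
clinically negative on imaging, *including the queried level itself*; FNA
applies only to levels explicitly flagged as FNA-assessed. If the midline
status is unknown it is marginalized. With a matrix of posterior draws the
risk is evaluated per draw, giving a histogram whose spread reflects
parameter uncertainty; with a single parameter set (for example the bundled
reference estimates) a point risk is returned. Note that the mean of
per-draw risks need not equal the risk at the posterior-mean parameters;
the difference is small at these magnitudes but not zero.

Predicted prevalences — for comparison against observed cohort frequencies
— are conditional probabilities of an involvement pattern (with masked
levels marginalized) given T-group and midline status, evaluated on the
hidden states directly since cohort consensus is treated as ground truth.
The matching observed quantity is summarized by a Beta$(k+1, n-k+1)$
posterior over the unknown prevalence from $k$ involved among $n$ patients
under a uniform prior, whose mode is $k/n$.

## The synthetic-cohort generator

`simulate_cohort()` is the generative mirror of the likelihood: it draws a
diagnosis time from the binomial prior, evolves the ipsilateral neck with
per-level Bernoulli spread events, evolves the crossing flag by per-step
Bernoulli trials, switches the contralateral rates to the mixed values from
the crossing step onwards (the same step convention as the likelihood
recursion, so simulator and inference agree exactly), and finally passes the
true states through the chosen reporting modality. Its defaults emulate the
structure of the multi-institutional OPSCC cohort tables: per-side
per-level tri-state columns, a T-category, and a midline flag, with an
optional uniform per-cell missingness rate.

What the generator does *not* emulate: institutional reporting artifacts
(levels systematically undissected at one center), correlated missingness,
HPV stratification, or subsite heterogeneity. Passing the simulation-based
tests therefore demonstrates internal consistency of likelihood, sampler
and simulator under the model's own assumptions — not that real cohorts
satisfy those assumptions.

## Numerical choices and test scales

* Stochasticity checks use an absolute tolerance of 1e-12 (double precision
  across 64×64 products); joint-distribution normalization 1e-10.
* Exhaustive oracles (event-by-event enumeration of spread trajectories and
  crossing times) are compared on two- and three-level graphs with up to
  four time steps, where enumeration is exact and cheap.
* The parameter-recovery experiment simulates 5,000 patients per T-group at
  the reference estimates with perfect observation and refits with a
  reduced configuration (4 walkers per dimension, burn-in capped at 3,500
  steps); every posterior mean is required to fall within three posterior
  standard deviations of the generating truth. These sizes keep the whole
  experiment in the ten-minute range on a single core while the posterior
  is still tight enough for the check to be meaningful.
* Simulator/likelihood agreement uses 50,000 simulated patients on the
  two-level toy and a chi-square goodness-of-fit over all
  (ipsi pattern, contra pattern, crossing flag) cells at level 0.01.

## Known limitations

* The model treats consensus involvement as ground truth during training;
  clinically diagnosed involvement cannot detect occult disease by
  definition, so prevalence may be over- or under-estimated by false
  positives/negatives in the training data.
* A single time-prior parameter per T-group carries the entire
  T-dependence; residual differences between early and advanced tumors are
  not captured.
* The graph is fixed; selecting arcs by model evidence, trinary involvement
  states, and subsite-specific mixtures are out of scope.
* Printed point risks evaluate the posterior at one parameter vector;
  summaries of per-draw risk histograms need not coincide with them exactly,
  though the difference is small at these risk magnitudes.
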