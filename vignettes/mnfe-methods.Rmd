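---
title: "Single-sample network flow entropy for tipping-point detection: models, choices, limits"
author: "mNFE package authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-sample network flow entropy: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mNFE)
```

# The problem

Progression toward a disease such as type 1 diabetes (T1D) is usefully
modeled as a nonlinear dynamical system with three regimes: a stable
healthy state, a *pre-disease (critical) state* at the edge of an abrupt
transition, and a stable disease state.  The critical state is still
reversible; the disease state largely is not.  Dynamic network biomarker
(DNB) theory says that as a system approaches its tipping point, a
subset of variables develops *critical collective fluctuations*: their
variances rise sharply, their mutual correlations rise, and their
correlations with the rest of the system fall.  Mean abundances, by
contrast, often barely move — which is why conventional differential
analysis misses the critical state.

This package scores longitudinal taxon-abundance profiles one sample at
a time.  Given a set of n reference samples (the individual's or
cohort's normal state), each new sample is asked: *how much does adding
you perturb the flow entropy of the reference association network?*

# The score

**Association networks.**  A sparse microbial association network is
inferred from the reference samples by neighborhood selection (the MB
estimator): every taxon is lasso-regressed on all others after a
within-sample centered log-ratio (CLR) transform, neighborhoods are
symmetrized by the OR rule, and the edge weight is the signed average of
the two regression coefficients.  This is the convention popularized for
compositional microbiome data by SPIEC-EASI.  The network of the
reference samples alone is the ARN; re-running the same estimator on the
reference samples plus one case sample (same node set, same penalty)
gives that sample's SSAN.

**Local networks.**  Every node of a network defines a local network:
the center taxon plus its first-order neighbors (M taxa in total,
degree + 1).

**Flow probabilities.**  For a center i with neighbors k = 1..M−1 over
samples j = 1..n, two distributions over the neighbors are formed:

* the joint probability `p(x_ij, x_kj)` is the per-sample log-ratio
  distance `D(x_ij, x_kj) = |log(x_ij / S(x_i)) − log(x_kj / S(x_k))|`
  normalized over neighbors, where `S(x_i)` is the geometric mean of
  taxon i across the samples (the per-species Aitchison centering);
* the conditional probability `p(x_kj | x_ij)` is the center–neighbor
  mutual information normalized over neighbors.

**Network flow entropy.**  With flow weights
`w_kj = x_ij · p(x_ij, x_kj) · p(x_kj | x_ij)` (x_ij the center's
within-sample relative abundance), the local NFE is
`−1/(M−1) · Σ_k Σ_j w_kj log w_kj`.  Isolated centers have NFE 0 by
convention.  All factors lie in (0, 1], so NFE ≥ 0.

**mNFE.**  The global score of a case sample at day T is the mean NFE
over the SSAN's local networks (computed on the n + 1 mixed samples)
minus the mean NFE over the ARN's local networks (n reference samples).
Per-taxon differentials — SSAN-local NFE minus ARN-local NFE per center
— feed the DNB ranking: at a called critical day the top 10 % (ceiling,
ties broken by taxon id) are reported as that individual's DNBs.

# Readings fixed where the formulas are ambiguous

Three points of the printed formulation admit more than one reading; the
package fixes them as follows and tests against an independently coded
brute-force oracle that implements the same reading.

* **Absolute value in D.**  Without it the "joint probabilities" could
  be negative and their normalization meaningless; D is therefore the
  absolute per-sample difference of the centered logs.  This is the only
  reading under which `p(x_ij, x_kj)` lies in [0, 1] and sums to 1 over
  neighbors.
* **Summation indices.**  The inner NFE sum is read as running over the
  M−1 neighbors and the n samples with the center fixed — the only
  assignment consistent with the objects the probabilities are built
  from.
* **Degenerate normalizers.**  If all neighbor distances vanish in a
  sample, the joint distribution for that sample is uniform over
  neighbors (the vanishing-perturbation limit); likewise a vanishing MI
  total yields a uniform conditional.  With fewer than 4 samples MI is
  not estimated and the conditional is uniform.

# Two log-ratio transforms

Two distinct centerings coexist deliberately.  Network inference uses
the *within-sample* CLR across taxa (the standard compositional
treatment; associations between taxa are only meaningful after removing
the per-sample total).  The flow probabilities use the *per-species*
centering across samples (each taxon divided by its geometric mean over
the sample set), which is what makes D the per-sample component of an
Aitchison distance between two taxa's trajectories.

# Estimator and algorithm choices

**Mutual information.**  No installed estimator being available, the
package implements binned MI: equal-width bins, `ceiling(n^(1/3))` bins
per margin, maximum-likelihood plug-in with the Miller–Madow
occupied-cell correction, clipped at 0 (the corrected estimate can dip
below zero under independence — the reason a clip is needed at all).
The square-root binning rule that is sometimes suggested was rejected
during design: at n = 1000 a 32 × 32 plug-in table carries ≈ 0.3 nats of
positive bias, which would swamp the null; with cube-root binning and
the correction, independent draws score ≈ 0.01 nats and a ρ = 0.9
bivariate Gaussian at n = 5000 lands within 0.06 nats of the closed form
−½·log(1−ρ²).  The bin count remains an argument.

**Lambda path and StARS.**  The penalty path is log-spaced, 20 values
from the largest absolute pairwise CLR correlation down to 1 % of it
(`lambdaMinRatio = 0.01`).  StARS stability selection (20 subsamples of
size 0.8 n, or 10√n for large n; instability target 0.05; densest
penalty whose monotonized instability stays below target) picks the
ARN's penalty.  For very small, strongly coupled systems — the eight-node
simulation is one — StARS finds no stable sparse regime and a fixed
mid-path penalty is the documented fallback (`stability = "fixed"`).

**SSANs.**  Each SSAN reuses the ARN's node set and penalty, so ARN and
SSAN are compared at matched sparsity; per-time-point re-selection would
change sparsity discontinuously between days.  A flag re-enables
re-selection, and `useRefMoments` optionally standardizes the mixed
matrix with the ARN's stored CLR moments (measuring the case sample
strictly against the reference geometry) instead of its own.

**Prevalence filter.**  Taxa must be non-zero in ≥ 20 % of the samples
used for a network; near-constant rows make neighborhood regression
unstable.  Exposed as `prevalenceMin`.

**Zeros.**  A pseudocount of 0.5 (the standard compositional zero
replacement) is added before closure wherever logs are taken; the value
is exposed everywhere.  Continuous, strictly positive simulation data
use 0.

**Edge signs.**  The two regression coefficients of an OR-rule edge are
averaged in magnitude; on a sign conflict the larger-magnitude
coefficient wins.  Deterministic and documented rather than deep.

# Reference conventions

The usual convention takes "the samples from the first two time points
or the normal samples" as the reference.  Two sample sizes are in
tension here: neighborhood selection needs a respectable n, while the
single-sample entropy comparison is most sensitive when the case sample
is one of few.  The cohort pipeline therefore pools every individual's
first two time points (all individuals are pre-symptomatic then) to
infer one stable ARN, but computes the NFE probabilities per individual
over that individual's own first two samples plus the case sample.  Both
halves follow a printed reading; the combination is this package's
design choice.

# Detection rules

The sharp-increase rule flags day T when `score_T > 1.5 · score_{T−1}`;
it is the package default for `detectTipping` and is scale invariant.
An alternative *deviation* rule flags day T when the score departs from
the running mean of all previous days by more than `zThreshold` (default
4) running standard deviations, needs at least three baseline points,
and catches sharp moves in either direction.

The deviation rule is the cohort pipeline's default because of an
empirical property of the flow entropy worth stating plainly: on the
synthetic cohorts, a strongly perturbed case sample *lowers* the mean
local NFE rather than raising it.  Two mechanisms act in the same
direction.  A perturbed sample's aligned deviations create additional
SSAN edges, and the 1/(M−1) normalization dilutes the entropy of the
enlarged neighborhoods; and the perturbed sample's large distances
concentrate the joint distribution on few neighbors, lowering entropy.
The perturbation is therefore a sharp *departure* — here a collapse —
from the individual's baseline, not a 1.5× rise, and a one-sided ratio
rule cannot see it.  The package reports the signed score exactly as
defined and leaves the trigger rule a configuration choice.

# The eight-node simulator

The validation model is an eight-node Hill-form regulatory network with
mixed activation and repression, built so that the bifurcation sits
exactly at p = 0.

* Node 1 is the critical core, `dx1/dt = B(p) + A(p)·x1²/(1+x1²) − d·x1`
  with d = 0.5.  The tangency point x_s where the Hill slope equals d is
  solved by `uniroot` at construction.  For p < 0 the amplitude and
  basal rate co-vary (`A = 1 + c·p/d`, `B = d·x_s − A·h(x_s)`, c = 2) so
  the fixed point stays pinned at x_s while its eigenvalue equals c·p:
  the approach to the tipping point is pure stability loss with no drift
  of the operating point — the cleanest realization of the DNB premise
  that means barely move while fluctuations grow.  At p = 0 the
  eigenvalue reaches zero and the fixed point meets the fold.  For
  p ≥ 0 the basal rate is pushed past the fold (a small `foldOffset`
  plus `0.02·p`), the low state is gone, and the trajectory escapes
  through the saddle-node ghost to the distant high state.
* Nodes 2–8 are a mixed activation/repression cascade driven by node 1
  with unit degradation, so the dominant Jacobian eigenvalue is node 1's
  (verified numerically by `grnDominantEigen`) and critical fluctuations
  propagate with gain through the cascade.
* States live at 10× the dimensionless units (`stateScale`), which fixes
  how large the prescribed absolute noise strengths σ ∈ {0.01, 0.05,
  0.1} are relative to the dynamics; all three then sit in the
  small-noise regime where the pre-fold barrier at p = −0.05 holds even
  at σ = 0.1.
* Integration is Euler–Maruyama, dt = 0.05, states floored at 10⁻⁶;
  the sweep runs quasi-statically ("a complete time series"): each grid
  point starts from the previous one's final state, the first grid
  point gets 1000 extra burn-in steps, and 50 states are recorded 4 time
  units apart (sampleEvery = 80) so that consecutive samples decorrelate
  except very close to criticality.

The sweep scores every recorded state of every later grid point as a
single case sample against the reference (the first two grid points'
samples, n = 100) and averages per grid point.  Pre-fold scores sit near
zero, the curve jumps by one to two orders of magnitude at the
transition, and settles on a plateau after it.  Because the post-fold
states are far from the reference in composition, the plateau level is
comparable between grid points; which plateau point carries the
numerical maximum is then sensitive to sampling noise.  The location of
the *sharp increase* is the robust signature; the strict argmax is the
stricter statistic that the acceptance suite measures.

# The synthetic cohort

`generateCohort` emulates a longitudinal 16S-style cohort at desk scale:
40 taxa, 15 individuals (10 control, 3 seroconverters, 2 T1D cases), 12
monthly samples each, multinomial counts at depth 20 000 over softmax
proportions from latent log-abundances.  The latent field follows a
chain association network (partial correlation 0.45).  Symptomatic
individuals carry a DNB block of 8 taxa that ramps over the 3 time
points before the programmed transition (day 270): intra-block
correlation rises to 0.95, per-taxon standard deviation rises 5-fold,
and the block decouples from the rest — the three DNB conditions — and
from the transition on, the block's latent mean shifts by 2.5 log units
(the disease state).  The block parameters were fixed by pilot runs so
that the programmed transition is detectable at this scale; they are all
arguments.

What the generator does *not* emulate: real 16S compositions are far
sparser and heavier-tailed, sequencing depth varies per sample,
individuals differ in baseline composition, taxa arrive and vanish, and
seroconversion does not announce itself with a synchronized
variance-correlation ramp.  Passing the cohort tests therefore shows the
pipeline detects the programmed critical-transition signature at desk
scale, not that it would reproduce any particular clinical cohort.

# Diversity and network-property baselines

Chao1 uses the bias-corrected form S_obs + F1(F1−1)/(2(F2+1)) (defined
when no doubletons occur; the classical form is behind `bias = FALSE`)
and refuses non-integer input rather than silently rounding — so alpha
diversity is computed before relative-abundance normalization.  Shannon
and Simpson come from vegan; Bray–Curtis is the normalized L1 form,
cross-checked against `vegan::vegdist` in the tests.  No rarefaction is
applied by default.  Fragility curves remove nodes in uniformly random
order (100 repeats by default; degree-descending "attack" behind a
flag), track the giant component's share of the remaining nodes, and
are summarized by the normalized trapezoid AUC.  A connected network's
curve starts at 1; a fragmented one starts at its largest component's
share.

# Problem sizes and determinism

The shipped validation workloads are sized for a desk machine: the
bifurcation sweep uses 16 grid points × 50 samples and 20 replicate
seeds per noise level; the cohort batch uses 20 seeds of the default
cohort; oracle equivalence uses 200 random local networks of up to 8
taxa and 10 samples.  All randomness flows through explicit seeds
(simulation, StARS subsampling, fragility orders), and child seeds are
derived from the one top-level seed, so every result in the acceptance
suite and the command-line runs is bit-reproducible.

# Known limitations

* Neighborhood selection at n ≈ 30 reference samples is noisy; single
  added samples can swap borderline edges, which is the dominant noise
  term of the cohort score series.  Denser penalties damp this noise but
  also dilute the entropy response; the default keeps the StARS choice.
* The mNFE response direction depends on regime: displacement-dominated
  settings (the eight-node model, where the case composition moves far
  from reference on all nodes) raise the score; sparse-block
  perturbations on larger taxon sets lower it (edge gain + 1/(M−1)
  dilution).  The detection layer exposes both one-sided and two-sided
  rules for this reason.
* The eight-node model is a constructed stand-in with the documented
  topology and a bifurcation placed at p = 0 by design; it is not a
  transcription of any published parameterization.
* Binned MI at n ≈ 30 samples is a coarse ranking device, not an
  efficient estimator; it is used only to weight neighbors relative to
  one another.
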