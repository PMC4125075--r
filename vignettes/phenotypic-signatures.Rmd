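---
title: "Wavelet phenotypic signatures from unbalanced bacterial growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet phenotypic signatures from unbalanced bacterial growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenosig)
```

## The idea

Bacteria growing in a batch culture are never at steady state: as they
consume the substrate they continuously change their own environment, and
the specific growth rate $\mu(t) = \frac{1}{OD}\frac{dOD}{dt}$ fluctuates
over the course of the experiment. These fluctuations are usually treated
as a nuisance. `phenosig` treats them as a *phenotype*: the cell-coupled
feedback between physiology and environment imprints strain-specific
temporal structure on $\mu(t)$, and a time–frequency decomposition of that
signal — a wavelet scaleogram — is a fingerprint that separates strains
and growth conditions better than the conventional scalar metrics
(maximal growth rate, final OD, total variation of $\mu$).

The package implements four connected analyses:

1. **Signature extraction and classification** — plate-reader OD curves to
   growth rates to db4 scaleograms, period selection by the
   Davies–Bouldin index, average-linkage clustering, and a leave-one-out
   misclassification analysis.
2. **Identifiability simulations** — random linear three-node models in
   which the same network is probed either with a constant input flux or
   with a consumable ("cell-coupled") nutrient, scored by local parameter
   identifiability from transfer-function sensitivities.
3. **Network-inference simulations** — random nonlinear models, noisy
   trajectories, a linear regression estimator $\dot y = Ay$, and the
   $n/m$ edge-recovery accuracy under both input modes.
4. **Reverse engineering of a growth model** — a three-variable ODE of
   batch growth, and a particle-swarm search that evolves model
   structures from a 12-component equation library and fits their
   parameters to growth-rate data.

A seeded synthetic-data module generates every input class these
pipelines need, so the whole analysis is reproducible end to end without
any laboratory data.

## Growth rates and denoising

`compute_growth_rate()` uses the discrete specific growth rate
$\mu_i = (OD_{i+1} - OD_{i-1})/(2\,\Delta t\, OD_i)$ at interior points.
Differencing optical densities directly is the default; the $\ln OD$
variant is available via `method = "log"` and agrees with it for slowly
varying curves. Wells containing nonpositive
OD values are rejected by default (`permissive = TRUE` masks them as
`NA`) — plate-reader blanks that drift below zero are a data problem, not
something to silently clip.

`denoise_curve()` implements `wden`-style wavelet shrinkage: a multilevel
db4 discrete wavelet transform with half-point symmetric boundary
extension, soft thresholding of **all** detail levels at the universal
threshold $\sigma\sqrt{2\ln N}$, with $\sigma$ estimated once from the
finest-level details as $\mathrm{MAD}/0.6745$ ("no rescaling": one global
noise scale). The decomposition depth defaults to
$\lfloor\log_2 N\rfloor - 2$. The filters are the standard orthonormal
8-tap Daubechies-4 pair; perfect reconstruction of the analysis/synthesis
pair is exercised in the tests to $10^{-10}$.

## The scaleogram

`wavelet_transform()` computes a continuous-style transform with the db4
mother wavelet discretized by the cascade algorithm (refinement level 10,
grid spacing $2^{-10}$). Three numerical conventions matter and are fixed
as follows:

* **Kernel normalization is $L^1$** (divide by the dilation $a$, not
  $\sqrt a$): equal-amplitude sinusoids then produce equal-magnitude
  ridges across scales, so the ridge of a period-$T$ oscillation sits at
  the row labeled $T$. With $L^2$ normalization the extra factor of $a$
  in row energy biases the ridge toward longer periods.
* **The scale-to-period map** uses the empirical center frequency of the
  discretized wavelet (the dominant FFT frequency of the cascade
  approximation, $\approx 0.699$ cycles per unit argument) rather than a
  nominal constant, so the labeling is consistent with the kernel
  actually used.
* **Kernels are centred on the magnitude peak of $\psi$**, so an isolated
  event at time $t_0$ responds maximally in the column nearest $t_0$ at
  every period; db4 is strongly asymmetric and left-aligned convolution
  would shift features by a scale-dependent lag.

Boundaries are zero-padded. Cells whose kernel overhangs the record are
*retained* (growth records are short relative to the informative periods,
and the long-period rows are often the discriminative ones) but flagged
in the `boundary` matrix so downstream analyses can mask them. The
default period grid has 64 logarithmically spaced periods from
$4\Delta t$ to the record duration.

`signature_vector()` extracts one row of the $|{\rm coefficient}|$ map as
the feature vector; `choose_period()` picks the row by minimizing the
Davies–Bouldin index of the features grouped by the known labels, with an
optional exclusion mask for period ranges known to be uninformative.
`expression_features()` reduces a profile to the two-feature summary
$(t^\*, p^\*)$: the argmax of the column sums $C_{total,t}$ and row sums
$C_{total,f}$, ties broken toward earlier times and smaller periods;
all-zero profiles return the first grid point flagged `degenerate`.

## Clustering and scoring

Hierarchical clustering is `stats::hclust` with average linkage on
Euclidean distances; trees are cut at an explicit `k` (the number of
expected groups — the package never guesses it from tree heights).
`davies_bouldin()` is the textbook index
$\frac1K\sum_i \max_{j\neq i} (S_i+S_j)/M_{ij}$; coincident centroids
score `Inf`. Misclassification counts are permutation-minimal: cluster
labels are arbitrary, so `misclassification_count()` scans all
assignments of clusters to groups exactly (group counts here never exceed
eight). The "bootstrap" of the classification is exactly leave-one-out:
drop each sample, recluster, count errors.

## Identifiability: constant versus cell-coupled inputs

Each random linear model has six distinct directed flux edges among the
cellular nodes P, Q, R (edge $X\to Y$ with rate $k$ moves mass:
$+kX$ into $\dot Y$, $-kX$ into $\dot X$), rates i.i.d. Uniform(0.1, 1).
The two experiment types are represented as initial-condition responses
of an augmented autonomous system:

* **constant input**: an integrator state $U$ ($\dot U = 0$, $U(0)=u$)
  feeds P, so the cellular block sees the step spectrum $u/s$;
* **cell-coupled input**: a nutrient state $N$ ($\dot N = -k_0 N$,
  $N(0)=N_0$) is consumed into P, spectrum $k_0 N_0/(s+k_0)$.

This representation is the substantive point: the two modes differ in
*where in frequency the experiment deposits its information* (a step
concentrates it at DC; a consumed nutrient spreads it over the band below
$k_0$), and that difference is what the identifiability comparison
measures. The sensitivity matrix H stacks
$\partial g/\partial k_j$ (real and imaginary parts, analytic via the
resolvent identity) over the observed nodes and 32 log-spaced frequencies
in $[10^{-2}, 10^2]$ rad/h, each frequency block weighted by
$\sqrt\omega$ — the natural quadrature weight on a log grid, so H
approximates the sensitivity functions in $L^2(d\omega)$ instead of
letting the lowest frequencies dominate the correlations. A parameter is
locally identifiable when its column is nonzero and no other column is
correlated with it beyond $|R| = 0.99$; the comparison counts the six
shared edge rates in both modes (the uptake rate $k_0$ shapes the
cell-coupled sensitivities but is not counted, keeping the counts
commensurable). Sensitivity of the conclusion to thresholds 0.95/0.999
can be checked by passing `threshold` to `compare_input_modes()`.

One caution established during development: pairwise-correlation
identifiability is **not monotone** in the observed-node set — an added
output block can push a single pairwise correlation above threshold even
though more data can only add information in the Fisher sense. The tests
therefore assert the ensemble-level statement (multi-node observation
beats single-node) rather than per-model monotonicity.

## Network inference: the n/m experiment

Random nonlinear models draw six links over mass-action fluxes,
Michaelis–Menten activation/repression, and multiplicative two-species
reactions; trajectories start from all-ones states and carry 20%
multiplicative Gaussian noise. The estimator is deliberately naive —
central-difference derivatives regressed on states, no intercept, no
regularization — because the question is about the *data*, not the
estimator. Three pipeline choices required care:

* **Recovery is sign-aware.** With a recall metric $n/m$ and a tiny
  magnitude threshold (0.005 on $|A_{ij}|$, robustness at 0.01), rawer
  noise inflates recall: estimator variance pushes weak entries above any
  small threshold, rewarding exactly the uninformative (constant-input)
  data. Requiring the detected influence to carry the correct sign
  (repression negative) restores honesty — noise produces random signs.
  The threshold still applies to the absolute value, so repressive links
  remain detectable.
* **Trajectories are wavelet-denoised** (`denoise_curve()`) before
  differencing — the package's own filtering step, and the reason the
  time–frequency machinery sits upstream of estimation in the first
  place.
* **The record extends well past the transient** (60 h at 0.1 h
  sampling): a constant input leaves most of the record at an
  uninformative steady state, which is precisely the handicap the
  comparison quantifies. N is included as a regressor in both modes; in
  constant mode its (noisy-)constant column plays the role of the
  intercept absorbing the input flux. Models whose integration fails are
  regenerated from follow-on seeds and counted in the result.

## The growth model

`growth_model()` is a minimal gene-network model of batch growth with a
single consumable substrate:

$$\dot G = k_1 \frac{P\,G}{K_G + G} - k_2 Q G - k_8 G - G^2$$
$$\dot P = k_3 \frac{N}{K_N + N} - k_5 P \qquad
  \dot Q = k_4 P - k_6 Q \qquad
  \dot N = -k_7 \frac{P\,N}{K_N + N}$$

with $\mu(t) = G(t)$ (proportionality constant of one) and
$OD(t) = OD_0\exp(\int\mu)$. G is a growth-rate modulator produced
autocatalytically by the nutrient-driven machinery pool P (the positive
feedback that delays and then accelerates the rise of $\mu$), repressed
by the burden/stress pool Q (the negative feedback that caps it), turned
over at $k_8$, and diluted by growth itself ($G^2$, per-capita rate
$\mu = G$). The coefficient of the dilution term is structurally one,
like the $\mu = G$ readout; this is what makes a uniform slowing of the
kinetic constants *lower* the attainable growth rate instead of merely
stretching time. $K_G, K_N$ are equilibrium-like half-saturation
constants and are held apart from the rate vector.

The default parameter set (`k1 = 1.8, k2 = 0.5, k3 = 1.0, k4 = 0.3,
k5 = 0.8, k6 = 1.5, k7 = 0.3, k8 = 1.2`; $K_G = 0.3$, $K_N = 0.1$) was
chosen once to give a realistic E. coli-like batch curve — peak
$\mu \approx 0.6\,h^{-1}$ at $\approx 4$ h, entry into stationary phase
(defined as $\mu$ falling below 5% of its own maximum after the peak —
the literature offers no standard definition, and a relative threshold
keeps the entry time comparable across perturbed curves) near 10 h, final
OD near 1 from an inoculum of 0.05 — and to reproduce two qualitative
perturbation phenotypes:

* **plasmid load** (`apply_perturbation(m, "plasmid")`, $k_4 \to 1.2$):
  more burden per unit machinery lowers peak $\mu$, but nutrient
  consumption runs through P, which is untouched, so the entry into
  stationary phase stays within one 10-min sample;
* **low temperature** (all $k_i \times 0.7$): peak $\mu$ drops *and*
  stationary entry is delayed by several hours, because the
  parameter-free dilution and readout terms do not slow down with the
  rate constants.

`summary_metrics()` reports the three conventional scalars (max $\mu$,
final OD, total variation of $\mu$ — the reading of "summation of
differences" adopted here); their failure to separate close strain pairs
that wavelet signatures separate is part of the test suite.

## Swarm search over equation components

The component library (`component_library()`) holds twelve templates: six
functional forms — constant, linear, quadratic, two-species product,
saturating activation $cX/(K+X)$, saturating repression $cK/(K+X)$ —
each usable as production or consumption, covering power-law, mass-action
and enzymatic kinetics. A candidate model picks terms for the
three-variable skeleton plus the substrate equation; its right-hand side
is compiled once (both to a parsed R closure and to an integer term table
integrated by a small C++ RK4 kernel, which agree to $10^{-6}$ against an
adaptive reference integration).

`swarm_fit_params()` is a standard particle swarm (inertia 0.72,
cognitive = social = 1.49, 50 particles — constriction-style values;
exact settings are configuration, not science) searching $\log_{10}$
parameter space over $[10^{-3}, 10]$; integration failures score `Inf`
rather than aborting. Fitness is the mean absolute growth-rate error per
time point, averaged over the supplied series — the same "average error
per time-point" unit (h$^{-1}$) used to report fit quality. The
self-recovery benchmark (fitting the true structure to noiseless
self-generated data, 50 particles, 300 iterations, 14 h record at 10-min
sampling) reaches a few $10^{-3}$ h$^{-1}$, comfortably below the 0.01
h$^{-1}$ instrument-readability scale used as the quality bar.

`swarm_search_structure()` evolves a population over a slot space: each
round fits every structure (the inner swarm is seeded deterministically
by the structure's identity and memoized, so ranking is reproducible and
re-encountered structures are never refitted), then every non-best
structure adopts the best structure's component at each differing slot
with probability 0.5 or resamples it; a member that has fully converged
onto the best resamples one random slot, so exploration never freezes.
Ties within $10^{-4}$ h$^{-1}$ rank by fewer terms (parsimony).

The benchmark space (`toy_structure_space()`) deserves a note, because
its design is a small identifiability lesson. Early versions put the open
slot on the *production* term of G or on the substrate-consumption law;
both are nearly unidentifiable from $\mu(t)$ alone, because the latent
pool P is flexible enough to absorb any single-input functional form —
structurally different candidates fit to within the optimizer's noise.
The shipped benchmark instead varies the **consumption law of the
observed variable itself** (quadratic growth-dilution vs first-order
turnover vs saturating removal): the decay tail of $\mu$ after substrate
exhaustion then directly exposes the component (power-law vs exponential
vs finite-time ramp), and a second condition at halved initial nutrient,
fitted jointly with shared parameters, pins it down. On this space the
search matches the exhaustive-enumeration optimum in 10/10 seeded runs
and recovers the generating structure in 8/10 (the misses are inner-PSO
fitness ties, shared by the enumeration oracle).

## The synthetic-data module

`make_strain_panel()` draws per-strain parameter vectors by jittering the
growth-model defaults (each rate scaled by a factor uniform in
$1 \pm 0.15$ — strain-to-strain kinetic variation of the order seen
between lab strains), applies the condition perturbations (plasmid, low
temperature, low nutrient = 50% initial substrate), simulates at 10-min
sampling over 14 h, and adds 2% multiplicative measurement noise per
replicate (plate-reader error grows with signal). Unstable jittered
parameter sets are resampled with a message. `make_expression_dataset()`
emulates regulon structure: each group of promoters shares a latent
condition-specific burst (group-specific dominant period and peak time),
and each promoter reports gain × latent + noise with promoter-specific
gains (the strong-versus-weak regulation contrast within one regulon).

What the generators deliberately do **not** emulate: growth-curve
artefacts (evaporation, condensation, blank drift), non-Gaussian reader
noise, plate position effects, biological replicate variation beyond
parameter jitter, and regulon cross-talk. Passing tests therefore show
that the pipelines extract the structure the generators plant under
realistic noise — not that any real strain pair is separable; on real
data the informative-period profile and the exclusion mask matter, and
the package exposes both.

## Numerical choices and degenerate inputs

* Uniform sampling is enforced to $10^{-9}$ relative tolerance; growth
  curves need $\ge 5$ points, transforms $\ge 16$.
* Requested periods must lie in $[2\Delta t, \mathrm{duration}]$;
  off-grid periods snap to the nearest row with a warning.
* All-zero profiles yield degenerate-flagged features; periods whose
  features are constant across samples score `Inf` in the
  Davies–Bouldin profile; if all periods are degenerate the first grid
  period is returned with a flag.
* `estimate_linear()` falls back to the minimum-norm solution (SVD
  pseudoinverse) on rank-deficient regressors, with a warning.
* ODE integration uses `deSolve::lsoda` (tight tolerances for reported
  simulations, relaxed ones inside optimization loops); candidate
  structures use the fixed-step RK4 kernel at two substeps per sample.
  Integration failures inside ensembles and swarms are penalized or
  regenerated, never fatal.

## Limitations

Classification quality on short records leans on boundary-affected
long-period rows; the `boundary` flags allow stricter analyses but the
default keeps them, matching full-width scaleogram practice. The $n/m$
metric remains recall-only (precision is not scored); the sign-aware
matching mitigates but does not remove its blindness to false positives.
The identifiability criterion is local and correlation-based — it neither
implies nor is implied by global structural identifiability. The swarm's
structure space grows combinatorially; the exhaustive oracle is only
available for deliberately small slot spaces.
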