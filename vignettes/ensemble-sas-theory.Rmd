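---
title: "Ensemble statistics of small-angle scattering profiles: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble statistics of small-angle scattering profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sascov)
```

# The problem

A small-angle scattering (SAS) experiment on a solution of macromolecules
measures the rotationally averaged intensity $I(q)$ at momentum transfer
$q = 4\pi\sin\theta/\lambda$. For a rigid structure with atoms at positions
$x_k$ the intensity is given exactly by the Debye formula

$$I(q) = \sum_{k=1}^N \sum_{l=1}^N f_k(q) f_l(q)
  \frac{\sin(q d_{kl})}{q d_{kl}},$$

where $d_{kl}$ is the inter-atomic distance and $f_k(q)$ the (solvent-
corrected) atomic form factor. But molecules in solution are not rigid: the
measured profile is an average over the conformers present, and the profiles
of individual conformers scatter around that average in a structured,
correlated way. This package computes that structure analytically for the
simplest thermal model, numerically for arbitrary conformer sets, and
provides diagnostics of what the structure implies for the information
content of a profile.

# The thermal model

Each atom $k$ is displaced independently about its mean position with an
isotropic Gaussian of per-coordinate standard deviation $\tau_k$ (Angstrom).
This is the classical Debye–Waller picture of thermal motion; `assign_tau()`
sets $\tau$ uniformly or from crystallographic B-factors via
$B = 8\pi^2\tau^2$.

Under this model the distance between two atoms follows a noncentral $\chi$
distribution with three degrees of freedom (`noncentral_chi_pdf()`), and the
thermal expectation of the Debye kernel has an exact closed form,

$$\mathrm{E}\,\frac{\sin(q d_{kl})}{q d_{kl}}
  = \frac{\sin(q d^\circ_{kl})}{q d^\circ_{kl}}
    \, e^{-q^2(\tau_k^2 + \tau_l^2)/2},$$

with $d^\circ$ the distance between mean positions. The ensemble-average
intensity (`mean_intensity()`) is therefore exact, not a small-$\tau$
expansion. For uniform $\tau$ it collapses to a convex combination of the
rigid profile and the incoherent self-term floor $\sum_k f_k^2$
(`mean_intensity_uniform()`); for a population of distinct conformations it
is the population-weighted sum of such terms (`mixture_mean_intensity()`).
One analytic consequence worth spelling out: the coherent (non-floor) part
of a component with deviation $\tau$ is damped by $e^{-q^2\tau^2}$, so the
ratio between a floppy ($\tau_B$) and a stiff ($\tau_A$) component of the
same structure is exactly $e^{-q^2(\tau_B^2-\tau_A^2)}$ — at $q = 0.4$,
$\tau_A = 0.3$, $\tau_B = 3$ this is $0.24$: the stiff conformation
dominates the structured signal at high angle by about 4:1, while at
$q = 0.05$ the two contribute almost equally ($0.98$).

# The profile covariance

The covariance $V(I(q_i), I(q_j))$ cannot be obtained exactly in closed form
(the bivariate noncentral $\chi$ density is not available), so it is
computed to second order in $\tau/d^\circ$. Only two classes of terms
survive: the covariance of a pair distance with itself (*autocovariance*)
and the covariance of two distances sharing one atom (*cross-covariance*);
distances with four distinct atoms are independent. With
$\sigma(x) = \frac{d}{dx}\frac{\sin x}{x}$ the kernels are

$$V^\circ_{ij}(d) = (\tau_k^2+\tau_l^2)\, q_i q_j\,
  \sigma(q_i d)\,\sigma(q_j d), \qquad
V_{ij}(d_{kl}, d_{kn}) = \nu\,\tau_k^2\, q_i q_j\,
  \sigma(q_i d_{kl})\,\sigma(q_j d_{kn}),$$

where $\nu$ is the cosine of the angle at the shared atom
(`geometric_nu()`); the shared-atom geometry enters through the bivariate
normal approximation of the two distances (`bivariate_normal_approx()`),
whose covariance is $\nu\tau_k^2$.

**Summation multiplicities.** Written as sums over ordered pairs $(k,l)$ and
ordered shared-atom triples $(k; l, n)$, the total covariance carries
multiplicities 2 and 4 respectively. Index conventions of this kind are easy
to get wrong by a factor of two, so the multiplicities were *fixed
empirically*: the implementation was required to agree elementwise with a
brute-force Monte-Carlo covariance on toy systems before being accepted
(the losing conventions disagree by factors 0.4–0.5). The winning convention
also follows from counting the surviving terms of the ordered four-index
expansion of $\mathrm{E}[I(q_i) I(q_j)]$: each unordered pair appears in
$2\times2 = 4$ equal same-pair combinations and each shared-atom triple in 4
equal ordered classes.

Two structural properties are exact and are enforced by construction:
the $q = 0$ row and column vanish identically (the $q_i q_j$ prefactor;
forward scattering counts electrons and carries no conformational variance),
and the covariance is linear in $\tau^2$, so doubling $\tau$ quadruples it.

`covariance_matrix()` returns the total with its auto/cross decomposition.
The cross term is the cost bottleneck; factorizing over the shared atom
reduces it to $O(N^2 |q|^2)$ matrix products, and a guard refuses structures
above 2000 atoms unless overridden. `correlation_matrix()` normalizes to
$\rho(q_i, q_j)$, leaves $q = 0$ entries undefined (`NaN`, never imputed),
clamps rounding excursions outside $[-1, 1]$ (counting them), and raises a
typed error if a diagonal entry is negative — the signature of the
second-order approximation breaking down for that structure and $\tau$.

# Information diagnostics

For jointly Gaussian intensities the mutual information between two profile
points is $-\tfrac12\log(1-\rho^2)$. Natural logarithms (nats) are used;
the choice of base rescales every value by the same constant and changes no
comparison. `neighbor_mi_profile()` evaluates this along an off-diagonal,
and `bandwidth_profile()` measures, for each $q_i$, the $q$-width of the
maximal contiguous run around the diagonal with $\rho \ge$ threshold.
"Bandwidth" has no standard operational definition in this context; the
contiguous-run-at-threshold definition used here (identity matrix gives 0,
all-ones matrix gives the full grid span) is one of several monotone
choices, all of which locate the bandwidth minimum identically — the
minimum's location, not the width's absolute value, is the scientifically
meaningful output. The default threshold is $\rho = 0.5$. On thermal
globules the test suite finds the bandwidth and neighbour-MI minima in the
mid-$q$ band $qR_G \approx 3.5$, the region where a SAS profile is locally
most informative.

# Numerical conformer ensembles

For explicit conformer sets (multi-model PDB files, trajectory frames
exported as such), `ensemble_profiles()` computes exact per-conformer Debye
profiles and `sample_mean_cov()` the weighted mean and unbiased sample
covariance. With $M$ uniform-weight conformers the $M-1$ denominator is
used; with general weights the effective-sample-size correction
$1-\sum w_m^2$ replaces it. At the ensemble sizes of interest
($M \ge 10^3$) the estimator choice is numerically immaterial, but it must
be fixed for reproducibility. `relative_sd()`, `confidence_band()` and
`compare_to_experiment()` derive the pointwise SD as a fraction of the mean,
Gaussian bands, and per-$q$ flags of where the ensemble SD exceeds an
experimental error bar (linear interpolation in $I$ vs $q$, because SDs
combine linearly). For flexible systems with $\tau$ of several Angstrom the
flagged region covers the mid/high-$q$ range even at 1% experimental noise —
ensemble averaging is then a measurable property of the profile, not a
nuisance.

# Form factors

The analytic theory is form-factor-agnostic: $f_k(q)$ enters every formula
as an external weight. The package embeds a standard four-Gaussian vacuum
parametrization for H, C, N, O, S, P, with the constant term re-centred so
that $f(0)$ equals the electron count exactly, plus a point pseudo-element
`"X"` with $f \equiv 1$. The solvent correction is deliberately simple: a
dummy-atom excluded-volume Gaussian scaled by `c1` and a uniform,
q-independent hydration addend scaled by `c2` (experimental, default off).
It exposes the conventional `c1`/`c2` knobs without claiming to reproduce
any particular hydration-layer model; quantitative comparison with
profiles computed by full solvation models is therefore approximate by
construction. Because correctness of the statistical theory cannot depend
on this stand-in, every oracle test runs with the point-atom model.

# Oracles and numerical choices

Two independent oracles back the analytic code paths:

* **Monte-Carlo** (`mc_mean_cov()`): direct sampling of the generative
  model with naive per-pair distance evaluation, sharing only the `sinc`
  kernel with the analytic code, plus jackknife (10-block) standard errors.
  Agreement assertions use
  $3\,\mathrm{SE} + C(\tau/d)^2\max_{ij}|V_{ij}|$ with $C = 5$; the second
  term is the allowance for the deliberate second-order truncation of the
  covariance formulas. It is scaled by the matrix max-norm rather than the
  individual entry because the truncation bias of an entry does not vanish
  where cancellation drives that entry itself through zero.
* **Quadrature** (`quadrature_mean_cov()`): a deterministic evaluation of
  the *exact* covariance for small structures — Gauss–Legendre integration
  against the noncentral-$\chi$ density for same-pair terms, and a 3-D
  Gauss–Hermite grid over the shared atom's displacement for shared-atom
  terms, the two distances being conditionally independent given that
  displacement with exactly known conditional means. Quadrature weights are
  renormalized so the $q = 0$ covariance row is exactly zero. This oracle
  exists because the truncation error of the second-order formulas at
  $\tau/d \le 0.04$ is a ~0.2% relative effect: Monte-Carlo sampling noise
  exceeds it at any realistic sample count, so the convergence *rate*
  (relative deviation shrinking $\times 4$ per halving of $\tau$, measured
  exponent $2.00$) is fitted against quadrature, while absolute agreement
  is asserted against Monte-Carlo. The quadrature oracle is itself validated
  against Monte-Carlo in the unit tests.

Other numerical choices: `sinc` and its derivative kernel switch to series
below $x = 10^{-4}$ (`sinc(0) = 1`, `sigma_kernel(0) = 0` exactly, no
division by zero anywhere, including $q = 0$); near-degenerate shared-atom
cosines are clipped to $[-1, 1]$; the default $q$ grid is 101 points on
$[0, 0.5]$ inverse Angstrom, which covers $qR_G$ well past the informative
mid-$q$ band for protein-sized particles; coordinates are Angstrom and $q$
inverse Angstrom throughout, with nm conversion left to the caller.

# The synthetic generator and what passing tests mean

`make_toy_structure()` produces uniform-ball globules ($R_G = \sqrt{3/5}R$),
random clouds, linear chains and two-domain shapes;
`mc_sample_ensemble()` realizes exactly the independent-Gaussian thermal
model. The generator emulates the *geometry* scales of the target systems
(protein-sized globules, $R_G \approx 12$ Angstrom, $\tau = 0.5$ Angstrom
for folded-protein-like stiffness, $\tau \gg 1$ for disordered-protein-like
flexibility) but not realistic protein features: no excluded volume between
atoms, no chain connectivity constraints, no correlated or anisotropic
motion, no solvent shell. Passing oracle tests therefore demonstrates that
the analytic formulas correctly describe the independent-Gaussian model at
small $\tau/d$ — which is exactly what they claim — and that the qualitative
SD and correlation structure (SD rising from zero to a single maximum then
decaying; strong near-diagonal correlation; a negative basin; minimal
bandwidth at mid-$q$) emerges already under that idealization. They say
nothing about how well independent isotropic motion approximates a real
protein's dynamics; correlated or anisotropic motion must be studied through
the numerical path on explicit conformer sets.

Problem sizes used by the test and acceptance runs (chosen as comfortable
desk-scale settings): $10^6$ samples per sinc-expectation geometry, $10^5$
conformers for mean/covariance oracles on 5–10-atom toys, $10^4$ conformers
for the numerical-path consistency check, and a 500-atom globule on the
101-point grid for the diagnostics.

# Known limitations

* Independent, isotropic, Gaussian atomic motion only; anisotropic or
  correlated motion must go through the numerical path.
* The covariance is second-order in $\tau/d^\circ$ and is not guaranteed
  positive-semidefinite; clamping events and negative-variance errors are
  surfaced, never silently repaired.
* The solvent correction is a stand-in with the right knobs, not a
  hydration-layer model.
* The exact closed-form autocovariance is deliberately not implemented
  (it is numerically unstable); the quadrature oracle fills that role for
  small systems.
* PDB input only (multi-model for ensembles); no mmCIF, no trajectory
  formats.
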