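# sascov — ensemble mean and covariance of small-angle scattering profiles

Small-angle X-ray/neutron scattering (SAS) measures the rotationally
averaged intensity I(q) of macromolecules in solution, at momentum transfer
q = 4π sin θ / λ (Å⁻¹). For a flexible molecule the measured profile is an
average over the conformers present, and the profiles of individual
conformers fluctuate around that average in a correlated, structured way.

`sascov` is an R package for structural biologists and method developers who
model SAS data of flexible systems (multi-domain proteins, intrinsically
disordered proteins, MD ensembles). It implements, around the exact Debye
formula

    I(q) = Σₖ Σₗ f_k(q) f_l(q) sin(q d_kl) / (q d_kl),

the statistics of the *thermal ensemble* in which every atom k is displaced
independently about its mean position with an isotropic Gaussian of
per-coordinate SD τ_k:

* the **exact ensemble-average intensity**
  E I(q) = Σₖₗ f_k f_l e^{−q²τ_k²/2} e^{−q²τ_l²/2} sinc(q d°_kl)
  + Σₖ (1 − e^{−q²τ_k²}) f_k², and its uniform-τ and mixture forms;
* the **analytic covariance** V(I(q_i), I(q_j)), second order in τ/d°,
  decomposed into autocovariance (a distance with itself) and
  cross-covariance (two distances sharing an atom) built from the kernel
  σ(x) = d/dx sinc(x), plus the correlation matrix ρ(q_i, q_j);
* **numerical ensemble statistics** (mean, covariance, relative SD,
  confidence bands, comparison against experimental error bars) for explicit
  conformer sets read from multi-model PDB files;
* **information diagnostics** of a profile correlation matrix: Gaussian
  mutual information −½ log(1 − ρ²) and the correlation bandwidth along the
  diagonal, which locate the most informative mid-q region;
* **synthetic structures with Monte-Carlo and quadrature oracles** that
  ground-truth every analytic operation;
* a **command line** (`exec/sascov`) with `profile`, `thermal`, `ensemble`,
  `info` and `synth` subcommands.

Units are Å and Å⁻¹ throughout. PDB input goes through bio3d; waters and
heteroatoms are excluded by default; thermal deviations can be set uniformly
or from B-factors (B = 8π²τ²).

## Worked example

A 500-atom synthetic globule with R_G ≈ 12 Å and folded-protein-like
stiffness (τ = 0.5 Å):

```r
library(sascov)

g  <- make_toy_structure("globule", 500, 12 / sqrt(3/5), seed = 2, element = "C")
g  <- assign_tau(g, "uniform", value = 0.5)
radius_of_gyration(g)
#> [1] 11.89262

ff  <- ff_model(c1 = 1)              # vacuum factors + excluded-volume term
mu  <- mean_intensity(g, ff = ff)    # exact thermal-ensemble average
cv  <- covariance_matrix(g, ff = ff) # second-order analytic covariance
rel <- relative_sd(mu, cv)
max(100 * rel$intensity)             # SD as % of the mean intensity
#> [1] 7.503539
attr(rel, "argmax_q")
#> [1] 0.29

rho <- correlation_matrix(cv)
min_correlation(rho)
#> $q_i 0.235   $q_j 0.325   $rho_min -0.5499459

bw <- bandwidth_profile(rho, threshold = 0.5)
ok <- which(is.finite(bw$width) & bw$q > 0)
bw$q[ok][which.min(bw$width[ok])] * radius_of_gyration(g)
#> [1] 3.448861
```

Reading the numbers: the ensemble SD vanishes at q = 0 (forward scattering
counts electrons and is conformation-independent), rises to a single maximum
and for this globule reaches 7.5% of the mean at q = 0.29 Å⁻¹ — comparable
to typical experimental noise, and an order of magnitude larger for
disordered systems with τ of several Å. Correlations are ≈1 near the
diagonal, show a negative basin (−0.55 between q = 0.235 and 0.325 Å⁻¹),
and the correlation bandwidth is narrowest at qR_G ≈ 3.4: the mid-q band
qR_G ~ 3–6 carries the highest density of independent information, which is
why it matters most in structure refinement.

The same computations run from a shell:

```sh
Rscript $(Rscript -e 'cat(file.path(find.package("sascov"), "exec", "sascov"))') \
    thermal --pdb structure.pdb --tau 0.5 --c1 1 --out run1
```

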