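---
title: "Information-theoretic density descriptors and hybrid regression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-theoretic density descriptors and hybrid regression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, numerical methods, tunable parameters
and design decisions behind **itaml**, and what the synthetic benchmark
does and does not establish about real data.

## The descriptor functionals

The package computes eleven information-theoretic (ITA) functionals of the
molecular electron density $\rho(\mathbf r)$, all in atomic units
(lengths in bohr, energies in hartree):

* **Shannon entropy** $S_S = -\int \rho \ln \rho \, d\mathbf r$ — spatial
  delocalization of the density.
* **Fisher information** $I_F = \int |\nabla\rho|^2/\rho \, d\mathbf r$ —
  sharpness/localization.
* **Ghosh–Berkowitz–Parr entropy**
  $S_{GBP} = -\int \tfrac32 k \rho\,[c + \ln(t/t_{TF})]\,d\mathbf r$, with
  the orbital kinetic-energy density
  $t = \sum_i \tfrac18 |\nabla\rho_i|^2/\rho_i - \tfrac18\nabla^2\rho$
  (which integrates to the non-interacting kinetic energy $T_S$), the
  Thomas–Fermi density $t_{TF} = c_K\rho^{5/3}$,
  $c_K = \tfrac3{10}(3\pi^2)^{2/3} \approx 2.8712$,
  $c = \tfrac53 + \ln(4\pi c_K/3)$, and $k = 1$ in atomic units
  (configurable).
* **Onicescu information energies** $E_n = \tfrac1{n-1}\int \rho^n$ for
  $n = 2, 3$.  The $1/(n-1)$ prefactor follows the classical definition
  and is configurable, since conventions differ in the literature.
* **Relative Rényi entropies**
  $R_n = \tfrac{1}{1-n}\log_{10}\int \rho^n/\rho_0^{\,n-1}$ for
  $n = 2, 3$ — note the decadic logarithm, kept exactly as conventionally
  printed, against the natural logarithms elsewhere.
* **Information gain** (Kullback–Leibler divergence)
  $I_G = \int\rho\ln(\rho/\rho_0)$, non-negative when $\rho$ and the
  reference $\rho_0$ share one normalization (Gibbs' inequality); the
  reference is therefore rescaled to the molecular electron count before
  $R_n$ and $I_G$ are evaluated.
* **Deformation functionals** $G_1, G_2, G_3$, sums over Hirshfeld atoms of
  relative-Laplacian and relative-Fisher integrands.  Because the
  stockholder ratio $\rho_A/\rho_A^0 = \rho/\rho^{pro}$ is the same for
  every atom, the sums collapse exactly to molecular-level integrals,
  which is how they are evaluated (no per-atom cancellation error).  The
  $G$ functionals use the *raw* atomic references, which carry no
  normalization clause.

The fixed canonical ordering `r paste(itaml::ita_names(), collapse = ", ")`
is used in every vector, table and file.

**Density floor.** Logarithms and ratios are regularized by a density floor
of $10^{-12}\,e^-/\mathrm{bohr}^3$: integrands are set to zero below it,
consistent with the $\rho\ln\rho \to 0$ limit.  The promolecule in the
stockholder weights uses a much smaller floor ($10^{-30}$); below it grid
points are assigned wholly to the nearest atom, which changes no integral
at double precision.

## Quadrature

All-space integrals use atom-centered grids glued by Becke's smooth
multicenter partition (three iterations of the smoothing polynomial
$p(\mu)=\tfrac32\mu-\tfrac12\mu^3$, no atomic-size adjustment).

* **Radial**: Gauss–Chebyshev (second kind) nodes mapped onto $[0,\infty)$
  by $r = r_m(1+x)/(1-x)$, with the element scale $r_m$ equal to half the
  Bragg–Slater radius (the full radius for hydrogen) — the customary
  choice for density-functional integration.
* **Angular**: a Gauss–Legendre ($\cos\theta$) × uniform-$\varphi$ product
  rule with $2k^2$ points ($k$ polar nodes, $2k$ azimuthal nodes), exact
  for spherical harmonics up to degree $2k-1$.  The classical
  octahedrally-symmetric angular rules used by many DFT codes exist only
  as tabulated generator coefficients; the product rule is generated in
  closed form at any size, at the cost of roughly 10–20 % more points for
  the same degree.  Valid sizes are therefore 8, 18, 32, 50, 72, 98, 128,
  162, 200, 242, 288, …
* **Resolutions**: the default is 75 radial × 288 angular per atom
  (comparable to a "fine" production setting); the coarse preset used by
  fast tests is 30 × 98.  On these grids a unit Gaussian integrates to 1
  within $10^{-6}$ and every closed-form descriptor value in the test
  suite is reproduced within $10^{-4}$ relative (within $10^{-6}$ for the
  smooth Gaussian cases).

Laplacian-carrying integrals ($G_1$, $G_2$) converge slowest: the exact
identity $\int\nabla^2\rho\,d\mathbf r = 0$ is met at the $10^{-3}$–$10^{-4}$
level on the default grid for multicenter systems, which sets the
attainable tolerance for the $G_1 = 0$ self-reference limit.

## Promolecular references

Relative descriptors and the Hirshfeld partition need spherically averaged
free-atom densities $\rho_A^0(r)$.  The bundled reference is an analytic
single-$\zeta$ Slater-type shell model generated from Slater's screening
rules, whose normalization $4\pi\int\rho_A^0 r^2\,dr = N_A$ is exact in
closed form; first and second radial derivatives are analytic, so
promolecule gradients and Laplacians carry no interpolation error.  This
is a deliberately simple, self-contained atomic model: when
quantitative reference atoms are required (e.g. atoms from a DFT code at a
specific functional/basis), load two-column radial tables with
`reference_from_tables()`; interpolation is then a cubic spline in
log-density (positivity-preserving) with linear log-tail extrapolation.
Whether pseudopotential-bearing elements should use valence-only reference
densities is left to the supplied tables; the bundled model is all-electron.

## Electrostatic descriptors and curation

The molecular electrostatic potential at a nucleus,
$V(\mathbf R_A) = \sum_{B\neq A} Z_B/|\mathbf R_A - \mathbf R_B|
- \int \rho/|\mathbf r - \mathbf R_A|$, excludes the probe's own nuclear
term; the integrable $1/r$ singularity is resolved by the probe-centered
radial shells ($r^2$ metric).  Carbonyl oxygens are identified by a
covalent-radius bond criterion (bond if the distance is below 1.15 × the
sum of covalent radii): a carbonyl-type oxygen is bonded to exactly one
atom, a carbon — which excludes ether and hydroxyl oxygens by bond count.
The descriptor row records both single-oxygen potentials and their exact
arithmetic mean.  Valence-NAO energy sums and HOMO/LUMO energies are
*ingested* from tables, never computed here.

Curation of the 000–349 quinone redox collection drops index 116
(structure not determinable from its name) and the duplicate pair 209/210,
retaining 347 molecules with first reduction potentials.  Published
descriptions of the collection state that 80 of the 347 lack a second
potential yet count 265 Q2 values (347 − 80 = 267); the curation function
reports whatever the data yields, and the synthetic roster reproduces the
80-missing reading, i.e. 267.  Potentials are carried in millivolt against
a saturated calomel electrode; unit conversions are the caller's job.

## The three regression back ends

All three consume the 13-feature space (11 ITA + HOMO + LUMO) with up to
three targets (Q1, Q2 in mV; Hammett $\sigma_p$) under an explicit-NA
missingness mask, share one stratified-by-family 80/20 split (k-fold
helpers are provided; 5 folds by default when used), and report RMSE, MAE
and $R^2$ in original units.

* **`lr`** — ordinary least squares per target via `lm.fit`, with a
  rank check that names collinear columns.
* **`mlp`** — 13 → 6 rectified units → 3 linear outputs, masked MSE
  (a missing label contributes zero gradient to its head), full-batch
  Adam (rate $10^{-3}$ by default), reduce-on-plateau schedule
  (factor 0.5, patience 10), early stopping (patience 100), default 2000
  epochs.  Features and targets are standardized on the training split
  only; the affine pair is exact, so de-standardized predictions are
  reported in original units.
* **`vqc`** — a hybrid model: classical encoder 13 → 16 (ReLU) → 12, the
  twelve outputs fed as per-qubit RX rotation angles into a 12-qubit
  circuit with two "basic entangling" layers (trainable RX on every qubit,
  then a CNOT ring $q \to q+1 \bmod 12$), Pauli-Z expectation readout on
  every qubit, and an affine head; 200 epochs by default with the same
  optimizer, loss and scheduler as the MLP.  Embedding angles receive no
  scaling beyond feature standardization.  The head is warm-started by a
  deterministic least-squares solve at the initial features, which removes
  the early epochs otherwise spent learning an output scale.

The circuit is simulated exactly by statevector evolution (compiled
kernels; amplitudes as separate real/imaginary arrays).  Gradients of all
rotation angles — including the embedding angles, through which the loss
backpropagates into the encoder — come from one adjoint backward pass at
about three forward-pass costs, and match central finite differences to
$10^{-8}$.  A brute-force dense-unitary oracle (Kronecker-product gate
matrices) verifies the engine on up to 4 qubits to $10^{-10}$.

Fits are deterministic and bitwise reproducible for a fixed seed, split
and configuration: initialization is the only randomness, training is
full-batch, and the best-validation parameters are returned.

## The synthetic benchmark

`make_toy_quinone()` builds a 12-center Gaussian "molecule" (hexagonal
ring, two para carbonyl-like oxygens, four hydrogen-like substituents)
whose promolecule is the same superposition, so at zero perturbation the
density *equals* its reference and every deformation measure has an exact
zero; a perturbation moves electrons from the carbonyl carbons to the
oxygens (60/40 between the two, so their potentials co-vary without being
identical), conserving the total count.  Exponents default to
$\alpha = 1\,\mathrm{bohr}^{-2}$ scale so the toy density decays on the
length scale real valence densities do — the scale the Bragg–Slater radial
maps are built for.

`generate_table()` draws 13 features from a block-correlated Gaussian
(within-block correlation 0.95 across four blocks, 0.3 between; invented
location/scale per feature), mimicking the strong collinearity of ITA
descriptor spaces, and maps them to targets by a planted mechanism:
affine, a random 6-unit rectifier net, or a random circuit model of the
production architecture.  A planted circuit teacher has its realized
embedding-angle spread normalized to 0.5 rad so the planted map stays in
the circuit's smooth response range, as gently varying structure–property
relations do.  Targets get Gaussian noise (defaults 100 mV for Q1, 120 mV
for Q2, 0.15 for $\sigma_p$ — fixture choices on the scale of
experimental redox scatter, not literature values) and per-task missing
labels.  Identical seeds give identical tables.

What passing the benchmark shows: the quadrature, partition, descriptor,
circuit and training machinery are each correct against independent
oracles, and the nonlinear models beat the linear baseline on nonlinear
planted maps.  What it does not show: anything about the accuracy
achievable on real quinone data, which depends on DFT densities, basis
sets and experimental error that the generator does not emulate.

## Known limitations

* **Teacher–student recovery of the circuit model.**  The recovery suite
  plants a circuit-model teacher (n = 300, noiseless, seeded) and trains a
  fresh model of the same architecture for 200 epochs.  The multilayer
  perceptron recovers its planted rectifier teacher to a few percent of
  the target spread, but the hybrid circuit model typically reaches only
  40–60 % of the validation spread, far from the few-percent regime — and
  its *training* error also stalls well above zero.  Exploratory
  experiments (wider/narrower students, more data, longer training,
  restarts, smoother teachers, schedule variants) moved this only
  modestly.  We report the measured ratio as-is: the non-convex landscape
  of the entangled circuit under plain full-batch Adam is the binding
  constraint, consistent with the modest (tens-of-percent-of-spread)
  accuracies hybrid circuit regressors attain in practice.  The
  benchmark entry is asserted at its nominal bound in the acceptance
  tests and fails there by design rather than being weakened.
* Grid accuracy for Laplacian-carrying integrals is the weakest link
  (see above); refine the radial grid first if $G_1/G_2$ matter.
* The bundled Slater-rule atoms are qualitative; quantitative relative
  descriptors need user-supplied reference tables.
* Cube-file input carries no orbital densities, so $S_{GBP}$ (and $T_S$)
  require analytic fields or user-supplied orbital data.
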