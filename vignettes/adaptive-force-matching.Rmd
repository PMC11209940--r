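---
title: "Adaptive force matching for alkane force fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive force matching for alkane force fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmatch)
```

## The problem

Liquid alkanes are held together almost entirely by dispersion: the heat
of vaporization is barely more than 1 kcal/mol per carbon, not far above
thermal energy at room temperature. A force field meant to reproduce a
quantum-mechanical potential energy surface for such molecules therefore
has to get weak, distance-sensitive interactions right, and small
parameterization errors turn into large percentage errors in bulk
properties. Adaptive force matching (AFM) addresses this by fitting every
force-field parameter to reference *atomic forces* computed on small
clusters with a correlated electronic-structure method, with no empirical
input: the force field is best understood as a proxy for running the
reference method at molecular-mechanics cost.

`afmatch` implements the complete parameterization machinery: the energy
model and its analytic forces, the linear force-matching solve, charge
extraction by eigendecomposition of the fitted charge-product matrix
(CMD), the separate dispersion fit against dimer dispersion energies, the
iterative sample/fit loop with a radial-distribution-function (RDF)
convergence diagnostic, and the long-range tail corrections needed when
the resulting model is simulated with a finite cutoff. Because the
package cannot ship an electronic-structure code, the reference data are
produced by a *synthetic* generator: a known ground-truth force field
plays the role of the quantum reference, which turns every fitting stage
into a falsifiable parameter-recovery experiment.

## The energy model

Atoms carry types, not identities: linear alkanes use terminal carbons
`C3`, secondary carbons `C2` and one hydrogen type `HC`; cyclic alkanes
need only `C2` and `HC`. The energy expression is

* bonds: $E = k_r (r - r_e)^2$,
* angles: $E = k_\theta (\theta - \theta_e)^2$,
* torsions: $E = A_t (1 + \cos(m\phi - \phi_0))$ with $m = 3$,
  $\phi_0 = 0$ for saturated chains; torsions involving hydrogen are not
  modeled,
* noncovalent pairs (more than two bonds apart, or intermolecular; 1-4
  pairs at full strength):
  $$u_{ab}(r) = \frac{k_e\,q_a q_b}{r} + A_{ab} e^{-b_{ab} r}
    - \frac{C_{6,ab}}{r^6 + r_d^6} - \frac{C_{8,ab}}{r^8 + r_d^8}.$$

Three conventions deserve a note. First, the harmonic terms carry **no
1/2 prefactor**; external parameters must be converted on import. Second,
short-range repulsion is exponential (exchange repulsion is better
approximated by $e^{-br}$ than by an $r^{-12}$ power law), and parameters
are **pair-specific**: no combining rules anywhere. Third, dispersion is
damped with the rational form $-C_n/(r^n + r_d^n)$. The damping distance
$r_d$ is set from van der Waals radii at configuration time and is never
fitted; the rational form was chosen because it removes the unphysical
short-range divergence of the inverse power laws while leaving the
$-C_n/r^n$ asymptote untouched, and the parameter file records the form
under a `damping` tag so alternatives could be added without ambiguity.
Dispersion coefficients exist only between carbon pairs; hydrogen pairs
interact through charges and repulsion alone. A $C_{10}$ term is
deliberately excluded — in exploratory fits of this family of models it
tends to come out repulsive, i.e. unstable.

Units are fixed throughout: Angstrom, kcal/mol, elementary charge,
radian, with $k_e = 332.06371$ kcal·Å/(mol·e²). Finite clusters are
evaluated without periodicity; frames carrying an orthorhombic box use
the minimum-image convention.

## The linear force-matching solve

Given training conformations with reference forces, every free parameter
enters the model force *linearly* once the repulsion exponents $b$, the
damping distances $r_d$ and (in the second pass) the charge products are
held fixed. Bonded terms stay linear through the reparameterization
$k_r$, $k_r r_e$ (and the angle analogue): the bond force along the bond
direction is $-2[k_r]\,r + 2[k_r r_e]$. The design matrix has one row per
Cartesian force component and one column per free parameter — the exact
derivative of the model force with respect to that parameter — and the
system is solved by singular value decomposition, keeping the
minimum-norm solution.

Two numerical choices matter:

* **Column equilibration.** Parameter scales span roughly six orders of
  magnitude (bond force constants ~10² vs charge products ~10⁻²), so a
  truncation threshold relative to the raw largest singular value would
  silently discard physically meaningful charge-product directions.
  Columns are normalized to unit Euclidean norm before the SVD and the
  solution is rescaled afterwards; the default relative threshold is
  `rcond = 1e-10`.
* **Soft neutrality constraints.** For every molecular species and atom
  type A, a row encoding $\sum_B n_B Q_{AB} = 0$ is appended with weight
  $10^3$ times the median force-row RMS. These rows pin the
  weakly-determined directions of the charge-product block without
  overriding the force data.

The repulsion exponent $b$ is *not* a linear parameter and is never part
of the solve; it is inherited from the initial model. An optional outer
grid scan (`scan_repulsion_b()`) refits the linear system for candidate
scalings of all $b$ values and picks the factor minimizing the force
residual, which keeps every individual solve linear.

## Charge Matrix Decomposition

Coulomb forces are linear in the charge *products* $Q_{AB}$, not the
charges, so the first pass fits all products as independent parameters.
With more than two atom types the fitted products generally violate the
rank-1 consistency $Q_{AB} Q_{CD} = Q_{AC} Q_{BD}$, so no charge vector
reproduces them exactly. CMD resolves this optimally: the product matrix
is real symmetric; take its largest eigenvalue $\lambda_1$ and
eigenvector $v$, and set $q_A = \sqrt{\lambda_1}\, v_A$. By the
Eckart–Young theorem this is the best rank-1 approximation in the
Frobenius norm. The eigenvector sign is arbitrary (flipping every charge
leaves all products unchanged), so the sign is anchored: hydrogen is made
non-negative, or, absent hydrogen, the least electronegative element on
the Pauling scale, ties broken by type-label order. If the matrix has no
positive eigenvalue — "imaginary charges" — every charge is set to zero;
$\lambda_1 = 0$ is folded into the same rule for continuity. A degenerate
dominant eigenvalue is resolved by the eigenvector with the largest
anchor component, with a warning.

The second pass then fixes the products at $q_A q_B$, subtracts their
Coulomb forces from the reference, and refits the remaining
non-Coulombic parameters. With only two atom types the
neutrality-constrained products are automatically rank-1 and the two
passes agree; the package still runs both for uniformity. If the CMD
charges violate molecular neutrality by more than $10^{-6}$ e (possible
under noise), a minimal-norm uniform shift restores it and a warning is
emitted.

## Dispersion fitting

Dispersion references are *energies*, not forces (second-order dimer
dispersion energies), so this stage is energy-based and runs once,
before the force-matching iterations; the coefficients are frozen
afterwards. Dimers are extracted from multi-molecule configurations with
nearest-atom distances in the closed window [5, 12] Å — closer pairs are
contaminated by exchange-dispersion, which the model does not represent,
and the window guarantees correct asymptotics. Each record contributes
one row: the reference energy against the damped
$-1/(r^6+r_d^6)$, $-1/(r^8+r_d^8)$ basis summed over intermolecular
carbon pairs. The same coefficient serves a given type pair regardless of
source molecule, so records from several species can be pooled in one
solve, which reduces statistical noise. Damping is active during the fit
with the production $r_d$ values (self-consistency; at ≥ 5 Å the damping
correction is tiny anyway). Negative fitted coefficients are flagged by
`stability_check()` as a stability warning.

A caveat the tests make explicit: when several carbon pairs are fitted
jointly, their basis columns are strongly collinear (every dimer contains
all pairs at similar distances), so individual coefficients of the
multi-pair fit are noise-sensitive even though the total dispersion
energy is well determined. The noise-robustness property is therefore
stated for the dominant C6 of a single-pair system (cyclopentane
homodimers).

## The AFM loop

One generation = sample conformations with the current model (Langevin
dynamics at 298 and 328 K, 100 frames per temperature in the reference
protocol), obtain reference forces from the oracle, refit everything by
the two-pass solve. The oracle interface is pluggable —
`mock_reference_oracle()` wraps the synthetic truth; real
electronic-structure outputs could be ingested through the same
interface. Convergence is judged on RDFs: after fitting, the package
resamples with the fitted model under the *same seeds* and declares
convergence when the tracked RDFs (carbon–carbon by default) differ from
the training RDFs by less than `tol = 0.05` in the max-abs metric. This
definition makes the fixed point exact: if the fitted model equals the
sampling model, the check trajectory is bitwise identical and the metric
is zero at generation one. The tolerance and the tracked pairs are this
package's defaults, documented rather than inherited. After convergence a
single global fit pools the frames of up to the last 4 generations.

The sampler is a BAOAB-splitting Langevin integrator, time step 1 fs,
friction 1/(2.0 ps) by default (the gas-phase property-calculation
setting), with the first 20% of each trajectory discarded as
equilibration — a conservative default. Sampling runs at fixed box; no
barostat is implemented, since training references are finite clusters
and property MD is out of scope. `make_training_cluster()` extracts the
6-molecule reference clusters: a seed molecule plus its five nearest
neighbors by minimum-image nearest-atom distance, unwrapped so the
cluster is whole.

## Tail corrections and property helpers

Truncating the dispersion at a cutoff $r_c$ removes energy and pressure
that the homogeneous-fluid tail integrals restore analytically, assuming
$g(r) = 1$ beyond the cutoff and undamped $-C_n/r^n$:

$$U_{tail} = -\sum_{(a,b)} 2\pi N_a \rho_b
  \left[\frac{C_6}{3 r_c^3} + \frac{C_8}{5 r_c^5}\right], \qquad
P_{tail} = -\sum_{(a,b)} \frac{2\pi}{3} \rho_a \rho_b
  \left[\frac{2 C_6}{r_c^3} + \frac{8 C_8}{5 r_c^5}\right],$$

summed over ordered type pairs (cross pairs count twice). Both formulas
are verified against direct numerical quadrature of their defining
integrals, which serves as the ground truth for the double-counting
convention. The $r^{-8}$ pressure term scales as $r_c^{-5}$, which is
what lets a correction known at one cutoff be transferred in closed form
to another, and the barostat of a truncated run must be set to
*target + |correction|* so that adding the attractive tail afterwards
lands on the target pressure. Slab (inhomogeneous) systems refuse the
correction with an explicit error — the homogeneous formula is simply
wrong there.

The property helpers are deliberately small:
$\Delta H_{vap} = U_{gas} - U_{liquid} + RT$ (the $RT$ term is the
standard ideal-gas work contribution; the package documents it as an
explicit convention), the centered finite-difference isothermal
compressibility $\kappa_T = \frac{2}{\rho_1+\rho_2}
\frac{\rho_2-\rho_1}{P_2-P_1}$, and Trouton's rule
$T_b = \Delta H_{vap} / (85\ \mathrm{J\,mol^{-1}K^{-1}})$.

## The synthetic reference generator

The generator replaces the electronic-structure stack. A complete
ground-truth force field (`alkane_ground_truth()`) defines the study
conditions: C–C bonds near 1.53 Å, backbone angles near 111°, hydrogen
charges of +0.05 e with group-neutral carbons, alkane-plausible
repulsion, dispersion and torsion magnitudes, with deliberately distinct
values across type pairs so that recovery errors cannot hide behind
symmetry. Training clusters are built by placing randomly oriented
molecules at molecule–molecule nearest-atom contacts drawn uniformly from
[1.9, 3.2] Å — the onset-to-peak range of intermolecular contact
distances in room-temperature liquid alkanes — and linear chains sample
anti/gauche backbone conformers (40% gauche) before placement, since
liquid alkanes are conformer mixtures. Both choices matter for
identifiability, not just realism: without close contacts and without
gauche exposure of the interior carbons, the carbon–carbon exponential
repulsion prefactors are essentially invisible to the force data — a
genuine property of exp-repulsion fitting, which the reference protocol
handles the same way by training on liquid-extracted clusters. Gaussian
coordinate perturbations of 0.035 Å · $\sqrt{T/298}$ per component stand
in for thermal vibration in `perturb` mode; `md` mode uses the actual
Langevin sampler under the truth model.

What the generator does *not* emulate: anharmonicity beyond what the
truth model itself contains, exchange-dispersion or any beyond-pairwise
physics (three-body dispersion is out of scope), charge flexibility, and
real liquid-state correlations beyond the contact-distance statistics
described above. Passing recovery tests therefore demonstrates that the
fitting machinery is correct and well conditioned under the stated noise,
not that the functional form suffices for real alkanes — that question
belongs to the electronic-structure side of the workflow, which this
package intentionally does not contain.

## Problem sizes and numerical defaults

The shipped tests and the acceptance script run: 6-molecule n-pentane
clusters (102 atoms), 30 noiseless and 200 noisy training frames;
dispersion fits on 200–400 dimers; AFM runs with 4 n-butane molecules in
a periodic box at the experimental-density box size, 10 frames per
temperature per generation with a 10-step stride. These sizes were chosen
so each stage carries clear statistical signal (the noiseless recoveries
are exact to ~10⁻¹², the 1% noise recoveries land within a few percent)
while a full run of everything stays in the minutes range on a single
core. Degenerate inputs are handled explicitly: zero bond/angle force
constants make the equilibrium value undefined, so such terms are dropped
with a warning rather than divided through; angles at exactly 0 or π are
rejected (undefined gradient); pair distances below 0.1 Å are treated as
data errors.

## Known limitations

* The sampler has no barostat and no Ewald electrostatics — training
  references are finite clusters or fixed-box liquids by design; bulk
  property MD is out of scope.
* Charge products, and hence charges, are conformation-independent; no
  polarizability or higher multipoles.
* The multi-pair dispersion fit is ill-conditioned under noise (see
  above); pooled multi-species data mitigate but do not remove this.
* The rational damping form is one defensible reading of
  "short-range-damped dispersion"; the parameter file's `damping` tag
  exists so a Tang–Toennies-style alternative could be added without
  breaking stored models.
* Whether 1-4 electrostatics should be scaled is answered here as "no"
  (the exclusion rule's plain reading); models imported from force fields
  with 1-4 scaling must be converted.
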