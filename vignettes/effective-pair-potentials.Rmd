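---
title: "Effective pair potentials between linear and circular DNA: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective pair potentials between linear and circular DNA: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnapairpmf)
```

## The problem

Short DNA molecules in dilute electrolyte repel each other, and both the
molecular architecture (a linear fragment versus a covalently closed
minicircle) and the valence of the counterions (Na⁺ versus Ca²⁺) shape that
repulsion. The quantity of interest is the effective pair potential
$V_\mathrm{eff}(r)$ between the centres of mass of two DNA molecules — the
potential of mean force (PMF) along the centre-of-mass separation $r$ —
together with the conformational and ion-atmosphere observables that explain
its shape: the relative orientation the pair adopts at close approach, the
flexibility of the backbone, and the degree of counterion condensation on
the polyanion.

`dnapairpmf` implements this programme at desk scale for two reference
molecules: a 24-bp linear duplex and a 65-bp torsionally relaxed minicircle,
in 0.1 M NaCl or CaCl₂ in a 15.0 nm periodic cubic box.

## The coarse-grained model

Each base pair is one bead carrying $-2\,e$ (the two phosphates of the
step), spaced by the canonical B-DNA rise of 0.338 nm, so the linear charge
density $-2e/0.338\,\mathrm{nm}$ matches double-stranded DNA. A duplex with
free 5′ ends has no 5′-terminal phosphates, so the linear model's first bead
is neutral and a 24-bp duplex carries $-46\,e$; this is exactly the charge
balance implied by the monovalent reference composition (295 Na⁺ − 203 Cl⁻
= 92 e for the pair). The minicircle is a planar regular $n$-gon of
circumference $n \times 0.338$ nm with every bead charged, i.e. $-130\,e$
for 65 bp. Its radius of gyration follows the thin-ring identity
$R_g = n \cdot \mathrm{rise} / 2\pi = 3.50$ nm for $n = 65$.

Reference ion counts imply a minicircle charge of $-128\,e$ (459 − 203 =
256 e per pair) rather than the $-130\,e$ this construction gives — most
plausibly a builder artifact in the original all-atom setup omitting one
phosphate per strand. The package computes ion counts from its own model
charge (463 Na⁺ for the ring pair) rather than replicating the discrepancy.

The Hamiltonian is an implicit-solvent bead model:

* **bonds**: harmonic, $\tfrac{1}{2} k_b (\ell - \ell_0)^2$, with $\ell_0$
  frozen at the construction geometry and $k_b = 8000$ kJ mol⁻¹ nm⁻²,
  stiff enough that bond-length fluctuations at 300 K
  ($\sqrt{k_BT/k_b} \approx 0.018$ nm) are small against the rise;
* **bending**: harmonic in the angle, $\tfrac{1}{2} k_\theta (\theta -
  \theta_0)^2$, with the default $k_\theta = k_BT\, l_p / \mathrm{rise}
  \approx 369$ kJ mol⁻¹ rad⁻² reproducing a DNA-like persistence length
  $l_p = 50$ nm at the 0.338 nm discretisation;
* **excluded volume**: WCA (cut-and-shifted Lennard-Jones) between all
  non-bonded site pairs, $\sigma = 0.35$ nm, $\varepsilon = k_BT$;
* **electrostatics**: $k_BT\, l_B z_i z_j \exp(-r/\lambda_D)/r$ between all
  charged pairs, minimum image, spherically cut and shifted at half the box
  edge, with the Bjerrum length $l_B = 0.7$ nm of water at 300 K.

Counterions (+1 or +2) and Cl⁻ co-ions are explicit. By default
$\lambda_D = 0$ (bare Coulomb): screening must *emerge* from the explicit
ions, because counterion condensation and release are the mechanism under
study — a uniform Debye background would assume away the physics. The
screened kernel is retained as an option and is used in the two-bead
validation system, where a closed form is wanted.

Ion counts follow the bulk-composition rule: the number of salt anions is
$\mathrm{round}(c \cdot V \cdot N_A)$ with the nominal box volume $V =
(15\,\mathrm{nm})^3$, rounded **up to the nearest even integer** for
divalent salt so CaCl₂ units are integral; counterions neutralise the DNA
and the salt cations. At 0.1 M this gives 203 / 204 anions and the
reference cation counts (295 Na⁺, 148 Ca²⁺ for the 24-bp pair) exactly. If
the DNA charge is not divisible by the valence, the residue is carried by
one reduced-charge counterion so assembled systems are exactly neutral.
Ions are placed by rejection sampling at least 0.5 nm from DNA beads and
0.35 nm from one another.

## Sampling

Configurations are sampled by Metropolis Monte Carlo rather than molecular
dynamics: every observable in the analysis is an equilibrium average, and
MC removes integrator, thermostat and constraint choices while satisfying
detailed balance with respect to $\exp[-(U + w)/k_BT]$ exactly. One sweep
is one trial displacement per ion plus, per molecule, one trial
displacement per bead, one rigid translation and one rigid rotation about
the centre of mass. Move amplitudes are auto-tuned to 30–50% acceptance
during equilibration and then frozen — tuning during production would break
detailed balance.

Umbrella sampling biases the centre-of-mass separation with
$w(r) = \tfrac{1}{2} k (r - r_c)^2$, $k = 5000$ kJ mol⁻¹ nm⁻², in windows
every 0.1 nm from 2 to 7 nm (51 windows). The COM separation is computed on
unwrapped molecular coordinates with no minimum image across the reaction
coordinate; this is safe because the largest sampled separation (7 nm) is
below half the box edge (7.5 nm).

The default per-window budget (5·10³ equilibration + 5·10⁴ production
sweeps, sampling every 10) is sized for desk-scale validation, not for
converged DNA physics: the full-system effective potentials from the
original explicit-solvent study (≈100 kJ/mol repulsion at 2 nm for the
minicircle pair, peaks at 2.1–2.2 nm, Na⁺–phosphate contact at 0.24 nm)
are far beyond this scale and are not reproduced here.

## WHAM

The unbiased density is reconstructed with the standard self-consistent
equations,
$$P(x_b) = \frac{\sum_i n_i(x_b)}{\sum_i N_i\, e^{(f_i - w_i(x_b))/k_BT}},
\qquad e^{-f_i/k_BT} = \sum_b P(x_b)\, e^{-w_i(x_b)/k_BT},$$
iterated in log space (log-sum-exp) so large bias energies cannot
underflow, with the gauge $f_1 \equiv 0$, convergence when
$\max_i |\Delta f_i| < 10^{-7}\,k_BT$, and bins of 0.05 nm over
[1.8, 7.2] nm — half the window spacing, fine enough to resolve peak
positions to 0.1 nm. Windows that share no occupied bin are an error, and
adjacent-window histogram overlaps below 0.05 are flagged. $V_\mathrm{eff}
= -k_BT \ln P$, set to zero exactly at the bin containing the reference
separation $r = 7.0$ nm; empty bins stay `NA` and are never interpolated.

No radial-entropy ($2 k_BT \ln r$) correction is applied: the output is the
standard distance-WHAM potential, as commonly presented. Consequently the
package's primary analytic oracle — two isolated charged beads, whose PMF
along $r$ is known in closed form — is compared against
$U(r) - U(r_\mathrm{ref}) - 2 k_BT \ln(r/r_\mathrm{ref})$: the measure term
is part of the expected result, not subtracted. The test suite requires
agreement within 0.5 $k_BT$ at every bin with at least 100 counts, and a
separate exact-sampling harmonic toy (Gaussian windows drawn analytically,
no sampler in the loop) must be recovered within 0.1 $k_BT$.

Statistical uncertainty comes from a per-window bootstrap (resample each
reaction-coordinate series with replacement, re-run WHAM, report per-bin
standard deviations). The original study reports no PMF uncertainties; the
bootstrap layer is this package's own addition.

## Conformational and ionic observables

The gyration tensor is the unweighted dyadic $S = N^{-1} \sum_i \mathbf{r}_i
\otimes \mathbf{r}_i$ in the COM frame (no mass factors), with eigenvalues
sorted descending and eigenvector signs fixed by making the first non-zero
component positive. The pair orientation angle is
$\theta = \arccos |\hat{p}_1 \cdot \hat{p}_2| \in [0°, 90°]$, where
$\hat{p}_k$ is a selected principal axis of molecule $k$: the *largest*
eigenvalue's axis for rods (the rod direction) and the *smallest* for rings
(the ring normal — an ideal flat ring has $\lambda_3^2 = 0$). The mode is
an explicit argument because the two conventions describe different
geometric questions; the package never guesses from context. Samples with a
degenerate spectrum for the selected mode are flagged rather than silently
reported.

The $(r, \theta)$ population is summarised by a product-Gaussian 2D KDE on
a 101 × 91 grid over [2, 7] nm × [0°, 90°], normalised to unit trapezoidal
integral. The bandwidth defaults to Scott's rule per dimension
($h_j = s_j n^{-1/6}$); no bandwidth is documented for the original
figures, so KDE plots are comparable only qualitatively.

RMSF uses Kabsch superposition (SVD with the determinant correction that
forbids reflections) of each frame onto a reference, then
$\mathrm{RMSF}_i = \sqrt{\langle |\mathbf{r}_i - \langle \mathbf{r}_i
\rangle|^2 \rangle}$ about the *time-mean* aligned position — the standard
fluctuation convention; the reference only fixes the alignment frame.

Ion–DNA structure is measured by $g(r)$ between site groups (minimum-image
distances, shell normalisation $4\pi r^2 \Delta r \cdot N_B/V$) and by the
coordination number $n(r_\mathrm{cut}) = 4\pi \rho_B \int_0^{r_\mathrm{cut}}
g r^2 \, dr$, with the first minimum of $g$ after its first peak as the
default shell boundary. In the coarse-grained mapping, "backbone sites" are
the DNA beads; groove-specific sites have no CG analogue and are out of
scope. For identical groups self-pairs are excluded while $\rho_B$ keeps
the full $N_B/V$, so an ideal gas integrated to the minimum-image limit
$L/2$ recovers the $\pi/6$ geometric fraction of $N_B$.

## What the synthetic systems do and do not emulate

The generator reproduces: the stiff polyanion pair with the correct linear
charge density and the two topologies, explicit mono-/divalent counterions
and co-ions at the reference compositions, thermal fluctuations at 300 K,
and restrained sampling of COM separations. It does not represent helical
twist, grooves, sequence, supercoiling, or explicit water — so passing
tests validate the estimators and the statistical machinery, and the CG
physics reproduces *mechanisms* (e.g. stronger divalent condensation, which
the suite logs on the ring pair at matched anion count) rather than the
all-atom numbers.

## Numerical choices and edge cases

* $k_BT = R \cdot T$: 2.494 kJ/mol at 300 K; energies kJ/mol, lengths nm,
  charges $e$.
* Overlapping point charges (r < 10⁻⁶ nm) are a hard error in the energy,
  not an infinity propagated into acceptance ratios.
* Histogram binning is left-closed right-open; a sample on an interior edge
  goes right; samples outside the bin range are an error, never clipped.
* WHAM convergence is monitored; a non-monotone residual over the final
  iterations triggers a warning.
* Eigen-decomposition near degeneracy: sorting is stable and the
  selected-axis gap is checked against 10⁻¹² nm².
* The master seed splits into per-window seeds as `seed + window_index`;
  all stochastic stages (placement, sampling, bootstrap) are bitwise
  reproducible under a fixed seed.
* Problem sizes in the shipped presets: the two-bead oracle uses 17 windows
  × 2·10⁴ production sweeps; the smoke preset runs 3 windows of the 24-bp
  pair in a reduced 10 nm box; the condensation comparison runs the ring
  pair at close approach for a few hundred sweeps. These are validation
  scales chosen so the whole suite runs in minutes; production-quality
  profiles need the full 51-window schedule and longer sampling.

## Worked example

```{r example, eval = FALSE}
library(dnapairpmf)

cfg <- preset_config("two-bead-oracle")
manifest <- run_pipeline(cfg, "oracle_run", seed = 11)

prof <- read_pmf_tsv(file.path("oracle_run", "pmf.tsv"),
                     reference_r = cfg$wham$reference_r)
ff <- forcefield_params(debye_length = cfg$forcefield$debye_length)
expected <- two_bead_expected_pmf(prof$bin_centers, -2, -2, ff,
                                  cfg$system$box_edge_nm,
                                  cfg$wham$reference_r)
plot(prof$bin_centers, prof$v_eff, xlab = "r (nm)",
     ylab = expression(V[eff] ~ "(kJ/mol)"))
lines(prof$bin_centers, expected - expected[which.min(abs(
  prof$bin_centers - cfg$wham$reference_r))], col = 2)
```

## Known limitations

* One bead per base pair cannot resolve groove-scale ion structure; the
  0.24 nm cation–phosphate contact distance of atomistic work maps onto the
  WCA contact (≈0.39 nm) here.
* The WCA diameter (0.35 nm) is a single global parameter; DNA–DNA steric
  contact at sub-nm separations is therefore softer than a 2 nm helix.
* The bare-Coulomb default with a cutoff at half the box edge neglects
  interactions beyond 7.5 nm; at 0.1 M the explicit-ion screening length
  (<1 nm) makes this negligible, but at much lower salt it would not be.
* Bootstrap errors assume independent samples within a window; the
  sampling stride only thins, it does not guarantee decorrelation.
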