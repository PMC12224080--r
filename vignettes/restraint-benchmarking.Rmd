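---
title: "Scoring optimized geometries against diffraction data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring optimized geometries against diffraction data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtalbench)
```

# The model

## Restrained least squares and the ΔR1 diagnostic

Crystallographic positional refinement minimizes, over the fractional
coordinates of the refined atoms and an overall scale $k$,

$$
M = \sum_h w_h \left(F^2_{o,h} - k\,F^2_{c,h}\right)^2
  + \sum_r w_r \left(D_r - T_r\right)^2 ,
$$

where $F^2_o$ are measured Bragg intensities, $F^2_c$ calculated ones,
$D_r$ a model interatomic distance and $T_r$ its restraint target taken
from an externally optimized geometry. Refinement is against $F^2_o$
(the SHELXL convention) while the agreement statistic is reported on
amplitudes, $R_1 = \sum\bigl||F_o|-|F_c|\bigr| / \sum|F_o|$ with
$|F_o| = \sqrt{\max(F_o^2, 0)}$.

The benchmarking idea is to run this twice with identical settings — once
unrestrained (UR), once restrained (RR) to the optimized geometry with
*tight* standard uncertainties — and read off
$\Delta R_1 = R_1(\mathrm{RR}) - R_1(\mathrm{UR})$. Because the restraints
are enforced essentially exactly, $\Delta R_1$ is not a quality-of-fit
statistic in the usual sense: a *large* value does not mean the restraints
are unusable, it means the optimized geometry disagrees with what the data
support. Relaxing the s.u.'s recovers the UR result (this limit is asserted
in the test suite to RMSCD $< 10^{-5}$ Å).

The coordinate-space counterpart is the RMSCD over matched non-hydrogen
atoms at a fixed unit cell,
$\mathrm{RMSCD} = \sqrt{\tfrac1n \sum_i |\,\mathbf{G}(\mathbf r_{1i}-\mathbf r_{2i})\,|^2}$,
with $\mathbf G$ the fractional-to-Cartesian matrix and each fractional
difference wrapped into $[-\tfrac12, \tfrac12)$ per component. Both scores
rank a set of degraded geometries the same way; the tests assert a
Spearman-type consistency indirectly through the monotone response of
$\Delta R_1$ to controlled coordinate error.

## Structure factors

The engine is a pure independent-atom model:

$$
F(\mathbf h) = \sum_{\mathrm{ops}} \sum_{\mathrm{atoms}}
o_a f_a(s)\, T_a(\mathbf h; R, U)\,
e^{2\pi i \mathbf h\cdot(R\mathbf r_a + \mathbf t)} ,
$$

with four-Gaussian Cromer–Mann form factors $f_a(s)$,
$s=\sin\theta/\lambda$, and anisotropic Debye–Waller factors
$T = \exp(-2\pi^2\, \mathbf h'^{\!\top} N U N \mathbf h')$, where
$\mathbf h' = R^{\top}\mathbf h$, $N = \mathrm{diag}(a^*, b^*, c^*)$ and
$U$ the CIF-convention tensor. Site multiplicity is carried by the
occupancy (SHELX convention), so the symmetry-summed $F$ equals the $F$ of
the same structure expanded to P1 — an identity the suite checks on 50
random fixtures to a relative error below $10^{-8}$, and the single
strongest correctness guarantee in the package. Anomalous dispersion,
extinction and aspherical (deformation-density) scattering are deliberately
out of scope: with hydrogen excluded from restraints and angles, IAM
refinement is an adequate reference for non-hydrogen coordinate
benchmarking, and every omitted correction would affect UR and RR alike.

## Thermal motion

At very low temperature, libration still shortens apparent bond lengths
slightly. A translation–libration–screw (TLS) model is fitted to the
Cartesian anisotropic ADPs of the non-hydrogen atoms by linear least
squares (20 parameters, $\mathrm{tr}\,S = 0$, at least 7 atoms), and bond
lengths are corrected by displacing each atom by
$\Delta\mathbf r = \tfrac12(\mathrm{tr}(L)\,I - L)(\mathbf r - \mathbf o)$.
For isotropic libration $L = \lambda I$ this elongates every distance by
exactly $\lambda d$, which the tests use as an analytic anchor. The same
mean elongation $\delta$ can be pushed into restraint targets:
bond targets shift by $\delta$ and 1–3 targets by the first-order
law-of-cosines propagation
$[(d_1 - d_2\cos\theta) + (d_2 - d_1\cos\theta)]\,\delta / D_{13}$,
which agrees with exact recomputation to below $10^{-6}$ Å for
$|\delta| \le 0.002$ Å. The Busing–Levy riding correction
$d + (\langle u^2_\perp\rangle_{\mathrm{rider}} -
\langle u^2_\perp\rangle_{\mathrm{parent}})/2d$ is provided for
hydrogen-like riders.

# Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `su_bond` / `su_angle` ("tight") | 0.0005 / 0.002 | Å | restraint s.u.'s that make ΔR1 diagnostic |
| `restraint_profile("practical")` | 0.01 / 0.03 | Å | the scale used to actually improve refinements |
| cluster `threshold` | 3.75 | Å | minimum contact distance for including a whole ASU image |
| `weight_a`, `weight_b` | 0.1, 0 | – | σ-based weighting $w = 1/[\sigma^2 + (aP)^2 + bP]$ |
| `restraint_weight_scale` | 1.0 | – | multiplier on $w_r = s\,\cdot\mathrm{scale}/\mathrm{su}^2$ |
| `h_u_multiplier` | 2.4 | – | riding-H $U_{\mathrm{iso}}$ as a multiple of the parent $U_{\mathrm{eq}}$ (3.0 for hydroxyl/methyl-type H) |
| `damping` | 1.0 | – | step multiplier; backtracking halves it further when needed |
| `convergence_tol` | 0.01 | – | stop when max shift/esd falls below this |

The relative weight of restraints against data is the one genuinely open
choice in the objective. We use $w_r = s/\mathrm{su}^2$ with
$s = \overline{w_h F_o^4}$ fixed from the first cycle: this normalizes a
restraint deviation of one s.u. to the same objective contribution as a
typical one-sigma-scale data residual, which is what makes a 0.0005 Å
s.u. behave as "tight" regardless of the data scale, and exposes the
remaining freedom as a single documented multiplier.

# Numerical choices

* **Orthogonalization convention**: $a\parallel x$, $b$ in the $x$–$y$
  plane. All published comparisons depend on it only through invariant
  distances.
* **Exact symmetry algebra**: operator translations are stored as rational
  numerator/denominator pairs; group closure is checked exactly, and
  operators are taken verbatim from the input file rather than from
  tables (origin conventions in deposited files vary).
* **Special positions**: P1 expansion merges copies closer than $10^{-4}$
  (fractional) and sums their occupancies, which is what keeps the
  P1-expansion structure-factor identity exact.
* **Floating origins**: in polar space groups (all three directions in P1,
  the $b$ direction in P2₁) the intensities are invariant under a rigid
  translation, so the normal matrix is singular. The refiner detects the
  polar directions from the rotation parts ($Rv = v$ for all $R$) and pins
  the mean refined coordinate along each with a strong pseudo-observation
  at the data's own weight scale.
* **Step control**: Gauss–Newton with an analytic Jacobian; the damped step
  is halved (up to 8 times) whenever it would increase the objective, so
  the objective is non-increasing across accepted cycles. Convergence is
  max shift/esd $< 0.01$ with esd's from the inverse normal matrix.
* **ADPs are held fixed** during both UR and RR. ΔR1 probes coordinate
  error; letting ADPs float would let them absorb part of the restraint
  conflict and blur the diagnostic. This also means the engine refines
  positions and scale only.
* **Bond perception** uses Cordero-style covalent radii with a 1.15
  tolerance factor, hydrogen limited to its nearest partner. Geometries
  whose 1–3 distances fall inside the bonding cutoff (compressed angles)
  should supply an explicit bond graph.
* **Matching tie-breaks**: greedy assignment on the combined figure of
  merit (extended-connectivity match ≫ position ≫ mass ≫ charge, weights
  100/10/1/1, configurable); ties broken by smallest Cartesian distance,
  then label order — fully deterministic. Hydrogens are mapped through
  their parents, never by the figure of merit.
* **Cluster translation bounds**: per axis,
  $\lceil (\mathrm{threshold} + \mathrm{diameter}) / t_i \rceil + 1$ cells,
  with $t_i$ the perpendicular cell thickness $1/|a_i^*|$ — robust for
  oblique cells, and verified against brute-force supercell enumeration.
  The contact rule uses all atoms including hydrogen by default (the
  alternative heavy-atom rule is a flag).
* **RMSCD** wraps per atom to the nearest image and does not remove a
  rigid shift by default; an optional mode subtracts the mean displacement
  first and is always recorded in the report, since cluster-style
  optimization can translate the whole ASU slightly within a fixed cell.
* **TLS origin** is the centroid of the fitted atoms, with no post-fit
  origin symmetrization: an origin shift only reparameterizes $(T, S)$
  and leaves both the predicted $U_{ij}$ and the libration correction
  unchanged, so the simpler convention is used and declared here.

# What the synthetic fixtures emulate — and what they do not

`make_toy_structure` grows a connected molecule with bond lengths in
1.2–1.6 Å, no intramolecular nonbonded contact under 2.0 Å, places it at
a general position with at least 2.0 Å between symmetry images, and
assigns ADPs from a rigid-body TLS model whose magnitudes
($T \approx 0.01$ Å², $L \approx 0.001$ rad²) match organic molecules
near 20 K. Hydrogens follow the riding convention
($U_{\mathrm{iso}} = 2.4\,U_{\mathrm{eq}}$(parent)). Simulated intensities
are $|F_c|^2(1+\varepsilon)$, $\varepsilon \sim N(0, \text{noise})$, for
the Laue-unique reflections to `d_min`.

This reproduces the *structure* of the benchmarking problem — symmetry,
resolution, noise, rigid-body thermal motion — but not real chemistry: no
valence rules, no realistic torsional landscape, no disorder, no solvent,
no systematic errors (absorption, extinction, truncation), and ADPs that
are *exactly* rigid-body. Passing tests therefore demonstrate the
correctness of the machinery (structure factors, symmetry, least squares,
TLS algebra, cluster enumeration) and the qualitative behaviour of the
diagnostics; they do not certify accuracy claims for any particular
quantum-chemical method on real data — for that, deposited structures and
their measured structure factors must be supplied.

Default problem sizes (chosen so a full run of the suite and the
acceptance script stays comfortably interactive): 4–8 heavy atoms, cells
of 7–12 Å, `d_min` = 0.9 Å (≈ 1000–1700 unique reflections), 2 % noise;
oracle sweeps use 50 fixtures and the TLS inverse problem 100.

# Known limitations

* IAM only: no aspherical scattering, no anomalous dispersion, no
  extinction — adequate for non-hydrogen coordinate benchmarking, not for
  charge-density work.
* Positions and scale are the only refined parameters; ADP refinement is
  out of scope by design (see above).
* Weighting-scheme constants $(a, b)$ are user-supplied, not optimized to
  convergence; both refinements share them, so ΔR1 comparisons remain
  internally consistent.
* The CIF reader covers the core-dictionary subset used by small-molecule
  depositions (cell, symmetry loop, atom sites, aniso loop, Biso/Uiso),
  not CIF2 or save frames.
* Restraints are generated intra-ASU only; for multi-component ASUs no
  inter-molecule restraints are created.
* The built-in space-group table covers the fixture settings (P1, P‑1,
  P2₁, P2₁/c); anything else must arrive through its operator list in the
  input file, which is also the recommended path.

```{r session}
sessionInfo()
```
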