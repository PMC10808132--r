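---
title: "Mechanics of DNA mechanocapsules: models, parameters and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanics of DNA mechanocapsules: models, parameters and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmcpull)
```

## Scope

A DNA mechanocapsule (DMC) is a wireframe DNA tetrahedron whose duplex edges
cage a molecular cargo; one strand — the force-bearing (FB) strand — carries
the cell-binding ligand, and its dehybridization under piconewton receptor
forces constitutes rupture and release. This package covers the
computational side of designing such capsules: the file formats, the
force-spectroscopy analysis of steered pulling trajectories, the geometric
metrics that decide whether a cargo stays caged, and the fluorescence
calibration arithmetic used to read out surface tension-probe experiments.
It deliberately does not re-implement a nucleotide-resolution DNA force
field; instead it ships a transparent bead–spring stand-in (below) so every
analysis can be driven end to end by generated data.

## Force reconstruction from dual harmonic traps

The pulling protocol tethers the anchor nucleotide to a fixed harmonic trap
of stiffness $k_1$ and the ligand nucleotide to a trap of stiffness $k_2$
translated at constant rate $v$ along the unit axis $\hat u$. Because the
two traps load the molecule in series, the probe stiffness is
$k_\mathrm{eff} = (k_1^{-1} + k_2^{-1})^{-1}$; the default 11.42 pN/nm traps
give 5.71 pN/nm. The reported force is the series-spring tension

$$F(t) = k_\mathrm{eff}\,\big[(\vec x_{\mathrm{trap},b} - \vec x_b) -
        (\vec x_{\mathrm{trap},a} - \vec x_a)\big]\cdot\hat u,$$

i.e. the *sum of the two spring stretches* projected on the pulling axis.
The difference of the two trap-to-nucleotide displacement vectors is what
makes the two stretches add: for a molecule under tension $T$ the moving
trap leads its nucleotide by $T/k_2$ while the anchored nucleotide leads its
trap by $T/k_1$, and the projection above returns exactly $T$. Forces are
reported positive in tension.

Two extension conventions are provided. The default, `"nucleotide"`, is the
projected separation of the two attachment nucleotides minus its value in
the first frame; it makes the post-rupture jump visible in force–extension
plots. The `"trap"` convention (trap separation) is the natural abscissa
when comparing against analytic spring chains, because there the slope of
force against extension is the full series stiffness of traps plus molecule.

**Smoothing.** Raw trap forces at 310 K are noisy, so the peak is detected
on an exponential moving average $y_i = \alpha x_i + (1-\alpha)y_{i-1}$.
The smoothing constant is not a physical parameter; the default
$\alpha = 2/(W+1)$ with a window $W$ of 1 % of the frames is scale-free in
trajectory length and is exposed as an argument.

**Rupture detection.** The candidate rupture force is the global maximum of
the smoothed force. Since a peak alone can be an artefact of run
termination, the detection is only declared valid when the smoothed force
falls below $(1-d)\times$ peak within the following $w$ fraction of frames;
$d = 0.5$ and $w = 0.1$ by default, both configurable. A symmetric slow
decline therefore does not count as rupture — only the characteristic sharp
drop of strand release does. Invalid detections return no force rather than
a misleading number.

## Structural metrics

**Hydrogen-bond state.** The simulator that produced a trajectory knows its
bond energies, but a file-based analysis does not; base-pair state is
therefore judged geometrically. Each nucleotide's hydrogen-bonding site is
placed 0.4 simulation length units along its base vector, and a designed
pair is *bound* when the two sites are closer than a cutoff (default 0.4
length units ≈ 0.34 nm) with anti-aligned base vectors. The cutoff is
deliberately configurable: for noisy bead-model trajectories a looser value
(≈ 2 units) separates the bimodal bound/unbound distance distribution more
robustly, while the tight default matches nucleotide-resolution geometries.
The denatured fraction is $1 - (\text{bound}/\text{designed})$ per frame,
quoted at the final frame. Whether the designed set should be the FB pairs
only or every pair in the structure depends on the question being asked;
both are supported by passing the corresponding pair list, and the two can
differ substantially (the FB duplex is the designed weak link).

**Pore geometry.** Each tetrahedron face is modelled as the triangle of its
three hinge nucleotides, and the pore size as the incircle radius
$r = 2A/P$ — the cross-section of the largest sphere that can pass. Hinge
nucleotides are part of the design specification, not auto-detected: vertex
geometry in a real wireframe structure depends on the strand routing, which
the analysis cannot infer. Per-frame series report all four radii plus
their maximum and mean (the plotting convention is to draw the maximum and
shade down to the mean). Leakage uses a strict inequality — a pore exactly
the cargo radius is not leaky — and triangles with area below
$10^{-9}\,\mathrm{nm^2}$ are treated as degenerate with $r = 0$.

## The bead–spring pulling simulator

The generator emulates the study conditions of a steered coarse-grained
pulling run: a DNA tetrahedron of 5 strands with 17–20 bp edges (0.34 nm
rise, so 6.8 nm edges at 20 bp), thermal noise at 310 K, and the dual-trap
protocol with 11.42 pN/nm traps moved at the converted canonical rate of
$1.4\times10^4$ nm/s. It is *not* an oxDNA re-implementation: one bead per
nucleotide, no helicity, no stacking, no sequence dependence, no salt. Its
purpose is to produce trajectories whose mechanics are known exactly — every
bond's rupture is planted and logged — so that the analysis code can be
validated against ground truth.

**Geometry.** Three face strands each traverse the three oriented edges of
one face; a fourth face strand is truncated, and the FB strand occupies the
first `fb_bp` positions of the remaining edge, leaving part of that edge
single-stranded. Each strand is offset 0.59 nm from its edge axis toward
its own face interior, which puts the two strands of a duplex 0.68 nm
apart — exactly 0.8 simulation length units, so the hydrogen-bonding sites
of a pair coincide and the geometric bound criterion holds at build time
with maximal margin. Base vectors point at the paired bead (and follow it
over the trajectory), so the same criterion applies unchanged to simulator
output.

**Dynamics.** Overdamped (first-order) Langevin integration:
$\Delta\vec x = (F/\gamma)\,\Delta t + \sqrt{2k_BT\,\Delta t/\gamma}\,\xi$.
Inertia is irrelevant for quasi-static pulling, and a first-order scheme
keeps the update rule — and therefore the planted-rupture bookkeeping —
trivially auditable. Thermal noise is drawn from R's random stream, so a
single `set.seed` fixes the entire run bit for bit; two runs with one seed
produce identical trajectories and bond-event logs. The integrator aborts
with a diagnostic if any bead moves more than one backbone rest length in a
single step (the signature of a timestep instability).

**Parameters and why.** Defaults, all exposed in `sim_params()`:

| parameter | default | rationale |
|---|---|---|
| backbone stiffness | 300 pN/nm | stiff enough that 30 pN loads stretch a 20-bond edge by ~1 nm, keeping faces near-rigid below rupture |
| structural bp stiffness / threshold | 50 pN/nm, 2.0 nm | breaking force 100 pN; threshold ≈ 7 σ of the measured thermal extension fluctuation (~0.21 nm), so structural pairs never break spontaneously at 310 K |
| FB bp stiffness / threshold | 10 pN/nm, 3.0 nm | planted per-bond rupture force 30 pN — the tens-of-pN regime of interest; ≈ 9 σ of the FB fluctuation (~0.32 nm) |
| friction γ | 10⁻⁵ pN·s/nm | effective (not water) friction; sets the slowest relaxation ≈ 10⁻⁵ s, ~100× shorter than the default pull duration, so pulling is quasi-static |
| timestep | 1.5 ns | $k_{max}\Delta t/\gamma \approx 0.1$, an order below the Euler stability limit |
| steps / stride | 7×10⁵ / 700 | 14.7 nm of trap travel at the canonical rate; 1001 frames |

Rupture forces of the full structure emerge from load sharing: the FB
duplex is loaded in shear, so its bonds break cooperatively and the rupture
force grows with the FB pair count (~2 FB pairs ≈ 26 pN, 4 ≈ 40–50 pN,
6 ≈ 59 pN at the default rate) and with the planted threshold. The suite
asserts exactly this monotone ordering — mirroring how longer force-bearing
strands give stronger capsules — and *not* any absolute force value:
mapping a bead-model rupture force onto a nucleotide-resolution one is
outside what this simulator can claim, and thermally assisted crossing
makes the measured peak loading-rate dependent, as in any force
spectroscopy.

**The rigid analog.** Placing both attachment points on the anchoring
strand makes a force-non-responsive design: the FB strand is bypassed and
the capsule survives forces an order of magnitude above the soft design's
rupture. Denaturation then proceeds by a different route — the pulled
strand's backbone stretches while its free-ended complement does not, and
the accumulated slip tears base pairs in the loaded span. The farther the
pull point sits from the anchor along the strand, the more pairs fall in
that span and the more denature, even though the softer span reaches a
*lower* final force at equal trap travel. The test suite uses pull points
spanning increasing fractions of the FB-complement region (positions 1–5)
and checks the non-decreasing trend. What this model cannot reproduce is
true overstretching: a harmonic backbone has no S-DNA transition, and a
duplex whose two strands are both anchored shares axial load without
straining its base pairs at all. Position-dependent denaturation therefore
requires a free-ended complement here, where in a nucleotide-resolution
model it arises in any overstretched duplex.

**Excluded volume** is off by default — below rupture the strands never
approach, and the n² term dominates the runtime — with a soft harmonic
repulsion available behind a flag.

## Problem sizes

The full-size analog (20 bp edges, 224 beads, 7×10⁵ steps) runs in ~15 s on
one CPU; the test suite's behavioural properties use an 8 bp-edge analog
(~90 beads, 2×10⁵ steps, ~2 s per run) so that 5-level × 10-seed
monotonicity scans stay inexpensive. The sub-rupture pore-radius bound is
measured on the full-size analog over three seeds with the pull terminated
while the smoothed force is below the planted per-bond threshold; at that
point the largest face incircle stays near its built value of ~1.75 nm,
well under the 2.3 nm cargo bound.

## File formats and units

Only the classic oxDNA dialect is supported (topology header
`N_nt N_strands`, rows `strand base 3' 5'`; configuration headers `t =`,
`b =`, `E =` followed by 9- or 15-column nucleotide rows), the dialect of
the tooling era the analysis targets; the newer `.top`-v2 format is out of
scope. Indices are 0-based in file order everywhere. Coordinates are
treated as unwrapped: the structure (~10 nm) is small against any sensible
box, so no minimum-image correction is applied. Unit conversions use
0.8518 nm and 3.03×10⁻¹² s per simulation unit; the force unit, 48.63 pN,
never appears in published protocol descriptions but is fixed by
consistency — 0.2 simulation stiffness units must equal the printed
11.42 pN/nm trap stiffness, which it does to 0.03 %.

## Assay formulas: conventions chosen

* **Quenching efficiency.** The formula is implemented as
  $(1 - I_q/I_{uq})\times100$: the alternative operator-precedence reading
  $1 - (I_q/I_{uq}\times 100)$ produces negative percentages for any real
  input and is inconsistent with efficiencies quoted near 87 %.
* **Spacing.** Probe spacing uses the square-lattice convention
  $\rho^{-1/2}$; 2890 µm⁻² gives 18.6 nm. A hexagonal-packing convention
  would report ~20 nm; the square-root convention is the one that
  reproduces the quoted ~18 nm.
* **Leaflet factor.** The bilayer calibration counts fluorescent lipid in
  both leaflets (factor 2, with the 0.72 nm² footprint). Whether a given
  calibration protocol bleaches or images one leaflet only is
  instrument-dependent, so the factor is an argument, not a constant.
* **Decay fits.** $I(t) = A e^{-\lambda t}$ by default, with an optional
  plateau term; the half-life is $\ln 2/\lambda$. Non-decaying data yield
  an invalid fit flag rather than an error or a negative half-life. Fits
  use Levenberg–Marquardt with log-linear starting values, and recover
  noiseless parameters exactly and 5 %-noise parameters within 10 %.

## Known limitations

* The simulator's absolute rupture forces are not comparable to
  nucleotide-resolution predictions; only orderings and trends are
  meaningful. Users with access to a full DNA model should treat the
  analysis modules as the product and the simulator as scaffolding.
* The geometric hydrogen-bond criterion misclassifies transiently stretched
  intact pairs at tight cutoffs on noisy trajectories; cutoff choice
  matters and is left to the caller.
* Hinge nucleotides, designed pair lists and attachment indices are inputs;
  nothing is inferred from sequence or geometry.
* No force-clamp protocol, no worm-like-chain fitting, no loading-rate
  (Bell–Evans) regression, no PDB export, and no support for
  LAMMPS/GROMACS trajectory formats.
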