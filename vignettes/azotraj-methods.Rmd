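---
title: "Methods: trajectory-ensemble analysis for azobenzene photoswitches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory-ensemble analysis for azobenzene photoswitches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(azotraj)
```

## The problem azotraj addresses

Nonadiabatic surface-hopping simulations of azobenzene-based photoswitches
(here: azo-escitalopram, an azobenzene-functionalized serotonin-reuptake
inhibitor) produce ensembles of classical trajectories, each carrying
per-frame nuclear geometries, adiabatic state energies and the label of the
active electronic surface. The observables of interest are statistical
properties of the ensemble, not of any one trajectory:

* **excited-state populations** — the fraction of trajectories on each
  surface at each time — and the lifetimes obtained by fitting kinetic
  models to them;
* the **photoisomerization quantum yield** and the split of the cis product
  into its two conformers;
* the **mechanism** (rotation about the N=N bond vs in-plane inversion of
  an NNC angle) inferred from the geometry at each S1 &rarr; S0 hop;
* **hydrogen-bond dynamics** between the solute heteroatoms and explicit
  water;
* the **ensemble absorption spectrum** and the excitation windows used to
  select initial conditions.

azotraj implements this analysis chain as reusable, tested functions, and
pairs it with a synthetic ensemble generator so every stage can be
validated without access to the original quantum-chemistry trajectories.

## Data model and internal coordinates

A trajectory is a time-ordered frame sequence with uniform step: coordinates
(Angstrom), state energies `E_S0..E_Sn` (eV), the 0-based active-state
index, and total energy, read and written as extended XYZ plus a TSV energy
table (`time_fs  E_S0 ... E_Sn  E_total  active_state`). Units are fixed at
Angstrom / eV / fs throughout; state indices are 0-based internally and
rendered as S0/S1/S2 in reports, which keeps hop detection free of
off-by-one errors.

Five named internal coordinates drive every classification (indices are
explicit inputs via `atom_selection()`, never guessed from element
patterns):

| symbol | atoms | role |
|---|---|---|
| theta | C-N=N-C dihedral | cis (< 30&deg;) vs trans (> 150&deg;) |
| alpha | C-C-N-C dihedral | cis conformer I (< 45&deg;) vs II (> 135&deg;) |
| omega | C-C-C-C dihedral | rotation (55-125&deg;) vs inversion (145-180&deg;) at the hop |
| gamma, gamma&prime; | C-N-N / N-N-C angles | inversion-pathway descriptors |

Classification always uses the folded dihedral magnitude in [0, 180]
degrees; the signed value (IUPAC convention) is retained because any fixed
sign convention works when only magnitudes are thresholded.
`build_fragment()` inverts the measurement: a Z-matrix-style (NeRF)
placement of a reduced 12-atom fragment — two ring anchors, the C-N=N-C
core, substituent markers carrying alpha and omega, and ether-O/F acceptor
markers — whose bond lengths are typical azobenzene values (C-N 1.42, N=N
1.25, C-C 1.40 Angstrom). Only geometric self-consistency matters: the
round trip `internal_coords(build_fragment(x)) == x` holds to 1e-6 degrees
and is the basis of the geometry test suite. Bond angles requested at
exactly 0 or 180 degrees (where the dependent dihedral is undefined) are
perturbed by 1e-4 degrees rather than rejected.

## The synthetic ensemble generator

The generator defines the study conditions; it is not a tuning knob. Its
generative law for hop times is exactly the kinetics the fits assume:

* **S1 start**: ground-state arrival at `t0 + Exp(tau1)` — the delayed
  exponential. Defaults mirror the study conditions (`t0` = 250 fs;
  `tau1` = 1939 fs gas / 2795 fs water for the n&rarr;pi* windows).
* **S2 start**: S2 &rarr; S1 after `Exp(tau2)`, then S1 &rarr; S0 after an
  additional `Exp(tau1)` (sequential two-step kinetics; `tau2` = 146 fs gas
  / 26 fs water, `tau1` = 1274 / 2292 fs).

Around that skeleton each trajectory realizes: Ornstein-Uhlenbeck thermal
noise on the CNNC dihedral about the trans minimum (relaxation rate 0.02
fs^-1, the Langevin-thermostat friction of the study conditions; stationary
sd 4 degrees), a descent into a hop geometry drawn uniformly from the
90-120 degree CNNC band, a CCCC dihedral at the hop drawn in [55, 125]
(rotational) or [145, 180] degrees (inversion), and post-hop torsional
relaxation (constant 150 fs) to a cis (&lt; 30&deg;) or trans (&gt;
150&deg;) product per the reactive probability. Cartesian frames are
emitted through `build_fragment()`, so every downstream stage measures real
coordinates.

**Outcome probabilities.** Reactivity equals the configured quantum yield.
The pathway is rotational with probability `p_rotational` (1.00 / 0.69 /
0.07 / 0.11 across the four presets). Conformer preference is expressed
conditionally on the pathway, reproducing the observed correlation
(rotation favors conformer I, inversion favors II) while matching the
marginal conformer-I fraction `phi_I = p_rot p(I|rot) + (1 - p_rot)
p(I|inv)` exactly; e.g. for the water pi&rarr;pi* preset, `p(I|inv)` = 0.35
was fixed and `p(I|rot)` = 0.8045 solves the constraint for `phi_I` = 0.40.

**Energies.** Per-state energies come from an analytic torsional model:
`E_S0 = 1.6 sin^2(theta)` eV, `E_S1 = E_S0 + gap(theta)` with
`gap = 0.10 + 1.3 ((theta - 105)/105)^2` eV, and an S2 shelf
`E_S2 = E_S1 + 0.8 + 0.4 cos^2(theta)`. The gap is parameterized directly
so that it stays below 0.3 eV across the whole 90-120 degree hop band
(a `sin^2`-type S1 cannot do this while remaining everywhere above S0);
the recorded gap at the hop itself is drawn from a folded normal
(sigma = 0.1 eV) so hop-geometry scatter has realistic spread. Only state
ordering and the in-band gap are ever asserted — absolute energetics are
out of scope. Total energy is constant to 1e-4 eV; `inject_energy_drift()`
adds a linear ramp to create quality-control test cases.

**Solvent.** Scheduled hydrogen-bond occupancies (per acceptor, linearly
interpolated over time) are realized as Bernoulli draws; bonded waters are
placed at 2.0 Angstrom / 165 degrees — a 0.2 Angstrom / 10 degree margin
inside the detection criteria, so counts never sit on a threshold — and
spectator waters are placed beyond 3.5 Angstrom of every acceptor. Setting
the placement distance or angle outside the criteria generates deliberate
violations for negative tests.

**Seeding.** Every parallel stream (ensemble &rarr; trajectory &rarr;
frame) gets its seed from `derive_seeds()`, a splitmix-style hash of
(master, index). A hash rather than a shared LCG orbit matters: nested
derivations from one orbit can hand two replicate ensembles almost the same
per-trajectory streams, silently destroying seed averaging.

**What the generator does not emulate.** No electronic structure, no forces
or momenta, no decoherence, no recrossing after the product is reached, no
solvent dynamics (shells are drawn independently per frame, so hydrogen-bond
lifetimes are not meaningful), and no correlation between hop time and
outcome (the study discusses such correlations; here they are independent
draws). Passing tests therefore validate the *analysis* chain — counting,
classification, fitting, detection — under known ground truth, not the
physics of any particular photoswitch.

## Quality control and bookkeeping

Trajectories whose total energy deviates from its **initial value** by more
than 0.5 eV (strictly) at any frame are excluded and only flagged, so
bookkeeping tables can report both the number run and the number analyzed.
The initial-value reference was chosen over the max-min spread because the
latter double-counts symmetric fluctuation. Trajectories that reach the
ground state and stay there **uninterrupted** for at least 500 fs are
truncated at first-arrival + 500 fs (the report states this convention);
any return to an excited state resets the dwell. Truncation is idempotent
and exclusion counts are monotone in the threshold — both properties are
tested.

## Population kinetics

Populations are trajectory fractions on the native frame grid;
early-terminated members count as ground state afterwards. Two fits are
provided, matching the two starting conditions:

* `P(t) = 1` for `t <= t0`, `exp(-(t - t0)/tau1)` after — fitted by least
  squares with `t0` initialized on a 0-500 fs grid in 10 fs steps and
  `tau` from a log-linear tail regression, refined by Nelder-Mead
  (deterministic). Because "the lifetime" of a delayed exponential is
  ambiguous, the fit reports `t0`, `tau1` and `t0 + tau1` separately.
* the irreversible two-step solution `P_bright = exp(-t/tau2)`,
  `P_S1 = tau1/(tau1 - tau2) (exp(-t/tau1) - exp(-t/tau2))` — fitted in
  two stages exactly as the study procedure prescribes: `tau2` first on the
  pooled population of S2 and above, then `tau1` with `tau2` fixed. The
  degenerate `tau1 = tau2` limit uses `(t/tau) exp(-t/tau)`. A joint
  2-parameter fit is available as a cross-check and agrees with the
  two-stage fit to 0.5% on noiseless curves.

`population_from_hop_times()` converts sampled hop times into survival
curves directly, which makes large recovery studies cheap: at the study
ensemble sizes (112 and 207 trajectories) the fits recover their generating
constants within 15% (tau1) and 20% (tau2) as means over 20 seeds.

## Yields, conformers, mechanisms

Eligible trajectories are those whose final active state is the ground
state, at the end of the run or after early termination. The quantum yield
is `Phi = n_cis / (n_cis + n_trans)` with cis meaning theta &lt; 30&deg;
and trans theta &gt; 150&deg; on the last retained frame. Ground-state
finals with intermediate theta are **counted and reported but excluded from
both numerator and denominator**: the thresholds classify only the two
basins, and surfacing the intermediate count keeps the alternative
(all-ground-state) denominator recomputable. The binomial uncertainty uses
`n = n_cis + n_trans`, the denominator of the ratio it describes.
Conformer fractions are taken over all cis trajectories, so
`phi_I + phi_II + (unassigned fraction) = 1`.

Hops are frame pairs where the active state steps from 1 to 0; geometry and
the S1-S0 gap are read from the first frame on the new surface (the
accepted hopping geometry — the pre-hop frame is retained in the record,
one time step away). Each reactive trajectory is classified by the CCCC
dihedral of its **last** S1 &rarr; S0 hop; records in the 125-145 degree
gap between the bands are reported as unassigned and excluded from the
ratio denominator, with their count surfaced.

## Hydrogen bonds

A water hydrogen donates a bond to a solute heteroatom X when the X...H
distance is at most 3.0 Angstrom (inclusive) and the donor angle
O_w-H&middot;&middot;&middot;X — vertex at the hydrogen, the standard
geometric criterion and the only angle definition under which a 120 degree
cutoff is conventional — strictly exceeds 120 degrees. Each hydrogen forms
at most one bond, assigned to the nearest qualifying acceptor (ties broken
by distance, then water id, for determinism); this prevents double counting
between the two azo nitrogens, which sit 1.25 Angstrom apart. The ensemble
series reports per-acceptor means and a total from which fluorine is
excluded, its occupancy being too volatile to average meaningfully.

## Spectra and excitation windows

The ensemble spectrum is the oscillator-strength-weighted sum of normalized
Gaussians (default sigma = 0.1 eV, grid 0.01 eV; the broadening scheme is a
package choice — all checks are shift- and round-trip-based, insensitive to
the kernel within reason). Per-state intensities integrate to the mean
oscillator strength of the state, which the tests verify to 0.5%. Band
maxima are global per-state maxima; local maxima above 20% of the peak are
reported as shoulders (the threshold makes a weak shoulder band detectable
on synthetic ensembles and is configurable), and boundary peaks are flagged
unreliable. Initial-condition selection inside an excitation window accepts
each in-window excitation with probability `f / f_max(window)` — the usual
dipole-weighted rejection sampler; selection counts are linear in `f`.

## Problem sizes and numerical choices

The package's default study scale keeps a full four-preset analysis within
minutes on one core: generator time steps of 10 fs (gas, 6 ps horizon) and
5 fs (water, 3 ps), i.e. about 600 frames per trajectory. Because hop times
are drawn continuously and mapped to the first grid frame at or after the
drawn time, grid survival curves are unbiased at any step size, so the
coarse grids cost resolution only, not accuracy. The hydrogen-bond series
is computed on a strided frame grid (default every 10th frame); shells are
redrawn independently per frame. Spectrum presets use 857 sampled
geometries. Tests that need tighter determinism (peak round trips) sample
20000 geometries so Monte-Carlo jitter stays below half a grid spacing.

Other numerical conventions, collected: strict QC threshold (a deviation of
exactly 0.5 eV is kept); inclusive hydrogen-bond distance; strict
hydrogen-bond angle; strict cis/trans/conformer thresholds (boundary values
fall in the unclassified categories); degenerate-angle perturbation of
1e-4 degrees in fragment construction; dihedral measurement errors against
an independent rotation-matrix oracle below 1e-9 degrees.

## Known limitations

* The generator's kinetics are exactly the fitted laws, so fit-recovery
  tests probe estimator quality, not model adequacy for real dynamics.
* Hop-time/outcome independence means correlations between decay speed and
  reactivity — present in real ensembles — are not emulated.
* The reduced 12-atom fragment carries only the five named coordinates;
  analyses needing other internal coordinates require a different template.
* Hydrogen-bond shells have no temporal persistence; only mean occupancies
  are meaningful.
* The delayed-exponential fit's `t0` and `tau1` trade off on short, heavily
  censored windows (e.g. 3 ps at `tau1` &approx; 2.8 ps); lifetime
  estimates there are best read as seed averages, which is how the
  acceptance script reports them.
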