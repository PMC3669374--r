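---
title: "Thermal response of a coarse-grained lattice protein"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal response of a coarse-grained lattice protein}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`latticefold` simulates a single protein chain on a cubic lattice in the
bond-fluctuation representation. Each of the N residues is a node anchored at
a lattice site; consecutive residues are tethered by bonds whose length
fluctuates between 2 and $\sqrt{10}$ lattice constants, i.e. bond vectors are
drawn from the 120 integer vectors with squared length in
$\{4,5,6,8,9,10\}$ (108 when the $\sqrt 8$ class is excluded, the classical
variant that prevents chain crossing). Compared with fixed-bond lattice
chains this gives each residue and each peptide bond many more degrees of
freedom while keeping all geometry integer-valued and fast to verify.

Non-adjacent residues $i,j$ closer than the cutoff $r_c = \sqrt 8$ interact
through a truncated generalized Lennard-Jones potential

$$U(r_{ij}) \;=\; |\epsilon_{ij}|\left(\frac{\sigma}{r_{ij}}\right)^{12}
 + \epsilon_{ij}\left(\frac{\sigma}{r_{ij}}\right)^{6},
 \qquad r_{ij} < r_c,\; \sigma = 1,$$

and zero at and beyond $r_c$ (truncated, not shifted — Metropolis dynamics
only ever uses energy differences, so a constant shift would be
inconsequential). The pair strength $\epsilon_{ij}$ comes from a 20×20
knowledge-based contact matrix: negative entries are attractive, positive
repulsive, and the $r^{-12}$ core keeps a hard repulsion at short distance
for either sign. For attractive pairs the minimum sits at $2^{1/6}\sigma$
with depth $|\epsilon_{ij}|/4$. Covalently bonded neighbours are excluded
from the contact sum. Within the cutoff a residue sees up to 92 lattice
sites — "order of hundred" interacting sites.

Dynamics are Metropolis Monte Carlo: a residue is picked uniformly at random,
a unit displacement is proposed (6 axial directions by default, the 26-cell
neighbourhood optionally), the move is rejected outright if it violates
excluded volume or takes an adjacent bond out of the allowed set, and
otherwise accepted with probability $\min(1, e^{-\Delta E/T})$, with $T$ the
reduced temperature. N attempted moves form one Monte Carlo step (MCS). The
engine keeps the running total energy incrementally from local shell sums;
the R-level `total_energy()` is an independent $O(N^2)$ implementation used
to verify the bookkeeping to $10^{-9}$ relative.

## Excluded volume: why the cube variant is the default

The chain description ("nodes" on a lattice) admits two readings of excluded
volume, and we implement both:

* `"cube"` (default): a residue occupies the 8 sites of the unit cube
  anchored at its coordinate — the classical bond-fluctuation rule.
* `"site"`: only the anchor site is excluded.

The default was chosen by measurement, not taste. With single-site exclusion
and bonds of length 2–$\sqrt{10}$, the excluded volume is so weak relative
to the bond length that short chains are nearly ideal: athermal chains of
N = 16–64 give an effective size exponent $\gamma \approx 0.51$
($R_g \propto N^\gamma$), far below self-avoiding-walk universality, and the
crossover to $\gamma \approx 0.588$ is pushed to chain lengths irrelevant
here. The cube rule restores self-avoiding statistics at short N (we measure
$\gamma = 0.625 \pm 0.010$ for N = 16–64), which is the regime the
scaling analysis $S(q) \propto q^{-1/\nu}$, $N \propto R_g^{D_e}$ assumes.
Single-site exclusion remains available via `excluded_volume = "site"`.

Under the cube rule the closest approach of two residues is 2, so contacts
live at squared distances 4, 5 and 6 (8 sits exactly at the cutoff and
contributes zero): the strongest contact energy is
$U(2) = -0.0154\,|\epsilon|$ for an attractive pair.

## Observables and analysis

* **Radius of gyration** — root-mean-square distance of residues from the
  chain centroid, always computed on unwrapped coordinates (the engine
  unwraps the chain across the periodic boundary at initialization and
  tracks real displacements thereafter).
* **Contact maps** — non-adjacent pairs within $r_c$, per snapshot, plus an
  ensemble contact-frequency map; the same cutoff as the energy, so every
  mapped contact carries energy unless its $\epsilon_{ij} = 0$.
* **Structure factor** —
  $S(q) = N^{-1}\langle|\sum_j e^{i\,\mathbf q\cdot\mathbf r_j}|^2\rangle$,
  spherically averaged over seeded random unit directions (50 per magnitude
  by default; a fixed direction set can be supplied for lattice-exact or
  analytic work). $S(q\to 0) = N$; over wavelengths comparable to the chain
  size $S(q) \propto q^{-D_e}$.
* **Effective dimension** — least-squares slope of $\log S$ vs $\log q$ over
  a window of 0.5 decades centred on $q^* = 2\pi/R_g$; $D_e \approx 1$ for a
  rod, $\approx 2$ for an ideal coil, $\approx 3$ for a compact globule, and
  $1/\nu \approx 1.7$ for a swollen self-avoiding coil.
* **Thermal sweep** — per temperature, an ensemble of independent seeded
  runs; the per-sample post-burn-in time average of $R_g$ is aggregated into
  mean ± SEM. `locate_Tc()` finds the interior maximum, refined by a local
  quadratic through the peak and its two neighbours (ties break toward lower
  T). `response_window()` operationalizes the non-monotonic range
  $\Delta T$ as 25%-of-rise threshold crossings (linearly interpolated)
  against baselines formed by the two lowest- and two highest-temperature
  grid points; the threshold is a parameter so sensitivity can be reported.
  `compare_potentials()` ranks potentials by $T_c$ with half-grid-spacing
  uncertainties.

## Reproducibility and numerical choices

Every run is driven by one integer seed; ensemble members get seeds derived
from the master seed by a fixed affine map modulo a prime, so ensembles are
reproducible as a set and independent of execution order. Boundary
conditions default to periodic with minimum-image distances (the chain,
$R_g \ll L = 64$, rarely feels the boundary); a closed box is available and
is used for exact enumeration. Degenerate inputs are errors, not silent
results: monotone sweep tables ("no interior peak"), fewer than 4 points in
a fit window, state spaces too large to enumerate, invalid conformations.

## What the synthetic generators emulate — and what they do not

The study protein (histone H2AX, 143 residues) and the published MJ, BT and
BFKV contact tables are inputs the package reads but does not distribute.
So that every stage is testable offline, the `synthetic_*` generators
produce: uniform (homopolymer), HP-like, block and null matrices; a
mixed-sign "knowledge-based-like" matrix
$\epsilon_{ij} = -s\,(h_i + h_j)$ built from the Kyte–Doolittle hydropathy
scale (hydrophobic pairs attract, polar/charged pairs repel), with
$s = 1/3$ so entries reach $\approx |3|$ — magnitudes comparable to
published tables — and the strongest contact is about $4T$ at the cold edge
and $1T$ at the hot edge of the default temperature grid 0.010–0.040; and a
SYNTHETIC histone-like sequence drawn i.i.d. from an approximate H2A-family
composition ($K{+}R \approx 22\%$, hydrophobic core fraction
$\approx 30\%$). Files shipped under `inst/extdata/` are labelled
`synthetic_*`.

These stand-ins validate the machinery — Boltzmann sampling against exact
enumeration, homopolymer theta-collapse, self-avoiding scaling, structure
factors — but they do not reproduce the sequence-specific thermal response
of H2AX. An i.i.d. composition-matched sequence carries a
composition-averaged interaction whose net repulsion per contact is only
0.1–0.25 T across the grid: far too weak to swell the chain beyond its
athermal size, which is exactly the overshoot that makes the real protein's
$R_g(T)$ peak at a characteristic temperature. The original observation is
itself sequence-specific — a same-family, same-size histone shows a plain
monotonic globule-to-coil transition — so passing or failing the peak test
with a synthetic stand-in says nothing about real H2AX. Reproducing the
$T_c$ ordering across MJ/BT/BFKV requires the published tables (place them
under `inst/extdata/potentials/` as `MJ.csv`, `BT.csv`, `BFKV.csv` with an
`h2ax.fasta` to activate that check).

## Desk-scale study conditions

The full study conditions (a $64^3$ lattice, $10^7$ MCS, 150 independent
samples per temperature) are the package defaults in
`default_run_config()`. Tests and the acceptance script use fixed desk-scale
profiles chosen once: $10^5$ MCS with 8 samples for 143-residue sweeps on
the grid 0.010–0.040 (step 0.0025); $10^5$ MCS with 32 samples for the
athermal scaling study; $2\times10^4$ MCS with 8 samples for the 32-mer
homopolymer contrast on the log-spaced grid 0.008–0.128 (the coldest point
placed where a desk-scale run still equilibrates); $10^6$ sweeps, thinned
every 20 after 10% burn-in, for the 3-mer enumeration check (thinning keeps
the chi-square independence assumption honest). Burn-in is the first 50% of
sweeps unless stated; records are flagged rather than discarded.

## Known limitations

* Single chain only; no solvent, no multi-chain systems, no cluster or
  reptation moves, no replica exchange. MCS is not calibrated physical time.
* At reduced temperatures where the strongest contacts exceed roughly
  5–8 T, desk-scale runs show kinetic trapping (glassy landscapes); the
  full $10^7$-MCS conditions relax much further.
* The effective-dimension fit inherits a small bias from curvature of
  $S(q)$ across the fit window (a 343-site ball reads
  $D_e \approx 2.8$, not 3.0, with the default 0.5-decade window).
* Quantitative values from the synthetic stand-ins (e.g. their $T_c$) are
  properties of those fixtures, not of H2AX.

## A minimal session

```{r, eval = FALSE}
library(latticefold)

seqn <- histone_like_sequence(143, seed = 5)   # synthetic stand-in
mat  <- synthetic_matrix("hydropathy")

sweep <- temperature_sweep(seqn, mat,
                           temperatures = seq(0.010, 0.040, by = 0.0025),
                           config = mc_config(n_mcs = 1e5, record_every = 2000),
                           n_samples = 8, master_seed = 99)
response_window(sweep)

traj <- simulate_chain(seqn, mat,
                       mc_config(temperature = 0.032, n_mcs = 1e5, seed = 1),
                       record_frames = TRUE)
sq <- structure_factor(traj$frames[!traj$records$burn_in],
                       q_magnitudes = exp(seq(log(0.1), log(2), length.out = 30)))
fit_effective_dimension(sq, rg = mean(traj$records$rg))
```
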