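---
title: "Boost potentials, reweighting and toy landscapes: the methods behind gamdr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boost potentials, reweighting and toy landscapes: the methods behind gamdr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gamdr)
```

## The model

Gaussian accelerated molecular dynamics modifies the potential below a
reference energy $E$:

$$V^*(r) = V(r) + \Delta V(r), \qquad
\Delta V(r) = \begin{cases}
\tfrac12 k\,(E - V(r))^2 & V(r) < E\\
0 & V(r) \ge E.
\end{cases}$$

Three principles fix the two parameters. Order preservation
($V_1 < V_2 \Rightarrow V_1^* < V_2^*$) and difference shrinking
($V_2^* - V_1^* < V_2 - V_1$) together bound the reference energy,
$V_{\max} \le E \le V_{\min} + 1/k$, which with
$k = k_0/(V_{\max}-V_{\min})$ restricts $k_0$ to $(0,1]$. The third
principle demands a narrow, near-Gaussian boost distribution:
$\sigma_{\Delta V} = k (E - V_{\mathrm{avg}})\,\sigma_V \le \sigma_0$,
with $\sigma_0$ a user limit that controls reweighting accuracy. At the
lower bound $E = V_{\max}$,
$k_0 = \min\!\big(1, \tfrac{\sigma_0}{\sigma_V}\cdot
\tfrac{V_{\max}-V_{\min}}{V_{\max}-V_{\mathrm{avg}}}\big)$; at the upper
bound $E = V_{\min} + 1/k$,
$k_0'' = \big(1-\tfrac{\sigma_0}{\sigma_V}\big)
\tfrac{V_{\max}-V_{\min}}{V_{\mathrm{avg}}-V_{\min}}$ is used when it
falls in $(0,1]$ and the lower-bound expression otherwise
(`compute_k0()` implements exactly this fallback; the effective bound is
returned as an attribute).

**Boosted forces.** The boost modifies forces through the chain rule:
$\nabla V^* = \big(1 - k\,(E - V)\big)\,\nabla V$ for $V < E$. Because
$k \le 1/(V_{\max}-V_{\min})$ and $E \le V_{\min} + 1/k$, the scale
factor stays in $[0, 1]$: forces are damped, never inverted — this is
precisely the smoothing property, and it is asserted by the
order-preservation tests.

**Dual boost.** For systems with a separable torsional term, one boost is
applied to the torsional energy and a second to the total potential
term. The torsional boost is evaluated first; the total-term boost acts
on the total potential including the torsional boost
($u = V + \Delta V_D$, then $\Delta V_P$ from $u$), following the
original convention for this scheme; the recorded, reweighting-relevant
boost is the sum. Whether the total-term statistics should include the
torsional boost is genuinely ambiguous in the method's descriptions; we
collect total-term statistics on $u$ so that the statistics describe the
energy the boost actually acts on.

## Units

kcal/mol, Angstrom, ps, K and amu throughout;
$k_B = 0.0019872041$ kcal/mol/K, and 1 kcal/mol = 418.4 amu A$^2$/ps$^2$
converts forces to accelerations.

## The staged protocol

`run_protocol()` mirrors the staging used in production GaMD studies at
toy scale: energy minimisation (backtracking gradient descent),
thermalisation, a conventional-MD window that collects potential
statistics, a boosted equilibration during which the parameters are
refreshed every statistics interval, and production with frozen
parameters. Two windowing rules matter:

* running $V_{\max}$ / $V_{\min}$ are monotone accumulators that are
  never reset once collection starts (including through the boosted
  equilibration), matching standard practice;
* $V_{\mathrm{avg}}$ and $\sigma_V$ are recomputed over the most recent
  statistics window (default 1000 steps), mirroring periodic
  recalculation of the average and SD during simulation.

Freezing the parameters for production is our choice (the staging
otherwise leaves it open); it makes every production frame carry a boost
drawn from one fixed $(E, k)$, which is what the per-bin reweighting
assumes.

**Stage sizing.** On a one-dimensional well the potential-energy
fluctuation range grows only logarithmically with sampling time, so the
running $V_{\max}$ — and with it the reference energy — climbs toward
the barrier top only during an extended *boosted* equilibration: each
refresh flattens the well bottom further, widening the energy
fluctuations that feed the next refresh. The defaults
(`cmd_collect = 1e5`, `gamd_equilibrate = 1e6`,
`gamd_produce = 5e5` steps at `dt = 0.001` ps) are sized by this
argument together with a Kramers estimate of crossing rates: at 300 K a
6 kcal/mol barrier is crossed by conventional MD about once per few
nanoseconds, while the boosted surface (reference energy near the
barrier top) is crossed every few tens of picoseconds. Friction
(1 ps$^{-1}$) and bead mass (12 amu) are ordinary coarse-bead values.

## Synthetic systems: what they emulate and what they do not

`make_double_well()` (quartic, exact barrier/separation/asymmetry by
construction, verified at analytically polished stationary points),
`make_wells_2d()` (sums of Gaussian wells) and `make_bead_chain()`
(harmonic bonds and angles, 3-fold cosine torsions with the barrier as
the only free scale, soft repulsion for beads more than three bonds
apart) stand in for all-atom receptor/G-protein complexes in a membrane.
They reproduce the *structure* of the problem — multiple metastable
states behind kcal-scale barriers, a separable dihedral term for dual
boost, planted conformational heterogeneity for clustering — but not its
dimensionality: in a toy system the potential-energy fluctuation
$\sigma_V$ (well below 1 kcal/mol) is tiny compared with a solvated
membrane system (tens of kcal/mol), so $k_0$ saturates at 1 here whereas
real systems operate at intermediate $k_0$. Passing tests therefore
validate the machinery (parameter arithmetic, force consistency,
reweighting identities, estimator behaviour), not force-field realism.

`plant_conformations()` draws frames from fixed templates plus isotropic
Gaussian noise with known state labels; it emulates a clustered
conformational ensemble with exact ground truth but has no dynamics and
no correlation between frames.

`reference_pmf()` integrates $e^{-V/k_BT}$ per bin (composite Simpson in
1D, midpoint tensor rule in 2D) — ground truth by quadrature, never by
simulation; sub-0.01 kcal/mol quadrature error at the default
subdivision is asserted against a dense Riemann-sum oracle.

## Reweighting choices

* Per-bin second-order cumulant:
  $F = F^* - (\langle\Delta V\rangle + \tfrac{\beta}{2}\sigma^2_{\Delta V})$
  with population variance. For 1D collective variables that are smooth
  functions of the coordinate the per-bin boost is nearly deterministic,
  so the correction is close to exact; the test suite compares it
  against brute-force exponential averaging wherever the per-bin
  anharmonicity is low.
* Anharmonicity diagnostic: KL divergence of the bin's $\Delta V$
  histogram from a moment-matched Gaussian, with 0.1 as the threshold
  below which the cumulant and exact estimators are expected to agree
  within 0.1 kcal/mol.
* Bins are half-open with the last bin closed; defaults are 50 bins per
  dimension. Bins with fewer than `min_samples = 10` frames are masked
  (reported missing, not infinite) and excluded from the min-shift.
* `locate_minima()` filters local minima by topographic prominence
  (union-find watershed): a minimum is kept when the lowest ridge to a
  deeper minimum is at least `depth_threshold` above it. This gives a
  principled meaning to "well depth" on noisy grids; ties are processed
  in free-energy order, making the result deterministic.

## Trajectory analyses

RMSD, RMSF and clustering all superpose with our Kabsch implementation
(SVD with determinant correction, reflections excluded; degenerate
collinear sets are rejected). Clustering is average-linkage hierarchical
agglomeration on the pairwise superposed-RMSD matrix, cut at the RMSD
cutoff (2.0 A default, the value used for agonist-pocket clustering in
receptor studies); average linkage is the default of the reference
trajectory-analysis tool, which names the algorithm but not the linkage.
Medoids (minimum mean within-cluster RMSD) represent clusters; clusters
are numbered by decreasing size. "Within r of group" selections are
resolved once on a stated reference frame and then fixed — re-resolving
per frame would make the measured atom set time-dependent. Group-pair
separations (for example a receptor motif against the C-terminal
residues of a partner) are reduced to centroid-to-centroid distances.

## Structure comparison

Parsing goes through bio3d (PDB and mmCIF), with alternate locations
reduced to the highest-occupancy conformer (ties toward altloc "A") and
the first model only. Residue pairing for matched-C$\alpha$ RMSD is by
author chain/residue number/insertion code within a user chain map;
unmatched residues are dropped with a message, because printed pair
counts in the literature rarely state their pairing rule and silent
divergence would be invisible. Salt bridges measure the minimum distance
over charged-group atoms (carboxylate O against guanidinium/amine N),
with a charge-centre convention (CG for Asp, CZ for Arg) available where
a study quotes centre distances; 4.0 A is the default cutoff between
charge centres. Domain motion superposes on an anchor domain and
extracts the moving domain's rotation as the trace angle
$\theta = \arccos\big((\mathrm{tr}\,R - 1)/2\big)$ of its Kabsch
rotation, with the mass-centre displacement computed after anchor
alignment — the selections used determine the number, so both selections
and pair counts are reported.

## Numerical and degenerate-input policy

BAOAB integration (exact Ornstein–Uhlenbeck step for the friction part;
at zero friction it reduces to velocity Verlet and conserves energy to
the symplectic limit), reflecting walls at the domain boundary, R's RNG
end-to-end so that a seed reproduces a run bit-for-bit. The compiled
kernel (1D polynomial potentials) and the R integrator share this
contract. Flat statistics ($V_{\max}=V_{\min}$ or $\sigma_V=0$) are
errors, not silent defaults; minimisation rejects divergent energies;
`pmf()` errors when every bin is masked.

## Known limitations

Single-particle analytic systems cannot exhibit the statistics-size
effects of solvated systems (see above); the bead-chain integrator is
pure R and intended for short runs; NPT ensembles, constraints and
long-range electrostatics are out of scope; clustering computes the full
pairwise RMSD matrix ($O(n^2)$ superpositions), appropriate for a few
thousand frames; mmCIF parsing inherits the beta status of the upstream
reader; accession-dependent structural comparisons require the user to
supply the deposited coordinate files, which are not redistributable.
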