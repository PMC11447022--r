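# gamdr

Gaussian accelerated molecular dynamics (GaMD) on desk-scale energy
landscapes, in R.

GaMD is an enhanced-sampling method for molecular simulation: when the
system potential `V(r)` falls below a reference energy `E`, a harmonic boost

    dV(r) = 1/2 k (E - V(r))^2,   V(r) < E     (else dV = 0)

is added, smoothing barriers without predefined collective variables. The
two parameters are determined automatically from potential statistics
collected during a short conventional-MD window: with
`k = k0 / (V_max - V_min)` and the reference energy at its lower bound
`E = V_max`,

    k0 = min(1, (sigma0 / sigma_V) * (V_max - V_min) / (V_max - V_avg)),

while the upper bound `E = V_min + 1/k` uses
`k0'' = (1 - sigma0/sigma_V) * (V_max - V_min) / (V_avg - V_min)` when that
value lies in (0, 1] and falls back to the lower-bound expression
otherwise. The user constant `sigma0` (default 6.0 kcal/mol) caps the
standard deviation of the boost so that the unbiased free-energy landscape
can be recovered by a per-bin cumulant expansion to the second order:

    F(bin) = -kB T log p*(bin) - ( <dV> + beta/2 Var(dV) ),  beta = 1/(kB T)

`gamdr` implements this machinery — boost law, automatic parameter
determination, dual-boost scheme (separate boosts on the torsional and
total energy terms), staged Langevin (BAOAB) protocol, and cumulant
reweighting — on analytic 1D/2D potentials and small bead-chain models
whose exact free-energy landscapes are known by direct Boltzmann
integration, so every stage of the pipeline can be verified quantitatively.
It also ships the accompanying trajectory analyses (named-pair distance
time courses, RMSD/RMSF, hierarchical agglomerative clustering at an RMSD
cutoff, 1D/2D free-energy profiles) and static structure-comparison metrics
used for receptor activation studies (Kabsch superposition, matched
C-alpha RMSD, atom displacement between states, salt-bridge/ionic-lock
detection, domain rotation and mass-centre displacement, interface
contacts) on standard PDB/mmCIF files.

Who is it for: anyone teaching, prototyping or validating GaMD-style
enhanced sampling and reweighting, and anyone needing scriptable,
tidyverse-friendly structural metrics without a full MD stack.

## Worked example

Double well with a 6 kcal/mol barrier, minima 4 A apart, simulated with
the staged protocol (conventional-MD statistics collection, boosted
equilibration with parameter refreshes, production with frozen
parameters) at 300 K:

```r
library(gamdr)

dw   <- make_double_well(barrier = 6, separation = 4)
traj <- run_protocol(dw, protocol(), gamd_controller(sigma0_total = 6),
                     seed = 1)

tidy(traj$metadata$boost_params$total)
#>   term      E     k    k0 sigma0 bound_mode V_max    V_min
#> 1 total  7.45 0.134     1      6 lower       7.45 3.28e-12

glance(traj)
#>   n_frames n_particles period_ps V_mean dV_mean sigma_dV
#> 1    50000           1      0.01   1.21    2.72    0.936
```

The frozen reference energy `E = 7.45` kcal/mol sits just above the
barrier top (the running `V_max` ratchets upward during the boosted
equilibration), `k0` saturates at 1, and the realised boost spread
`sigma_dV = 0.94` kcal/mol is far below the `sigma0 = 6` accuracy limit —
the regime in which second-order cumulant reweighting is accurate.
Reweighting the production trajectory and comparing with the exact
landscape from direct Boltzmann integration:

```r
edges   <- list(seq(-6, 6, length.out = 51))
ref     <- reference_pmf(dw, grid = edges)
profile <- pmf(traj_x(traj), traj$boost$dV_sum, bins = edges)

pmf_rmse(profile, ref)
#> 0.145  (kcal/mol, over bins with >= 10 samples)

locate_minima(profile, depth_threshold = 1)
#>     bin     x free_energy prominence
#> 1    17 -2.04       0         Inf
#> 2    34  2.04       0.247       5.89
```

Both planted wells are recovered at their true positions (+-2 A) with a
near-6 kcal/mol separating ridge; a conventional-MD run of the same length
stays trapped in one well. `autoplot(profile)` draws the profile,
`autoplot(traj)` the time courses.

Structure comparison works on standard coordinate files:

```r
active   <- parse_structure("complex_state.pdb")
inactive <- parse_structure("apo_state.cif")
matched_ca_rmsd(active, inactive)          # paired C-alpha RMSD + n_pairs
salt_bridge(active, acidic = list(chain = "A", resno = 145),
            basic = list(chain = "A", resno = 146))
domain_motion(active, inactive, anchor = list(chain = "A"),
              moving = list(chain = "B"))  # rotation angle + COM shift
```

A thin command-line front end (`inst/cli/gamdr`) exposes the pipeline as
`simulate | reweight | analyze | compare` subcommands over YAML
configurations.

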