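# mgatekit

Trajectory and structure analyses for the **matrix gate (m-gate)** of
mitochondrial carrier proteins — the salt-bridge / hydrogen-bond network
that seals the matrix side of the cytosol-open carrier — plus a synthetic
trajectory generator with exact ground truth for validating every analysis
end to end.

The package is aimed at structural bioinformaticians analysing molecular
dynamics trajectories of three-domain carriers (the ADP/ATP carrier and its
SLC25 relatives): given a reference structure, a multi-model PDB trajectory
and a declarative configuration (helix residue ranges, interaction pairs,
cutoffs, frame window), it computes

* **interaction occupancies** — per-frame detection of salt bridges
  (minimum side-chain N–O distance ≤ 4.0 Å by default), hydrogen bonds
  (D–A ≤ 3.5 Å, H–D–A ≤ 30° when hydrogens exist), arginine guanidinium
  stacking, and ligand contacts; percent occupancy over an analysis window;
  intra-helical / inter-helical / other classification against the helix
  map; per-domain-pair **attachment scores**;
* **C3 symmetry deviation ψ** — for each residue *triplet* (equivalent
  positions of the three homologous domains, e.g. 33/138/235), the mean
  absolute deviation of its Cα-triangle's angles from 60°:
  ψ = ⅓ Σᵢ |θᵢ − 60°|, with ψ = 0 for perfect threefold symmetry and
  ψ → 80° at collinearity;
* **structural dynamics** — Kabsch least-squares superposition, per-residue
  RMSF about the iteratively fitted window-average structure, per-frame
  minimum heavy-atom distance between residue groups, **gap (crevice)
  events** as maximal runs of frames above an openness cutoff, and counts
  of solvent bridging an interface;
* **system comparison** — aligned occupancy / ψ / RMSF differences between
  two systems (e.g. wild type vs mutant), with absent edges counted as 0%.

The **toy-carrier generator** builds a six-helix bundle whose domains are
exact 120° rotations of each other, then injects controlled deviations:
domain-1 rotation/shift, isotropic Gaussian noise, two-state Markov
"contact channels" whose bound/unbound distance bands never overlap the
detection cutoff (so occupancy recovery is exact, not statistical), and
slab solvent. Everything stochastic is seeded and reproducible.

## Worked example

```r
library(mgatekit)

spec <- toy_carrier_spec(helix_length = 30, n_frames = 2000, noise_sigma = 0.3,
                         seed = 42,
                         channels = list(channel_spec(3, 65, k_on = 0.2, k_off = 0.1),
                                         channel_spec(123, 25, k_on = 0.05, k_off = 0.05)))
carrier <- build_toy_carrier(spec)
sim <- simulate_trajectory(carrier)

cfg <- as_mgate_config(list(
  helix_map = list(H1 = c(1, 30), H2 = c(31, 60), H3 = c(61, 90),
                   H4 = c(91, 120), H5 = c(121, 150), H6 = c(151, 180)),
  triplet_offsets = list(odd = c(0, 60, 120)),
  triplets = c(5, 15, 25),
  interactions = list(list(type = "salt_bridge", a = 3, b = 65),
                      list(type = "salt_bridge", a = 123, b = 25))))

bundle <- run_pipeline(cfg, carrier$structure, sim$trajectory)
bundle$occupancy_table
#>   res_a res_b        type         class occupancy_pct below_floor n_frames_window
#> 1     3    65 salt_bridge inter_helical       73.3125       FALSE            1600
#> 2   123    25 salt_bridge inter_helical       51.4375       FALSE            1600
```

The two channels were simulated with Markov rates whose stationary
probabilities are 2/3 and 1/2; the measured occupancies (73.3% and 51.4%
over the window that discards the first 20% of frames) equal the realized
ground-truth on-fractions *exactly* — `100 * colMeans(sim$ground_truth$states[win, ])`
returns the same `73.3125 51.4375` — because the generator's distance bands
are separated from the 4 Å cutoff by construction.

```r
bundle$psi_summary
#>   triplet mean_psi_deg sd_psi_deg n_frames
#> 1       5    1.0006099  0.5064362     1600
#> 2      15    0.9958231  0.5163154     1600
#> 3      25    1.2463460  0.6475039     1600
```

The bundle is symmetric, so mean ψ ≈ 1° here is pure noise floor (0.3 Å
Gaussian noise on ~10 Å triangles); rebuilding with
`domain1_rotation = 10` shifts every triplet's ψ to the analytic value
3.33°. RMSF likewise recovers the injected noise:
`mean(bundle$rmsf$rmsf)` is 0.516 Å against the isotropic-noise prediction
σ√3 = 0.520 Å.

## Analysis workflow

`analysis/01_simulate.R` … `05_compare.R` run a two-system study
(a symmetric reference vs a domain-1-perturbed system with a weakened
H1:H3 contact) end to end: generation, occupancy network + attachment
scores, ψ series and rotation-response curve, RMSF / distance / gap /
solvent analyses, and the between-system deltas. Tables land under
`results/`; regenerable bulk trajectories under `scratch/`. Each script is
a thin driver over the package functions and prints what it found.

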