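---
title: "Matrix-gate network and symmetry analyses: models, parameters, validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matrix-gate network and symmetry analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgatekit)
```

## The scientific setting

Mitochondrial carriers such as the ADP/ATP carrier (AAC) are built from
three homologous domains, each contributing one odd- and one even-numbered
transmembrane helix to a six-helix bundle with threefold pseudo-symmetry.
On the matrix side of the cytosol-open state, charged residues of the
conserved Px[DE]xx[KR] motifs — together with additional "non-motif" basic
residues lining the pocket — form a network of salt bridges and hydrogen
bonds known as the matrix gate (m-gate). Questions about this gate are
naturally quantitative: which residue pairs interact, for what fraction of
a trajectory, whether the contacts run within one helix or between helices,
how tightly each pair of domains is stitched together, how far the bundle
deviates from ideal C3 symmetry, and whether inter-helix interfaces
transiently open into solvent-accessible crevices.

`mgatekit` implements that analysis stack over standard structure and
multi-model-PDB trajectory input, and pairs it with a synthetic
"toy carrier" generator whose ground truth is known exactly, so every
analysis can be validated end to end rather than only eyeballed on real
trajectories.

## The psi symmetry metric

Residues at equivalent positions of the three domains form a *triplet*,
indexed by the domain-1 residue number. The three C-alpha atoms of a
triplet span a triangle with interior angles
$\theta_1, \theta_2, \theta_3$; the symmetry deviation is

$$\psi = \tfrac{1}{3}\sum_{i=1}^{3} \lvert \theta_i - 60^\circ \rvert .$$

$\psi = 0$ exactly for an equilateral triangle (perfect C3 symmetry) and
tends to $80^\circ$ as the triangle degenerates toward collinearity
(angles $180, 0, 0$). Two design choices deserve a note:

* **Absolute deviations.** The three signed deviations from 60 degrees sum
  to zero for every triangle, so a signed mean is identically zero; the
  absolute value is the only non-degenerate reading of "average deviation
  from 60 degrees". A root-mean-square variant is available
  (`psi(..., method = "rms")`) for sensitivity analyses; it is
  order-equivalent but weighs large deviations more.
* **No superposition.** The metric is internal to each triangle and hence
  invariant under rigid motion and uniform scaling of the whole structure;
  fitting before measuring would only add noise. This invariance is
  enforced by property tests to $10^{-9}$ degrees.

Coincident points are treated as a data error, not as $\psi = 80$: extreme
but valid asymmetry and corrupt coordinates should not be conflated.

For the carrier fold the default triplet offsets are `(0, +105, +202)` in
the odd-helix frame, so triplet 33 maps to residues 33/138/235 and triplet
29 to 29/134/231. The offsets are plain configuration
(`triplet_offsets` in the analysis config) because equivalent-position
bookkeeping differs between homologs and numbering schemes.

## Interactions and occupancy

An interaction is present in a frame when its geometric criterion holds:

| type | criterion | defaults |
|---|---|---|
| salt bridge | min side-chain N–O distance $\le$ cutoff | 4.0 Å, boundary counts |
| H-bond | donor–acceptor distance $\le d$; H–donor–acceptor angle $\le \alpha$ when hydrogens exist | 3.5 Å, 30° |
| guanidinium stacking | plane-centroid distance $\le d$ and interplanar angle (folded into [0°, 90°]) $\le \alpha$ | 5.0 Å, 30° |
| ligand contact | as H-bond/salt bridge with a HETATM partner selection | — |

These are widely used conventions rather than physical constants, and every
cutoff is configurable; on the synthetic data used for validation the
recovered occupancies are independent of the exact cutoff by construction
(see below). Hydrogen-free topologies (crystal structures, the toy model)
fall back to distance-only H-bond detection, which is the standard
compromise when protons are absent.

**Occupancy** is the percentage of analyzed frames in which the criterion
holds. The default analysis window discards the first 20% of frames —
production trajectories typically need their early, equilibration-adjacent
portion excluded, and one-fifth is the package default; both the fraction
and explicit frame bounds are configurable, as is a frame stride.
Occupancies are kept exact in memory and rounded to one decimal
(half away from zero) only when written to CSV. Rows below a 5% reporting
floor are flagged rather than dropped, so differencing two systems never
loses an edge. For replicate runs of one system `occupancy_multi()`
supports both combination conventions — the unweighted mean of
per-trajectory occupancies, and pooling all window frames into one
fraction — which coincide exactly for equal-length windows.

**Classification** uses a declarative helix map (named residue ranges with
a kind: transmembrane helix, matrix helix, or loop). A pair is
intra-helical when both partners lie on the same transmembrane helix,
inter-helical for two different helices, and *other* when either partner
sits in a loop or matrix helix. **Attachment scores** then summarize
domain-pair coupling as the sum of inter-helical occupancies between
helices of the two domains — the quantity that distinguishes a symmetric
network from one in which two domains bind tightly while the third hangs
loose.

## Dynamics analyses

* **Superposition** is a least-squares Kabsch fit with the rotation
  constrained proper (det = +1); a degenerate (collinear) fit group is an
  error. The implementation is checked against an independent
  quaternion-based fit to $10^{-9}$ Å.
* **RMSF** is computed about the window-average structure after iterative
  fitting: frames are fitted to a provisional average, the average is
  recomputed, and one refinement pass is applied. This matches standard
  trajectory practice; a crystal-reference mode is a matter of passing
  `fit_selection`/reference coordinates explicitly. For isotropic Gaussian
  displacement with standard deviation $\sigma$ per coordinate the expected
  RMSF is $\sigma\sqrt{3}$, which is what the recovery tests assert.
  Fitting absorbs six rigid-body degrees of freedom out of $3N$, biasing
  RMSF down by roughly a factor $\sqrt{1 - 6/(3N)}$ — about 0.5% for the
  180-residue toy bundle, well inside the 5% recovery tolerance.
* **Minimum-distance series** take the per-frame minimum over all
  cross-pairs of heavy atoms of two groups, as is conventional for
  contact-breakage plots.
* **Gap events** formalize "a crevice opened": maximal runs of consecutive
  frames with distance strictly above an openness cutoff (default 6.0 Å),
  discarding runs shorter than a minimum duration (default 10 frames).
  The criterion is deliberately simple and shift-equivariant: adding a
  constant to the series and the cutoff leaves events unchanged.
* **Bridging solvent counts** report, per frame, the number of solvent
  oxygens within a radius of *both* interface groups — the solvent that
  actually connects the pocket to bulk, not merely nearby water.

## The synthetic toy carrier

The generator emulates exactly the features the analyses consume, and
nothing else:

| parameter | default | meaning |
|---|---|---|
| `helix_length` | 30 residues | C-alpha per helix |
| `bundle_radius` | 12 Å | helix axis distance from bundle axis |
| `helix_radius`, `rise_per_residue`, `twist_per_residue` | 2.3 Å, 1.5 Å, 100° | ideal alpha-helix geometry |
| `domain1_rotation`, `domain1_radial_shift` | 0°, 0 Å | injected asymmetry of domain 1 |
| `noise_sigma` | 0.3 Å | per-coordinate Gaussian noise per frame |
| channels: `k_on`, `k_off` | — | per-frame Markov transition probabilities |
| channels: `d_on`, `d_off`, `jitter` | 3 Å, 8 Å, 0.2 Å | bound/unbound distance bands |

Domains 2 and 3 are exact 120°/240° rotations of domain 1, so the
symmetric reference has $\psi \equiv 0$ and the structure is invariant
under rotation-plus-relabeling to $10^{-9}$ Å. A 0.3 Å default noise was
chosen once as a realistic scale for well-ordered transmembrane C-alpha
fluctuations (RMSF $\approx 0.5$ Å); tests that probe noise recovery set
their own $\sigma$ explicitly.

Contact channels stand in for salt-bridge dynamics: a two-state Markov
chain switches a pair of charge-site pseudo-atoms (`CS`, one per channel
residue) between distance bands. Crucially, the second site is re-placed
*at the exact per-frame band distance from the first site's noisy
position*, so the realized inter-site distance is always inside the
state's band regardless of noise, and the channel invariant
`d_on + 3*jitter < cutoff < d_off − 3*jitter` guarantees that geometric
detection reproduces the Markov state sequence with **zero** errors. This
is what makes occupancy recovery an exact test, not a statistical one.
Moving a dedicated pseudo-atom (rather than whole residues) keeps channels
decoupled from each other and from the noise field; one global seed
expands into per-component seeds so adding a channel never changes another
component's realization.

The stationary probability of a channel is $k_{on}/(k_{on}+k_{off})$.
When comparing a realized on-fraction against it, the appropriate standard
error is the binomial one inflated for chain autocorrelation,
$\mathrm{SE} = \sqrt{p(1-p)/n \cdot (1+\rho)/(1-\rho)}$ with
$\rho = 1 - k_{on} - k_{off}$: for slow chains ($\rho \to 1$) the naive
binomial SE understates the sampling noise many-fold, and a 3-SE test
would fail for perfectly correct code.

Solvent pseudo-particles are single `O` atoms resampled uniformly in a
user-defined slab each frame, with no excluded volume — sufficient for
exercising bridging-solvent counts, and nothing more.

### What the toy model does *not* emulate

No forces, membrane, thermostat or barostat; no periodic boundary
conditions (real trajectories are assumed pre-imaged); no side-chain
chemistry beyond the pseudo-atoms; no correlated motions, so RMSF is flat
by construction. Passing the recovery tests therefore demonstrates that
the *measurement* code is correct and self-consistent — it says nothing
about whether a particular force field or sampling protocol produces
realistic occupancies. Absolute occupancies and psi values of the real
carrier depend on microsecond-scale simulations that are outside this
package's scope.

## Numerical choices and degenerate inputs

* Coordinates in Å, residue numbers 1-based (PDB convention), frames
  0-based in all output tables, times in ps.
* PDB parsing keeps the highest-occupancy alternate conformer and rejects
  insertion codes, so (chain, residue number) is always unambiguous.
  Multi-model PDB is the normative trajectory format; round-trips preserve
  coordinates to the 0.001 Å field precision.
* Triangle angles come from the law of cosines with the cosine clamped to
  [-1, 1]; triangles with a side below $10^{-6}$ Å raise a degenerate-input
  error.
* The salt-bridge boundary (distance exactly equal to the cutoff) counts
  as formed, and the gap-openness boundary (distance exactly equal to the
  cutoff) counts as closed; both conventions are documented rather than
  left to floating-point accident.
* Pipeline outputs embed a config hash and never a timestamp, so reruns
  are byte-identical — determinism is a tested property, not an aspiration.

## Validation problem sizes

The test-suite and acceptance-script study sizes were chosen as the
smallest that make each statistical check sharp: 20,000 frames for
occupancy recovery over three channels at $(k_{on}, k_{off}) \in
\{(0.2, 0.1), (0.05, 0.05), (0.9, 0.1)\}$; 10,000 frames at
$\sigma = 0.5$ Å for RMSF recovery within 5% of $\sigma\sqrt{3}$; 1,000
random rigid-plus-scaling transforms for psi invariance; 2,000 frames for
gap-event boundary recovery; and a 5,000-frame, 386-atom (180 C-alpha,
6 charge-site, 200 solvent) run for end-to-end pipeline determinism. The
analysis drivers under `analysis/` use 3,000-frame versions of the same
two-system study.

## Known limitations

* The atom selection mini-language covers residue/name/segment/chain
  conjunctions, which is all the analyses need; it is not a general query
  engine (no negation, no distance-based selections).
* H-bond detection with explicit hydrogens scans frames individually and
  is correspondingly slower than the vectorized distance-only path; for
  microsecond-scale real trajectories a stride is advisable.
* Gap detection is one-dimensional (a distance series against a cutoff).
  Pore-profile analyses along a channel axis are out of scope.
* `classify_interaction` trusts the helix map; residues outside every
  segment are an error unless a default class is supplied, which is the
  safe behavior when maps and mutants drift apart.
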