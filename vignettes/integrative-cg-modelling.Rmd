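---
title: "Integrative coarse-grained modelling of partially resolved complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative coarse-grained modelling of partially resolved complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexcore)
```

## The problem

High-resolution structures of large multi-domain complexes routinely leave a
quarter or more of the protein unresolved: intrinsically disordered regions
and flexible terminal segments average out in cryo-EM maps.  Huntingtin in
complex with HAP40 is the motivating case — the folded HEAT-repeat core is
resolved at high resolution while exon 1 and a long internal disordered
region are invisible — but the situation is generic.  `flexcore` models the
*complete* chain: the resolved residues form a quasi-rigid core, the
unresolved residues are explicit flexible chains, and two kinds of solution
data constrain the resulting conformational ensemble:

* **cross-linking mass spectrometry (XL-MS)** contributes residue-pair upper
  distance bounds (about 25 Å between Cα atoms for a lysine-reactive
  reagent such as PhoX), applied during simulation as stochastically
  switched sigmoidal restraints;
* **small-angle X-ray scattering (SAXS)** contributes a global size/shape
  profile, used after simulation to reweight the ensemble by sparse
  non-negative least squares.

## The bead model

Each residue is one bead at its Cα position.  Energies in kcal/mol,
distances in Å.

For **flexible** regions, consecutive beads are joined by harmonic bonds and
angles,

$$V_b = K_b (b - b_0)^2, \qquad V_\alpha = K_\alpha (\alpha - \alpha_0)^2,$$

with $K_b = 50$ kcal/mol/Å², $b_0 = 3.8$ Å, $K_\alpha = 1.75$
kcal/mol/rad², $\alpha_0 = 112^\circ$.  The angle constant is interpreted
per rad², the dimensionally consistent reading of the quadratic form.
Angle terms are applied only to consecutive triples containing at least one
flexible bead; the internal geometry of the core is maintained by the
structure-based terms below.  Excluded volume between non-bonded beads is a
pure repulsion

$$V_R = \varepsilon_R (\sigma_R / r_{ij})^{12}$$

with $\sigma_R = 4$ Å and $\varepsilon_R = 2$ kcal/mol, truncated at 12 Å
where it is below $2\times10^{-6}$ kcal/mol (plain truncation, evaluated
with a direct pair loop — at the bead counts this package targets a cell
list buys nothing).

The **quasi-rigid core** is a Gō-type structure-based model: consecutive
resolved beads keep pseudo-bonds at their reference separation, and every
resolved pair within 8 Å (sequence separation ≥ 3) becomes a native
contact with a 12-10 potential

$$V_{\mathrm{Go}} = \varepsilon\left[5 (r_0/r)^{12} - 6 (r_0/r)^{10}\right],$$

minimised (at depth $-\varepsilon$) at the deposited geometry.  The exact
Gō parameterisation behind the published model is not specified anywhere,
so the well depth is a package design choice with "the core stays
quasi-rigid at 300 K" as the tested contract.  The default is
$\varepsilon = 3$ kcal/mol (≈ 5 kT per contact at 300 K): a 60-residue
test domain has only ~2.5 contacts per bead, essentially all surface, and
shallower wells (1–2 kcal/mol) let such a small domain melt — its native
state stops being the free-energy minimum even though it remains the energy
minimum.  Larger real domains are buried-contact-rich and less sensitive to
this choice; it is exposed as `ff_params(go_epsilon = )`.  A test asserts
the contract directly: maximum core RMSD below 2 Å over a $10^5$-step
300 K run.

## Switched cross-link restraints

Observed cross-links are mutually incompatible in any single conformation
of a flexible complex, so imposing all of them at once is wrong, and a
harmonic restraint to a far-away partner would generate destabilising
forces.  Both problems are solved the same way as in the source model: a
**sigmoidal** restraint on the Cα–Cα distance $l_k$ of cross-link $k$,

$$V_l^k = \frac{K_{\mathrm{XL}}}{1 + e^{-\beta\,(l_k - l_0)}},$$

with $K_{\mathrm{XL}} = 10$ kcal/mol, $\beta = 0.5$ Å⁻¹ and $l_0 = 25$ Å
(the PhoX distance limit).  The force is maximal at $l_0$ and vanishes at
large distance, so restraints can be switched on against arbitrary
conformations.  At any time only $N_c = 5$ randomly chosen restraints are
active; the active set is re-drawn uniformly without replacement every
$\tau_{\mathrm{XL}} = 0.5$ ns (about 2000 re-draws in a 1000 ns
trajectory).  Drawing *without* replacement is deliberate: with
replacement, a duplicated index would silently double $K_{\mathrm{XL}}$.

## Dynamics

Langevin dynamics with the BAOAB splitting; friction 1 ps⁻¹, uniform bead
mass 110 Da, default timestep 10 fs, 300 K (none of these are stated for
the source simulations; they are standard coarse-grained practice, and the
SAXS experiments were conducted at 300 K).  With friction 0 the integrator
reduces exactly to velocity Verlet, which the energy-conservation test
exercises (drift < 0.1% over $10^4$ 1-fs steps).  Frames are written every
`save_interval` ps — 800 ns at 100 ps spacing gives the 8000-model
ensembles used in the published analysis.  A single integer seed fixes the
initial chain growth, the initial velocities, the restraint schedule and
the thermostat noise (via R's RNG), making trajectories bit-reproducible.

Flexible chains are initialised as self-avoiding random walks with step
$b_0$ grown from their rigid anchors (biased towards the far anchor when a
run bridges two rigid segments), then relaxed by 500 steps of capped
steepest descent before dynamics.

## SAXS: profiles, descriptors, reweighting

Per-conformation profiles use the Debye sum over beads with a uniform form
factor, $I(q) = f^2\sum_{ij}\operatorname{sinc}(q r_{ij})$.  This replaces
an atomic profile calculator: absolute intensities lack excluded-volume
and hydration terms, so the supported uses are *relative* — ensemble
averaging, $\chi$ ranking, weight fitting and radius-of-gyration
extraction, for which a uniform-form-factor Debye sum on Cα beads is
adequate (the uniform-sphere test pins the Guinier radius to the analytic
$R\sqrt{3/5}$ within 3%).

Diagnostics follow standard practice: Guinier fit of $\ln I$ vs $q^2$
(default window $0.015 < q < 0.025$ Å⁻¹, the published analysis window),
dimensionless Kratky transform, and $P(r)$ by Tikhonov-regularised indirect
Fourier transform with non-negativity, clamped endpoints, an L-curve
(maximum-curvature) choice of the regularisation parameter, and an optional
non-negative flat baseline that absorbs $q$-independent scattering (for
point-bead profiles, the $N f^2$ self-term, which would otherwise alias
into $P(r)$ near $r = 0$).  Perceptual quality criteria of classical IFT
programs are out of scope.

Ensemble reweighting minimises

$$\chi_{\mathrm{SAXS}} = \left[\frac{1}{N_q}\sum_i
\left(\frac{I_{\exp}(q_i) - \alpha I_{\mathrm{avrg}}(q_i)}{\sigma(q_i)}\right)^2
\right]^{1/2}, \qquad
I_{\mathrm{avrg}}(q) = \sum_k I^k_{\mathrm{calc}}(q)\, w_k,$$

over non-negative weights $w_k$ summing to one, with at most `sparsity`
non-zero entries: σ-weighted non-negative least squares followed by
iterative support pruning and refitting.  This implements the stated
objective of sparse ensemble selection without reproducing any particular
published search heuristic.  Two scale conventions are kept side by side:
`as_printed`, $\alpha = \sum I_{\exp} I_{\mathrm{avrg}} / \sum I_{\exp}
I_{\exp}$, and `least_squares`, $\alpha = \sum I_{\exp} I_{\mathrm{avrg}} /
\sum I_{\mathrm{avrg}} I_{\mathrm{avrg}}$.  The first is the published
formula, the second is the actual minimiser of the unweighted residual;
they agree exactly when $I_{\mathrm{avrg}} = I_{\exp}$, and neither is
silently "corrected" to the other.  The fitted model is an S3 object with
`coef`, `predict`, `residuals`, `summary` and `plot` methods.

## What the synthetic data emulate — and what they do not

The generator produces the same three inputs a real study provides:

* `make_toy_complex()`: a deterministic α-helix bundle core (1.5 Å rise,
  2.3 Å helix radius, helix axes ~10 Å apart — packed-bundle spacing, so
  the contact map actually holds the bundle together) with flexible tails
  recorded in SEQRES but absent from the coordinates, exactly how
  unresolved regions appear in deposited entries.  The default 60 + 20
  residues reproduces the ~25% unresolved fraction of the motivating
  complex.
* `sample_crosslinks()`: links drawn from the contact statistics of a
  ground-truth ensemble — true links from pairs in contact (≥ 0.5
  weighted frequency at 25 Å) among designated cross-linkable sites (every
  7th residue, a lysine-like density), decoys from pairs essentially never
  in contact (≤ 0.05).  True links prefer pairs touching a flexible bead
  and require ≥ 10 residues separation on the same chain: core-internal
  and short-range links are satisfied by construction and would make
  restraint-efficacy comparisons vacuous, mirroring why real XL-MS
  analyses discard short loops.
* `synthesize_saxs()`: a noisy mixture profile from known weights, with
  $\sigma = $ `noise_rel` $\times I$ (1% by default, a typical
  well-measured SAXS error scale).

Ground-truth ensembles are produced by the package's own engine *at a
different seed* than any recovery run, so recovery tests are not circular
at the trajectory level.  In the decoy-rejection benchmark, decoys are
conformers of structurally *wrong* models (bundles repacked at different
radii): decoys drawn from the same trajectory as the truth can be linearly
combined to mimic intermediate states — coarse-grained SAXS profiles are
close to a one-parameter family in $R_g$ — which turns "reject the decoys"
into an ill-posed demand no method could meet.

What the toys do **not** emulate: sequence-specific chain statistics (no
per-residue potentials), instrument smearing and inter-particle effects in
SAXS, peptide-level cross-link identification noise (scores are synthetic
and all pass the cutoff), and the sheer size of a real complex (~3500
residues vs 80).  Passing tests therefore demonstrate correctness of the
machinery and recoverability under controlled conditions, not field
performance on experimental data.

## Numerical and design notes

* Forces are the analytic gradient; a finite-difference sweep over 100
  random configurations (tolerance $10^{-5}$ relative) guards every term.
* Superposition is Kabsch via SVD with a determinant correction
  (cross-checked against an independent implementation and a brute-force
  rotation search in the tests).
* Residue identity is (chain, author residue number); insertion codes are
  rejected rather than silently renumbered.  Altlocs: first listed, only
  Cα atoms are read.
* Restraint subsets are drawn without replacement (see above); the epoch
  length, $N_c$, and all force-field constants are configurable.
* The sigmoid restraint evaluation guards $r \to 0$; the angle gradient
  guards collinear triples; NNLS failures at extreme regularisation are
  skipped on the L-curve grid.
* Degenerate inputs: zero-length flexible runs are ignored with a warning;
  an empty restraint list runs unconstrained; a one-member ensemble gets
  weight 1.
* Problem sizes in the tests and the acceptance script (60–100 beads,
  0.1–1 ns trajectories, 50-decoy pools) were chosen as the smallest
  systems that exercise every contract with comfortable margins; the
  engine itself has no size-specific assumptions.

## Known limitations

* The Debye calculator's absolute intensity scale is arbitrary; do not
  compare $I(0)$ across systems with different bead counts as if it were a
  molecular weight estimate.
* Weight fitting inherits the ill-posedness of SAXS: near-degenerate
  conformer profiles split weight arbitrarily; the sparsity constraint
  mitigates but cannot remove this.
* The quasi-rigid core is a model assumption, not an inference: genuinely
  plastic domains will be held artificially native-like.
* Accession-based validation against the deposited huntingtin-HAP40 models
  requires files fetched from the PDB and the publication supplement
  (`scripts/fetch_accessions.R`); they cannot be redistributed here.

## A minimal session

```{r example, eval = FALSE}
spec <- toy_spec()
gt <- toy_ground_truth(spec, total_time = 600, save_interval = 10)

dir.create("demo")
write_toy_pdb(gt$toy, "demo/structure.pdb")
sample_crosslinks(gt$ensemble, gt$topology, n_links = 8,
                  decoy_fraction = 0, seed = 3, path = "demo/crosslinks.csv")
w <- rep(0, n_frames(gt$ensemble)); w[c(5, 30, 55)] <- c(0.6, 0.3, 0.1)
prof <- synthesize_saxs(gt$ensemble, w, seq(0.005, 0.30, by = 0.005),
                        noise_rel = 0.01, seed = 4)
write_saxs(prof, "demo/saxs.dat")

report <- run_integrative(list(
  structure = "demo/structure.pdb",
  crosslinks = "demo/crosslinks.csv",
  saxs = "demo/saxs.dat",
  outdir = "demo/out", seed = 9,
  ff = list(tau_xl = 20),
  sim = list(total_time = 300, save_interval = 5),
  analysis = list(sparsity = 10)))
```
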