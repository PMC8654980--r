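# flexcore

Coarse-grained integrative modelling of multi-domain protein complexes
whose deposited structures leave large flexible regions unresolved.

Cryo-EM models of complexes like huntingtin–HAP40 resolve the folded
HEAT-repeat core at high resolution while a quarter of the protein — the
exon 1 region and a long internal disordered segment — is invisible.
`flexcore` models the complete chain as a Cα bead polymer: resolved
residues form a quasi-rigid Gō-like core, unresolved residues are explicit
flexible chains, and two kinds of solution data constrain the ensemble —
cross-linking mass spectrometry (XL-MS) distance bounds applied *during*
Langevin dynamics as stochastically switched restraints, and small-angle
X-ray scattering (SAXS) applied *after* dynamics by sparse ensemble
reweighting.

## The model

Energies in kcal/mol, distances in Å.  Flexible regions: harmonic bonds
and angles

> V_b = K_b (b − b₀)²,  V_α = K_α (α − α₀)²

with K_b = 50, b₀ = 3.8 Å, K_α = 1.75, α₀ = 112°; excluded volume
V_R = ε_R (σ_R/r)¹² with ε_R = 2, σ_R = 4 Å.  The resolved core is a
structure-based 12-10 native-contact model (contacts within 8 Å,
|i−j| ≥ 3) whose minimum is the deposited geometry.  Cross-link k with
Cα–Cα distance l_k contributes the sigmoidal restraint

> V_l^k = K_XL / (1 + exp(−β (l_k − l₀)))

with K_XL = 10, β = 0.5 Å⁻¹ and l₀ = 25 Å (the PhoX lysine cross-linker
limit); its force peaks at l₀ and vanishes at large distance, so a random
subset of N_c = 5 restraints can be re-drawn every τ_XL = 0.5 ns without
force blow-ups.  Ensembles are reweighted against SAXS by minimising

> χ_SAXS = [ (1/N_q) Σᵢ ((I_exp(qᵢ) − α·I_avrg(qᵢ))/σ(qᵢ))² ]^½,
> I_avrg = Σₖ I_calc^k · w_k

over sparse non-negative weights w (NNLS with support pruning), with
per-conformer profiles from a Debye sum over beads.  Guinier, dimensionless
Kratky and regularised-IFT P(r) diagnostics are included, as is a
synthetic-data generator (structure + cross-link table + SAXS curve with
known ground truth) used throughout the tests.

## Worked example

```r
library(flexcore)

## synthetic complex: 60-residue helix-bundle core + 20-residue flexible tail
spec <- toy_spec()
gt <- toy_ground_truth(spec, total_time = 600, save_interval = 10)
gt$topology
#> CG topology: 80 beads (60 rigid, 20 flexible), 79 bonds, 20 angles, 149 native contacts

## cross-links sampled from the ground truth, then used as switched restraints
links <- sample_crosslinks(gt$ensemble, gt$topology, n_links = 8,
                           decoy_fraction = 0, seed = 3)
restr <- restraints_from_links(gt$topology, links)
topo <- gt$topology; topo$params <- ff_params(tau_xl = 20)
ens_r <- run_cg(topo, sim_config(300, save_interval = 5, seed = 11,
                                 restraints = restr))
ens_u <- run_cg(topo, sim_config(300, save_interval = 5, seed = 11))
satisfaction_fraction(ens_u, restr, 25)   # fraction of frames with all links <= 25 A
#> [1] 0.80
satisfaction_fraction(ens_r, restr, 25)
#> [1] 1.00

## SAXS reweighting: recover known 3-state weights from a noisy mixture
q <- seq(0.005, 0.30, by = 0.005)
rg <- ensemble_rg(gt$ensemble); ord <- order(rg)
idx <- c(ord[1], ord[round(length(ord)/2)], ord[length(ord)])
icalc <- sapply(idx, function(k) debye_profile(frame_coords(gt$ensemble, k), q)$I)
prof <- synthesize_saxs(NULL, c(0.6, 0.3, 0.1), q, noise_rel = 0.01,
                        seed = 11, profiles = icalc)
fit <- fit_saxs_weights(icalc, prof$I, prof$sigma, q = q)
summary(fit)
#> Sparse SAXS ensemble fit over 3 conformers (sparsity limit Inf)
#>   chi = 0.91888  (uniform-weight chi = 5.7602)
#>   alpha = 1.0024  [as_printed]
#>   support:
#>     conformer 1: w = 0.5925
#>     conformer 2: w = 0.3020
#>     conformer 3: w = 0.1055
```

The restrained run satisfies the imposed cross-links in every saved frame
where the free run does so in 80%, and the reweighting recovers the true
(0.6, 0.3, 0.1) mixture to within 0.01 at 1% noise with χ ≈ 1 (noise
level), against χ ≈ 5.8 for uniform weights.

`run_integrative()` chains all stages (build → simulate, unconstrained and
restrained → cross-link mapping → SAXS reweighting → flexible-region
metrics) from a single JSON/list config into a seeded, reproducible output
bundle; `inst/cli/flexcore-cli.R` is a thin command-line wrapper.

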