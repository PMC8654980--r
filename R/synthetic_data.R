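#' Specification for a synthetic rigid-core / flexible-tail complex
#'
#' Defines a toy complex with the statistical structure the analysis
#' assumes: a deterministic quasi-rigid helix-bundle core (ideal alpha
#' helix geometry: 1.5 A rise per residue, 2.3 A Calpha helix radius) and
#' one or more flexible chains that are "unresolved" in the emitted PDB,
#' mirroring how missing regions appear in deposited models.  Defaults give
#' an 80-residue chain whose flexible quarter matches the ~25% unresolved
#' fraction typical of large complexes with disordered regions.
#'
#' @param core_size number of resolved core residues.
#' @param n_helices helices in the bundle.
#' @param helix_rise rise per residue along the helix axis, A.
#' @param helix_radius Calpha helix radius, A.
#' @param bundle_radius distance of each helix axis from the bundle axis, A.
#' @param tails list of flexible chains, each `list(end = "N"|"C",
#'   length = <residues>)`.
#' @param n_links number of cross-links to sample.
#' @param decoy_fraction fraction of sampled links that are decoys (pairs
#'   rarely in contact in the ground truth).
#' @param noise_rel relative Gaussian noise (and sigma column) of the
#'   synthetic SAXS curve.
#' @param true_weights weights of the ground-truth conformers mixed into
#'   the synthetic SAXS curve.
#' @param linkable_every designate every k-th residue as cross-linkable.
#' @param seed integer seed for every random element.
#' @return class `toy_spec` (validated list).
#' @export
toy_spec <- function(core_size = 60, n_helices = 3, helix_rise = 1.5,
                     helix_radius = 2.3, bundle_radius = 5.8,
                     tails = list(list(end = "C", length = 20)),
                     n_links = 10, decoy_fraction = 0.2, noise_rel = 0.01,
                     true_weights = c(0.6, 0.3, 0.1), linkable_every = 7,
                     seed = 1) {
  stopifnot(core_size >= n_helices, n_helices >= 1, helix_rise > 0,
            helix_radius > 0, n_links >= 1,
            decoy_fraction >= 0, decoy_fraction <= 1, noise_rel >= 0,
            all(true_weights >= 0), sum(true_weights) > 0)
  for (t in tails) stopifnot(t$end %in% c("N", "C"), t$length >= 0)
  structure(list(core_size = core_size, n_helices = n_helices,
                 helix_rise = helix_rise, helix_radius = helix_radius,
                 bundle_radius = bundle_radius, tails = tails,
                 n_links = n_links, decoy_fraction = decoy_fraction,
                 noise_rel = noise_rel,
                 true_weights = true_weights / sum(true_weights),
                 linkable_every = linkable_every, seed = as.integer(seed)),
            class = "toy_spec")
}

#' Build the synthetic complex
#'
#' Generates the deterministic core coordinates (no randomness: the same
#' spec always yields the same structure), flags tail residues absent, and
#' returns the structure plus the flexible-region description.
#'
#' @param spec a [toy_spec()].
#' @return list with `structure` (a `ca_structure` whose tail residues are
#'   absent), `flexible` (data frame `chain`, `resno` of flexible residues),
#'   and `full_sequences` (per-chain residue vectors for
#'   [build_topology()]).
#' @export
make_toy_complex <- function(spec) {
  n <- spec$core_size
  nh <- spec$n_helices
  per <- ceiling(n / nh)
  xyz <- matrix(0, n, 3)
  twist <- 2 * pi / 3.6                      # ~100 degrees per residue
  i <- 0
  for (h in seq_len(nh)) {
    m <- min(per, n - i)
    if (m <= 0) break
    phi <- 2 * pi * (h - 1) / nh
    cx <- spec$bundle_radius * cos(phi)
    cy <- spec$bundle_radius * sin(phi)
    up <- h %% 2 == 1
    for (t in seq_len(m)) {
      z <- if (up) (t - 1) * spec$helix_rise else (m - t) * spec$helix_rise
      xyz[i + t, ] <- c(cx + spec$helix_radius * cos(twist * t + phi),
                        cy + spec$helix_radius * sin(twist * t + phi),
                        z)
    }
    i <- i + m
  }
  if (min(stats::dist(xyz)) < 1)
    stop("make_toy_complex: core geometry produces overlapping beads (< 1 A)")

  n_pre <- sum(vapply(spec$tails, function(t)
    if (t$end == "N") t$length else 0L, numeric(1)))
  n_post <- sum(vapply(spec$tails, function(t)
    if (t$end == "C") t$length else 0L, numeric(1)))
  resno_core <- seq_len(n) + n_pre
  all_resno <- seq_len(n_pre + n + n_post)
  flex_resno <- setdiff(all_resno, resno_core)

  atoms <- data.frame(chain = "A", resno = all_resno, resname = "ALA",
                      x = NA_real_, y = NA_real_, z = NA_real_,
                      present = all_resno %in% resno_core,
                      stringsAsFactors = FALSE)
  atoms[match(resno_core, atoms$resno), c("x", "y", "z")] <- xyz
  st <- new_ca_structure(atoms, source = "synthetic toy complex")
  list(structure = st,
       flexible = data.frame(chain = rep("A", length(flex_resno)),
                             resno = flex_resno),
       full_sequences = list(A = all_resno))
}

#' Write a synthetic complex as a PDB fixture
#'
#' ATOM records for the resolved core only, SEQRES covering the full
#' sequence, so [read_structure()] recovers the flexible residues as
#' absent -- exactly the shape of a deposited model with unresolved regions.
#'
#' @param toy a [make_toy_complex()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_toy_pdb <- function(toy, path) {
  a <- toy$structure$atoms
  seqres <- a[, c("chain", "resno", "resname")]
  pres <- a[a$present, , drop = FALSE]
  write_ca_pdb(as.matrix(pres[, c("x", "y", "z")]),
               pres[, c("chain", "resno", "resname")], path, seqres = seqres)
}

#' Run the ground-truth simulation of a toy complex
#'
#' Convenience wrapper: builds the topology and runs an unconstrained
#' trajectory whose frames serve as the ground-truth conformational
#' ensemble for sampling cross-links and synthesizing SAXS data.  The
#' ground truth uses its own seed offset so that recovery tests run the
#' engine at a different seed than the data generation.
#'
#' @param spec a [toy_spec()].
#' @param total_time simulated time, ps.
#' @param save_interval frame spacing, ps.
#' @param temperature thermostat temperature, K.
#' @param params optional [ff_params()].
#' @return list with `topology`, `ensemble`, and the `toy` complex.
#' @export
toy_ground_truth <- function(spec, total_time = 2000, save_interval = 10,
                             temperature = 300, params = ff_params()) {
  toy <- make_toy_complex(spec)
  topo <- build_topology(toy$structure, toy$full_sequences, params = params,
                         linkable_every = spec$linkable_every)
  cfg <- sim_config(total_time = total_time, save_interval = save_interval,
                    temperature = temperature, seed = spec$seed + 7919L)
  ens <- run_cg(topo, cfg)
  list(topology = topo, ensemble = ens, toy = toy)
}

#' Sample cross-links from a ground-truth ensemble
#'
#' True links are drawn from cross-linkable (lysine-designated) bead pairs
#' whose weighted contact frequency in the ground truth is at least 0.5;
#' decoys from pairs with frequency at most 0.05.  Pairs with at least one
#' flexible endpoint are preferred for true links (rigid-rigid pairs are
#' used only when the flexible pool runs out): links within the rigid core
#' are always satisfied by construction and carry no information for
#' restraining the flexible regions, which is what cross-links are used for
#' here.  All records get scores above the default identification cutoff of
#' 40, so the filter keeps them and satisfaction statistics probe geometry,
#' not scoring.
#'
#' @param ensemble ground-truth `cg_ensemble`.
#' @param topology the matching `cg_topology` (for the linkable set).
#' @param n_links total links to emit.
#' @param decoy_fraction fraction of decoys.
#' @param threshold contact threshold, A.
#' @param seed integer seed.
#' @param true_weights optional ground-truth frame weights.
#' @param min_separation minimum residue separation for same-chain pairs
#'   (default 10); short-range links are trivially satisfied and carry no
#'   structural information, mirroring the short-loop filtering customary in
#'   cross-linking studies.
#' @param path optional CSV output path.
#' @return data frame in the cross-link CSV schema (`chain_a`, `res_a`,
#'   `chain_b`, `res_b`, `score`) with a logical `decoy` column; written to
#'   `path` (without the `decoy` column) when given.
#' @export
sample_crosslinks <- function(ensemble, topology, n_links = 10,
                              decoy_fraction = 0.2, threshold = 25, seed = 1,
                              true_weights = NULL, min_separation = 10,
                              path = NULL) {
  stopifnot(n_links >= 1)
  if (!is.null(true_weights)) ensemble <- set_weights(ensemble, true_weights)
  link <- topology$linkable
  if (length(link) < 2) stop("sample_crosslinks: fewer than two linkable sites")
  pairs <- expand.grid(i = link, j = link)
  pairs <- pairs[pairs$i < pairs$j, , drop = FALSE]
  bd <- topology$beads
  same <- bd$chain[pairs$i] == bd$chain[pairs$j]
  pairs <- pairs[!same | abs(bd$resno[pairs$j] - bd$resno[pairs$i]) >=
                   min_separation, , drop = FALSE]
  pairs <- contact_frequency(ensemble, pairs, threshold)
  true_pool <- pairs[pairs$frequency >= 0.5, , drop = FALSE]
  decoy_pool <- pairs[pairs$frequency <= 0.05, , drop = FALSE]
  n_decoy <- round(n_links * decoy_fraction)
  n_true <- n_links - n_decoy
  if (nrow(true_pool) < n_true || nrow(decoy_pool) < n_decoy)
    stop(sprintf(paste0(
      "sample_crosslinks: insufficient eligible pairs (%d true / need %d, ",
      "%d decoy / need %d); use a larger ensemble or adjust the threshold"),
      nrow(true_pool), n_true, nrow(decoy_pool), n_decoy))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  flex <- topology$beads$flexible
  pref <- which(flex[true_pool$i] | flex[true_pool$j])
  take <- if (length(pref) >= n_true) sample(pref, n_true)
  else c(pref, sample(setdiff(seq_len(nrow(true_pool)), pref),
                      n_true - length(pref)))
  pick_t <- true_pool[take, , drop = FALSE]
  pick_d <- if (n_decoy > 0)
    decoy_pool[sample.int(nrow(decoy_pool), n_decoy), , drop = FALSE]
  else decoy_pool[0, , drop = FALSE]
  if (nrow(pick_t) && !any(flex[pick_t$i] | flex[pick_t$j]))
    warning("sample_crosslinks: no sampled true link touches a flexible bead; ",
            "restraints will be uninformative for the flexible regions")
  beads <- topology$beads
  mk <- function(p, decoy, score_lo, score_hi) {
    if (!nrow(p)) return(NULL)
    data.frame(chain_a = beads$chain[p$i], res_a = beads$resno[p$i],
               chain_b = beads$chain[p$j], res_b = beads$resno[p$j],
               score = stats::runif(nrow(p), score_lo, score_hi),
               decoy = decoy, stringsAsFactors = FALSE)
  }
  out <- rbind(mk(pick_t, FALSE, 55, 100), mk(pick_d, TRUE, 41, 70))
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.csv(out[, setdiff(names(out), "decoy")], path,
                     row.names = FALSE)
  out
}

#' Synthesize a noisy SAXS curve from a known weighted ensemble
#'
#' `I_exp(q) = alpha_true sum_k w_k I_k(q)` with multiplicative Gaussian
#' noise of relative s.d. `noise_rel`; the sigma column is
#' `noise_rel * I`.
#'
#' @param ensemble a `cg_ensemble` (or a matrix of per-conformer profiles
#'   via `profiles`).
#' @param true_weights weights over frames/conformers (normalized).
#' @param q_grid scattering vector grid, 1/A.
#' @param noise_rel relative noise level (>= 0).
#' @param seed integer seed.
#' @param alpha_true overall scale of the synthetic experiment.
#' @param profiles optional precomputed `N_q x N_ens` profile matrix
#'   (skips the Debye computation).
#' @return a [saxs_profile()] with `sigma` (absent when `noise_rel = 0`).
#' @export
synthesize_saxs <- function(ensemble, true_weights, q_grid, noise_rel = 0.01,
                            seed = 1, alpha_true = 1, profiles = NULL) {
  stopifnot(noise_rel >= 0, all(true_weights >= 0), sum(true_weights) > 0)
  w <- true_weights / sum(true_weights)
  if (is.null(profiles)) profiles <- ensemble_profiles(ensemble, q_grid)
  stopifnot(ncol(profiles) == length(w))
  mean_I <- alpha_true * as.numeric(profiles %*% w)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  I <- mean_I + stats::rnorm(length(mean_I), 0, noise_rel * mean_I)
  sigma <- noise_rel * mean_I
  saxs_profile(q_grid, I, if (noise_rel > 0) sigma else NULL)
}
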