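#' Coarse-grained force-field parameters
#'
#' Container for every constant of the Calpha bead model: harmonic bond and
#' angle terms for flexible chains, pure repulsion between non-bonded beads,
#' the Go-like native-contact term holding the resolved core quasi-rigid, and
#' the sigmoidal cross-link restraint used for stochastically switched
#' distance restraints.
#'
#' Defaults follow the published coarse-grained model of the HTT-HAP40
#' complex: `k_b` = 50 kcal/mol/A^2 with `b_0` = 3.8 A; `k_a` = 1.75
#' kcal/mol/rad^2 with `a_0` = 112 degrees; excluded volume
#' `eps_r` = 2.0 kcal/mol, `sig_r` = 4 A; cross-link restraint
#' `k_xl` = 10 kcal/mol, slope `beta` = 0.5 /A, upper bound `l_0` = 25 A
#' (the lysine cross-linker distance limit), `n_c` = 5 simultaneously active
#' restraints re-drawn every `tau_xl` = 500 ps.  The Go term (depth
#' `go_epsilon`, native-contact cutoff `go_cutoff`) is a standard
#' structure-based 12-10 potential.
#'
#' @param k_b bond stiffness, kcal/mol/A^2.
#' @param b_0 equilibrium virtual bond length, A.
#' @param k_a angle stiffness, kcal/mol/rad^2.
#' @param a_0 equilibrium virtual bond angle, radians (default 112 degrees).
#' @param eps_r repulsion strength, kcal/mol.
#' @param sig_r repulsion radius, A.
#' @param k_xl cross-link restraint height, kcal/mol.
#' @param beta sigmoid slope, 1/A.
#' @param l_0 cross-link upper distance bound, A.
#' @param n_c number of simultaneously active restraints.
#' @param tau_xl restraint re-selection interval, ps.
#' @param go_epsilon native-contact well depth, kcal/mol.
#' @param go_cutoff native-contact enumeration cutoff, A.
#' @param rep_cutoff nonbonded truncation distance, A (the repulsion at 12 A
#'   is below 2e-6 kcal/mol, so plain truncation is used).
#' @return An object of class `ff_params` (a validated named list).
#' @examples
#' p <- ff_params()
#' restraint_energy(p$l_0, p)  # K_XL / 2 at the midpoint
#' @export
ff_params <- function(k_b = 50, b_0 = 3.8, k_a = 1.75, a_0 = 112 * pi / 180,
                      eps_r = 2.0, sig_r = 4.0, k_xl = 10, beta = 0.5,
                      l_0 = 25, n_c = 5, tau_xl = 500, go_epsilon = 3.0,
                      go_cutoff = 8.0, rep_cutoff = 12.0) {
  p <- list(k_b = k_b, b_0 = b_0, k_a = k_a, a_0 = a_0, eps_r = eps_r,
            sig_r = sig_r, k_xl = k_xl, beta = beta, l_0 = l_0, n_c = n_c,
            tau_xl = tau_xl, go_epsilon = go_epsilon, go_cutoff = go_cutoff,
            rep_cutoff = rep_cutoff)
  for (nm in c("k_b", "b_0", "k_a", "eps_r", "sig_r", "k_xl", "beta", "l_0",
               "tau_xl", "go_epsilon", "go_cutoff", "rep_cutoff")) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0)
      stop("ff_params: '", nm, "' must be a single positive number")
  }
  if (!is.numeric(a_0) || a_0 <= 0 || a_0 >= pi)
    stop("ff_params: 'a_0' must lie in (0, pi) radians")
  if (n_c < 1 || n_c != round(n_c)) stop("ff_params: 'n_c' must be an integer >= 1")
  p$n_c <- as.integer(n_c)
  class(p) <- "ff_params"
  p
}

#' @export
print.ff_params <- function(x, ...) {
  cat("Coarse-grained force-field parameters\n")
  cat(sprintf("  bonds:      K_b = %g kcal/mol/A^2, b_0 = %g A\n", x$k_b, x$b_0))
  cat(sprintf("  angles:     K_a = %g kcal/mol/rad^2, a_0 = %.1f deg\n",
              x$k_a, x$a_0 * 180 / pi))
  cat(sprintf("  repulsion:  eps_R = %g kcal/mol, sig_R = %g A (cutoff %g A)\n",
              x$eps_r, x$sig_r, x$rep_cutoff))
  cat(sprintf("  Go core:    eps = %g kcal/mol, contact cutoff = %g A\n",
              x$go_epsilon, x$go_cutoff))
  cat(sprintf("  cross-link: K_XL = %g kcal/mol, beta = %g /A, l_0 = %g A, N_c = %d, tau_XL = %g ps\n",
              x$k_xl, x$beta, x$l_0, x$n_c, x$tau_xl))
  invisible(x)
}

#' Simulation configuration for the Langevin engine
#'
#' @param total_time total simulated time, ps.
#' @param timestep integration timestep, ps (default 0.01 ps = 10 fs, a
#'   standard choice for Calpha bead models).
#' @param temperature thermostat temperature, K.
#' @param friction Langevin friction, 1/ps; `0` gives the deterministic
#'   velocity-Verlet (NVE) limit.
#' @param mass uniform bead mass, Da (average amino-acid residue mass).
#' @param save_interval trajectory frame spacing, ps; must be a positive
#'   multiple of `timestep`.
#' @param seed integer seed governing initial placement, velocities, the
#'   restraint schedule, and thermostat noise.
#' @param restraints optional restraint set, a data frame with columns `i`,
#'   `j` (bead indices) as produced by [restraints_from_links()]; may be
#'   empty for unconstrained runs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(total_time, timestep = 0.01, temperature = 300,
                       friction = 1.0, mass = 110, save_interval = 100,
                       seed = 1, restraints = NULL) {
  if (timestep <= 0) stop("sim_config: timestep must be positive")
  if (save_interval <= 0) stop("sim_config: save_interval must be positive")
  k <- save_interval / timestep
  if (abs(k - round(k)) > 1e-8)
    stop("sim_config: save_interval must be a multiple of timestep")
  if (total_time < save_interval)
    stop("sim_config: total_time must be at least one save_interval")
  if (friction < 0) stop("sim_config: friction must be >= 0")
  structure(list(total_time = total_time, timestep = timestep,
                 temperature = temperature, friction = friction, mass = mass,
                 save_interval = save_interval, seed = as.integer(seed),
                 restraints = restraints),
            class = "sim_config")
}

# Boltzmann constant, kcal/mol/K
.kB <- 0.001987204259
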