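#' Closed-form energy terms of the bead model
#'
#' Scalar forms of the individual potentials, each returning the energy with
#' the derivative with respect to its scalar argument as attribute `"deriv"`.
#' These are the same expressions evaluated by the compiled kernels; the
#' scalar versions exist for direct inspection and testing.
#'
#' * `bond_energy`: `K_b (b - b_0)^2`
#' * `angle_energy`: `K_a (alpha - alpha_0)^2`
#' * `repulsive_energy`: `eps_R (sig_R / r)^12`
#' * `go_contact_energy`: `eps [5 (r0/r)^12 - 6 (r0/r)^10]`, minimum `-eps`
#'   at `r = r0`
#' * `restraint_energy`: `K_XL / (1 + exp(-beta (l - l_0)))`, the sigmoidal
#'   cross-link restraint whose force peaks at `l = l_0` and vanishes at
#'   large distance (which is what makes random restraint switching safe)
#'
#' @param b,alpha,r,l scalar (or vector) argument: bond length (A), angle
#'   (rad), inter-bead distance (A), restraint distance (A).
#' @param r_native native-contact reference distance (A).
#' @param params an [ff_params()] object.
#' @return energy in kcal/mol, with attribute `deriv`.
#' @examples
#' p <- ff_params()
#' bond_energy(4.8, p)        # 50 * 1^2
#' restraint_energy(25, p)    # K_XL / 2
#' @name energy_terms
NULL

#' @rdname energy_terms
#' @export
bond_energy <- function(b, params = ff_params()) {
  stopifnot(all(b > 0))
  e <- params$k_b * (b - params$b_0)^2
  attr(e, "deriv") <- 2 * params$k_b * (b - params$b_0)
  e
}

#' @rdname energy_terms
#' @export
angle_energy <- function(alpha, params = ff_params()) {
  stopifnot(all(alpha > 0), all(alpha < pi))
  e <- params$k_a * (alpha - params$a_0)^2
  attr(e, "deriv") <- 2 * params$k_a * (alpha - params$a_0)
  e
}

#' @rdname energy_terms
#' @export
repulsive_energy <- function(r, params = ff_params()) {
  if (any(r == 0)) stop("repulsive_energy: singular distance r = 0")
  stopifnot(all(r > 0))
  e <- params$eps_r * (params$sig_r / r)^12
  attr(e, "deriv") <- -12 * params$eps_r * params$sig_r^12 / r^13
  e
}

#' @rdname energy_terms
#' @export
go_contact_energy <- function(r, r_native, params = ff_params()) {
  stopifnot(all(r > 0), all(r_native > 0))
  s <- r_native / r
  e <- params$go_epsilon * (5 * s^12 - 6 * s^10)
  attr(e, "deriv") <- 60 * params$go_epsilon * (s^10 - s^12) / r
  e
}

#' @rdname energy_terms
#' @export
restraint_energy <- function(l, params = ff_params()) {
  stopifnot(all(l >= 0))
  s <- 1 / (1 + exp(-params$beta * (l - params$l_0)))
  e <- params$k_xl * s
  attr(e, "deriv") <- params$k_xl * params$beta * s * (1 - s)
  e
}

#' Total energy and forces of a configuration
#'
#' Sums bonds, angles, native contacts, non-bonded repulsion and the active
#' cross-link restraints, returning the analytic forces (the exact negative
#' gradient of the energy).
#'
#' @param topology a `cg_topology`.
#' @param coords n x 3 coordinate matrix (A), one row per bead.
#' @param restraints optional data frame of candidate restraints (`i`, `j`
#'   bead columns).
#' @param active integer indices into `restraints` that are currently
#'   switched on (default: all of them).
#' @return list with `energy` (kcal/mol) and `forces` (n x 3, kcal/mol/A).
#' @export
total_energy_forces <- function(topology, coords, restraints = NULL,
                                active = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(topology$beads))
    stop("total_energy_forces: coordinate count does not match bead count")
  if (any(!is.finite(coords)))
    stop("total_energy_forces: non-finite coordinate")
  if (is.null(active))
    active <- if (is.null(restraints)) integer() else seq_len(nrow(restraints))
  cg_energy_forces_cpp(coords, .topo_cpp(topology, restraints),
                       as.integer(active - 1L))
}
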