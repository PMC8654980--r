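#' Trajectory frame schedule
#'
#' Frames are saved every `save_interval` ps, so a run of `total_time` ps
#' yields `floor(total_time / save_interval)` frames (an 800 ns run saved
#' every 100 ps gives an ensemble of 8000 models).
#'
#' @param total_time total simulated time, ps.
#' @param save_interval frame spacing, ps.
#' @return numeric vector of save times (ps).
#' @export
frame_schedule <- function(total_time, save_interval) {
  if (save_interval <= 0) stop("frame_schedule: save_interval must be positive")
  if (save_interval > total_time) {
    warning("frame_schedule: save_interval exceeds total_time; empty schedule")
    return(numeric(0))
  }
  seq_len(floor(total_time / save_interval)) * save_interval
}

#' Stochastic restraint-switching schedule
#'
#' The restrained simulation keeps only a small number `n_c` of the
#' candidate cross-link restraints active at a time, re-drawing the active
#' subset uniformly (without replacement) from all `n_xl` candidates every
#' `tau_xl` ps.  A 1000 ns run with `tau_xl` = 0.5 ns re-draws ~2000 times.
#'
#' @param n_xl number of candidate restraints.
#' @param n_c number active per epoch.
#' @param tau_xl epoch length, ps.
#' @param total_time total simulated time, ps.
#' @param seed integer seed (draws are reproducible for a fixed seed).
#' @return object of class `restraint_schedule`: list with `start` (epoch
#'   start times, ps) and `active` (n_epochs x n_c matrix of restraint
#'   indices in `[1, n_xl]`, distinct within each row).
#' @export
restraint_schedule <- function(n_xl, n_c, tau_xl, total_time, seed = 1) {
  if (n_c < 1) stop("restraint_schedule: n_c must be >= 1")
  if (n_xl < n_c)
    stop("restraint_schedule: fewer candidate restraints (", n_xl,
         ") than active slots (", n_c, "); lower n_c")
  n_epochs <- ceiling(total_time / tau_xl)
  act <- matrix(0L, n_epochs, n_c)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  for (e in seq_len(n_epochs)) act[e, ] <- sample.int(n_xl, n_c)
  structure(list(start = (seq_len(n_epochs) - 1) * tau_xl, tau_xl = tau_xl,
                 active = act), class = "restraint_schedule")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Initial coordinates for flexible regions
#'
#' Rigid beads start at their reference coordinates.  Each flexible run is
#' grown as a self-avoiding random walk with step `b_0` from its rigid
#' anchor (biased towards the anchor on the far side when the run bridges
#' two rigid segments), keeping every new bead at least `sig_r / 2` from all
#' placed beads, and the full configuration is then relaxed by steepest
#' descent.
#'
#' @param topology a `cg_topology`.
#' @param seed integer seed.
#' @param relax_steps steepest-descent steps after growth (default 500).
#' @param max_retry placement retries per bead before accepting the best
#'   candidate.
#' @return n x 3 coordinate matrix.
#' @export
initialize_flexible <- function(topology, seed = 1, relax_steps = 500,
                                max_retry = 50) {
  beads <- topology$beads
  n <- nrow(beads)
  coords <- as.matrix(beads[, c("x", "y", "z")])
  dimnames(coords) <- NULL
  if (!any(beads$flexible)) return(coords)
  b0 <- topology$params$b_0
  dmin <- topology$params$sig_r / 2
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)

  rand_dir <- function() {
    v <- stats::rnorm(3)
    v / sqrt(sum(v^2))
  }
  placed <- which(!beads$flexible)

  for (ch in unique(beads$chain)) {
    idx <- which(beads$chain == ch)
    flex <- idx[beads$flexible[idx]]
    if (!length(flex)) next
    runs <- split(flex, cumsum(c(1, diff(flex) != 1)))
    for (run in runs) {
      lo <- min(run); hi <- max(run)
      before <- if ((lo - 1) %in% idx && !beads$flexible[lo - 1]) lo - 1 else NA
      after <- if ((hi + 1) %in% idx && !beads$flexible[hi + 1]) hi + 1 else NA
      # grow from the preceding anchor when there is one, else backwards
      # from the following anchor; a fully flexible chain grows from origin
      if (!is.na(before)) {
        order_run <- run; anchor <- before; target <- after
      } else if (!is.na(after)) {
        order_run <- rev(run); anchor <- after; target <- NA
      } else {
        order_run <- run; anchor <- NA; target <- NA
      }
      pos <- if (!is.na(anchor)) coords[anchor, ] else c(0, 0, 0)
      remaining <- length(order_run)
      for (b in order_run) {
        best <- NULL; best_clash <- Inf
        for (try in seq_len(max_retry)) {
          d <- rand_dir()
          if (!is.na(target)) {
            tv <- coords[target, ] - pos
            td <- sqrt(sum(tv^2))
            w <- min(2, max(0, td / (remaining * b0)))  # pull when taut
            d <- d + w * tv / max(td, 1e-9)
            d <- d / sqrt(sum(d^2))
          }
          cand <- pos + b0 * d
          clash <- if (length(placed))
            min(sqrt(colSums((t(coords[placed, , drop = FALSE]) - cand)^2)))
          else Inf
          if (clash >= dmin) { best <- cand; break }
          if (dmin - clash < best_clash) { best_clash <- dmin - clash; best <- cand }
        }
        if (is.null(best)) stop("initialize_flexible: placement failure")
        coords[b, ] <- best
        placed <- c(placed, b)
        pos <- best
        remaining <- remaining - 1
      }
    }
  }
  raw <- coords
  if (relax_steps > 0)
    coords <- relax_cpp(coords, .topo_cpp(topology), as.integer(relax_steps), 0.2)
  attr(coords, "unrelaxed") <- raw
  coords
}

#' Run Langevin dynamics on a coarse-grained topology
#'
#' BAOAB Langevin integration of the bead model at the configured
#' temperature, with optional stochastically switched cross-link restraints:
#' when `config$restraints` is non-empty, `n_c` restraints are active at any
#' time and re-drawn every `tau_xl` ps (both taken from the force-field
#' parameters).  With `friction = 0` the integrator reduces to velocity
#' Verlet (NVE).  The trajectory is fully determined by `config$seed`.
#'
#' @param topology a `cg_topology`.
#' @param config a [sim_config()].
#' @param coords optional starting coordinates; default
#'   [initialize_flexible()] from the derived seed.
#' @param schedule optional [restraint_schedule()]; built from the derived
#'   seed when restraints are present and no schedule is given.
#' @return An object of class `cg_ensemble`: list with `coords` (array
#'   `c(3, n_beads, n_frames)`), `time` (ps), `energy` (data frame with
#'   potential/kinetic energy per frame), `weights` (`NULL` until set),
#'   `topology`, `schedule`, and `config`.
#' @export
run_cg <- function(topology, config, coords = NULL, schedule = NULL) {
  p <- topology$params
  restr <- config$restraints
  n_steps <- round(config$total_time / config$timestep)
  save_every <- round(config$save_interval / config$timestep)

  if (is.null(coords))
    coords <- initialize_flexible(topology, seed = config$seed + 1L)
  coords <- as.matrix(coords)

  have_restr <- !is.null(restr) && nrow(restr) > 0
  if (have_restr && is.null(schedule))
    schedule <- restraint_schedule(nrow(restr), p$n_c, p$tau_xl,
                                   config$total_time, seed = config$seed + 2L)
  epochs <- if (have_restr) schedule$active else matrix(integer(), 0, 0)
  epoch_steps <- if (have_restr) max(1L, round(p$tau_xl / config$timestep)) else 1L

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  n <- nrow(coords)
  vel <- matrix(stats::rnorm(3 * n), n, 3) *
    sqrt(.kB * config$temperature * 418.4 / config$mass)

  out <- run_langevin_cpp(coords, vel, .topo_cpp(topology, restr),
                          config$timestep, as.integer(n_steps),
                          config$friction, config$mass,
                          .kB * config$temperature,
                          as.integer(save_every),
                          epochs, as.integer(epoch_steps))
  structure(list(coords = out$frames,
                 time = out$time,
                 energy = data.frame(time = out$time, potential = out$epot,
                                     kinetic = out$ekin),
                 weights = NULL,
                 topology = topology,
                 schedule = schedule,
                 config = config), class = "cg_ensemble")
}

#' Construct an ensemble from explicit frames
#'
#' @param frames list of n x 3 coordinate matrices.
#' @param topology optional `cg_topology`.
#' @param time optional frame times (ps).
#' @param weights optional non-negative per-frame weights (normalized to
#'   sum 1).
#' @return a `cg_ensemble`.
#' @export
cg_ensemble <- function(frames, topology = NULL, time = NULL, weights = NULL) {
  stopifnot(length(frames) >= 1)
  n <- nrow(frames[[1]])
  arr <- array(0, c(3, n, length(frames)))
  for (k in seq_along(frames)) {
    stopifnot(nrow(frames[[k]]) == n)
    arr[, , k] <- t(frames[[k]])
  }
  e <- structure(list(coords = arr,
                      time = if (is.null(time)) seq_along(frames) else time,
                      energy = NULL, weights = NULL, topology = topology,
                      schedule = NULL, config = NULL), class = "cg_ensemble")
  if (!is.null(weights)) e <- set_weights(e, weights)
  e
}

#' Number of frames / beads in an ensemble
#' @param ensemble a `cg_ensemble`.
#' @return integer.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[3]

#' @rdname n_frames
#' @export
n_beads <- function(ensemble) dim(ensemble$coords)[2]

#' Extract one frame as an n x 3 matrix
#' @param ensemble a `cg_ensemble`.
#' @param k frame index.
#' @return n x 3 coordinate matrix.
#' @export
frame_coords <- function(ensemble, k) t(ensemble$coords[, , k])

#' Attach per-frame weights to an ensemble
#' @param ensemble a `cg_ensemble`.
#' @param weights non-negative weights, one per frame (normalized to sum 1).
#' @return the ensemble with `weights` set.
#' @export
set_weights <- function(ensemble, weights) {
  stopifnot(length(weights) == n_frames(ensemble), all(weights >= 0),
            sum(weights) > 0)
  ensemble$weights <- weights / sum(weights)
  ensemble
}

.frame_weights <- function(ensemble) {
  if (is.null(ensemble$weights)) rep(1 / n_frames(ensemble), n_frames(ensemble))
  else ensemble$weights
}

#' @export
print.cg_ensemble <- function(x, ...) {
  cat(sprintf("CG ensemble: %d frames x %d beads%s%s\n", n_frames(x), n_beads(x),
              if (!is.null(x$time)) sprintf(", t = %g..%g ps", min(x$time), max(x$time)) else "",
              if (!is.null(x$weights)) ", weighted" else ""))
  invisible(x)
}

#' Radius of gyration of each frame
#'
#' @param ensemble a `cg_ensemble`.
#' @param beads optional bead subset (indices).
#' @return numeric vector, one Rg (A) per frame.
#' @export
ensemble_rg <- function(ensemble, beads = NULL) {
  if (is.null(beads)) beads <- seq_len(n_beads(ensemble))
  vapply(seq_len(n_frames(ensemble)), function(k) {
    xyz <- t(ensemble$coords[, beads, k, drop = FALSE][, , 1])
    c0 <- colMeans(xyz)
    sqrt(mean(rowSums(sweep(xyz, 2, c0)^2)))
  }, numeric(1))
}

#' Per-frame distance between two beads
#' @param ensemble a `cg_ensemble`.
#' @param i,j bead indices.
#' @return numeric vector of distances (A).
#' @export
bead_distance <- function(ensemble, i, j) {
  d <- ensemble$coords[, i, ] - ensemble$coords[, j, ]
  if (is.null(dim(d))) sqrt(sum(d^2)) else sqrt(colSums(d^2))
}

#' Write an ensemble as multi-model PDB plus per-frame CSV
#'
#' @param ensemble a `cg_ensemble` carrying its topology.
#' @param pdb_path,csv_path output paths (either may be `NULL` to skip).
#' @return invisibly, a list of the written paths.
#' @export
write_ensemble <- function(ensemble, pdb_path = NULL, csv_path = NULL) {
  if (!is.null(pdb_path)) {
    stopifnot(!is.null(ensemble$topology))
    write_ca_pdb(ensemble$coords, ensemble$topology$beads, pdb_path)
  }
  if (!is.null(csv_path)) {
    df <- data.frame(frame = seq_len(n_frames(ensemble)), time = ensemble$time)
    if (!is.null(ensemble$energy)) {
      df$potential <- ensemble$energy$potential
      df$kinetic <- ensemble$energy$kinetic
    }
    if (!is.null(ensemble$weights)) df$weight <- ensemble$weights
    utils::write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(list(pdb = pdb_path, csv = csv_path))
}
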