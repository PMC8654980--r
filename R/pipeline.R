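#' Per-region ensemble metrics
#'
#' Quantifies how much conformational space a region (e.g. a flexible tail
#' or disordered segment) explores relative to the rigid core: each frame is
#' superposed on the core beads, then the metrics are computed with the
#' ensemble's weights (uniform when none are set).
#'
#' @param ensemble a `cg_ensemble`.
#' @param region bead indices of the region of interest.
#' @param core bead indices of the reference core.
#' @param weights optional per-frame weights (overrides the ensemble's).
#' @param threshold contact distance for the region-to-core map, A.
#' @param rg_breaks histogram breaks for the region radius of gyration.
#' @return object of class `region_metrics`: list with `rmsf` (per region
#'   bead, A), `rg` (per-frame region Rg), `rg_hist` (weighted histogram,
#'   masses summing to 1), and `contact_map` (region x core frequency
#'   matrix).
#' @export
region_metrics <- function(ensemble, region, core, weights = NULL,
                           threshold = 25, rg_breaks = 20) {
  if (!length(region)) stop("region_metrics: empty region")
  if (length(core) < 3) stop("region_metrics: core needs at least 3 beads")
  if (!is.null(weights)) ensemble <- set_weights(ensemble, weights)
  w <- .frame_weights(ensemble)
  nf <- n_frames(ensemble)
  ref <- frame_coords(ensemble, 1)[core, , drop = FALSE]
  aligned <- array(0, c(nf, length(region), 3))
  rg <- numeric(nf)
  for (k in seq_len(nf)) {
    fc <- frame_coords(ensemble, k)
    sp <- superpose_coords(fc[core, , drop = FALSE], ref)
    fc <- apply_superposition(sp, fc)
    aligned[k, , ] <- fc[region, , drop = FALSE]
    xyz <- fc[region, , drop = FALSE]
    c0 <- colMeans(xyz)
    rg[k] <- sqrt(mean(rowSums(sweep(xyz, 2, c0)^2)))
  }
  mean_pos <- apply(aligned, c(2, 3), function(v) sum(v * w))
  rmsf <- sqrt(vapply(seq_along(region), function(b) {
    dev <- sweep(matrix(aligned[, b, ], ncol = 3), 2, mean_pos[b, ])
    sum(w * rowSums(dev^2))
  }, numeric(1)))
  h <- graphics::hist(rg, breaks = rg_breaks, plot = FALSE)
  mass <- vapply(seq_len(length(h$breaks) - 1), function(b)
    sum(w[rg >= h$breaks[b] & (rg < h$breaks[b + 1] |
                                 (b == length(h$breaks) - 1 & rg <= h$breaks[b + 1]))]),
    numeric(1))
  pairs <- expand.grid(i = region, j = core)
  pairs <- contact_frequency(ensemble, pairs, threshold)
  cmap <- matrix(pairs$frequency, nrow = length(region),
                 dimnames = list(region, core))
  structure(list(rmsf = stats::setNames(rmsf, region), rg = rg,
                 rg_hist = list(breaks = h$breaks, mass = mass),
                 contact_map = cmap, threshold = threshold),
            class = "region_metrics")
}

#' @export
print.region_metrics <- function(x, ...) {
  cat(sprintf("Region metrics: %d beads, mean RMSF %.2f A, mean region Rg %.2f A\n",
              length(x$rmsf), mean(x$rmsf), mean(x$rg)))
  invisible(x)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' End-to-end integrative modelling run
#'
#' Orchestrates build -> simulate (unconstrained and, when cross-links are
#' given, restrained) -> cross-link mapping -> SAXS reweighting -> region
#' metrics -> report.  Stages without inputs are skipped and logged.  All
#' randomness derives from `config$seed`; re-running with the same config
#' and seed reproduces every output byte for byte.
#'
#' @param config an R list (or path to a JSON file) with entries:
#'   `structure` (path, required), `crosslinks` (CSV path, optional),
#'   `saxs` (profile path, optional), `outdir` (required), `seed`
#'   (default 1), `ff` (named [ff_params()] overrides), `sim` (named
#'   [sim_config()] overrides: `total_time`, `save_interval`, ...),
#'   `analysis` (`score_cutoff`, `l_0`, `contact_threshold`, `fit_qmax`,
#'   `sparsity`, `guinier` window).
#' @return invisibly, the report list (also written as `report.json` with a
#'   `MANIFEST.json` of all artifacts and their checksums).
#' @export
run_integrative <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (is.null(config$structure)) stop("run_integrative: config$structure is required")
  if (is.null(config$outdir)) stop("run_integrative: config$outdir is required")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  an <- config$analysis
  get_an <- function(nm, default) if (is.null(an[[nm]])) default else an[[nm]]
  l_0 <- get_an("l_0", 25)
  score_cutoff <- get_an("score_cutoff", 40)
  cthr <- get_an("contact_threshold", 25)
  fit_qmax <- get_an("fit_qmax", 0.30)
  sparsity <- get_an("sparsity", 20)
  guinier_win <- get_an("guinier", c(0.015, 0.025))

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  log_lines <- character()
  logit <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  artifacts <- character()
  report <- list(seed = seed)
  report$config_hash <- unname(.hash_obj(config[setdiff(names(config), "outdir")]))

  for (p in c("structure", "crosslinks", "saxs"))
    if (!is.null(config[[p]]) && !file.exists(config[[p]]))
      stop("run_integrative: config$", p, " path does not exist: ", config[[p]])

  # --- build ---------------------------------------------------------------
  params <- do.call(ff_params, as.list(config$ff))
  topo <- .stage("build", {
    st <- read_structure(config$structure)
    build_topology(st, full_sequences = config$full_sequences,
                   params = params)
  })
  logit("build: %d beads (%d flexible), %d native contacts",
        nrow(topo$beads), sum(topo$beads$flexible), nrow(topo$contacts))
  write_topology_json(topo, out("topology.json"))
  artifacts <- c(artifacts, "topology.json")
  report$n_beads <- nrow(topo$beads)
  report$n_flexible <- sum(topo$beads$flexible)

  # --- cross-links ---------------------------------------------------------
  restr <- NULL
  if (!is.null(config$crosslinks)) {
    links <- .stage("xlmap", read_crosslinks(config$crosslinks,
                                             score_cutoff = score_cutoff))
    st <- read_structure(config$structure)
    mapping <- map_crosslinks(links, st, l_0 = l_0)
    write_xl_mapping(mapping, out("crosslinks_static.tsv"))
    artifacts <- c(artifacts, "crosslinks_static.tsv")
    restr <- restraints_from_links(topo, links)
    report$crosslinks <- c(list(n_records = nrow(links)), summary(mapping))
    logit("xlmap: %d records, %d mappable on the deposited model",
          nrow(links), attr(mapping, "n_mappable"))
  } else logit("xlmap: no cross-link table; stage skipped")

  # --- simulate ------------------------------------------------------------
  simcfg <- as.list(config$sim)
  if (is.null(simcfg$total_time)) simcfg$total_time <- 1000
  mkcfg <- function(seed_off, restraints) {
    do.call(sim_config, c(simcfg, list(seed = seed + seed_off,
                                       restraints = restraints)))
  }
  ens_u <- .stage("simulate", run_cg(topo, mkcfg(0L, NULL)))
  write_ensemble(ens_u, out("ensemble_unconstrained.pdb"),
                 out("ensemble_unconstrained.csv"))
  artifacts <- c(artifacts, "ensemble_unconstrained.pdb",
                 "ensemble_unconstrained.csv")
  logit("simulate: unconstrained, %d frames", n_frames(ens_u))
  ens_r <- NULL
  if (!is.null(restr) && nrow(restr) > 0) {
    ens_r <- .stage("simulate", run_cg(topo, mkcfg(1L, restr)))
    write_ensemble(ens_r, out("ensemble_restrained.pdb"),
                   out("ensemble_restrained.csv"))
    artifacts <- c(artifacts, "ensemble_restrained.pdb",
                   "ensemble_restrained.csv")
    logit("simulate: restrained against %d cross-links, %d frames",
          nrow(restr), n_frames(ens_r))
    sat_u <- satisfaction_fraction(ens_u, restr, l_0)
    sat_r <- satisfaction_fraction(ens_r, restr, l_0)
    freq_u <- contact_frequency(ens_u, restr, cthr)
    freq_r <- contact_frequency(ens_r, restr, cthr)
    cmp <- compare_ensembles(freq_r, freq_u)
    report$restraints <- list(
      n = nrow(restr), satisfaction_unconstrained = sat_u,
      satisfaction_restrained = sat_r,
      mean_frequency_unconstrained = mean(freq_u$frequency),
      mean_frequency_restrained = mean(freq_r$frequency))
    utils::write.csv(cmp$aligned, out("contact_frequency_comparison.csv"),
                     row.names = FALSE)
    artifacts <- c(artifacts, "contact_frequency_comparison.csv")
  }

  # --- SAXS ----------------------------------------------------------------
  if (!is.null(config$saxs)) {
    fit_ens <- if (!is.null(ens_r)) ens_r else ens_u
    fit <- .stage("saxsfit", {
      prof <- read_saxs(config$saxs)
      sel <- prof$q > 0 & prof$q < fit_qmax
      prof <- prof[sel, , drop = FALSE]
      if (is.null(prof$sigma)) prof$sigma <- 0.01 * prof$I
      icalc <- ensemble_profiles(fit_ens, prof$q)
      fit_saxs_weights(icalc, prof$I, prof$sigma, sparsity = sparsity,
                       q = prof$q)
    })
    logit("saxsfit: chi %.4g (uniform %.4g), %d conformers in support",
          fit$chi, fit$chi_uniform, length(fit$support))
    gn <- tryCatch(guinier_rg(saxs_profile(fit$q, fit$i_exp, fit$sigma),
                              guinier_win[1], guinier_win[2]),
                   error = function(e) NULL)
    jsonlite::write_json(
      list(weights = fit$weights, alpha = fit$alpha, chi = fit$chi,
           chi_uniform = fit$chi_uniform, support = fit$support,
           variant = fit$alpha_variant, q_range = range(fit$q),
           guinier_rg = if (!is.null(gn)) gn$rg else NULL),
      out("saxs_fit.json"), digits = NA, auto_unbox = TRUE)
    artifacts <- c(artifacts, "saxs_fit.json")
    report$saxs <- list(chi = fit$chi, chi_uniform = fit$chi_uniform,
                        alpha = fit$alpha, n_support = length(fit$support),
                        guinier_rg = if (!is.null(gn)) gn$rg else NA)
    fit_ens <- set_weights(fit_ens, fit$weights)
    if (!is.null(ens_r)) ens_r <- fit_ens else ens_u <- fit_ens
  } else logit("saxsfit: no SAXS profile; stage skipped")

  # --- region metrics ------------------------------------------------------
  flex <- which(topo$beads$flexible)
  rigid <- which(!topo$beads$flexible)
  if (length(flex) && length(rigid) >= 3) {
    best <- if (!is.null(ens_r)) ens_r else ens_u
    rm <- .stage("metrics", region_metrics(best, flex, rigid, threshold = cthr))
    report$region <- list(mean_rmsf = mean(rm$rmsf),
                          mean_region_rg = sum(.frame_weights(best) * rm$rg))
    logit("metrics: flexible-region mean RMSF %.2f A", mean(rm$rmsf))
  }

  # --- report + manifest ---------------------------------------------------
  jsonlite::write_json(report, out("report.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, out("run.log"))
  artifacts <- c(artifacts, "report.json", "run.log")
  manifest <- list(seed = seed, config_hash = report$config_hash,
                   complete = TRUE,
                   files = lapply(artifacts, function(f)
                     list(file = f, md5 = unname(tools::md5sum(out(f))))))
  jsonlite::write_json(manifest, out("MANIFEST.json"), digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}

.hash_obj <- function(obj) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  tools::md5sum(tf)
}
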