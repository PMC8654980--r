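#' Read / write a three-column SAXS profile
#'
#' Plain ASCII with columns q (1/A), I(q), and optionally sigma(q);
#' whitespace or comma separated, `#` comments ignored.
#'
#' @param path input file.
#' @return object of class `saxs_profile`: data frame with columns `q`, `I`
#'   and (if present) `sigma`.
#' @export
read_saxs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(trimws(lines), "[,[:space:]]+")
  nc <- min(lengths(parts))
  if (nc < 2) stop("read_saxs: need at least two columns (q, I)")
  m <- t(vapply(parts, function(p) as.numeric(p[seq_len(min(nc, 3))]),
                numeric(min(nc, 3))))
  df <- data.frame(q = m[, 1], I = m[, 2])
  if (ncol(m) >= 3) df$sigma <- m[, 3]
  saxs_profile(df$q, df$I, df$sigma)
}

#' @rdname read_saxs
#' @param profile a `saxs_profile`.
#' @export
write_saxs <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# q I sigma", con)
  sig <- if (is.null(profile$sigma)) rep(NA, nrow(profile)) else profile$sigma
  writeLines(sprintf("%.8g %.10g %.10g", profile$q, profile$I, sig), con)
  invisible(path)
}

#' Construct a SAXS profile object
#'
#' @param q scattering vector grid, 1/A, strictly increasing, `>= 0`.
#' @param I intensities (arbitrary units).
#' @param sigma optional experimental errors (same units as `I`).
#' @return class `saxs_profile` (a data frame).
#' @export
saxs_profile <- function(q, I, sigma = NULL) {
  stopifnot(length(q) == length(I), all(is.finite(q)), all(q >= 0),
            all(diff(q) > 0))
  df <- data.frame(q = q, I = I)
  if (!is.null(sigma) && !all(is.na(sigma))) {
    stopifnot(length(sigma) == length(q))
    df$sigma <- sigma
  }
  class(df) <- c("saxs_profile", "data.frame")
  df
}

#' Debye-formula scattering profile of a bead model
#'
#' `I(q) = f^2 sum_ij sin(q r_ij) / (q r_ij)` over all bead pairs (self
#' terms included), with a uniform per-bead form factor `f`, so
#' `I(0) = (N f)^2`.  This is the coarse-grained stand-in for an atomic
#' profile calculator: absolute intensities carry no excluded-volume or
#' hydration terms, and the supported uses are relative -- ensemble
#' averaging, weight fitting, chi ranking, and Rg extraction.
#'
#' @param coords n x 3 bead coordinates (A), or a `cg_ensemble` frame via
#'   [frame_coords()].
#' @param q_grid scattering vector grid (1/A).
#' @param f per-bead form factor (default 1).
#' @return a [saxs_profile()] (no `sigma`).
#' @export
debye_profile <- function(coords, q_grid, f = 1) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1) stop("debye_profile: empty coordinates")
  stopifnot(ncol(coords) == 3)
  saxs_profile(q_grid, as.numeric(debye_profile_cpp(coords, q_grid, f)))
}

#' Matrix of per-frame Debye profiles of an ensemble
#'
#' @param ensemble a `cg_ensemble`.
#' @param q_grid scattering vector grid (1/A).
#' @param f per-bead form factor.
#' @return matrix `length(q_grid) x n_frames`, one profile per column.
#' @export
ensemble_profiles <- function(ensemble, q_grid, f = 1) {
  vapply(seq_len(n_frames(ensemble)), function(k)
    as.numeric(debye_profile_cpp(frame_coords(ensemble, k), q_grid, f)),
    numeric(length(q_grid)))
}

#' Guinier fit
#'
#' Linear fit of `ln I` against `q^2` inside the window, giving
#' `R_g = sqrt(-3 slope)` and `I(0) = exp(intercept)`.  The default window
#' 0.015 < q < 0.025 1/A is the low-q range appropriate for a particle of
#' this size class.
#'
#' @param profile a `saxs_profile`.
#' @param q_min,q_max Guinier window bounds (1/A).
#' @return list with `rg` (A), `i0`, `n` (points used), `window`.
#' @export
guinier_rg <- function(profile, q_min = 0.015, q_max = 0.025) {
  sel <- profile$q > q_min & profile$q < q_max & profile$I > 0
  if (sum(sel) < 3)
    stop("guinier_rg: fewer than 3 positive points in the Guinier window")
  fit <- stats::lm(log(I) ~ I(q^2), data = profile[sel, ])
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0 || -slope < 1e-10)
    stop("guinier_rg: non-negative (or numerically flat) Guinier slope; ",
         "profile is not Guinier-like in this window")
  list(rg = sqrt(-3 * slope), i0 = exp(unname(stats::coef(fit)[1])),
       n = sum(sel), window = c(q_min, q_max))
}

#' Dimensionless Kratky transform
#'
#' @param profile a `saxs_profile`.
#' @param rg radius of gyration (A).
#' @param i0 forward scattering.
#' @return data frame with `x = q Rg` and `y = (q Rg)^2 I(q) / I(0)`.
#' @export
kratky_dimensionless <- function(profile, rg, i0) {
  stopifnot(rg > 0, i0 > 0)
  x <- profile$q * rg
  data.frame(x = x, y = x^2 * profile$I / i0)
}

#' Pair distance distribution P(r) by regularized indirect Fourier transform
#'
#' Inverts `I(q) = 4 pi int P(r) sinc(q r) dr` on `[0, D_max]` with
#' non-negative P(r), clamped endpoints (`P(0) = P(D_max) = 0`) and a
#' second-derivative (smoothness) Tikhonov penalty; the regularization
#' parameter is picked on an L-curve (corner of maximum curvature) unless
#' given.  Residuals are sigma-weighted when the profile has errors.
#'
#' @param profile a `saxs_profile` (with `sigma` when available).
#' @param d_max maximum particle dimension, A.
#' @param n_r real-space grid size.
#' @param lambda optional fixed regularization parameter.
#' @param normalize if `TRUE`, scale so `int P(r) dr = 1`.
#' @param baseline if `TRUE` (default) fit an additional non-negative flat
#'   baseline alongside P(r).  This absorbs q-independent scattering (for
#'   point-bead Debye profiles, the self-term `N f^2`), the analogue of the
#'   constant subtraction offered by standard indirect-transform programs;
#'   without it that component aliases into P(r) near r = 0.
#' @param chi_warn warn when the forward-model fit quality (reduced chi on
#'   sigma-weighted residuals, or relative residual otherwise) exceeds this.
#' @return object of class `pr_function`: list with `r`, `pr`, `d_max`,
#'   `lambda`, `chi` (forward residual), and `rg` (real-space radius of
#'   gyration from P(r)).
#' @export
pr_function <- function(profile, d_max, n_r = 101, lambda = NULL,
                        normalize = FALSE, baseline = TRUE, chi_warn = 5) {
  stopifnot(d_max > 0, n_r >= 10)
  q <- profile$q
  I <- profile$I
  sig <- if (!is.null(profile$sigma)) profile$sigma else rep(1, length(q))
  stopifnot(all(sig > 0))
  r <- seq(0, d_max, length.out = n_r)
  dr <- r[2] - r[1]
  # design matrix on interior points (endpoints clamped to zero)
  ri <- r[2:(n_r - 1)]
  A <- outer(q, ri, function(qq, rr) {
    qr <- qq * rr
    s <- ifelse(qr < 1e-12, 1, sin(qr) / qr)
    4 * pi * s * dr
  })
  if (baseline) A <- cbind(A, 1)
  Aw <- A / sig
  bw <- I / sig
  m <- length(ri)
  ncol_fit <- ncol(A)
  D2 <- diag(-2, m)
  D2[cbind(1:(m - 1), 2:m)] <- 1
  D2[cbind(2:m, 1:(m - 1))] <- 1
  D2 <- D2 / dr^2
  D2f <- cbind(D2, matrix(0, m, ncol_fit - m))  # baseline not smoothed

  solve_l <- function(l) {
    M <- rbind(Aw, sqrt(l) * D2f)
    rhs <- c(bw, rep(0, m))
    sol <- pracma::lsqnonneg(M, rhs)$x
    p <- sol[seq_len(m)]
    res <- sqrt(mean((Aw %*% sol - bw)^2))
    pen <- sqrt(sum((D2 %*% p)^2))
    list(p = p, base = if (baseline) sol[ncol_fit] else 0,
         res = res, pen = pen)
  }

  if (is.null(lambda)) {
    lams <- 10^seq(-8, 2, length.out = 12) * dr^4
    fits <- lapply(lams, function(l) tryCatch(solve_l(l), error = function(e) NULL))
    ok <- !vapply(fits, is.null, logical(1))
    if (!any(ok)) stop("pr_function: non-negative least squares failed at every ",
                       "regularization level; try a smaller n_r")
    lams <- lams[ok]; fits <- fits[ok]
    if (length(lams) < 3) {
      best <- length(lams); lambda <- lams[best]; fit <- fits[[best]]
    } else {
    lr <- log(vapply(fits, `[[`, numeric(1), "res"))
    lp <- log(pmax(vapply(fits, `[[`, numeric(1), "pen"), 1e-300))
    # discrete curvature of the L-curve; fall back to mid-grid if flat
    k <- rep(-Inf, length(lams))
    for (ii in 2:(length(lams) - 1)) {
      x1 <- lr[ii] - lr[ii - 1]; y1 <- lp[ii] - lp[ii - 1]
      x2 <- lr[ii + 1] - lr[ii]; y2 <- lp[ii + 1] - lp[ii]
      k[ii] <- (x1 * y2 - y1 * x2) /
        max((sqrt(x1^2 + y1^2) * sqrt(x2^2 + y2^2)), 1e-300)
    }
    best <- which.max(k)
    if (!is.finite(k[best])) best <- ceiling(length(lams) / 2)
    lambda <- lams[best]
    fit <- fits[[best]]
    }
  } else {
    fit <- solve_l(lambda)
  }
  pr <- c(0, fit$p, 0)
  chi <- fit$res
  if (is.finite(chi_warn) && chi > chi_warn)
    warning(sprintf(
      "pr_function: poor forward fit (residual %.3g); d_max = %g may be too small",
      chi, d_max))
  norm <- sum(pr) * dr
  rg <- if (norm > 0) sqrt(sum(r^2 * pr) / (2 * sum(pr))) else NA_real_
  if (normalize && norm > 0) pr <- pr / norm
  structure(list(r = r, pr = pr, d_max = d_max, lambda = lambda,
                 baseline = fit$base, chi = chi, rg = rg),
            class = "pr_function")
}

#' @export
print.pr_function <- function(x, ...) {
  cat(sprintf("P(r): d_max = %g A, real-space Rg = %.2f A, peak at r = %.1f A, forward residual %.3g\n",
              x$d_max, x$rg, x$r[which.max(x$pr)], x$chi))
  invisible(x)
}

#' Profile scale factor between experiment and model
#'
#' Two variants of the scalar scale `alpha` applied to the model average:
#' `as_printed` is `sum(I_exp I_avrg) / sum(I_exp I_exp)`; `least_squares`
#' is `sum(I_exp I_avrg) / sum(I_avrg I_avrg)`, the minimizer of the
#' unweighted residual.  The two coincide only when `I_avrg = I_exp`; both
#' are kept deliberately (neither is silently "corrected" to the other).
#'
#' @param i_exp,i_avrg equal-length intensity vectors.
#' @param variant `"as_printed"` (default) or `"least_squares"`.
#' @return the scalar scale factor.
#' @export
scale_alpha <- function(i_exp, i_avrg, variant = c("as_printed", "least_squares")) {
  variant <- match.arg(variant)
  stopifnot(length(i_exp) == length(i_avrg))
  num <- sum(i_exp * i_avrg)
  den <- if (variant == "as_printed") sum(i_exp * i_exp) else sum(i_avrg * i_avrg)
  if (den == 0) stop("scale_alpha: zero denominator")
  num / den
}

#' Goodness of fit between scaled model average and experiment
#'
#' `chi = sqrt( (1/N_q) sum_i ((I_exp(q_i) - alpha I_avrg(q_i)) / sigma(q_i))^2 )`
#'
#' @param i_exp,i_avrg,sigma equal-length vectors; `sigma > 0`.
#' @param alpha scale factor (see [scale_alpha()]).
#' @return the chi value (dimensionless, `>= 0`).
#' @export
chi_saxs <- function(i_exp, i_avrg, sigma, alpha = 1) {
  stopifnot(length(i_exp) == length(i_avrg), length(sigma) == length(i_exp),
            all(sigma > 0))
  sqrt(mean(((i_exp - alpha * i_avrg) / sigma)^2))
}

#' Fit sparse non-negative ensemble weights to a SAXS profile
#'
#' Finds per-conformer weights `w_k >= 0`, `sum w_k = 1`, such that the
#' scaled ensemble average `alpha sum_k w_k I_calc_k(q)` matches the
#' experimental profile, by sigma-weighted non-negative least squares
#' followed by iterative support pruning to at most `sparsity` non-zero
#' weights (a sparse-ensemble-selection style fit: the stated objective --
#' a small set of non-negative weights minimizing the discrepancy -- without
#' any particular published search heuristic).  The overall scale is
#' absorbed by the fit and re-expressed through [scale_alpha()].
#'
#' @param i_calc matrix `N_q x N_ens` of per-conformer profiles on the
#'   experimental q grid.
#' @param i_exp experimental intensities, length `N_q`.
#' @param sigma experimental errors, length `N_q` (`> 0`).
#' @param sparsity maximum number of non-zero weights (default: no limit).
#' @param alpha_variant variant used to report `alpha` and `chi`
#'   (see [scale_alpha()]).
#' @param q optional q grid, kept for reporting.
#' @return An object of class `saxs_fit` with components `weights`, `alpha`,
#'   `chi`, `i_avrg`, `chi_uniform`, `support` (indices of non-zero
#'   weights), plus the inputs needed by its methods.  Methods: `print`,
#'   `summary`, `coef` (the weights), `predict` (the scaled fitted profile),
#'   `residuals` (sigma-weighted), `plot`.
#' @examples
#' q <- seq(0.01, 0.3, by = 0.01)
#' a <- exp(-q^2 * 400); b <- exp(-q^2 * 900)
#' iexp <- 0.6 * a + 0.4 * b
#' fit <- fit_saxs_weights(cbind(a, b), iexp, sigma = 0.01 * iexp)
#' coef(fit)  # ~ (0.6, 0.4)
#' @export
fit_saxs_weights <- function(i_calc, i_exp, sigma, sparsity = Inf,
                             alpha_variant = c("as_printed", "least_squares"),
                             q = NULL) {
  alpha_variant <- match.arg(alpha_variant)
  i_calc <- as.matrix(i_calc)
  nq <- nrow(i_calc); nens <- ncol(i_calc)
  stopifnot(length(i_exp) == nq, length(sigma) == nq, all(sigma > 0))
  if (!is.null(q) && length(q) != nq)
    stop("fit_saxs_weights: q grid length does not match the profiles")

  Aw <- i_calc / sigma
  bw <- i_exp / sigma

  nnls_support <- function(sup) {
    v <- rep(0, nens)
    if (length(sup) == 1) {
      a <- Aw[, sup]
      v[sup] <- max(0, sum(a * bw) / sum(a * a))
    } else {
      v[sup] <- pracma::lsqnonneg(Aw[, sup, drop = FALSE], bw)$x
    }
    v
  }

  sup <- seq_len(nens)
  v <- nnls_support(sup)
  # prune to the requested support size, refitting each time
  while (sum(v > 0) > sparsity) {
    keep <- order(v, decreasing = TRUE)[seq_len(max(1, min(sparsity, sum(v > 0) - 1)))]
    v <- nnls_support(sort(keep))
  }
  if (sum(v) == 0) {             # degenerate: fall back to best single conformer
    chis <- apply(Aw, 2, function(a) {
      al <- sum(a * bw) / sum(a * a)
      sqrt(mean((bw - al * a)^2))
    })
    v[which.min(chis)] <- 1
  }
  w <- v / sum(v)
  i_avrg <- as.numeric(i_calc %*% w)
  alpha <- scale_alpha(i_exp, i_avrg, alpha_variant)
  chi <- chi_saxs(i_exp, i_avrg, sigma, alpha)
  w_u <- rep(1 / nens, nens)
  i_u <- as.numeric(i_calc %*% w_u)
  chi_u <- chi_saxs(i_exp, i_u, sigma, scale_alpha(i_exp, i_u, alpha_variant))

  structure(list(weights = w, alpha = alpha, chi = chi, i_avrg = i_avrg,
                 chi_uniform = chi_u, support = which(w > 0),
                 alpha_variant = alpha_variant, q = q, i_exp = i_exp,
                 sigma = sigma, n_ens = nens, sparsity = sparsity),
            class = "saxs_fit")
}

#' @export
print.saxs_fit <- function(x, ...) {
  cat(sprintf("SAXS ensemble fit: %d conformers, %d in support, chi = %.4g (uniform %.4g), alpha = %.4g [%s]\n",
              x$n_ens, length(x$support), x$chi, x$chi_uniform, x$alpha,
              x$alpha_variant))
  invisible(x)
}

#' @export
summary.saxs_fit <- function(object, ...) {
  w <- object$weights[object$support]
  cat(sprintf("Sparse SAXS ensemble fit over %d conformers (sparsity limit %s)\n",
              object$n_ens, format(object$sparsity)))
  cat(sprintf("  chi = %.5g  (uniform-weight chi = %.5g)\n",
              object$chi, object$chi_uniform))
  cat(sprintf("  alpha = %.5g  [%s]\n", object$alpha, object$alpha_variant))
  cat("  support:\n")
  for (k in order(w, decreasing = TRUE))
    cat(sprintf("    conformer %d: w = %.4f\n", object$support[k], w[k]))
  invisible(object)
}

#' @export
coef.saxs_fit <- function(object, ...) object$weights

#' @export
predict.saxs_fit <- function(object, ...) object$alpha * object$i_avrg

#' @export
residuals.saxs_fit <- function(object, ...) {
  (object$i_exp - object$alpha * object$i_avrg) / object$sigma
}

#' @export
plot.saxs_fit <- function(x, ...) {
  q <- if (!is.null(x$q)) x$q else seq_along(x$i_exp)
  graphics::plot(q, x$i_exp, log = "y", pch = 16, cex = 0.5,
                 xlab = "q (1/A)", ylab = "I(q)", ...)
  graphics::lines(q, x$alpha * x$i_avrg, col = 2, lwd = 2)
  graphics::legend("topright", c("experiment", "fitted ensemble"),
                   pch = c(16, NA), lty = c(NA, 1), col = c(1, 2), bty = "n")
  invisible(x)
}
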