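sphere_grid <- function(R = 30, spacing = 4.2) {
  g <- seq(-R, R, by = spacing)
  pts <- as.matrix(expand.grid(g, g, g))
  pts[rowSums(pts^2) <= R^2, ]
}

test_that("Debye limits: single bead, sinc zero, forward intensity", {
  q <- seq(0, 0.5, by = 0.01)
  one <- debye_profile(matrix(0, 1, 3), q)
  expect_true(all(one$I == 1))                       # f^2, no interference
  d <- 20
  two <- debye_profile(rbind(c(0, 0, 0), c(0, 0, d)), pi / d)
  expect_equal(two$I, 2, tolerance = 1e-12)          # 2 + 2 sinc(pi) = 2
  n <- 17
  set.seed(4)
  cloud <- matrix(rnorm(3 * n, sd = 10), n, 3)
  expect_equal(debye_profile(cloud, 0)$I, n^2)       # I(0) = (N f)^2
  expect_equal(debye_profile(cloud, 0, f = 2)$I, (2 * n)^2)
  expect_error(debye_profile(cloud[0, , drop = FALSE], q), "empty")
})

test_that("Debye profiles are invariant under rigid motion", {
  set.seed(9)
  x <- matrix(rnorm(60, sd = 12), 20, 3)
  q <- seq(0.005, 0.4, by = 0.005)
  i1 <- debye_profile(x, q)$I
  ax <- rand_unit(); th <- 1.1
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  i2 <- debye_profile(sweep(x %*% t(R), 2, c(5, -40, 13), "+"), q)$I
  expect_lt(max(abs(i2 - i1) / i1), 1e-10)
})

test_that("Guinier fit of a uniform bead sphere recovers R sqrt(3/5)", {
  R <- 30
  pts <- sphere_grid(R)
  prof <- debye_profile(pts, seq(0.004, 0.05, by = 0.001))
  gn <- guinier_rg(prof)
  expect_lt(abs(gn$rg - R * sqrt(3 / 5)) / (R * sqrt(3 / 5)), 0.03)
  expect_equal(gn$i0, nrow(pts)^2, tolerance = 0.005)   # Guinier I0 vs (N f)^2
})

test_that("Guinier inversion is exact on an exact Guinier curve", {
  q <- seq(0.001, 0.05, length.out = 80)
  prof <- saxs_profile(q, 7 * exp(-q^2 * 40^2 / 3))
  gn <- guinier_rg(prof, 0, 0.05)
  expect_equal(gn$rg, 40, tolerance = 1e-9)
  expect_equal(gn$i0, 7, tolerance = 1e-9)

  # 1% multiplicative noise, 50 points in the window: Rg within +- 1 A
  set.seed(12)
  errs <- replicate(20, {
    noisy <- saxs_profile(q, prof$I * (1 + rnorm(length(q), 0, 0.01)))
    guinier_rg(noisy, 0, 0.05)$rg - 40
  })
  expect_lt(max(abs(errs)), 1)

  flat <- saxs_profile(q, rep(3, length(q)))
  expect_error(guinier_rg(flat, 0, 0.05), "not Guinier")
  expect_error(guinier_rg(prof, 0.015, 0.0155), "fewer than 3")
})

test_that("dimensionless Kratky transform has its closed-form anchors", {
  q <- seq(0, 0.2, length.out = 801)
  prof <- saxs_profile(q, 7 * exp(-q^2 * 40^2 / 3))
  k <- kratky_dimensionless(prof, 40, 7)
  expect_equal(k$y[1], 0)                             # ordinate 0 at q = 0
  expect_equal(k$y[which.min(abs(k$x - sqrt(3)))], 3 * exp(-1), tolerance = 1e-4)
  k2 <- kratky_dimensionless(saxs_profile(q, 5 * prof$I), 40, 5 * 7)
  expect_equal(k2$y, k$y)                             # scale invariance
})

test_that("P(r) inversion recovers pair geometry and normalizes", {
  d <- 12
  q <- seq(0.005, 0.8, by = 0.005)
  prof <- debye_profile(rbind(c(0, 0, 0), c(0, 0, d)), q)
  prof$sigma <- 0.01 * prof$I + 1e-4
  pr <- pr_function(prof, d_max = 20, n_r = 81)
  expect_lt(abs(pr$r[which.max(pr$pr)] - d), 0.3)  # within one grid step
  expect_true(all(pr$pr >= 0))
  expect_equal(pr$pr[1], 0)
  expect_equal(pr$pr[length(pr$pr)], 0)

  prn <- pr_function(prof, d_max = 20, n_r = 81, normalize = TRUE)
  dr <- prn$r[2] - prn$r[1]
  expect_equal(sum(prn$pr) * dr, 1, tolerance = 1e-9)
})

test_that("real-space Rg from P(r) agrees with the Guinier Rg for a sphere", {
  pts <- sphere_grid(30)
  q <- seq(0.004, 0.12, by = 0.002)
  prof <- debye_profile(pts, q)
  prof$sigma <- 0.01 * prof$I + 1e-6
  gn <- guinier_rg(prof)
  pr <- pr_function(prof, d_max = 65, n_r = 81)
  expect_lt(abs(pr$rg - gn$rg) / gn$rg, 0.05)
})

test_that("both printed scale-factor variants evaluate as written", {
  expect_equal(scale_alpha(c(1, 2), c(1, 2)), 1)
  expect_equal(scale_alpha(c(1, 2), c(1, 2), "least_squares"), 1)
  # hand case where the two deliberately disagree
  expect_equal(scale_alpha(c(4, 2), c(2, 1), "as_printed"), 10 / 20)
  expect_equal(scale_alpha(c(4, 2), c(2, 1), "least_squares"), 10 / 5)
  # homogeneity of the printed form: alpha(c I_exp) = alpha(I_exp) / c
  i1 <- c(3, 1, 4); i2 <- c(2, 7, 1)
  expect_equal(scale_alpha(5 * i1, i2), scale_alpha(i1, i2) / 5)
  expect_error(scale_alpha(c(0, 0), c(1, 1)), "zero denominator")
})

test_that("chi reproduces its printed form and scalings", {
  expect_equal(chi_saxs(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1), alpha = 1), 0)
  expect_equal(chi_saxs(c(3, 3), c(1, 1), c(1, 1), alpha = 2), 1)
  set.seed(3)
  ie <- runif(10, 1, 2); ia <- runif(10, 1, 2); s <- runif(10, 0.1, 0.2)
  expect_equal(chi_saxs(ie, ia, 2 * s), chi_saxs(ie, ia, s) / 2)
  expect_gte(chi_saxs(ie, ia, s), 0)
})

test_that("weight fitting: forced single conformer and noiseless exactness", {
  q <- seq(0.01, 0.3, by = 0.005)
  a <- exp(-q^2 * 400)
  fit1 <- fit_saxs_weights(cbind(a), 2 * a, sigma = 0.01 * a, q = q)
  expect_equal(coef(fit1), 1)

  b <- exp(-q^2 * 900); c3 <- exp(-q^2 * 400) * (1 + sin(20 * q) / 5)
  icalc <- cbind(a, b, c3)
  w <- c(0.6, 0.3, 0.1)
  iexp <- as.numeric(icalc %*% w)
  fit <- fit_saxs_weights(icalc, iexp, sigma = rep(1, length(q)), q = q)
  expect_equal(coef(fit), w, tolerance = 1e-6)
  expect_equal(fit$chi, 0, tolerance = 1e-8)
  expect_equal(fit$alpha, 1, tolerance = 1e-8)
  expect_equal(predict(fit), iexp, tolerance = 1e-8)
  expect_equal(as.numeric(residuals(fit)), rep(0, length(q)), tolerance = 1e-7)
})

test_that("weight fitting never does worse than uniform weights", {
  set.seed(21)
  q <- seq(0.01, 0.3, by = 0.01)
  for (rep in 1:5) {
    icalc <- sapply(1:6, function(k) exp(-q^2 * runif(1, 200, 1200)))
    iexp <- as.numeric(icalc %*% (stats::runif(6) |> (\(x) x / sum(x))())) *
      (1 + rnorm(length(q), 0, 0.02))
    fit <- fit_saxs_weights(icalc, iexp, sigma = 0.02 * iexp, q = q)
    expect_lte(fit$chi, fit$chi_uniform + 1e-9)
    expect_gte(min(coef(fit)), 0)
    expect_equal(sum(coef(fit)), 1, tolerance = 1e-9)
  }
})

test_that("sparsity pruning caps the support and refits", {
  set.seed(5)
  q <- seq(0.01, 0.3, by = 0.01)
  icalc <- sapply(1:12, function(k) exp(-q^2 * (150 + 90 * k)))
  iexp <- as.numeric(icalc %*% rep(1 / 12, 12))
  fit <- fit_saxs_weights(icalc, iexp, sigma = 0.01 * iexp, sparsity = 3, q = q)
  expect_lte(length(fit$support), 3)
  expect_equal(sum(coef(fit)), 1, tolerance = 1e-9)
})

test_that("SAXS ASCII profiles round-trip including comments", {
  q <- seq(0.01, 0.1, by = 0.01)
  prof <- saxs_profile(q, exp(-q^2 * 300), 0.01 * exp(-q^2 * 300))
  f <- withr::local_tempfile(fileext = ".dat")
  write_saxs(prof, f)
  p2 <- read_saxs(f)
  expect_equal(p2$q, prof$q, tolerance = 1e-7)
  expect_equal(p2$I, prof$I, tolerance = 1e-9)
  expect_equal(p2$sigma, prof$sigma, tolerance = 1e-9)
})
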