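p0 <- ff_params()

test_that("printed closed forms are reproduced exactly", {
  expect_equal(as.numeric(bond_energy(3.8, p0)), 0)
  expect_equal(as.numeric(bond_energy(4.8, p0)), 50)          # 50 * 1^2
  expect_equal(as.numeric(angle_energy(p0$a_0, p0)), 0)
  expect_equal(as.numeric(angle_energy(p0$a_0 + 0.5, p0)), 0.4375)  # 1.75 * 0.25
  expect_equal(as.numeric(repulsive_energy(4, p0)), 2)        # r = sigma_R
  expect_equal(as.numeric(repulsive_energy(8, p0)), 2 / 4096) # (1/2)^12
  expect_equal(as.numeric(restraint_energy(25, p0)), 5)       # K_XL / 2 at l_0
  expect_equal(as.numeric(restraint_energy(0, p0)),
               10 / (1 + exp(12.5)), tolerance = 1e-12)       # ~3.7e-5
})

test_that("scalar derivatives match central finite differences", {
  h <- 1e-6
  fd <- function(f, x) (as.numeric(f(x + h)) - as.numeric(f(x - h))) / (2 * h)
  expect_equal(attr(bond_energy(4.3, p0), "deriv"),
               fd(function(x) bond_energy(x, p0), 4.3), tolerance = 1e-6)
  expect_equal(attr(angle_energy(1.3, p0), "deriv"),
               fd(function(x) angle_energy(x, p0), 1.3), tolerance = 1e-6)
  expect_equal(attr(repulsive_energy(4.5, p0), "deriv"),
               fd(function(x) repulsive_energy(x, p0), 4.5), tolerance = 1e-4)
  expect_equal(attr(restraint_energy(30, p0), "deriv"),
               fd(function(x) restraint_energy(x, p0), 30), tolerance = 1e-8)
  expect_equal(attr(go_contact_energy(5.5, 5, p0), "deriv"),
               fd(function(x) go_contact_energy(x, 5, p0), 5.5),
               tolerance = 1e-5)
})

test_that("repulsion is monotone decreasing and singular only at zero", {
  r <- seq(3, 12, by = 0.25)
  v <- as.numeric(repulsive_energy(r, p0))
  expect_true(all(diff(v) < 0))
  expect_error(repulsive_energy(0, p0), "singular")
})

test_that("native-contact well has its minimum at the reference distance", {
  r0 <- 6.2
  expect_equal(as.numeric(go_contact_energy(r0, r0, p0)), -p0$go_epsilon)
  expect_equal(attr(go_contact_energy(r0, r0, p0), "deriv"), 0, tolerance = 1e-12)
  expect_lt(abs(as.numeric(go_contact_energy(5 * r0, r0, p0))), 1e-3)
  # below-minimum value everywhere else
  r <- seq(4, 30, by = 0.1)
  expect_true(all(as.numeric(go_contact_energy(r, r0, p0)) >= -p0$go_epsilon))
})

test_that("sigmoidal restraint force vanishes at large distance", {
  expect_lt(attr(restraint_energy(50, p0), "deriv"), 1e-4)
  expect_lt(attr(restraint_energy(100, p0), "deriv"), 1e-10)
  # force is maximal at the distance limit l_0
  l <- seq(1, 60, by = 0.5)
  dv <- attr(restraint_energy(l, p0), "deriv")
  expect_equal(l[which.max(dv)], p0$l_0)
})

test_that("topology counting: absent residues become bonded flexible beads", {
  xyz <- matrix(0, 10, 3); xyz[, 1] <- seq(0, by = 3.8, length.out = 10)
  st <- new_test_structure(xyz, present = !(1:10 %in% 4:6))
  topo <- build_topology(st, list(A = 1:10))
  expect_equal(sum(topo$beads$flexible), 3)
  expect_equal(sum(!topo$beads$flexible), 7)
  expect_equal(nrow(topo$bonds), 9)
  # angle terms exist exactly for consecutive triples touching a flexible bead
  expected_triples <- 0
  for (i in 1:8) if (any((i:(i + 2)) %in% 4:6)) expected_triples <- expected_triples + 1
  expect_equal(nrow(topo$angles), expected_triples)
  expect_true(all(topo$bonds$b0[topo$bonds$i %in% 3:6 | topo$bonds$j %in% 4:7] == 3.8))
})

test_that("native contacts match an independent double-loop enumeration", {
  gt <- get_toy_gt()
  topo <- gt$topology
  b <- topo$beads
  rigid <- which(!b$flexible)
  found <- 0
  for (a in seq_along(rigid)) for (c in seq_along(rigid)) {
    if (a >= c) next
    i <- rigid[a]; j <- rigid[c]
    d <- sqrt(sum((as.numeric(b[i, c("x", "y", "z")]) -
                     as.numeric(b[j, c("x", "y", "z")]))^2))
    if (d <= topo$params$go_cutoff &&
        !(b$chain[i] == b$chain[j] && abs(j - i) < 3)) found <- found + 1
  }
  expect_equal(nrow(topo$contacts), found)
  expect_true(all(abs(topo$contacts$i - topo$contacts$j) >= 3))
  expect_true(all(!b$flexible[topo$contacts$i] & !b$flexible[topo$contacts$j]))
})

test_that("empty chains and empty flexible overrides are handled", {
  st <- random_ca_structure(5)
  expect_error(build_topology(st, list(A = integer())), "zero residues")
  expect_warning(build_topology(st, list(A = 1:5),
                                flexible_override = data.frame(chain = "B",
                                                               resno = 1)),
                 "matched no residues")
})

test_that("forces are the exact negative gradient across random configurations", {
  topo <- small_topology()
  n <- nrow(topo$beads)
  restr <- data.frame(i = c(1L, 2L), j = c(n - 1L, n))
  x0 <- initialize_flexible(topo, seed = 4)
  set.seed(202)
  h <- 1e-5
  worst <- 0
  for (cfg in 1:100) {
    x <- x0 + matrix(rnorm(3 * n, sd = 0.3), n, 3)
    ef <- total_energy_forces(topo, x, restr)
    scale <- max(1, max(abs(ef$forces)))
    for (k in sample.int(3 * n, 6)) {     # spot-check components each config
      xp <- x; xp[k] <- xp[k] + h
      xm <- x; xm[k] <- xm[k] - h
      fd <- -(total_energy_forces(topo, xp, restr)$energy -
                total_energy_forces(topo, xm, restr)$energy) / (2 * h)
      worst <- max(worst, abs(fd - ef$forces[k]) / scale)
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("energy is invariant under global rotation and translation", {
  topo <- small_topology()
  n <- nrow(topo$beads)
  x <- initialize_flexible(topo, seed = 5)
  e0 <- total_energy_forces(topo, x)$energy
  set.seed(31)
  for (rep in 1:5) {
    ax <- rand_unit(); th <- runif(1, 0, 2 * pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
                byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    x2 <- sweep(x %*% t(R), 2, rnorm(3, sd = 50), "+")
    expect_equal(total_energy_forces(topo, x2)$energy, e0, tolerance = 1e-8)
  }
})

test_that("an active restraint adds exactly its sigmoidal energy", {
  topo <- small_topology()
  n <- nrow(topo$beads)
  x <- initialize_flexible(topo, seed = 6)
  restr <- data.frame(i = 1L, j = n)
  l <- sqrt(sum((x[1, ] - x[n, ])^2))
  e_off <- total_energy_forces(topo, x, restr, active = integer())$energy
  e_on <- total_energy_forces(topo, x, restr, active = 1L)$energy
  expect_equal(e_on - e_off, as.numeric(restraint_energy(l, topo$params)),
               tolerance = 1e-10)
})

test_that("the reference state of a fully rigid topology is near a minimum", {
  toy <- make_toy_complex(toy_spec(tails = list()))
  topo <- build_topology(toy$structure, toy$full_sequences)
  ref <- as.matrix(topo$beads[, c("x", "y", "z")])
  ef <- total_energy_forces(topo, ref)
  expect_lt(max(abs(ef$forces)), 0.5)
  set.seed(8)
  for (rep in 1:10) {
    pert <- ref + matrix(rnorm(length(ref), sd = 0.3), nrow(ref), 3)
    expect_gt(total_energy_forces(topo, pert)$energy, ef$energy)
  }
  # relaxation takes it further downhill with vanishing residual force
  xr <- flexcore:::relax_cpp(ref, flexcore:::.topo_cpp(topo), 2000L, 0.2)
  efr <- total_energy_forces(topo, xr)
  expect_lte(efr$energy, ef$energy)
  expect_lt(max(abs(efr$forces)), 0.05)
})

test_that("coordinate shape and finiteness are validated", {
  topo <- small_topology()
  expect_error(total_energy_forces(topo, matrix(0, 3, 3)), "does not match")
  x <- initialize_flexible(topo, seed = 2)
  x[2, 1] <- NaN
  expect_error(total_energy_forces(topo, x), "finite")
})

test_that("topology JSON serialization round-trips", {
  topo <- small_topology()
  f <- withr::local_tempfile(fileext = ".json")
  write_topology_json(topo, f)
  t2 <- read_topology_json(f)
  expect_equal(t2$bonds$b0, topo$bonds$b0)
  expect_equal(t2$contacts$r0, topo$contacts$r0)
  expect_equal(t2$params$k_b, topo$params$k_b)
  x <- initialize_flexible(topo, seed = 3)
  expect_equal(total_energy_forces(t2, x)$energy,
               total_energy_forces(topo, x)$energy, tolerance = 1e-12)
})
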