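test_that("PDB fixture round-trips residues, coordinates and absences", {
  f <- tiny_pdb(withr::local_tempfile(fileext = ".pdb"))
  st <- read_structure(f)
  expect_s3_class(st, "ca_structure")
  expect_equal(nrow(st$atoms), 3)
  expect_true(all(st$atoms$present))
  expect_equal(st$atoms$chain, rep("A", 3))
  expect_equal(st$atoms$x, c(0, 3.8, 7.6))

  f2 <- tiny_pdb(withr::local_tempfile(fileext = ".pdb"), drop = 2)
  st2 <- read_structure(f2)
  expect_equal(nrow(st2$atoms), 3)          # SEQRES keeps residue 2 in the table
  expect_equal(sum(st2$atoms$present), 2)
  expect_false(st2$atoms$present[st2$atoms$resno == 2])
})

test_that("unreadable input and insertion codes are rejected", {
  expect_error(read_structure(tempfile()), "not found")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   1A      3.800   0.000   0.000  1.00  0.00           C",
    "END"), f)
  expect_error(read_structure(f), "nsertion")
  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER  no atoms here", "END"), f3)
  expect_error(read_structure(f3), ".")
})

test_that("superposition recovers identity and inverts applied rigid motions", {
  st <- random_ca_structure(12, seed = 3)
  sp <- superpose(st, st)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-8)

  th <- pi / 2
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")])
  moved <- sweep(xyz %*% t(Rz), 2, c(10, 0, 0), "+")
  st2 <- new_test_structure(moved)
  sp2 <- superpose(st2, st)
  expect_equal(sp2$rmsd, 0, tolerance = 1e-9)
  expect_equal(sp2$rotation %*% Rz, diag(3), tolerance = 1e-8)
})

test_that("RMSD matches a brute-force minimization over rotations", {
  ref <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  mob <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 2))
  # independent oracle: direct search over Euler angles on centred coords
  cref <- sweep(ref, 2, colMeans(ref))
  cmob <- sweep(mob, 2, colMeans(mob))
  euler_rot <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  }
  obj <- function(a) sqrt(mean(rowSums((cmob %*% t(euler_rot(a)) - cref)^2)))
  best <- Inf
  grid <- seq(0, 2 * pi, length.out = 7)[-7]
  for (a1 in grid) for (a2 in grid) for (a3 in grid) {
    o <- stats::optim(c(a1, a2, a3), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
    best <- min(best, o$value)
  }
  sp <- superpose_coords(mob, ref)
  expect_equal(sp$rmsd, best, tolerance = 1e-6)
})

test_that("superposition agrees with an independent library implementation", {
  set.seed(11)
  ref <- matrix(rnorm(30, sd = 6), 10, 3)
  mob <- ref + matrix(rnorm(30, sd = 0.8), 10, 3)
  sp <- superpose_coords(mob, ref)
  fit <- bio3d::fit.xyz(fixed = as.numeric(t(ref)), mobile = as.numeric(t(mob)),
                        fixed.inds = 1:30, mobile.inds = 1:30)
  rmsd_bio3d <- sqrt(mean(colSums(matrix((fit - as.numeric(t(ref)))^2, 3))))
  expect_equal(sp$rmsd, rmsd_bio3d, tolerance = 1e-6)
})

test_that("rmsd is symmetric and invariant under rigid transforms", {
  for (seed in 1:5) {
    set.seed(seed)
    a <- matrix(rnorm(24, sd = 5), 8, 3)
    b <- a + matrix(rnorm(24, sd = 1), 8, 3)
    expect_equal(superpose_coords(a, b)$rmsd, superpose_coords(b, a)$rmsd,
                 tolerance = 1e-9)
    ax <- rand_unit(); th <- runif(1, 0, pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
                byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    b2 <- sweep(b %*% t(R), 2, rnorm(3, sd = 20), "+")
    expect_equal(superpose_coords(a, b2)$rmsd, superpose_coords(a, b)$rmsd,
                 tolerance = 1e-8)
  }
})

test_that("superposition input validation catches degenerate selections", {
  st <- random_ca_structure(5)
  expect_error(superpose(st, st, data.frame(chain = "A", resno = 1:2)),
               "under-determined")
  st2 <- random_ca_structure(3)
  expect_error(superpose(st, st2, data.frame(chain = "A", resno = c(1, 2, 5))),
               "A:5")
})

test_that("Calpha distances: identity, 3-4-5 triangle, brute-force all pairs", {
  st <- new_test_structure(rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(ca_distance(st, c("A", 1), c("A", 1)), 0)
  expect_equal(ca_distance(st, c("A", 1), c("A", 2)), 5)

  st10 <- random_ca_structure(10, seed = 7)
  m <- ca_distance_matrix(st10)
  xyz <- as.matrix(st10$atoms[, c("x", "y", "z")])
  for (i in 1:10) for (j in 1:10)
    expect_equal(m[i, j], sqrt(sum((xyz[i, ] - xyz[j, ])^2)), tolerance = 1e-12)
  expect_equal(m, t(m))
  # triangle inequality on every triple
  for (i in 1:8) for (j in (i + 1):9) for (k in (j + 1):10)
    expect_lte(m[i, k], m[i, j] + m[j, k] + 1e-12)
})

test_that("absent residues are unmappable for distances", {
  st <- new_test_structure(rbind(c(0, 0, 0), c(3, 4, 0), c(6, 0, 0)),
                           present = c(TRUE, FALSE, TRUE))
  expect_error(ca_distance(st, c("A", 1), c("A", 2)), "unmappable")
})

test_that("multi-model Calpha PDB writing round-trips through the reader", {
  res <- data.frame(chain = "A", resno = 1:6, resname = "ALA")
  fr <- lapply(1:3, function(k) matrix(k + seq_len(18) / 10, 6, 3))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ca_pdb(fr, res, f)
  txt <- readLines(f)
  expect_equal(sum(grepl("^MODEL", txt)), 3)
  expect_equal(sum(grepl("^ATOM", txt)), 18)
  pdb <- bio3d::read.pdb(f, multi = TRUE, verbose = FALSE)
  expect_equal(nrow(pdb$xyz), 3)
  expect_equal(matrix(pdb$xyz[2, ], 6, 3, byrow = TRUE), fr[[2]],
               tolerance = 1e-3, ignore_attr = TRUE)
})
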