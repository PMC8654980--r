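# Shared fixtures, all generated in code.

# hand-written 3-residue PDB text; drop = residue numbers whose ATOM record
# is omitted (they stay in SEQRES, i.e. unresolved)
tiny_pdb <- function(path, drop = integer()) {
  coords <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0))
  lines <- c(
    "SEQRES   1 A    3  ALA ALA ALA                                       ",
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1:3, 1:3, coords[, 1], coords[, 2], coords[, 3])[setdiff(1:3, drop)],
    "END")
  writeLines(lines, path)
  path
}

random_ca_structure <- function(n, seed = 1, chain = "A") {
  set.seed(seed)
  xyz <- matrix(stats::rnorm(3 * n, sd = 8), n, 3)
  new_test_structure(xyz, chain = chain)
}

new_test_structure <- function(xyz, chain = "A", resno = seq_len(nrow(xyz)),
                               present = rep(TRUE, nrow(xyz))) {
  atoms <- data.frame(chain = chain, resno = resno, resname = "ALA",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      present = present, stringsAsFactors = FALSE)
  atoms$x[!present] <- NA; atoms$y[!present] <- NA; atoms$z[!present] <- NA
  flexcore:::new_ca_structure(atoms)
}

# small mixed rigid/flexible topology used by force and engine tests
small_topology <- function(n_rigid = 8, n_flex = 4, params = ff_params()) {
  set.seed(99)
  # compact rigid blob with realistic near-neighbour spacing
  xyz <- matrix(0, n_rigid, 3)
  for (i in 2:n_rigid)
    xyz[i, ] <- xyz[i - 1, ] + 3.8 * rand_unit()
  st <- new_test_structure(rbind(xyz, matrix(0, n_flex, 3)),
                           present = c(rep(TRUE, n_rigid), rep(FALSE, n_flex)))
  build_topology(st, list(A = seq_len(n_rigid + n_flex)), params = params)
}

rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# toy ground truth shared by several test files; built once per test run
toy_gt_cache <- new.env()
get_toy_gt <- function() {
  if (is.null(toy_gt_cache$gt))
    toy_gt_cache$gt <- toy_ground_truth(toy_spec(), total_time = 600,
                                        save_interval = 10)
  toy_gt_cache$gt
}

kinetic_temperature <- function(ensemble) {
  mean(ensemble$energy$kinetic) * 2 / (3 * n_beads(ensemble) * 0.001987204259)
}

core_rmsd_trace <- function(ensemble, topology) {
  core <- which(!topology$beads$flexible)
  ref <- as.matrix(topology$beads[core, c("x", "y", "z")])
  vapply(seq_len(n_frames(ensemble)), function(k)
    superpose_coords(frame_coords(ensemble, k)[core, , drop = FALSE], ref)$rmsd,
    numeric(1))
}
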