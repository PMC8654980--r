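write_xl_csv <- function(rows) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

test_that("score filtering is strict and unordered duplicates collapse", {
  f <- write_xl_csv(data.frame(
    chain_a = c("A", "A", "A"), res_a = c(10, 11, 12),
    chain_b = c("B", "B", "B"), res_b = c(20, 21, 22),
    score = c(35, 40, 55)))
  xl <- read_crosslinks(f, score_cutoff = 40)
  expect_equal(nrow(xl), 1)       # strictly greater than the cutoff
  expect_equal(xl$res_a, 12)

  f2 <- write_xl_csv(data.frame(
    chain_a = c("A", "B"), res_a = c(10, 20),
    chain_b = c("B", "A"), res_b = c(20, 10),
    score = c(50, 60)))
  xl2 <- read_crosslinks(f2)
  expect_equal(nrow(xl2), 1)
  expect_equal(xl2$score, 60)     # best score kept
  expect_equal(xl2$chain_a, "A")  # canonical order
})

test_that("empty tables, schema errors and bad rows are reported", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("chain_a,res_a,chain_b,res_b,score", f)
  expect_equal(nrow(read_crosslinks(f)), 0)

  f2 <- write_xl_csv(data.frame(chain_a = "A", res_a = 1, chain_b = "B",
                                score = 50))
  expect_error(read_crosslinks(f2), "res_b")

  f3 <- write_xl_csv(data.frame(chain_a = "A", res_a = "ten", chain_b = "B",
                                res_b = 2, score = 50))
  expect_error(read_crosslinks(f3), "row")
})

test_that("custom column mappings accommodate exporter variants", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(ProteinA = "A", PosA = 3, ProteinB = "B",
                              PosB = 9, XlinkScore = 77), f, row.names = FALSE)
  xl <- read_crosslinks(f, columns = c(chain_a = "ProteinA", res_a = "PosA",
                                       chain_b = "ProteinB", res_b = "PosB",
                                       score = "XlinkScore"))
  expect_equal(nrow(xl), 1)
  expect_equal(xl$res_b, 9)
})

test_that("mapping straddles the distance limit and skips unresolved endpoints", {
  st <- new_test_structure(rbind(c(0, 0, 0), c(0, 0, 24), c(0, 0, 50), c(1, 0, 0)),
                           present = c(TRUE, TRUE, TRUE, FALSE))
  rec <- data.frame(chain_a = "A", res_a = c(1, 1, 1),
                    chain_b = "A", res_b = c(2, 3, 4), score = 50)
  m <- map_crosslinks(rec, st, l_0 = 25)
  expect_equal(m$satisfied, c(TRUE, FALSE, FALSE))
  expect_true(is.na(m$distance[3]))
  expect_equal(attr(m, "n_mappable"), 2)
  expect_equal(attr(m, "mean_distance"), mean(c(24, 50)))   # unmappable excluded
  expect_equal(attr(m, "fraction_satisfied"), 0.5)

  st2 <- new_test_structure(rbind(c(0, 0, 0), c(0, 0, 26)))
  m2 <- map_crosslinks(data.frame(chain_a = "A", res_a = 1, chain_b = "A",
                                  res_b = 2, score = 50), st2, l_0 = 25)
  expect_false(m2$satisfied)
})

test_that("mapping summary equals an independent recomputation and is order-stable", {
  st <- random_ca_structure(20, seed = 5)
  set.seed(6)
  rec <- data.frame(chain_a = "A", res_a = sample(1:10, 8),
                    chain_b = "A", res_b = sample(11:20, 8), score = 60)
  m <- map_crosslinks(rec, st)
  manual <- vapply(seq_len(nrow(rec)), function(i)
    ca_distance(st, c("A", rec$res_a[i]), c("A", rec$res_b[i])), numeric(1))
  expect_equal(m$distance, manual)
  expect_equal(attr(m, "mean_distance"), mean(manual))
  m_rev <- map_crosslinks(rec[8:1, ], st)
  expect_equal(sort(m_rev$distance), sort(m$distance))
  expect_equal(attr(m_rev, "mean_distance"), attr(m, "mean_distance"))
})

test_that("contact frequencies respect weights and degenerate cases", {
  near <- matrix(c(0, 0, 0, 0, 0, 10), 2, 3, byrow = TRUE)
  far <- matrix(c(0, 0, 0, 0, 0, 30), 2, 3, byrow = TRUE)
  ens <- cg_ensemble(list(near, near, near))
  pairs <- data.frame(i = 1L, j = 2L)
  expect_equal(contact_frequency(ens, pairs)$frequency, 1)
  expect_equal(contact_frequency(cg_ensemble(list(far, far)), pairs)$frequency, 0)

  two_state <- set_weights(cg_ensemble(list(near, far)), c(0.7, 0.3))
  expect_equal(contact_frequency(two_state, pairs)$frequency, 0.7)
  expect_equal(satisfaction_fraction(two_state, pairs), 0.7)
})

test_that("one-frame contact frequency equals static mapping satisfaction", {
  gt <- get_toy_gt()
  topo <- gt$topology
  k <- 17
  fc <- frame_coords(gt$ensemble, k)
  one <- cg_ensemble(list(fc))
  link <- topo$linkable
  pairs <- expand.grid(i = link[1:4], j = link[8:11])
  freq <- contact_frequency(one, pairs, threshold = 25)$frequency
  st <- new_test_structure(fc, resno = topo$beads$resno)
  rec <- data.frame(chain_a = "A", res_a = topo$beads$resno[pairs$i],
                    chain_b = "A", res_b = topo$beads$resno[pairs$j], score = 99)
  m <- map_crosslinks(rec, st, l_0 = 25)
  expect_equal(freq, as.numeric(m$satisfied))
})

test_that("ensemble comparison aligns shared pairs and reports the rest", {
  fa <- data.frame(i = c(1, 2, 3), j = c(4, 5, 6), frequency = c(0.8, 0.5, 0.1))
  fb <- data.frame(i = c(1, 2), j = c(4, 5), frequency = c(0.5, 0.5))
  cmp <- compare_ensembles(fa, fb)
  expect_equal(nrow(cmp$aligned), 2)
  expect_equal(cmp$aligned$difference[1], 0.3)     # sorted by |difference|
  expect_equal(cmp$unshared$i, 3)

  same <- compare_ensembles(fa, fa)
  expect_true(all(same$aligned$difference == 0))
  expect_equal(nrow(same$unshared), 0)

  disjoint <- compare_ensembles(fa[1, ], fb[2, ])
  expect_equal(nrow(disjoint$aligned), 0)
  expect_equal(nrow(disjoint$unshared), 2)
})
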