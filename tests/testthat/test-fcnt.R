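# Nanotube builder: lattice bookkeeping, bond-graph valence, grafting and
# charge redistribution.

test_that("periodic tube atom counts and period follow the closed forms", {
  m <- build_zigzag_cnt(lattice_spec(17, 14))
  expect_equal(nrow(m$atoms), 952)
  expect_equal(m$periodic_length, 5.952, tolerance = 1e-9)
  expect_equal(nrow(build_zigzag_cnt(lattice_spec(10, 1))$atoms), 40)
  expect_error(lattice_spec(4, 1), "degenerate")
})

test_that("wall atoms lie on the ideal cylinder and have valence 3", {
  m <- build_zigzag_cnt(lattice_spec(6, 2))
  r <- sqrt(m$atoms$x^2 + m$atoms$y^2)
  expect_lt(max(abs(r - m$meta$radius)), 0.2)
  # independent brute-force neighbor search including periodic images
  cnt <- oracle_neighbor_counts(as.matrix(m$atoms[, c("x", "y", "z")]),
                                1.6, m$periodic_length * 10)
  expect_true(all(cnt == 3L))
  # bond list agrees with the oracle and holds no duplicates
  expect_equal(nrow(m$bonds), sum(cnt) / 2)
  key <- paste(pmin(m$bonds[, 1], m$bonds[, 2]),
               pmax(m$bonds[, 1], m$bonds[, 2]))
  expect_false(anyDuplicated(key) > 0)
})

test_that("capped clusters reproduce the printed atom counts", {
  expect_equal(nrow(build_capped_cluster(10, 7, "carboxylate")$atoms), 164)
  expect_equal(nrow(build_capped_cluster(10, 7, "carboxylic_acid")$atoms),
               165)
  m <- build_capped_cluster(10, 2)
  expect_equal(nrow(m$atoms), 60)
  expect_equal(sum(m$atoms$element == "H"), 20)
  expect_error(build_capped_cluster(10, 2, "carboxylate"), "placement")
})

test_that("coverage grafting places ceil(coverage * N_C) groups", {
  m <- build_zigzag_cnt(lattice_spec(17, 14))
  g <- graft_groups(m, graft_spec("carboxylate", coverage_fraction = 0.02,
                                  rng_seed = 11))
  expect_equal(g$meta$n_groups, 20L)
  # sp3 bookkeeping: every anchor has 4 bonds in the topology
  deg <- tabulate(c(g$bonds[, 1], g$bonds[, 2]), nrow(g$atoms))
  sp3 <- which(g$atoms$hyb == "sp3" & g$atoms$wall)
  expect_true(all(deg[sp3] == 4L))
  expect_true(all(deg[which(g$atoms$wall & g$atoms$hyb == "sp2")] == 3L))
})

test_that("grafting is deterministic per seed and inert for 0 groups", {
  m <- build_zigzag_cnt(lattice_spec(8, 3))
  g1 <- graft_groups(m, graft_spec("carboxylate", n_groups = 4,
                                   rng_seed = 5))
  g2 <- graft_groups(m, graft_spec("carboxylate", n_groups = 4,
                                   rng_seed = 5))
  expect_identical(g1$meta$anchors, g2$meta$anchors)
  expect_identical(g1$atoms, g2$atoms)
  g0 <- graft_groups(m, graft_spec("carboxylate", n_groups = 0,
                                   rng_seed = 5))
  expect_identical(g0$atoms, m$atoms)
  expect_equal(sum(g0$atoms$charge), 0)
  expect_error(
    graft_groups(m, graft_spec("carboxylate", n_groups = 60,
                               rng_seed = 5)),
    "at most")
})

test_that("residual charge redistribution restores the formal charge", {
  m <- build_zigzag_cnt(lattice_spec(10, 4))
  g <- graft_groups(m, graft_spec("carboxylate", n_groups = 5,
                                  rng_seed = 2))
  b <- redistribute_residual_charge(g)
  expect_equal(sum(b$atoms$charge), -5, tolerance = 1e-12)
  expect_equal(b$net_charge, -5)
  # idempotent on a balanced model
  b2 <- redistribute_residual_charge(b)
  expect_equal(sum(b2$atoms$charge), -5, tolerance = 1e-12)
  expect_lt(abs(b2$meta$charge_adjustment), 1e-14)
  # acid form balances to zero
  ga <- graft_groups(m, graft_spec("carboxylic_acid", n_groups = 5,
                                   rng_seed = 2))
  expect_equal(sum(redistribute_residual_charge(ga)$atoms$charge), 0,
               tolerance = 1e-12)
  # motif charges are preserved verbatim by the redistribution
  motif_rows <- which(!is.na(b$atoms$motif) & !b$atoms$wall)
  expect_identical(b$atoms$charge[motif_rows], g$atoms$charge[motif_rows])
})

test_that("arithmetic identity: residual spread matches group deficit", {
  m <- build_zigzag_cnt(lattice_spec(8, 3))
  ch <- motif_charge_set("carboxylate", o1 = -0.775, o2 = -0.775)
  # group sum: 0.08 - 0.12 + 0.12 + 0.74 - 1.55 - 4*0.04 = -0.89
  g <- graft_groups(m, graft_spec("carboxylate", n_groups = 2,
                                  rng_seed = 3), charges = ch)
  expect_equal(sum(g$atoms$charge), 2 * -0.89, tolerance = 1e-9)
  b <- redistribute_residual_charge(g)
  n_free <- sum(b$atoms$wall & is.na(b$atoms$motif))
  expect_equal(b$meta$charge_adjustment, -(2 * -0.89 - (-2)) / n_free,
               tolerance = 1e-12)
})
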