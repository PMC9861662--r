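# Pair energetics: closed forms, oracle equivalence, and the symmetry /
# scaling properties of the LJ + Coulomb sums.

qtab <- function() ff_params(data.frame(type = "Q", sigma = 0.3,
                                        epsilon = 0))

test_that("Coulomb term hits the closed form for unit charges at 1 nm", {
  xyz <- rbind(c(0, 0, 0), c(10, 0, 0))
  e <- pair_energy(xyz, 1, 2, charges = c(1, -1), params = qtab(),
                   types = c("Q", "Q"))
  expect_equal(e$E_coulomb, -138.935458, tolerance = 1e-9)
  expect_equal(e$E_LJ, 0)
  expect_equal(e$E_total, e$E_LJ + e$E_coulomb)
})

test_that("LJ is zero at sigma and -eps at the 2^(1/6) sigma minimum", {
  p <- ff_params()
  tb <- p$table
  sig <- (tb$sigma[tb$type == "Na"] + tb$sigma[tb$type == "Cl"]) / 2
  eps <- sqrt(tb$epsilon[tb$type == "Na"] * tb$epsilon[tb$type == "Cl"])
  at_sig <- pair_energy(rbind(c(0, 0, 0), c(10 * sig, 0, 0)), 1, 2,
                        charges = c(0, 0), params = p,
                        types = c("Na", "Cl"))
  expect_equal(at_sig$E_LJ, 0, tolerance = 1e-9)
  rmin <- 2^(1 / 6) * sig
  at_min <- pair_energy(rbind(c(0, 0, 0), c(10 * rmin, 0, 0)), 1, 2,
                        charges = c(0, 0), params = p,
                        types = c("Na", "Cl"))
  expect_equal(at_min$E_LJ, -eps, tolerance = 1e-9)
  expect_equal(-eps, -sqrt(0.366 * 0.149), tolerance = 1e-12)
})

test_that("pairs beyond the 1.2 nm cutoff contribute nothing", {
  xyz <- rbind(c(0, 0, 0), c(12.000001, 0, 0))
  e <- pair_energy(xyz, 1, 2, charges = c(1, 1), params = ff_params(),
                   types = c("Na", "Cl"))
  expect_equal(e$E_total, 0)
  # exactly at the cutoff the pair still counts (r <= r_c)
  e2 <- pair_energy(rbind(c(0, 0, 0), c(12, 0, 0)), 1, 2,
                    charges = c(1, 1), params = qtab(),
                    types = c("Q", "Q"))
  expect_gt(abs(e2$E_coulomb), 0)
})

test_that("vectorized energies equal the brute-force oracle", {
  set.seed(21)
  p <- ff_params()
  box <- c(25, 25, 25)
  for (rep in 1:5) {
    n <- 120
    xyz <- cbind(runif(n, 0, box[1]), runif(n, 0, box[2]),
                 runif(n, 0, box[3]))
    types <- sample(c("C", "O", "H", "N"), n, replace = TRUE)
    q <- round(rnorm(n, 0, 0.3), 3)
    ga <- 1:40; gb <- 41:120
    e <- pair_energy(xyz, ga, gb, q, p, box = box, types = types)
    o <- oracle_pair_energy(xyz, ga, gb, q, types, p, box = box)
    expect_equal(e$E_LJ, o$E_LJ, tolerance = 1e-8)
    expect_equal(e$E_coulomb, o$E_coulomb, tolerance = 1e-8)
  }
})

test_that("energy is symmetric, translation invariant, charge-quadratic", {
  set.seed(8)
  p <- ff_params()
  box <- c(30, 30, 30)
  n <- 60
  xyz <- cbind(runif(n, 0, 30), runif(n, 0, 30), runif(n, 0, 30))
  types <- sample(c("C", "O"), n, replace = TRUE)
  q <- rnorm(n, 0, 0.2)
  a <- 1:30; b <- 31:60
  e1 <- pair_energy(xyz, a, b, q, p, box = box, types = types)
  e2 <- pair_energy(xyz, b, a, q, p, box = box, types = types)
  expect_equal(e1$E_total, e2$E_total, tolerance = 1e-10)
  shift <- sweep(xyz, 2, c(30, -60, 30), `+`)   # box-commensurate
  e3 <- pair_energy(shift, a, b, q, p, box = box, types = types)
  expect_equal(e1$E_total, e3$E_total, tolerance = 1e-10)
  e4 <- pair_energy(xyz, a, b, 2 * q, p, box = box, types = types)
  expect_equal(e4$E_coulomb, 4 * e1$E_coulomb, tolerance = 1e-10)
  expect_equal(e4$E_LJ, e1$E_LJ)
})

test_that("cutoff truncation is bounded by the discarded tail", {
  set.seed(4)
  p <- ff_params()
  xyz <- cbind(runif(50, 0, 30), runif(50, 0, 30), runif(50, 0, 30))
  types <- rep(c("C", "O"), 25)
  q <- rep(c(0.1, -0.1), 25)
  e <- pair_energy(xyz, 1:25, 26:50, q, p, types = types)
  full <- oracle_pair_energy(xyz, 1:25, 26:50, q, types, p,
                             use_cutoff = FALSE)
  tail_bound <- abs(full$E_total -
                      oracle_pair_energy(xyz, 1:25, 26:50, q, types, p,
                                         use_cutoff = TRUE)$E_total)
  expect_lte(abs(e$E_total - full$E_total), tail_bound + 1e-10)
})

test_that("overlapping atoms are flagged but still scored", {
  xyz <- rbind(c(0, 0, 0), c(0.3, 0, 0))
  e <- pair_energy(xyz, 1, 2, charges = c(0, 0), params = ff_params(),
                   types = c("C", "C"))
  expect_equal(e$n_overlap, 1)
  expect_true(is.finite(e$E_LJ) && e$E_LJ > 0)
  expect_error(pair_energy(xyz, 1, 1, charges = c(0, 0),
                           params = ff_params(), types = c("C", "C")),
               "disjoint")
})

test_that("mean pair energies average per molecule and frame", {
  # two single-atom molecules: one interacting, one far away
  at <- rbind(toy_atom_row("C", type = "fcnt", molid = 0L),
              toy_atom_row("O", molid = 1L),
              toy_atom_row("O", molid = 2L))
  at$charge <- c(0.5, -0.5, -0.5)
  coords <- array(0, c(3, 3, 4))
  for (f in 1:4) {
    coords[1, , f] <- c(0, 0, 0)
    coords[2, , f] <- c(5, 0, 0)       # within cutoff
    coords[3, , f] <- c(40, 40, 40)    # far outside
  }
  tr <- make_toy_traj(coords, at, box = c(100, 100, 100),
                      molecules = list(list(molid = 1, kind = "toy"),
                                       list(molid = 2, kind = "toy")),
                      fcnt_rows = 1L)
  res <- mean_pair_energy(tr, ff_params(), n_blocks = 2)
  single <- pair_energy(coords[, , 1], 1, 2, at$charge,
                        ff_params(), box = c(100, 100, 100),
                        types = at$element)
  expect_equal(res$E_total, single$E_total / 2, tolerance = 1e-10)
  expect_equal(res$se, 0)
  expect_equal(res$n_molecules, 2)
})
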