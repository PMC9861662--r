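# Torsions, Boltzmann-inversion free-energy maps, conformer occupancies,
# RMSF and ring puckering.

test_that("torsion follows the IUPAC sign convention", {
  cis <- rbind(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0), c(-1, 1, 0))
  expect_equal(torsion(cis, 1:4), 0, tolerance = 1e-10)
  trans <- rbind(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0), c(-1, -1, 0))
  expect_equal(abs(torsion(trans, 1:4)), 180, tolerance = 1e-10)
  skew <- rbind(c(1, 1, 0), c(1, 0, 0), c(-1, 0, 0), c(-1, 0.5, 0.8))
  t1 <- torsion(skew, 1:4)
  mirror <- skew; mirror[, 3] <- -mirror[, 3]
  expect_equal(torsion(mirror, 1:4), -t1, tolerance = 1e-10)
  # rigid motion invariance
  R <- cntglycan:::rotation_matrix(c(1, 2, 3), 1.1)
  moved <- sweep(skew %*% t(R), 2, c(5, -3, 2), `+`)
  expect_equal(torsion(moved, 1:4), t1, tolerance = 1e-8)
  collinear <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_error(torsion(collinear, 1:4), "collinear")
})

test_that("free-energy maps invert the histogram and cap empty bins", {
  th <- thermo_context(310)
  expect_equal(th$kT, 0.0083144621 * 310, tolerance = 1e-12)
  # all samples in one bin
  m <- free_energy_map(rep(-70, 50), rep(-110, 50), th)
  expect_equal(min(m$F), 0)
  expect_equal(sum(m$P > 0), 1)
  expect_true(all(m$F[m$P == 0] == m$cap))
  expect_true(all(m$F >= 0))
  # round trip on occupied bins: P = Pmax * exp(-F/kT)
  set.seed(2)
  phi <- runif(5000, -180, 180); psi <- runif(5000, -180, 180)
  m2 <- free_energy_map(phi, psi, th, bin_width = 30)
  occ <- m2$P > 0
  expect_equal(m2$P[occ], max(m2$P) * exp(-m2$F[occ] / m2$kT),
               tolerance = 1e-12)
})

test_that("uniform sampling keeps the map flat to sampling noise", {
  set.seed(6)
  m <- free_energy_map(runif(50000, -180, 180), runif(50000, -180, 180),
                       bin_width = 10)
  expect_true(all(is.finite(m$F)))
  expect_lt(max(m$F), 1.5 * m$kT)
})

test_that("a two-basin 80/20 sample recovers kT*log(4)", {
  spec <- torsion_surface_spec(data.frame(
    phi = c(-70, 60), psi = c(-110, 170), weight = c(0.8, 0.2),
    sd = c(15, 15)))
  set.seed(31)
  s <- sample_torsion_basins(spec, 50000)
  m <- free_energy_map(s[, 1], s[, 2])
  df <- basin_delta_f(m, c(-70, -110), c(60, 170))
  expect_equal(df, thermo_context()$kT * log(4), tolerance = 0.3)
})

test_that("conformer occupancies split samples into angular windows", {
  set.seed(7)
  syn <- rnorm(500, -110, 10)
  anti <- rnorm(500, 70, 10)
  fr <- conformer_occupancy(c(syn, anti), psi_windows("syn_anti"))
  expect_equal(unname(fr["syn"]), 0.5, tolerance = 3 * sqrt(0.25 / 1000))
  expect_equal(sum(fr), 1, tolerance = 0.01)
  all_syn <- conformer_occupancy(syn, psi_windows("syn_anti"))
  expect_equal(unname(all_syn), c(1, 0))
  tr <- conformer_occupancy(c(syn, anti), psi_windows("trans"))
  expect_equal(unname(tr), 0)
  expect_error(conformer_occupancy(syn, list(a = c(0, 60), b = c(30, 60))),
               "overlap")
})

test_that("RMSF of isotropic jitter converges to sqrt(3)*sd", {
  set.seed(10)
  n <- 10; nf <- 4000; sd0 <- 0.5
  base <- matrix(rnorm(n * 3, sd = 5), n)
  coords <- array(base, c(n, 3, nf)) +
    array(rnorm(n * 3 * nf, sd = sd0), c(n, 3, nf))
  r <- rmsf(coords, fit = FALSE)
  se <- sd(r) / sqrt(n)
  expect_lt(abs(mean(r) - sqrt(3) * sd0), 3 * se + 0.02)
  # static coordinates fluctuate not at all
  expect_equal(rmsf(array(base, c(n, 3, 5)), fit = FALSE), rep(0, n))
  expect_error(rmsf(array(base, c(n, 3, 1))), "2 frames")
  # no-fit RMSF is invariant under a constant translation of all frames
  shifted <- sweep(coords, 2, c(4, 4, 4), `+`)
  expect_equal(rmsf(shifted, fit = FALSE), r, tolerance = 1e-10)
  # fitting removes rigid diffusion: drifting rigid body has ~0 RMSF
  drift <- array(base, c(n, 3, 50))
  for (f in 1:50) drift[, , f] <- base + f * matrix(c(0.3, 0, 0), n, 3,
                                                    byrow = TRUE)
  expect_lt(max(rmsf(drift, fit = TRUE)), 1e-8)
})

test_that("Cremer-Pople classifies constructed ring shapes", {
  chair <- cntglycan:::ring_coords()
  p <- ring_pucker(chair, 1:6)
  expect_equal(p$class, "chair")
  expect_lt(p$theta, 10)
  expect_gt(p$Q, 0.3)
  boat <- chair; boat[, 3] <- 0.3 * c(1, -0.5, -0.5, 1, -0.5, -0.5)
  pb <- ring_pucker(boat, 1:6)
  expect_equal(pb$class, "boat")
  expect_equal(pb$theta, 90, tolerance = 1)
  # a twisted deformation between boat meridians is a skew-boat
  skew <- chair
  skew[, 3] <- 0.3 * sqrt(1 / 3) * cos(pi / 6 + 2 * (0:5) * 2 * pi / 6)
  ps <- ring_pucker(skew, 1:6)
  expect_equal(ps$class, "skew-boat")
  planar <- chair; planar[, 3] <- 0
  expect_equal(ring_pucker(planar, 1:6)$class, "undefined")
  expect_error(ring_pucker(chair, 1:5), "6 ring atoms")
})
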