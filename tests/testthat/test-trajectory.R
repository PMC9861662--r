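# Synthetic-trajectory generator: frame bookkeeping, two-state kinetics,
# torsion sampling statistics and construction guarantees.

test_that("frame scheduler reproduces sample counts and rejects remainders", {
  expect_equal(frame_count(600, 200), 3000L)
  expect_equal(frame_count(1, 200), 5L)
  expect_error(frame_count(600, 7), "divide")
})

test_that("zero switching probabilities freeze the adsorption state", {
  sys <- small_system(copies = 2)
  tr <- generate_trajectory(sys, adsorption_scenario(
    p_desorb = 0, p_adsorb = 1, start_state = "adsorbed"),
    n_frames = 40, seed = 1)
  expect_true(all(tr$states))
  tr2 <- generate_trajectory(sys, adsorption_scenario(
    p_desorb = 0, p_adsorb = 0, start_state = "desorbed"),
    n_frames = 40, seed = 1)
  expect_true(all(!tr2$states))
  expect_true(all(diff(tr$times) > 0))
  expect_equal(dim(tr$coords)[1], nrow(sys$atoms))
})

test_that("adsorbed fraction matches the chain's stationary distribution", {
  sys <- small_system(copies = 20)
  tr <- generate_trajectory(sys, adsorption_scenario(
    p_desorb = 0.1, p_adsorb = 0.3), n_frames = 150, seed = 7)
  per_mol <- rowMeans(tr$states)
  est <- mean(per_mol)
  se <- sd(per_mol) / sqrt(length(per_mol))
  expect_lt(abs(est - 0.75), 3 * se)
})

test_that("basin occupancy of torsion samples is binomial in the weights", {
  spec <- torsion_surface_spec(data.frame(
    phi = c(-70, -80), psi = c(-110, 60), weight = c(0.8, 0.2),
    sd = c(15, 15)))
  set.seed(5)
  s <- sample_torsion_basins(spec, 2000)
  phat <- mean(attr(s, "basin") == 1)
  expect_lt(abs(phat - 0.8), 3 * sqrt(0.8 * 0.2 / 2000))
  expect_error(torsion_surface_spec(data.frame(
    phi = 0, psi = 0, weight = 0.9, sd = 10)), "sum to 1")
})

test_that("sampled torsions pass a chi-square fit against the mixture", {
  spec <- torsion_surface_spec(data.frame(
    phi = c(-70, 60), psi = c(-110, 170), weight = c(0.5, 0.5),
    sd = c(12, 12)))
  set.seed(3)
  s <- sample_torsion_basins(spec, 10000)
  # expected bin masses from a dense wrapped-normal grid
  for (col in 1:2) {
    edges <- seq(-180, 180, by = 10)
    grid <- seq(-179.975, 179.975, by = 0.05)
    dens <- rep(0, length(grid))
    for (b in seq_len(nrow(spec$basins))) {
      mu <- spec$basins[[c("phi", "psi")[col]]][b]
      for (k in -2:2)
        dens <- dens + spec$basins$weight[b] *
          dnorm(grid + 360 * k, mu, spec$basins$sd[b])
    }
    p_exp <- vapply(seq_len(length(edges) - 1), function(i) {
      sum(dens[grid >= edges[i] & grid < edges[i + 1]])
    }, 0)
    p_exp <- p_exp / sum(p_exp)
    obs <- table(cut(s[, col], edges))
    keep <- p_exp * length(s[, col]) >= 5
    chi <- sum((as.numeric(obs[keep]) -
                  p_exp[keep] * 10000)^2 / (p_exp[keep] * 10000))
    pval <- pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
    expect_gt(pval, 0.01)
  }
})

test_that("per-frame torsion resampling lands where sampled", {
  ch <- build_decamer("Ch", 4)
  cnt <- build_zigzag_cnt(lattice_spec(8, 3))
  sys <- assemble(cnt, ch, copies = 1, conc_M = 0, seed = 2)
  spec <- torsion_surface_spec(data.frame(
    phi = -70, psi = -110, weight = 1, sd = 20))
  tr <- generate_trajectory(sys, adsorption_scenario(
    jitter_sd = 0, r_max_adsorbed = Inf), torsions = spec,
    n_frames = 20, seed = 4)
  measured <- traj_torsions(tr, 1)
  expect_equal(as.vector(measured), as.vector(aperm(
    tr$torsion_samples[[1]], c(1, 2, 3))), tolerance = 1e-5)
})

test_that("trajectories are deterministic per seed", {
  sys <- small_system(copies = 2)
  t1 <- generate_trajectory(sys, adsorption_scenario(), n_frames = 10,
                            seed = 13)
  t2 <- generate_trajectory(sys, adsorption_scenario(), n_frames = 10,
                            seed = 13)
  expect_identical(t1$coords, t2$coords)
})

test_that("always-adsorbed side-A scenarios put face A inside face B", {
  sys <- small_system(copies = 2)
  tr <- generate_trajectory(sys, adsorption_scenario(
    facing = "A", facing_noise_sd = 0, jitter_sd = 0), n_frames = 50,
    seed = 6)
  nf <- dim(tr$coords)[3]
  for (m in 1:2) {
    ra <- molecule_rows(tr, m, names = face_atoms("GlcNAc", "A"))
    rb <- molecule_rows(tr, m, names = face_atoms("GlcNAc", "B"))
    for (f in seq_len(nf)) {
      da <- sqrt(rowSums(tr$coords[ra, 1:2, f]^2))
      db <- sqrt(rowSums(tr$coords[rb, 1:2, f]^2))
      expect_lt(max(da), min(db))
    }
  }
})
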