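# Radial profiles, monolayer metrics, orientation classification and
# detachment events.

static_atom_traj <- function(r_by_frame, names = "C1") {
  nf <- length(r_by_frame)
  na <- length(names)
  at <- do.call(rbind, lapply(names, toy_atom_row))
  coords <- array(0, c(na, 3, nf))
  for (f in seq_len(nf)) coords[, 1, f] <- r_by_frame[f]
  make_toy_traj(coords, at, box = c(100, 100, 100),
                molecules = list(list(molid = 1, kind = "toy")))
}

test_that("a static atom lands all its counts in one bin", {
  tr <- static_atom_traj(rep(10, 100))
  p <- radial_profile(tr, 1)
  expect_equal(sum(p$counts), 100)
  bin <- findInterval(10, p$edges)
  expect_equal(p$counts[bin], 100)
})

test_that("profile counts are conserved and rotation invariant", {
  sys <- small_system(copies = 3)
  tr <- generate_trajectory(sys, adsorption_scenario(), n_frames = 30,
                            seed = 2)
  rows <- which(tr$atoms$type == "glycan")
  p <- radial_profile(tr, rows)
  expect_equal(sum(p$counts), length(rows) * 30)
  # rigid rotation about the tube axis leaves the histogram unchanged
  th <- 0.83
  R <- cntglycan:::rotation_matrix(c(0, 0, 1), th)
  tr2 <- tr
  for (f in 1:30) tr2$coords[, , f] <- tr$coords[, , f] %*% t(R)
  expect_equal(radial_profile(tr2, rows)$counts, p$counts)
  expect_error(radial_profile(tr, integer(0)), "empty")
})

test_that("monolayer scenarios never cross the 15 A bound", {
  sys <- small_system(copies = 3)
  tr <- generate_trajectory(sys, adsorption_scenario(facing = "A"),
                            n_frames = 60, seed = 5)
  rows <- which(tr$atoms$type == "glycan")
  p <- radial_profile(tr, rows)
  lm <- layer_metrics(p)
  expect_equal(unname(lm$fraction["r15"]), 1.0)
  expect_equal(unname(lm$fraction["r20"]), 1.0)
  expect_lte(lm$decay_radius, 15)
  # cumulative fractions are monotone in r
  expect_true(all(diff(cumsum(p$counts)) >= 0))
})

test_that("scripted desorbed frames shift the 20 A fraction exactly", {
  tr <- static_atom_traj(c(rep(10, 90), rep(25, 10)))
  lm <- layer_metrics(radial_profile(tr, 1))
  expect_equal(unname(lm$fraction["r20"]), 0.90)
  expect_equal(unname(lm$fraction["r15"]), 0.90)
  expect_gte(lm$decay_radius, 25)
})

test_that("orientation classifier recovers the scripted facing side", {
  sys <- small_system(copies = 2)
  tra <- generate_trajectory(sys, adsorption_scenario(facing = "A"),
                             n_frames = 150, seed = 3)
  expect_equal(orientation(tra)$label, "A(H1-H5)")
  trb <- generate_trajectory(sys, adsorption_scenario(facing = "B"),
                             n_frames = 150, seed = 3)
  expect_equal(orientation(trb)$label, "B(H2-H4/O4)")
})

test_that("isotropic orientations come out indeterminate", {
  sys <- small_system(copies = 4)
  tr <- generate_trajectory(sys, adsorption_scenario(
    facing = "isotropic"), n_frames = 500, seed = 17)
  expect_equal(orientation(tr)$label, "indeterminate")
})

test_that("detachment events honor the run-length threshold", {
  # molecule of six ring atoms moving radially in a scripted pattern
  rnames <- c("O5", "C1", "C2", "C3", "C4", "C5")
  fixed <- static_atom_traj(rep(12, 50), names = rnames)
  d0 <- detachment_events(fixed)
  expect_equal(nrow(d0$events[["1"]]), 0)
  expect_equal(d0$fraction_beyond, 0)
  # a 10-frame excursion beyond 20 A
  r <- rep(12, 50); r[21:30] <- 26
  exc <- static_atom_traj(r, names = rnames)
  d1 <- detachment_events(exc)
  expect_equal(d1$events[["1"]], data.frame(start = 21L, end = 30L))
  expect_equal(d1$fraction_beyond, 10 / 50)
  # 2-frame excursions are below min_frames = 3
  r2 <- rep(12, 50); r2[5:6] <- 26
  d2 <- detachment_events(static_atom_traj(r2, names = rnames))
  expect_equal(nrow(d2$events[["1"]]), 0)
  expect_equal(d2$fraction_beyond, 2 / 50)
  # exactly at the threshold is not "beyond" (strict inequality)
  r3 <- rep(20, 50)
  d3 <- detachment_events(static_atom_traj(r3, names = rnames))
  expect_equal(d3$fraction_beyond, 0)
})
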