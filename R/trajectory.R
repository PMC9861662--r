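# Synthetic-trajectory generator.
#
# Stands in for production MD: every downstream analysis is exercised on
# trajectories whose statistical structure is known exactly.  Each glycan
# molecule follows a two-state (adsorbed/desorbed) Markov chain; adsorbed
# molecules sit in a monolayer at a configurable radial distance from the
# tube axis with a chosen molecular face toward the surface, desorbed
# molecules are displaced beyond a radial threshold.  Glycosidic torsions
# are resampled each frame from a wrapped-normal basin mixture.  Poses are
# rigid otherwise; an isotropic positional jitter models thermal noise.

#' Number of stored frames of a production run
#'
#' @param duration_ns run length in ns.
#' @param interval_ps frame spacing in ps (must divide the duration).
#' @return integer frame count.
#' @examples
#' frame_count(600, 200)  # 3000
#' @export
frame_count <- function(duration_ns, interval_ps) {
  stopifnot(duration_ns > 0, interval_ps > 0)
  tot_ps <- duration_ns * 1000
  if (abs(tot_ps %% interval_ps) > 1e-9)
    stop("interval does not divide the run duration evenly")
  as.integer(round(tot_ps / interval_ps))
}

#' Adsorption scenario for the synthetic generator
#'
#' @param p_desorb per-frame probability of leaving the adsorbed state.
#' @param p_adsorb per-frame probability of re-adsorbing.
#' @param r_offset mean radial distance of an adsorbed molecule's center
#'   above the tube radius, angstrom.
#' @param r_sd radial spread of the adsorbed layer, angstrom.
#' @param r_max_adsorbed radial bound that every atom of an adsorbed
#'   molecule must respect (monolayer construction; default 15 angstrom).
#'   Set `Inf` to lift the constraint (e.g. for decamers).
#' @param desorbed_r_min minimum center distance of a desorbed molecule,
#'   angstrom.
#' @param facing molecular face presented to the surface: `"A"`
#'   (H1-H5 side), `"B"` (H2-H4/O4 side) or `"isotropic"`.
#' @param facing_noise_sd angular noise of the facing direction, degrees.
#' @param jitter_sd isotropic per-atom positional noise, angstrom.
#' @param start_state `"stationary"` (draw from the chain's stationary
#'   distribution), `"adsorbed"` or `"desorbed"`.
#' @param frozen_pose keep a single rigid pose for all frames (only the
#'   jitter varies) -- used for fluctuation calibrations.
#' @export
adsorption_scenario <- function(p_desorb = 0, p_adsorb = 1,
                                r_offset = 4, r_sd = 0.8,
                                r_max_adsorbed = 15,
                                desorbed_r_min = 20,
                                facing = c("A", "B", "isotropic"),
                                facing_noise_sd = 10,
                                jitter_sd = 0.3,
                                start_state = c("stationary", "adsorbed",
                                                "desorbed"),
                                frozen_pose = FALSE) {
  facing <- match.arg(facing)
  start_state <- match.arg(start_state)
  stopifnot(p_desorb >= 0, p_desorb <= 1, p_adsorb >= 0, p_adsorb <= 1,
            r_sd >= 0, jitter_sd >= 0)
  structure(as.list(environment()), class = "adsorption_scenario")
}

#' Torsion basin mixture
#'
#' @param basins data.frame with columns phi, psi (centers, degrees),
#'   weight and sd (wrapped-normal spread, degrees).  Weights must sum
#'   to 1.
#' @export
torsion_surface_spec <- function(basins) {
  stopifnot(is.data.frame(basins),
            all(c("phi", "psi", "weight", "sd") %in% names(basins)))
  if (abs(sum(basins$weight) - 1) > 1e-9)
    stop("basin weights must sum to 1")
  structure(list(basins = basins), class = "torsion_surface_spec")
}

#' Sample (phi, psi) pairs from a basin mixture
#'
#' Basin membership is multinomial in the weights; within a basin both
#' angles are independent wrapped normals.
#'
#' @param spec a [torsion_surface_spec()].
#' @param n number of samples.
#' @return matrix n x 2 (phi, psi, degrees) with attribute `"basin"`.
#' @export
sample_torsion_basins <- function(spec, n) {
  b <- spec$basins
  idx <- sample.int(nrow(b), n, replace = TRUE, prob = b$weight)
  out <- cbind(phi = wrap_angle(stats::rnorm(n, b$phi[idx], b$sd[idx])),
               psi = wrap_angle(stats::rnorm(n, b$psi[idx], b$sd[idx])))
  attr(out, "basin") <- idx
  out
}

# two-state chain: TRUE = adsorbed
markov_states <- function(n, p_desorb, p_adsorb, start_state) {
  s0 <- switch(start_state,
               adsorbed = TRUE, desorbed = FALSE,
               stationary = {
                 pi_ads <- if (p_desorb + p_adsorb == 0) 1 else
                   p_adsorb / (p_desorb + p_adsorb)
                 stats::runif(1) < pi_ads
               })
  st <- logical(n); st[1] <- s0
  if (n > 1) {
    u <- stats::runif(n - 1)
    for (t in 2:n)
      st[t] <- if (st[t - 1]) u[t - 1] >= p_desorb else u[t - 1] < p_adsorb
  }
  st
}

# face direction (unit vector) of a chain in given coordinates
face_vector <- function(chain, xyz) {
  res1 <- chain$residues[1]
  a <- which(chain$atoms$resno == 1 & chain$atoms$name %in%
               face_atoms(res1, "A"))
  b <- which(chain$atoms$resno == 1 & chain$atoms$name %in%
               face_atoms(res1, "B"))
  unitv(colMeans(xyz[a, , drop = FALSE]) - colMeans(xyz[b, , drop = FALSE]))
}

# one rigid pose of template coordinates (centered) for a molecule
pose_molecule <- function(txyz, chain, adsorbed, scen, r_tube, bx, ext,
                          r_clear = r_tube) {
  if (nrow(chain$linkages) > 0 && scen$facing != "isotropic") {
    # oligomer: principal axis along the tube, face rotated inward
    pc1 <- svd(txyz)$v[, 1]
    R1 <- rotation_between(pc1, c(0, 0, 1))
    xyz <- txyz %*% t(R1)
    f <- face_vector(chain, xyz)
    fxy <- c(f[1], f[2], 0)
    th_pos <- stats::runif(1, 0, 2 * pi)
    inward <- -c(cos(th_pos), sin(th_pos), 0)
    if (vnorm(fxy) > 1e-8) {
      spin <- atan2(inward[2], inward[1]) - atan2(fxy[2], fxy[1])
      xyz <- xyz %*% t(rotation_matrix(c(0, 0, 1), spin))
    }
  } else if (scen$facing == "isotropic") {
    xyz <- txyz %*% t(random_rotation())
    th_pos <- stats::runif(1, 0, 2 * pi)
  } else {
    f <- face_vector(chain, txyz)
    if (scen$facing == "B") f <- -f
    th_pos <- stats::runif(1, 0, 2 * pi)
    u0 <- -c(cos(th_pos), sin(th_pos), 0)   # toward the axis
    tilt <- stats::rnorm(1, 0, scen$facing_noise_sd) * pi / 180
    perp <- unitv(crossp(u0, c(0, 0, 1)))
    axn <- unitv(cos(stats::runif(1, 0, 2 * pi)) * perp +
                 sin(stats::runif(1, 0, 2 * pi)) * c(0, 0, 1))
    u <- as.numeric(rotation_matrix(axn, tilt) %*% u0)
    R1 <- rotation_between(f, u)
    xyz <- txyz %*% t(R1)
    xyz <- rotate_about_axis(xyz, c(0, 0, 0), u, stats::runif(1, 0, 2 * pi))
  }
  if (adsorbed) {
    r_lo <- r_tube + 2
    r_hi <- if (is.finite(scen$r_max_adsorbed))
      scen$r_max_adsorbed - ext else r_tube + scen$r_offset + 3 * scen$r_sd
    if (r_hi <= r_lo)
      stop("monolayer bound infeasible for this molecule; raise ",
           "r_max_adsorbed (or set it to Inf)")
    repeat {
      r <- stats::rnorm(1, r_tube + scen$r_offset, scen$r_sd)
      if (r > r_lo && r < r_hi) break
    }
  } else {
    r <- stats::runif(1, scen$desorbed_r_min + 2,
                      max(min(bx[1], bx[2]) / 2,
                          scen$desorbed_r_min + 4))
  }
  cen <- c(r * cos(th_pos), r * sin(th_pos), stats::runif(1, 0, bx[3]))
  out <- sweep(xyz, 2, cen, `+`)
  if (adsorbed && r_clear > 0) {
    # keep every atom clear of the outermost fCNT atom radius (poses are
    # rigid, not energy-relaxed; this bounds steric overlap)
    rmin <- min(sqrt(out[, 1]^2 + out[, 2]^2))
    gap <- (r_clear + 1.8) - rmin
    if (gap > 0) {
      shift <- min(gap, max(0, (if (is.finite(scen$r_max_adsorbed))
        scen$r_max_adsorbed - ext else Inf) - r))
      out[, 1:2] <- sweep(out[, 1:2, drop = FALSE], 2,
                          shift * c(cos(th_pos), sin(th_pos)), `+`)
    }
  }
  out
}

#' Generate a synthetic trajectory
#'
#' @param system a [assemble()]d `cnt_system`.
#' @param scenario an [adsorption_scenario()].
#' @param torsions optional [torsion_surface_spec()]; when given, every
#'   glycosidic linkage of every molecule is resampled each frame.
#' @param n_frames number of frames.
#' @param dt_ps frame spacing in ps (default 200).
#' @param seed RNG seed; the whole trajectory is deterministic in it.
#' @return object of class `cnt_traj`: the system atom table, a
#'   natoms x 3 x nframes coordinate array (angstrom), box, strictly
#'   increasing times (ps), the hidden per-molecule state sequences and
#'   the torsion samples used.
#' @export
generate_trajectory <- function(system, scenario = adsorption_scenario(),
                                torsions = NULL, n_frames = 100L,
                                dt_ps = 200, seed = 1L) {
  stopifnot(inherits(system, "cnt_system"), n_frames >= 1)
  set.seed(seed)
  na <- nrow(system$atoms)
  nm <- length(system$molecules)
  coords <- array(NA_real_, c(na, 3L, n_frames))
  static <- as.matrix(system$atoms[, c("x", "y", "z")])
  for (f in seq_len(n_frames)) coords[, , f] <- static
  r_tube <- if (!is.null(system$fcnt)) system$fcnt$meta$radius else 0
  r_clear <- if (length(system$fcnt_rows) > 0)
    max(sqrt(static[system$fcnt_rows, 1]^2 +
             static[system$fcnt_rows, 2]^2)) else 0
  states <- matrix(TRUE, nm, n_frames)
  tsamples <- vector("list", nm)
  for (m in seq_len(nm)) {
    mol <- system$molecules[[m]]
    rows <- molecule_rows(system, m)
    txyz0 <- as.matrix(mol$chain$atoms[, c("x", "y", "z")])
    nlk <- nrow(mol$chain$linkages)
    ext0 <- glycan_extent(mol$chain)
    if (scenario$frozen_pose) {
      base <- pose_molecule(sweep(txyz0, 2, colMeans(txyz0)), mol$chain,
                            TRUE, scenario, r_tube, system$box, ext0,
                            r_clear)
      jit <- array(stats::rnorm(length(rows) * 3 * n_frames,
                                sd = scenario$jitter_sd),
                   c(length(rows), 3L, n_frames))
      coords[rows, , ] <- array(base, c(length(rows), 3L, n_frames)) + jit
      next
    }
    states[m, ] <- markov_states(n_frames, scenario$p_desorb,
                                 scenario$p_adsorb, scenario$start_state)
    if (!is.null(torsions) && nlk > 0) {
      ts <- array(NA_real_, c(nlk, 2L, n_frames))
    }
    for (f in seq_len(n_frames)) {
      txyz <- txyz0
      if (!is.null(torsions) && nlk > 0) {
        sm <- sample_torsion_basins(torsions, nlk)
        ts[, , f] <- sm
        for (l in seq_len(nlk))
          txyz <- set_linkage_torsion(mol$chain, txyz, l, sm[l, 1],
                                      sm[l, 2])
      }
      cen <- colMeans(txyz)
      ext <- max(sqrt(rowSums(sweep(txyz, 2, cen)^2)))
      xyz <- pose_molecule(sweep(txyz, 2, cen), mol$chain, states[m, f],
                           scenario, r_tube, system$box, ext, r_clear)
      if (scenario$jitter_sd > 0)
        xyz <- xyz + stats::rnorm(length(xyz), sd = scenario$jitter_sd)
      coords[rows, , f] <- xyz
    }
    if (!is.null(torsions) && nlk > 0) tsamples[[m]] <- ts
  }
  structure(list(atoms = system$atoms[, setdiff(names(system$atoms),
                                                c("x", "y", "z"))],
                 coords = coords, box = system$box,
                 times = (seq_len(n_frames) - 1) * dt_ps,
                 molecules = system$molecules,
                 fcnt_rows = system$fcnt_rows, ion_rows = system$ion_rows,
                 fcnt = system$fcnt, axis_xy = system$axis_xy,
                 states = states, torsion_samples = tsamples,
                 scenario = scenario, seed = seed),
            class = "cnt_traj")
}

#' Measured glycosidic torsions over a trajectory
#'
#' @param traj a `cnt_traj`.
#' @param molid molecule id.
#' @return list of data.frames (one per frame is wasteful; instead an
#'   array nlinkages x 2 x nframes of measured phi/psi, degrees).
#' @export
traj_torsions <- function(traj, molid) {
  chain <- traj$molecules[[molid]]$chain
  rows <- which(traj$atoms$type == "glycan" & traj$atoms$molid == molid)
  nlk <- nrow(chain$linkages)
  nf <- dim(traj$coords)[3]
  out <- array(NA_real_, c(nlk, 2L, nf),
               dimnames = list(NULL, c("phi", "psi"), NULL))
  quads <- lapply(seq_len(nlk), function(l) linkage_quadruples(chain, l))
  for (f in seq_len(nf)) {
    xyz <- traj$coords[rows, , f]
    for (l in seq_len(nlk)) {
      out[l, 1, f] <- torsion(xyz, quads[[l]]$phi)
      out[l, 2, f] <- torsion(xyz, quads[[l]]$psi)
    }
  }
  out
}

#' @export
print.cnt_traj <- function(x, ...) {
  cat(sprintf(
    "cnt_traj: %d atoms, %d frames (dt %.0f ps), %d molecules\n",
    dim(x$coords)[1], dim(x$coords)[3], diff(x$times[1:2]),
    length(x$molecules)))
  invisible(x)
}
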