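# Conformational analysis: glycosidic torsions, 2D free-energy maps by
# Boltzmann inversion, conformer-class occupancies, RMSF and Cremer-Pople
# ring puckering.

KB_KJMOL <- 0.0083144621  # Boltzmann constant, kJ/(mol K)

#' Thermodynamic context
#'
#' @param temperature_K temperature in kelvin (default 310, body
#'   temperature).
#' @return list with `temperature_K` and `kT` (kJ/mol).
#' @export
thermo_context <- function(temperature_K = 310) {
  stopifnot(temperature_K > 0)
  list(temperature_K = temperature_K, kT = KB_KJMOL * temperature_K)
}

#' Signed torsion angle of four atoms in a frame
#'
#' IUPAC convention: cis = 0 degrees, range (-180, 180].
#'
#' @param xyz n x 3 coordinate matrix (one frame).
#' @param quad four distinct atom indices.
#' @return angle in degrees.
#' @export
torsion <- function(xyz, quad) {
  stopifnot(length(quad) == 4, !anyDuplicated(quad))
  dihedral_points(xyz[quad[1], ], xyz[quad[2], ],
                  xyz[quad[3], ], xyz[quad[4], ])
}

#' Free-energy map over (phi, psi) by Boltzmann inversion
#'
#' The sample is histogrammed on a periodic grid; the free energy is
#' F = -kT * log(P / Pmax), so the modal bin has F = 0 and F >= 0
#' everywhere.  Bins with no samples are capped at
#' `max(finite F) + kT`.
#'
#' @param phi,psi torsion samples in degrees.
#' @param thermo a [thermo_context()].
#' @param bin_width grid spacing in degrees (default 5; must divide 360).
#' @return object of class `torsion_map`: `centers` (bin centers), `P`
#'   (probability matrix, phi rows x psi columns), `F` (kJ/mol), `n`,
#'   `kT`, `cap`.
#' @export
free_energy_map <- function(phi, psi, thermo = thermo_context(),
                            bin_width = 5) {
  stopifnot(length(phi) == length(psi), length(phi) >= 1)
  if (360 %% bin_width != 0) stop("bin_width must divide 360")
  nb <- as.integer(360 / bin_width)
  ix <- floor((wrap_angle(phi) + 180) / bin_width) %% nb + 1L
  iy <- floor((wrap_angle(psi) + 180) / bin_width) %% nb + 1L
  counts <- matrix(0, nb, nb)
  tb <- table(factor(ix, levels = 1:nb), factor(iy, levels = 1:nb))
  counts[] <- as.numeric(tb)
  P <- counts / length(phi)
  Fm <- matrix(NA_real_, nb, nb)
  occ <- P > 0
  Fm[occ] <- -thermo$kT * log(P[occ] / max(P))
  cap <- if (any(occ)) max(Fm[occ]) + thermo$kT else NA_real_
  Fm[!occ] <- cap
  structure(list(centers = -180 + (seq_len(nb) - 0.5) * bin_width,
                 P = P, F = Fm, n = length(phi), kT = thermo$kT,
                 cap = cap, bin_width = bin_width),
            class = "torsion_map")
}

#' Free-energy difference between two basins of a torsion map
#'
#' Averages the bin probabilities over a small periodic window around each
#' basin center (reducing single-bin shot noise) and returns
#' `-kT * log(P_b / P_a)`.
#'
#' @param map a `torsion_map`.
#' @param center_a,center_b c(phi, psi) basin centers in degrees.
#' @param half_bins half-width of the averaging window in bins (default 1,
#'   i.e. a 3x3 window).
#' @return free energy of basin b relative to basin a, kJ/mol.
#' @export
basin_delta_f <- function(map, center_a, center_b, half_bins = 1L) {
  nb <- length(map$centers)
  win <- function(center) {
    i0 <- floor((wrap_angle(center[1]) + 180) / map$bin_width) + 1L
    j0 <- floor((wrap_angle(center[2]) + 180) / map$bin_width) + 1L
    ii <- ((i0 - half_bins - 1L):(i0 + half_bins - 1L)) %% nb + 1L
    jj <- ((j0 - half_bins - 1L):(j0 + half_bins - 1L)) %% nb + 1L
    mean(map$P[ii, jj])
  }
  pa <- win(center_a); pb <- win(center_b)
  if (pa == 0 || pb == 0) stop("empty basin window")
  -map$kT * log(pb / pa)
}

#' Fraction of torsion samples in named angular windows
#'
#' Classes are windows on one torsion coordinate (typically psi):
#' syn-type conformers lie within a half-width of the canonical basin
#' value, anti-type within a half-width of that value + 180 degrees.
#' Windows in a single call must not overlap (report e.g. a quasi-trans
#' window in a separate call).
#'
#' @param samples torsion samples in degrees.
#' @param classes named list; each element c(center, half_width) degrees.
#' @return named numeric vector of fractions.
#' @export
conformer_occupancy <- function(samples, classes) {
  cent <- vapply(classes, `[`, 0, 1)
  hw <- vapply(classes, `[`, 0, 2)
  for (i in seq_along(classes)) for (j in seq_along(classes)) {
    if (i < j && abs(wrap_angle(cent[i] - cent[j])) < hw[i] + hw[j])
      stop("overlapping class windows: ", names(classes)[i], ", ",
           names(classes)[j])
  }
  vapply(seq_along(classes), function(i) {
    mean(abs(wrap_angle(samples - cent[i])) < hw[i])
  }, 0, USE.NAMES = FALSE) -> fr
  names(fr) <- names(classes)
  fr
}

#' Canonical conformer windows for the glycosidic psi torsion
#'
#' syn: within 60 degrees of the built canonical value (-110); anti:
#' within 60 degrees of that value + 180.  The quasi-trans window
#' (180 +/- 30) overlaps anti and is meant for a separate call.
#' @param which `"syn_anti"` or `"trans"`.
#' @export
psi_windows <- function(which = c("syn_anti", "trans")) {
  which <- match.arg(which)
  if (which == "syn_anti")
    list(syn = c(PSI_START, 60), anti = c(PSI_START + 180, 60))
  else list(trans = c(180, 30))
}

#' Root-mean-square fluctuation per atom
#'
#' `RMSF_i = sqrt(mean |r_i(t) - <r_i>|^2)` over frames.  With
#' `fit = TRUE` every frame is first superposed (least squares, proper
#' rotation) onto the mean structure of the fit selection, removing rigid
#' diffusion; with `fit = FALSE` raw coordinates are used.
#'
#' @param coords natoms x 3 x nframes array (angstrom).
#' @param sel atom indices to report (default all).
#' @param fit superpose frames before measuring.
#' @param fit_sel atoms used for the superposition (default `sel`).
#' @return numeric vector of RMSF values (angstrom) for `sel`.
#' @export
rmsf <- function(coords, sel = seq_len(dim(coords)[1]), fit = TRUE,
                 fit_sel = sel) {
  nf <- dim(coords)[3]
  if (nf < 2) stop("need at least 2 frames")
  if (fit) {
    ref <- coords[fit_sel, , 1, drop = TRUE]
    aligned <- coords
    for (it in 1:2) {
      for (f in seq_len(nf)) {
        tr <- kabsch(aligned[fit_sel, , f], ref)
        aligned[, , f] <- apply_rigid(aligned[, , f], tr)
      }
      ref <- apply(aligned[fit_sel, , , drop = FALSE], c(1, 2), mean)
    }
    coords <- aligned
  }
  mean_xyz <- apply(coords[sel, , , drop = FALSE], c(1, 2), mean)
  dev2 <- sweep(coords[sel, , , drop = FALSE], c(1, 2), mean_xyz)^2
  sqrt(apply(dev2, 1, sum) / nf)
}

#' Cremer-Pople puckering of a six-membered ring
#'
#' Computes the puckering amplitude Q (angstrom), polar angle theta and
#' phase phi_p (degrees) from the standard Cremer-Pople construction and
#' classifies the shape: chair when theta < 45 or > 135 degrees, otherwise
#' boat when phi_p lies within 15 degrees of a multiple of 60, else
#' skew-boat; undefined when Q < 0.1 angstrom (near-planar).  With ring
#' atoms ordered O5, C1..C5 the built 4C1 chair gives theta near 0.
#'
#' @param xyz coordinate matrix of the frame.
#' @param ring six atom indices in ring order O5, C1, C2, C3, C4, C5.
#' @return list(Q, theta, phi_p, class).
#' @export
ring_pucker <- function(xyz, ring) {
  if (length(ring) != 6) stop("need exactly 6 ring atoms")
  r <- xyz[ring, , drop = FALSE]
  r <- sweep(r, 2, colMeans(r))
  j <- 0:5
  r1 <- colSums(r * sin(2 * pi * j / 6))
  r2 <- colSums(r * cos(2 * pi * j / 6))
  nvec <- unitv(crossp(r1, r2))
  z <- as.numeric(r %*% nvec)
  q2c <- sqrt(2 / 6) * sum(z * cos(4 * pi * j / 6))
  q2s <- -sqrt(2 / 6) * sum(z * sin(4 * pi * j / 6))
  q3 <- sqrt(1 / 6) * sum(z * (-1)^j)
  q2 <- sqrt(q2c^2 + q2s^2)
  Q <- sqrt(q2^2 + q3^2)
  theta <- atan2(q2, q3) * 180 / pi
  phi_p <- (atan2(q2s, q2c) * 180 / pi) %% 360
  cls <- if (Q < 0.1) "undefined"
  else if (theta < 45 || theta > 135) "chair"
  else {
    m <- min(abs(wrap_angle(phi_p - seq(0, 300, by = 60))))
    if (m <= 15) "boat" else "skew-boat"
  }
  list(Q = Q, theta = theta, phi_p = phi_p, class = cls)
}
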