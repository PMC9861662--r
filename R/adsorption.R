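# Axis-referenced adsorption analysis: radial density profiles (raw
# counts, matching the "number of counts" convention), monolayer metrics,
# orientation-side classification from face-atom profiles, and
# detachment-event detection.

radial_distances <- function(traj, rows, frames) {
  ax <- traj$axis_xy
  dx <- min_image(traj$coords[rows, 1, frames, drop = FALSE] - ax[1],
                  traj$box[1])
  dy <- min_image(traj$coords[rows, 2, frames, drop = FALSE] - ax[2],
                  traj$box[2])
  sqrt(dx^2 + dy^2)
}

#' Radial density profile around the tube axis
#'
#' Histogram of the in-plane distance r = sqrt((x-x0)^2 + (y-y0)^2) of the
#' selected atoms from the tube axis, accumulated over frames, with
#' minimum image in x and y.  Counts are raw occurrence counts (not
#' volume-normalized), so they sum to `atoms x frames` when the range
#' covers the box.
#'
#' @param traj a `cnt_traj`.
#' @param rows atom row indices to histogram.
#' @param bin_width bin width in angstrom (default 0.5).
#' @param r_max histogram range (default: the box-corner distance, so
#'   every atom is counted).
#' @param frames frame subset.
#' @return object of class `radial_profile`: `edges`, `mids`, `counts`,
#'   `n_atoms`, `n_frames`.
#' @export
radial_profile <- function(traj, rows, bin_width = 0.5, r_max = NULL,
                           frames = seq_len(dim(traj$coords)[3])) {
  if (length(rows) == 0) stop("empty selection")
  if (is.null(r_max))
    r_max <- sqrt(sum((traj$box[1:2] / 2)^2)) + bin_width
  r <- radial_distances(traj, rows, frames)
  edges <- seq(0, ceiling(r_max / bin_width) * bin_width, by = bin_width)
  counts <- tabulate(pmin(floor(r / bin_width) + 1L, length(edges) - 1L),
                     nbins = length(edges) - 1L)
  structure(list(edges = edges, mids = edges[-1] - bin_width / 2,
                 counts = counts, n_atoms = length(rows),
                 n_frames = length(frames), bin_width = bin_width),
            class = "radial_profile")
}

#' Monolayer metrics of a radial profile
#'
#' @param profile a [radial_profile()].
#' @param radii radii (angstrom) at which cumulative fractions are
#'   reported (default the 15 and 20 angstrom layer criteria).
#' @param decay_level cumulative fraction defining the decay radius
#'   (default 0.99).
#' @return list: `fraction` (named cumulative fractions at `radii`),
#'   `decay_radius` (smallest r beyond which the cumulative fraction
#'   stays >= `decay_level`).
#' @export
layer_metrics <- function(profile, radii = c(15, 20), decay_level = 0.99) {
  cum <- cumsum(profile$counts) / sum(profile$counts)
  frac <- vapply(radii, function(r) {
    i <- findInterval(r, profile$edges[-1] - 1e-9)
    if (i == 0) 0 else cum[min(i, length(cum))]
  }, 0)
  names(frac) <- paste0("r", radii)
  decay_radius <- profile$edges[-1][which(cum >= decay_level)[1]]
  list(fraction = frac, decay_radius = decay_radius)
}

smooth3 <- function(x) {
  n <- length(x)
  as.numeric(stats::filter(x, rep(1 / 3, 3), sides = 2)) -> s
  s[1] <- mean(x[1:2]); s[n] <- mean(x[(n - 1):n])
  s
}

first_peak_radius <- function(profile, min_rel_height = 0.05) {
  s <- smooth3(profile$counts)
  thr <- min_rel_height * max(s)
  n <- length(s)
  for (i in seq_len(n)) {
    left <- if (i == 1) -Inf else s[i - 1]
    right <- if (i == n) -Inf else s[i + 1]
    if (s[i] > thr && s[i] >= left && s[i] > right)
      return(profile$mids[i])
  }
  NA_real_
}

#' Orientation-side classification from face-atom density profiles
#'
#' For every molecule of a residue class, profiles of the side-A (H1-H5)
#' and side-B (H2-H4 or H2-O4) atoms are accumulated; the preferred side
#' is the one whose smoothed profile peaks first (smaller first-peak
#' radius).  Within `tolerance` the call is `"indeterminate"`.
#'
#' @param traj a `cnt_traj`.
#' @param molids molecules to pool (default: all).
#' @param bin_width profile bin width, angstrom.
#' @param tolerance minimum peak separation for a determinate call
#'   (default 1 angstrom).
#' @return list: `side_a_peak`, `side_b_peak` (angstrom), `separation`,
#'   `label` in `{"A(H1-H5)", "B(H2-H4/O4)", "indeterminate"}`.
#' @export
orientation <- function(traj, molids = seq_along(traj$molecules),
                        bin_width = 0.5, tolerance = 1.0) {
  rows_a <- integer(0); rows_b <- integer(0)
  for (m in molids) {
    chain <- traj$molecules[[m]]$chain
    for (rn in seq_along(chain$residues)) {
      code <- chain$residues[rn]
      rows_a <- c(rows_a, molecule_rows(traj, m,
                                        names = face_atoms(code, "A"),
                                        resno = rn))
      rows_b <- c(rows_b, molecule_rows(traj, m,
                                        names = face_atoms(code, "B"),
                                        resno = rn))
    }
  }
  if (length(rows_a) == 0 || length(rows_b) == 0)
    stop("missing face atoms")
  pa <- radial_profile(traj, rows_a, bin_width)
  pb <- radial_profile(traj, rows_b, bin_width)
  ra <- first_peak_radius(pa); rb <- first_peak_radius(pb)
  sep <- rb - ra
  label <- if (is.na(sep) || abs(sep) < tolerance) "indeterminate"
  else if (sep > 0) "A(H1-H5)" else "B(H2-H4/O4)"
  list(side_a_peak = ra, side_b_peak = rb, separation = sep,
       label = label, profile_a = pa, profile_b = pb)
}

#' Detachment events of molecules from the tube surface
#'
#' The molecule position is the center of geometry of its ring atoms
#' (C1-C5, O5 of every residue).  An event is a run of at least
#' `min_frames` consecutive frames with center radial distance strictly
#' greater than `r_threshold`.
#'
#' @param traj a `cnt_traj`.
#' @param molids molecules to analyze.
#' @param r_threshold radial threshold, angstrom (default 20).
#' @param min_frames minimum run length (default 3).
#' @return list per molecule: data.frame(start, end) of events, plus
#'   `fraction_beyond` of molecule-frames past the threshold.
#' @export
detachment_events <- function(traj, molids = seq_along(traj$molecules),
                              r_threshold = 20, min_frames = 3L) {
  ring_names <- c("O5", "C1", "C2", "C3", "C4", "C5")
  nf <- dim(traj$coords)[3]
  out <- list()
  beyond_total <- 0L
  for (m in molids) {
    rows <- molecule_rows(traj, m, names = ring_names)
    # center of geometry of the ring atoms, then its radial distance
    cen_x <- colMeans(traj$coords[rows, 1, , drop = FALSE])
    cen_y <- colMeans(traj$coords[rows, 2, , drop = FALSE])
    r <- sqrt(min_image(cen_x - traj$axis_xy[1], traj$box[1])^2 +
              min_image(cen_y - traj$axis_xy[2], traj$box[2])^2)
    runs <- rle(as.vector(r > r_threshold))
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- runs$values & runs$lengths >= min_frames
    out[[as.character(m)]] <- data.frame(start = starts[keep],
                                         end = ends[keep])
    beyond_total <- beyond_total + sum(r > r_threshold)
  }
  list(events = out,
       fraction_beyond = beyond_total / (length(molids) * nf))
}
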