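# Pairwise nonbonded energetics: Lennard-Jones + Coulomb between atom
# groups with a plain cutoff and the minimum-image convention.
#
# E_LJ   = sum 4*eps_ij * ((sig_ij/r)^12 - (sig_ij/r)^6)
# E_coul = sum f * q_i * q_j / r,  f = 138.935458 kJ mol^-1 nm e^-2
#
# Long-range (reciprocal-space) electrostatics is deliberately absent:
# this is a truncated-sum analysis tool, not an MD engine, so absolute
# Coulomb values differ from Ewald-based references.

COULOMB_K <- 138.935458   # kJ mol^-1 nm e^-2

#' Nonbonded force-field parameters
#'
#' Per-type sigma (nm) and epsilon (kJ/mol) with Lorentz-Berthelot mixing
#' (arithmetic sigma, geometric epsilon).  The shipped table is a toy
#' element-based set for synthetic-trajectory work -- except Na+ and Cl-,
#' which carry the amber values used by the emulated study
#' (eps 0.366 / 0.149 kJ/mol, sigma 0.244 / 0.448 nm).  Real force-field
#' import is an extension point: supply your own table.
#'
#' @param table data.frame(type, sigma, epsilon); defaults to the shipped
#'   toy set keyed by element.
#' @param cutoff_nm interaction cutoff (default 1.2 nm).
#' @param coulomb_k Coulomb factor, kJ mol^-1 nm e^-2.
#' @return object of class `ff_params`.
#' @export
ff_params <- function(table = NULL, cutoff_nm = 1.2,
                      coulomb_k = COULOMB_K) {
  if (is.null(table))
    table <- data.frame(
      type = c("C", "O", "N", "H", "Na", "Cl"),
      sigma = c(0.340, 0.296, 0.325, 0.106, 0.244, 0.448),
      epsilon = c(0.360, 0.879, 0.711, 0.0657, 0.366, 0.149),
      stringsAsFactors = FALSE)
  stopifnot(all(c("type", "sigma", "epsilon") %in% names(table)),
            all(table$sigma >= 0), all(table$epsilon >= 0), cutoff_nm > 0)
  structure(list(table = table, cutoff_nm = cutoff_nm,
                 coulomb_k = coulomb_k, mixing = "lorentz-berthelot"),
            class = "ff_params")
}

#' Read a nonbonded parameter table
#'
#' Plain whitespace-separated text with a header line
#' `type sigma epsilon` (sigma in nm, epsilon in kJ/mol); comment lines
#' start with `#`.
#' @param path file path.
#' @param ... passed to [ff_params()].
#' @export
read_ff_table <- function(path, ...) {
  tb <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  ff_params(table = tb, ...)
}

lookup_params <- function(types, params) {
  i <- match(types, params$table$type)
  if (anyNA(i)) stop("unknown atom types: ",
                     paste(unique(types[is.na(i)]), collapse = ", "))
  list(sigma = params$table$sigma[i], epsilon = params$table$epsilon[i])
}

#' Pair-interaction energy between two atom groups in one frame
#'
#' Sums over all intergroup pairs with minimum-image distance r <= cutoff.
#' Distances enter in nm; coordinates are in angstrom.
#'
#' @param xyz natoms x 3 coordinate matrix, angstrom.
#' @param group_a,group_b disjoint atom index vectors.
#' @param charges per-atom charges (e) for all atoms.
#' @param types per-atom type labels matching the parameter table
#'   (default: the atom elements, via `attr(xyz, "element")` or the
#'   `elements` argument).
#' @param params an [ff_params()].
#' @param box c(Lx, Ly, Lz) in angstrom, or NULL for an open system.
#' @param elements per-atom elements used as types when `types` is NULL.
#' @return list(E_LJ, E_coulomb, E_total, n_overlap); `n_overlap` counts
#'   pairs closer than 0.5 angstrom (energies are still returned).
#' @export
pair_energy <- function(xyz, group_a, group_b, charges, params = ff_params(),
                        box = NULL, types = NULL, elements = NULL) {
  if (length(intersect(group_a, group_b)) > 0)
    stop("groups must be disjoint")
  if (is.null(types)) {
    if (is.null(elements)) stop("give types or elements")
    types <- elements
  }
  pa <- lookup_params(types[group_a], params)
  pb <- lookup_params(types[group_b], params)
  d_ang <- pair_distances(xyz[group_a, , drop = FALSE],
                          xyz[group_b, , drop = FALSE],
                          if (is.null(box)) c(NA, NA, NA) else box)
  r <- d_ang / 10                          # nm
  n_overlap <- sum(d_ang < 0.5)
  within <- r <= params$cutoff_nm
  sig <- outer(pa$sigma, pb$sigma, `+`) / 2
  eps <- sqrt(outer(pa$epsilon, pb$epsilon))
  qq <- outer(charges[group_a], charges[group_b])
  sr6 <- (sig[within] / r[within])^6
  e_lj <- sum(4 * eps[within] * (sr6^2 - sr6))
  e_c <- sum(params$coulomb_k * qq[within] / r[within])
  list(E_LJ = e_lj, E_coulomb = e_c, E_total = e_lj + e_c,
       n_overlap = n_overlap)
}

#' Per-frame, per-molecule fCNT interaction energies
#'
#' @param traj a `cnt_traj`.
#' @param params an [ff_params()].
#' @param frames frame subset (default all).
#' @return data.frame(frame, molid, class, E_LJ, E_coulomb, E_total).
#' @export
pair_energy_series <- function(traj, params = ff_params(),
                               frames = seq_len(dim(traj$coords)[3])) {
  stopifnot(length(traj$fcnt_rows) > 0)
  out <- list()
  charges <- traj$atoms$charge
  elements <- traj$atoms$element
  for (f in frames) {
    xyz <- traj$coords[, , f]
    for (m in seq_along(traj$molecules)) {
      rows <- which(traj$atoms$type == "glycan" & traj$atoms$molid == m)
      e <- pair_energy(xyz, traj$fcnt_rows, rows, charges, params,
                       box = traj$box, types = elements)
      out[[length(out) + 1L]] <- data.frame(
        frame = f, molid = m, class = traj$molecules[[m]]$kind,
        E_LJ = e$E_LJ, E_coulomb = e$E_coulomb, E_total = e$E_total)
    }
  }
  do.call(rbind, out)
}

#' Mean pair-interaction energy per molecule class
#'
#' Averages the per-frame, per-molecule fCNT interaction energy over all
#' molecules of a class and all frames; expressed per single molecule.
#' The uncertainty is the standard error of `n_blocks` block means over
#' the frame series (the emulated study never defines its error bars;
#' block averaging is this package's choice).
#'
#' @param traj a `cnt_traj`.
#' @param params an [ff_params()].
#' @param n_blocks number of blocks for the error estimate (default 5).
#' @return data.frame(class, E_LJ, E_coulomb, E_total, se, n_molecules,
#'   n_frames).
#' @export
mean_pair_energy <- function(traj, params = ff_params(), n_blocks = 5L) {
  nf <- dim(traj$coords)[3]
  if (nf < 2) stop("need at least 2 frames")
  ser <- pair_energy_series(traj, params)
  out <- list()
  for (cl in unique(ser$class)) {
    s <- ser[ser$class == cl, ]
    perfr <- stats::aggregate(s[, c("E_LJ", "E_coulomb", "E_total")],
                              by = list(frame = s$frame), FUN = mean)
    blk <- cut(seq_len(nrow(perfr)), n_blocks, labels = FALSE)
    bm <- tapply(perfr$E_total, blk, mean)
    se <- if (stats::sd(perfr$E_total) == 0) 0 else
      stats::sd(bm) / sqrt(length(bm))
    out[[cl]] <- data.frame(
      class = cl, E_LJ = mean(perfr$E_LJ),
      E_coulomb = mean(perfr$E_coulomb), E_total = mean(perfr$E_total),
      se = se, n_molecules = length(unique(s$molid)), n_frames = nf)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
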