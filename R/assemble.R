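# Simulation-box assembly: the fCNT on the box center axis, glycan copies
# placed around it without overlap, and Na+/Cl- ions at a prescribed ionic
# strength plus neutralizing counterions.  Explicit water is never placed;
# the analyses in this package do not use water coordinates, and the
# typical content of the emulated boxes (ca. 4200-4500 waters) is recorded
# as metadata only.

AVOGADRO_PER_NM3 <- 0.602214076   # N_A * (1 mol/L) in molecules per nm^3

#' Box specification
#'
#' @param lx,ly,lz edge lengths in nm; `lz` should equal the nanotube
#'   periodic length.
#' @export
box_spec <- function(lx = 5.5, ly = 5.5, lz = 5.952) {
  stopifnot(lx > 0, ly > 0, lz > 0)
  structure(list(lx = lx, ly = ly, lz = lz), class = "box_spec")
}

#' Salt ion counts for a box
#'
#' Number of Na+/Cl- pairs is `round(c * N_A * V)`; neutralizing
#' counterions for the net solute charge are added on top.
#'
#' @param conc_M ionic strength in mol/L.
#' @param volume_nm3 box volume in nm^3.
#' @param net_solute_charge total solute charge in e (integer).
#' @return list(n_na, n_cl).
#' @examples
#' ion_counts(0.15, 180)            # 16 pairs
#' @export
ion_counts <- function(conc_M, volume_nm3, net_solute_charge = 0) {
  stopifnot(conc_M >= 0, volume_nm3 > 0)
  base <- round(conc_M * AVOGADRO_PER_NM3 * volume_nm3)
  q <- round(net_solute_charge)
  list(n_na = base + max(0L, -q), n_cl = base + max(0L, q))
}

#' Enumerate the studied molecular systems
#'
#' Ten base systems (three monosaccharides and the two single decamers,
#' each against both carboxyl protonation states), four crowded systems
#' (four HA or Ch decamers per tube), and one free chondroitin chain in
#' water: fifteen descriptors in total.
#'
#' @param mono_copies number of monosaccharide molecules per box (not
#'   printed in the source study; default 20).
#' @return data.frame(label, saccharide, copies, fcnt).
#' @export
study_manifest <- function(mono_copies = 20L) {
  fcnts <- c("CNT-COOH", "CNT-COO-")
  base <- expand.grid(saccharide = c("GlcA", "GlcNAc", "GalNAc", "HA", "Ch"),
                      fcnt = fcnts, stringsAsFactors = FALSE)
  base$copies <- ifelse(base$saccharide %in% c("HA", "Ch"), 1L, mono_copies)
  base$label <- ifelse(base$copies == 1L,
                       paste0("1", base$saccharide, "/", base$fcnt),
                       paste0(base$saccharide, "/", base$fcnt))
  four <- expand.grid(saccharide = c("HA", "Ch"), fcnt = fcnts,
                      stringsAsFactors = FALSE)
  four$copies <- 4L
  four$label <- paste0("4", four$saccharide, "/", four$fcnt)
  free <- data.frame(saccharide = "Ch", fcnt = "none", copies = 1L,
                     label = "1Ch/water", stringsAsFactors = FALSE)
  out <- rbind(base, four, free)[, c("label", "saccharide", "copies", "fcnt")]
  rownames(out) <- NULL
  out
}

glycan_extent <- function(chain) {
  xyz <- as.matrix(chain$atoms[, c("x", "y", "z")])
  cen <- colMeans(xyz)
  max(sqrt(rowSums(sweep(xyz, 2, cen)^2)))
}

#' Assemble a periodic simulation box
#'
#' The nanotube axis runs along z through (0, 0); box coordinates span
#' `[-L/2, L/2)` in x and y and `[0, Lz)` in z.  Glycan copies are placed
#' at random poses with no interatomic distance below `min_dist` between
#' distinct molecules (minimum image), then ions are inserted the same
#' way.  Deterministic for a fixed seed.
#'
#' @param fcnt an `fcnt_model` (charges should already be redistributed),
#'   or NULL for a tube-free box.
#' @param glycan a `glycan_chain` to replicate.
#' @param copies number of copies to place.
#' @param box a [box_spec()]; default derives z from the tube period.
#' @param conc_M ionic strength (mol/L), default 0.15.
#' @param seed RNG seed.
#' @param min_dist minimum intermolecular distance, angstrom.
#' @param max_tries placement attempts per molecule before failing.
#' @return object of class `cnt_system`.
#' @export
assemble <- function(fcnt, glycan, copies = 1L, box = NULL, conc_M = 0.15,
                     seed = 1L, min_dist = 2.0, max_tries = 2000L) {
  if (is.null(box)) {
    lz <- if (!is.null(fcnt) && is.finite(fcnt$periodic_length))
      fcnt$periodic_length else 5.952
    box <- box_spec(lz = lz)
  }
  bx <- c(box$lx, box$ly, box$lz) * 10   # angstrom
  set.seed(seed)
  atoms <- NULL
  molecules <- list()
  if (!is.null(fcnt)) {
    fa <- fcnt$atoms
    atoms <- data.frame(type = "fcnt", molid = 0L, resname = "CNT",
                        resno = 1L, name = fa$name, element = fa$element,
                        charge = fa$charge, x = fa$x, y = fa$y, z = fa$z,
                        stringsAsFactors = FALSE)
  }
  placed <- if (is.null(atoms)) matrix(numeric(0), ncol = 3) else
    as.matrix(atoms[, c("x", "y", "z")])
  ext <- glycan_extent(glycan)
  r_tube <- if (!is.null(fcnt)) fcnt$meta$radius else 0
  txyz <- as.matrix(glycan$atoms[, c("x", "y", "z")])
  txyz <- sweep(txyz, 2, colMeans(txyz))
  for (m in seq_len(copies)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      r <- stats::runif(1, r_tube + 3, max(bx[1], 2 * (r_tube + 4)) / 2)
      th <- stats::runif(1, 0, 2 * pi)
      cen <- c(r * cos(th), r * sin(th), stats::runif(1, 0, bx[3]))
      xyz <- sweep(txyz %*% t(random_rotation()), 2, cen, `+`)
      if (nrow(placed) == 0 ||
          min(pair_distances(xyz, placed, bx)) >= min_dist) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop(sprintf("placement failed for molecule %d of %d", m,
                          copies))
    ga <- glycan$atoms
    newat <- data.frame(type = "glycan", molid = m, resname = ga$resname,
                        resno = ga$resno, name = ga$name,
                        element = ga$element, charge = ga$charge,
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        stringsAsFactors = FALSE)
    atoms <- rbind(atoms, newat)
    placed <- rbind(placed, xyz)
    molecules[[m]] <- list(molid = m, chain = glycan,
                           kind = if (length(glycan$residues) > 1)
                             glycan$kind %||% "oligomer"
                           else glycan$residues[1])
  }
  net <- sum(atoms$charge)
  if (abs(net - round(net)) > 1e-6)
    warning(sprintf("non-integral solute charge %.6f e", net))
  nion <- ion_counts(conc_M, prod(bx) / 1000, net)
  ion_el <- c(rep("Na", nion$n_na), rep("Cl", nion$n_cl))
  if (length(ion_el) > 0) {
    for (k in seq_along(ion_el)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        p <- c(stats::runif(1, -bx[1] / 2, bx[1] / 2),
               stats::runif(1, -bx[2] / 2, bx[2] / 2),
               stats::runif(1, 0, bx[3]))
        if (min(pair_distances(matrix(p, 1), placed, bx)) >= min_dist) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("ion placement failed")
      atoms <- rbind(atoms, data.frame(
        type = "ion", molid = NA_integer_, resname = ion_el[k],
        resno = 1L, name = ion_el[k], element = ion_el[k],
        charge = if (ion_el[k] == "Na") 1 else -1,
        x = p[1], y = p[2], z = p[3], stringsAsFactors = FALSE))
      placed <- rbind(placed, p)
    }
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, box = bx, axis_xy = c(0, 0),
                 fcnt = fcnt, molecules = molecules,
                 fcnt_rows = which(atoms$type == "fcnt"),
                 ion_rows = which(atoms$type == "ion"),
                 meta = list(seed = seed, conc_M = conc_M,
                             n_na = nion$n_na, n_cl = nion$n_cl,
                             water_note = paste("explicit water not",
                               "placed; emulated boxes hold ca. 4200-4500",
                               "TIP3P molecules"))),
            class = "cnt_system")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Atom row indices of one placed molecule
#' @param system a `cnt_system` (or `cnt_traj`).
#' @param molid molecule id (1-based).
#' @param names optional atom-name filter.
#' @param resno optional residue-number filter.
#' @export
molecule_rows <- function(system, molid, names = NULL, resno = NULL) {
  sel <- which(system$atoms$type == "glycan" & system$atoms$molid == molid)
  if (!is.null(resno)) sel <- sel[system$atoms$resno[sel] %in% resno]
  if (!is.null(names)) sel <- sel[system$atoms$name[sel] %in% names]
  sel
}

#' @export
print.cnt_system <- function(x, ...) {
  cat(sprintf(
    "cnt_system: %d atoms, %d glycan molecules, %d Na+ %d Cl-, box %s nm\n",
    nrow(x$atoms), length(x$molecules), x$meta$n_na, x$meta$n_cl,
    paste(sprintf("%.3f", x$box / 10), collapse = " x ")))
  cat(sprintf("  net charge %.6f e\n", sum(x$atoms$charge)))
  invisible(x)
}
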