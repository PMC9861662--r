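# Idealized 3D builders for GlcA, GlcNAc and GalNAc residues and for
# hyaluronan (HA) / chondroitin (Ch) decamers.
#
# Rings are built as ideal 4C1 chairs: the six ring atoms (ordered O5,
# C1..C5) sit at 60-degree steps on a circle of radius rho with z
# alternating +/- h, giving a uniform ring bond length.  Substituents are
# placed along ideal tetrahedral directions; axial vs equatorial is decided
# by the out-of-plane component.  GalNAc differs from GlcNAc only by the
# axial O4 (C4 epimer); GlcA carries a deprotonated carboxylate at C6
# (formal charge -1).  Glycosidic linkages use the IUPAC torsions
# phi = O5-C1-O1-C'n and psi = C1-O1-C'n-C'(n-1), n = 3 or 4.

RING_BOND <- 1.50          # uniform idealized ring bond length, angstrom
PHI_START <- -70           # initial glycosidic phi (syn basin), degrees
PSI_START <- -110          # initial glycosidic psi, degrees

ring_coords <- function() {
  b <- RING_BOND
  h <- 0.25 * b / 1.54
  rho <- sqrt(b^2 - 4 * h^2)
  j <- 0:5
  cbind(x = rho * cos(j * pi / 3), y = rho * sin(j * pi / 3),
        z = h * (-1)^(j + 1))
}

# tetrahedral substituent directions at ring position j (0-based; ring xyz
# as rows O5,C1..C5): returns list(axial, equatorial) unit vectors
subst_dirs <- function(ring, j) {
  p <- ring[j + 1, ]
  u1 <- unitv(ring[(j - 1) %% 6 + 1, ] - p)
  u2 <- unitv(ring[(j + 1) %% 6 + 1, ] - p)
  w <- -unitv(u1 + u2)
  v <- unitv(crossp(u1, u2))
  delta <- 54.75 * pi / 180
  d1 <- w * cos(delta) + v * sin(delta)
  d2 <- w * cos(delta) - v * sin(delta)
  if (abs(d1[3]) >= abs(d2[3])) list(axial = d1, equatorial = d2)
  else list(axial = d2, equatorial = d1)
}

#' Idealized residue template
#'
#' Returns the atom table (IUPAC names, elements, positions in angstrom,
#' charges in e) of a single beta-D residue in an ideal 4C1 chair.
#'
#' @param code one of `"GlcA"`, `"GlcNAc"`, `"GalNAc"`.
#' @return list with `atoms`, `code`, `formal_charge`.
#' @export
residue_template <- function(code = c("GlcA", "GlcNAc", "GalNAc")) {
  code <- match.arg(code)
  ring <- ring_coords()
  rn <- c("O5", "C1", "C2", "C3", "C4", "C5")
  center <- colMeans(ring)
  atoms <- data.frame(name = rn,
                      element = substr(rn, 1, 1),
                      x = ring[, 1], y = ring[, 2], z = ring[, 3],
                      charge = 0, stringsAsFactors = FALSE)
  add <- function(name, element, pos, charge = 0) {
    atoms <<- rbind(atoms, data.frame(name = name, element = element,
                                      x = pos[1], y = pos[2], z = pos[3],
                                      charge = charge,
                                      stringsAsFactors = FALSE))
  }
  pos_of <- function(name) {
    as.numeric(atoms[match(name, atoms$name), c("x", "y", "z")])
  }
  hydroxyl <- function(cn, j, orient) {
    d <- subst_dirs(ring, j)[[orient]]
    o <- ring[j + 1, ] + 1.43 * d
    add(sub("C", "O", cn), "O", o)
    add(sub("C", "HO", cn), "H", o + 0.96 * unitv(o - center))
  }
  ring_h <- function(cn, j, orient) {
    d <- subst_dirs(ring, j)[[orient]]
    add(sub("C", "H", cn), "H", ring[j + 1, ] + 1.10 * d)
  }
  # C1: beta anomer, O1 equatorial, H1 axial
  hydroxyl("C1", 1, "equatorial"); ring_h("C1", 1, "axial")
  # C2: O2 (GlcA) or N-acetyl (GlcNAc/GalNAc), equatorial; H2 axial
  if (code == "GlcA") hydroxyl("C2", 2, "equatorial")
  ring_h("C2", 2, "axial")
  # C3: O3 equatorial, H3 axial
  hydroxyl("C3", 3, "equatorial"); ring_h("C3", 3, "axial")
  # C4: O4 equatorial for gluco-configuration, axial for galacto (GalNAc)
  if (code == "GalNAc") {
    hydroxyl("C4", 4, "axial"); ring_h("C4", 4, "equatorial")
  } else {
    hydroxyl("C4", 4, "equatorial"); ring_h("C4", 4, "axial")
  }
  # C5: exocyclic C6 equatorial, H5 axial
  d5 <- subst_dirs(ring, 5)
  c6 <- ring[6, ] + 1.52 * d5$equatorial
  add("C6", "C", c6); ring_h("C5", 5, "axial")
  u <- unitv(c6 - ring[6, ])
  p <- unitv(crossp(u, if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)))
  if (code == "GlcA") {
    # deprotonated carboxylate: two equivalent oxygens, -0.5 e each
    add("O6A", "O", c6 + 1.25 * unitv(u * cos(pi / 3) + p * sin(pi / 3)),
        charge = -0.5)
    add("O6B", "O", c6 + 1.25 * unitv(u * cos(pi / 3) - p * sin(pi / 3)),
        charge = -0.5)
  } else {
    add("H61", "H", c6 + 1.10 * unitv(u * cos(1.2) + p * sin(1.2)))
    add("H62", "H", c6 + 1.10 * unitv(u * cos(1.2) - p * sin(1.2)))
    o6 <- c6 + 1.43 * u
    add("O6", "O", o6)
    add("HO6", "H", o6 + 0.96 * u)
  }
  if (code != "GlcA") {
    # N-acetyl at C2 (planar amide, methyl cap)
    dn <- subst_dirs(ring, 2)$equatorial
    n2 <- ring[3, ] + 1.45 * dn
    un <- unitv(n2 - ring[3, ])
    q <- unitv(crossp(un, if (abs(un[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)))
    add("N2", "N", n2)
    add("HN2", "H", n2 + 1.01 * unitv(un * cos(pi / 3) + q * sin(pi / 3)))
    c7 <- n2 + 1.33 * unitv(un * cos(pi / 3) - q * sin(pi / 3))
    add("C7", "C", c7)
    u7 <- unitv(c7 - n2)
    add("O7", "O", c7 + 1.23 * unitv(u7 * cos(pi / 3) + q * sin(pi / 3)))
    c8 <- c7 + 1.50 * unitv(u7 * cos(pi / 3) - q * sin(pi / 3))
    add("C8", "C", c8)
    b8 <- unitv(c8 - c7)
    e1 <- unitv(crossp(b8, q)); e2 <- crossp(b8, e1)
    for (k in 0:2)
      add(paste0("H8", k + 1), "H",
          c8 + 1.10 * (b8 * (1 / 3) +
                       (cos(2 * pi * k / 3) * e1 +
                        sin(2 * pi * k / 3) * e2) * sqrt(8) / 3))
  }
  list(atoms = atoms, code = code,
       formal_charge = if (code == "GlcA") -1L else 0L)
}

resname3 <- c(GlcA = "GCA", GlcNAc = "NAG", GalNAc = "NGA")

new_glycan_chain <- function(atoms, residues, linkages) {
  structure(list(atoms = atoms, residues = residues, linkages = linkages,
                 reducing_end = TRUE,
                 formal_charge = sum(residues == "GlcA") * -1L),
            class = "glycan_chain")
}

glycan_atom_idx <- function(chain, resno, name) {
  i <- which(chain$atoms$resno == resno & chain$atoms$name == name)
  if (length(i) != 1L)
    stop(sprintf("atom %s of residue %d not found", name, resno))
  i
}

#' Build a single monosaccharide
#'
#' @param code `"GlcA"`, `"GlcNAc"` or `"GalNAc"`.
#' @return a `glycan_chain` with one residue and no linkages.
#' @export
build_monosaccharide <- function(code) {
  tmpl <- residue_template(code)
  atoms <- cbind(tmpl$atoms,
                 resname = resname3[[code]], resno = 1L,
                 stringsAsFactors = FALSE)
  new_glycan_chain(atoms, residues = code,
                   linkages = data.frame(donor = integer(0),
                                         acceptor = integer(0),
                                         type = character(0),
                                         n = integer(0)))
}

# Append residue `code` to the chain through a beta-1,n linkage from the
# last residue's C1, at torsions (phi, psi).  The donor O1 becomes the
# glycosidic oxygen (its HO1 is removed); the acceptor's On/HOn are removed.
extend_chain <- function(chain, code, n, phi = PHI_START, psi = PSI_START) {
  i <- length(chain$residues)
  tmpl <- residue_template(code)
  cn <- paste0("C", n); on <- paste0("O", n); cn1 <- paste0("C", n - 1)
  tp <- function(name) {
    as.numeric(tmpl$atoms[match(name, tmpl$atoms$name), c("x", "y", "z")])
  }
  o5d <- chain$atoms[glycan_atom_idx(chain, i, "O5"), c("x", "y", "z")]
  c1d <- chain$atoms[glycan_atom_idx(chain, i, "C1"), c("x", "y", "z")]
  o1d <- chain$atoms[glycan_atom_idx(chain, i, "O1"), c("x", "y", "z")]
  o5d <- as.numeric(o5d); c1d <- as.numeric(c1d); o1d <- as.numeric(o1d)
  b_on_cn <- vnorm(tp(on) - tp(cn))
  b_cn_cn1 <- vnorm(tp(cn) - tp(cn1))
  a_on_cn_cn1 <- acos(sum(unitv(tp(on) - tp(cn)) *
                          unitv(tp(cn1) - tp(cn)))) * 180 / pi
  cn_t <- place_atom(o5d, c1d, o1d, b_on_cn, 117, phi)
  cn1_t <- place_atom(c1d, o1d, cn_t, b_cn_cn1, a_on_cn_cn1, psi)
  tr <- kabsch(rbind(tp(on), tp(cn), tp(cn1)), rbind(o1d, cn_t, cn1_t))
  keep <- !(tmpl$atoms$name %in% c(on, sub("O", "HO", on)))
  newat <- tmpl$atoms[keep, , drop = FALSE]
  xyz <- apply_rigid(as.matrix(newat[, c("x", "y", "z")]), tr)
  newat$x <- xyz[, 1]; newat$y <- xyz[, 2]; newat$z <- xyz[, 3]
  newat <- cbind(newat, resname = resname3[[code]], resno = i + 1L,
                 stringsAsFactors = FALSE)
  # the donor HO1 is displaced by the linkage
  drop <- which(chain$atoms$resno == i & chain$atoms$name == "HO1")
  atoms <- rbind(chain$atoms[-drop, , drop = FALSE], newat)
  rownames(atoms) <- NULL
  lk <- rbind(chain$linkages,
              data.frame(donor = i, acceptor = i + 1L,
                         type = paste0("b1", n), n = n))
  new_glycan_chain(atoms, c(chain$residues, code), lk)
}

#' Build an HA or Ch decamer (or a shorter oligomer)
#'
#' Residues alternate GlcA and the N-acetyl hexosamine (GlcNAc for HA,
#' GalNAc for Ch), joined by alternating beta-1,3 (from GlcA) and
#' beta-1,4 (from the hexosamine) linkages; the reducing end is left
#' unfunctionalized.  All linkages start in the syn basin
#' (phi = -70, psi = -110 degrees).
#'
#' @param kind `"HA"` or `"Ch"`.
#' @param length number of residues (default 10).
#' @return a `glycan_chain` with `length` residues and `length - 1`
#'   linkages.
#' @examples
#' ha <- build_decamer("HA")
#' ha$formal_charge  # -5: five deprotonated GlcA residues
#' @export
build_decamer <- function(kind = c("HA", "Ch"), length = 10L) {
  kind <- match.arg(kind)
  hexnac <- if (kind == "HA") "GlcNAc" else "GalNAc"
  codes <- rep(c("GlcA", hexnac), length.out = length)
  chain <- build_monosaccharide(codes[1])
  for (i in seq_len(length - 1L)) {
    n <- if (codes[i] == "GlcA") 3L else 4L
    chain <- extend_chain(chain, codes[i + 1L], n)
  }
  chain$kind <- kind
  chain
}

#' Torsion-defining atom indices of a linkage
#'
#' @param chain a `glycan_chain`.
#' @param linkage linkage number (row of `chain$linkages`).
#' @return list with `phi` and `psi`, each 4 atom indices into
#'   `chain$atoms`: phi = (O5, C1, O1, C'n), psi = (C1, O1, C'n, C'(n-1)).
#' @export
linkage_quadruples <- function(chain, linkage) {
  lk <- chain$linkages[linkage, ]
  d <- lk$donor; a <- lk$acceptor; n <- lk$n
  gi <- function(r, nm) glycan_atom_idx(chain, r, nm)
  list(phi = c(gi(d, "O5"), gi(d, "C1"), gi(d, "O1"), gi(a, paste0("C", n))),
       psi = c(gi(d, "C1"), gi(d, "O1"), gi(a, paste0("C", n)),
               gi(a, paste0("C", n - 1L))))
}

#' Measure all glycosidic torsions of a chain
#'
#' @param chain a `glycan_chain`.
#' @param xyz optional coordinate matrix overriding `chain$atoms` (same
#'   atom order), e.g. a trajectory frame.
#' @return data.frame(linkage, type, phi, psi) in degrees.
#' @export
glycan_torsions <- function(chain, xyz = NULL) {
  if (is.null(xyz)) xyz <- as.matrix(chain$atoms[, c("x", "y", "z")])
  nlk <- nrow(chain$linkages)
  out <- data.frame(linkage = seq_len(nlk), type = chain$linkages$type,
                    phi = NA_real_, psi = NA_real_)
  for (l in seq_len(nlk)) {
    q <- linkage_quadruples(chain, l)
    out$phi[l] <- dihedral_points(xyz[q$phi[1], ], xyz[q$phi[2], ],
                                  xyz[q$phi[3], ], xyz[q$phi[4], ])
    out$psi[l] <- dihedral_points(xyz[q$psi[1], ], xyz[q$psi[2], ],
                                  xyz[q$psi[3], ], xyz[q$psi[4], ])
  }
  out
}

#' Set one linkage's torsions on a coordinate matrix
#'
#' Rotates everything downstream of the linkage (residues past the donor)
#' about the C1-O1 axis to reach the requested phi, then about the O1-C'n
#' axis for psi; upstream atoms and all internal geometry are untouched.
#'
#' @param chain a `glycan_chain`.
#' @param xyz coordinate matrix for the chain's atoms.
#' @param linkage linkage number.
#' @param phi,psi target torsions in degrees.
#' @return the modified coordinate matrix.
#' @export
set_linkage_torsion <- function(chain, xyz, linkage, phi, psi) {
  q <- linkage_quadruples(chain, linkage)
  lk <- chain$linkages[linkage, ]
  downstream <- which(chain$atoms$resno > lk$donor)
  rot <- function(xyz, axis_from, axis_to, quad, target) {
    cur <- dihedral_points(xyz[quad[1], ], xyz[quad[2], ],
                           xyz[quad[3], ], xyz[quad[4], ])
    delta <- (target - cur) * pi / 180
    p0 <- xyz[axis_from, ]
    ax <- xyz[axis_to, ] - p0
    xyz[downstream, ] <- rotate_about_axis(
      xyz[downstream, , drop = FALSE], p0, ax, delta)
    new <- dihedral_points(xyz[quad[1], ], xyz[quad[2], ],
                           xyz[quad[3], ], xyz[quad[4], ])
    if (abs(wrap_angle(new - target)) > 1e-6) {
      xyz[downstream, ] <- rotate_about_axis(
        xyz[downstream, , drop = FALSE], p0, ax, -2 * delta)
    }
    xyz
  }
  xyz <- rot(xyz, q$phi[2], q$phi[3], q$phi, phi)
  rot(xyz, q$psi[2], q$psi[3], q$psi, psi)
}

#' Atoms defining a molecular face
#'
#' Each pyranose presents two faces: side A carries the H1 and H5 ring
#' hydrogens, side B the H2 and H4 hydrogens -- except for GalNAc, whose
#' axial O4 replaces H4 on that side.  The orientation statistic uses
#' exactly these pairs; `extended = TRUE` additionally includes H3 on side
#' A for geometric robustness.
#'
#' @param code residue code.
#' @param side `"A"` or `"B"`.
#' @param extended include H3 on side A.
#' @return character vector of atom names.
#' @export
face_atoms <- function(code = c("GlcA", "GlcNAc", "GalNAc"),
                       side = c("A", "B"), extended = FALSE) {
  code <- match.arg(code); side <- match.arg(side)
  if (side == "A") {
    if (extended) c("H1", "H3", "H5") else c("H1", "H5")
  } else {
    if (code == "GalNAc") c("H2", "O4") else c("H2", "H4")
  }
}

#' @export
print.glycan_chain <- function(x, ...) {
  cat(sprintf("glycan_chain: %d residues (%s), %d atoms, charge %+d e\n",
              length(x$residues), paste(x$residues, collapse = "-"),
              nrow(x$atoms), x$formal_charge))
  invisible(x)
}
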