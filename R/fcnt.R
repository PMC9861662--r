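# Functionalized carbon nanotube (fCNT) builder.
#
# Zigzag (n,0) tubes are generated by rolling a graphene sheet: lattice
# vectors a1 = a(1,0), a2 = a(1/2, sqrt(3)/2) with a = sqrt(3)*a_cc, chiral
# vector C = n*a1 (rolled direction), translational period T = 3*a_cc along
# the tube axis (z).  Each translational cell carries 4n carbons.  Carboxyl
# groups are grafted onto randomly chosen wall carbons; the anchor carbon
# and one bonded neighbor are rehybridized sp2 -> sp3 (the neighbor receives
# a hydrogen to keep its valence), and the residual group charge is spread
# uniformly over the remaining wall carbons so the net charge is exactly
# -1 e per carboxylate group (0 per carboxylic acid).

# Default aromatic C-C distance, nm.  Chosen so that the 14-cell (17,0)
# period equals the 5.952 nm box edge exactly (3 * a_cc * 14 = 5.952 nm);
# within 0.3% of the graphite value.
A_CC_DEFAULT_NM <- 5.952 / 42

#' Lattice specification for a zigzag (n,0) nanotube
#'
#' @param chirality_n chiral index n of the zigzag (n,0) tube; must be >= 5.
#' @param cells number of translational unit cells along the axis (each
#'   cell holds `4 * chirality_n` carbons and spans `3 * a_cc`).
#' @param a_cc carbon-carbon bond length in nm.
#' @return object of class `lattice_spec`.
#' @export
lattice_spec <- function(chirality_n, cells, a_cc = A_CC_DEFAULT_NM) {
  if (chirality_n < 5) stop("degenerate tube: chirality_n must be >= 5")
  if (cells < 1) stop("cells must be >= 1")
  if (a_cc <= 0) stop("a_cc must be positive")
  structure(list(chirality_n = as.integer(chirality_n),
                 cells = as.integer(cells), a_cc = a_cc),
            class = "lattice_spec")
}

# Raw wall-atom coordinates (angstrom) for `cells` periodic cells of an
# (n,0) tube; z in [0, 3*a_cc*cells).
zigzag_wall_coords <- function(n, cells, a_cc_ang) {
  a <- sqrt(3) * a_cc_ang              # graphene lattice constant
  radius <- sqrt(3) * n * a_cc_ang / (2 * pi)
  # one period: 4 z-levels at 0, a_cc/2, 3a_cc/2, 2a_cc; n atoms per level
  i <- rep(seq_len(n) - 1L, times = 4L)
  lev <- rep(0:3, each = n)
  # unrolled x (along chiral vector) and y (-> z) per level
  x <- a * (i + c(0, 0.5, 0.5, 1)[lev + 1L])
  z1 <- a_cc_ang * c(0, 0.5, 1.5, 2)[lev + 1L]
  xs <- rep(x, times = cells)
  zs <- rep(z1, times = cells) + rep((seq_len(cells) - 1L) * 3 * a_cc_ang,
                                     each = 4L * n)
  theta <- 2 * pi * (xs %% (n * a)) / (n * a)
  cbind(x = radius * cos(theta), y = radius * sin(theta), z = zs)
}

# Bond list by brute-force neighbor search at `cutoff` (angstrom), with
# minimum image along z when box_z is finite.  Returns matrix [i, j,
# periodic] with i < j; periodic = 1 when the bond crosses the z boundary.
detect_bonds <- function(xyz, cutoff = 1.6, box_z = NA) {
  d <- pair_distances(xyz, xyz, box = c(NA, NA, box_z))
  d[upper.tri(d, diag = TRUE)] <- Inf
  idx <- which(d < cutoff & d > 0.1, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(matrix(integer(0), ncol = 3,
                  dimnames = list(NULL, c("i", "j", "periodic"))))
  per <- if (is.na(box_z)) rep(0L, nrow(idx)) else
    as.integer(abs(xyz[idx[, 1], 3] - xyz[idx[, 2], 3]) > box_z / 2)
  cbind(i = idx[, 2], j = idx[, 1], periodic = per)
}

# Angles (all bonded triplets) and proper dihedrals (all bonded
# quadruplets) from a bond list; a term is flagged periodic when any of
# its constituent bonds is.
bonded_terms <- function(bonds, natoms) {
  nb <- vector("list", natoms)
  per <- new.env(hash = TRUE)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
    assign(paste(min(i, j), max(i, j)), bonds[k, 3], envir = per)
  }
  bper <- function(i, j) get(paste(min(i, j), max(i, j)), envir = per)
  ang <- list(); dih <- list()
  for (j in seq_len(natoms)) {
    ns <- nb[[j]]
    if (length(ns) >= 2) {
      cmb <- utils::combn(sort(ns), 2)
      for (c2 in seq_len(ncol(cmb))) {
        i <- cmb[1, c2]; k <- cmb[2, c2]
        ang[[length(ang) + 1L]] <- c(i, j, k, bper(i, j) | bper(j, k))
      }
    }
  }
  for (b in seq_len(nrow(bonds))) {
    j <- bonds[b, 1]; k <- bonds[b, 2]
    for (i in setdiff(nb[[j]], k)) for (l in setdiff(nb[[k]], j)) {
      if (i == l) next
      q <- c(i, j, k, l)
      if (i > l) q <- rev(q)
      dih[[paste(q, collapse = " ")]] <-
        c(q, bper(i, j) | bper(j, k) | bper(k, l))
    }
  }
  list(
    angles = if (length(ang)) do.call(rbind, ang) else
      matrix(integer(0), ncol = 4),
    dihedrals = if (length(dih)) do.call(rbind, unname(dih)) else
      matrix(integer(0), ncol = 5))
}

new_fcnt_model <- function(atoms, bonds, periodic_length, meta) {
  terms <- bonded_terms(bonds, nrow(atoms))
  structure(list(atoms = atoms, bonds = bonds,
                 angles = terms$angles, dihedrals = terms$dihedrals,
                 periodic_length = periodic_length,
                 net_charge = sum(atoms$charge), meta = meta),
            class = "fcnt_model")
}

#' Build a periodic, unfunctionalized zigzag nanotube
#'
#' All carbons are placed exactly on the ideal cylinder of radius
#' `sqrt(3) * n * a_cc / (2*pi)`, axis along z, z in `[0, 3*a_cc*cells)`.
#' Bonds, angles and dihedrals wrap across the periodic z boundary and are
#' flagged as such.  All charges are zero.
#'
#' @param spec a [lattice_spec()].
#' @return an `fcnt_model`: atom table (element, name, charge, position in
#'   angstrom, sp2/sp3 tag), bond/angle/dihedral index tables with periodic
#'   flags, `periodic_length` (nm) and `net_charge` (e).
#' @examples
#' m <- build_zigzag_cnt(lattice_spec(17, 14))
#' nrow(m$atoms)  # 952
#' @export
build_zigzag_cnt <- function(spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  a_ang <- spec$a_cc * 10
  xyz <- zigzag_wall_coords(spec$chirality_n, spec$cells, a_ang)
  atoms <- data.frame(element = "C", name = "C", charge = 0,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      hyb = "sp2", wall = TRUE, motif = NA_integer_,
                      stringsAsFactors = FALSE)
  lz <- 3 * a_ang * spec$cells
  bonds <- detect_bonds(xyz, box_z = lz)
  new_fcnt_model(atoms, bonds, periodic_length = lz / 10,
                 meta = list(chirality_n = spec$chirality_n,
                             cells = spec$cells, a_cc = spec$a_cc,
                             radius = sqrt(3) * spec$chirality_n * a_ang /
                               (2 * pi),
                             group_kind = "none", n_groups = 0L,
                             n_carboxylate = 0L))
}

#' Default partial charges for the carboxyl grafting motif
#'
#' The motif comprises the sp3 anchor carbon bearing the carboxyl group,
#' the rehybridized sp3 neighbor carbon with its added hydrogen, the
#' carboxyl carbon and its two oxygens (plus the acidic hydrogen for the
#' protonated form), and a small induced charge on each wall carbon
#' adjacent to the two sp3 centers.  The shipped values are a
#' configuration default whose group sums are deliberately non-integral;
#' [redistribute_residual_charge()] restores the exact formal charge.
#'
#' @param group_kind `"carboxylate"` or `"carboxylic_acid"`.
#' @param ... named overrides for individual charges (e).
#' @return object of class `motif_charge_set`.
#' @export
motif_charge_set <- function(group_kind = c("carboxylate", "carboxylic_acid"),
                             ...) {
  group_kind <- match.arg(group_kind)
  ch <- if (group_kind == "carboxylate") {
    list(anchor = 0.08, neighbor = -0.12, neighbor_h = 0.12,
         carboxyl_c = 0.74, o1 = -0.80, o2 = -0.80, ho = NULL,
         wall_adj = -0.04)
  } else {
    list(anchor = 0.08, neighbor = -0.12, neighbor_h = 0.12,
         carboxyl_c = 0.66, o1 = -0.58, o2 = -0.62, ho = 0.44,
         wall_adj = -0.04)
  }
  over <- list(...)
  for (nm in names(over)) ch[[nm]] <- over[[nm]]
  stopifnot(all(vapply(ch[!vapply(ch, is.null, TRUE)], is.finite, TRUE)))
  structure(c(ch, list(group_kind = group_kind)), class = "motif_charge_set")
}

#' Grafting specification
#'
#' @param group_kind carboxylate or carboxylic_acid.
#' @param n_groups number of groups; alternatively give `coverage_fraction`
#'   (fraction of wall carbons; the count is `ceiling(coverage * N_C)`).
#' @param coverage_fraction see above (e.g. 0.02).
#' @param rng_seed integer seed making anchor selection reproducible.
#' @param min_anchor_separation minimum bond-graph distance between any two
#'   anchor carbons (default 3, preventing fused motifs).
#' @export
graft_spec <- function(group_kind = c("carboxylate", "carboxylic_acid"),
                       n_groups = NULL, coverage_fraction = NULL,
                       rng_seed = 1L, min_anchor_separation = 3L) {
  group_kind <- match.arg(group_kind)
  if (is.null(n_groups) && is.null(coverage_fraction))
    stop("give n_groups or coverage_fraction")
  structure(list(group_kind = group_kind, n_groups = n_groups,
                 coverage_fraction = coverage_fraction,
                 rng_seed = as.integer(rng_seed),
                 min_anchor_separation = as.integer(min_anchor_separation)),
            class = "graft_spec")
}

# adjacency list over a bond matrix
adjacency_list <- function(bonds, natoms) {
  nb <- vector("list", natoms)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

# all atoms within bond-graph distance < sep of `start` (BFS)
graph_ball <- function(nb, start, sep) {
  seen <- start; frontier <- start
  for (d in seq_len(sep - 1L)) {
    frontier <- setdiff(unique(unlist(nb[frontier])), seen)
    if (length(frontier) == 0L) break
    seen <- c(seen, frontier)
  }
  seen
}

# Internal: add one carboxyl motif at (anchor, neighbor); returns updated
# atoms/bonds.  Geometry: carboxyl carbon 1.52 A outward from the anchor
# (tilted away from the neighbor), sp2 oxygens splayed 62 deg either side,
# neighbor hydrogen 1.09 A outward tilted away from the anchor.
add_motif <- function(atoms, bonds, anchor, neighbor, charges, motif_id) {
  kind <- charges$group_kind
  pa <- as.numeric(atoms[anchor, c("x", "y", "z")])
  pn <- as.numeric(atoms[neighbor, c("x", "y", "z")])
  r_a <- unitv(c(pa[1], pa[2], 0))
  r_n <- unitv(c(pn[1], pn[2], 0))
  tv <- unitv(pn - pa)
  c_pos <- pa + 1.52 * unitv(r_a - 0.30 * tv)
  u <- unitv(c_pos - pa)
  p <- unitv(crossp(u, tv))          # roughly axial, keeps O away from wall
  o1 <- c_pos + 1.25 * unitv(u * cos(62 * pi / 180) + p * sin(62 * pi / 180))
  o2 <- c_pos + 1.25 * unitv(u * cos(62 * pi / 180) - p * sin(62 * pi / 180))
  hn <- pn + 1.09 * unitv(r_n + 0.35 * tv)
  newat <- data.frame(
    element = c("C", "O", "O", "H"),
    name = c("CX", "OX1", "OX2", "HC"),
    charge = c(charges$carboxyl_c, charges$o1, charges$o2,
               charges$neighbor_h),
    x = c(c_pos[1], o1[1], o2[1], hn[1]),
    y = c(c_pos[2], o1[2], o2[2], hn[2]),
    z = c(c_pos[3], o1[3], o2[3], hn[3]),
    hyb = c("sp2", NA, NA, NA), wall = FALSE, motif = motif_id,
    stringsAsFactors = FALSE)
  if (kind == "carboxylic_acid") {
    ho <- o2 + 0.96 * unitv(o2 - c_pos)
    newat <- rbind(newat, data.frame(
      element = "H", name = "HO", charge = charges$ho,
      x = ho[1], y = ho[2], z = ho[3], hyb = NA, wall = FALSE,
      motif = motif_id, stringsAsFactors = FALSE))
  }
  base <- nrow(atoms)
  atoms$hyb[c(anchor, neighbor)] <- "sp3"
  atoms$motif[c(anchor, neighbor)] <- motif_id
  atoms$charge[anchor] <- atoms$charge[anchor] + charges$anchor
  atoms$charge[neighbor] <- atoms$charge[neighbor] + charges$neighbor
  atoms <- rbind(atoms, newat)
  cx <- base + 1L
  nb2 <- rbind(c(anchor, cx, 0L), c(cx, base + 2L, 0L), c(cx, base + 3L, 0L),
               c(neighbor, base + 4L, 0L))
  if (kind == "carboxylic_acid")
    nb2 <- rbind(nb2, c(base + 3L, base + 5L, 0L))
  colnames(nb2) <- c("i", "j", "periodic")
  list(atoms = atoms, bonds = rbind(bonds, nb2))
}

#' Graft carboxyl groups onto a nanotube model
#'
#' Anchors are drawn without replacement from the wall carbons (seeded),
#' subject to a minimum bond-graph separation; for each anchor one bonded
#' wall neighbor is chosen at random and rehybridized together with the
#' anchor.  Motif charges are applied verbatim; call
#' [redistribute_residual_charge()] afterwards to restore the integral
#' formal charge.
#'
#' @param model an `fcnt_model`.
#' @param graft a [graft_spec()].
#' @param charges a [motif_charge_set()] (defaults to the shipped set for
#'   the requested group kind).
#' @return the functionalized `fcnt_model`.
#' @export
graft_groups <- function(model, graft,
                         charges = motif_charge_set(graft$group_kind)) {
  stopifnot(inherits(model, "fcnt_model"), inherits(graft, "graft_spec"))
  atoms <- model$atoms
  wall_idx <- which(atoms$wall)
  n_c <- length(wall_idx)
  n_groups <- if (!is.null(graft$n_groups)) as.integer(graft$n_groups)
    else as.integer(ceiling(graft$coverage_fraction * n_c))
  if (n_groups == 0L) return(model)
  nb <- adjacency_list(model$bonds, nrow(atoms))
  set.seed(graft$rng_seed)
  cand <- sample(wall_idx)
  blocked <- rep(FALSE, nrow(atoms))
  anchors <- integer(0); neighbors <- integer(0)
  for (a in cand) {
    if (length(anchors) == n_groups) break
    if (blocked[a]) next
    free_nb <- setdiff(nb[[a]], c(anchors, neighbors))
    free_nb <- free_nb[atoms$wall[free_nb] & !blocked[free_nb]]
    if (length(free_nb) == 0L) next
    nn <- if (length(free_nb) == 1L) free_nb else sample(free_nb, 1L)
    anchors <- c(anchors, a); neighbors <- c(neighbors, nn)
    blocked[graph_ball(nb, a, graft$min_anchor_separation)] <- TRUE
    blocked[nn] <- TRUE
  }
  if (length(anchors) < n_groups)
    stop(sprintf(paste0("separation constraint infeasible: requested %d ",
                        "groups, at most %d placeable"),
                 n_groups, length(anchors)))
  bonds <- model$bonds
  for (g in seq_len(n_groups)) {
    res <- add_motif(atoms, bonds, anchors[g], neighbors[g], charges, g)
    atoms <- res$atoms; bonds <- res$bonds
  }
  # induced charge on wall carbons adjacent to the sp3 centers
  for (g in seq_len(n_groups)) {
    adj <- setdiff(unique(c(nb[[anchors[g]]], nb[[neighbors[g]]])),
                   c(anchors[g], neighbors[g]))
    adj <- adj[atoms$wall[adj]]
    atoms$charge[adj] <- atoms$charge[adj] + charges$wall_adj
  }
  meta <- model$meta
  meta$group_kind <- charges$group_kind
  meta$n_groups <- n_groups
  meta$n_carboxylate <- if (charges$group_kind == "carboxylate") n_groups
    else 0L
  meta$anchors <- anchors
  meta$graft_seed <- graft$rng_seed
  new_fcnt_model(atoms, bonds, model$periodic_length, meta)
}

#' Spread residual motif charge over the nanotube wall
#'
#' Each wall carbon not belonging to a motif receives the same
#' compensating charge so that the total charge equals exactly the formal
#' value: -1 e per carboxylate group, 0 per carboxylic-acid group.
#' Idempotent on an already balanced model.
#'
#' @param model a grafted `fcnt_model`.
#' @return the model with balanced charges; the per-atom adjustment is
#'   recorded in `model$meta$charge_adjustment`.
#' @export
redistribute_residual_charge <- function(model) {
  stopifnot(inherits(model, "fcnt_model"))
  target <- -model$meta$n_carboxylate
  eligible <- which(model$atoms$wall & is.na(model$atoms$motif))
  residual <- sum(model$atoms$charge) - target
  adj <- -residual / length(eligible)
  model$atoms$charge[eligible] <- model$atoms$charge[eligible] + adj
  # absorb floating-point dust into one atom so the sum is exact
  dust <- sum(model$atoms$charge) - target
  model$atoms$charge[eligible[1]] <- model$atoms$charge[eligible[1]] - dust
  model$net_charge <- target
  model$meta$charge_adjustment <- adj
  model
}

#' Build a finite hydrogen-capped (n,0) cluster, optionally carboxylated
#'
#' The cluster holds `rings` zigzag rings of `2n` wall carbons each plus
#' `2n` capping hydrogens (one per dangling axial bond, n per end, C-H
#' 1.09 angstrom).  When a group kind is requested a single motif is
#' grafted onto a mid-cluster carbon.
#'
#' @param n chiral index of the (n,0) cluster.
#' @param rings number of zigzag rings (>= 2; >= 3 to host a motif away
#'   from the caps).
#' @param group_kind `"none"`, `"carboxylate"` or `"carboxylic_acid"`.
#' @param charges optional [motif_charge_set()].
#' @return a finite `fcnt_model` (`periodic_length` = NA).
#' @examples
#' nrow(build_capped_cluster(10, 7, "carboxylate")$atoms)      # 164
#' nrow(build_capped_cluster(10, 7, "carboxylic_acid")$atoms)  # 165
#' @export
build_capped_cluster <- function(n, rings,
                                 group_kind = c("none", "carboxylate",
                                                "carboxylic_acid"),
                                 charges = NULL) {
  group_kind <- match.arg(group_kind)
  if (rings < 2) stop("rings must be >= 2")
  a_ang <- A_CC_DEFAULT_NM * 10
  cells <- ceiling(rings / 2)
  xyz <- zigzag_wall_coords(n, cells, a_ang)
  # z-levels: 4 per cell; one ring = 2 consecutive levels
  lev <- round(xyz[, 3] / (a_ang / 2))
  keep_levels <- sort(unique(lev))[seq_len(2L * rings)]
  xyz <- xyz[lev %in% keep_levels, , drop = FALSE]
  lev <- lev[lev %in% keep_levels]
  # caps: bottom level misses its axial bond downward, top level upward
  bot <- xyz[lev == min(lev), , drop = FALSE]
  top <- xyz[lev == max(lev), , drop = FALSE]
  hcap <- rbind(sweep(bot, 2, c(0, 0, 1.09)),
                sweep(top, 2, c(0, 0, -1.09), `-`))
  atoms <- data.frame(
    element = c(rep("C", nrow(xyz)), rep("H", nrow(hcap))),
    name = c(rep("C", nrow(xyz)), rep("HT", nrow(hcap))),
    charge = 0,
    x = c(xyz[, 1], hcap[, 1]), y = c(xyz[, 2], hcap[, 2]),
    z = c(xyz[, 3], hcap[, 3]),
    hyb = c(rep("sp2", nrow(xyz)), rep(NA, nrow(hcap))),
    wall = c(rep(TRUE, nrow(xyz)), rep(FALSE, nrow(hcap))),
    motif = NA_integer_, stringsAsFactors = FALSE)
  bonds <- detect_bonds(as.matrix(atoms[, c("x", "y", "z")]), cutoff = 1.6)
  meta <- list(chirality_n = n, cells = NA, a_cc = A_CC_DEFAULT_NM,
               radius = sqrt(3) * n * a_ang / (2 * pi),
               group_kind = group_kind,
               n_groups = if (group_kind == "none") 0L else 1L,
               n_carboxylate = if (group_kind == "carboxylate") 1L else 0L)
  if (group_kind == "none")
    return(new_fcnt_model(atoms, bonds, NA_real_, meta))
  if (rings < 3) stop("placement error: need >= 3 rings to host a motif")
  if (is.null(charges)) charges <- motif_charge_set(group_kind)
  zmid <- mean(range(atoms$z[atoms$wall]))
  interior <- atoms$wall
  interior[seq_along(lev)] <- interior[seq_along(lev)] &
    lev != min(lev) & lev != max(lev)
  wall_idx <- which(interior)
  anchor <- wall_idx[which.min(abs(atoms$z[wall_idx] - zmid))]
  nb <- adjacency_list(bonds, nrow(atoms))
  nbw <- nb[[anchor]][atoms$wall[nb[[anchor]]]]
  neighbor <- nbw[which.min(abs(atoms$z[nbw] - zmid))]
  res <- add_motif(atoms, bonds, anchor, neighbor, charges, 1L)
  new_fcnt_model(res$atoms, res$bonds, NA_real_, meta)
}

#' @export
print.fcnt_model <- function(x, ...) {
  cat(sprintf(
    "fcnt_model: %d atoms (%d wall C), %d bonds, %s, groups: %d %s\n",
    nrow(x$atoms), sum(x$atoms$wall), nrow(x$bonds),
    if (is.na(x$periodic_length)) "finite"
    else sprintf("periodic z = %.4f nm", x$periodic_length),
    x$meta$n_groups, x$meta$group_kind))
  cat(sprintf("  net charge %.6f e\n", sum(x$atoms$charge)))
  invisible(x)
}
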