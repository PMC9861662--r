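# Independent brute-force oracles and small fixture builders.  The
# oracles are deliberately written as explicit double loops with scalar
# arithmetic so they share no code path with the package's vectorized
# implementations.

mi1 <- function(d, l) if (is.na(l)) d else d - l * round(d / l)

# all-pairs LJ + Coulomb, explicit double loop
oracle_pair_energy <- function(xyz, ga, gb, charges, types, params,
                               box = NULL, use_cutoff = TRUE) {
  tb <- params$table
  e_lj <- 0; e_c <- 0
  bx <- if (is.null(box)) c(NA, NA, NA) else box
  for (i in ga) for (j in gb) {
    dx <- mi1(xyz[i, 1] - xyz[j, 1], bx[1])
    dy <- mi1(xyz[i, 2] - xyz[j, 2], bx[2])
    dz <- mi1(xyz[i, 3] - xyz[j, 3], bx[3])
    r <- sqrt(dx^2 + dy^2 + dz^2) / 10
    if (use_cutoff && r > params$cutoff_nm) next
    ti <- match(types[i], tb$type); tj <- match(types[j], tb$type)
    sig <- (tb$sigma[ti] + tb$sigma[tj]) / 2
    eps <- sqrt(tb$epsilon[ti] * tb$epsilon[tj])
    e_lj <- e_lj + 4 * eps * ((sig / r)^12 - (sig / r)^6)
    e_c <- e_c + params$coulomb_k * charges[i] * charges[j] / r
  }
  list(E_LJ = e_lj, E_coulomb = e_c, E_total = e_lj + e_c)
}

# all-pairs hydrogen-bond count, explicit double loop
oracle_count_hbonds <- function(xyz, donors, acceptors, crit, box = NULL) {
  bx <- if (is.null(box)) c(NA, NA, NA) else box
  n <- 0L
  for (k in seq_len(nrow(donors))) {
    d <- donors[k, 1]; h <- donors[k, 2]
    for (a in acceptors) {
      if (a == d) next
      da <- c(mi1(xyz[a, 1] - xyz[d, 1], bx[1]),
              mi1(xyz[a, 2] - xyz[d, 2], bx[2]),
              mi1(xyz[a, 3] - xyz[d, 3], bx[3]))
      rd <- sqrt(sum(da^2))
      if (rd >= crit$d_max) next
      dh <- c(mi1(xyz[h, 1] - xyz[d, 1], bx[1]),
              mi1(xyz[h, 2] - xyz[d, 2], bx[2]),
              mi1(xyz[h, 3] - xyz[d, 3], bx[3]))
      ang <- acos(max(-1, min(1, sum(da * dh) /
                                (rd * sqrt(sum(dh^2)))))) * 180 / pi
      if (ang < crit$theta_max) n <- n + 1L
    }
  }
  n
}

# neighbor count by explicit image enumeration (periodic z)
oracle_neighbor_counts <- function(xyz, cutoff, box_z) {
  n <- nrow(xyz)
  cnt <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    for (s in c(-1, 0, 1)) {
      d <- xyz[j, ] + c(0, 0, s * box_z) - xyz[i, ]
      if (sqrt(sum(d^2)) < cutoff) { cnt[i] <- cnt[i] + 1L; break }
    }
  }
  cnt
}

# minimal hand-made trajectory for analysis unit tests
make_toy_traj <- function(coords, atoms, box = c(100, 100, 100),
                          molecules = list(), fcnt_rows = integer(0),
                          fcnt = NULL, dt_ps = 200) {
  nf <- dim(coords)[3]
  structure(list(atoms = atoms, coords = coords, box = box,
                 times = (seq_len(nf) - 1) * dt_ps,
                 molecules = molecules, fcnt_rows = fcnt_rows,
                 ion_rows = integer(0), fcnt = fcnt, axis_xy = c(0, 0),
                 states = NULL, torsion_samples = NULL),
            class = "cnt_traj")
}

toy_atom_row <- function(name, element = substr(name, 1, 1),
                         type = "glycan", molid = 1L, resno = 1L,
                         resname = "UNK", charge = 0) {
  data.frame(type = type, molid = molid, resname = resname, resno = resno,
             name = name, element = element, charge = charge,
             stringsAsFactors = FALSE)
}

# a small functionalized system + trajectory, reused across tests
small_system <- function(n_groups = 4L, group = "carboxylate",
                         glycan = "GlcNAc", copies = 2L, seed = 3L) {
  cnt <- build_zigzag_cnt(lattice_spec(8, 3))
  if (n_groups > 0) {
    cnt <- graft_groups(cnt, graft_spec(group, n_groups = n_groups,
                                        rng_seed = seed))
    cnt <- redistribute_residual_charge(cnt)
  }
  assemble(cnt, build_monosaccharide(glycan), copies = copies,
           conc_M = 0.15, seed = seed)
}

# random frame with donors/acceptors for the hydrogen-bond oracle; mixes
# near-threshold geometries with background atoms
random_hb_frame <- function(n_donors = 25, n_acceptors = 50,
                            n_filler = 100, box = c(20, 20, 20)) {
  nd <- n_donors
  dpos <- cbind(runif(nd, 0, box[1]), runif(nd, 0, box[2]),
                runif(nd, 0, box[3]))
  # hydrogens near their donors; acceptors biased toward donors so the
  # criterion actually fires
  hpos <- dpos + matrix(rnorm(nd * 3, sd = 0.6), nd)
  hpos <- dpos + (hpos - dpos) /
    sqrt(rowSums((hpos - dpos)^2)) * 0.97
  na <- n_acceptors
  near <- sample(nd, na, replace = TRUE)
  apos <- dpos[near, ] + matrix(rnorm(na * 3, sd = 2.0), na)
  fpos <- cbind(runif(n_filler, 0, box[1]), runif(n_filler, 0, box[2]),
                runif(n_filler, 0, box[3]))
  xyz <- rbind(dpos, hpos, apos, fpos)
  list(xyz = xyz, donors = cbind(1:nd, nd + 1:nd),
       acceptors = 2L * nd + seq_len(na), box = box)
}
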