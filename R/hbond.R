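# Geometric hydrogen-bond counting under a strict criterion:
# acceptor-donor distance < 3 angstrom AND the angle at the donor heavy
# atom between the D->A and D->H vectors < 20 degrees (both strict).
# So-called weak hydrogen bonds (3.0 <= d < 3.5) are never counted.

#' Hydrogen-bond criterion
#'
#' @param d_max maximum acceptor-donor distance, angstrom (strict `<`).
#' @param theta_max maximum acceptor-donor-H angle at the donor heavy
#'   atom, degrees (strict `<`).
#' @export
hbond_criterion <- function(d_max = 3.0, theta_max = 20) {
  stopifnot(d_max > 0, theta_max > 0, theta_max < 90)
  structure(list(d_max = d_max, theta_max = theta_max),
            class = "hbond_criterion")
}

#' Count hydrogen bonds in one frame
#'
#' @param xyz frame coordinate matrix, angstrom.
#' @param donors two-column matrix (heavy-atom index, hydrogen index); a
#'   donor without an attached hydrogen is an error.
#' @param acceptors acceptor heavy-atom indices.
#' @param criterion an [hbond_criterion()].
#' @param box periodic box (angstrom) or NULL.
#' @return integer count of donor-acceptor pairs satisfying the
#'   criterion (pairs where the acceptor is the donor atom itself are
#'   skipped).
#' @export
count_hbonds <- function(xyz, donors, acceptors,
                         criterion = hbond_criterion(), box = NULL) {
  donors <- matrix(as.integer(donors), ncol = 2)
  if (anyNA(donors)) stop("donor without attached hydrogen")
  if (nrow(donors) == 0 || length(acceptors) == 0) return(0L)
  bx <- if (is.null(box)) c(NA, NA, NA) else box
  d_da <- pair_distances(xyz[donors[, 1], , drop = FALSE],
                         xyz[acceptors, , drop = FALSE], bx)
  # D->H unit vectors (minimum image)
  vh <- cbind(min_image(xyz[donors[, 2], 1] - xyz[donors[, 1], 1], bx[1]),
              min_image(xyz[donors[, 2], 2] - xyz[donors[, 1], 2], bx[2]),
              min_image(xyz[donors[, 2], 3] - xyz[donors[, 1], 3], bx[3]))
  vh <- vh / sqrt(rowSums(vh^2))
  # D->A components
  ax <- min_image(outer(xyz[acceptors, 1], xyz[donors[, 1], 1], `-`), bx[1])
  ay <- min_image(outer(xyz[acceptors, 2], xyz[donors[, 1], 2], `-`), bx[2])
  az <- min_image(outer(xyz[acceptors, 3], xyz[donors[, 1], 3], `-`), bx[3])
  # cos(angle at donor) for each acceptor (rows) x donor (cols)
  num <- sweep(ax, 2, vh[, 1], `*`) + sweep(ay, 2, vh[, 2], `*`) +
    sweep(az, 2, vh[, 3], `*`)
  cosang <- num / t(d_da)
  same <- outer(acceptors, donors[, 1], `==`)
  hit <- t(d_da) < criterion$d_max &
    cosang > cos(criterion$theta_max * pi / 180) & !same
  sum(hit)
}

# Donor/acceptor role tables for a trajectory: fCNT carboxyl groups on
# one side, carbohydrate molecules on the other.
hbond_roles <- function(traj) {
  at <- traj$atoms
  fc <- traj$fcnt_rows
  # fCNT motif oxygens: OX1/OX2 acceptors; acid O-H (OX2-HO) donor
  ox <- fc[at$name[fc] %in% c("OX1", "OX2")]
  ho <- fc[at$name[fc] == "HO"]
  fcnt_donors <- NULL
  if (length(ho) > 0) {
    # pair each HO with the nearest OX2 by construction order: HO follows
    # its motif's OX2 in the atom table
    ox2 <- fc[at$name[fc] == "OX2"]
    fcnt_donors <- cbind(vapply(ho, function(h) max(ox2[ox2 < h]), 0L), ho)
  }
  gl <- which(at$type == "glycan")
  # carbohydrate donors: hydroxyl O-H and amide N-H
  hname <- at$name[gl]
  carb_donors <- NULL
  hyd <- gl[grepl("^HO[1-6]$", hname)]
  if (length(hyd) > 0) {
    heavy <- vapply(hyd, function(h) {
      o <- which(at$type == "glycan" & at$molid == at$molid[h] &
                 at$resno == at$resno[h] &
                 at$name == sub("HO", "O", at$name[h]))
      o[1]
    }, 0L)
    carb_donors <- cbind(heavy, hyd)
  }
  hn <- gl[hname == "HN2"]
  if (length(hn) > 0) {
    heavy <- vapply(hn, function(h) {
      which(at$type == "glycan" & at$molid == at$molid[h] &
            at$resno == at$resno[h] & at$name == "N2")[1]
    }, 0L)
    carb_donors <- rbind(carb_donors, cbind(heavy, hn))
  }
  # carbohydrate acceptors: all oxygens
  carb_acceptors <- gl[at$element[gl] == "O"]
  list(fcnt_acceptors = ox, fcnt_donors = fcnt_donors,
       carb_donors = carb_donors, carb_acceptors = carb_acceptors,
       group_kind = if (!is.null(traj$fcnt)) traj$fcnt$meta$group_kind
       else "none")
}

#' Mean hydrogen-bond counts between fCNT carboxyl groups and glycans
#'
#' Counts are split by the carboxyl group's role: the carboxylate can act
#' as an acceptor only, while the carboxylic acid can accept and donate.
#'
#' @param traj a `cnt_traj` whose fCNT carries carboxyl motifs.
#' @param criterion an [hbond_criterion()].
#' @param frames frame subset.
#' @return list: `per_frame` data.frame(frame, acceptor_count,
#'   donor_count) and `mean` (named means over frames).
#' @export
mean_hbonds <- function(traj, criterion = hbond_criterion(),
                        frames = seq_len(dim(traj$coords)[3])) {
  if (length(frames) == 0) stop("empty trajectory")
  roles <- hbond_roles(traj)
  acc <- integer(length(frames)); don <- integer(length(frames))
  for (k in seq_along(frames)) {
    xyz <- traj$coords[, , frames[k]]
    acc[k] <- count_hbonds(xyz, roles$carb_donors, roles$fcnt_acceptors,
                           criterion, traj$box)
    don[k] <- if (is.null(roles$fcnt_donors)) 0L else
      count_hbonds(xyz, roles$fcnt_donors, roles$carb_acceptors,
                   criterion, traj$box)
  }
  per_frame <- data.frame(frame = frames, acceptor_count = acc,
                          donor_count = don)
  list(per_frame = per_frame,
       mean = c(carboxyl_as_acceptor = mean(acc),
                carboxyl_as_donor = mean(don)),
       group_kind = roles$group_kind)
}
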