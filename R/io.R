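# Coordinate readers/writers (PDB via bio3d; GRO and extended XYZ as
# documented plain-text formats) and the plain-text topology table.
# Internal unit is the angstrom; GRO files are nm at the format boundary
# (exact factor 10).

as_atom_table <- function(x) {
  if (inherits(x, "fcnt_model"))
    data.frame(name = x$atoms$name, element = x$atoms$element,
               resname = "CNT", resno = 1L,
               x = x$atoms$x, y = x$atoms$y, z = x$atoms$z,
               stringsAsFactors = FALSE)
  else if (inherits(x, "glycan_chain"))
    data.frame(name = x$atoms$name, element = x$atoms$element,
               resname = x$atoms$resname, resno = x$atoms$resno,
               x = x$atoms$x, y = x$atoms$y, z = x$atoms$z,
               stringsAsFactors = FALSE)
  else if (inherits(x, "cnt_system"))
    data.frame(name = x$atoms$name, element = x$atoms$element,
               resname = x$atoms$resname, resno = x$atoms$resno,
               x = x$atoms$x, y = x$atoms$y, z = x$atoms$z,
               stringsAsFactors = FALSE)
  else stop("cannot interpret object as an atom table")
}

#' Write a model, chain or system to PDB (angstrom)
#'
#' Atom names are truncated to 4 characters; written through bio3d.
#' @param x an `fcnt_model`, `glycan_chain` or `cnt_system`.
#' @param path output file.
#' @export
write_pdb <- function(x, path) {
  at <- as_atom_table(x)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, resid = substr(at$resname, 1, 3),
                   eleno = seq_len(nrow(at)),
                   elety = substr(at$name, 1, 4), elesy = at$element)
  invisible(path)
}

#' Read coordinates from PDB, GRO or extended XYZ
#'
#' The format is taken from the file extension unless given.  PDB files
#' may hold multiple MODELs; extended XYZ files may hold multiple frames.
#' Round-trips with the paired writers are lossless at format precision
#' (PDB 1e-3 angstrom, GRO 1e-3 nm).
#'
#' @param path input file.
#' @param format `"pdb"`, `"gro"` or `"xyz"` (default: from extension).
#' @return list: `atoms` (name, element, resname, resno), `coords`
#'   (natoms x 3 x nframes array, angstrom), `box` (angstrom, NA when the
#'   format carries none).
#' @export
read_coordinates <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  switch(format,
         pdb = read_pdb_frames(path),
         gro = read_gro(path),
         xyz = read_xyz(path),
         stop("unrecognized format: ", format))
}

read_pdb_frames <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz); na <- ncol(xyz) / 3
  coords <- array(NA_real_, c(na, 3, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  list(atoms = data.frame(name = pdb$atom$elety,
                          element = pdb$atom$elesy,
                          resname = pdb$atom$resid,
                          resno = pdb$atom$resno,
                          stringsAsFactors = FALSE),
       coords = coords, box = c(NA, NA, NA))
}

#' Write a GRO file (nm)
#'
#' @param x object with an atom table (see [write_pdb()]).
#' @param path output file.
#' @param box box vector in angstrom (written as nm); defaults to the
#'   system box or zeros.
#' @export
write_gro <- function(x, path, box = NULL) {
  at <- as_atom_table(x)
  if (is.null(box))
    box <- if (inherits(x, "cnt_system")) x$box
    else if (inherits(x, "fcnt_model") && is.finite(x$periodic_length))
      c(0, 0, x$periodic_length * 10)
    else c(0, 0, 0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("generated by cntglycan", sprintf("%5d", nrow(at))), con)
  writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     at$resno %% 100000, substr(at$resname, 1, 5),
                     substr(at$name, 1, 5),
                     seq_len(nrow(at)) %% 100000,
                     at$x / 10, at$y / 10, at$z / 10), con)
  writeLines(sprintf("%10.5f%10.5f%10.5f", box[1] / 10, box[2] / 10,
                     box[3] / 10), con)
  invisible(path)
}

read_gro <- function(path) {
  ln <- readLines(path)
  if (length(ln) < 3) stop("truncated GRO file: ", path)
  na <- suppressWarnings(as.integer(trimws(ln[2])))
  if (is.na(na)) stop("malformed atom count at line 2 of ", path)
  if (length(ln) < na + 3) stop("truncated GRO file: expected ", na + 3,
                                " lines, found ", length(ln))
  al <- ln[3:(na + 2)]
  parse_num <- function(s, line) {
    v <- suppressWarnings(as.numeric(s))
    if (anyNA(v)) stop("malformed GRO record at line ", line, " of ", path)
    v
  }
  resno <- suppressWarnings(as.integer(substr(al, 1, 5)))
  if (anyNA(resno))
    stop("malformed GRO record at line ", which(is.na(resno))[1] + 2,
         " of ", path)
  x <- numeric(na); y <- numeric(na); z <- numeric(na)
  for (i in seq_len(na)) {
    x[i] <- parse_num(substr(al[i], 21, 28), i + 2)
    y[i] <- parse_num(substr(al[i], 29, 36), i + 2)
    z[i] <- parse_num(substr(al[i], 37, 44), i + 2)
  }
  bv <- suppressWarnings(as.numeric(strsplit(trimws(ln[na + 3]),
                                             "\\s+")[[1]]))
  if (length(bv) < 3 || anyNA(bv[1:3]))
    stop("malformed box line at line ", na + 3, " of ", path)
  atoms <- data.frame(name = trimws(substr(al, 11, 15)),
                      element = substr(trimws(substr(al, 11, 15)), 1, 1),
                      resname = trimws(substr(al, 6, 10)),
                      resno = as.integer(resno),
                      stringsAsFactors = FALSE)
  coords <- array(c(x, y, z) * 10, c(na, 3, 1))
  list(atoms = atoms, coords = coords, box = bv[1:3] * 10)
}

#' Write a trajectory (or single structure) as extended XYZ
#'
#' One block per frame: atom count, a comment line carrying
#' `Lattice="..."` (angstrom) and `Time=<ps>`, then `element x y z`
#' lines in angstrom.
#'
#' @param traj a `cnt_traj`, or any object with an atom table.
#' @param path output file.
#' @export
write_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(traj, "cnt_traj")) {
    el <- traj$atoms$element
    nf <- dim(traj$coords)[3]
    for (f in seq_len(nf)) {
      writeLines(sprintf("%d", length(el)), con)
      writeLines(sprintf(
        'Lattice="%.4f 0 0 0 %.4f 0 0 0 %.4f" Time=%.1f',
        traj$box[1], traj$box[2], traj$box[3], traj$times[f]), con)
      writeLines(sprintf("%-2s %12.5f %12.5f %12.5f", el,
                         traj$coords[, 1, f], traj$coords[, 2, f],
                         traj$coords[, 3, f]), con)
    }
  } else {
    at <- as_atom_table(traj)
    writeLines(sprintf("%d", nrow(at)), con)
    writeLines('Lattice="0 0 0 0 0 0 0 0 0" Time=0.0', con)
    writeLines(sprintf("%-2s %12.5f %12.5f %12.5f", at$element,
                       at$x, at$y, at$z), con)
  }
  invisible(path)
}

read_xyz <- function(path) {
  ln <- readLines(path)
  frames <- list(); boxes <- list(); i <- 1L
  el <- NULL
  while (i <= length(ln)) {
    if (trimws(ln[i]) == "") { i <- i + 1L; next }
    na <- suppressWarnings(as.integer(trimws(ln[i])))
    if (is.na(na)) stop("malformed atom count at line ", i, " of ", path)
    if (i + 1L + na > length(ln))
      stop("truncated XYZ frame starting at line ", i, " of ", path)
    lat <- regmatches(ln[i + 1L],
                      regexec('Lattice="([^"]*)"', ln[i + 1L]))[[1]]
    bx <- c(NA, NA, NA)
    if (length(lat) == 2) {
      v <- as.numeric(strsplit(trimws(lat[2]), "\\s+")[[1]])
      if (length(v) == 9) bx <- v[c(1, 5, 9)]
    }
    rec <- ln[(i + 2L):(i + 1L + na)]
    parts <- strsplit(trimws(rec), "\\s+")
    bad <- which(lengths(parts) < 4)
    if (length(bad) > 0)
      stop("malformed XYZ record at line ", i + 1L + bad[1], " of ", path)
    el <- vapply(parts, `[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(xyz))
      stop("non-numeric coordinate in frame starting at line ", i,
           " of ", path)
    frames[[length(frames) + 1L]] <- xyz
    boxes[[length(boxes) + 1L]] <- bx
    i <- i + 2L + na
  }
  if (length(frames) == 0) stop("no frames in ", path)
  coords <- array(NA_real_, c(nrow(frames[[1]]), 3, length(frames)))
  for (f in seq_along(frames)) coords[, , f] <- frames[[f]]
  list(atoms = data.frame(name = el, element = el, resname = "UNK",
                          resno = 1L, stringsAsFactors = FALSE),
       coords = coords, box = boxes[[1]])
}

#' Write the bonded topology of an fCNT model as plain text
#'
#' Sections `[atoms]` (index, name, element, charge, sp tag),
#' `[bonds]`, `[angles]`, `[dihedrals]` -- each bonded line lists atom
#' indices followed by a periodic flag (1 when the term crosses the z
#' boundary).
#'
#' @param model an `fcnt_model`.
#' @param path output file.
#' @export
write_topology <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  at <- model$atoms
  writeLines(c(sprintf("; net_charge %.12f e", sum(at$charge)),
               sprintf("; periodic_length_nm %s",
                       format(model$periodic_length)),
               "[atoms]"), con)
  writeLines(sprintf("%6d %-4s %-2s %12.8f %s", seq_len(nrow(at)),
                     at$name, at$element, at$charge,
                     ifelse(is.na(at$hyb), "-", at$hyb)), con)
  writeLines("[bonds]", con)
  writeLines(sprintf("%6d %6d %d", model$bonds[, 1], model$bonds[, 2],
                     model$bonds[, 3]), con)
  writeLines("[angles]", con)
  if (nrow(model$angles) > 0)
    writeLines(sprintf("%6d %6d %6d %d", model$angles[, 1],
                       model$angles[, 2], model$angles[, 3],
                       model$angles[, 4]), con)
  writeLines("[dihedrals]", con)
  if (nrow(model$dihedrals) > 0)
    writeLines(sprintf("%6d %6d %6d %6d %d", model$dihedrals[, 1],
                       model$dihedrals[, 2], model$dihedrals[, 3],
                       model$dihedrals[, 4], model$dihedrals[, 5]), con)
  invisible(path)
}
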