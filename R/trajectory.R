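#' Trajectory container and torsion-angle extraction
#'
#' A `Trajectory` couples a topology [StructureModel] with an
#' `n_frames x n_atoms x 3` coordinate array in Angstrom. Readers exist
#' for multi-model PDB and DCD (native R) and XTC (decoded via the
#' system's Python MDAnalysis installation, converting nm to Angstrom).
#'
#' @name trajectory
NULL

#' Construct a trajectory
#' @param topology a [StructureModel]
#' @param coords `n_frames x n_atoms x 3` array (Angstrom)
#' @param stride_ps optional frame interval metadata, picoseconds
#' @return a `Trajectory`
#' @export
Trajectory <- function(topology, coords, stride_ps = NA_real_) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    abort("coords must be an n_frames x n_atoms x 3 array", "topology_error")
  if (dim(coords)[2] != nrow(topology$atoms))
    abort(sprintf("atom count mismatch: topology %d vs frames %d",
                  nrow(topology$atoms), dim(coords)[2]), "topology_error")
  if (dim(coords)[1] < 1L) abort("trajectory needs >= 1 frame",
                                 "frame_boundary_error")
  structure(list(topology = topology, coords = coords, stride_ps = stride_ps),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms\n", n_frames(x),
              dim(x$coords)[2]))
  invisible(x)
}

#' Number of frames
#' @param traj a [Trajectory]
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame as a StructureModel
#' @param traj a [Trajectory]
#' @param i frame index
#' @export
frame_model <- function(traj, i) {
  if (i < 1 || i > n_frames(traj))
    abort(sprintf("frame %d out of range", i), "frame_boundary_error")
  m <- traj$topology
  m$atoms$x <- traj$coords[i, , 1]
  m$atoms$y <- traj$coords[i, , 2]
  m$atoms$z <- traj$coords[i, , 3]
  m
}

read_multimodel_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- trimws(substr(lines, 1, 6))
  starts <- which(rec == "MODEL")
  if (!length(starts)) starts <- 1L
  ends <- c(starts[-1] - 1L, length(lines))
  frames <- list()
  for (k in seq_along(starts)) {
    seg <- lines[starts[k]:ends[k]]
    segrec <- trimws(substr(seg, 1, 6))
    sel <- segrec %in% c("ATOM", "HETATM")
    if (!any(sel)) next
    frames[[length(frames) + 1L]] <-
      resolve_altlocs(parse_pdb_atom_lines(seg[sel], which(sel)))
  }
  if (!length(frames)) abort("no coordinate models in file", "empty_structure")
  nat <- vapply(frames, nrow, 1L)
  if (length(unique(nat)) != 1L)
    abort("models differ in atom count", "topology_error")
  topo <- StructureModel(frames[[1]], source_id =
                           tools::file_path_sans_ext(basename(path)))
  coords <- array(NA_real_, dim = c(length(frames), nat[1], 3))
  for (k in seq_along(frames)) {
    coords[k, , 1] <- frames[[k]]$x
    coords[k, , 2] <- frames[[k]]$y
    coords[k, , 3] <- frames[[k]]$z
  }
  list(topology = topo, coords = coords)
}

read_dcd_coords <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  m1 <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (m1 != 84) { endian <- "big"; seek(con, 0)
    m1 <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (m1 != 84) abort("not a DCD file (bad header record)", "format_error") }
  hdr <- readBin(con, "raw", 4)  # 'CORD'
  icntrl <- readBin(con, "integer", 20, size = 4, endian = endian)
  readBin(con, "integer", 1, size = 4, endian = endian)  # trailing marker
  nframes <- icntrl[1]
  has_cell <- icntrl[11] == 1
  ## title block
  tlen <- readBin(con, "integer", 1, size = 4, endian = endian)
  readBin(con, "raw", tlen)
  readBin(con, "integer", 1, size = 4, endian = endian)
  ## natoms block
  readBin(con, "integer", 1, size = 4, endian = endian)
  natoms <- readBin(con, "integer", 1, size = 4, endian = endian)
  readBin(con, "integer", 1, size = 4, endian = endian)
  frames <- list()
  repeat {
    if (has_cell) {
      mk <- readBin(con, "integer", 1, size = 4, endian = endian)
      if (!length(mk)) break
      readBin(con, "double", 6, size = 8, endian = endian)
      readBin(con, "integer", 1, size = 4, endian = endian)
    }
    xs <- list()
    ok <- TRUE
    for (d in 1:3) {
      mk <- readBin(con, "integer", 1, size = 4, endian = endian)
      if (!length(mk)) { ok <- FALSE; break }
      if (mk != 4L * natoms)
        abort("truncated or corrupt DCD frame record", "frame_boundary_error")
      v <- readBin(con, "double", natoms, size = 4, endian = endian)
      if (length(v) != natoms)
        abort("truncated DCD coordinate block", "frame_boundary_error")
      readBin(con, "integer", 1, size = 4, endian = endian)
      xs[[d]] <- v
    }
    if (!ok) break
    frames[[length(frames) + 1L]] <- xs
  }
  if (!length(frames)) abort("DCD contains no frames", "frame_boundary_error")
  coords <- array(NA_real_, dim = c(length(frames), natoms, 3))
  for (k in seq_along(frames)) for (d in 1:3)
    coords[k, , d] <- frames[[k]][[d]]
  coords
}

#' Write a DCD trajectory file
#'
#' Minimal CHARMM-format writer (no unit cell), used for fixtures and
#' round-trip tests.
#'
#' @param traj a [Trajectory]
#' @param path output path
#' @export
write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nat <- dim(traj$coords)[2]; nf <- n_frames(traj)
  icntrl <- integer(20); icntrl[1] <- nf; icntrl[20] <- 24
  writeBin(84L, con, size = 4)
  writeBin(charToRaw("CORD"), con)
  writeBin(icntrl, con, size = 4)
  writeBin(84L, con, size = 4)
  title <- sprintf("%-80s", "gpcrdimer trajectory")
  writeBin(84L, con, size = 4)   # 4 + 80
  writeBin(1L, con, size = 4)
  writeBin(charToRaw(title), con)
  writeBin(84L, con, size = 4)
  writeBin(4L, con, size = 4)
  writeBin(as.integer(nat), con, size = 4)
  writeBin(4L, con, size = 4)
  for (k in seq_len(nf)) for (d in 1:3) {
    writeBin(4L * nat, con, size = 4)
    writeBin(as.numeric(traj$coords[k, , d]), con, size = 4)
    writeBin(4L * nat, con, size = 4)
  }
  invisible(path)
}

#' Write a multi-model PDB file
#' @param traj a [Trajectory]
#' @param path output path
#' @export
write_multimodel_pdb <- function(traj, path) {
  out <- character(0)
  for (k in seq_len(n_frames(traj))) {
    m <- frame_model(traj, k)
    lines <- vapply(seq_len(nrow(m$atoms)), function(i)
      format_pdb_line(m$atoms[i, ], i), character(1))
    out <- c(out, sprintf("MODEL     %4d", k), lines, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

read_xtc_coords <- function(path) {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    abort("XTC reading requires a python interpreter with MDAnalysis on PATH",
          "format_error")
  tmp <- tempfile(fileext = ".bin")
  script <- sprintf(paste0(
    "import sys, numpy as np\n",
    "import MDAnalysis.coordinates.XTC as X\n",
    "r = X.XTCReader(%s)\n",
    "fr = [ts.positions.astype('float64').copy() for ts in r]\n",
    "arr = np.stack(fr)\n",
    "hdr = np.array(arr.shape, dtype='int64')\n",
    "with open(%s, 'wb') as f:\n",
    "    f.write(hdr.tobytes()); f.write(arr.tobytes())\n"),
    deparse(path), deparse(tmp))
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  st <- system2(py, sf, stdout = TRUE, stderr = TRUE)
  if (!file.exists(tmp) || file.info(tmp)$size == 0)
    abort(paste("XTC decode failed:", paste(st, collapse = "\n")),
          "format_error")
  con <- file(tmp, "rb")
  on.exit({ close(con); unlink(c(tmp, sf)) })
  dims <- readBin(con, "integer", 3, size = 8)
  vals <- readBin(con, "double", prod(dims), size = 8)
  ## MDAnalysis positions are already Angstrom
  aperm(array(vals, dim = rev(dims)), c(3, 2, 1))
}

#' Load a trajectory
#'
#' @param topology a [StructureModel] or path to a structure file
#' @param traj_path optional coordinate file (DCD or XTC); if `NULL`,
#'   `topology` must be a multi-model PDB path whose models become frames
#' @param format `"auto"`, `"pdb"` (multi-model), `"dcd"`, or `"xtc"`
#' @param stride_ps frame interval metadata, picoseconds
#' @return a [Trajectory]
#' @export
load_trajectory <- function(topology, traj_path = NULL,
                            format = c("auto", "pdb", "dcd", "xtc"),
                            stride_ps = NA_real_) {
  format <- match.arg(format)
  if (is.null(traj_path)) {
    if (!is.character(topology))
      abort("need a trajectory file or a multi-model PDB path",
            "topology_error")
    mm <- read_multimodel_pdb(topology)
    return(Trajectory(mm$topology, mm$coords, stride_ps))
  }
  topo <- if (inherits(topology, "StructureModel")) topology
          else read_structure(topology)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(traj_path)),
                     dcd = "dcd", xtc = "xtc", "pdb")
  coords <- switch(format,
                   dcd = read_dcd_coords(traj_path),
                   xtc = read_xtc_coords(traj_path),
                   pdb = read_multimodel_pdb(traj_path)$coords)
  Trajectory(topo, coords, stride_ps)
}

#' Dihedral angle of four points
#'
#' IUPAC sign convention: looking from `b` to `c`, the angle is positive
#' for a clockwise rotation of the far bond. Result in degrees in
#' (-180, 180].
#'
#' @param p1,p2,p3,p4 xyz triples, or matrices (n x 3) for vectorized use
#' @return degrees (vector if inputs are matrices)
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  tomat <- function(p) if (is.matrix(p)) p else matrix(p, 1)
  p1 <- tomat(p1); p2 <- tomat(p2); p3 <- tomat(p3); p4 <- tomat(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(u, v)
    cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
          u[, 3] * v[, 1] - u[, 1] * v[, 3],
          u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  m1 <- cross(n1, b2 / sqrt(rowSums(b2^2)))
  x <- rowSums(n1 * n2); y <- rowSums(m1 * n2)
  wrap180(rad2deg(atan2(y, x)))
}

CHI1_GAMMA <- c(SER = "OG", THR = "OG1", CYS = "SG", VAL = "CG1",
                ILE = "CG1", ALA = NA, GLY = NA)

chi1_gamma_atom <- function(resname) {
  if (resname %in% names(CHI1_GAMMA)) return(CHI1_GAMMA[[resname]])
  "CG"  # default gamma atom for long side chains
}

#' Extract phi/psi/chi1 torsion time series from a trajectory
#'
#' Standard backbone dihedrals phi = C(i-1)-N-CA-C and
#' psi = N-CA-C-N(i+1), plus chi1 = N-CA-CB-gamma. Missing atoms (chain
#' termini, glycine chi1, unmodelled side chains) yield `NA` (masked), not
#' an error. Angles are degrees wrapped to (-180, 180].
#'
#' @param traj a [Trajectory]
#' @return a `TorsionSeries`: list with `residues` (data frame chain,
#'   resno, resname) and `angles` (`n_frames x n_residues x 3` array,
#'   slices phi/psi/chi1)
#' @export
compute_torsions <- function(traj) {
  at <- traj$topology$atoms
  poly <- which(!at$het)
  keys <- atom_res_key(at)
  res <- unique(data.frame(chain = at$chain[poly], resno = at$resno[poly],
                           icode = at$icode[poly], resname = at$resname[poly],
                           stringsAsFactors = FALSE))
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  nr <- nrow(res); nf <- n_frames(traj)
  find_atom <- function(chain, resno, icode, name) {
    w <- which(at$chain == chain & at$resno == resno & at$icode == icode &
               at$atom == name)
    if (length(w)) w[1] else NA_integer_
  }
  angles <- array(NA_real_, dim = c(nf, nr, 3),
                  dimnames = list(NULL, res_key(res$chain, res$resno,
                                                res$icode),
                                  c("phi", "psi", "chi1")))
  P <- function(idx) traj$coords[, idx, , drop = FALSE][, 1, ]
  for (i in seq_len(nr)) {
    ch <- res$chain[i]; rn <- res$resno[i]; ic <- res$icode[i]
    iN <- find_atom(ch, rn, ic, "N"); iCA <- find_atom(ch, rn, ic, "CA")
    iC <- find_atom(ch, rn, ic, "C")
    ## previous/next residue in same chain by author numbering
    prev <- which(res$chain == ch & res$resno == rn - 1L)
    nxt <- which(res$chain == ch & res$resno == rn + 1L)
    if (length(prev) && !anyNA(c(iN, iCA, iC))) {
      iCp <- find_atom(ch, rn - 1L, res$icode[prev[1]], "C")
      if (!is.na(iCp))
        angles[, i, 1] <- dihedral_angle(P(iCp), P(iN), P(iCA), P(iC))
    }
    if (length(nxt) && !anyNA(c(iN, iCA, iC))) {
      iNn <- find_atom(ch, rn + 1L, res$icode[nxt[1]], "N")
      if (!is.na(iNn))
        angles[, i, 2] <- dihedral_angle(P(iN), P(iCA), P(iC), P(iNn))
    }
    gam <- chi1_gamma_atom(res$resname[i])
    if (!is.na(gam) && !anyNA(c(iN, iCA))) {
      iCB <- find_atom(ch, rn, ic, "CB")
      iG <- if (!is.na(gam)) find_atom(ch, rn, ic, gam) else NA_integer_
      if (!anyNA(c(iCB, iG)))
        angles[, i, 3] <- dihedral_angle(P(iN), P(iCA), P(iCB), P(iG))
    }
  }
  structure(list(residues = res, angles = angles), class = "TorsionSeries")
}

#' Circular mean of angles in degrees
#' @param x angles in degrees (NA ignored)
#' @return mean direction in (-180, 180]
#' @export
circular_mean <- function(x) {
  x <- x[!is.na(x)]
  wrap180(rad2deg(atan2(mean(sin(deg2rad(x))), mean(cos(deg2rad(x))))))
}

#' Export a torsion series as a TSV matrix (frame x residue-angle)
#' @param series a `TorsionSeries`
#' @param path output path
#' @export
write_torsions_tsv <- function(series, path) {
  nf <- dim(series$angles)[1]
  cols <- list(frame = seq_len(nf))
  keys <- dimnames(series$angles)[[2]]
  for (j in seq_along(keys)) for (t in 1:3) {
    nm <- paste0(keys[j], ".", c("phi", "psi", "chi1")[t])
    cols[[nm]] <- series$angles[, j, t]
  }
  utils::write.table(as.data.frame(cols, check.names = FALSE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
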