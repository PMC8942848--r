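#' Synthetic-data generators
#'
#' Seeded generators for every input the analysis pipeline consumes: ideal
#' helical dimers with planted rigid-body segment motions (ground truth
#' recorded exactly), coupled-torsion trajectories with von Mises marginals
#' and a hidden two-state mode shared along a planted residue chain, and
#' contact time series with exact planted presence frequencies.
#'
#' @name synthetic_data
NULL

#' Sample from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler. Mean `mu` in degrees,
#' concentration `kappa`; returns degrees in (-180, 180].
#'
#' @param n sample count
#' @param mu mean direction, degrees
#' @param kappa concentration (0 = uniform)
#' @return numeric vector of angles, degrees
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) return(wrap180(stats::runif(n, -180, 180)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1); u3 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) {
      theta <- sign(u3 - 0.5) * acos(f)
      out[i] <- theta
      i <- i + 1L
    }
  }
  wrap180(rad2deg(out) + mu)
}

helix_radius <- function(rise, twist, ca_dist = 3.8) {
  sqrt(ca_dist^2 - rise^2) / (2 * sin(deg2rad(twist) / 2))
}

#' Build an ideal alpha-helix model along z
#'
#' C-alpha positions follow the exact helix parametrization (radius chosen
#' so consecutive C-alpha atoms are 3.8 A apart); stub N, C, O and CB
#' atoms are attached with a per-residue rigid offset rotated with the
#' helix phase, so the model behaves as a proper helical backbone for
#' superposition and axis fitting.
#'
#' @param n residues (>= 4)
#' @param rise rise per residue along z, Angstrom
#' @param twist twist per residue, degrees
#' @param chain chain id
#' @param resname residue name for all residues
#' @param origin xyz offset applied to the whole helix
#' @param start_resno first author residue number
#' @return a [StructureModel]
#' @export
make_ideal_helix <- function(n, rise = 1.5, twist = 100, chain = "A",
                             resname = "ALA", origin = c(0, 0, 0),
                             start_resno = 1L) {
  if (n < 4) abort("need n >= 4 residues", "configuration_error")
  r <- helix_radius(rise, twist)
  theta <- deg2rad(twist) * (seq_len(n) - 1L)
  ca <- cbind(r * cos(theta), r * sin(theta), rise * (seq_len(n) - 1L))
  ## local stub offsets (helix frame), rotated by the per-residue phase
  stubs <- list(N = c(-0.45, -1.2, -0.8), C = c(-0.55, 1.1, 0.7),
                O = c(-1.6, 1.6, 0.6), CB = c(1.4, 0.3, -0.6))
  rows <- list()
  for (i in seq_len(n)) {
    Rz <- rotation_about_axis(c(0, 0, 1), theta[i])
    for (nm in c("N", "CA", "C", "O", "CB")) {
      pos <- if (nm == "CA") ca[i, ] else ca[i, ] + as.vector(Rz %*% stubs[[nm]])
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain, resno = start_resno + i - 1L, icode = "",
        resname = resname, atom = nm,
        element = substr(nm, 1, 1), x = pos[1] + origin[1],
        y = pos[2] + origin[2], z = pos[3] + origin[3], occ = 1, b = 0,
        het = FALSE, stringsAsFactors = FALSE)
    }
  }
  StructureModel(do.call(rbind, rows), source_id = "ideal_helix")
}

#' Specification for synthetic generators
#'
#' @param n_res residues per protomer
#' @param rise,twist helix geometry (1.5 A, 100 degrees: ideal alpha helix)
#' @param transforms list of planted motions, each a list with `segment`
#'   (`c(start, end)` on protomer B), and any of `translation` (xyz, A),
#'   `hinge_deg` (rotation about an axis perpendicular to the helix at the
#'   segment start) and `axial_deg` (rotation about the segment's own axis)
#' @param chain_residues planted coupled-residue chain for the torsion
#'   generator: data frame chain/resno
#' @param kappa von Mises concentration of null torsions
#' @param mode_offset_deg torsion-mean offset applied in the hidden "on"
#'   mode along the planted chain
#' @param mode_prob probability of the "on" mode (i.i.d. per frame)
#' @param n_frames trajectory length
#' @param contacts planted contact list: data frame with columns
#'   `res_a`, `res_b` (residue numbers) and `frequency`
#' @param seed RNG seed; all outputs are bit-reproducible given the seed
#' @return a `SyntheticSpec` list
#' @export
synthetic_spec <- function(n_res = 30, rise = 1.5, twist = 100,
                           transforms = list(), chain_residues = NULL,
                           kappa = 8, mode_offset_deg = 120,
                           mode_prob = 0.5, n_frames = 500,
                           contacts = NULL, seed = 1) {
  structure(list(n_res = n_res, rise = rise, twist = twist,
                 transforms = transforms, chain_residues = chain_residues,
                 kappa = kappa, mode_offset_deg = mode_offset_deg,
                 mode_prob = mode_prob, n_frames = n_frames,
                 contacts = contacts, seed = seed),
            class = "SyntheticSpec")
}

## rigid transform of selected atoms (axial, then hinge, then translation)
apply_segment_transform <- function(atoms, sel, tr) {
  X <- as.matrix(atoms[sel, c("x", "y", "z")])
  R <- diag(3)
  seg_atoms <- atoms[sel, , drop = FALSE]
  ca_rows <- which(seg_atoms$atom == "CA")
  Xca <- as.matrix(seg_atoms[ca_rows, c("x", "y", "z")])
  ax <- axis_from_points(Xca)
  pivot_start <- Xca[1, ]
  centroid <- ax$centroid
  Y <- X
  if (!is.null(tr$axial_deg) && tr$axial_deg != 0) {
    Ra <- rotation_about_axis(ax$direction, deg2rad(tr$axial_deg))
    Y <- sweep(sweep(Y, 2, centroid) %*% t(Ra), 2, centroid, `+`)
    R <- Ra %*% R
  }
  if (!is.null(tr$hinge_deg) && tr$hinge_deg != 0) {
    perp <- unitv(pracma_nullvec(ax$direction))
    Rh <- rotation_about_axis(perp, deg2rad(tr$hinge_deg))
    Y <- sweep(sweep(Y, 2, pivot_start) %*% t(Rh), 2, pivot_start, `+`)
    R <- Rh %*% R
  }
  if (!is.null(tr$translation)) {
    Y <- sweep(Y, 2, as.numeric(tr$translation), `+`)
  }
  atoms[sel, c("x", "y", "z")] <- Y
  list(atoms = atoms, moved = Y, orig = X)
}

## a deterministic vector perpendicular to u
pracma_nullvec <- function(u) {
  u <- unitv(u)
  v <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unitv(v - sum(v * u) * u)
}

#' Generate a toy dimer in two states with planted segment motions
#'
#' State A is two parallel ideal helices ("protomers", chains R and S,
#' labelled A/B) roughly 10 A apart. State B applies each planted
#' transform of `spec$transforms` to its residue segment on protomer B's
#' chain; protomer A is untouched, so a global alignment on protomer A is
#' the identity and planted displacements are recovered exactly. The
#' ground-truth record carries the exact per-C-alpha displacement of every
#' moved residue and the planted hinge/axial angles.
#'
#' @param spec a [synthetic_spec()]
#' @param separation inter-protomer axis separation, Angstrom
#' @return list with `state_a`, `state_b` ([StructureModel]s) and
#'   `truth` (list: per-transform displacement table, hinge/axial angles)
#' @export
make_toy_dimer_states <- function(spec, separation = 10) {
  segs <- lapply(spec$transforms, `[[`, "segment")
  if (length(segs) > 1) {
    m <- do.call(rbind, segs)
    o <- order(m[, 1]); m <- m[o, , drop = FALSE]
    if (any(m[-1, 1] <= m[-nrow(m), 2]))
      abort("planted transform segments overlap", "configuration_error")
  }
  ha <- make_ideal_helix(spec$n_res, spec$rise, spec$twist, chain = "R")
  hb <- make_ideal_helix(spec$n_res, spec$rise, spec$twist, chain = "S",
                         origin = c(separation, 0, 0))
  atoms <- rbind(ha$atoms, hb$atoms)
  state_a <- assign_protomers(StructureModel(atoms, source_id = "toy_state_a"),
                              c("R", "S"))
  atoms_b <- atoms
  truth <- list()
  for (tr in spec$transforms) {
    sel <- atoms_b$chain == "S" & atoms_b$resno >= tr$segment[1] &
      atoms_b$resno <= tr$segment[2]
    res <- apply_segment_transform(atoms_b, sel, tr)
    atoms_b <- res$atoms
    ca_sel <- which(atoms$chain == "S" & atoms$atom == "CA" &
                    atoms$resno >= tr$segment[1] & atoms$resno <= tr$segment[2])
    ca_sel_b <- which(atoms_b$chain == "S" & atoms_b$atom == "CA" &
                      atoms_b$resno >= tr$segment[1] &
                      atoms_b$resno <= tr$segment[2])
    disp <- sqrt(rowSums((as.matrix(atoms_b[ca_sel_b, c("x", "y", "z")]) -
                          as.matrix(atoms[ca_sel, c("x", "y", "z")]))^2))
    truth[[length(truth) + 1L]] <- list(
      segment = tr$segment,
      translation = tr$translation %||% c(0, 0, 0),
      hinge_deg = tr$hinge_deg %||% 0,
      axial_deg = tr$axial_deg %||% 0,
      displacement = data.frame(resno = atoms$resno[ca_sel],
                                displacement = disp))
  }
  state_b <- assign_protomers(StructureModel(atoms_b,
                                             source_id = "toy_state_b"),
                              c("R", "S"))
  list(state_a = state_a, state_b = state_b, truth = truth)
}

## ---- torsion trajectory via NeRF rebuild ----------------------------------

## place atom D for every frame: A,B,C are n x 3, bond/angle scalar,
## dihedral scalar or length-n (degrees)
nerf_place <- function(A, B, C, bond, angle_deg, dihedral_deg) {
  ## negated so that dihedral_angle(A, B, C, D) == dihedral_deg (IUPAC sign)
  ang <- deg2rad(angle_deg); dih <- -deg2rad(dihedral_deg)
  bc <- C - B
  bc <- bc / sqrt(rowSums(bc^2))
  ab <- B - A
  n <- cbind(ab[, 2] * bc[, 3] - ab[, 3] * bc[, 2],
             ab[, 3] * bc[, 1] - ab[, 1] * bc[, 3],
             ab[, 1] * bc[, 2] - ab[, 2] * bc[, 1])
  n <- n / sqrt(rowSums(n^2))
  m <- cbind(n[, 2] * bc[, 3] - n[, 3] * bc[, 2],
             n[, 3] * bc[, 1] - n[, 1] * bc[, 3],
             n[, 1] * bc[, 2] - n[, 2] * bc[, 1])
  d2 <- cbind(-bond * cos(ang), bond * sin(ang) * cos(dih),
              bond * sin(ang) * sin(dih))
  C + d2[, 1] * bc + d2[, 2] * m + d2[, 3] * n
}

BOND <- c(N_CA = 1.458, CA_C = 1.525, C_N = 1.329, CA_CB = 1.530,
          CB_OG = 1.417, C_O = 1.231)
ANGLE <- c(C_N_CA = 121.7, N_CA_C = 111.2, CA_C_N = 116.2, N_CA_CB = 110.5,
           CA_CB_OG = 110.8, CA_C_O = 120.8)

#' Simulate a coupled-torsion trajectory
#'
#' Serine-like residues are rebuilt frame by frame from sampled torsions
#' with a NeRF chain-extension, so [compute_torsions()] inverts the
#' generator exactly. Null residues draw phi/psi/chi1 independently from
#' von Mises distributions around fixed per-residue means; residues on the
#' planted chain share a hidden two-state mode (i.i.d. Bernoulli per
#' frame) that offsets their torsion means by `mode_offset_deg`, inducing
#' mutual information along the chain (bounded above by the 1-bit entropy
#' of the mode).
#'
#' Two chains R and S (protomers A/B) are generated; a planted chain may
#' span both, emulating cross-interface coupling.
#'
#' @param spec a [synthetic_spec()]; `chain_residues` may be `NULL` for a
#'   fully null trajectory
#' @return list with `trajectory` ([Trajectory]), `truth` (list: per-frame
#'   mode, planted residue keys, sampled torsions)
#' @export
simulate_coupled_torsion_trajectory <- function(spec) {
  nf <- spec$n_frames
  if (nf < 100) warning("fewer than 100 frames; MI estimates will be noisy")
  set.seed(spec$seed)
  chains <- c("R", "S")
  n_per <- spec$n_res
  planted <- spec$chain_residues
  planted_keys <- if (!is.null(planted))
    res_key(planted$chain, planted$resno) else character()
  mode <- stats::rbinom(nf, 1, spec$mode_prob)
  res_tab <- expand.grid(resno = seq_len(n_per), chain = chains,
                         stringsAsFactors = FALSE)[, c("chain", "resno")]
  res_tab <- res_tab[order(res_tab$chain, res_tab$resno), ]
  nr <- nrow(res_tab)
  ## fixed per-residue mean torsions: near-helical backbone, staggered chi1
  mu <- cbind(phi = stats::runif(nr, -80, -50),
              psi = stats::runif(nr, -60, -30),
              chi1 = sample(c(-60, 60, 180), nr, replace = TRUE) +
                stats::runif(nr, -10, 10))
  tors <- array(NA_real_, dim = c(nf, nr, 3))
  for (i in seq_len(nr)) {
    on_chain <- res_key(res_tab$chain[i], res_tab$resno[i]) %in% planted_keys
    for (t in 1:3) {
      base <- rvonmises(nf, 0, spec$kappa)
      mean_t <- rep(mu[i, t], nf)
      if (on_chain) mean_t <- mean_t + mode * spec$mode_offset_deg
      tors[, i, t] <- wrap180(base + mean_t)
    }
  }
  ## rebuild coordinates per chain with NeRF (vectorized across frames)
  rows <- list()
  coords <- NULL
  atom_counter <- 0L
  for (ci in seq_along(chains)) {
    ch <- chains[ci]
    ridx <- which(res_tab$chain == ch)
    offset <- c(0, (ci - 1) * 30, 0)
    ## seed atoms of residue 1 (same in every frame)
    Npos <- matrix(rep(c(0, 0, 0), each = nf), nf)
    CApos <- matrix(rep(c(BOND["N_CA"], 0, 0), each = nf), nf)
    ang0 <- deg2rad(ANGLE["N_CA_C"])
    Cpos <- matrix(rep(c(BOND["N_CA"] - BOND["CA_C"] * cos(ang0),
                         BOND["CA_C"] * sin(ang0), 0), each = nf), nf)
    chain_rows <- list(); chain_xyz <- list()
    prevC <- NULL
    for (k in seq_along(ridx)) {
      i <- ridx[k]
      if (k == 1L) {
        N <- Npos; CA <- CApos; C <- Cpos
      } else {
        ## N from psi(prev), CA from omega=180, C from phi(this)
        N <- nerf_place(prevN, prevCA, prevC, BOND["C_N"], ANGLE["CA_C_N"],
                        tors[, ridx[k - 1L], 2])
        CA <- nerf_place(prevCA, prevC, N, BOND["N_CA"], ANGLE["C_N_CA"], 180)
        C <- nerf_place(prevC, N, CA, BOND["CA_C"], ANGLE["N_CA_C"],
                        tors[, i, 1])
      }
      ## CB off the backbone with a fixed improper-style dihedral, OG by chi1
      CB <- nerf_place(C, N, CA, BOND["CA_CB"], ANGLE["N_CA_CB"], 123)
      OG <- nerf_place(N, CA, CB, BOND["CB_OG"], ANGLE["CA_CB_OG"],
                       tors[, i, 3])
      for (nm in c("N", "CA", "C", "CB", "OG")) {
        atom_counter <- atom_counter + 1L
        chain_rows[[length(chain_rows) + 1L]] <- data.frame(
          chain = ch, resno = res_tab$resno[i], icode = "", resname = "SER",
          atom = nm, element = substr(nm, 1, 1), x = 0, y = 0, z = 0,
          occ = 1, b = 0, het = FALSE, stringsAsFactors = FALSE)
        chain_xyz[[length(chain_xyz) + 1L]] <-
          sweep(switch(nm, N = N, CA = CA, C = C, CB = CB, OG = OG), 2,
                offset, `+`)
      }
      prevN <- N; prevCA <- CA; prevC <- C
    }
    rows <- c(rows, chain_rows)
    coords <- c(coords, chain_xyz)
  }
  atoms <- do.call(rbind, rows)
  arr <- array(NA_real_, dim = c(nf, nrow(atoms), 3))
  for (j in seq_along(coords)) arr[, j, ] <- coords[[j]]
  topo <- assign_protomers(StructureModel(atoms, source_id = "synthetic_traj"),
                           c("R", "S"))
  traj <- Trajectory(topo, arr)
  list(trajectory = traj,
       truth = list(mode = mode, planted = planted_keys, torsions = tors,
                    residues = res_tab, seed = spec$seed))
}

#' Plant a contact time series
#'
#' Builds a two-chain C-alpha toy system where each planted residue pair
#' is within van der Waals contact distance in exactly
#' `frequency * n_frames` frames (error if that product is not an
#' integer) and far apart otherwise. Contact frames are a seeded random
#' subset, so frequencies are exact by construction.
#'
#' @param spec a [synthetic_spec()] with a `contacts` data frame
#'   (`res_a`, `res_b`, `frequency`)
#' @return list with `trajectory` and `truth` (planted frequencies)
#' @export
plant_contact_series <- function(spec) {
  ct <- spec$contacts
  if (is.null(ct) || !nrow(ct)) abort("spec$contacts is empty",
                                      "configuration_error")
  nf <- spec$n_frames
  k <- ct$frequency * nf
  if (any(abs(k - round(k)) > 1e-9))
    abort("frequencies must be rational with the frame count", "configuration_error")
  k <- as.integer(round(k))
  set.seed(spec$seed)
  npair <- nrow(ct)
  ## chain R: fixed residues on a line, 12 A apart; chain S: partners that
  ## toggle between 3.5 A (contact) and 25 A (no contact)
  mk_atom <- function(chain, resno, x, y, z)
    data.frame(chain = chain, resno = resno, icode = "", resname = "ALA",
               atom = "CA", element = "C", x = x, y = y, z = z, occ = 1,
               b = 0, het = FALSE, stringsAsFactors = FALSE)
  rows <- list()
  for (p in seq_len(npair)) {
    rows[[length(rows) + 1L]] <- mk_atom("R", ct$res_a[p], 12 * p, 0, 0)
    rows[[length(rows) + 1L]] <- mk_atom("S", ct$res_b[p], 12 * p, 3.5, 0)
  }
  atoms <- do.call(rbind, rows)
  arr <- array(NA_real_, dim = c(nf, nrow(atoms), 3))
  for (j in seq_len(nrow(atoms))) arr[, j, ] <-
    matrix(rep(as.numeric(atoms[j, c("x", "y", "z")]), each = nf), nf)
  for (p in seq_len(npair)) {
    on_frames <- if (k[p] > 0) sample(nf, k[p]) else integer()
    srow <- 2L * p
    y <- rep(25, nf); y[on_frames] <- 3.5
    arr[, srow, 2] <- y
  }
  topo <- assign_protomers(StructureModel(atoms, source_id = "planted_contacts"),
                           c("R", "S"))
  list(trajectory = Trajectory(topo, arr),
       truth = ct)
}
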