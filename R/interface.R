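#' Dimer-interface analysis
#'
#' Shrake-Rupley solvent-accessible surface area (SASA), buried interface
#' area of a homodimer, typed residue-residue contact detection, contact
#' persistence across trajectory frames, a reduced-forcefield
#' inter-protomer interaction energy, and ligand-contact residue listing.
#'
#' Contact criteria (getcontacts-style defaults): van der Waals contact if
#' the heavy-atom distance is at most r_vdW(i) + r_vdW(j) + 0.5 A; hydrogen
#' bond if a donor-acceptor N/O pair is within 3.5 A (and, when an H is
#' modelled on the donor, the D-H...A angle is at least 110 degrees); salt
#' bridge if charged-group N/O atoms are within 4.0 A; cation-pi if a
#' cationic N is within 6.0 A of an aromatic ring centroid and within 60
#' degrees of the ring normal.
#'
#' @name interface
NULL

#' Shrake-Rupley solvent-accessible surface area
#'
#' @param model a [StructureModel]; hydrogens are included if present
#' @param probe probe radius in Angstrom (water: 1.4)
#' @param n_points sphere sample points per atom
#' @param atoms optional logical/integer subset of rows of `model$atoms`
#'   to compute areas for (occlusion still uses all atoms in `model`)
#' @return a `SasaResult`: list with `atom_area` (Angstrom^2 per atom),
#'   `residue_area` (named by residue key `chain|resno|icode`), `probe`,
#'   `n_points`
#' @export
shrake_rupley_sasa <- function(model, probe = 1.4, n_points = 960,
                               atoms = NULL) {
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- vdw_radius(a$element)
  n <- nrow(a)
  sphere <- fibonacci_sphere(n_points)
  idx <- if (is.null(atoms)) seq_len(n) else seq_len(n)[atoms]
  area <- numeric(n)
  rext <- rad + probe
  for (i in idx) {
    ri <- rext[i]
    pts <- sweep(sphere * ri, 2, xyz[i, ], `+`)
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nbr <- which(d2 < (ri + rext)^2 & d2 > 0)
    acc <- rep(TRUE, n_points)
    for (j in nbr) {
      dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > rext[j]^2
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * ri^2 * sum(acc) / n_points
  }
  keys <- atom_res_key(a)
  res_area <- tapply(area[idx], keys[idx], sum)
  structure(list(atom_area = area, residue_area = res_area,
                 probe = probe, n_points = n_points),
            class = "SasaResult")
}

submodel <- function(model, chains) {
  keep <- model$atoms$chain %in% chains
  m <- model
  m$atoms <- model$atoms[keep, , drop = FALSE]
  m$protomer_map <- model$protomer_map[names(model$protomer_map) %in% chains]
  m
}

#' Buried dimer-interface area
#'
#' `(SASA(A alone) + SASA(B alone) - SASA(AB complex)) / 2`, the standard
#' PISA-style buried-area convention, computed over the two receptor
#' protomer chains only (ligands/waters excluded).
#'
#' @param model a [StructureModel] with both protomers assigned
#' @param probe probe radius, Angstrom
#' @param n_points sphere points per atom
#' @return buried area in Angstrom^2 (list with `area`, `per_protomer`)
#' @export
buried_interface_area <- function(model, probe = 1.4, n_points = 960) {
  if (length(model$protomer_map) < 2)
    abort("dimer required: both protomers must be assigned", "dimer_required")
  cha <- protomer_chain(model, "A"); chb <- protomer_chain(model, "B")
  strip <- function(m) { m$atoms <- m$atoms[!m$atoms$het, , drop = FALSE]; m }
  mA <- strip(submodel(model, cha)); mB <- strip(submodel(model, chb))
  mAB <- strip(submodel(model, c(cha, chb)))
  sA <- sum(shrake_rupley_sasa(mA, probe, n_points)$atom_area)
  sB <- sum(shrake_rupley_sasa(mB, probe, n_points)$atom_area)
  sAB_res <- shrake_rupley_sasa(mAB, probe, n_points)
  sAB <- sum(sAB_res$atom_area)
  cplx_by_chain <- tapply(sAB_res$atom_area, mAB$atoms$chain, sum)
  list(area = (sA + sB - sAB) / 2,
       per_protomer = c(A = unname(sA - cplx_by_chain[[cha]]),
                        B = unname(sB - cplx_by_chain[[chb]])))
}

## ---- typed contacts -------------------------------------------------------

SIDECHAIN_CATIONS <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"),
                          HIS = c("ND1", "NE2"))
SIDECHAIN_ANIONS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
AROMATIC_RINGS <- list(PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                       TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                       TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
HB_DONOR_ATOMS <- c("N", "ND1", "ND2", "NE", "NE1", "NE2", "NH1", "NH2",
                    "NZ", "OG", "OG1", "OH", "SG", "OW")
HB_ACCEPTOR_ATOMS <- c("O", "OD1", "OD2", "OE1", "OE2", "OG", "OG1", "OH",
                       "ND1", "NE2", "OXT", "OW", "SD")

resolve_residue_set <- function(model, set) {
  ## set: residue keys, data.frame(chain,resno[,icode]), or integer resnos
  if (is.data.frame(set)) {
    ic <- if ("icode" %in% names(set)) set$icode else ""
    return(res_key(set$chain, set$resno, ic))
  }
  if (is.character(set)) return(set)
  if (is.numeric(set)) {
    a <- model$atoms[model$atoms$resno %in% set & !model$atoms$het, ]
    return(unique(atom_res_key(a)))
  }
  abort("cannot interpret residue set", "configuration_error")
}

ring_centroids <- function(atoms) {
  res <- split(seq_len(nrow(atoms)), atom_res_key(atoms))
  out <- list()
  for (k in names(res)) {
    rows <- res[[k]]
    rn <- atoms$resname[rows[1]]
    ring <- AROMATIC_RINGS[[rn]]
    if (is.null(ring)) next
    sel <- rows[atoms$atom[rows] %in% ring]
    if (length(sel) < 5) next
    X <- as.matrix(atoms[sel, c("x", "y", "z")])
    ctr <- colMeans(X)
    sv <- svd(sweep(X, 2, ctr))
    out[[k]] <- list(centroid = ctr, normal = sv$v[, 3])
  }
  out
}

#' Detect typed residue-residue contacts between two groups
#'
#' Emits one record per (residue pair, contact type) under the criteria in
#' the package contact defaults (see [interface]). Hydrogen atoms, when
#' present, refine hydrogen-bond geometry; otherwise the distance criterion
#' alone is used (cryo-EM models rarely include H).
#'
#' @param model a [StructureModel] (a single frame)
#' @param group_a,group_b disjoint residue sets: residue keys
#'   (`"chain|resno|"`), data frames with chain/resno, or residue numbers
#' @param frame frame index recorded on the output (default `"static"`)
#' @return data frame of `ContactRecord`s: res_a, res_b (residue keys),
#'   type, distance
#' @export
detect_contacts <- function(model, group_a, group_b, frame = "static") {
  ka <- resolve_residue_set(model, group_a)
  kb <- resolve_residue_set(model, group_b)
  if (length(intersect(ka, kb)))
    abort("contact groups must be disjoint", "configuration_error")
  empty <- data.frame(res_a = character(), res_b = character(),
                      type = character(), distance = numeric(),
                      frame = character(), stringsAsFactors = FALSE)
  if (!length(ka) || !length(kb)) {
    warning("empty contact group; returning no contacts")
    return(empty)
  }
  at <- model$atoms
  keys <- atom_res_key(at)
  ia <- which(keys %in% ka); ib <- which(keys %in% kb)
  ia_h <- ia[at$element[ia] != "H"]; ib_h <- ib[at$element[ib] != "H"]
  if (!length(ia_h) || !length(ib_h)) return(empty)
  Xa <- as.matrix(at[ia_h, c("x", "y", "z")])
  Xb <- as.matrix(at[ib_h, c("x", "y", "z")])
  ra <- vdw_radius(at$element[ia_h]); rb <- vdw_radius(at$element[ib_h])
  D <- sqrt(outer(rowSums(Xa^2), rowSums(Xb^2), `+`) - 2 * Xa %*% t(Xb))
  recs <- list()
  add <- function(i, j, type, d) {
    recs[[length(recs) + 1L]] <<- data.frame(
      res_a = keys[i], res_b = keys[j], type = type, distance = d,
      frame = as.character(frame), stringsAsFactors = FALSE)
  }
  ## van der Waals
  thr <- outer(ra, rb, `+`) + 0.5
  hits <- which(D <= thr, arr.ind = TRUE)
  for (r in seq_len(nrow(hits)))
    add(ia_h[hits[r, 1]], ib_h[hits[r, 2]], "vdw", D[hits[r, 1], hits[r, 2]])
  ## hydrogen bonds (donor in either group)
  hb_pairs <- function(idx_d, idx_a, Dm, transpose) {
    don <- which(at$atom[idx_d] %in% HB_DONOR_ATOMS &
                 at$element[idx_d] %in% c("N", "O", "S"))
    acc <- which(at$atom[idx_a] %in% HB_ACCEPTOR_ATOMS &
                 at$element[idx_a] %in% c("N", "O", "S"))
    for (i in don) for (j in acc) {
      d <- if (transpose) Dm[j, i] else Dm[i, j]
      if (d > 3.5 || d <= 0) next
      gi <- idx_d[i]; gj <- idx_a[j]
      ## D-H...A angle when an H bonded to the donor is present
      ok <- TRUE
      hsel <- which(at$element == "H" & keys == keys[gi])
      if (length(hsel)) {
        dpos <- as.numeric(at[gi, c("x", "y", "z")])
        apos <- as.numeric(at[gj, c("x", "y", "z")])
        hd <- as.matrix(at[hsel, c("x", "y", "z")])
        dh <- sqrt(rowSums(sweep(hd, 2, dpos)^2))
        hs <- hsel[dh < 1.3]
        if (length(hs)) {
          ang <- vapply(hs, function(h) {
            hp <- as.numeric(at[h, c("x", "y", "z")])
            v1 <- dpos - hp; v2 <- apos - hp
            rad2deg(acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                      (vnorm(v1) * vnorm(v2))))))
          }, numeric(1))
          ok <- any(ang >= 110)
        }
      }
      if (ok) {
        if (transpose) add(gj, gi, "hbond", d) else add(gi, gj, "hbond", d)
      }
    }
  }
  hb_pairs(ia_h, ib_h, D, transpose = FALSE)
  hb_pairs(ib_h, ia_h, D, transpose = TRUE)
  ## salt bridges
  charged_idx <- function(idx, table) {
    keep <- logical(length(idx))
    for (k in seq_along(idx)) {
      nm <- table[[at$resname[idx[k]]]]
      keep[k] <- !is.null(nm) && at$atom[idx[k]] %in% nm
    }
    idx[keep]
  }
  cat_a <- charged_idx(ia_h, SIDECHAIN_CATIONS)
  ani_a <- charged_idx(ia_h, SIDECHAIN_ANIONS)
  cat_b <- charged_idx(ib_h, SIDECHAIN_CATIONS)
  ani_b <- charged_idx(ib_h, SIDECHAIN_ANIONS)
  sb <- function(set1, set2) {
    for (i in set1) for (j in set2) {
      d <- vnorm(as.numeric(at[i, c("x", "y", "z")]) -
                 as.numeric(at[j, c("x", "y", "z")]))
      if (d <= 4.0) {
        if (i %in% ia_h) add(i, j, "saltbridge", d) else add(j, i, "saltbridge", d)
      }
    }
  }
  sb(cat_a, ani_b); sb(ani_a, cat_b)
  ## cation-pi
  rings_a <- ring_centroids(at[ia_h, , drop = FALSE])
  rings_b <- ring_centroids(at[ib_h, , drop = FALSE])
  catpi <- function(cations, rings, cation_in_a) {
    for (i in cations) for (k in names(rings)) {
      cpos <- as.numeric(at[i, c("x", "y", "z")])
      v <- cpos - rings[[k]]$centroid
      d <- vnorm(v)
      if (d > 6.0 || d < 1e-6) next
      off <- rad2deg(acos(min(1, abs(sum(unitv(v) * rings[[k]]$normal)))))
      if (off <= 60) {
        if (cation_in_a)
          recs[[length(recs) + 1L]] <<- data.frame(
            res_a = keys[i], res_b = k, type = "cationpi", distance = d,
            frame = as.character(frame), stringsAsFactors = FALSE)
        else
          recs[[length(recs) + 1L]] <<- data.frame(
            res_a = k, res_b = keys[i], type = "cationpi", distance = d,
            frame = as.character(frame), stringsAsFactors = FALSE)
      }
    }
  }
  catpi(cat_a, rings_b, TRUE); catpi(cat_b, rings_a, FALSE)
  if (!length(recs)) return(empty)
  out <- do.call(rbind, recs)
  ## one record per (pair, type): keep the shortest distance
  out <- out[order(out$res_a, out$res_b, out$type, out$distance), ]
  out <- out[!duplicated(out[, c("res_a", "res_b", "type")]), ]
  rownames(out) <- NULL
  out
}

#' Contact persistence over a trajectory
#'
#' A residue pair counts as "in contact" in a frame if any contact type
#' links it; its frequency is the fraction of frames with a contact. A pair
#' is persistent iff frequency is strictly greater than `threshold`
#' (default 0.60, matching the "more than 60% of simulation time" rule —
#' a pair at exactly 60% is NOT persistent).
#'
#' @param traj a [Trajectory]
#' @param group_a,group_b residue sets (see [detect_contacts()])
#' @param threshold persistence threshold, strict
#' @return data frame: res_a, res_b, frequency, persistent
#' @export
contact_persistence <- function(traj, group_a, group_b, threshold = 0.60) {
  nf <- n_frames(traj)
  if (nf < 1) abort("trajectory has no frames", "frame_boundary_error")
  tally <- new.env(parent = emptyenv())
  for (f in seq_len(nf)) {
    m <- frame_model(traj, f)
    cc <- suppressWarnings(detect_contacts(m, group_a, group_b, frame = f))
    if (!nrow(cc)) next
    pairs <- unique(paste(cc$res_a, cc$res_b, sep = "@"))
    for (p in pairs) assign(p, (get0(p, envir = tally) %||% 0L) + 1L,
                            envir = tally)
  }
  keys <- ls(tally)
  if (!length(keys))
    return(data.frame(res_a = character(), res_b = character(),
                      frequency = numeric(), persistent = logical()))
  counts <- vapply(keys, get, numeric(1), envir = tally)
  parts <- strsplit(keys, "@", fixed = TRUE)
  out <- data.frame(res_a = vapply(parts, `[`, "", 1),
                    res_b = vapply(parts, `[`, "", 2),
                    frequency = counts / nf, stringsAsFactors = FALSE)
  out$persistent <- out$frequency > threshold
  out <- out[order(-out$frequency, out$res_a, out$res_b), ]
  rownames(out) <- NULL
  out
}

## ---- reduced forcefield ---------------------------------------------------

COULOMB_K <- 332.0636  # kcal A / (mol e^2)

## generic per-class LJ parameters: epsilon (kcal/mol), rmin/2 (A)
LJ_PARAMS <- list(C = c(eps = 0.078, rmin2 = 2.04),
                  N = c(eps = 0.170, rmin2 = 1.85),
                  O = c(eps = 0.120, rmin2 = 1.70),
                  S = c(eps = 0.450, rmin2 = 2.00),
                  H = c(eps = 0.022, rmin2 = 1.32),
                  P = c(eps = 0.585, rmin2 = 2.15))

## reduced charge set: formal charges on charged side-chain groups, small
## polar charges on the backbone; everything else neutral
atom_charge <- function(resname, atom, element) {
  ch <- numeric(length(atom))
  ch[atom == "N"] <- -0.30
  ch[atom == "O"] <- -0.40
  ch[atom == "C"] <- 0.40
  ch[atom == "CA"] <- 0.10
  ch[atom == "H"] <- 0.20
  for (i in seq_along(atom)) {
    an <- SIDECHAIN_ANIONS[[resname[i]]]
    if (!is.null(an) && atom[i] %in% an) ch[i] <- -0.5
    ca <- SIDECHAIN_CATIONS[[resname[i]]]
    if (!is.null(ca) && atom[i] %in% ca)
      ch[i] <- 1.0 / length(ca)
  }
  ch
}

#' Inter-group interaction energy (reduced forcefield)
#'
#' Pairwise-additive 12-6 Lennard-Jones plus Coulomb energy between all
#' atom pairs across two residue groups, with a 12 A cutoff and Coulomb
#' constant 332.0636 kcal A mol^-1 e^-2. Charges and LJ parameters come
#' from a deliberately simplified per-atom-class table; values are labelled
#' "reduced forcefield" and are meant for state-to-state ordering, not
#' absolute CHARMM-level accuracy.
#'
#' @param model a [StructureModel]
#' @param group_a,group_b residue sets (see [detect_contacts()])
#' @param cutoff pair cutoff in Angstrom
#' @param charges optional numeric vector overriding per-atom charges
#' @return list with `vdw`, `coulomb`, `total` (kcal/mol), and
#'   `forcefield = "reduced"`
#' @export
interface_interaction_energy <- function(model, group_a, group_b,
                                         cutoff = 12.0, charges = NULL) {
  at <- model$atoms
  keys <- atom_res_key(at)
  ia <- which(keys %in% resolve_residue_set(model, group_a))
  ib <- which(keys %in% resolve_residue_set(model, group_b))
  if (!length(ia) || !length(ib))
    abort("empty atom group for energy", "configuration_error")
  el <- toupper(at$element)
  missing_lj <- setdiff(unique(el[c(ia, ib)]), names(LJ_PARAMS))
  if (length(missing_lj))
    abort(paste("no LJ parameters for element(s):",
                paste(missing_lj, collapse = ", ")), "configuration_error")
  q <- charges %||% atom_charge(at$resname, at$atom, el)
  eps <- vapply(el, function(e) LJ_PARAMS[[e]]["eps"], numeric(1))
  rm2 <- vapply(el, function(e) LJ_PARAMS[[e]]["rmin2"], numeric(1))
  Xa <- as.matrix(at[ia, c("x", "y", "z")])
  Xb <- as.matrix(at[ib, c("x", "y", "z")])
  D2 <- outer(rowSums(Xa^2), rowSums(Xb^2), `+`) - 2 * Xa %*% t(Xb)
  D <- sqrt(pmax(D2, 0))
  within <- D <= cutoff & D > 0
  if (!any(within)) return(list(vdw = 0, coulomb = 0, total = 0,
                                forcefield = "reduced"))
  Eij <- sqrt(outer(eps[ia], eps[ib]))      # Lorentz-Berthelot
  Rij <- outer(rm2[ia], rm2[ib], `+`)       # rmin_ij
  sr6 <- (Rij / pmax(D, 1e-6))^6
  vdw_m <- Eij * (sr6^2 - 2 * sr6)
  cou_m <- COULOMB_K * outer(q[ia], q[ib]) / pmax(D, 1e-6)
  vdw <- sum(vdw_m[within]); cou <- sum(cou_m[within])
  list(vdw = vdw, coulomb = cou, total = vdw + cou, forcefield = "reduced")
}

#' Receptor residues in contact with a ligand chain
#'
#' A receptor residue qualifies if any of its heavy atoms lies within the
#' van der Waals contact criterion (r_i + r_j + 0.5 A) of any ligand heavy
#' atom.
#'
#' @param model a [StructureModel]
#' @param ligand_chain chain id of the ligand
#' @param receptor_chains chains to scan; defaults to the protomer chains
#' @return data frame of contacting residues (chain, resno, resname) with
#'   attribute `count`
#' @export
ligand_contact_residues <- function(model, ligand_chain,
                                    receptor_chains = names(model$protomer_map)) {
  at <- model$atoms
  lig <- at[at$chain == ligand_chain & at$element != "H", , drop = FALSE]
  if (!nrow(lig)) abort(paste("no ligand atoms in chain", ligand_chain),
                        "format_error")
  rec <- at[at$chain %in% receptor_chains & at$element != "H" & !at$het, ,
            drop = FALSE]
  Xl <- as.matrix(lig[, c("x", "y", "z")])
  Xr <- as.matrix(rec[, c("x", "y", "z")])
  rl <- vdw_radius(lig$element); rr <- vdw_radius(rec$element)
  D <- sqrt(pmax(outer(rowSums(Xr^2), rowSums(Xl^2), `+`) - 2 * Xr %*% t(Xl), 0))
  thr <- outer(rr, rl, `+`) + 0.5
  hit <- rowSums(D <= thr) > 0
  res <- unique(rec[hit, c("chain", "resno", "resname")])
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "count") <- nrow(res)
  res
}
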