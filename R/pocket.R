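#' Ligand-binding pocket volume by grid flood fill
#'
#' HOLLOW-style cavity volumetry: a cubic voxel grid is laid over a
#' bounding sphere around a seed point; voxels farther than
#' `r_vdW + probe` from every protein heavy atom are "empty"; the pocket
#' is the 6-connected empty component containing the seed, and its volume
#' is the voxel count times `spacing^3`.
#'
#' @name pocket
NULL

#' Estimate a pocket volume
#'
#' @param model a [StructureModel]; heavy atoms of all non-water chains
#'   are treated as protein/ligand-excluding walls unless `chains` narrows
#'   the selection
#' @param seed numeric xyz triple inside the pocket, or a ligand chain id
#'   (seed = ligand heavy-atom centroid)
#' @param spacing voxel edge, Angstrom (<= 1)
#' @param probe probe radius, Angstrom
#' @param bounding_radius radius of the search sphere around the seed
#' @param chains optional chain subset forming the pocket walls
#' @return a `PocketGrid`: list with `volume` (Angstrom^3), `n_voxels`,
#'   `spacing`, `seed`, `bounding_radius`, and `voxels` (n x 3 centers of
#'   pocket voxels)
#' @export
pocket_volume <- function(model, seed, spacing = 0.5, probe = 1.4,
                          bounding_radius = 15, chains = NULL) {
  if (spacing > 1) abort("grid spacing must be <= 1 A", "configuration_error")
  at <- model$atoms
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  at <- at[at$element != "H" & at$resname != "HOH", , drop = FALSE]
  if (is.character(seed) && length(seed) == 1L) {
    lig <- at[at$chain == seed, , drop = FALSE]
    if (!nrow(lig)) abort(paste("seed chain not found:", seed), "format_error")
    seed_pt <- unname(colMeans(as.matrix(lig[, c("x", "y", "z")])))
    ## ligand atoms are not pocket walls
    at <- at[at$chain != seed, , drop = FALSE]
  } else seed_pt <- as.numeric(seed)

  half <- ceiling(bounding_radius / spacing)
  ax <- seed_pt[1] + spacing * (-half:half)
  ay <- seed_pt[2] + spacing * (-half:half)
  az <- seed_pt[3] + spacing * (-half:half)
  nx <- length(ax); ny <- length(ay); nz <- length(az)
  ## occupancy array: TRUE = blocked
  occ <- array(FALSE, dim = c(nx, ny, nz))
  if (nrow(at)) {
    X <- as.matrix(at[, c("x", "y", "z")])
    rad <- vdw_radius(at$element) + probe
    keep <- sqrt(rowSums(sweep(X, 2, seed_pt)^2)) <= bounding_radius +
      max(rad) + spacing
    X <- X[keep, , drop = FALSE]; rad <- rad[keep]
    for (k in seq_len(nrow(X))) {
      r <- rad[k]
      ix <- which(abs(ax - X[k, 1]) <= r)
      iy <- which(abs(ay - X[k, 2]) <= r)
      iz <- which(abs(az - X[k, 3]) <= r)
      if (!length(ix) || !length(iy) || !length(iz)) next
      dx2 <- (ax[ix] - X[k, 1])^2
      dy2 <- (ay[iy] - X[k, 2])^2
      dz2 <- (az[iz] - X[k, 3])^2
      blk <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2
      occ[ix, iy, iz] <- occ[ix, iy, iz, drop = FALSE] | blk
    }
  }
  ## restrict to bounding sphere
  gx <- (ax - seed_pt[1])^2; gy <- (ay - seed_pt[2])^2; gz <- (az - seed_pt[3])^2
  inside <- outer(outer(gx, gy, `+`), gz, `+`) <= bounding_radius^2
  empty <- !occ & inside
  si <- c(half + 1L, half + 1L, half + 1L)
  if (!empty[si[1], si[2], si[3]])
    abort("seed point is buried inside the protein volume", "seed_buried")
  ## 6-connected flood fill from the seed (vectorized frontier BFS)
  visited <- array(FALSE, dim = dim(occ))
  lin <- function(i, j, k) i + nx * (j - 1L) + nx * ny * (k - 1L)
  frontier <- lin(si[1], si[2], si[3])
  visited[frontier] <- TRUE
  offs <- c(-1L, 1L, -nx, nx, -nx * ny, nx * ny)
  total <- nx * ny * nz
  ## neighbour validity masks below avoid wrapping across grid faces
  while (length(frontier)) {
    cand <- integer(0)
    for (o in seq_along(offs)) {
      nb <- frontier + offs[o]
      ok <- nb >= 1L & nb <= total
      ## prevent x-wrap for +-1 moves
      if (offs[o] == -1L) ok <- ok & ((frontier - 1L) %% nx) != 0L
      if (offs[o] == 1L) ok <- ok & (frontier %% nx) != 0L
      ## prevent y-wrap for +-nx moves
      if (offs[o] == -nx) ok <- ok & (((frontier - 1L) %/% nx) %% ny) != 0L
      if (offs[o] == nx) ok <- ok & (((frontier - 1L) %/% nx) %% ny) != (ny - 1L)
      cand <- c(cand, nb[ok])
    }
    cand <- unique(cand)
    cand <- cand[empty[cand] & !visited[cand]]
    visited[cand] <- TRUE
    frontier <- cand
  }
  n_pocket <- sum(visited)
  idx <- which(visited, arr.ind = TRUE)
  structure(list(volume = n_pocket * spacing^3, n_voxels = n_pocket,
                 spacing = spacing, probe = probe, seed = seed_pt,
                 bounding_radius = bounding_radius,
                 voxels = cbind(ax[idx[, 1]], ay[idx[, 2]], az[idx[, 3]])),
            class = "PocketGrid")
}

#' @export
print.PocketGrid <- function(x, ...) {
  cat(sprintf("PocketGrid: %.1f A^3 (%d voxels at %.2f A spacing)\n",
              x$volume, x$n_voxels, x$spacing))
  invisible(x)
}

#' Pocket contraction between two states
#'
#' Computes both pocket volumes with a shared seed rule and reports the
#' volume change `V_b - V_a` and the fractional contraction
#' `(V_a - V_b) / V_a`.
#'
#' The shared seed rule: if `seed` is a ligand chain id, the centroid is
#' taken in the state that has the ligand and transferred to the other
#' state via superposition of protomer A (so ligand-free states are probed
#' at the transformed pocket location).
#'
#' @param state_a,state_b [StructureModel]s
#' @param seed xyz triple (used for both states) or a ligand chain id
#' @param align_protomer protomer used to transfer the seed between states
#' @param ... passed to [pocket_volume()]
#' @return list with `volume_a`, `volume_b`, `delta` (V_b - V_a) and
#'   `fraction` ((V_a - V_b)/V_a)
#' @export
pocket_contraction <- function(state_a, state_b, seed,
                               align_protomer = "A", ...) {
  seeds <- list(a = seed, b = seed)
  if (is.character(seed) && length(seed) == 1L && nchar(seed) <= 2) {
    has_a <- seed %in% state_a$atoms$chain
    has_b <- seed %in% state_b$atoms$chain
    if (has_a && !has_b) {
      lig <- state_a$atoms[state_a$atoms$chain == seed &
                           state_a$atoms$element != "H", ]
      ctr <- colMeans(as.matrix(lig[, c("x", "y", "z")]))
      p <- pair_common_calpha(state_b, state_a, align_protomer)
      sup <- kabsch_superpose(p$b, p$a)  # maps state_a frame -> state_b frame
      seeds$b <- as.numeric(apply_superposition(sup, matrix(ctr, 1)))
      seeds$a <- seed
    } else if (has_b && !has_a) {
      lig <- state_b$atoms[state_b$atoms$chain == seed &
                           state_b$atoms$element != "H", ]
      ctr <- colMeans(as.matrix(lig[, c("x", "y", "z")]))
      p <- pair_common_calpha(state_a, state_b, align_protomer)
      sup <- kabsch_superpose(p$b, p$a)
      seeds$a <- as.numeric(apply_superposition(sup, matrix(ctr, 1)))
      seeds$b <- seed
    }
  }
  va <- pocket_volume(state_a, seeds$a, ...)$volume
  vb <- pocket_volume(state_b, seeds$b, ...)$volume
  list(volume_a = va, volume_b = vb, delta = vb - va,
       fraction = if (va > 0) (va - vb) / va else NA_real_)
}
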