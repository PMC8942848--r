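#' Rigid-body superposition and inter-state geometry
#'
#' Tools that quantify conformational transitions between receptor states:
#' least-squares (Kabsch) superposition, per-residue C-alpha displacement
#' after a "global alignment" (all common C-alpha of one protomer), helix
#' axis fitting, and kink / axial-rotation angles between states.
#'
#' @name geometry
NULL

#' Kabsch superposition of two ordered point sets
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' `mobile` and `reference` (SVD solution with determinant correction, so
#' `det(rotation) = +1` always).
#'
#' @param mobile n x 3 matrix
#' @param reference n x 3 matrix, same row order/pairing
#' @return a `Superposition`: list with `rotation` (3x3), `translation`
#'   (length 3; maps mobile as `x %*% t(R) + t`), `rmsd` (Angstrom) and
#'   `n_atoms`
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference))
    abort(sprintf("point sets differ in length (%d vs %d)", nrow(mobile),
                  nrow(reference)), "pairing_error")
  n <- nrow(mobile)
  if (n < 3) abort("need at least 3 points", "degenerate_geometry")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  ## collinearity check: second singular value of centered set ~ 0
  sv <- svd(P)$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    abort("degenerate (collinear) point set", "degenerate_geometry")
  H <- crossprod(P, Q)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- cr - as.vector(R %*% cm)
  moved <- P %*% t(R)
  rmsd <- sqrt(sum((moved - Q)^2) / n)
  structure(list(rotation = R, translation = t, rmsd = rmsd, n_atoms = n),
            class = "Superposition")
}

#' @export
print.Superposition <- function(x, ...) {
  cat(sprintf("Superposition: rmsd %.3f A over %d atoms\n", x$rmsd, x$n_atoms))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param sup a `Superposition`
#' @param xyz n x 3 matrix
#' @return transformed n x 3 matrix
#' @export
apply_superposition <- function(sup, xyz) {
  sweep(as.matrix(xyz) %*% t(sup$rotation), 2, sup$translation, `+`)
}

## C-alpha table of one protomer: data.frame(resno, x, y, z), ordered
calpha_table <- function(model, protomer, selection = NULL) {
  ch <- protomer_chain(model, protomer)
  a <- model$atoms
  sel <- a$chain == ch & a$atom == "CA" & !a$het
  a <- a[sel, , drop = FALSE]
  if (!is.null(selection)) a <- a[a$resno %in% selection, , drop = FALSE]
  a <- a[!duplicated(paste(a$resno, a$icode)), , drop = FALSE]
  a[order(a$resno), c("resno", "x", "y", "z"), drop = FALSE]
}

#' Pair the common C-alpha atoms of a protomer in two models
#'
#' Returns the C-alpha coordinates of residues modelled in both structures
#' (intersection of author residue numbers), ordered by residue number.
#' This is the pairing behind reported counts such as "r.m.s.d. over N
#' C-alpha atoms, protomer A aligned".
#'
#' @param a,b [StructureModel]s with protomers assigned
#' @param protomer protomer label, `"A"` or `"B"`
#' @param selection optional residue-number set restricting the pairing
#' @return list with matrices `a`, `b` (n x 3) and `resno` (length n)
#' @export
pair_common_calpha <- function(a, b, protomer = "A", selection = NULL) {
  ta <- calpha_table(a, protomer, selection)
  tb <- calpha_table(b, protomer, selection)
  common <- intersect(ta$resno, tb$resno)
  if (!length(common))
    abort("no residues in common between the two models", "no_common_residues")
  common <- sort(common)
  ia <- match(common, ta$resno); ib <- match(common, tb$resno)
  list(a = as.matrix(ta[ia, c("x", "y", "z")]),
       b = as.matrix(tb[ib, c("x", "y", "z")]),
       resno = common)
}

#' RMSD between two states after Kabsch alignment of one protomer
#'
#' @inheritParams pair_common_calpha
#' @return a `Superposition` (`b` is mobile, `a` is reference), with
#'   `resno` attached
#' @export
aligned_rmsd <- function(a, b, protomer = "A", selection = NULL) {
  p <- pair_common_calpha(a, b, protomer, selection)
  sup <- kabsch_superpose(p$b, p$a)
  sup$resno <- p$resno
  sup
}

#' Per-residue C-alpha displacement between two states
#'
#' Superposes `b` onto `a` using all common C-alpha atoms of
#' `align_protomer` ("global alignment"), then reports the Euclidean
#' distance between corresponding target C-alpha positions. Targets not
#' modelled in both structures are flagged missing rather than failing the
#' whole report.
#'
#' @param a,b [StructureModel]s with protomers assigned
#' @param align_protomer protomer used for the global alignment
#' @param targets data frame with columns `protomer` and `resno` (a
#'   `resname` column, if present, is carried through), or an integer
#'   vector of residue numbers on `align_protomer`
#' @return a `DisplacementReport` data frame: protomer, resno,
#'   displacement (Angstrom), missing flag
#' @export
residue_displacement <- function(a, b, align_protomer = "A", targets) {
  if (is.numeric(targets))
    targets <- data.frame(protomer = align_protomer, resno = as.integer(targets))
  p <- pair_common_calpha(a, b, align_protomer)
  sup <- kabsch_superpose(p$b, p$a)
  out <- targets
  out$displacement <- NA_real_
  out$missing <- TRUE
  for (i in seq_len(nrow(targets))) {
    ta <- calpha_table(a, targets$protomer[i], targets$resno[i])
    tb <- calpha_table(b, targets$protomer[i], targets$resno[i])
    if (nrow(ta) == 1L && nrow(tb) == 1L) {
      xb <- apply_superposition(sup, as.matrix(tb[, c("x", "y", "z")]))
      out$displacement[i] <- vnorm(as.numeric(xb) -
                                   as.numeric(ta[, c("x", "y", "z")]))
      out$missing[i] <- FALSE
    }
  }
  class(out) <- c("DisplacementReport", class(out))
  out
}

#' Fit a helix axis through a residue range
#'
#' Kahn's method: second differences of consecutive C-alpha positions are
#' exactly perpendicular to the helix axis, so cross products of
#' consecutive second differences give the axis direction (exact for an
#' ideal helix; averaged over the range for noisy ones). Oriented N to C.
#' A plain principal-axis fit carries a phase-imbalance bias of a degree
#' or two on short segments, which this estimator avoids.
#'
#' @param model a [StructureModel]
#' @param protomer protomer label
#' @param range inclusive residue-number range `c(start, end)`
#' @return a `HelixAxis`: list with `centroid`, `direction` (unit, N->C),
#'   `range`, `residual` (RMS distance of C-alpha from the axis, Angstrom)
#' @export
fit_helix_axis <- function(model, protomer, range) {
  ta <- calpha_table(model, protomer, seq(range[1], range[2]))
  if (nrow(ta) < 4)
    abort(sprintf("need >= 4 C-alpha in range %d-%d (found %d)",
                  range[1], range[2], nrow(ta)), "degenerate_geometry")
  X <- as.matrix(ta[, c("x", "y", "z")])
  n <- nrow(X)
  ## second differences point from the helix rim toward the axis
  U <- X[-c(1, n), , drop = FALSE] * (-2) + X[-c(n - 1, n), , drop = FALSE] +
    X[-c(1, 2), , drop = FALSE]
  nc <- X[n, ] - X[1, ]
  if (nrow(U) >= 2) {
    V1 <- U[-nrow(U), , drop = FALSE]; V2 <- U[-1, , drop = FALSE]
    A <- cbind(V1[, 2] * V2[, 3] - V1[, 3] * V2[, 2],
               V1[, 3] * V2[, 1] - V1[, 1] * V2[, 3],
               V1[, 1] * V2[, 2] - V1[, 2] * V2[, 1])
    len <- sqrt(rowSums(A^2))
    A <- A[len > 1e-10, , drop = FALSE] / len[len > 1e-10]
    sgn <- sign(A %*% nc)
    dir <- colSums(A * as.vector(sgn))
    if (vnorm(dir) < 1e-8) dir <- axis_from_points(X)$direction
    dir <- unitv(dir)
  } else dir <- axis_from_points(X)$direction
  if (sum(dir * nc) < 0) dir <- -dir
  ctr <- colMeans(X)
  perp <- sweep(X, 2, ctr)
  perp <- perp - outer(as.vector(perp %*% dir), dir)
  radii <- sqrt(rowSums(perp^2))
  structure(list(centroid = ctr, direction = dir, range = range,
                 residual = stats::sd(radii)),
            class = "HelixAxis")
}

axis_from_points <- function(X) {
  ctr <- colMeans(X)
  s <- svd(sweep(X, 2, ctr))
  dir <- s$v[, 1]
  if (sum(dir * (X[nrow(X), ] - X[1, ])) < 0) dir <- -dir
  list(centroid = ctr, direction = dir)
}

#' Helix kink angle between two states
#'
#' After globally aligning `b` onto `a` (common C-alpha of
#' `align_protomer`), fits the axis of `segment` in both states and returns
#' the angle between the two N->C oriented axes, in degrees within
#' \\[0, 180\\]. `kink_angle(a, a, ...)` is 0 and the measure is symmetric
#' in its first two arguments.
#'
#' @inheritParams residue_displacement
#' @param protomer protomer carrying the segment
#' @param segment inclusive residue range `c(start, end)`
#' @return angle in degrees
#' @export
kink_angle <- function(a, b, protomer = "A", segment,
                       align_protomer = "A") {
  p <- pair_common_calpha(a, b, align_protomer)
  sup <- kabsch_superpose(p$b, p$a)
  seg <- seq(segment[1], segment[2])
  Xa <- as.matrix(calpha_table(a, protomer, seg)[, c("x", "y", "z")])
  Xb <- as.matrix(calpha_table(b, protomer, seg)[, c("x", "y", "z")])
  if (nrow(Xa) < 4 || nrow(Xb) < 4)
    abort("segment too short for axis fit", "degenerate_geometry")
  Xb <- apply_superposition(sup, Xb)
  da <- axis_from_points(Xa)$direction
  db <- axis_from_points(Xb)$direction
  rad2deg(acos(pmin(1, pmax(-1, sum(da * db)))))
}

## swing-twist decomposition: rotation angle of R about unit axis u
twist_about_axis <- function(R, u) {
  u <- unitv(u)
  ## quaternion from rotation matrix
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    w <- 0.25 * s
    v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / s
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    v <- numeric(3)
    v[i] <- 0.25 * s
    w <- (R[k, j] - R[j, k]) / s
    v[j] <- (R[j, i] + R[i, j]) / s
    v[k] <- (R[k, i] + R[i, k]) / s
  }
  p <- sum(v * u)
  ang <- 2 * atan2(abs(p), abs(w))  # magnitude of twist in [0, pi]
  rad2deg(ang)
}

#' Axial rotation of a helix segment between two states
#'
#' Computes the optimal rigid transform taking the segment's C-alpha set in
#' `a` to that in `b`, then extracts the rotation component about the mean
#' of the two helix axes (swing-twist decomposition). Reported in degrees
#' within \\[0, 180\\].
#'
#' @inheritParams kink_angle
#' @return axial rotation angle in degrees
#' @export
axial_rotation_angle <- function(a, b, protomer = "A", segment) {
  seg <- seq(segment[1], segment[2])
  pa <- calpha_table(a, protomer, seg)
  pb <- calpha_table(b, protomer, seg)
  common <- intersect(pa$resno, pb$resno)
  if (length(common) < 4)
    abort("segment needs >= 4 common residues (one helix turn)",
          "degenerate_geometry")
  Xa <- as.matrix(pa[match(common, pa$resno), c("x", "y", "z")])
  Xb <- as.matrix(pb[match(common, pb$resno), c("x", "y", "z")])
  sup <- kabsch_superpose(Xa, Xb)
  da <- axis_from_points(Xa)$direction
  db <- axis_from_points(Xb)$direction
  u <- da + db
  if (vnorm(u) < 1e-8) u <- da  # antiparallel axes: fall back to state-a axis
  twist_about_axis(sup$rotation, u)
}
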