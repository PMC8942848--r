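# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
abort <- function(msg, class) {
  stop(structure(class = c(class, "gpcrdimer_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## wrap angle (degrees) to (-180, 180]
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) abort("zero-length vector", "degenerate_geometry")
  v / n
}

## rotation matrix about unit axis u by angle (radians), Rodrigues form
rotation_about_axis <- function(u, angle) {
  u <- unitv(u)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## residue keys "chain|resno|icode" used wherever residues index lists/sets
res_key <- function(chain, resno, icode = "") {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  paste(chain, resno, icode, sep = "|")
}

atom_res_key <- function(atoms) res_key(atoms$chain, atoms$resno, atoms$icode)

## van der Waals radii (Bondi) by element
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)

vdw_radius <- function(element) {
  el <- toupper(trimws(element))
  r <- VDW_RADII[el]
  if (anyNA(r)) {
    bad <- unique(el[is.na(r)])
    abort(sprintf("no van der Waals radius configured for element(s): %s",
                  paste(bad, collapse = ", ")), "configuration_error")
  }
  unname(r)
}

## deterministic near-uniform points on the unit sphere (generalized spiral)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
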