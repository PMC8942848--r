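# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests themselves write.

atom_row <- function(chain, resno, atom, element, x, y, z,
                     resname = "ALA", icode = "", occ = 1, b = 0,
                     het = FALSE) {
  data.frame(chain = chain, resno = as.integer(resno), icode = icode,
             resname = resname, atom = atom, element = element,
             x = x, y = y, z = z, occ = occ, b = b, het = het,
             stringsAsFactors = FALSE)
}

point_model <- function(xyz, chain = "A", element = "C", resname = "ALA") {
  rows <- lapply(seq_len(nrow(xyz)), function(i)
    atom_row(chain, i, "CA", element, xyz[i, 1], xyz[i, 2], xyz[i, 3],
             resname = resname))
  StructureModel(do.call(rbind, rows))
}

## two frozen 5-point sets for the Kabsch brute-force oracle
frozen_points_a <- function() matrix(c(
  0.212, -1.337, 0.764,
  1.508, 0.631, -0.249,
  -0.902, 0.411, 1.102,
  0.337, 1.255, 0.871,
  -1.155, -0.960, -2.488), ncol = 3, byrow = TRUE)

frozen_points_b <- function() matrix(c(
  1.129, 0.441, -0.518,
  -0.417, 2.008, 0.364,
  0.772, -1.503, 0.203,
  -0.807, -0.406, 1.319,
  -0.677, -0.540, -1.368), ncol = 3, byrow = TRUE)

## independent brute-force oracle: minimise RMSD over rotations by
## multi-start Nelder-Mead on Euler angles (never calls kabsch_superpose)
brute_force_min_rmsd <- function(mobile, reference, n_starts = 40) {
  Pc <- sweep(mobile, 2, colMeans(mobile))
  Qc <- sweep(reference, 2, colMeans(reference))
  euler_R <- function(a) {
    Rz <- matrix(c(cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1]), 0,
                   0, 0, 1), 3)
    Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0,
                   sin(a[2]), 0, cos(a[2])), 3)
    Rx <- matrix(c(1, 0, 0, 0, cos(a[3]), sin(a[3]),
                   0, -sin(a[3]), cos(a[3])), 3)
    Rz %*% Ry %*% Rx
  }
  obj <- function(a) {
    R <- euler_R(a)
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  set.seed(99)
  best <- Inf
  for (k in seq_len(n_starts)) {
    a0 <- stats::runif(3, -pi, pi)
    r <- stats::optim(a0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    r <- stats::optim(r$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
    if (r$value < best) best <- r$value
  }
  best
}

random_rigid_transform <- function() {
  ax <- gpcrdimer:::unitv(stats::rnorm(3))
  ang <- stats::runif(1, 0, 2 * pi)
  list(R = gpcrdimer:::rotation_about_axis(ax, ang), t = stats::rnorm(3, sd = 5))
}

transform_model <- function(model, R, t) {
  X <- as.matrix(model$atoms[, c("x", "y", "z")])
  Y <- sweep(X %*% t(R), 2, t, `+`)
  model$atoms$x <- Y[, 1]; model$atoms$y <- Y[, 2]; model$atoms$z <- Y[, 3]
  model
}

## hollow spherical shell of carbon atoms: cavity of effective radius
## (R_shell - r_vdw(C) - probe) around the origin
shell_model <- function(r_shell = 8.1, n = 900) {
  pts <- gpcrdimer:::fibonacci_sphere(n) * r_shell
  point_model(pts)
}

## exhaustive minimum-weight simple path between two nodes (oracle)
enumerate_min_path <- function(graph, src, dst) {
  n <- length(graph$nodes)
  W <- matrix(Inf, n, n)
  for (r in seq_len(nrow(graph$edges))) {
    i <- graph$edges$from[r]; j <- graph$edges$to[r]
    W[i, j] <- W[j, i] <- graph$edges$weight[r]
  }
  best <- list(weight = Inf, path = NULL)
  recurse <- function(path, w) {
    u <- path[length(path)]
    if (u == dst) {
      if (w < best$weight - 1e-12) best <<- list(weight = w, path = path)
      return()
    }
    for (v in seq_len(n)) {
      if (is.finite(W[u, v]) && !(v %in% path)) recurse(c(path, v), w + W[u, v])
    }
  }
  recurse(src, 0)
  best
}

## PHE ring in the xy-plane with a LYS NZ 4 A along the ring normal
AROMATIC_RING_FIXTURE <- function() {
  ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  ang <- seq(0, 300, by = 60) * pi / 180
  rows <- do.call(rbind, lapply(seq_along(ring_names), function(i)
    atom_row("A", 10, ring_names[i], "C", 1.39 * cos(ang[i]),
             1.39 * sin(ang[i]), 0, resname = "PHE")))
  rows <- rbind(rows, atom_row("B", 20, "NZ", "N", 0, 0, 4, resname = "LYS"))
  list(model = StructureModel(rows), group_a = "B|20|", group_b = "A|10|")
}

## hand-computable 3-level joint distribution: the exact MI oracle
mi_oracle_table <- function() {
  matrix(c(30, 10, 0,
           10, 30, 10,
           0, 10, 20), 3, 3, byrow = TRUE)
}

mi_from_counts <- function(cts) {
  p <- cts / sum(cts)
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in 1:3) for (j in 1:3)
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  s
}

## angles that land exactly in bins 1..3 of a 3-bin circular histogram
angle_for_bin <- function(b) c(-120, 0, 120)[b]

series_from_counts <- function(cts) {
  xs <- ys <- numeric(0)
  for (i in 1:3) for (j in 1:3) {
    xs <- c(xs, rep(angle_for_bin(i), cts[i, j]))
    ys <- c(ys, rep(angle_for_bin(j), cts[i, j]))
  }
  list(x = xs, y = ys)
}
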