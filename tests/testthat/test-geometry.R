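test_that("kabsch recovers exact transforms and matches the brute-force oracle", {
  X <- frozen_points_a()
  ## identity
  s0 <- kabsch_superpose(X, X)
  expect_equal(s0$rmsd, 0, tolerance = 1e-12)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)
  ## known 90-degree rotation about z plus translation
  R <- gpcrdimer:::rotation_about_axis(c(0, 0, 1), pi / 2)
  Y <- sweep(X %*% t(R), 2, c(1, -2, 3), `+`)
  s1 <- kabsch_superpose(Y, X)
  expect_equal(s1$rmsd, 0, tolerance = 1e-9)
  expect_equal(apply_superposition(s1, Y), X, tolerance = 1e-9)
  ## frozen 5-point pair: agreement with rotation-search oracle to 1e-6
  A <- frozen_points_a(); B <- frozen_points_b()
  s2 <- kabsch_superpose(A, B)
  expect_gt(s2$rmsd, 0.1)  # non-trivial case
  expect_equal(s2$rmsd, brute_force_min_rmsd(A, B), tolerance = 1e-6)
  expect_equal(det(s2$rotation), 1, tolerance = 1e-9)
  ## errors
  expect_error(kabsch_superpose(A[1:4, ], B), class = "pairing_error")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line), class = "degenerate_geometry")
})

test_that("rmsd and displacement metrics are invariant under common rigid motions", {
  sp <- synthetic_spec(n_res = 20, transforms = list(
    list(segment = c(12, 20), translation = c(4, -2, 1), hinge_deg = 15)))
  d <- make_toy_dimer_states(sp)
  base_sup <- aligned_rmsd(d$state_a, d$state_b, "A")
  base_disp <- residue_displacement(d$state_a, d$state_b, "A",
                                    data.frame(protomer = "B", resno = 16))
  base_kink <- kink_angle(d$state_a, d$state_b, "B", c(12, 20), "A")
  set.seed(42)
  for (k in 1:5) {
    tr <- random_rigid_transform()
    a2 <- transform_model(d$state_a, tr$R, tr$t)
    b2 <- transform_model(d$state_b, tr$R, tr$t)
    expect_equal(aligned_rmsd(a2, b2, "A")$rmsd, base_sup$rmsd,
                 tolerance = 1e-9)
    expect_equal(residue_displacement(a2, b2, "A",
                                      data.frame(protomer = "B",
                                                 resno = 16))$displacement,
                 base_disp$displacement, tolerance = 1e-9)
    expect_equal(kink_angle(a2, b2, "B", c(12, 20), "A"), base_kink,
                 tolerance = 1e-6)
  }
})

test_that("common-calpha pairing uses the modelled intersection", {
  d <- make_toy_dimer_states(synthetic_spec(n_res = 30))$state_a
  p <- pair_common_calpha(d, d, "A")
  expect_equal(length(p$resno), 30L)
  ## drop 10 C-terminal residues from one copy
  d2 <- d
  d2$atoms <- d2$atoms[!(d2$atoms$chain == "R" & d2$atoms$resno > 20), ]
  p2 <- pair_common_calpha(d, d2, "A")
  expect_equal(p2$resno, 1:20)
  sup <- aligned_rmsd(d, d2, "A")
  expect_equal(sup$n_atoms, 20L)
  expect_equal(sup$rmsd, 0, tolerance = 1e-12)
  ## disjoint residue sets
  d3 <- d
  d3$atoms$resno <- d3$atoms$resno + 100L
  expect_error(pair_common_calpha(d, d3, "A"), class = "no_common_residues")
})

test_that("planted sub-segment displacements are recovered to 1e-6", {
  set.seed(7)
  for (k in 1:5) {
    tvec <- stats::rnorm(3)
    sp <- synthetic_spec(n_res = 25, transforms = list(
      list(segment = c(15, 25), translation = tvec)))
    d <- make_toy_dimer_states(sp)
    targ <- data.frame(protomer = "B", resno = c(10, 20))
    rep <- residue_displacement(d$state_a, d$state_b, "A", targ)
    expect_equal(rep$displacement[1], 0, tolerance = 1e-9)       # anchor region
    expect_equal(rep$displacement[2], sqrt(sum(tvec^2)), tolerance = 1e-6)
    ## ground-truth record agrees
    tr <- d$truth[[1]]$displacement
    expect_equal(rep$displacement[2],
                 tr$displacement[tr$resno == 20], tolerance = 1e-9)
  }
  ## unmodelled target flagged, not fatal
  sp <- synthetic_spec(n_res = 10)
  d <- make_toy_dimer_states(sp)
  rep <- residue_displacement(d$state_a, d$state_b, "A",
                              data.frame(protomer = "B", resno = c(5, 99)))
  expect_false(rep$missing[1])
  expect_true(rep$missing[2])
})

test_that("helix axis fitting is accurate and N->C oriented", {
  h <- make_ideal_helix(15)
  ax <- fit_helix_axis(assign_protomers(h, "A"), "A", c(1, 15))
  expect_equal(as.numeric(ax$direction), c(0, 0, 1), tolerance = 1e-3)
  ## rotated helix: axis rotates with it
  R <- gpcrdimer:::rotation_about_axis(c(1, 0, 0), pi / 6)
  h2 <- transform_model(assign_protomers(h, "A"), R, c(0, 0, 0))
  ax2 <- fit_helix_axis(h2, "A", c(1, 15))
  expect_equal(as.numeric(ax2$direction), as.numeric(R %*% c(0, 0, 1)),
               tolerance = 1e-3)
  ## noisy helix: within 5 degrees of true axis
  set.seed(11)
  hn <- assign_protomers(h, "A")
  nca <- sum(hn$atoms$atom == "CA")
  jit <- matrix(stats::rnorm(nrow(hn$atoms) * 3, sd = 0.3), ncol = 3)
  hn$atoms[, c("x", "y", "z")] <- hn$atoms[, c("x", "y", "z")] + jit
  axn <- fit_helix_axis(hn, "A", c(1, 15))
  ang <- acos(abs(sum(axn$direction * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 5)
  expect_error(fit_helix_axis(hn, "A", c(1, 3)), class = "degenerate_geometry")
})

test_that("kink angle recovers planted hinges; zero and symmetric", {
  sp <- synthetic_spec(n_res = 30, transforms = list(
    list(segment = c(18, 30), hinge_deg = 25)))
  d <- make_toy_dimer_states(sp)
  expect_equal(kink_angle(d$state_a, d$state_a, "B", c(18, 30), "A"), 0,
               tolerance = 1e-9)
  k_ab <- kink_angle(d$state_a, d$state_b, "B", c(18, 30), "A")
  k_ba <- kink_angle(d$state_b, d$state_a, "B", c(18, 30), "A")
  expect_equal(k_ab, 25, tolerance = 1e-3)
  expect_equal(k_ab, k_ba, tolerance = 1e-6)
})

test_that("axial rotation decomposes planted twists, alone and composed", {
  sp <- synthetic_spec(n_res = 30, transforms = list(
    list(segment = c(12, 30), axial_deg = 170)))
  d <- make_toy_dimer_states(sp)
  expect_equal(axial_rotation_angle(d$state_a, d$state_a, "B", c(12, 30)), 0,
               tolerance = 1e-9)
  expect_equal(axial_rotation_angle(d$state_a, d$state_b, "B", c(12, 30)),
               170, tolerance = 1e-3)
  ## composite: 60 axial + 10 hinge -> axial component 60 +- 2
  sp2 <- synthetic_spec(n_res = 30, transforms = list(
    list(segment = c(12, 30), axial_deg = 60, hinge_deg = 10)))
  d2 <- make_toy_dimer_states(sp2)
  expect_equal(axial_rotation_angle(d2$state_a, d2$state_b, "B", c(12, 30)),
               60, tolerance = 2 / 60)
})
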