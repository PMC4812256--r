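test_that("Kabsch superposition recovers exact rigid motions", {
  set.seed(1)
  ref <- matrix(stats::rnorm(30), 10, 3)
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  mobile <- sweep(ref %*% t(R), 2, c(1, -2, 0.5), "+")
  fit <- kabsch_fit(mobile, ref)
  expect_lt(fit$rmsd, 1e-10)
  expect_lt(max(abs(fit$transform(mobile) - ref)), 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  # translation-only offset: identity rotation
  fit2 <- kabsch_fit(sweep(ref, 2, c(3, 0, -1), "+"), ref)
  expect_lt(max(abs(fit2$rotation - diag(3))), 1e-10)
  expect_lt(fit2$rmsd, 1e-12)
  # degenerate inputs are rejected
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_fit(line, line), "degenerate|collinear")
  expect_error(kabsch_fit(ref[1:2, ], ref[1:2, ]), "3 points")
})

test_that("Kabsch RMSD matches a rotation-search oracle on perturbed point sets", {
  set.seed(21)
  for (i in 1:5) {
    P <- matrix(stats::rnorm(12), 4, 3)
    Q <- P
    Q[1, ] <- Q[1, ] + stats::rnorm(3, sd = 0.3)
    expect_lt(abs(kabsch_fit(P, Q)$rmsd - grid_rmsd_oracle(P, Q)), 1e-3)
  }
})

test_that("centre of mass honours the requested weighting", {
  top <- topology(elety = c("CA", "CA"), resno = c(1, 2))
  co <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(com(co, top, weighting = "mass"), c(1, 0, 0))
  # masses 1 and 3 at x = 0 and x = 4 -> x = 3
  top13 <- topology(elety = c("X1", "X2"), resno = c(1, 2),
                    element = c("C", "C"), mass = c(1, 3))
  expect_equal(com(rbind(c(0, 0, 0), c(4, 0, 0)), top13)[1], 3)
  # heteroatomic C/O pair: mass-weighted differs from geometric by the
  # mass-fraction shift
  co2 <- rbind(c(0, 0, 0), c(1, 0, 0))
  topCO <- topology(elety = c("C", "O"), resno = c(1, 2))
  mO <- topCO$mass[2]; mC <- topCO$mass[1]
  expect_equal(com(co2, topCO, weighting = "mass")[1], mO / (mC + mO))
  expect_equal(com(co2, topCO, weighting = "geometric")[1], 0.5)
  expect_error(com(co2, topCO, sel = integer(0)), "empty")
})

test_that("COM cloud is exact on identity ensembles and invariant to global rigid motion", {
  ref <- make_toy_structure(toy_architecture(10, 10, 5, 15))
  r <- ref$arch$ranges
  fit_sel <- select_atoms(ref$topology, c(1, r$lobe_b[2]), "CA")
  com_sel <- select_atoms(ref$topology, r$appended, "all")
  ident <- traj_from_coords(ref$topology,
                            replicate(5, frame_coords(ref, 1),
                                      simplify = FALSE))
  cloud <- com_cloud(ident, fit_sel, com_sel, ref)
  expect_lt(max(abs(sweep(cloud$points, 2, cloud$reference))), 1e-12)
  # rigid motion of every frame leaves the fitted cloud unchanged
  mx <- state_mixture(list(list(), list(translation = c(1.5, 0, 0))),
                      c(0.5, 0.5))
  sim <- simulate_hinge_trajectory(ref, mx, noise_model(0.02, 0.04, 3), 40)
  set.seed(8)
  moved <- apply_rigid_motion(sim$trajectory, random_rotation(), c(5, -3, 2))
  c1 <- com_cloud(sim$trajectory, fit_sel, com_sel, ref)
  c2 <- com_cloud(moved, fit_sel, com_sel, ref)
  expect_lt(max(abs(c1$points - c2$points)), 1e-6)
})

test_that("distance-from-start distribution recovers planted offsets", {
  ref <- make_toy_structure(toy_architecture(10, 10, 5, 15))
  r <- ref$arch$ranges
  fit_sel <- select_atoms(ref$topology, c(1, r$lobe_b[2]), "CA")
  com_sel <- select_atoms(ref$topology, r$appended, "all")
  ident <- traj_from_coords(ref$topology,
                            replicate(4, frame_coords(ref, 1),
                                      simplify = FALSE))
  d0 <- distance_from_start(com_cloud(ident, fit_sel, com_sel, ref))
  expect_equal(d0$mean, 0)
  expect_equal(d0$peak, 0)
  expect_equal(sum(d0$counts), 4)
  # single planted offset of 1.5 nm = 15 Angstrom at near-zero noise
  off <- state_mixture(list(list(translation = c(0, 1.5, 0))))
  sim <- simulate_hinge_trajectory(ref, off, noise_model(1e-4, 1e-4, 2), 200)
  d15 <- distance_from_start(com_cloud(sim$trajectory, fit_sel, com_sel, ref))
  expect_lt(abs(d15$mean - 15), 0.5)
  # 0.5/0.5 mixture of offsets 0 and 20 Angstrom: mean near 10
  mx <- state_mixture(list(list(), list(translation = c(2, 0, 0))),
                      c(0.5, 0.5))
  simm <- simulate_hinge_trajectory(ref, mx, noise_model(1e-3, 1e-3, 7), 1000)
  dmix <- distance_from_start(com_cloud(simm$trajectory, fit_sel, com_sel, ref))
  expect_lt(abs(dmix$mean - 10), 3 * 10 * sqrt(0.25 / 1000) + 0.5)
})

test_that("pair distance distribution peaks follow exhaustive pair counting", {
  # all points identical: single bin at zero
  same <- matrix(1, 5, 3)
  p0 <- pair_distance_distribution(same)
  expect_equal(p0$peak, 0)
  expect_equal(sum(p0$counts), choose(5, 2))
  # equilateral triangle with 1 nm sides: all three pair distances 10 A
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  pt <- pair_distance_distribution(tri)
  expect_equal(pt$peak, 10)
  expect_equal(sum(pt$counts), 3)
  # two tight blobs 20 A apart: the peak follows max(p^2 + (1-p)^2, 2p(1-p))
  set.seed(13)
  for (p in c(0.8, 0.5)) {
    n <- 400
    z <- stats::rbinom(n, 1, p)
    pts <- cbind(2 * z + stats::rnorm(n, sd = 0.01),
                 stats::rnorm(n, sd = 0.01), stats::rnorm(n, sd = 0.01))
    pd <- pair_distance_distribution(pts)
    # independent brute-force enumeration of the same point set
    same_blob <- sum(choose(table(z), 2))
    cross_blob <- prod(table(z))
    expected_peak <- if (same_blob > cross_blob) 0 else 20
    expect_equal(pd$peak, expected_peak)
  }
})

test_that("residue pair distances honour the atom rule", {
  top <- topology(elety = c("N", "CA", "C", "N", "CA", "C"),
                  resno = c(1, 1, 1, 2, 2, 2))
  co <- rbind(c(0, 0.2, 0), c(0, 0, 0), c(0.1, -0.1, 0),
              c(0.9, 0.1, 0), c(1, 0, 0), c(1.2, 0, 0))
  trj <- traj_from_coords(top, list(co, co))
  ca <- residue_pair_distance_series(trj, 1, 2, "CA")
  expect_equal(ca$distance, c(10, 10))
  expect_equal(ca$mean, mean(ca$distance))
  ch <- residue_pair_distance_series(trj, 1, 2, "closest-heavy")
  # closest heavy pair is C(1) at (0.1,-0.1,0) vs N(2) at (0.9,0.1,0)
  expect_equal(ch$mean, 10 * sqrt(0.8^2 + 0.2^2), tolerance = 1e-10)
  expect_lt(ch$mean, ca$mean)
})

test_that("dihedral series follow the sign convention and circular statistics", {
  top <- topology(elety = rep("CA", 4), resno = 1:4)
  trans <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  trj <- traj_from_coords(top, list(trans))
  expect_equal(abs(dihedral_series(trj, 1:4)$angles), 180)
  twist <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 1))
  ds <- dihedral_series(traj_from_coords(top, list(twist)), 1:4)
  expect_equal(abs(ds$angles), 90)
  expect_equal(ds$angles, dihedral_oracle(twist), tolerance = 1e-9)
  # random quadruples agree with the independent implementation
  set.seed(31)
  for (i in 1:10) {
    q <- matrix(stats::rnorm(12), 4, 3)
    got <- dihedral_series(traj_from_coords(top, list(q)), 1:4)$angles
    expect_equal(got, dihedral_oracle(q), tolerance = 1e-9)
  }
  # wrap-around circular mean
  expect_equal(circular_mean(c(170, -170)), 180)
  expect_equal(circular_mean(c(10, 20)), 15, tolerance = 1e-10)
  expect_lt(circular_variance(c(10, 10)), 1e-12)
  # collinear triple: NA with warning
  line <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_warning(dd <- dihedral_series(traj_from_coords(top, list(line)), 1:4),
                 "collinear")
  expect_true(is.na(dd$angles))
})

test_that("circular mean of wrapped-normal samples recovers the planted location", {
  set.seed(17)
  for (mu in c(103, 42, -170)) {
    ang <- mu + stats::rnorm(2000, sd = 20)
    ang <- ((ang + 180) %% 360) - 180
    got <- circular_mean(ang)
    diff <- ((got - mu + 180) %% 360) - 180
    expect_lt(abs(diff), 3 * 20 / sqrt(2000))
  }
})

test_that("RMSD series vanish for rigid copies and check pairwise lengths", {
  ref <- make_toy_structure(toy_architecture(6, 6, 3, 8))
  sel <- select_atoms(ref$topology, c(1, 23), "CA")
  ident <- traj_from_coords(ref$topology,
                            replicate(3, frame_coords(ref, 1),
                                      simplify = FALSE))
  expect_equal(rmsd_series(ident, ref, sel), rep(0, 3), tolerance = 1e-12)
  set.seed(4)
  rot <- rigid_motion_traj(ref, 3)
  expect_lt(max(rmsd_series(rot, ref, sel)), 1e-9)
  # perturbed frame agrees with the rotation-search oracle
  top4 <- ca_topology(4)
  P <- matrix(stats::rnorm(12), 4, 3)
  Q <- P; Q[2, ] <- Q[2, ] + c(0.2, -0.1, 0.15)
  tp <- traj_from_coords(top4, list(P))
  expect_lt(abs(rmsd_series(tp, Q, NULL)[1] - grid_rmsd_oracle(P, Q)), 1e-3)
  expect_error(rmsd_series(rot, subset_frames(rot, 1:2), sel), "matched")
})
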