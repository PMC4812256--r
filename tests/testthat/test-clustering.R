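test_that("RMSD matrices honour fit semantics and match a pairwise Kabsch oracle", {
  ref <- make_toy_structure(toy_architecture(6, 6, 3, 8))
  sel <- select_atoms(ref$topology, c(1, 23), "CA")
  ident <- traj_from_coords(ref$topology,
                            replicate(4, frame_coords(ref, 1),
                                      simplify = FALSE))
  expect_lt(max(rmsd_matrix(ident, sel)), 1e-12)
  # a rigidly rotated frame: zero with fitting, nonzero without
  set.seed(2)
  co <- frame_coords(ref, 1)
  rot <- sweep(co %*% t(random_rotation()), 2, c(1, 1, 1), "+")
  two <- traj_from_coords(ref$topology, list(co, rot))
  expect_lt(rmsd_matrix(two, sel, fit = TRUE)[1, 2], 1e-9)
  expect_gt(rmsd_matrix(two, sel, fit = FALSE)[1, 2], 0.1)
  # 5 arbitrary frames: entry-by-entry agreement with direct kabsch_fit calls
  frames <- lapply(1:5, function(i) co + matrix(stats::rnorm(length(co),
                                                             sd = 0.1),
                                                ncol = 3))
  trj5 <- traj_from_coords(ref$topology, frames)
  m <- rmsd_matrix(trj5, sel, fit = TRUE)
  idx <- as.integer(sel)
  for (i in 1:4) for (j in (i + 1):5) {
    direct <- kabsch_fit(frames[[i]][idx, ], frames[[j]][idx, ])$rmsd
    expect_equal(m[i, j], direct, tolerance = 1e-10)
  }
  expect_equal(unclass(m), t(unclass(m)))
  expect_equal(diag(m), rep(0, 5))
})

test_that("gromos clustering handles degenerate and block-structured matrices", {
  # everything mutually close: one cluster seeded at the lowest index
  m1 <- matrix(0.1, 7, 7); diag(m1) <- 0
  cl1 <- gromos_cluster(m1, 0.35)
  expect_equal(length(cl1$populations), 1)
  expect_equal(cl1$populations, 1)
  expect_equal(cl1$seeds, 1)  # full tie broken by lowest frame index
  # two blobs of 6 and 4 frames
  m2 <- matrix(1, 10, 10)
  m2[1:6, 1:6] <- 0.1; m2[7:10, 7:10] <- 0.1; diag(m2) <- 0
  cl2 <- gromos_cluster(m2, 0.35)
  expect_equal(cl2$populations, c(0.6, 0.4))
  expect_equal(sort(unique(cl2$assignment[1:6])), 1)
  expect_equal(sort(unique(cl2$assignment[7:10])), 2)
})

test_that("gromos clustering agrees exactly with the brute-force oracle", {
  for (seed in 1:20) {
    n <- 4 + seed %% 7
    m <- random_rmsd_matrix(n, seed)
    got <- gromos_cluster(m, 0.5)
    ora <- gromos_oracle(m, 0.5)
    expect_identical(got$assignment, ora$assignment)
    expect_identical(got$centers, ora$centers)
    expect_equal(got$populations, ora$populations)
  }
})

test_that("cluster count never increases with the cutoff and output is a partition", {
  for (seed in 1:10) {
    m <- random_rmsd_matrix(12, seed + 100)
    counts <- vapply(c(0.1, 0.2, 0.35, 0.5, 0.8),
                     function(cc) length(gromos_cluster(m, cc)$populations),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
    cl <- gromos_cluster(m, 0.35)
    expect_true(all(cl$assignment >= 1))
    expect_equal(sum(cl$populations), 1)
    expect_true(all(diff(cl$populations) <= 0))
  }
})

test_that("label decomposition recovers planted state-label designs", {
  ref <- make_toy_structure(toy_architecture(8, 8, 4, 10))
  sel <- select_atoms(ref$topology, c(1, 30), "CA")
  mk <- function(state, tag) {
    mx <- state_mixture(list(list(translation = c(2 * (state - 1), 0, 0))))
    sim <- simulate_hinge_trajectory(ref, mx, noise_model(0, 0, state), 50,
                                     dt = 1,
                                     label = provenance_label(tag,
                                                              c(NBD = tag)))
    sim$trajectory
  }
  meta <- build_meta(list(mk(1, "A"), mk(2, "B")), 0.05)
  cl <- gromos_cluster(rmsd_matrix(meta, sel), 0.35)
  expect_equal(cl$populations, c(0.5, 0.5))
  dec <- decompose_by_label(cl, meta, top_k = 2)
  expect_equal(unname(unclass(dec)[, 1:2]), diag(2))
  expect_true(all(abs(rowSums(unclass(dec)) - 1) < 1e-12))
  # single label: decomposition equals overall populations
  meta1 <- build_meta(list(mk(1, "A")), 0.05)
  cl1 <- gromos_cluster(rmsd_matrix(meta1, sel), 0.35)
  dec1 <- decompose_by_label(cl1, meta1, top_k = 1)
  expect_equal(unname(unclass(dec1)[1, 1]), cl1$populations[1])
  expect_warning(decompose_by_label(cl, meta, top_k = 10), "clamped")
})

test_that("shuffled labels collapse the decomposition to overall populations", {
  ref <- make_toy_structure(toy_architecture(8, 8, 4, 10))
  sel <- select_atoms(ref$topology, c(1, 30), "CA")
  mx <- state_mixture(list(list(), list(translation = c(2, 0, 0))),
                      c(0.5, 0.5))
  sim <- simulate_hinge_trajectory(ref, mx, noise_model(0.01, 0.01, 6), 200)
  cl <- gromos_cluster(rmsd_matrix(sim$trajectory, sel), 0.35)
  set.seed(99)
  labels <- sample(rep(c("A", "B"), each = 100))
  dec <- decompose_by_label(cl, labels, top_k = length(cl$populations))
  for (lab in c("A", "B")) {
    cnt <- round(unclass(dec)[lab, seq_along(cl$populations)] * 100)
    p <- stats::chisq.test(cnt, p = cl$populations)$p.value
    expect_gt(p, 0.01)
  }
})

test_that("representatives are the medoids of their clusters", {
  # singleton and declared-centre cases
  m <- matrix(1, 3, 3); m[1, 2] <- m[2, 1] <- 0.1; diag(m) <- 0
  cl <- gromos_cluster(m, 0.2)
  expect_equal(cl$populations, c(2 / 3, 1 / 3))
  expect_equal(cl$centers[2], 3)
  # medoid minimises the summed RMSD to members, checked exhaustively
  for (seed in 1:10) {
    mm <- random_rmsd_matrix(6, seed + 500)
    clr <- gromos_cluster(mm, 0.45)
    for (k in seq_along(clr$populations)) {
      grp <- which(clr$assignment == k)
      sums <- vapply(grp, function(i) sum(mm[i, grp]), numeric(1))
      expect_equal(clr$centers[k], grp[which.min(sums)])
    }
  }
  # extraction round trip
  ref <- make_toy_structure(toy_architecture(5, 5, 3, 6))
  trj <- traj_from_coords(ref$topology,
                          replicate(3, frame_coords(ref, 1),
                                    simplify = FALSE))
  clx <- gromos_cluster(rmsd_matrix(trj, NULL), 0.35)
  rep1 <- representative(clx, 1, trj)
  expect_equal(rep1$xyz[1, ], trj$xyz[clx$centers[1], ])
  expect_error(representative(clx, 5, trj), "no such cluster")
})
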