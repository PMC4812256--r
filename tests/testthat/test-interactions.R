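# two single-atom residues at a controlled separation (nm)
two_res_traj <- function(gaps) {
  top <- topology(elety = c("CB", "CB"), resno = c(1, 2))
  traj_from_coords(top, lapply(gaps, function(g)
    rbind(c(0, 0, 0), c(g, 0, 0))))
}

test_that("contacts follow the minimum heavy-atom distance criterion", {
  expect_true(contact_series(two_res_traj(0.40), 1, 2, 0.45)$present[1, 1])
  expect_false(contact_series(two_res_traj(0.50), 1, 2, 0.45)$present[1, 1])
  # hydrogens are excluded from the minimum
  toph <- topology(elety = c("CB", "HB", "CB"), resno = c(1, 1, 2))
  co <- rbind(c(0, 0, 0), c(0.3, 0, 0), c(0.6, 0, 0))
  trjh <- traj_from_coords(toph, list(co))
  expect_false(contact_series(trjh, 1, 2, 0.45)$present[1, 1])  # C-C 0.6 nm
  expect_error(contact_series(trjh, 1, 1, 0.45), "disjoint")
  # constructed 10-frame series against a per-frame brute-force oracle
  set.seed(5)
  gaps <- ifelse(1:10 %in% c(1, 3, 5), 0.40, 0.55)
  trj <- two_res_traj(gaps)
  cs <- contact_series(trj, 1, 2, 0.45)
  oracle <- vapply(seq_len(10), function(f) {
    co <- frame_coords(trj, f)
    sqrt(sum((co[1, ] - co[2, ])^2)) <= 0.45
  }, logical(1))
  expect_equal(cs$present[, 1], oracle)
  expect_equal(which(cs$present[, 1]), c(1L, 3L, 5L))
})

test_that("hydrogen bonds require distance and, when hydrogens exist, angle", {
  mk_hb <- function(angle_deg, d = 0.28) {
    top <- topology(elety = c("N", "H", "O"), resno = c(1, 1, 2))
    th <- angle_deg * pi / 180
    co <- rbind(c(0, 0, 0),
                0.10 * c(cos(th), sin(th), 0),
                c(d, 0, 0))
    traj_from_coords(top, list(co))
  }
  expect_true(hbond_series(mk_hb(5), 1, 2)$present[1, 1])
  expect_false(hbond_series(mk_hb(60), 1, 2)$present[1, 1])
  expect_false(hbond_series(mk_hb(5, d = 0.4), 1, 2)$present[1, 1])
  expect_false(attr(hbond_series(mk_hb(5), 1, 2), "hydrogen_free"))
  # hydrogen-free fallback: distance criterion only, flagged
  topnf <- topology(elety = c("N", "O"), resno = c(1, 2))
  trjnf <- traj_from_coords(topnf, list(rbind(c(0, 0, 0), c(0.3, 0, 0))))
  hnf <- hbond_series(trjnf, 1, 2)
  expect_true(hnf$present[1, 1])
  expect_true(attr(hnf, "hydrogen_free"))
  expect_error(hbond_series(two_res_traj(0.3), 1, 2), "donor")
})

test_that("every hydrogen bond is also a contact at a matched cutoff", {
  ref <- make_toy_structure(toy_architecture(8, 8, 4, 10), backbone = TRUE)
  sim <- simulate_hinge_trajectory(ref, state_mixture(list(list())),
                                   noise_model(0.02, 0.03, 7), 50)
  pl <- plant_interaction(sim$trajectory, 4, 26, 0.5, seed = 2)
  hb <- hbond_series(pl$trajectory, 4, 26)
  ct <- contact_series(pl$trajectory, 4, 26, cutoff = 0.45)
  expect_true(all(!hb$present | ct$present))
})

test_that("the persistence filter keeps records at or above the threshold with exact occupancy", {
  gaps <- c(rep(0.3, 4), rep(0.8, 6))        # occupancy 0.4
  s40 <- contact_series(two_res_traj(gaps), 1, 2, 0.45)
  kept <- persistence_filter(s40, 0.30)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$occupancy, 0.4)
  s20 <- contact_series(two_res_traj(c(rep(0.3, 2), rep(0.8, 8))), 1, 2, 0.45)
  expect_equal(nrow(persistence_filter(s20, 0.30)), 0)
  # threshold zero keeps pairs present in at least one frame, not absent ones
  s0 <- contact_series(two_res_traj(rep(0.8, 10)), 1, 2, 0.45)
  expect_equal(nrow(persistence_filter(list(s20, s0), 0)), 1)
  expect_equal(persistence_filter(list(s20, s0), 0)$occupancy, 0.2)
})

test_that("interface maps use time-averaged minimum distances", {
  # 4 single-atom residues: only pair (1,3) within 6 A
  top <- topology(elety = rep("CB", 4), resno = 1:4)
  co <- rbind(c(0, 0, 0), c(0, 3, 0), c(0.5, 0, 0), c(3, 3, 0))
  trj <- traj_from_coords(top, list(co))
  im <- interface_map(trj, c(1, 2), c(3, 4), threshold = 6)
  expect_equal(im$residues_a, 1)
  expect_equal(im$residues_b, 3)
  expect_equal(im$matrix["1", "3"], 5)
  # all pairs beyond the threshold: empty interface
  far <- traj_from_coords(top, list(co * 10))
  imf <- interface_map(far, c(1, 2), c(3, 4), threshold = 6)
  expect_length(imf$residues_a, 0)
  # average semantics: frames at 4 and 10 A average to 7 -> excluded
  trj2 <- traj_from_coords(topology(elety = c("CB", "CB"), resno = 1:2),
                           list(rbind(c(0, 0, 0), c(0.4, 0, 0)),
                                rbind(c(0, 0, 0), c(1.0, 0, 0))))
  im2 <- interface_map(trj2, 1, 2, threshold = 6)
  expect_equal(im2$matrix[1, 1], 7)
  expect_length(im2$residues_a, 0)
  # the per-frame-fraction mode lists the same pair (below threshold half the time)
  im3 <- interface_map(trj2, 1, 2, threshold = 6, mode = "fraction")
  expect_equal(im3$matrix[1, 1], 0.5)
  expect_equal(im3$residues_a, 1)
  # role symmetry: swapping the groups transposes the interface
  im_sw <- interface_map(trj, c(3, 4), c(1, 2), threshold = 6)
  expect_equal(im_sw$residues_a, 3)
  expect_equal(im_sw$residues_b, 1)
  expect_equal(t(im_sw$matrix), im$matrix, ignore_attr = TRUE)
})

test_that("strand content separates ideal hairpins from helices", {
  ref <- make_toy_structure(toy_architecture(8, 8, 6, 14), backbone = TRUE)
  sim <- simulate_hinge_trajectory(ref, state_mixture(list(list())),
                                   noise_model(0.01, 0.02, 3), 20)
  rng <- c(17, 22)
  hairpin <- plant_strand_segment(sim$trajectory, rng, fraction = 1, seed = 1)
  expect_equal(strand_content(hairpin$trajectory, rng)$content, 1)
  helix <- plant_strand_segment(sim$trajectory, rng, fraction = 0, seed = 1)
  expect_equal(strand_content(helix$trajectory, rng)$content, 0)
  mixed <- plant_strand_segment(sim$trajectory, rng, fraction = 0.3, seed = 4)
  sc <- strand_content(mixed$trajectory, rng)
  expect_equal(sc$content, 0.3)
  # per-frame flags match the planted frames for every residue of the range
  expect_equal(which(rowSums(sc$per_frame) == 6), mixed$planted_frames)
  expect_error(strand_content(sim$trajectory, c(1, 3), min_sep = 5),
               NA)  # plain ranges with backbone succeed
})
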