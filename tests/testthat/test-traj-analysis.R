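make_two_state_traj <- function(n = 400, noise = 0.3, occ = c(0.7, 0.3),
                                sep = 5, seed = 31, p = 8) {
  states <- make_conformer_states(p = p, k = 2, sep = sep, seed = seed)
  plant_conformations(n, states, noise_sd = noise, occupancies = occ,
                      seed = seed)
}

test_that("distance time courses are exact on fixed geometries", {
  coords <- array(0, dim = c(3, 2, 3))
  coords[, 2, 1] <- 3; coords[, 2, 2] <- 4
  tr <- new_trajectory(coords)
  d <- distance_timecourse(tr, 1, 2)
  expect_equal(d$distance, rep(5, 3))
  coords2 <- coords; coords2[, 2, ] <- 0
  expect_equal(distance_timecourse(new_trajectory(coords2), 1, 2)$distance,
               rep(0, 3))
  expect_error(distance_timecourse(tr, 1:2, 1), "exactly one")
})

test_that("planted contact gives a bimodal distance histogram at the planted values", {
  p <- 4
  base <- matrix(c(0, 0, 0, 2, 0, 0, 8, 0, 0, 12, 0, 0), p, 3, byrow = TRUE)
  apart <- base; apart[2, 1] <- 7 # contact broken in state 2
  tr <- plant_conformations(2000, list(base, apart), noise_sd = 0.1,
                            occupancies = c(0.5, 0.5), seed = 8)
  d <- distance_timecourse(tr, 1, 2)$distance
  lab <- tr$metadata$labels
  expect_equal(mean(d[lab == 1]), 2, tolerance = 0.05)
  expect_equal(mean(d[lab == 2]), 7, tolerance = 0.05)
})

test_that("RMSD to the first frame is zero and superposition removes rigid motion", {
  tr <- make_two_state_traj(n = 30, noise = 0.2, seed = 5)
  ref <- frame_coords(tr, 1)
  r <- rmsd_timecourse(tr, ref, superpose = TRUE)
  expect_equal(r$rmsd[1], 0, tolerance = 1e-9)
  # rigid-body rotated + translated copy of the reference
  Q <- rotation_matrix(c(1, 2, 3), 35)
  moved <- ref %*% t(Q)
  moved <- sweep(moved, 2, c(4, -2, 7), "+")
  coords <- array(0, dim = c(2, nrow(ref), 3))
  coords[1, , ] <- ref; coords[2, , ] <- moved
  tr2 <- new_trajectory(coords)
  r2 <- rmsd_timecourse(tr2, ref, superpose = TRUE)
  expect_lt(r2$rmsd[2], 1e-8)
  # translated copy without superposition reports the shift
  coords[2, , ] <- sweep(ref, 2, c(1, 0, 0), "+")
  tr3 <- new_trajectory(coords)
  expect_equal(rmsd_timecourse(tr3, ref, superpose = FALSE)$rmsd[2], 1)
})

test_that("superposed RMSD never exceeds unsuperposed RMSD frame-wise", {
  tr <- make_two_state_traj(n = 50, noise = 0.4, seed = 6)
  ref <- frame_coords(tr, 1)
  a <- rmsd_timecourse(tr, ref, superpose = TRUE)$rmsd
  b <- rmsd_timecourse(tr, ref, superpose = FALSE)$rmsd
  expect_true(all(a <= b + 1e-9))
})

test_that("frozen trajectories have zero RMSF everywhere", {
  tmpl <- matrix(rnorm(18), 6, 3)
  tr <- plant_conformations(10, list(tmpl), noise_sd = 0, seed = 1)
  expect_equal(rmsf(tr)$rmsf, rep(0, 6), tolerance = 1e-10)
  expect_error(rmsf(plant_conformations(1, list(tmpl), seed = 1)), "2 frames")
})

test_that("an isotropically jittered particle shows RMSF = sigma * sqrt(3)", {
  set.seed(12)
  p <- 5; n <- 10000; sigma <- 0.5
  base <- matrix(rnorm(p * 3, sd = 4), p, 3)
  coords <- array(rep(base, each = n), dim = c(n, p, 3))
  coords[, p, ] <- coords[, p, ] + matrix(rnorm(n * 3, sd = sigma), n, 3)
  tr <- new_trajectory(coords)
  r <- rmsf(tr, reference = base, selection = 1:(p - 1))
  expect_equal(r$rmsf[p], sigma * sqrt(3), tolerance = 0.05)
  expect_lt(max(r$rmsf[1:(p - 1)]), 1e-9)
})

test_that("RMSF is invariant to a global rigid-body motion of every frame", {
  tr <- make_two_state_traj(n = 40, noise = 0.25, seed = 13)
  r0 <- rmsf(tr)
  Q <- rotation_matrix(c(0, 0, 1), 60)
  coords <- tr$coords
  for (f in seq_len(n_frames(tr))) {
    coords[f, , ] <- sweep(frame_coords(tr, f) %*% t(Q), 2, c(10, -5, 2), "+")
  }
  r1 <- rmsf(new_trajectory(coords))
  expect_equal(r1$rmsf, r0$rmsf, tolerance = 1e-8)
})

test_that("RMSF difference profiles carry the A minus B sign convention", {
  quiet <- make_two_state_traj(n = 60, noise = 0.1, seed = 14)
  mobile <- make_two_state_traj(n = 60, noise = 0.5, seed = 15)
  d <- rmsf_difference(mobile, quiet)
  expect_equal(d$d_rmsf, d$rmsf_a - d$rmsf_b)
  expect_gt(mean(d$d_rmsf), 0)
})

test_that("identical frames collapse to one cluster; huge cutoffs do too", {
  tmpl <- matrix(rnorm(24), 8, 3)
  tr <- plant_conformations(15, list(tmpl), noise_sd = 0, seed = 2)
  cs <- cluster_frames(tr, cutoff = 2)
  expect_equal(nrow(cs$medoids), 1)
  tr2 <- make_two_state_traj(n = 40, seed = 16)
  cs2 <- cluster_frames(tr2, cutoff = 1e4)
  expect_equal(nrow(cs2$medoids), 1)
})

test_that("planted two-state trajectories are recovered at the 2 A cutoff with binomial cluster sizes", {
  tr <- make_two_state_traj(n = 1000, noise = 0.3, occ = c(0.7, 0.3),
                            sep = 5, seed = 17)
  cs <- cluster_frames(tr, cutoff = 2.0)
  expect_equal(nrow(cs$medoids), 2)
  agree <- label_agreement(tr$metadata$labels, cs$labels)
  expect_gte(agree, 0.99)
  # cluster sizes within 3 sigma of the binomial expectation
  n1 <- sum(tr$metadata$labels == 1)
  expect_lt(abs(n1 - 700), 3 * sqrt(1000 * 0.7 * 0.3))
  expect_lt(abs(max(cs$medoids$size) - n1), 11) # <= 1% mislabels
})

test_that("clustering is invariant to frame permutation up to label renaming", {
  tr <- make_two_state_traj(n = 120, seed = 18)
  cs <- cluster_frames(tr, cutoff = 2)
  set.seed(19)
  perm <- sample(n_frames(tr))
  tr2 <- new_trajectory(tr$coords[perm, , , drop = FALSE])
  cs2 <- cluster_frames(tr2, cutoff = 2)
  expect_equal(label_agreement(cs$labels[perm], cs2$labels), 1)
})

test_that("cluster medoids minimise the mean RMSD to their own cluster", {
  tr <- make_two_state_traj(n = 80, seed = 20)
  cs <- cluster_frames(tr, cutoff = 2)
  D <- gamdr:::pairwise_rmsd(tr, NULL)
  for (k in cs$medoids$cluster) {
    members <- which(cs$labels == k)
    means <- rowMeans(D[members, members, drop = FALSE])
    expect_equal(min(means),
                 means[match(cs$medoids$frame[k], members)],
                 tolerance = 1e-12)
  }
})

test_that("within-radius selections are resolved once on the stated frame", {
  coords <- matrix(c(0, 0, 0, 3, 0, 0, 10, 0, 0), 3, 3, byrow = TRUE)
  sel <- select_within(coords, group = 1, radius = 4)
  expect_equal(sel, 2L)
  expect_equal(select_within(coords, 1, 4, include_group = TRUE), c(1L, 2L))
  expect_error(select_within(coords, 3, 0.5), "no particles")
})

test_that("centre-of-mass group distances reduce groups to centroids", {
  coords <- array(0, dim = c(2, 4, 3))
  coords[, 2, 1] <- 2 # group A = {1, 2}, centroid x = 1
  coords[, 3, 1] <- 7; coords[, 4, 1] <- 9 # group B centroid x = 8
  tr <- new_trajectory(coords)
  d <- com_distance_timecourse(tr, 1:2, 3:4)
  expect_equal(d$distance, rep(7, 2))
})
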