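test_that("symmetric double well has minima at +/-sep/2 and the stated barrier", {
  dw <- make_double_well(6, 4)
  expect_equal(dw$minima$x, c(-2, 2), tolerance = 1e-8)
  expect_equal(dw$minima$energy, c(0, 0), tolerance = 1e-10)
  expect_equal(potential_energy(dw, 0) - potential_energy(dw, 2), 6,
               tolerance = 1e-8)
})

test_that("double-well coefficients verified at stationary points found by an independent root-finder", {
  dw <- make_double_well(5, 4)
  # oracle: bracketed local optimisation, independent of polyroot
  left <- stats::optimize(function(x) potential_energy(dw, x), c(-4, -0.5))
  right <- stats::optimize(function(x) potential_energy(dw, x), c(0.5, 4))
  top <- stats::optimize(function(x) -potential_energy(dw, x), c(-1.5, 1.5))
  expect_equal(right$minimum - left$minimum, 4, tolerance = 1e-5)
  expect_equal(-top$objective - min(left$objective, right$objective), 5,
               tolerance = 1e-7)
})

test_that("asymmetric double well realises the well-depth difference at T -> 0", {
  dw <- make_double_well(6, 4, asymmetry = 2)
  expect_equal(diff(range(dw$minima$energy)), 2, tolerance = 1e-6)
  # right-hand well is the global minimum and the zero of energy
  expect_equal(min(dw$minima$energy), 0, tolerance = 1e-9)
  expect_lt(dw$minima$x[which.min(dw$minima$energy)] * -1, 0)
  # separation and barrier preserved
  expect_equal(diff(dw$minima$x), 4, tolerance = 1e-6)
  top <- potential_energy(dw, dw$params$barrier_top)
  expect_equal(top - min(dw$minima$energy), 6, tolerance = 1e-6)
})

test_that("invalid double-well arguments are rejected", {
  expect_error(make_double_well(-1, 4), "barrier")
  expect_error(make_double_well(6, 0), "separation")
  expect_error(make_double_well(6, 4, asymmetry = 7), "asymmetry")
})

test_that("named minima of analytic potentials are true stationary points", {
  for (spec in list(make_double_well(6, 4), make_double_well(8, 5, 1.5),
                    make_harmonic_well(2),
                    make_wells_2d(rbind(c(-3, -3), c(3, 3)), c(4, 5)))) {
    g <- potential_gradient(spec,
                            as.matrix(spec$minima[, seq_len(spec$dimensionality)]))
    expect_lt(max(abs(g)), 1e-6)
  }
})

test_that("bead chains have n_beads - 3 torsions and validate n_beads", {
  expect_equal(nrow(make_bead_chain(4)$torsions), 1)
  expect_equal(nrow(make_bead_chain(6)$torsions), 3)
  expect_error(make_bead_chain(3), "n_beads")
})

test_that("torsional energy matches direct cosine-series evaluation", {
  bs <- make_bead_chain(6, torsion_barrier = 3)
  xyz <- bead_start_coords(bs)
  # all-trans: every torsion at 180 deg, term-by-term oracle
  oracle <- sum(bs$torsions$amp * (1 + cos(bs$torsions$per * pi)))
  expect_equal(bead_energy(bs, xyz)$torsional, oracle, tolerance = 1e-12)
  expect_equal(oracle, 0)
  # perturbed geometry: evaluate each torsion angle directly
  set.seed(42)
  xyz2 <- xyz + matrix(rnorm(length(xyz), sd = 0.15), nrow(xyz), 3)
  phis <- vapply(seq_len(nrow(bs$torsions)), function(t) {
    gamdr:::bead_dihedral(xyz2, bs$torsions$i[t], bs$torsions$j[t],
                          bs$torsions$k[t], bs$torsions$l[t])
  }, numeric(1))
  oracle2 <- sum(bs$torsions$amp * (1 + cos(bs$torsions$per * phis)))
  expect_equal(bead_energy(bs, xyz2)$torsional, oracle2, tolerance = 1e-12)
})

test_that("zero-barrier chains have identically zero torsional energy", {
  bs <- make_bead_chain(4, torsion_barrier = 0)
  set.seed(7)
  for (i in 1:5) {
    xyz <- bead_start_coords(bs) + matrix(rnorm(12, sd = 0.3), 4, 3)
    expect_identical(bead_energy(bs, xyz)$torsional, 0)
  }
})

test_that("torsional plus non-torsional energy equals total to machine precision", {
  bs <- make_bead_chain(7, torsion_barrier = 2.5)
  set.seed(11)
  for (i in 1:10) {
    xyz <- bead_start_coords(bs) + matrix(rnorm(21, sd = 0.2), 7, 3)
    e <- bead_energy(bs, xyz)
    expect_identical(e$total, e$torsional + e$non_torsional)
  }
})

test_that("bead-system analytic gradients match central differences", {
  bs <- make_bead_chain(6, torsion_barrier = 3)
  set.seed(3)
  xyz <- bead_start_coords(bs) + matrix(rnorm(18, sd = 0.1), 6, 3)
  g <- bead_gradient(bs, xyz)
  g_num_tot <- numerical_gradient(function(c) bead_energy(bs, c)$total, xyz)
  g_num_tor <- numerical_gradient(function(c) bead_energy(bs, c)$torsional, xyz)
  expect_equal(g$total, g_num_tot, tolerance = 1e-5)
  expect_equal(g$torsional, g_num_tor, tolerance = 1e-5)
})

test_that("reference PMF of a flat potential is zero in every equal-width bin", {
  flat <- gamdr:::new_potential_spec(
    "poly", 1, list(coef = 5), domain = matrix(c(-2, 2), 1, 2),
    minima = tibble::tibble(x = 0, energy = 5))
  rp <- reference_pmf(flat, grid = 20)
  expect_equal(rp$free_energy, rep(0, 20), tolerance = 1e-12)
})

test_that("reference PMF of the harmonic well matches the analytic profile", {
  hw <- make_harmonic_well(1)
  edges <- seq(-3, 3, length.out = 61)
  rp <- reference_pmf(hw, grid = list(edges), temperature = 300)
  analytic <- 0.5 * rp$x^2
  analytic <- analytic - min(analytic)
  expect_lt(max(abs(rp$free_energy - analytic)), 0.02)
})

test_that("reference PMF agrees with a dense Riemann-sum oracle", {
  for (spec in list(make_double_well(6, 4), make_double_well(4, 3, 1))) {
    edges <- seq(-3.5, 3.5, length.out = 36)
    rp <- reference_pmf(spec, grid = list(edges), temperature = 300)
    oracle <- riemann_pmf(spec, edges, 300)
    expect_lt(max(abs(rp$free_energy - oracle)), 0.01)
  }
})

test_that("reference PMF of a symmetric double well is symmetric", {
  dw <- make_double_well(6, 4)
  rp <- reference_pmf(dw, grid = list(seq(-4, 4, length.out = 41)))
  expect_equal(rp$free_energy, rev(rp$free_energy), tolerance = 1e-9)
})

test_that("reference PMF warns when the grid misses a named minimum", {
  dw <- make_double_well(6, 4)
  expect_warning(reference_pmf(dw, grid = list(seq(0, 4, length.out = 11))),
                 "minima")
  expect_error(reference_pmf(dw, grid = list(c(0, 1, 1, 2))), "bins")
})

test_that("planted conformations: single noiseless state gives identical frames", {
  tmpl <- matrix(rnorm(15), 5, 3)
  tr <- plant_conformations(20, list(tmpl), noise_sd = 0, seed = 1)
  expect_equal(n_frames(tr), 20)
  for (f in 2:20) expect_identical(frame_coords(tr, f), frame_coords(tr, 1))
  expect_equal(raw_rmsd <- sqrt(mean(rowSums((frame_coords(tr, 1) -
                                                frame_coords(tr, 7))^2))), 0)
})

test_that("planted conformations honour degenerate occupancies", {
  states <- lapply(1:3, function(i) matrix(i * 10, 4, 3))
  tr <- plant_conformations(50, states, noise_sd = 0,
                            occupancies = c(1, 0, 0), seed = 2)
  expect_true(all(tr$metadata$labels == 1))
})

test_that("planted conformations are bit-reproducible for a fixed seed", {
  states <- list(matrix(0, 4, 3), matrix(5, 4, 3))
  a <- plant_conformations(100, states, noise_sd = 0.3,
                           occupancies = c(0.7, 0.3), seed = 99)
  b <- plant_conformations(100, states, noise_sd = 0.3,
                           occupancies = c(0.7, 0.3), seed = 99)
  expect_identical(a$coords, b$coords)
  expect_identical(a$metadata$labels, b$metadata$labels)
})

test_that("planted-conformation inputs are validated", {
  expect_error(plant_conformations(10, list()), "non-empty")
  expect_error(plant_conformations(10, list(matrix(0, 3, 3)),
                                   occupancies = c(0.5, 0.4)), "sum to 1")
  expect_error(plant_conformations(10, list(matrix(0, 3, 3)),
                                   noise_sd = -1), "noise_sd")
})
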