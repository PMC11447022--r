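test_that("minimisation converges to the unique harmonic minimum", {
  hw <- make_harmonic_well(1)
  st <- minimize(hw, sim_state(3), max_steps = 2000)
  expect_lt(abs(st$coords), 1e-4)
})

test_that("minimisation from just right of the barrier top descends into the right-hand well", {
  dw <- make_double_well(6, 4)
  # oracle: the gradient sign at the start decides the basin
  expect_lt(potential_gradient(dw, 0.1), 0)
  st <- minimize(dw, sim_state(0.1), max_steps = 5000)
  expect_equal(as.numeric(st$coords), 2, tolerance = 1e-3)
})

test_that("minimisation at a minimum returns immediately with zero displacement", {
  dw <- make_double_well(6, 4)
  st <- minimize(dw, sim_state(2), max_steps = 100, tol = 1e-5)
  expect_equal(as.numeric(st$coords), 2, tolerance = 1e-9)
  bs <- make_bead_chain(5, torsion_barrier = 2)
  ms <- minimize(bs, max_steps = 3000, tol = 1e-4)
  expect_lt(attr(ms, "gradient_norm"), 1e-3)
})

test_that("at T = 0 and zero friction a resting state at a minimum is a fixed point", {
  dw <- make_double_well(6, 4)
  st <- sim_state(2)
  st2 <- step_langevin(dw, st, dt = 0.001, friction = 0, temperature = 1e-12)
  expect_equal(as.numeric(st2$coords), 2, tolerance = 1e-9)
  expect_equal(as.numeric(st2$velocities), 0, tolerance = 1e-9)
})

test_that("identical seeds give bit-identical trajectories", {
  dw <- make_double_well(6, 4)
  p <- protocol(thermalize = 500, cmd_collect = 2000, gamd_equilibrate = 2000,
                gamd_produce = 5000, stats_interval = 500)
  a <- run_protocol(dw, p, gamd_controller(), seed = 5)
  b <- run_protocol(dw, p, gamd_controller(), seed = 5)
  expect_identical(a$coords, b$coords)
  expect_identical(a$boost, b$boost)
  # and the R integrator path as well
  bs <- make_bead_chain(4, torsion_barrier = 2)
  pr <- protocol(minimize = 100, thermalize = 50, cmd_collect = 100,
                 gamd_equilibrate = 0, gamd_produce = 200,
                 stats_interval = 50, record_stride = 5)
  ta <- run_protocol(bs, pr, NULL, seed = 3)
  tb <- run_protocol(bs, pr, NULL, seed = 3)
  expect_identical(ta$coords, tb$coords)
})

test_that("zero-friction harmonic dynamics conserve energy to better than 1e-3 kcal/mol over 1e4 steps", {
  hw <- make_harmonic_well(1)
  st <- sim_state(1, 2)
  energy <- function(s) {
    0.5 * as.numeric(s$coords)^2 +
      0.5 * hw$mass * as.numeric(s$velocities)^2 / kcal_accel
  }
  e0 <- energy(st)
  drift <- 0
  set.seed(1)
  for (i in 1:10000) {
    st <- step_langevin(hw, st, dt = 0.001, friction = 0, temperature = 300)
    drift <- max(drift, abs(energy(st) - e0))
  }
  expect_lt(drift, 1e-3)
})

test_that("long thermostatted runs satisfy equipartition within 5%", {
  hw <- make_harmonic_well(1)
  p <- protocol(thermalize = 20000, cmd_collect = 0, gamd_equilibrate = 0,
                gamd_produce = 2e6, record_stride = 20, friction = 5)
  tr <- run_protocol(hw, p, NULL, seed = 2)
  kT <- thermal_energy(300)
  # positional variance kB T / k_spring
  expect_equal(var(traj_x(tr)), kT / 1, tolerance = 0.05)
  # kinetic energy per degree of freedom kB T / 2
  ke <- 0.5 * hw$mass * mean(tr$metadata$velocities^2) / kcal_accel
  expect_equal(ke, kT / 2, tolerance = 0.05)
})

test_that("unboosted protocols record identically zero boost", {
  dw <- make_double_well(6, 4)
  p <- protocol(thermalize = 200, cmd_collect = 1000, gamd_equilibrate = 500,
                gamd_produce = 2000, stats_interval = 500)
  tr <- run_protocol(dw, p, NULL, seed = 1)
  expect_true(all(tr$boost$dV_sum == 0))
})

test_that("boosted runs satisfy V* = V + dV with dV given by the frozen parameters", {
  dw <- make_double_well(6, 4)
  p <- protocol(thermalize = 1000, cmd_collect = 5000, gamd_equilibrate = 5000,
                gamd_produce = 5000, stats_interval = 1000)
  tr <- run_protocol(dw, p, gamd_controller(), seed = 4)
  params <- tr$metadata$boost_params$total
  expect_s3_class(params, "boost_parameters")
  recomputed <- boost_energy(tr$energies$V_total, params)
  expect_equal(tr$boost$dV_total, recomputed, tolerance = 1e-12)
  expect_true(all(tr$boost$dV_sum >= 0))
  expect_true(all(tr$boost$dV_sum[tr$energies$V_total >= params$E] == 0))
})

test_that("replicas differ only by seed and share protocol metadata", {
  dw <- make_double_well(6, 4)
  p <- protocol(thermalize = 200, cmd_collect = 1000, gamd_equilibrate = 1000,
                gamd_produce = 2000, stats_interval = 500, n_replicas = 3)
  trs <- run_replicas(dw, p, gamd_controller(), seed_base = 10)
  expect_length(trs, 3)
  expect_equal(vapply(trs, function(t) t$metadata$seed, numeric(1)),
               c(10, 11, 12))
  expect_false(identical(trs[[1]]$coords, trs[[2]]$coords))
  for (t in trs) expect_identical(t$metadata$protocol, p)
})

test_that("dual boost on a system without a torsional term is rejected", {
  dw <- make_double_well(6, 4)
  p <- protocol(thermalize = 100, cmd_collect = 500, gamd_equilibrate = 500,
                gamd_produce = 500, stats_interval = 100)
  expect_error(run_protocol(dw, p, gamd_controller(dual = TRUE), seed = 1),
               "torsional")
})

test_that("dual-boost bead runs record both boost terms consistently", {
  bs <- make_bead_chain(5, torsion_barrier = 2)
  p <- protocol(minimize = 300, thermalize = 200, cmd_collect = 600,
                gamd_equilibrate = 400, gamd_produce = 600,
                stats_interval = 200, record_stride = 4)
  tr <- run_protocol(bs, p, gamd_controller(dual = TRUE), seed = 6)
  bp <- tr$metadata$boost_params
  expect_s3_class(bp$dihedral, "boost_parameters")
  oracle <- dual_boost_step(tr$energies$V_total, tr$energies$V_dihedral,
                            bp$total, bp$dihedral)
  expect_equal(tr$boost$dV_dihedral, oracle$dV_torsional, tolerance = 1e-10)
  expect_equal(tr$boost$dV_total, oracle$dV_total_term, tolerance = 1e-10)
  expect_equal(tr$boost$dV_sum, oracle$dV_sum, tolerance = 1e-10)
})

test_that("crossing counter uses hysteresis", {
  expect_equal(count_crossings(c(-2, -1.5, 0, -1.8, 0.5, 2, 1.5, -2)), 2)
  expect_equal(count_crossings(c(-2, -0.5, 0.5, -2)), 0)
  expect_equal(count_crossings(rep(-2, 10)), 0)
})
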