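#' Simulation state
#'
#' Minimal container for instantaneous coordinates and velocities. Analytic
#' systems use a numeric coordinate vector (length = dimensionality);
#' bead systems an `n_beads x 3` matrix.
#'
#' @param coords coordinates, A.
#' @param velocities velocities, A/ps (defaults to rest).
#' @param step integer step index.
#' @return an object of class `sim_state`.
#' @export
sim_state <- function(coords, velocities = NULL, step = 0L) {
  if (is.null(velocities)) velocities <- coords * 0
  structure(list(coords = coords, velocities = velocities,
                 step = as.integer(step)),
            class = "sim_state")
}

# ---- generic system interface ------------------------------------------

sys_energy <- function(system, coords) {
  if (inherits(system, "potential_spec")) {
    list(total = potential_energy(system, matrix(coords, 1)),
         torsional = NA_real_)
  } else if (inherits(system, "bead_system")) {
    e <- bead_energy(system, coords)
    list(total = e$total, torsional = e$torsional)
  } else stop("unsupported system")
}

sys_gradient <- function(system, coords) {
  if (inherits(system, "potential_spec")) {
    list(total = as.numeric(potential_gradient(system, matrix(coords, 1))),
         torsional = NULL)
  } else if (inherits(system, "bead_system")) {
    g <- bead_gradient(system, coords)
    list(total = g$total, torsional = g$torsional)
  } else stop("unsupported system")
}

sys_masses <- function(system, coords) {
  if (inherits(system, "potential_spec")) {
    rep(system$mass, length(coords))
  } else {
    matrix(rep(system$masses, 3), ncol = 3)
  }
}

sys_start <- function(system) {
  if (inherits(system, "potential_spec")) {
    m <- as.matrix(system$minima[, seq_len(system$dimensionality)])
    as.numeric(m[which.min(system$minima$energy), ])
  } else {
    bead_start_coords(system)
  }
}

sys_reflect <- function(system, coords, velocities) {
  if (inherits(system, "potential_spec")) {
    for (d in seq_len(system$dimensionality)) {
      lo <- system$domain[d, 1]; hi <- system$domain[d, 2]
      for (it in 1:64) {
        if (coords[d] < lo) { coords[d] <- 2 * lo - coords[d]; velocities[d] <- -velocities[d] }
        else if (coords[d] > hi) { coords[d] <- 2 * hi - coords[d]; velocities[d] <- -velocities[d] }
        else break
      }
    }
  }
  list(coords = coords, velocities = velocities)
}

# boosted force; boost = list(total = params|NULL, dihedral = params|NULL)
# dV* = s_P * (grad V_nontors + s_D * grad V_tors), the chain rule on the
# harmonic boost (forces are scaled down below E).
boosted_force <- function(system, coords, boost = NULL) {
  g <- sys_gradient(system, coords)
  e <- sys_energy(system, coords)
  if (is.null(boost) || (is.null(boost$total) && is.null(boost$dihedral))) {
    return(list(force = -g$total, energies = e,
                dV = list(dihedral = 0, total = 0, sum = 0)))
  }
  s_D <- 1; dV_d <- 0
  if (!is.null(boost$dihedral)) {
    if (is.null(g$torsional)) {
      stop("dual boost requested but the system has no separable torsional term")
    }
    vd <- e$torsional
    if (vd < boost$dihedral$E) {
      s_D <- 1 - boost$dihedral$k * (boost$dihedral$E - vd)
      dV_d <- 0.5 * boost$dihedral$k * (boost$dihedral$E - vd)^2
    }
  }
  grad_u <- if (!is.null(g$torsional)) {
    g$total - g$torsional + s_D * g$torsional
  } else g$total
  u <- e$total + dV_d
  s_P <- 1; dV_p <- 0
  if (!is.null(boost$total) && u < boost$total$E) {
    s_P <- 1 - boost$total$k * (boost$total$E - u)
    dV_p <- 0.5 * boost$total$k * (boost$total$E - u)^2
  }
  list(force = -s_P * grad_u, energies = e,
       dV = list(dihedral = dV_d, total = dV_p, sum = dV_d + dV_p))
}

#' Energy minimisation by backtracking gradient descent
#'
#' Steepest descent with Armijo backtracking; the energy is non-increasing
#' over accepted steps. Stops when the gradient norm falls below `tol` or
#' after `max_steps` accepted steps.
#'
#' @param system a [potential_spec] or `bead_system`.
#' @param state a [sim_state] (or bare coordinates); default system start.
#' @param max_steps maximum accepted steps.
#' @param tol gradient-norm tolerance, kcal/mol/A.
#' @return a [sim_state] with attributes `converged`, `gradient_norm`,
#'   `energy`.
#' @export
minimize <- function(system, state = NULL, max_steps = 500, tol = 1e-6) {
  if (is.null(state)) state <- sim_state(sys_start(system))
  if (!inherits(state, "sim_state")) state <- sim_state(state)
  x <- state$coords
  e <- sys_energy(system, x)$total
  if (!is.finite(e)) stop("divergent energy at the starting coordinates")
  t_step <- 1e-3
  steps <- 0
  repeat {
    g <- sys_gradient(system, x)$total
    gn <- sqrt(sum(g^2))
    if (gn < tol || steps >= max_steps) break
    accepted <- FALSE
    for (bt in 1:40) {
      x_new <- x - t_step * g
      e_new <- sys_energy(system, x_new)$total
      if (is.finite(e_new) && e_new <= e - 1e-4 * t_step * gn^2) {
        x <- x_new; e <- e_new
        t_step <- t_step * 1.5
        accepted <- TRUE
        break
      }
      t_step <- t_step / 2
    }
    if (!accepted) break
    steps <- steps + 1
  }
  if (!is.finite(e)) stop("energy diverged during minimisation")
  out <- sim_state(x, x * 0, step = steps)
  attr(out, "converged") <- sqrt(sum(sys_gradient(system, x)$total^2)) < tol
  attr(out, "gradient_norm") <- sqrt(sum(sys_gradient(system, x)$total^2))
  attr(out, "energy") <- e
  out
}

#' One Langevin (BAOAB) step
#'
#' Single update of the BAOAB splitting at timestep `dt` (ps), friction
#' (1/ps) and temperature (K), optionally under a boost. Uses R's RNG, so a
#' sequence of steps is deterministic given `set.seed()`.
#'
#' @param system a [potential_spec] or `bead_system`.
#' @param state a [sim_state].
#' @param dt timestep, ps (> 0).
#' @param friction friction coefficient, 1/ps (0 gives the symplectic NVE
#'   limit).
#' @param temperature temperature, K.
#' @param boost list with elements `total` and/or `dihedral`
#'   ([finalize_parameters()] objects), or NULL for plain dynamics.
#' @return updated [sim_state]; attributes `energies` (total, torsional)
#'   and `dV` (dihedral, total, sum) evaluated at the new coordinates.
#' @export
step_langevin <- function(system, state, dt, friction = 1, temperature = 300,
                          boost = NULL) {
  if (dt <= 0) stop("dt must be > 0")
  x <- state$coords; v <- state$velocities
  m <- sys_masses(system, x)
  kT <- thermal_energy(temperature)
  c1 <- exp(-friction * dt)
  c2 <- sqrt(1 - c1^2)
  sig <- sqrt(kT * kcal_accel / m)
  bf <- boosted_force(system, x, boost)
  if (any(!is.finite(bf$force))) stop("non-finite force")
  v <- v + 0.5 * dt * bf$force / m * kcal_accel
  x <- x + 0.5 * dt * v
  r <- sys_reflect(system, x, v); x <- r$coords; v <- r$velocities
  noise <- if (is.matrix(x)) matrix(rnorm(length(x)), nrow(x), 3) else rnorm(length(x))
  v <- c1 * v + c2 * sig * noise
  x <- x + 0.5 * dt * v
  r <- sys_reflect(system, x, v); x <- r$coords; v <- r$velocities
  bf <- boosted_force(system, x, boost)
  if (any(!is.finite(bf$force))) stop("non-finite force")
  v <- v + 0.5 * dt * bf$force / m * kcal_accel
  out <- sim_state(x, v, state$step + 1L)
  attr(out, "energies") <- bf$energies
  attr(out, "dV") <- bf$dV
  out
}

#' Staged simulation protocol
#'
#' Stage lengths are in integration steps: minimisation, thermalisation,
#' a conventional-MD window that collects potential statistics, a boosted
#' equilibration during which the boost parameters are refreshed every
#' `stats_interval` steps, and production with frozen parameters.
#'
#' @param dt timestep, ps.
#' @param friction Langevin friction, 1/ps.
#' @param temperature temperature, K.
#' @param minimize,thermalize,cmd_collect,gamd_equilibrate,gamd_produce
#'   stage lengths in steps (all >= 0).
#' @param stats_interval statistics window length in steps
#'   (<= `cmd_collect` when statistics are collected).
#' @param record_stride store one frame every this many production steps.
#' @param n_replicas number of independent replicas (distinct seeds).
#' @return an object of class `gamd_protocol`.
#' @export
protocol <- function(dt = 0.001, friction = 1, temperature = 300,
                     minimize = 200, thermalize = 5000, cmd_collect = 100000,
                     gamd_equilibrate = 1000000, gamd_produce = 500000,
                     stats_interval = 1000, record_stride = 10,
                     n_replicas = 1) {
  stages <- c(minimize = minimize, thermalize = thermalize,
              cmd_collect = cmd_collect, gamd_equilibrate = gamd_equilibrate,
              gamd_produce = gamd_produce)
  if (any(stages < 0)) stop("all stage lengths must be >= 0")
  if (cmd_collect > 0 && stats_interval > cmd_collect) {
    stop("stats_interval must not exceed the cmd_collect stage length")
  }
  stopifnot(dt > 0, friction >= 0, temperature > 0, stats_interval >= 1,
            record_stride >= 1, n_replicas >= 1)
  structure(list(dt = dt, friction = friction, temperature = temperature,
                 stages = stages, stats_interval = stats_interval,
                 record_stride = record_stride,
                 n_replicas = as.integer(n_replicas)),
            class = "gamd_protocol")
}

#' Run the staged simulation protocol
#'
#' Executes minimisation, thermalisation, statistics collection, boosted
#' equilibration (parameters refreshed every statistics interval, running
#' V_max/V_min never reset) and production with frozen parameters. With
#' `controller = NULL` every stage is conventional MD and all recorded boost
#' energies are zero.
#'
#' 1D polynomial systems are propagated by a compiled kernel; other systems
#' use the R integrator.
#'
#' @param system a [potential_spec] or `bead_system`.
#' @param protocol a [protocol()].
#' @param controller a [gamd_controller()] or NULL (plain cMD).
#' @param seed RNG seed for this run.
#' @param start starting coordinates (default: the system's deepest named
#'   minimum / all-trans chain).
#' @return a [new_trajectory()] of the production stage; `metadata` carries
#'   the frozen boost parameters, final statistics, per-stage log and the
#'   realised boost SD.
#' @export
run_protocol <- function(system, protocol, controller = NULL, seed = 1,
                         start = NULL) {
  stopifnot(inherits(protocol, "gamd_protocol"))
  if (!is.null(controller)) {
    stopifnot(inherits(controller, "gamd_controller"))
    if (controller$dual && !inherits(system, "bead_system")) {
      stop("dual boost requires a system with a separable torsional term")
    }
    if (protocol$stages["cmd_collect"] < 2) {
      stop("boosted runs need a cmd_collect stage to gather statistics")
    }
  }
  if (inherits(system, "potential_spec") && system$kind == "poly") {
    run_protocol_poly(system, protocol, controller, seed, start)
  } else {
    run_protocol_r(system, protocol, controller, seed, start)
  }
}

run_protocol_poly <- function(system, protocol, controller, seed, start) {
  set.seed(seed)
  p <- protocol
  coef <- system$params$coef
  lo <- system$domain[1, 1]; hi <- system$domain[1, 2]
  m <- system$mass
  kT <- thermal_energy(p$temperature)

  st <- minimize(system, if (is.null(start)) NULL else sim_state(start),
                 max_steps = p$stages[["minimize"]])
  x <- as.numeric(st$coords)
  v <- sqrt(kT * kcal_accel / m) * rnorm(1) # randomised initial velocity

  seg <- function(n, boost, E, k, stride) {
    cpp_langevin_poly(coef, lo, hi, x, v, m, p$dt, p$friction, kT,
                      as.integer(n), as.integer(stride), boost, E, k)
  }
  log <- list()
  if (p$stages[["thermalize"]] > 0) {
    r <- seg(p$stages[["thermalize"]], FALSE, 0, 0, 0L)
    x <- r$x_final; v <- r$v_final
    log <- c(log, list(tibble::tibble(stage = "thermalize",
                                      steps = p$stages[["thermalize"]],
                                      V_mean = r$stat_mean)))
  }
  acc <- stats_acc_new()
  if (p$stages[["cmd_collect"]] > 0) {
    left <- p$stages[["cmd_collect"]]
    while (left > 0) {
      n <- min(p$stats_interval, left)
      r <- seg(n, FALSE, 0, 0, 0L)
      x <- r$x_final; v <- r$v_final
      acc <- stats_acc_update(acc, r$stat_min, r$stat_max, r$stat_mean,
                              r$stat_m2, r$stat_n)
      left <- left - n
    }
    log <- c(log, list(tibble::tibble(stage = "cmd_collect",
                                      steps = p$stages[["cmd_collect"]],
                                      V_mean = acc$win_mean)))
  }
  params <- NULL
  if (!is.null(controller) && p$stages[["gamd_equilibrate"]] > 0) {
    left <- p$stages[["gamd_equilibrate"]]
    while (left > 0) {
      params <- finalize_parameters(stats_acc_as_stats(acc),
                                    controller$sigma0_total,
                                    controller$bound_mode, "total")
      n <- min(p$stats_interval, left)
      r <- seg(n, TRUE, params$E, params$k, 0L)
      x <- r$x_final; v <- r$v_final
      acc <- stats_acc_update(acc, r$stat_min, r$stat_max, r$stat_mean,
                              r$stat_m2, r$stat_n)
      left <- left - n
    }
    params <- finalize_parameters(stats_acc_as_stats(acc),
                                  controller$sigma0_total,
                                  controller$bound_mode, "total")
    log <- c(log, list(tibble::tibble(stage = "gamd_equilibrate",
                                      steps = p$stages[["gamd_equilibrate"]],
                                      V_mean = acc$win_mean)))
  } else if (is.null(controller) && p$stages[["gamd_equilibrate"]] > 0) {
    r <- seg(p$stages[["gamd_equilibrate"]], FALSE, 0, 0, 0L)
    x <- r$x_final; v <- r$v_final
  }

  boosted <- !is.null(controller)
  if (boosted && is.null(params)) {
    params <- finalize_parameters(stats_acc_as_stats(acc),
                                  controller$sigma0_total,
                                  controller$bound_mode, "total")
  }
  r <- seg(p$stages[["gamd_produce"]], boosted,
           if (boosted) params$E else 0, if (boosted) params$k else 0,
           p$record_stride)
  nf <- length(r$x)
  coords <- array(0, dim = c(nf, 1, 3))
  coords[, 1, 1] <- r$x
  energies <- tibble::tibble(frame = seq_len(nf), V_total = r$V,
                             V_dihedral = NA_real_)
  boost_tbl <- tibble::tibble(frame = seq_len(nf), dV_dihedral = 0,
                              dV_total = r$dV, dV_sum = r$dV)
  sigma_dV <- if (nf > 1) sqrt(mean((r$dV - mean(r$dV))^2)) else 0
  if (boosted && sigma_dV > params$sigma0 * 1.1) {
    message(sprintf(
      "sigma_dV = %.3f kcal/mol exceeds sigma0 = %.3f by more than 10%%",
      sigma_dV, params$sigma0))
  }
  new_trajectory(
    coords, energies, boost_tbl,
    period_ps = p$dt * p$record_stride,
    metadata = list(seed = seed, protocol = p,
                    system_kind = "poly",
                    velocities = r$v, velocities_final = r$v_final,
                    boost_params = list(total = params, dihedral = NULL),
                    stats = if (acc$n_total > 0) stats_acc_as_stats(acc) else NULL,
                    sigma_dV = sigma_dV,
                    stage_log = dplyr::bind_rows(log)))
}

run_protocol_r <- function(system, protocol, controller, seed, start) {
  set.seed(seed)
  p <- protocol
  kT <- thermal_energy(p$temperature)
  st <- minimize(system, if (is.null(start)) NULL else sim_state(start),
                 max_steps = p$stages[["minimize"]])
  m <- sys_masses(system, st$coords)
  state <- sim_state(st$coords, sqrt(kT * kcal_accel / m) *
                       (if (is.matrix(st$coords))
                          matrix(rnorm(length(st$coords)), nrow(st$coords), 3)
                        else rnorm(length(st$coords))))

  run_plain <- function(state, n) {
    Vs <- numeric(n); Vd <- numeric(n)
    for (i in seq_len(n)) {
      state <- step_langevin(system, state, p$dt, p$friction, p$temperature)
      e <- attr(state, "energies")
      Vs[i] <- e$total; Vd[i] <- e$torsional
    }
    list(state = state, V = Vs, Vd = Vd)
  }
  if (p$stages[["thermalize"]] > 0) {
    state <- run_plain(state, p$stages[["thermalize"]])$state
  }

  dual <- !is.null(controller) && controller$dual
  acc_p <- stats_acc_new(); acc_d <- stats_acc_new()
  upd <- function(acc, v) {
    stats_acc_update(acc, min(v), max(v), mean(v),
                     sum((v - mean(v))^2), length(v))
  }
  if (p$stages[["cmd_collect"]] > 0) {
    left <- p$stages[["cmd_collect"]]
    while (left > 0) {
      n <- min(p$stats_interval, left)
      r <- run_plain(state, n)
      state <- r$state
      acc_p <- upd(acc_p, r$V)
      if (dual) acc_d <- upd(acc_d, r$Vd)
      left <- left - n
    }
  }

  make_boost <- function() {
    if (is.null(controller)) return(NULL)
    pd <- if (dual) finalize_parameters(stats_acc_as_stats(acc_d),
                                        controller$sigma0_dihedral,
                                        controller$bound_mode, "dihedral")
          else NULL
    pt <- finalize_parameters(stats_acc_as_stats(acc_p),
                              controller$sigma0_total,
                              controller$bound_mode, "total")
    list(total = pt, dihedral = pd)
  }
  run_boosted <- function(state, n, boost) {
    Vs <- numeric(n); Vd <- numeric(n)
    for (i in seq_len(n)) {
      state <- step_langevin(system, state, p$dt, p$friction, p$temperature,
                             boost = boost)
      e <- attr(state, "energies")
      dv <- attr(state, "dV")
      Vs[i] <- e$total + dv$dihedral # total-term statistic includes dV_D
      Vd[i] <- e$torsional
    }
    list(state = state, V = Vs, Vd = Vd)
  }
  boost <- NULL
  if (!is.null(controller) && p$stages[["gamd_equilibrate"]] > 0) {
    left <- p$stages[["gamd_equilibrate"]]
    while (left > 0) {
      boost <- make_boost()
      n <- min(p$stats_interval, left)
      r <- run_boosted(state, n, boost)
      state <- r$state
      acc_p <- upd(acc_p, r$V)
      if (dual) acc_d <- upd(acc_d, r$Vd)
      left <- left - n
    }
    boost <- make_boost()
  } else if (!is.null(controller)) {
    boost <- make_boost()
  } else if (p$stages[["gamd_equilibrate"]] > 0) {
    state <- run_plain(state, p$stages[["gamd_equilibrate"]])$state
  }

  n_prod <- p$stages[["gamd_produce"]]
  nf <- n_prod %/% p$record_stride
  np <- if (is.matrix(state$coords)) nrow(state$coords) else 1L
  coords <- array(0, dim = c(nf, np, 3))
  V_tot <- numeric(nf); V_dih <- numeric(nf)
  dV_d <- numeric(nf); dV_p <- numeric(nf)
  irec <- 0
  for (i in seq_len(n_prod)) {
    state <- step_langevin(system, state, p$dt, p$friction, p$temperature,
                           boost = boost)
    if (i %% p$record_stride == 0) {
      irec <- irec + 1
      cc <- state$coords
      if (!is.matrix(cc)) {
        cc <- cbind(matrix(cc, 1), matrix(0, 1, 3 - length(cc)))
      }
      coords[irec, , ] <- cc
      e <- attr(state, "energies"); dv <- attr(state, "dV")
      V_tot[irec] <- e$total; V_dih[irec] <- e$torsional
      dV_d[irec] <- dv$dihedral; dV_p[irec] <- dv$total
    }
  }
  dV_sum <- dV_d + dV_p
  sigma_dV <- if (nf > 1) sqrt(mean((dV_sum - mean(dV_sum))^2)) else 0
  new_trajectory(
    coords,
    tibble::tibble(frame = seq_len(nf), V_total = V_tot, V_dihedral = V_dih),
    tibble::tibble(frame = seq_len(nf), dV_dihedral = dV_d, dV_total = dV_p,
                   dV_sum = dV_sum),
    period_ps = p$dt * p$record_stride,
    metadata = list(seed = seed, protocol = p,
                    system_kind = class(system)[1],
                    boost_params = boost,
                    stats = if (acc_p$n_total > 0) stats_acc_as_stats(acc_p) else NULL,
                    sigma_dV = sigma_dV))
}

#' Run independent replicas
#'
#' Repeats [run_protocol()] with distinct seeds; all other protocol metadata
#' is identical across replicas (randomised initial velocities come from the
#' seed).
#'
#' @inheritParams run_protocol
#' @param seeds integer vector of seeds; default `seed_base + 0:(n-1)` with
#'   `n = protocol$n_replicas`.
#' @param seed_base base seed used when `seeds` is NULL.
#' @return list of [new_trajectory()] objects.
#' @export
run_replicas <- function(system, protocol, controller = NULL, seeds = NULL,
                         seed_base = 1, start = NULL) {
  if (is.null(seeds)) {
    seeds <- seed_base + seq_len(protocol$n_replicas) - 1L
  }
  lapply(seeds, function(s) run_protocol(system, protocol, controller,
                                         seed = s, start = start))
}

#' Count barrier crossings of a 1D series
#'
#' A crossing is a transition from the region `x <= lower` to `x >= upper`
#' or back; excursions that do not reach the far region are not counted
#' (hysteresis, so noise at the barrier top is ignored).
#'
#' @param x numeric series (e.g. `traj_x(traj)`).
#' @param lower,upper region boundaries, A.
#' @return integer crossing count.
#' @export
count_crossings <- function(x, lower = -1, upper = 1) {
  region <- ifelse(x <= lower, -1L, ifelse(x >= upper, 1L, 0L))
  region <- region[region != 0L]
  if (length(region) < 2) return(0L)
  sum(diff(region) != 0L)
}
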