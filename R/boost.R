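#' Potential-energy statistics for boost-parameter determination
#'
#' Exact max/min/mean/SD (population SD) of a windowed potential-energy
#' series, the quantities from which the boost parameters are derived.
#'
#' @param energy_series numeric vector of potential energies, kcal/mol.
#' @param window integer `c(start, end)` into the series; default whole
#'   series.
#' @return an object of class `potential_stats` with fields `V_max`, `V_min`,
#'   `V_avg`, `sigma_V`, `n_samples`, `window`.
#' @examples
#' collect_statistics(c(1, 2, 3)) # sigma_V = sqrt(2/3)
#' @export
collect_statistics <- function(energy_series, window = NULL) {
  if (is.null(window)) window <- c(1L, length(energy_series))
  if (window[1] < 1 || window[2] > length(energy_series) ||
      window[2] < window[1]) {
    stop("window must lie within the series")
  }
  v <- energy_series[window[1]:window[2]]
  if (length(v) < 2) stop("need at least 2 samples in the window")
  new_potential_stats(max(v), min(v), mean(v),
                      sqrt(mean((v - mean(v))^2)), length(v), window)
}

#' Construct potential statistics directly
#'
#' Builds a `potential_stats` object from known summary values (rather than
#' from a series via [collect_statistics()]); invariants
#' `V_min <= V_avg <= V_max`, `sigma_V >= 0`, `n_samples >= 2` are enforced.
#'
#' @param V_max,V_min,V_avg,sigma_V summary statistics, kcal/mol.
#' @param n_samples number of samples the summary is based on.
#' @param window optional `(start, end)` step window.
#' @return a `potential_stats` object.
#' @export
potential_stats <- function(V_max, V_min, V_avg, sigma_V, n_samples = 2,
                            window = c(NA, NA)) {
  new_potential_stats(V_max, V_min, V_avg, sigma_V, n_samples, window)
}

new_potential_stats <- function(V_max, V_min, V_avg, sigma_V, n_samples,
                                window = c(NA, NA)) {
  if (!(V_min <= V_avg && V_avg <= V_max)) {
    stop("potential statistics must satisfy V_min <= V_avg <= V_max")
  }
  if (sigma_V < 0) stop("sigma_V must be >= 0")
  if (n_samples < 2) stop("n_samples must be >= 2")
  structure(list(V_max = V_max, V_min = V_min, V_avg = V_avg,
                 sigma_V = sigma_V, n_samples = as.integer(n_samples),
                 window = window),
            class = "potential_stats")
}

#' @export
print.potential_stats <- function(x, ...) {
  cat(sprintf(
    "<potential_stats> n=%d  V in [%.4g, %.4g], avg %.4g, sigma %.4g kcal/mol\n",
    x$n_samples, x$V_min, x$V_max, x$V_avg, x$sigma_V))
  invisible(x)
}

#' Effective harmonic force constant fraction k0
#'
#' Determines the dimensionless boost strength `k0` in (0, 1] from potential
#' statistics and the reweighting-accuracy limit `sigma0`. With the reference
#' energy at its lower bound (`E = V_max`),
#' `k0 = min(1, (sigma0/sigma_V) * (V_max - V_min)/(V_max - V_avg))`.
#' With E at its upper bound (`E = V_min + 1/k`),
#' `k0'' = (1 - sigma0/sigma_V) * (V_max - V_min)/(V_avg - V_min)`, which is
#' used only if it falls in (0, 1]; otherwise the lower-bound expression is
#' used instead (the standard fallback rule).
#'
#' @param stats a `potential_stats`.
#' @param sigma0 upper limit on the boost-potential SD, kcal/mol.
#' @param bound_mode `"lower"` or `"upper"`.
#' @return `k0` (numeric in (0, 1]), with attribute `bound_mode` giving the
#'   mode actually in effect after the fallback rule.
#' @examples
#' s <- new_potential_stats(40, 0, 10, 12, 100)
#' compute_k0(s, sigma0 = 6, "lower") # 2/3
#' @export
compute_k0 <- function(stats, sigma0, bound_mode = c("lower", "upper")) {
  bound_mode <- match.arg(bound_mode)
  stopifnot(inherits(stats, "potential_stats"), sigma0 > 0)
  rng <- stats$V_max - stats$V_min
  if (rng <= 0) stop("flat statistics: V_max must exceed V_min")
  if (stats$sigma_V <= 0) stop("sigma_V must be > 0")
  k0_lower <- min(1, (sigma0 / stats$sigma_V) * rng /
                    (stats$V_max - stats$V_avg))
  if (bound_mode == "upper") {
    k0pp <- (1 - sigma0 / stats$sigma_V) * rng / (stats$V_avg - stats$V_min)
    if (k0pp > 0 && k0pp <= 1) {
      return(structure(k0pp, bound_mode = "upper"))
    }
  }
  structure(k0_lower, bound_mode = "lower")
}

#' Finalise boost parameters from potential statistics
#'
#' Combines [compute_k0()] with the bound on the reference energy:
#' `k = k0 / (V_max - V_min)`; lower mode sets `E = V_max`, upper mode
#' `E = V_min + 1/k`. The result always satisfies
#' `V_max <= E <= V_min + 1/k` and `0 < k0 <= 1`.
#'
#' @inheritParams compute_k0
#' @param term which energy term the boost applies to (`"total"` or
#'   `"dihedral"`).
#' @return an object of class `boost_parameters` with fields `E`, `k`, `k0`,
#'   `sigma0`, `bound_mode`, `term`.
#' @export
finalize_parameters <- function(stats, sigma0 = 6,
                                bound_mode = c("lower", "upper"),
                                term = c("total", "dihedral")) {
  bound_mode <- match.arg(bound_mode)
  term <- match.arg(term)
  k0 <- compute_k0(stats, sigma0, bound_mode)
  mode_used <- attr(k0, "bound_mode")
  k0 <- as.numeric(k0)
  rng <- stats$V_max - stats$V_min
  k <- k0 / rng
  E <- if (mode_used == "lower") stats$V_max else stats$V_min + 1 / k
  if (!(stats$V_max <= E + 1e-9 && E <= stats$V_min + 1 / k + 1e-9)) {
    stop("internal error: E outside [V_max, V_min + 1/k]")
  }
  structure(list(E = E, k = k, k0 = k0, sigma0 = sigma0,
                 bound_mode = mode_used, term = term,
                 V_max = stats$V_max, V_min = stats$V_min,
                 V_avg = stats$V_avg, sigma_V = stats$sigma_V),
            class = "boost_parameters")
}

#' @export
print.boost_parameters <- function(x, ...) {
  cat(sprintf(
    "<boost_parameters> term=%s  E=%.4g  k=%.4g /(kcal/mol)  k0=%.4g  (%s bound)\n",
    x$term, x$E, x$k, x$k0, x$bound_mode))
  invisible(x)
}

#' Harmonic boost potential
#'
#' `dV = 0.5 k (E - V)^2` when `V < E`, else 0 (vectorised). The boosted
#' potential is `V* = V + dV`; below E the boost preserves energetic order
#' and shrinks energy differences, smoothing the landscape.
#'
#' @param V potential energies, kcal/mol.
#' @param params a `boost_parameters` object (or list with `E` and `k`).
#' @return boost energies dV >= 0, kcal/mol.
#' @examples
#' p <- list(E = 10, k = 0.01)
#' boost_energy(6, p) # 0.08
#' @export
boost_energy <- function(V, params) {
  stopifnot(is.numeric(V), all(is.finite(V)))
  ifelse(V < params$E, 0.5 * params$k * (params$E - V)^2, 0)
}

#' One dual-boost evaluation
#'
#' The torsional boost is computed first from the torsional energy; the
#' total-term boost is then computed from the total potential with the
#' torsional boost already added. The recorded boost used in reweighting is
#' the sum of the two.
#'
#' @param total_V total potential energy, kcal/mol (may be a vector).
#' @param torsional_V torsional energy, kcal/mol (same length).
#' @param params_total boost parameters for the total term (NULL disables).
#' @param params_torsional boost parameters for the torsional term
#'   (NULL or `k0 = 0` disables, reducing to a single total boost).
#' @return list with `dV_torsional`, `dV_total_term`, `dV_sum`.
#' @export
dual_boost_step <- function(total_V, torsional_V, params_total,
                            params_torsional = NULL) {
  dV_d <- if (is.null(params_torsional) ||
              isTRUE(params_torsional$k0 == 0)) {
    rep(0, length(total_V))
  } else {
    boost_energy(torsional_V, params_torsional)
  }
  dV_p <- if (is.null(params_total)) {
    rep(0, length(total_V))
  } else {
    boost_energy(total_V + dV_d, params_total)
  }
  list(dV_torsional = dV_d, dV_total_term = dV_p, dV_sum = dV_d + dV_p)
}

#' Boost controller settings
#'
#' Collects the per-term boost configuration used by [run_protocol()]:
#' `sigma0` limits (kcal/mol, default 6.0 for both terms), the reference
#' energy bound and whether the dual-boost scheme (dihedral + total) is in
#' effect. Dual boost requires a system with a separable torsional term.
#'
#' @param sigma0_total,sigma0_dihedral SD limits of the boost per term.
#' @param bound_mode `"lower"` (default) or `"upper"` reference energy bound.
#' @param dual apply the dual-boost scheme.
#' @return an object of class `gamd_controller`.
#' @export
gamd_controller <- function(sigma0_total = 6, sigma0_dihedral = 6,
                            bound_mode = c("lower", "upper"), dual = FALSE) {
  bound_mode <- match.arg(bound_mode)
  stopifnot(sigma0_total > 0, sigma0_dihedral > 0)
  structure(list(sigma0_total = sigma0_total,
                 sigma0_dihedral = sigma0_dihedral,
                 bound_mode = bound_mode, dual = dual),
            class = "gamd_controller")
}

# --- running statistics used by the engine ------------------------------
# V_max / V_min are monotone accumulators (never reset); V_avg / sigma_V are
# recomputed over the most recent statistics window.
stats_acc_new <- function() {
  list(vmin = Inf, vmax = -Inf, win_mean = NA_real_, win_sd = NA_real_,
       win_n = 0, n_total = 0)
}

stats_acc_update <- function(acc, seg_min, seg_max, seg_mean, seg_m2, seg_n) {
  acc$vmin <- min(acc$vmin, seg_min)
  acc$vmax <- max(acc$vmax, seg_max)
  acc$win_mean <- seg_mean
  acc$win_sd <- sqrt(max(0, seg_m2 / seg_n))
  acc$win_n <- seg_n
  acc$n_total <- acc$n_total + seg_n
  acc
}

stats_acc_as_stats <- function(acc) {
  # clamp: the window mean always lies inside the monotone range
  avg <- min(max(acc$win_mean, acc$vmin), acc$vmax)
  new_potential_stats(acc$vmax, acc$vmin, avg, acc$win_sd,
                      max(2, acc$n_total))
}
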