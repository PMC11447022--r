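#' Tidy a free-energy grid
#' @param x a [pmf_grid].
#' @param ... unused.
#' @return tibble of bins (centre coordinates, counts, boost statistics,
#'   free energy, mask).
#' @method tidy pmf_grid
#' @export
tidy.pmf_grid <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of a free-energy grid
#' @param x a [pmf_grid].
#' @param ... unused.
#' @return tibble: bin count, masked fraction, pooled boost SD, free-energy
#'   range, temperature.
#' @method glance pmf_grid
#' @export
glance.pmf_grid <- function(x, ...) {
  rep <- reweight_report(x)
  tibble::tibble(n_bins = nrow(x), masked_fraction = rep$masked_fraction,
                 sigma_dV = rep$sigma_dV,
                 max_anharmonicity = rep$max_anharmonicity,
                 f_range = diff(range(x$free_energy, na.rm = TRUE)),
                 temperature = pmf_temperature(x))
}

#' Tidy a cluster assignment
#' @param x a `cluster_set`.
#' @param ... unused.
#' @return tibble with `frame`, `cluster`.
#' @method tidy cluster_set
#' @export
tidy.cluster_set <- function(x, ...) {
  tibble::tibble(frame = seq_along(x$labels), cluster = x$labels)
}

#' One-row summary of a clustering
#' @param x a `cluster_set`.
#' @param ... unused.
#' @method glance cluster_set
#' @export
glance.cluster_set <- function(x, ...) {
  tibble::tibble(n_frames = x$n_frames, n_clusters = nrow(x$medoids),
                 cutoff = x$cutoff,
                 largest_fraction = max(x$medoids$size) / x$n_frames)
}

#' Tidy a superposition result
#' @param x a `superposition_result`.
#' @param ... unused.
#' @return one-row tibble with `rmsd`, `n_pairs`, `angle_deg` and the
#'   translation components.
#' @method tidy superposition_result
#' @export
tidy.superposition_result <- function(x, ...) {
  tibble::tibble(rmsd = x$rmsd, n_pairs = x$n_pairs,
                 angle_deg = rotation_angle(x$rotation),
                 tx = x$translation[1], ty = x$translation[2],
                 tz = x$translation[3])
}

#' Tidy boost parameters
#' @param x a `boost_parameters` object.
#' @param ... unused.
#' @method tidy boost_parameters
#' @export
tidy.boost_parameters <- function(x, ...) {
  tibble::tibble(term = x$term, E = x$E, k = x$k, k0 = x$k0,
                 sigma0 = x$sigma0, bound_mode = x$bound_mode,
                 V_max = x$V_max, V_min = x$V_min)
}

#' One-row summary of a trajectory
#' @param x a `gamd_trajectory`.
#' @param ... unused.
#' @return tibble with frame/particle counts, mean potential, boost mean
#'   and SD.
#' @method glance gamd_trajectory
#' @export
glance.gamd_trajectory <- function(x, ...) {
  tibble::tibble(n_frames = n_frames(x), n_particles = n_particles(x),
                 period_ps = x$period_ps,
                 V_mean = mean(x$energies$V_total),
                 dV_mean = mean(x$boost$dV_sum),
                 sigma_dV = sqrt(mean((x$boost$dV_sum -
                                         mean(x$boost$dV_sum))^2)))
}
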