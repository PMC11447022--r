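#' Trajectory container
#'
#' A `gamd_trajectory` holds frames of coordinates together with per-frame
#' energy terms and per-frame boost records. Coordinates are stored as an
#' `n_frames x n_particles x 3` array in Angstrom; analytic 1D/2D systems use
#' a single "particle" whose unused coordinates are zero.
#'
#' @param coords numeric array `n_frames x n_particles x 3`.
#' @param energies tibble with columns `frame`, `V_total` and (optionally)
#'   `V_dihedral` in kcal/mol; may be `NULL` for purely geometric fixtures.
#' @param boost tibble with columns `frame`, `dV_dihedral`, `dV_total`,
#'   `dV_sum` (kcal/mol); `NULL` means an unboosted trajectory (all zero).
#' @param period_ps time between stored frames, ps.
#' @param metadata free-form list (seed, protocol, system description,
#'   planted state labels, frozen boost parameters, stage log, ...).
#' @return an object of class `gamd_trajectory`.
#' @export
new_trajectory <- function(coords, energies = NULL, boost = NULL,
                           period_ps = 1, metadata = list()) {
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (!all(is.finite(coords))) stop("trajectory coordinates must be finite")
  nf <- dim(coords)[1]
  if (is.null(energies)) {
    energies <- tibble::tibble(frame = seq_len(nf), V_total = NA_real_,
                               V_dihedral = NA_real_)
  }
  if (!"V_dihedral" %in% names(energies)) energies$V_dihedral <- NA_real_
  if (is.null(boost)) {
    boost <- tibble::tibble(frame = seq_len(nf), dV_dihedral = 0,
                            dV_total = 0, dV_sum = 0)
  }
  if (nrow(energies) != nf || nrow(boost) != nf) {
    stop("energies and boost records must have one row per frame")
  }
  structure(list(coords = coords, energies = tibble::as_tibble(energies),
                 boost = tibble::as_tibble(boost),
                 period_ps = period_ps, metadata = metadata),
            class = "gamd_trajectory")
}

#' @export
print.gamd_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<gamd_trajectory> %d frames x %d particles, %.4g ps/frame\n",
              d[1], d[2], x$period_ps))
  if (any(x$boost$dV_sum > 0)) {
    cat(sprintf("  boosted: mean dV = %.3f kcal/mol, sd = %.3f\n",
                mean(x$boost$dV_sum), stats::sd(x$boost$dV_sum)))
  }
  invisible(x)
}

#' Number of frames / particles in a trajectory
#' @param traj a `gamd_trajectory`.
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname n_frames
#' @export
n_particles <- function(traj) dim(traj$coords)[2]

#' Coordinates of one frame
#' @param traj a `gamd_trajectory`.
#' @param frame frame index.
#' @return `n_particles x 3` matrix.
#' @export
frame_coords <- function(traj, frame) {
  stopifnot(frame >= 1, frame <= n_frames(traj))
  matrix(traj$coords[frame, , ], ncol = 3)
}

#' First-coordinate time series of a one-particle trajectory
#'
#' Convenience collective variable for analytic 1D systems.
#' @param traj a `gamd_trajectory`.
#' @return numeric vector, one value per frame.
#' @export
traj_x <- function(traj) traj$coords[, 1, 1]

#' Long-format view of a trajectory
#'
#' @param x a `gamd_trajectory`.
#' @param ... unused.
#' @return tibble with `frame`, `time_ps`, `particle`, `x`, `y`, `z`.
#' @importFrom tibble as_tibble
#' @method as_tibble gamd_trajectory
#' @export
as_tibble.gamd_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  tibble::tibble(
    frame = rep(seq_len(d[1]), times = d[2]),
    time_ps = rep(seq_len(d[1]) * x$period_ps, times = d[2]),
    particle = rep(seq_len(d[2]), each = d[1]),
    x = as.vector(x$coords[, , 1]),
    y = as.vector(x$coords[, , 2]),
    z = as.vector(x$coords[, , 3]))
}

#' Concatenate trajectories frame-wise
#'
#' Replica trajectories are combined before reweighting, mirroring the
#' practice of pooling snapshots from independent production runs.
#' @param ... `gamd_trajectory` objects with identical particle counts.
#' @return a single `gamd_trajectory`; metadata keeps the per-replica seeds.
#' @export
traj_bind <- function(...) {
  trajs <- list(...)
  if (length(trajs) == 1 && is.list(trajs[[1]]) &&
      !inherits(trajs[[1]], "gamd_trajectory")) {
    trajs <- trajs[[1]]
  }
  stopifnot(length(trajs) >= 1)
  np <- vapply(trajs, n_particles, integer(1))
  if (length(unique(np)) != 1) stop("particle counts differ across trajectories")
  coords <- do.call(abind3, lapply(trajs, function(t) t$coords))
  energies <- dplyr::bind_rows(lapply(trajs, function(t) t$energies))
  boost <- dplyr::bind_rows(lapply(trajs, function(t) t$boost))
  energies$frame <- seq_len(nrow(energies))
  boost$frame <- seq_len(nrow(boost))
  new_trajectory(coords, energies, boost, period_ps = trajs[[1]]$period_ps,
                 metadata = list(replicas = lapply(trajs, function(t) t$metadata)))
}

# bind 3D arrays along the first dimension
abind3 <- function(...) {
  arrs <- list(...)
  d2 <- dim(arrs[[1]])[2]
  n <- sum(vapply(arrs, function(a) dim(a)[1], numeric(1)))
  out <- array(0, dim = c(n, d2, 3))
  at <- 0
  for (a in arrs) {
    k <- dim(a)[1]
    if (k > 0) out[at + seq_len(k), , ] <- a
    at <- at + k
  }
  out
}
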