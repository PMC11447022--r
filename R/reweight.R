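#' Binned free-energy surface
#'
#' A `pmf_grid` is a tibble with one row per bin (bin index, bin-centre
#' coordinates, sample count, boost statistics, anharmonicity diagnostic,
#' reweighted free energy and a mask for under-sampled bins), carrying the
#' bin edges, temperature and collective-variable names as attributes. Bins
#' are half-open `[lo, hi)`, last bin closed; the minimum over unmasked bins
#' is zero.
#'
#' @name pmf_grid
NULL

new_pmf_grid <- function(df, edges, temperature, cv_names) {
  structure(tibble::as_tibble(df),
            edges = edges, temperature = temperature, cv_names = cv_names,
            class = c("pmf_grid", class(tibble::tibble())))
}

#' @export
print.pmf_grid <- function(x, ...) {
  cat(sprintf("<pmf_grid> %dD, %d bins (%d masked), T = %g K\n",
              length(attr(x, "edges")), nrow(x), sum(x$masked),
              attr(x, "temperature")))
  NextMethod()
}

#' Bin edges / temperature of a pmf_grid
#' @param grid a [pmf_grid].
#' @return list of edge vectors (one per dimension) / temperature in K.
#' @export
pmf_edges <- function(grid) attr(grid, "edges")

#' @rdname pmf_edges
#' @export
pmf_temperature <- function(grid) attr(grid, "temperature")

#' Second-order cumulant reweighting correction
#'
#' Gaussian approximation to the exponential boost average for one bin:
#' returns `-(1/beta) * (beta * mean(dV) + beta^2/2 * var(dV))`
#' = `-(mean(dV) + beta * var(dV) / 2)` (population variance), the free-energy
#' shift that is added to the biased bin free energy
#' `F*(bin) = -kB T log p*(bin)` to recover the unbiased value. When the
#' boost in a bin is exactly Gaussian this equals the exact estimator
#' `-(1/beta) * log(mean(exp(beta * dV)))`.
#'
#' @param deltaV boost-energy samples falling in the bin, kcal/mol.
#' @param temperature temperature, K.
#' @param min_samples bins with fewer samples are masked (returns `NA`).
#' @return correction in kcal/mol, or `NA_real_` if the bin is masked.
#' @export
cumulant_correction <- function(deltaV, temperature, min_samples = 10) {
  if (length(deltaV) < min_samples) return(NA_real_)
  beta <- 1 / thermal_energy(temperature)
  m <- mean(deltaV)
  v <- mean((deltaV - m)^2)
  -(m + beta * v / 2)
}

# KL divergence of the dV sample histogram from a Gaussian with matched
# mean and SD; 0 for (near-)constant samples.
dv_anharmonicity <- function(deltaV, n_hist = 20) {
  n <- length(deltaV)
  if (n < 2) return(0)
  m <- mean(deltaV)
  s <- sqrt(mean((deltaV - m)^2))
  if (s < 1e-8) return(0)
  br <- seq(m - 5 * s, m + 5 * s, length.out = n_hist + 1)
  x <- pmin(pmax(deltaV, br[1]), br[n_hist + 1])
  idx <- findInterval(x, br, rightmost.closed = TRUE)
  p <- tabulate(idx, nbins = n_hist) / n
  ctr <- (br[-1] + br[-(n_hist + 1)]) / 2
  q <- dnorm(ctr, m, s)
  q <- q / sum(q)
  keep <- p > 0
  sum(p[keep] * log(p[keep] / q[keep]))
}

#' Reweighted free-energy profile from a boosted trajectory
#'
#' Histograms collective-variable values into half-open bins, converts
#' biased populations to free energies, applies the per-bin second-order
#' cumulant correction of the recorded boost and min-shifts over unmasked
#' bins. With all-zero boost this is an ordinary Boltzmann histogram PMF.
#'
#' @param cv collective-variable values: numeric vector (1D) or two-column
#'   matrix / data frame (2D), one row per frame.
#' @param boost per-frame total boost energies `dV` (kcal/mol); zeros, a
#'   numeric vector, or a `gamd_trajectory` whose `boost$dV_sum` is used.
#' @param bins number of bins (scalar or per-dimension) or list of edge
#'   vectors.
#' @param temperature temperature, K.
#' @param min_samples bins with fewer samples are masked (missing, not
#'   infinite).
#' @return a [pmf_grid].
#' @export
pmf <- function(cv, boost = NULL, bins = 50, temperature = 300,
                min_samples = 10) {
  if (inherits(boost, "gamd_trajectory")) boost <- boost$boost$dV_sum
  cvm <- if (is.null(dim(cv))) matrix(as.numeric(cv), ncol = 1)
         else as.matrix(cv)
  nd <- ncol(cvm)
  if (!nd %in% c(1, 2)) stop("cv must be 1D or 2D")
  n <- nrow(cvm)
  if (is.null(boost)) boost <- rep(0, n)
  if (length(boost) != n) stop("cv values and boost records must align by frame")
  cv_names <- colnames(cvm)
  if (is.null(cv_names)) cv_names <- c("x", "y")[seq_len(nd)]

  edges <- if (is.list(bins)) lapply(bins, as.numeric) else {
    nb <- rep(as.integer(bins), length.out = nd)
    lapply(seq_len(nd), function(d) {
      seq(min(cvm[, d]), max(cvm[, d]), length.out = nb[d] + 1)
    })
  }
  for (e in edges) if (any(diff(e) <= 0)) stop("bin edges must increase")

  idx <- matrix(0L, n, nd)
  for (d in seq_len(nd)) {
    idx[, d] <- findInterval(cvm[, d], edges[[d]], rightmost.closed = TRUE)
  }
  nb <- vapply(edges, function(e) length(e) - 1L, integer(1))
  inside <- rowSums(idx >= 1 & idx <= matrix(nb, n, nd, byrow = TRUE)) == nd
  if (!all(inside)) {
    warning(sum(!inside), " frames fall outside the bin range and are dropped")
    idx <- idx[inside, , drop = FALSE]
    boost <- boost[inside]
  }
  lin <- if (nd == 1) idx[, 1] else (idx[, 2] - 1L) * nb[1] + idx[, 1]
  total_bins <- prod(nb)

  count <- tabulate(lin, nbins = total_bins)
  beta <- 1 / thermal_energy(temperature)
  grp <- split(boost, factor(lin, levels = seq_len(total_bins)))
  mean_dV <- vapply(grp, function(v) if (length(v)) mean(v) else NA_real_,
                    numeric(1))
  sd_dV <- vapply(grp, function(v) {
    if (length(v) < 2) return(if (length(v)) 0 else NA_real_)
    sqrt(mean((v - mean(v))^2))
  }, numeric(1))
  anh <- vapply(grp, dv_anharmonicity, numeric(1))
  corr <- vapply(grp, cumulant_correction, numeric(1),
                 temperature = temperature, min_samples = min_samples)
  masked <- count < min_samples
  if (all(masked)) stop("all bins are masked; not enough samples")
  f_star <- ifelse(count > 0, -log(count / sum(count)) / beta, NA_real_)
  f <- ifelse(masked, NA_real_, f_star + corr)
  f <- f - min(f[!masked])

  ctr <- lapply(seq_len(nd), function(d) {
    e <- edges[[d]]; (e[-1] + e[-length(e)]) / 2
  })
  df <- tibble::tibble(bin = seq_len(total_bins))
  if (nd == 1) {
    df[[cv_names[1]]] <- ctr[[1]]
  } else {
    df[[cv_names[1]]] <- rep(ctr[[1]], times = nb[2])
    df[[cv_names[2]]] <- rep(ctr[[2]], each = nb[1])
  }
  df$count <- count
  df$mean_dV <- unname(mean_dV)
  df$sd_dV <- unname(sd_dV)
  df$anharmonicity <- unname(anh)
  df$free_energy <- unname(f)
  df$masked <- masked
  new_pmf_grid(df, edges, temperature, cv_names)
}

#' Reweighting quality report
#'
#' @param grid a [pmf_grid] from [pmf()].
#' @param boost optional per-frame boost vector for the global SD (otherwise
#'   pooled from per-bin statistics).
#' @return one-row tibble: global boost SD, fraction of masked bins, maximum
#'   and count-weighted mean anharmonicity.
#' @export
reweight_report <- function(grid, boost = NULL) {
  stopifnot(inherits(grid, "pmf_grid"))
  sig <- if (!is.null(boost)) {
    sqrt(mean((boost - mean(boost))^2))
  } else {
    ok <- grid$count > 0
    m <- sum(grid$count[ok] * grid$mean_dV[ok]) / sum(grid$count[ok])
    sqrt(sum(grid$count[ok] * (grid$sd_dV[ok]^2 +
                                 (grid$mean_dV[ok] - m)^2)) /
           sum(grid$count[ok]))
  }
  tibble::tibble(
    sigma_dV = sig,
    masked_fraction = mean(grid$masked),
    max_anharmonicity = max(grid$anharmonicity[grid$count > 0], 0),
    mean_anharmonicity = if (any(grid$count > 0)) {
      sum(grid$anharmonicity[grid$count > 0] * grid$count[grid$count > 0]) /
        sum(grid$count)
    } else 0)
}

#' Local minima of a free-energy surface
#'
#' Finds local minima over the 2-neighbourhood (1D) or 4-neighbourhood (2D)
#' of unmasked bins and filters them by topographic prominence: a minimum is
#' kept when the lowest ridge separating it from any deeper kept minimum
#' lies at least `depth_threshold` kcal/mol above it (union-find watershed;
#' the global minimum is always kept). Results are sorted by free energy and
#' reported at bin centres.
#'
#' @param grid a [pmf_grid].
#' @param depth_threshold minimum well depth (prominence), kcal/mol.
#' @return tibble of minima: bin centre coordinates, `free_energy`,
#'   `prominence` (Inf for the global minimum); may be empty.
#' @export
locate_minima <- function(grid, depth_threshold = 0) {
  stopifnot(inherits(grid, "pmf_grid"))
  edges <- pmf_edges(grid)
  nd <- length(edges)
  nb <- vapply(edges, function(e) length(e) - 1L, integer(1))
  f <- grid$free_energy
  f[grid$masked | is.na(f)] <- Inf
  if (all(!is.finite(f))) stop("grid has no unmasked bins")

  nbrs <- function(b) {
    if (nd == 1) {
      c(if (b > 1) b - 1, if (b < nb[1]) b + 1)
    } else {
      i <- (b - 1) %% nb[1] + 1
      j <- (b - 1) %/% nb[1] + 1
      c(if (i > 1) b - 1, if (i < nb[1]) b + 1,
        if (j > 1) b - nb[1], if (j < nb[2]) b + nb[1])
    }
  }
  is_min <- vapply(seq_along(f), function(b) {
    is.finite(f[b]) && all(f[b] <= f[nbrs(b)])
  }, logical(1))

  ord <- order(f)
  parent <- seq_along(f)
  comp_min <- rep(NA_integer_, length(f)) # deepest bin of each component
  prominence <- rep(NA_real_, length(f))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  active <- rep(FALSE, length(f))
  for (b in ord) {
    if (!is.finite(f[b])) break
    active[b] <- TRUE
    comp_min[b] <- b
    for (nb2 in nbrs(b)) {
      if (!active[nb2]) next
      ra <- find(b); rb <- find(nb2)
      if (ra == rb) next
      ma <- comp_min[ra]; mb <- comp_min[rb]
      shallower <- if (f[ma] <= f[mb]) mb else ma
      deeper <- if (f[ma] <= f[mb]) ma else mb
      if (is_min[shallower] && is.na(prominence[shallower])) {
        prominence[shallower] <- f[b] - f[shallower]
      }
      parent[ra] <- rb
      comp_min[find(rb)] <- deeper
    }
  }
  glob <- ord[1]
  prominence[glob] <- Inf
  keep <- which(is_min & (is.na(prominence) | prominence >= depth_threshold))
  # minima never merged kept with Inf prominence (isolated basins)
  prominence[keep][is.na(prominence[keep])] <- Inf
  keep <- keep[f[keep] < Inf]
  keep <- keep[order(f[keep])]
  ctr <- lapply(seq_len(nd), function(d) {
    e <- edges[[d]]; (e[-1] + e[-length(e)]) / 2
  })
  nm <- attr(grid, "cv_names")
  out <- tibble::tibble(bin = keep)
  if (nd == 1) {
    out[[nm[1]]] <- ctr[[1]][keep]
  } else {
    out[[nm[1]]] <- ctr[[1]][(keep - 1) %% nb[1] + 1]
    out[[nm[2]]] <- ctr[[2]][(keep - 1) %/% nb[1] + 1]
  }
  out$free_energy <- f[keep]
  out$prominence <- prominence[keep]
  out
}

#' Compare two free-energy grids on identical bins
#'
#' @param grid_a,grid_b [pmf_grid] objects with identical bin edges.
#' @param min_count only bins with at least this many samples in `grid_a`
#'   enter the comparison (reference grids with `count = NA` always enter).
#' @return RMSE of the free energies over the compared bins, kcal/mol.
#' @export
pmf_rmse <- function(grid_a, grid_b, min_count = 10) {
  ea <- pmf_edges(grid_a); eb <- pmf_edges(grid_b)
  stopifnot(length(ea) == length(eb))
  for (d in seq_along(ea)) {
    if (length(ea[[d]]) != length(eb[[d]]) ||
        max(abs(ea[[d]] - eb[[d]])) > 1e-9) {
      stop("grids must share identical bin edges")
    }
  }
  ok <- !grid_a$masked & !grid_b$masked &
    (is.na(grid_a$count) | grid_a$count >= min_count) &
    (is.na(grid_b$count) | grid_b$count >= min_count)
  if (!any(ok)) stop("no comparable bins")
  d <- grid_a$free_energy[ok] - grid_b$free_energy[ok]
  sqrt(mean(d^2))
}

#' Barrier height of a 1D double-well profile
#'
#' Free energy of the highest point on the path between the two deepest
#' minima, relative to the global minimum. `NA` if any intervening bin is
#' masked.
#'
#' @param grid a 1D [pmf_grid].
#' @return barrier height, kcal/mol.
#' @export
pmf_barrier_1d <- function(grid) {
  stopifnot(length(pmf_edges(grid)) == 1)
  mins <- locate_minima(grid)
  if (nrow(mins) < 2) return(NA_real_)
  b <- sort(mins$bin[1:2])
  path <- grid$free_energy[b[1]:b[2]]
  if (any(is.na(path))) return(NA_real_)
  max(path) - min(grid$free_energy, na.rm = TRUE)
}
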