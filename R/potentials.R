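#' Analytic potential specifications
#'
#' A `potential_spec` describes an analytic energy surface on a bounded box
#' with reflecting walls: either a 1D polynomial (`kind = "poly"`, coefficient
#' vector `coef` with `coef[i]` multiplying `x^(i-1)`) or a 2D sum of inverted
#' Gaussian wells (`kind = "gauss2d"`). Energies are kcal/mol, coordinates
#' Angstrom. Named minima are true local minima of the functional form
#' (gradient norm < 1e-6 at each, validated at construction).
#'
#' @name potential_spec
NULL

new_potential_spec <- function(kind, dimensionality, params, domain, minima,
                               mass = 12) {
  spec <- structure(
    list(kind = kind, dimensionality = as.integer(dimensionality),
         params = params, domain = domain, minima = minima, mass = mass),
    class = "potential_spec")
  g <- potential_gradient(spec, as.matrix(minima[, seq_len(dimensionality)]))
  gn <- sqrt(rowSums(matrix(g, ncol = dimensionality)^2))
  if (any(gn > 1e-6)) {
    stop("named minima are not stationary (gradient norm ",
         format(max(gn)), ")")
  }
  spec
}

#' @export
print.potential_spec <- function(x, ...) {
  cat(sprintf("<potential_spec> %s, %dD, %d named minima, mass %.3g amu\n",
              x$kind, x$dimensionality, nrow(x$minima), x$mass))
  invisible(x)
}

#' Evaluate a potential and its gradient
#'
#' @param spec a [potential_spec].
#' @param x coordinates: numeric vector for 1D specs (vectorised), or an
#'   `n x 2` matrix for 2D specs.
#' @return `potential_energy`: energies in kcal/mol; `potential_gradient`:
#'   gradient(s) in kcal/mol/A, same shape as `x`.
#' @export
potential_energy <- function(spec, x) {
  stopifnot(inherits(spec, "potential_spec"))
  if (spec$kind == "poly") {
    x <- as.numeric(x)
    poly_eval(spec$params$coef, x)
  } else if (spec$kind == "gauss2d") {
    x <- matrix(x, ncol = 2)
    ctr <- spec$params$centers
    v <- rep(0, nrow(x))
    for (i in seq_len(nrow(ctr))) {
      d2 <- (x[, 1] - ctr[i, 1])^2 + (x[, 2] - ctr[i, 2])^2
      v <- v - spec$params$depths[i] * exp(-d2 / (2 * spec$params$width^2))
    }
    v
  } else stop("unknown potential kind: ", spec$kind)
}

#' @rdname potential_energy
#' @export
potential_gradient <- function(spec, x) {
  stopifnot(inherits(spec, "potential_spec"))
  if (spec$kind == "poly") {
    x <- as.numeric(x)
    poly_eval(poly_deriv(spec$params$coef), x)
  } else if (spec$kind == "gauss2d") {
    x <- matrix(x, ncol = 2)
    ctr <- spec$params$centers
    g <- matrix(0, nrow(x), 2)
    w2 <- spec$params$width^2
    for (i in seq_len(nrow(ctr))) {
      dx <- x[, 1] - ctr[i, 1]; dy <- x[, 2] - ctr[i, 2]
      e <- spec$params$depths[i] * exp(-(dx^2 + dy^2) / (2 * w2)) / w2
      g[, 1] <- g[, 1] + dx * e
      g[, 2] <- g[, 2] + dy * e
    }
    g
  } else stop("unknown potential kind: ", spec$kind)
}

poly_eval <- function(coef, x) {
  v <- rep(0, length(x))
  for (i in rev(seq_along(coef))) v <- v * x + coef[i]
  v
}

poly_deriv <- function(coef) {
  n <- length(coef)
  if (n <= 1) return(0)
  coef[-1] * seq_len(n - 1)
}

# real stationary points of a 1D polynomial, sorted; roots polished by Newton
poly_stationary <- function(coef) {
  d <- poly_deriv(coef)
  d2 <- poly_deriv(d)
  r <- polyroot(d)
  re <- Re(r)[abs(Im(r)) < 1e-6]
  for (i in 1:3) {
    slope <- poly_eval(d2, re)
    ok <- abs(slope) > 1e-12
    re[ok] <- re[ok] - poly_eval(d, re[ok]) / slope[ok]
  }
  sort(unique(round(re, 9)))
}

#' Two-well 1D quartic potential
#'
#' Constructs a quartic double well `V(x) = c4 x^4 + c2 x^2 + c1 x + c0` whose
#' two minima are `separation` apart, whose barrier top lies `barrier`
#' kcal/mol above the lower (right-hand) minimum, and whose left well sits
#' `asymmetry` kcal/mol above the right well. The global minimum is shifted
#' to zero. With `asymmetry = 0` this is exactly
#' `barrier * ((2x/separation)^2 - 1)^2`.
#'
#' @param barrier barrier height above the lower minimum, kcal/mol (> 0).
#' @param separation distance between the two minima, A (> 0).
#' @param asymmetry well-depth difference, kcal/mol (0 <= asymmetry < barrier).
#' @param mass particle mass in amu used when the spec is simulated.
#' @return a [potential_spec] with named minima and an analytic gradient.
#' @examples
#' dw <- make_double_well(6, 4)
#' potential_energy(dw, c(-2, 0, 2)) # 0, 6, 0
#' @export
make_double_well <- function(barrier, separation, asymmetry = 0, mass = 12) {
  if (!is.numeric(barrier) || barrier <= 0) stop("barrier must be > 0")
  if (!is.numeric(separation) || separation <= 0) stop("separation must be > 0")
  if (!is.numeric(asymmetry) || asymmetry < 0 || asymmetry >= barrier) {
    stop("asymmetry must lie in [0, barrier)")
  }
  a <- separation / 2
  sym <- c(0, 0, -2 * barrier / a^2, 0, barrier / a^4) # barrier*((x/a)^2-1)^2 - barrier
  coef <- sym
  if (asymmetry > 0) {
    # solve (c4, c2, c1) so that separation, barrier and well-depth
    # difference are met exactly at the true stationary points
    resid <- function(p) {
      cf <- c(0, p[3], p[2], 0, p[1])
      st <- poly_stationary(cf)
      if (length(st) != 3) return(rep(1e3, 3))
      v <- poly_eval(cf, st)
      # sign convention: the right-hand well is the deeper one
      c((st[3] - st[1]) - separation,
        (v[2] - min(v[1], v[3])) - barrier,
        (v[1] - v[3]) - asymmetry)
    }
    sol <- stats::optim(c(sym[5], sym[3], -asymmetry / separation),
                        function(p) sum(resid(p)^2), method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-15))
    if (sol$value > 1e-10) stop("double-well construction did not converge")
    coef <- c(0, sol$par[3], sol$par[2], 0, sol$par[1])
  }
  st <- poly_stationary(coef)
  v <- poly_eval(coef, st)
  coef[1] <- coef[1] - min(v[c(1, 3)])
  v <- poly_eval(coef, st)
  minima <- tibble::tibble(x = st[c(1, 3)], energy = v[c(1, 3)])
  domain <- c(st[1] - separation, st[3] + separation)
  new_potential_spec("poly", 1,
                     list(coef = coef, barrier_top = st[2],
                          barrier = barrier, separation = separation,
                          asymmetry = asymmetry),
                     domain = matrix(domain, 1, 2), minima = minima,
                     mass = mass)
}

#' Harmonic 1D potential
#'
#' `V(x) = 0.5 * k_spring * x^2`, mainly used as a reference system with
#' closed-form thermodynamics.
#'
#' @param k_spring force constant, kcal/mol/A^2.
#' @param extent half-width of the reflecting box, A.
#' @param mass particle mass, amu.
#' @return a [potential_spec].
#' @export
make_harmonic_well <- function(k_spring = 1, extent = 10, mass = 12) {
  stopifnot(k_spring > 0, extent > 0)
  new_potential_spec("poly", 1, list(coef = c(0, 0, k_spring / 2)),
                     domain = matrix(c(-extent, extent), 1, 2),
                     minima = tibble::tibble(x = 0, energy = 0), mass = mass)
}

#' 2D multi-well Gaussian potential
#'
#' Sum of inverted Gaussian wells
#' `V(r) = -sum_i depth_i exp(-|r - c_i|^2 / (2 width^2))` on a bounded box.
#' Wells must be far enough apart that each centre remains a true local
#' minimum (validated).
#'
#' @param centers `k x 2` matrix of well centres, A.
#' @param depths well depths, kcal/mol (length k, > 0).
#' @param width common Gaussian width, A.
#' @param box half-width of the square reflecting box, A.
#' @param mass particle mass, amu.
#' @return a [potential_spec] with `kind = "gauss2d"`.
#' @examples
#' fw <- make_wells_2d(rbind(c(-3,-3), c(3,-3), c(-3,3), c(3,3)),
#'                     depths = c(5, 4, 4, 5), width = 1)
#' @export
make_wells_2d <- function(centers, depths, width = 1, box = NULL, mass = 12) {
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == 2, length(depths) == nrow(centers),
            all(depths > 0), width > 0)
  if (is.null(box)) box <- max(abs(centers)) + 3 * width
  spec <- new_potential_spec(
    "gauss2d", 2, list(centers = centers, depths = depths, width = width),
    domain = rbind(c(-box, box), c(-box, box)),
    minima = tibble::tibble(x = centers[, 1], y = centers[, 2],
                            energy = NA_real_),
    mass = mass)
  spec$minima$energy <- potential_energy(spec, centers)
  spec
}

#' Reference free-energy profile by direct Boltzmann integration
#'
#' Computes the exact (to quadrature accuracy) free energy per bin,
#' `F(bin) = -kB T log integral_bin exp(-V / kB T)`, normalised so that the
#' minimum over bins is zero. This is the simulation-free ground truth
#' against which reweighted profiles are compared. Bins are half-open
#' `[lo, hi)` with the last bin closed.
#'
#' @param potential a [potential_spec].
#' @param grid number of bins (scalar or per-dimension vector), or a list of
#'   bin-edge vectors (one per dimension) covering the region of interest.
#' @param temperature temperature, K.
#' @param subdiv quadrature points per bin and dimension.
#' @return a [pmf_grid] with `count = NA` and zero boost corrections.
#' @export
reference_pmf <- function(potential, grid = 50, temperature = 300,
                          subdiv = 32) {
  stopifnot(inherits(potential, "potential_spec"))
  nd <- potential$dimensionality
  edges <- resolve_edges(grid, potential$domain, nd)
  for (d in seq_len(nd)) {
    if (any(diff(edges[[d]]) <= 0)) stop("zero-measure or inverted bins")
    mn <- as.matrix(potential$minima)[, d]
    if (any(mn < edges[[d]][1] | mn > tail(edges[[d]], 1))) {
      warning("grid does not cover all named minima")
    }
  }
  beta <- 1 / thermal_energy(temperature)
  if (nd == 1) {
    e <- edges[[1]]
    nb <- length(e) - 1
    z <- numeric(nb)
    for (b in seq_len(nb)) {
      # composite Simpson inside the bin
      xs <- seq(e[b], e[b + 1], length.out = subdiv + 1)
      w <- simpson_weights(subdiv) * (e[b + 1] - e[b]) / subdiv
      z[b] <- sum(w * exp(-beta * potential_energy(potential, xs)))
    }
    f <- -log(z) / beta
    df <- tibble::tibble(bin = seq_len(nb),
                         x = (e[-1] + e[-(nb + 1)]) / 2,
                         count = NA_integer_, mean_dV = 0, sd_dV = 0,
                         anharmonicity = 0,
                         free_energy = f - min(f), masked = FALSE)
    new_pmf_grid(df, edges, temperature, "x")
  } else {
    ex <- edges[[1]]; ey <- edges[[2]]
    nbx <- length(ex) - 1; nby <- length(ey) - 1
    sub <- max(8, subdiv %/% 2)
    z <- matrix(0, nbx, nby)
    for (i in seq_len(nbx)) {
      xs <- ex[i] + (seq_len(sub) - 0.5) * (ex[i + 1] - ex[i]) / sub
      for (j in seq_len(nby)) {
        ys <- ey[j] + (seq_len(sub) - 0.5) * (ey[j + 1] - ey[j]) / sub
        pts <- cbind(rep(xs, times = sub), rep(ys, each = sub))
        da <- (ex[i + 1] - ex[i]) * (ey[j + 1] - ey[j]) / sub^2
        z[i, j] <- sum(exp(-beta * potential_energy(potential, pts))) * da
      }
    }
    f <- -log(z) / beta
    df <- tibble::tibble(
      bin = seq_len(nbx * nby),
      x = rep((ex[-1] + ex[-(nbx + 1)]) / 2, times = nby),
      y = rep((ey[-1] + ey[-(nby + 1)]) / 2, each = nbx),
      count = NA_integer_, mean_dV = 0, sd_dV = 0, anharmonicity = 0,
      free_energy = as.vector(f) - min(f), masked = FALSE)
    new_pmf_grid(df, edges, temperature, c("x", "y"))
  }
}

simpson_weights <- function(n) {
  stopifnot(n %% 2 == 0)
  w <- rep(c(4, 2), length.out = n - 1)
  c(1, w, 1) / 3
}

resolve_edges <- function(grid, domain, nd) {
  if (is.list(grid)) {
    stopifnot(length(grid) == nd)
    return(lapply(grid, as.numeric))
  }
  nb <- rep(as.integer(grid), length.out = nd)
  lapply(seq_len(nd), function(d) {
    seq(domain[d, 1], domain[d, 2], length.out = nb[d] + 1)
  })
}

#' Planted-conformation trajectory generator
#'
#' Draws frames from a small set of template coordinate sets plus isotropic
#' Gaussian noise, recording the true state label of every frame. Used as
#' ground truth for clustering and RMSD analyses.
#'
#' @param n_frames number of frames.
#' @param states list of `p x 3` template coordinate matrices (same p).
#' @param noise_sd isotropic Gaussian noise per coordinate, A (>= 0).
#' @param occupancies state probabilities (sums to 1).
#' @param seed RNG seed; the generator is bit-reproducible for a fixed seed.
#' @return a [new_trajectory()] object; `metadata$labels` holds the planted
#'   state of every frame.
#' @export
plant_conformations <- function(n_frames, states, noise_sd = 0,
                                occupancies = NULL, seed = 1) {
  if (length(states) == 0) stop("states must be a non-empty list")
  states <- lapply(states, function(s) matrix(as.numeric(s), ncol = 3))
  p <- nrow(states[[1]])
  if (!all(vapply(states, nrow, integer(1)) == p)) {
    stop("all state templates must have the same number of particles")
  }
  if (is.null(occupancies)) occupancies <- rep(1 / length(states), length(states))
  if (abs(sum(occupancies) - 1) > 1e-8) stop("occupancies must sum to 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  labels <- sample.int(length(states), n_frames, replace = TRUE,
                       prob = occupancies)
  coords <- array(0, dim = c(n_frames, p, 3))
  for (f in seq_len(n_frames)) {
    coords[f, , ] <- states[[labels[f]]] +
      if (noise_sd > 0) matrix(rnorm(3 * p, sd = noise_sd), p, 3) else 0
  }
  new_trajectory(coords, period_ps = 1,
                 metadata = list(labels = labels, seed = seed,
                                 noise_sd = noise_sd,
                                 occupancies = occupancies))
}
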