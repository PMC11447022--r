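#' Bead-chain model with a separable torsional term
#'
#' A minimal polymer-like system whose total potential is a sum of harmonic
#' bonds, harmonic angles, cosine torsions and a soft pairwise repulsion.
#' The torsional energy is tracked separately from the total at every frame,
#' which is what the dual-boost protocol requires (one boost on the torsional
#' term, one on the total potential term).
#'
#' Terms (kcal/mol, A, rad): bonds `0.5 kb (r - r0)^2`; angles
#' `0.5 ka (theta - theta0)^2`; torsions `amp (1 + cos(per * phi - phase))`
#' with `amp = torsion_barrier / 2`, `per = 3`, `phase = 0` (zero at the
#' all-trans geometry, barrier `torsion_barrier` between rotamers); repulsion
#' `eps (1 - r/rcut)^2` for `r < rcut` between beads at least 3 bonds apart.
#'
#' @param n_beads number of beads (>= 4, so at least one torsion).
#' @param torsion_barrier rotamer barrier, kcal/mol (>= 0).
#' @param kb,r0 bond force constant (kcal/mol/A^2) and length (A).
#' @param ka,theta0 angle force constant (kcal/mol/rad^2) and angle (rad).
#' @param eps,rcut soft-repulsion strength (kcal/mol) and cutoff (A).
#' @param mass per-bead mass, amu.
#' @return an object of class `bead_system` with `n_beads - 3` torsions.
#' @examples
#' bs <- make_bead_chain(6, torsion_barrier = 3)
#' nrow(bs$torsions) # 3
#' @export
make_bead_chain <- function(n_beads, torsion_barrier = 3, kb = 300, r0 = 1.53,
                            ka = 40, theta0 = 111 * pi / 180,
                            eps = 1, rcut = 2.0, mass = 12) {
  n_beads <- as.integer(n_beads)
  if (n_beads < 4) stop("n_beads must be >= 4 (at least one torsion)")
  if (torsion_barrier < 0) stop("torsion_barrier must be >= 0")
  bonds <- tibble::tibble(i = 1:(n_beads - 1), j = 2:n_beads, k = kb, r0 = r0)
  angles <- if (n_beads >= 3) {
    tibble::tibble(i = 1:(n_beads - 2), j = 2:(n_beads - 1), k = 3:n_beads,
                   ka = ka, theta0 = theta0)
  } else tibble::tibble()
  torsions <- tibble::tibble(i = 1:(n_beads - 3), j = 2:(n_beads - 2),
                             k = 3:(n_beads - 1), l = 4:n_beads,
                             amp = torsion_barrier / 2, per = 3L, phase = 0)
  structure(list(n_beads = n_beads, bonds = bonds, angles = angles,
                 torsions = torsions, eps = eps, rcut = rcut,
                 masses = rep(mass, n_beads),
                 torsion_barrier = torsion_barrier,
                 geom = list(r0 = r0, theta0 = theta0)),
            class = "bead_system")
}

#' @export
print.bead_system <- function(x, ...) {
  cat(sprintf("<bead_system> %d beads, %d torsions (barrier %.3g kcal/mol)\n",
              x$n_beads, nrow(x$torsions), x$torsion_barrier))
  invisible(x)
}

#' All-trans starting coordinates for a bead chain
#'
#' Planar zigzag with the system's equilibrium bond length and angle; all
#' torsions are trans (phi = 180 deg), where the torsional energy is zero.
#'
#' @param system a `bead_system`.
#' @return `n_beads x 3` coordinate matrix.
#' @export
bead_start_coords <- function(system) {
  stopifnot(inherits(system, "bead_system"))
  n <- system$n_beads
  r0 <- system$geom$r0; th <- system$geom$theta0
  xy <- matrix(0, n, 3)
  step_x <- r0 * sin(th / 2)
  step_y <- r0 * cos(th / 2)
  for (i in seq_len(n)) {
    xy[i, 1] <- (i - 1) * step_x
    xy[i, 2] <- if (i %% 2 == 0) step_y else 0
  }
  xy
}

#' Energy terms of a bead system
#'
#' @param system a `bead_system`.
#' @param coords `n_beads x 3` matrix, A.
#' @return list with `total`, `torsional` and `non_torsional` energies in
#'   kcal/mol; `total == torsional + non_torsional` to machine precision.
#' @export
bead_energy <- function(system, coords) {
  coords <- matrix(coords, ncol = 3)
  eb <- 0
  for (b in seq_len(nrow(system$bonds))) {
    d <- coords[system$bonds$j[b], ] - coords[system$bonds$i[b], ]
    r <- sqrt(sum(d^2))
    eb <- eb + 0.5 * system$bonds$k[b] * (r - system$bonds$r0[b])^2
  }
  ea <- 0
  if (nrow(system$angles) > 0) {
    for (a in seq_len(nrow(system$angles))) {
      th <- bead_angle(coords, system$angles$i[a], system$angles$j[a],
                       system$angles$k[a])
      ea <- ea + 0.5 * system$angles$ka[a] * (th - system$angles$theta0[a])^2
    }
  }
  et <- 0
  for (t in seq_len(nrow(system$torsions))) {
    phi <- bead_dihedral(coords, system$torsions$i[t], system$torsions$j[t],
                         system$torsions$k[t], system$torsions$l[t])
    et <- et + system$torsions$amp[t] *
      (1 + cos(system$torsions$per[t] * phi - system$torsions$phase[t]))
  }
  er <- 0
  n <- system$n_beads
  for (i in seq_len(n - 3)) {
    for (j in (i + 3):n) {
      r <- sqrt(sum((coords[j, ] - coords[i, ])^2))
      if (r < system$rcut) er <- er + system$eps * (1 - r / system$rcut)^2
    }
  }
  non_t <- eb + ea + er
  list(total = non_t + et, torsional = et, non_torsional = non_t)
}

bead_angle <- function(coords, i, j, k) {
  u <- coords[i, ] - coords[j, ]; v <- coords[k, ] - coords[j, ]
  ct <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, ct)))
}

bead_dihedral <- function(coords, i, j, k, l) {
  b1 <- coords[j, ] - coords[i, ]
  b2 <- coords[k, ] - coords[j, ]
  b3 <- coords[l, ] - coords[k, ]
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Analytic gradient of the bead-system potential
#'
#' @param system a `bead_system`.
#' @param coords `n_beads x 3` matrix.
#' @return list of `n_beads x 3` gradient matrices (kcal/mol/A):
#'   `total`, `torsional`, `non_torsional`.
#' @export
bead_gradient <- function(system, coords) {
  coords <- matrix(coords, ncol = 3)
  n <- system$n_beads
  g_nt <- matrix(0, n, 3)
  for (b in seq_len(nrow(system$bonds))) {
    i <- system$bonds$i[b]; j <- system$bonds$j[b]
    d <- coords[j, ] - coords[i, ]
    r <- sqrt(sum(d^2))
    f <- system$bonds$k[b] * (r - system$bonds$r0[b]) * d / r
    g_nt[i, ] <- g_nt[i, ] - f
    g_nt[j, ] <- g_nt[j, ] + f
  }
  for (a in seq_len(nrow(system$angles))) {
    i <- system$angles$i[a]; j <- system$angles$j[a]; k <- system$angles$k[a]
    u <- coords[i, ] - coords[j, ]; v <- coords[k, ] - coords[j, ]
    lu <- sqrt(sum(u^2)); lv <- sqrt(sum(v^2))
    ct <- sum(u * v) / (lu * lv)
    ct <- pmin(1, pmax(-1, ct))
    th <- acos(ct)
    st <- sqrt(max(1e-12, 1 - ct^2))
    dEdth <- system$angles$ka[a] * (th - system$angles$theta0[a])
    dth_di <- (ct * u / lu - v / lv) / (lu * st)
    dth_dk <- (ct * v / lv - u / lu) / (lv * st)
    g_nt[i, ] <- g_nt[i, ] + dEdth * dth_di
    g_nt[k, ] <- g_nt[k, ] + dEdth * dth_dk
    g_nt[j, ] <- g_nt[j, ] - dEdth * (dth_di + dth_dk)
  }
  for (i in seq_len(n - 3)) {
    for (j in (i + 3):n) {
      d <- coords[j, ] - coords[i, ]
      r <- sqrt(sum(d^2))
      if (r < system$rcut) {
        f <- -2 * system$eps * (1 - r / system$rcut) / system$rcut * d / r
        g_nt[i, ] <- g_nt[i, ] - f
        g_nt[j, ] <- g_nt[j, ] + f
      }
    }
  }
  g_t <- matrix(0, n, 3)
  for (t in seq_len(nrow(system$torsions))) {
    i <- system$torsions$i[t]; j <- system$torsions$j[t]
    k <- system$torsions$k[t]; l <- system$torsions$l[t]
    b1 <- coords[j, ] - coords[i, ]
    b2 <- coords[k, ] - coords[j, ]
    b3 <- coords[l, ] - coords[k, ]
    n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
    lb2 <- sqrt(sum(b2^2))
    phi <- bead_dihedral(coords, i, j, k, l)
    per <- system$torsions$per[t]
    dEdphi <- -system$torsions$amp[t] * per *
      sin(per * phi - system$torsions$phase[t])
    n1sq <- sum(n1^2); n2sq <- sum(n2^2)
    if (n1sq < 1e-12 || n2sq < 1e-12) next # collinear, force undefined -> 0
    dphi_d1 <- lb2 / n1sq * n1
    dphi_d4 <- -lb2 / n2sq * n2
    s12 <- sum(b1 * b2) / lb2^2
    s32 <- sum(b3 * b2) / lb2^2
    dphi_d2 <- -(1 + s12) * dphi_d1 + s32 * dphi_d4
    dphi_d3 <- s12 * dphi_d1 - (1 + s32) * dphi_d4
    g_t[i, ] <- g_t[i, ] + dEdphi * dphi_d1
    g_t[j, ] <- g_t[j, ] + dEdphi * dphi_d2
    g_t[k, ] <- g_t[k, ] + dEdphi * dphi_d3
    g_t[l, ] <- g_t[l, ] + dEdphi * dphi_d4
  }
  list(total = g_nt + g_t, torsional = g_t, non_torsional = g_nt)
}
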