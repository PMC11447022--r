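#' Kabsch superposition
#'
#' Least-squares optimal rigid rotation and translation of paired coordinate
#' set `B` onto `A` (reflections excluded, `det = +1`). The returned
#' `rotation` acts on row vectors: `fitted = (B - centroid_B) %*% rotation +
#' centroid_A`, and `rmsd` is the minimised value.
#'
#' @param A,B `n x 3` paired coordinate matrices, `n >= 3`, non-collinear.
#' @return an object of class `superposition_result` with fields `rotation`
#'   (3x3, orthonormal), `translation` (length 3: `centroid_A - centroid_B
#'   %*% rotation`... applied as `B %*% rotation + translation`), `rmsd` (A)
#'   and `n_pairs`.
#' @examples
#' A <- matrix(rnorm(12), 4, 3)
#' kabsch(A, A)$rmsd # 0
#' @export
kabsch <- function(A, B) {
  A <- matrix(as.numeric(as.matrix(A)), ncol = 3)
  B <- matrix(as.numeric(as.matrix(B)), ncol = 3)
  n <- nrow(A)
  if (nrow(B) != n) stop("coordinate sets must be paired (equal length)")
  if (n < 3) stop("need at least 3 paired points")
  cA <- colMeans(A); cB <- colMeans(B)
  Ac <- sweep(A, 2, cA); Bc <- sweep(B, 2, cB)
  for (M in list(Ac, Bc)) {
    sv <- svd(M)$d
    if (sv[2] < 1e-8 * max(sv[1], 1e-12)) {
      stop("degenerate (collinear) coordinate set")
    }
  }
  H <- crossprod(Bc, Ac)
  s <- svd(H)
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- Bc %*% R
  rmsd <- sqrt(mean(rowSums((Ac - fitted)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cA - cB %*% R),
                 rmsd = rmsd, n_pairs = n),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f A over %d pairs (angle %.2f deg)\n",
              x$rmsd, x$n_pairs, rotation_angle(x$rotation)))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param coords `n x 3` matrix.
#' @param sp a `superposition_result`.
#' @return transformed `n x 3` matrix.
#' @export
apply_superposition <- function(coords, sp) {
  sweep(as.matrix(coords) %*% sp$rotation, 2, sp$translation, "+")
}

#' Rotation angle of a 3x3 rotation matrix
#'
#' `theta = acos((tr(R) - 1) / 2)`, in degrees, in `[0, 180]`.
#' @param R orthonormal 3x3 matrix.
#' @return angle in degrees.
#' @export
rotation_angle <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

# raw (no superposition) rmsd between paired sets
raw_rmsd <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

resolve_selection <- function(traj, selection) {
  p <- n_particles(traj)
  if (is.null(selection)) return(seq_len(p))
  selection <- as.integer(selection)
  if (length(selection) == 0) stop("empty selection")
  if (any(selection < 1 | selection > p)) stop("selection out of range")
  selection
}

#' Particles within a radius of a group
#'
#' Resolves a "within r A of group G" selection on a single (reference)
#' frame; the result is a fixed index set, not re-evaluated per frame.
#'
#' @param coords `p x 3` reference coordinates (e.g. `frame_coords(traj, 1)`).
#' @param group indices of the group G.
#' @param radius cutoff, A.
#' @param include_group include G itself in the result.
#' @return integer particle indices (error if empty).
#' @export
select_within <- function(coords, group, radius, include_group = FALSE) {
  coords <- matrix(coords, ncol = 3)
  stopifnot(length(group) >= 1, radius >= 0)
  d2 <- matrix(Inf, nrow(coords), length(group))
  for (gi in seq_along(group)) {
    d2[, gi] <- rowSums(sweep(coords, 2, coords[group[gi], ])^2)
  }
  hit <- which(apply(d2, 1, min) <= radius^2)
  if (!include_group) hit <- setdiff(hit, group)
  else hit <- union(hit, group)
  if (length(hit) == 0) stop("selection resolves to no particles")
  sort(hit)
}

#' Distance time course between two particles
#'
#' @param traj a `gamd_trajectory`.
#' @param a,b single particle indices.
#' @return tibble with `frame`, `time_ps`, `distance` (A).
#' @export
distance_timecourse <- function(traj, a, b) {
  if (length(a) != 1 || length(b) != 1) {
    stop("a and b must each select exactly one particle")
  }
  a <- resolve_selection(traj, a); b <- resolve_selection(traj, b)
  d <- sqrt(rowSums((traj$coords[, a, , drop = FALSE] -
                       traj$coords[, b, , drop = FALSE])[, 1, ]^2))
  tibble::tibble(frame = seq_len(n_frames(traj)),
                 time_ps = seq_len(n_frames(traj)) * traj$period_ps,
                 distance = d)
}

#' RMSD time course against a reference conformation
#'
#' @param traj a `gamd_trajectory`.
#' @param reference `p x 3` reference coordinates (full particle set).
#' @param selection particle indices measured (default all).
#' @param superpose Kabsch-align each frame onto the reference selection
#'   before measuring.
#' @return tibble with `frame`, `time_ps`, `rmsd` (A).
#' @export
rmsd_timecourse <- function(traj, reference, selection = NULL,
                            superpose = TRUE) {
  sel <- resolve_selection(traj, selection)
  reference <- matrix(reference, ncol = 3)
  if (nrow(reference) != n_particles(traj)) {
    stop("reference must have one row per trajectory particle")
  }
  ref_sel <- reference[sel, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    fc <- frame_coords(traj, f)[sel, , drop = FALSE]
    if (superpose) kabsch(ref_sel, fc)$rmsd else raw_rmsd(ref_sel, fc)
  }, numeric(1))
  tibble::tibble(frame = seq_len(n_frames(traj)),
                 time_ps = seq_len(n_frames(traj)) * traj$period_ps,
                 rmsd = vals)
}

#' Per-particle root-mean-square fluctuation
#'
#' Each frame is superposed onto the reference on the stated selection
#' (Kabsch); the RMSF of particle i is then
#' `sqrt(mean(|x_i - <x_i>|^2))` over frames, about the particle's own mean
#' position. Invariant to a rigid-body motion applied to every frame.
#'
#' @param traj a `gamd_trajectory` with >= 2 frames.
#' @param reference `p x 3` reference (default: first frame).
#' @param selection particle indices used for the superposition (default
#'   all); RMSF is still reported for every particle.
#' @return tibble with `particle`, `rmsf` (A).
#' @export
rmsf <- function(traj, reference = NULL, selection = NULL) {
  nf <- n_frames(traj)
  if (nf < 2) stop("RMSF needs at least 2 frames")
  sel <- resolve_selection(traj, selection)
  if (is.null(reference)) reference <- frame_coords(traj, 1)
  reference <- matrix(reference, ncol = 3)
  p <- n_particles(traj)
  aligned <- array(0, dim = c(nf, p, 3))
  ref_sel <- reference[sel, , drop = FALSE]
  for (f in seq_len(nf)) {
    fc <- frame_coords(traj, f)
    sp <- kabsch(ref_sel, fc[sel, , drop = FALSE])
    aligned[f, , ] <- apply_superposition(fc, sp)
  }
  means <- apply(aligned, c(2, 3), mean)
  dev2 <- array(0, dim = c(nf, p))
  for (k in 1:3) {
    dev2 <- dev2 + sweep(aligned[, , k], 2, means[, k])^2
  }
  tibble::tibble(particle = seq_len(p), rmsf = sqrt(colMeans(dev2)))
}

#' Per-particle RMSF difference between two trajectories
#'
#' Flexibility change profile, sign convention `A - B`.
#'
#' @param traj_a,traj_b trajectories over the same particles.
#' @param ... passed to [rmsf()].
#' @return tibble with `particle`, `rmsf_a`, `rmsf_b`, `d_rmsf = rmsf_a -
#'   rmsf_b`.
#' @export
rmsf_difference <- function(traj_a, traj_b, ...) {
  ra <- rmsf(traj_a, ...); rb <- rmsf(traj_b, ...)
  stopifnot(nrow(ra) == nrow(rb))
  tibble::tibble(particle = ra$particle, rmsf_a = ra$rmsf, rmsf_b = rb$rmsf,
                 d_rmsf = ra$rmsf - rb$rmsf)
}

# pairwise superposed RMSD matrix over a selection
pairwise_rmsd <- function(traj, selection = NULL) {
  sel <- resolve_selection(traj, selection)
  nf <- n_frames(traj)
  cs <- vector("list", nf)
  g <- numeric(nf)
  for (f in seq_len(nf)) {
    m <- frame_coords(traj, f)[sel, , drop = FALSE]
    m <- sweep(m, 2, colMeans(m))
    cs[[f]] <- m
    g[f] <- sum(m^2)
  }
  n <- length(sel)
  D <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) {
    ci <- cs[[i]]
    for (j in (i + 1):nf) {
      H <- crossprod(cs[[j]], ci)
      s <- svd(H)
      d <- sign(det(s$u) * det(s$v))
      tr <- s$d[1] + s$d[2] + d * s$d[3]
      D[i, j] <- D[j, i] <- sqrt(max(0, (g[i] + g[j] - 2 * tr) / n))
    }
  }
  D
}

#' Hierarchical agglomerative clustering of frames at an RMSD cutoff
#'
#' Average-linkage agglomeration on the pairwise superposed-RMSD matrix of
#' the selected particles; merging stops once no inter-cluster linkage
#' distance is below `cutoff`. Each cluster reports its medoid frame (the
#' member minimising the mean RMSD to its own cluster).
#'
#' @param traj a `gamd_trajectory`.
#' @param selection particle indices clustered on (default all).
#' @param cutoff RMSD cutoff, A.
#' @return an object of class `cluster_set`: `labels` (frame to cluster,
#'   clusters numbered by decreasing size), `medoids` tibble, `cutoff`.
#' @export
cluster_frames <- function(traj, selection = NULL, cutoff = 2.0) {
  sel <- resolve_selection(traj, selection)
  D <- pairwise_rmsd(traj, sel)
  nf <- nrow(D)
  if (nf < 2) stop("need at least 2 frames to cluster")
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  raw <- stats::cutree(hc, h = cutoff)
  # renumber by decreasing cluster size (ties by first occurrence)
  sizes <- sort(table(raw), decreasing = TRUE)
  remap <- stats::setNames(seq_along(sizes), names(sizes))
  labels <- as.integer(remap[as.character(raw)])
  medoids <- vapply(seq_along(sizes), function(k) {
    members <- which(labels == k)
    if (length(members) == 1) return(members)
    sub <- D[members, members, drop = FALSE]
    members[which.min(rowMeans(sub))]
  }, integer(1))
  structure(list(labels = labels,
                 medoids = tibble::tibble(cluster = seq_along(sizes),
                                          frame = medoids,
                                          size = as.integer(sizes)),
                 cutoff = cutoff, n_frames = nf, hclust = hc),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d frames -> %d clusters at %.2f A cutoff\n",
              x$n_frames, nrow(x$medoids), x$cutoff))
  print(x$medoids)
  invisible(x)
}

#' Best label agreement against a planted truth
#'
#' Maximum fraction of frames on which predicted cluster labels match the
#' planted state labels, over all one-to-one relabelings (evaluated
#' exhaustively; intended for small numbers of clusters).
#'
#' @param truth,pred integer label vectors of equal length.
#' @return agreement fraction in `[0, 1]`.
#' @export
label_agreement <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  tl <- sort(unique(truth)); pl <- sort(unique(pred))
  k <- max(length(tl), length(pl))
  if (k > 6) stop("label_agreement supports up to 6 labels")
  conf <- table(factor(truth, levels = tl), factor(pred, levels = pl))
  perms <- perm_all(seq_len(k))
  best <- 0
  for (pr in perms) {
    hits <- 0
    for (i in seq_along(tl)) {
      j <- pr[i]
      if (j <= length(pl)) hits <- hits + conf[i, j]
    }
    best <- max(best, hits)
  }
  best / length(truth)
}

perm_all <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perm_all(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

#' Centre-of-mass distance between two particle groups over time
#'
#' Reduction used for loosely defined "group to group" separations (for
#' example a receptor motif versus the C-terminal residues of a partner
#' protein); both groups are reduced to their unweighted centroid per frame.
#'
#' @param traj a `gamd_trajectory`.
#' @param group_a,group_b particle index vectors.
#' @return tibble with `frame`, `time_ps`, `distance` (A).
#' @export
com_distance_timecourse <- function(traj, group_a, group_b) {
  ga <- resolve_selection(traj, group_a)
  gb <- resolve_selection(traj, group_b)
  nf <- n_frames(traj)
  d <- vapply(seq_len(nf), function(f) {
    fc <- frame_coords(traj, f)
    sqrt(sum((colMeans(fc[ga, , drop = FALSE]) -
                colMeans(fc[gb, , drop = FALSE]))^2))
  }, numeric(1))
  tibble::tibble(frame = seq_len(nf), time_ps = seq_len(nf) * traj$period_ps,
                 distance = d)
}
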