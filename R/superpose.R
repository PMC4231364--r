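# Stability metrics: Kabsch superposition, RMSD/RMSF, atom-pair distances.
# All computation is in Angstrom; nm output is a presentation option.

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between a
#' mobile and a reference point set: both sets are centered, the rotation
#' is obtained from the SVD of the 3x3 cross-covariance matrix, and a sign
#' correction on the smallest singular direction suppresses reflections so
#' the rotation determinant is +1.
#'
#' Coordinates are row vectors, so the aligned mobile set is
#' `sweep(mobile, 2, centroid_mobile) %*% rotation`, translated onto the
#' reference centroid.
#'
#' @param mobile,reference `n x 3` coordinate matrices (Å), `n >= 3`,
#'   non-collinear.
#' @return An object of class `superposition` with `rotation` (3x3 proper
#'   orthogonal, right-multiplication convention), `translation`
#'   (3-vector), `rmsd` (Å), and `aligned` (the transformed mobile set).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3L || ncol(reference) != 3L)
    hk_stop_invalid("mobile", "coordinate sets must be n x 3")
  if (nrow(mobile) != nrow(reference))
    hk_stop_invalid("mobile", sprintf(
      "atom count mismatch: %d mobile vs %d reference",
      nrow(mobile), nrow(reference)))
  if (nrow(mobile) < 3L)
    hk_stop_invalid("mobile", "need at least 3 atoms for superposition")
  if (anyNA(mobile) || anyNA(reference) ||
      !all(is.finite(mobile)) || !all(is.finite(reference)))
    hk_stop_invalid("mobile", "coordinates must be finite")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  svP <- svd(P)$d
  if (svP[2] <= 1e-8 * max(svP[1], 1e-12))
    hk_stop_invalid("mobile", "selected atoms are collinear or coincident; superposition is ill-posed")
  M <- crossprod(P, Q)
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  aligned <- P %*% R + matrix(cr, nrow(P), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((P %*% R - Q)^2)))
  structure(list(rotation = R,
                 translation = cr - as.numeric(cm %*% R),
                 rmsd = rmsd, aligned = aligned),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Superposition: RMSD = %.6g A, det(rotation) = %+.3f\n",
              x$rmsd, det(x$rotation)))
  invisible(x)
}

rmsd_points <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' RMSD time course of a trajectory
#'
#' Superposes the selected atoms of every frame onto the same selection in
#' the reference frame and reports the per-frame RMSD over that selection.
#'
#' @param traj A [trajectory()].
#' @param reference Reference frame index (default 1) or an `n x 3`
#'   coordinate matrix for the full atom set.
#' @param selection Atom selection (default `"backbone"`); see
#'   [select_atoms()].
#' @param units `"angstrom"` (default) or `"nm"`.
#' @return data.frame with columns `time` (ns) and `rmsd`.
#' @export
rmsd_timeseries <- function(traj, reference = 1L, selection = "backbone",
                            units = c("angstrom", "nm")) {
  stopifnot(inherits(traj, "trajectory"))
  units <- match.arg(units)
  idx <- select_atoms(traj, selection)
  if (length(idx) < 3L)
    hk_stop_invalid("selection", "resolves to fewer than 3 atoms")
  ref <- if (is.matrix(reference)) reference else frame_coords(traj, reference)
  refsel <- ref[idx, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    kabsch_superpose(frame_coords(traj, f)[idx, , drop = FALSE], refsel)$rmsd
  }, numeric(1))
  if (units == "nm") vals <- vals / 10
  data.frame(time = traj$times, rmsd = vals)
}

# Superpose every frame's fit-selection onto `ref` (matrix over fit atoms)
# and return the full-atom aligned array.
align_frames <- function(traj, fit_idx, ref) {
  out <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    x <- frame_coords(traj, f)
    sp <- kabsch_superpose(x[fit_idx, , drop = FALSE], ref)
    cm <- colMeans(x[fit_idx, , drop = FALSE])
    out[f, , ] <- sweep(x, 2, cm) %*% sp$rotation +
      matrix(colMeans(ref), nrow(x), 3, byrow = TRUE)
  }
  out
}

#' Per-residue RMSF of a trajectory
#'
#' Root-mean-square fluctuation of each selected atom about its
#' time-averaged position, after removing global rigid-body motion by
#' iterative superposition onto the mean structure (two passes: superpose
#' onto the first frame, recompute the mean, superpose onto the mean; the
#' RMSF is taken about the final mean):
#' \deqn{\mathrm{RMSF}_i = \sqrt{\langle \|x_i - \bar x_i\|^2 \rangle}.}
#'
#' @param traj A [trajectory()].
#' @param selection Atoms to report, one per residue for the conventional
#'   per-residue profile (default `"calpha"`).
#' @param fit_selection Atoms used for the superposition (defaults to
#'   `selection`); restricting it e.g. to a rigid core leaves mobile atoms
#'   free to express their fluctuation.
#' @param superpose Set `FALSE` to skip rigid-body removal (for
#'   trajectories already aligned).
#' @param units `"angstrom"` or `"nm"`.
#' @return data.frame with columns `resno`, `resname`, `chain`, `rmsf`.
#' @export
rmsf_per_residue <- function(traj, selection = "calpha",
                             fit_selection = selection, superpose = TRUE,
                             units = c("angstrom", "nm")) {
  stopifnot(inherits(traj, "trajectory"))
  units <- match.arg(units)
  idx <- select_atoms(traj, selection)
  if (length(idx) == 0L)
    hk_stop_invalid("selection", "resolves to no atoms")
  coords <- traj$coords
  if (superpose) {
    fit_idx <- select_atoms(traj, fit_selection)
    if (length(fit_idx) < 3L)
      hk_stop_invalid("fit_selection", "resolves to fewer than 3 atoms")
    ref <- frame_coords(traj, 1L)[fit_idx, , drop = FALSE]
    tmp <- traj
    for (pass in 1:2) {
      coords <- align_frames(tmp, fit_idx, ref)
      mean_fit <- apply(coords[, fit_idx, , drop = FALSE], c(2, 3), mean)
      ref <- matrix(mean_fit, ncol = 3)
      tmp$coords <- coords
    }
  }
  xbar <- apply(coords[, idx, , drop = FALSE], c(2, 3), mean)
  dev2 <- sweep(coords[, idx, , drop = FALSE], c(2, 3), xbar)^2
  rmsf <- sqrt(apply(dev2, 2, mean) * 3)  # mean over frames & coords, x3 for the norm
  if (units == "nm") rmsf <- rmsf / 10
  a <- traj$atoms[idx, , drop = FALSE]
  data.frame(resno = a$resno, resname = a$resname, chain = a$chain,
             rmsf = rmsf, row.names = NULL)
}

#' Atom-pair distance time course
#'
#' Euclidean distance between two uniquely specified atoms in every frame;
#' the canonical use is monitoring catalytic-triad integrity via the
#' His-Ser distance (His N\eqn{\epsilon}2 to Ser O\eqn{\gamma} by
#' default in serine hydrolases).
#'
#' @param traj A [trajectory()].
#' @param atom_spec_a,atom_spec_b Selections each resolving to exactly one
#'   atom (e.g. `"A:208:NE2"`, `"A:130:OG"`); an ambiguous spec fails with
#'   the list of candidate atoms.
#' @param units `"angstrom"` or `"nm"`.
#' @return data.frame with columns `time` (ns) and `distance`.
#' @export
distance_timeseries <- function(traj, atom_spec_a, atom_spec_b,
                                units = c("angstrom", "nm")) {
  stopifnot(inherits(traj, "trajectory"))
  units <- match.arg(units)
  ia <- resolve_single_atom(traj, atom_spec_a, "atom_spec_a")
  ib <- resolve_single_atom(traj, atom_spec_b, "atom_spec_b")
  diff <- traj$coords[, ia, , drop = FALSE] - traj$coords[, ib, , drop = FALSE]
  d <- sqrt(apply(diff^2, 1, sum))
  if (units == "nm") d <- d / 10
  data.frame(time = traj$times, distance = d)
}
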