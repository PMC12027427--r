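#' Residue displacement covariance matrix
#'
#' Computes c(i,j) = < dr_i . dr_j >_t over the trajectory, where
#' dr_i(t) = r_i(t) - <r_i> is the displacement 3-vector of residue i's
#' selected atom about its time average and the bracket is the plain average
#' over frames (denominator F, not F-1: the choice cancels in the normalised
#' cross-correlation). Frames are first superposed onto the mean structure
#' (one iterated pass) so that global rotation and translation do not
#' masquerade as internal motion.
#'
#' @param traj an `allopath_trajectory`.
#' @param selection atom indices, one per residue (default: Calpha atoms).
#' @param superpose remove rigid-body motion first (default TRUE).
#' @return list of class `allopath_covariance` with `c` (n_res x n_res,
#'   Angstrom^2), `mean_structure` (n_res x 3) and `residues` (global
#'   indices).
#' @export
covariance_matrix <- function(traj, selection = NULL, superpose = TRUE) {
  if (traj$n_frames < 2) validation_error("covariance needs at least 2 frames")
  selection <- selection %||% select_atoms(traj$structure, "ca")
  coords <- traj$coords[, selection, , drop = FALSE]
  if (superpose) {
    fit <- fit_to_mean(coords)
    coords <- fit$coords
    mu <- fit$mean
  } else {
    mu <- apply(coords, c(2, 3), mean)
  }
  F <- dim(coords)[1]; n <- dim(coords)[2]
  # displacement components as F x n matrices per axis; c = sum over axes of
  # the per-axis second-moment matrices.
  cc <- matrix(0, n, n)
  for (ax in 1:3) {
    D <- coords[, , ax] - matrix(mu[, ax], F, n, byrow = TRUE)
    cc <- cc + crossprod(D) / F
  }
  cc <- (cc + t(cc)) / 2
  structure(list(c = cc, mean_structure = mu,
                 residues = traj$structure$atoms$residue_index[selection]),
            class = "allopath_covariance")
}

#' Dynamic cross-correlation matrix (DCCM)
#'
#' Pearson-style normalisation of the displacement covariance:
#' C(i,j) = c(i,j) / sqrt(c(i,i) c(j,j)). C(i,j) = +1 for perfectly
#' correlated (in-phase) residue motions, -1 for perfectly anticorrelated
#' ones. The diagonal is set to exactly 1.
#'
#' @param cov an `allopath_covariance` from [covariance_matrix()], or a
#'   trajectory (in which case the covariance is computed first).
#' @param ... passed to [covariance_matrix()] when `cov` is a trajectory.
#' @return matrix of class `allopath_dccm` with residue labels.
#' @export
dccm <- function(cov, ...) {
  if (inherits(cov, "allopath_trajectory")) cov <- covariance_matrix(cov, ...)
  if (!inherits(cov, "allopath_covariance"))
    validation_error("dccm expects a covariance or trajectory")
  v <- diag(cov$c)
  zero <- which(v <= 0)
  if (length(zero))
    validation_error("immobile residue %d has zero variance and cannot be normalised",
                     cov$residues[zero[1]])
  C <- cov$c / sqrt(outer(v, v))
  C <- (C + t(C)) / 2
  diag(C) <- 1
  dimnames(C) <- list(cov$residues, cov$residues)
  class(C) <- c("allopath_dccm", class(C))
  C
}

#' Residue contact matrix (RCM)
#'
#' freq(i,j) = fraction of frames in which the pair distance is below the
#' cutoff. Distance modes: `"ca"` uses the Calpha-Calpha distance;
#' `"min_heavy"` (default) uses the minimum distance over the residues'
#' heavy atoms, the smallest-distance convention of contact-map tools.
#' `statistic = "mean_distance"` instead returns the time-averaged pair
#' distance (Angstrom).
#'
#' @param traj an `allopath_trajectory`.
#' @param cutoff contact cutoff, Angstrom (default 10).
#' @param distance_mode `"min_heavy"` or `"ca"`.
#' @param statistic `"frequency"` (default) or `"mean_distance"`.
#' @param residues restrict to these global residue indices (default: all
#'   protein residues).
#' @return matrix of class `allopath_contact` (frequency in [0,1] with unit
#'   diagonal, or mean distance with zero diagonal), residue-labelled, plus
#'   attributes `cutoff` and `distance_mode`.
#' @export
contact_matrix <- function(traj, cutoff = 10, distance_mode = c("min_heavy", "ca"),
                           statistic = c("frequency", "mean_distance"),
                           residues = NULL) {
  distance_mode <- match.arg(distance_mode)
  statistic <- match.arg(statistic)
  if (cutoff <= 0) validation_error("contact cutoff must be positive")
  at <- traj$structure$atoms
  prot <- select_atoms(traj$structure, "protein")
  residues <- residues %||% sort(unique(at$residue_index[prot]))
  n <- length(residues)
  acc <- matrix(0, n, n)
  if (distance_mode == "ca") {
    sel <- select_atoms(traj$structure, "ca")
    sel <- sel[match(residues, at$residue_index[sel])]
    if (anyNA(sel)) validation_error("residue without Calpha atom in contact selection")
    for (f in seq_len(traj$n_frames)) {
      dm <- as.matrix(stats::dist(traj$coords[f, sel, , drop = TRUE]))
      acc <- acc + if (statistic == "frequency") (dm < cutoff) else dm
    }
  } else {
    heavy <- intersect(select_atoms(traj$structure, "heavy"), prot)
    heavy <- heavy[at$residue_index[heavy] %in% residues]
    grp <- match(at$residue_index[heavy], residues)
    one_atom <- identical(grp, seq_len(n))
    pair_i <- grp[row(diag(length(heavy)))]   # row residue of each atom pair
    pair_j <- grp[col(diag(length(heavy)))]
    key <- (pair_i - 1L) * n + pair_j         # flat residue-pair id per atom pair
    for (f in seq_len(traj$n_frames)) {
      dm <- as.matrix(stats::dist(traj$coords[f, heavy, , drop = TRUE]))
      if (one_atom) {
        rd <- dm
      } else {
        # residue-pair minimum over atom-pair distances
        rd <- matrix(Inf, n, n)
        mins <- vapply(split(as.vector(dm), key), min, numeric(1))
        rd[as.integer(names(mins))] <- mins
        rd <- t(rd)
      }
      acc <- acc + if (statistic == "frequency") (rd < cutoff) else rd
    }
  }
  m <- acc / traj$n_frames
  m <- (m + t(m)) / 2
  diag(m) <- if (statistic == "frequency") 1 else 0
  dimnames(m) <- list(residues, residues)
  attr(m, "cutoff") <- cutoff
  attr(m, "distance_mode") <- distance_mode
  attr(m, "statistic") <- statistic
  class(m) <- c("allopath_contact", class(m))
  m
}
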