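#' Principal component analysis of Calpha coordinates
#'
#' Frames are superposed onto the mean structure (one iterated pass) to
#' remove translation and rotation, then the 3n x 3n Cartesian covariance of
#' the selected atoms is eigen-decomposed. Projections of the centred frames
#' onto the eigenvectors give the conformational coordinates used for the
#' free-energy landscape; the cumulative variance of PC1+PC2 summarises how
#' much of the ensemble's motion the landscape plane captures.
#'
#' @param traj an `allopath_trajectory`.
#' @param selection atom indices, one per residue (default: Calpha atoms).
#' @param superpose remove rigid-body motion first (default TRUE).
#' @return list of class `allopath_pca`: `eigenvalues` (Angstrom^2,
#'   descending), `eigenvectors` (3n x k, orthonormal columns), `projections`
#'   (n_frames x k, Angstrom), `variance_fraction`, `cum_var12` (fraction of
#'   total variance in PC1+PC2) and `mean_structure`.
#' @export
pca_ca <- function(traj, selection = NULL, superpose = TRUE) {
  if (traj$n_frames <= 1) validation_error("PCA needs more than one frame")
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
  X <- matrix(coords, F, 3 * n)  # column layout: x_1..x_n, y_1..y_n, z_1..z_n
  X <- sweep(X, 2, colMeans(X))
  S <- crossprod(X) / F
  eig <- eigen(S, symmetric = TRUE)
  vf <- eig$values / sum(eig$values)
  structure(list(
    eigenvalues = eig$values,
    eigenvectors = eig$vectors,
    projections = X %*% eig$vectors,
    variance_fraction = vf,
    cum_var12 = sum(vf[1:min(2, length(vf))]),
    mean_structure = mu,
    residues = traj$structure$atoms$residue_index[selection]
  ), class = "allopath_pca")
}

#' @export
print.allopath_pca <- function(x, ...) {
  cat(sprintf("PCA: %d modes; PC1 %.2f%%, PC2 %.2f%%, PC1+PC2 %.2f%% of variance\n",
              length(x$eigenvalues), 100 * x$variance_fraction[1],
              100 * x$variance_fraction[2], 100 * x$cum_var12))
  invisible(x)
}

#' Free-energy landscape over PC1/PC2 by Boltzmann inversion
#'
#' Bins the first two principal-component projections on a B x B grid and
#' converts occupancy to relative free energy, G_b = -kT ln(P_b / P_max), so
#' the most populated bin sits at exactly 0 and empty bins are unvisited
#' (G = Inf). Because only probability ratios enter, scaling all counts by a
#' constant leaves G unchanged.
#'
#' @param projections n_frames x >=2 matrix (or an `allopath_pca`), Angstrom.
#' @param bins grid size per axis, B >= 2 (default 50).
#' @param temperature Kelvin (default 300).
#' @param units `"kJ/mol"` (default) or `"kT"`.
#' @return list of class `allopath_fel`: `P` (B x B, sums to 1), `G`,
#'   `edges1`, `edges2`, `mids1`, `mids2`, `temperature`, `units`.
#' @export
free_energy_landscape <- function(projections, bins = 50, temperature = 300,
                                  units = c("kJ/mol", "kT")) {
  units <- match.arg(units)
  if (inherits(projections, "allopath_pca")) projections <- projections$projections
  projections <- as.matrix(projections)
  if (ncol(projections) < 2) validation_error("need at least two projection columns")
  if (bins < 2) validation_error("need at least 2 bins per axis")
  if (!nrow(projections)) validation_error("no frames to bin")
  kB <- 0.008314462618  # kJ/mol/K
  kT <- if (units == "kT") 1 else kB * temperature

  bin_edges <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)   # all projections identical
    seq(r[1], r[2], length.out = bins + 1)
  }
  e1 <- bin_edges(projections[, 1]); e2 <- bin_edges(projections[, 2])
  i1 <- pmin(findInterval(projections[, 1], e1, rightmost.closed = TRUE), bins)
  i2 <- pmin(findInterval(projections[, 2], e2, rightmost.closed = TRUE), bins)
  counts <- matrix(0, bins, bins)
  tab <- table(factor(i1, levels = seq_len(bins)), factor(i2, levels = seq_len(bins)))
  counts[] <- as.numeric(tab)
  P <- counts / sum(counts)
  G <- matrix(Inf, bins, bins)
  occ <- P > 0
  G[occ] <- -kT * log(P[occ] / max(P))
  structure(list(P = P, G = G, edges1 = e1, edges2 = e2,
                 mids1 = (e1[-1] + e1[-length(e1)]) / 2,
                 mids2 = (e2[-1] + e2[-length(e2)]) / 2,
                 temperature = temperature, units = units),
            class = "allopath_fel")
}

#' Tidy a free-energy landscape for output
#'
#' @param fel an `allopath_fel`.
#' @param occupied_only drop unvisited bins (default TRUE).
#' @return data.frame (PC1, PC2, P, G) over bin centres.
#' @export
fel_table <- function(fel, occupied_only = TRUE) {
  d <- expand.grid(PC1 = fel$mids1, PC2 = fel$mids2)
  d$P <- as.vector(fel$P)
  d$G <- as.vector(fel$G)
  if (occupied_only) d <- d[d$P > 0, , drop = FALSE]
  rownames(d) <- NULL
  d
}
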