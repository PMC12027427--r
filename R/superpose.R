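#' Optimal least-squares rigid-body superposition
#'
#' Superposes `mobile` onto `reference` by the rotation/translation that
#' minimises the RMSD over the selected atoms (Kabsch algorithm via singular
#' value decomposition, with the determinant correction that excludes
#' reflections). The whole mobile frame is transformed; the RMSD is reported
#' over the selection.
#'
#' @param mobile n x 3 coordinate matrix (Angstrom).
#' @param reference n x 3 coordinate matrix.
#' @param selection atom indices used for the fit (default: all atoms).
#' @param weights optional per-selected-atom weights (e.g. masses);
#'   default uniform.
#' @return list with `coords` (transformed mobile, n x 3) and `rmsd`
#'   (Angstrom, over the selection).
#' @export
superpose <- function(mobile, reference, selection = NULL, weights = NULL) {
  mobile <- as_coord_matrix(mobile)
  reference <- as_coord_matrix(reference)
  if (nrow(mobile) != nrow(reference))
    validation_error("mobile and reference differ in atom count")
  selection <- selection %||% seq_len(nrow(mobile))
  if (!length(selection)) validation_error("empty selection for superposition")
  if (any(selection < 1 | selection > nrow(mobile)))
    validation_error("selection index out of range")
  P <- mobile[selection, , drop = FALSE]
  Q <- reference[selection, , drop = FALSE]
  w <- weights %||% rep(1, nrow(P))
  w <- w / sum(w)

  cp <- colSums(P * w)
  cq <- colSums(Q * w)
  Pc <- sweep(P, 2, cp)
  Qc <- sweep(Q, 2, cq)
  if (nrow(Pc) < 3 || qr(Pc)$rank < 2)
    validation_error("degenerate superposition: need >= 3 non-collinear selection atoms")

  H <- crossprod(Pc * w, Qc)            # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)   # row-vector convention: x' = x R

  moved <- sweep(mobile, 2, cp) %*% R
  moved <- sweep(moved, 2, cq, FUN = "+")
  dif <- moved[selection, , drop = FALSE] - Q
  list(coords = moved, rmsd = sqrt(sum(w * rowSums(dif^2))))
}

# Superpose every frame of a coords array onto a reference frame (n x 3).
# Returns the transformed array; used by metrics, covariance and PCA.
superpose_frames <- function(coords, reference, selection = NULL) {
  out <- coords
  for (f in seq_len(dim(coords)[1])) {
    out[f, , ] <- superpose(coords[f, , , drop = TRUE], reference, selection)$coords
  }
  out
}

# One pass of the usual iterated-mean fit: superpose all frames onto their
# time average, then recompute the average.
fit_to_mean <- function(coords, selection = NULL) {
  mean0 <- apply(coords, c(2, 3), mean)
  fitted <- superpose_frames(coords, mean0, selection)
  list(coords = fitted, mean = apply(fitted, c(2, 3), mean))
}
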