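#' Atom selections on a structure
#'
#' Convenience selector returning atom indices. `ca` picks one alpha-carbon
#' per residue (for one-atom-per-residue models such as coarse Calpha traces,
#' every atom counts as its residue's Calpha); `protein` excludes ligand and
#' glycan chains; `heavy` drops hydrogens.
#'
#' @param structure an `allopath_structure`.
#' @param what one of `"ca"`, `"protein"`, `"heavy"`, `"all"`.
#' @return integer atom indices in structure order.
#' @export
select_atoms <- function(structure, what = c("ca", "protein", "heavy", "all")) {
  what <- match.arg(what)
  at <- structure$atoms
  protein_chains <- structure$chains$chain_id[!structure$chains$role %in% c("ligand", "glycan")]
  idx <- switch(what,
    all = seq_len(nrow(at)),
    heavy = which(at$element != "H"),
    protein = which(at$chain %in% protein_chains),
    ca = {
      cand <- which(at$name == "CA" & at$chain %in% protein_chains)
      if (length(cand)) cand else which(at$chain %in% protein_chains &
                                          !duplicated(at$residue_index))
    })
  if (!length(idx)) validation_error("selection '%s' matched no atoms", what)
  idx
}

#' RMSD time series over a trajectory
#'
#' Each frame is optimally superposed onto the reference over the selection,
#' and the least-squares RMSD after superposition is reported.
#'
#' @param traj an `allopath_trajectory`.
#' @param reference frame index (default 1) or an n x 3 coordinate matrix.
#' @param selection atom indices (default: Calpha atoms).
#' @param units `"angstrom"` (default) or `"nm"` for GROMACS-style plots.
#' @return data.frame with columns `time` (ps) and `rmsd`.
#' @export
rmsd_series <- function(traj, reference = 1L, selection = NULL, units = c("angstrom", "nm")) {
  units <- match.arg(units)
  selection <- selection %||% select_atoms(traj$structure, "ca")
  if (!length(selection)) validation_error("empty selection")
  ref <- if (is.matrix(reference)) reference else traj$coords[reference, , , drop = TRUE]
  vals <- vapply(seq_len(traj$n_frames), function(f) {
    superpose(traj$coords[f, , , drop = TRUE], ref, selection)$rmsd
  }, numeric(1))
  scale <- if (units == "nm") 0.1 else 1
  data.frame(time = (seq_len(traj$n_frames) - 1) * traj$timestep,
             rmsd = vals * scale)
}

#' Radius of gyration of one frame
#'
#' Rg = sqrt( sum_i m_i |r_i - r_com|^2 / sum_i m_i ), mass-weighted about
#' the centre of mass of the selection.
#'
#' @param frame n x 3 coordinate matrix (Angstrom).
#' @param selection atom indices (default all).
#' @param masses per-atom masses for the full frame (default: unit masses).
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(frame, selection = NULL, masses = NULL) {
  frame <- as_coord_matrix(frame)
  selection <- selection %||% seq_len(nrow(frame))
  masses <- masses %||% rep(1, nrow(frame))
  m <- masses[selection]
  if (sum(m) <= 0) validation_error("zero total mass in Rg selection")
  r <- frame[selection, , drop = FALSE]
  com <- colSums(r * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(r, 2, com)^2)) / sum(m))
}

#' Radius-of-gyration time series
#'
#' @inheritParams rmsd_series
#' @param masses per-atom masses (default: from the structure's elements).
#' @return data.frame with columns `time` (ps) and `rg`.
#' @export
rg_series <- function(traj, selection = NULL, masses = NULL, units = c("angstrom", "nm")) {
  units <- match.arg(units)
  selection <- selection %||% select_atoms(traj$structure, "ca")
  masses <- masses %||% traj$structure$atoms$mass
  vals <- vapply(seq_len(traj$n_frames), function(f) {
    radius_of_gyration(traj$coords[f, , , drop = TRUE], selection, masses)
  }, numeric(1))
  scale <- if (units == "nm") 0.1 else 1
  data.frame(time = (seq_len(traj$n_frames) - 1) * traj$timestep, rg = vals * scale)
}

#' Per-residue root mean square fluctuation
#'
#' RMSF_i = sqrt( <|r_i(t) - <r_i>|^2>_t ) per selected atom, after one pass
#' of superposition onto the time-average structure (compute mean, superpose
#' all frames onto it, recompute mean) when `superpose_first` is TRUE.
#'
#' @param traj an `allopath_trajectory`.
#' @param selection atom indices, one per residue (default: Calpha atoms).
#' @param superpose_first remove global rotation/translation first
#'   (default TRUE).
#' @return data.frame with columns `residue` (global index) and `rmsf`
#'   (Angstrom).
#' @export
rmsf_profile <- function(traj, selection = NULL, superpose_first = TRUE) {
  if (traj$n_frames < 2) validation_error("RMSF needs at least 2 frames")
  selection <- selection %||% select_atoms(traj$structure, "ca")
  coords <- traj$coords[, selection, , drop = FALSE]
  if (superpose_first) coords <- fit_to_mean(coords)$coords
  mu <- apply(coords, c(2, 3), mean)
  sq <- vapply(seq_len(dim(coords)[1]), function(f) {
    rowSums((coords[f, , , drop = TRUE] - mu)^2)
  }, numeric(length(selection)))
  data.frame(residue = traj$structure$atoms$residue_index[selection],
             rmsf = sqrt(rowMeans(matrix(sq, nrow = length(selection)))))
}
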