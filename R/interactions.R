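#' Geometric criteria for non-covalent interaction detection
#'
#' Defaults follow the usual geometric definitions: a hydrogen bond needs a
#' donor-acceptor distance under 3 Angstrom and a D-H...A angle over 150
#' degrees; hydrophobic contacts a Calpha-Calpha distance under 4 Angstrom
#' between hydrophobic residues; cation-pi a ring-atom to cationic-nitrogen
#' distance under 6 Angstrom; pi-pi a ring-centroid distance under 5
#' Angstrom.
#'
#' @param hbond_max_dist Angstrom (default 3.0).
#' @param hbond_min_angle degrees, D-H...A vertex at the hydrogen
#'   (default 150).
#' @param hydrophobic_max_dist Angstrom (default 4.0).
#' @param cation_pi_max_dist Angstrom (default 6.0).
#' @param pi_pi_max_centroid_dist Angstrom (default 5.0).
#' @return list of class `allopath_criteria`.
#' @export
interaction_criteria <- function(hbond_max_dist = 3.0, hbond_min_angle = 150,
                                 hydrophobic_max_dist = 4.0,
                                 cation_pi_max_dist = 6.0,
                                 pi_pi_max_centroid_dist = 5.0) {
  d <- c(hbond_max_dist, hydrophobic_max_dist, cation_pi_max_dist, pi_pi_max_centroid_dist)
  if (any(d <= 0)) validation_error("interaction distance thresholds must be positive")
  if (hbond_min_angle <= 0 || hbond_min_angle > 180)
    validation_error("hydrogen-bond angle threshold must be in (0, 180]")
  structure(list(hbond_max_dist = hbond_max_dist, hbond_min_angle = hbond_min_angle,
                 hydrophobic_max_dist = hydrophobic_max_dist,
                 cation_pi_max_dist = cation_pi_max_dist,
                 pi_pi_max_centroid_dist = pi_pi_max_centroid_dist),
            class = "allopath_criteria")
}

.hydrophobic_resnames <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP")
.ring_atoms <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
)
.cation_atoms <- c("NZ", "NH1", "NH2", "NE")

new_events <- function() {
  data.frame(frame = integer(), type = character(),
             res_a = integer(), atom_a = character(),
             res_b = integer(), atom_b = character(),
             distance = numeric(), angle = numeric(),
             stringsAsFactors = FALSE)
}

#' Locate hydrogen-bond donors, acceptors, aromatic rings and cations
#'
#' Donors are N/O/S atoms with a covalently attached hydrogen (H within
#' 1.3 Angstrom in the reference coordinates); acceptors are all N/O/S
#' atoms. Aromatic rings are recognised by residue name and canonical ring
#' atom names (Phe, Tyr, His, and both Trp rings); cationic nitrogens are
#' Lys NZ and Arg NH1/NH2/NE (matching atom names on a ligand count too, so
#' e.g. a ligand guanidinium is picked up).
#'
#' @param structure an `allopath_structure`.
#' @param coords n x 3 reference coordinates used to resolve attached
#'   hydrogens (default: the structure's own coordinates).
#' @return list with `donors` (data.frame donor, hydrogen, residue),
#'   `acceptors` (data.frame atom, residue), `rings` (list of residue/atom
#'   index sets), `cations` (data.frame atom, residue).
#' @export
interaction_groups <- function(structure, coords = NULL) {
  at <- structure$atoms
  coords <- coords %||% as.matrix(at[, c("x", "y", "z")])
  heavy_da <- which(at$element %in% c("N", "O", "S"))
  hyd <- which(at$element == "H")
  dl <- list()
  if (length(hyd) && length(heavy_da)) {
    for (h in hyd) {
      # a hydrogen is bonded within its own residue: closest same-residue
      # N/O/S within covalent range is its donor
      cand <- heavy_da[at$residue_index[heavy_da] == at$residue_index[h]]
      if (!length(cand)) next
      d2 <- rowSums(sweep(coords[cand, , drop = FALSE], 2, coords[h, ])^2)
      k <- which.min(d2)
      if (d2[k] < 1.3^2) {
        dl[[length(dl) + 1L]] <- data.frame(donor = cand[k], hydrogen = h,
                                            residue = at$residue_index[h])
      }
    }
  }
  donors <- if (length(dl)) do.call(rbind, dl) else
    data.frame(donor = integer(), hydrogen = integer(), residue = integer())
  acceptors <- data.frame(atom = heavy_da, residue = at$residue_index[heavy_da])
  rings <- list()
  for (res in unique(at$residue_index)) {
    ridx <- which(at$residue_index == res)
    rn <- at$resname[ridx[1]]
    if (!rn %in% names(.ring_atoms)) next
    for (ring_names in .ring_atoms[[rn]]) {
      idx <- ridx[match(ring_names, at$name[ridx])]
      if (anyNA(idx)) next
      rings[[length(rings) + 1L]] <- list(residue = res, atoms = idx)
    }
  }
  cations <- which(at$name %in% .cation_atoms & at$element == "N")
  list(donors = donors, acceptors = acceptors, rings = rings,
       cations = data.frame(atom = cations, residue = at$residue_index[cations]))
}

#' Detect hydrogen bonds in one frame
#'
#' An event is recorded when the donor-acceptor distance is below
#' `hbond_max_dist` and the D-H...A angle (vertex at the hydrogen) exceeds
#' `hbond_min_angle`, for donor and acceptor on different residues. Donors
#' without a resolvable hydrogen are skipped with a warning.
#'
#' @param coords n x 3 frame coordinates (Angstrom).
#' @param donors data.frame with columns `donor`, `hydrogen`, `residue`
#'   (atom indices; `hydrogen` may be NA, the donor is then skipped).
#' @param acceptors data.frame with columns `atom`, `residue`.
#' @param criteria an [interaction_criteria()] list.
#' @param atoms optional atom table for labels (name per atom index).
#' @return events data.frame (type `"hbond"`).
#' @export
detect_hbonds <- function(coords, donors, acceptors, criteria = interaction_criteria(),
                          atoms = NULL) {
  coords <- as_coord_matrix(coords)
  ev <- new_events()
  if (!nrow(donors) || !nrow(acceptors)) return(ev)
  no_h <- is.na(donors$hydrogen)
  if (any(no_h)) {
    warning(sprintf("%d donor(s) without attached hydrogen skipped", sum(no_h)))
    donors <- donors[!no_h, , drop = FALSE]
  }
  name_of <- function(i) if (is.null(atoms)) as.character(i) else atoms$name[i]
  for (k in seq_len(nrow(donors))) {
    d <- donors$donor[k]; h <- donors$hydrogen[k]
    keep <- acceptors$residue != donors$residue[k]
    acc <- acceptors[keep, , drop = FALSE]
    if (!nrow(acc)) next
    dv <- sweep(coords[acc$atom, , drop = FALSE], 2, coords[d, ])
    dist_da <- sqrt(rowSums(dv^2))
    cand <- which(dist_da < criteria$hbond_max_dist)
    for (m in cand) {
      a <- acc$atom[m]
      v1 <- coords[d, ] - coords[h, ]
      v2 <- coords[a, ] - coords[h, ]
      ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                 (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))))) * 180 / pi
      if (ang > criteria$hbond_min_angle) {
        ev <- rbind(ev, data.frame(frame = NA_integer_, type = "hbond",
                                   res_a = donors$residue[k], atom_a = name_of(d),
                                   res_b = acc$residue[m], atom_b = name_of(a),
                                   distance = dist_da[m], angle = ang))
      }
    }
  }
  ev
}

#' Detect hydrophobic contacts in one frame
#'
#' Pairs of hydrophobic-class residues (Ala, Val, Leu, Ile, Pro, Phe, Met,
#' Trp) that are not sequence neighbours (|i - j| > 1) count as interacting
#' when the configured distance is below `hydrophobic_max_dist`. The default
#' distance is Calpha-Calpha as printed in the geometric criterion;
#' `mode = "sidechain"` instead uses the minimum distance over side-chain
#' carbon atoms, which is the more permissive convention.
#'
#' @param coords n x 3 frame coordinates.
#' @param structure an `allopath_structure`.
#' @param criteria an [interaction_criteria()] list.
#' @param mode `"ca"` (default) or `"sidechain"`.
#' @return events data.frame (type `"hydrophobic"`).
#' @export
detect_hydrophobic <- function(coords, structure, criteria = interaction_criteria(),
                               mode = c("ca", "sidechain")) {
  mode <- match.arg(mode)
  coords <- as_coord_matrix(coords)
  at <- structure$atoms
  ev <- new_events()
  hres <- sort(unique(at$residue_index[at$resname %in% .hydrophobic_resnames]))
  if (length(hres) < 2) return(ev)
  rep_atoms <- lapply(hres, function(r) {
    ridx <- which(at$residue_index == r)
    if (mode == "ca") {
      ca <- ridx[at$name[ridx] == "CA"]
      if (!length(ca)) ridx[1] else ca[1]
    } else {
      sc <- ridx[at$element[ridx] == "C" & !at$name[ridx] %in% c("CA", "C", "O", "N")]
      if (!length(sc)) ridx[at$name[ridx] == "CA"] else sc
    }
  })
  for (ii in seq_along(hres)[-length(hres)]) {
    for (jj in (ii + 1):length(hres)) {
      if (abs(hres[jj] - hres[ii]) <= 1) next
      da <- coords[rep_atoms[[ii]], , drop = FALSE]
      db <- coords[rep_atoms[[jj]], , drop = FALSE]
      dmin <- Inf; best <- c(1L, 1L)
      for (a in seq_len(nrow(da))) {
        dd <- sqrt(rowSums(sweep(db, 2, da[a, ])^2))
        if (min(dd) < dmin) { dmin <- min(dd); best <- c(a, which.min(dd)) }
      }
      if (dmin < criteria$hydrophobic_max_dist) {
        ev <- rbind(ev, data.frame(frame = NA_integer_, type = "hydrophobic",
                                   res_a = hres[ii],
                                   atom_a = at$name[rep_atoms[[ii]][best[1]]],
                                   res_b = hres[jj],
                                   atom_b = at$name[rep_atoms[[jj]][best[2]]],
                                   distance = dmin, angle = NA_real_))
      }
    }
  }
  ev
}

#' Detect cation-pi interactions in one frame
#'
#' An event is recorded when the minimum distance from any aromatic ring
#' atom (Phe/Tyr/Trp/His rings) to a cationic nitrogen (Lys NZ, Arg
#' NH1/NH2/NE, or equivalently named ligand nitrogens) is below
#' `cation_pi_max_dist`, ring and cation on different residues.
#'
#' @param coords n x 3 frame coordinates.
#' @param rings list of rings from [interaction_groups()].
#' @param cations data.frame with columns `atom`, `residue`.
#' @param criteria an [interaction_criteria()] list.
#' @param atoms optional atom table for labels.
#' @return events data.frame (type `"cation_pi"`).
#' @export
detect_cation_pi <- function(coords, rings, cations, criteria = interaction_criteria(),
                             atoms = NULL) {
  coords <- as_coord_matrix(coords)
  ev <- new_events()
  if (!length(rings) || !nrow(cations)) return(ev)
  name_of <- function(i) if (is.null(atoms)) as.character(i) else atoms$name[i]
  for (ring in rings) {
    for (k in seq_len(nrow(cations))) {
      if (cations$residue[k] == ring$residue) next
      dd <- sqrt(rowSums(sweep(coords[ring$atoms, , drop = FALSE], 2,
                               coords[cations$atom[k], ])^2))
      if (min(dd) < criteria$cation_pi_max_dist) {
        ev <- rbind(ev, data.frame(frame = NA_integer_, type = "cation_pi",
                                   res_a = ring$residue,
                                   atom_a = name_of(ring$atoms[which.min(dd)]),
                                   res_b = cations$residue[k],
                                   atom_b = name_of(cations$atom[k]),
                                   distance = min(dd), angle = NA_real_))
      }
    }
  }
  ev
}

#' Detect pi-pi stacking in one frame
#'
#' An event is recorded when the centroids of two aromatic rings on
#' different residues are closer than `pi_pi_max_centroid_dist`.
#'
#' @param coords n x 3 frame coordinates.
#' @param rings list of rings from [interaction_groups()].
#' @param criteria an [interaction_criteria()] list.
#' @return events data.frame (type `"pi_pi"`).
#' @export
detect_pi_pi <- function(coords, rings, criteria = interaction_criteria()) {
  coords <- as_coord_matrix(coords)
  ev <- new_events()
  if (length(rings) < 2) return(ev)
  cent <- t(vapply(rings, function(r) colMeans(coords[r$atoms, , drop = FALSE]),
                   numeric(3)))
  for (a in seq_along(rings)[-length(rings)]) {
    for (b in (a + 1):length(rings)) {
      if (rings[[a]]$residue == rings[[b]]$residue) next
      d <- sqrt(sum((cent[a, ] - cent[b, ])^2))
      if (d < criteria$pi_pi_max_centroid_dist) {
        ev <- rbind(ev, data.frame(frame = NA_integer_, type = "pi_pi",
                                   res_a = rings[[a]]$residue, atom_a = "ring",
                                   res_b = rings[[b]]$residue, atom_b = "ring",
                                   distance = d, angle = NA_real_))
      }
    }
  }
  ev
}

#' Detect all interaction types over a trajectory
#'
#' Runs the four geometric detectors on every frame and concatenates the
#' per-frame events.
#'
#' @param traj an `allopath_trajectory`.
#' @param criteria an [interaction_criteria()] list.
#' @param types subset of `c("hbond", "hydrophobic", "cation_pi", "pi_pi")`.
#' @param hydrophobic_mode passed to [detect_hydrophobic()].
#' @return events data.frame with `frame` filled in.
#' @export
detect_interactions <- function(traj, criteria = interaction_criteria(),
                                types = c("hbond", "hydrophobic", "cation_pi", "pi_pi"),
                                hydrophobic_mode = "ca") {
  st <- traj$structure
  groups <- interaction_groups(st, traj$coords[1, , , drop = TRUE])
  out <- list()
  for (f in seq_len(traj$n_frames)) {
    xyz <- traj$coords[f, , , drop = TRUE]
    ev <- list()
    if ("hbond" %in% types)
      ev$h <- detect_hbonds(xyz, groups$donors, groups$acceptors, criteria, st$atoms)
    if ("hydrophobic" %in% types)
      ev$p <- detect_hydrophobic(xyz, st, criteria, hydrophobic_mode)
    if ("cation_pi" %in% types)
      ev$c <- detect_cation_pi(xyz, groups$rings, groups$cations, criteria, st$atoms)
    if ("pi_pi" %in% types)
      ev$s <- detect_pi_pi(xyz, groups$rings, criteria)
    ev <- do.call(rbind, ev)
    if (!is.null(ev) && nrow(ev)) {
      ev$frame <- f
      out[[length(out) + 1L]] <- ev
    }
  }
  if (!length(out)) return(new_events())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Occupancy and per-frame count statistics for an interaction type
#'
#' Occupancy is the percentage of frames in which at least one event of the
#' type touches the site (either partner's residue in the site selection);
#' the count statistics are the minimum, maximum and mean number of event
#' pairs per frame, with frames lacking events counting as zero.
#'
#' @param events events data.frame from [detect_interactions()].
#' @param n_frames total number of trajectory frames.
#' @param site residue indices defining the site (required; use all residues
#'   for a whole-molecule table).
#' @param type one interaction type, or NULL for one row per type present.
#' @param label site name for the output row.
#' @return data.frame (site, type, occupancy_pct, min, max, mean).
#' @export
occupancy_table <- function(events, n_frames, site, type = NULL, label = "site") {
  if (!length(site)) validation_error("empty site selection")
  types <- type %||% unique(events$type)
  if (!length(types)) types <- character(0)
  rows <- lapply(types, function(tp) {
    sel <- events[events$type == tp &
                    (events$res_a %in% site | events$res_b %in% site), , drop = FALSE]
    per_frame <- tabulate(sel$frame, nbins = n_frames)
    data.frame(site = label, type = tp,
               occupancy_pct = 100 * sum(per_frame > 0) / n_frames,
               min = min(per_frame), max = max(per_frame), mean = mean(per_frame))
  })
  if (!length(rows))
    return(data.frame(site = character(), type = character(),
                      occupancy_pct = numeric(), min = numeric(),
                      max = numeric(), mean = numeric()))
  do.call(rbind, rows)
}
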