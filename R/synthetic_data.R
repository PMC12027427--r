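#' Synthetic ensembles with known ground truth
#'
#' The generator emulates the statistical structure that the analysis
#' pipeline measures, without pretending to be physics: residue positions on
#' a helical Calpha trace (3.8 Angstrom spacing) fluctuate about their rest
#' positions with Gaussian displacements whose residue-residue correlation
#' matrix is prescribed exactly. Correlation is isotropic per axis (the same
#' rho on x, y and z), so the dot-product cross-correlation recovered by
#' [dccm()] equals the generating rho in expectation and ground truth stays
#' analytic.
#'
#' @name synthetic-data
NULL

# Wide helical Calpha trace with 3.8 A spacing between consecutive residues.
# The default 10 A radius / 20-degree turn keeps the curve self-avoiding
# (adjacent turns sit ~28 A apart) and makes spatial contacts at a 10 A
# cutoff banded in sequence (|i-j| <= 2), so planted communication chains
# cannot be short-circuited by through-space shortcuts; the wide radius also
# leaves all three rigid-body rotations well determined when frames are
# superposed, so least-squares fitting does not leak displacement variance
# into spurious cross-correlations.
ca_trace <- function(n_res, radius = 10, turn_deg = 20) {
  theta <- (seq_len(n_res) - 1) * turn_deg * pi / 180
  chord_xy <- 2 * radius * sin(turn_deg * pi / 360)
  if (chord_xy >= 3.8) validation_error("trace turn too tight for 3.8 A spacing")
  rise <- sqrt(3.8^2 - chord_xy^2)
  cbind(radius * cos(theta), radius * sin(theta), rise * (seq_len(n_res) - 1))
}

# Minimal structure constructor for generated systems.
make_ca_structure <- function(n_res, chains = NULL, resnames = "GLY") {
  chains <- chains %||% data.frame(chain_id = "A", role = "protein", n_res = n_res)
  if (sum(chains$n_res) != n_res)
    validation_error("chain lengths sum to %d but n_res is %d", sum(chains$n_res), n_res)
  map <- renumber_chains(stats::setNames(lapply(chains$n_res, seq_len), chains$chain_id))
  base <- ca_trace(n_res)
  # separate chains in space so the trace stays self-avoiding across chains
  offset <- 18 * (match(map$chain_id, chains$chain_id) - 1)
  resnames <- rep_len(resnames, n_res)
  atoms <- data.frame(
    serial = seq_len(n_res), name = "CA", element = "C",
    resname = resnames, chain = map$chain_id, resno = map$resno,
    residue_index = map$residue_index,
    x = base[, 1] + offset, y = base[, 2], z = base[, 3],
    mass = element_mass("C"), stringsAsFactors = FALSE
  )
  new_structure(atoms, chains, map)
}

# Symmetric PSD square root with eigenvalue clipping.
psd_sqrt <- function(S, floor_frac = 1e-10) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, floor_frac * max(e$values))
  e$vectors %*% (sqrt(lam) * t(e$vectors))
}

validate_correlation <- function(R, tol = 1e-8) {
  if (!isSymmetric(unname(R), tol = 1e-10))
    validation_error("correlation matrix must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-10)
    validation_error("correlation matrix must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(ev))
    validation_error("correlation matrix is not positive semidefinite (min eigenvalue %.3g)",
                     min(ev))
  invisible(R)
}

#' Specification for a synthetic Gaussian ensemble
#'
#' @param n_res number of residues.
#' @param correlation target residue-residue correlation matrix (symmetric
#'   PSD, unit diagonal; default identity).
#' @param sigma per-residue displacement scale, Angstrom (default 1;
#'   recycled).
#' @param n_frames number of frames.
#' @param seed RNG seed (mandatory: generation must be reproducible).
#' @param chains optional data.frame (chain_id, role, n_res).
#' @param resnames residue names for the trace (default "GLY"; recycled).
#' @param timestep ps per frame (default 10).
#' @return validated spec list of class `allopath_ensemble_spec`.
#' @export
ensemble_spec <- function(n_res, correlation = NULL, sigma = 1, n_frames = 1000,
                          seed, chains = NULL, resnames = "GLY", timestep = 10) {
  if (missing(seed)) validation_error("ensemble_spec requires an explicit seed")
  correlation <- correlation %||% diag(n_res)
  if (!all(dim(correlation) == n_res))
    validation_error("correlation must be %d x %d", n_res, n_res)
  validate_correlation(correlation)
  sigma <- rep_len(sigma, n_res)
  if (any(sigma <= 0)) validation_error("sigma must be positive")
  structure(list(n_res = n_res, correlation = correlation, sigma = sigma,
                 n_frames = n_frames, seed = as.integer(seed), chains = chains,
                 resnames = resnames, timestep = timestep),
            class = "allopath_ensemble_spec")
}

#' Generate a Gaussian Calpha ensemble with prescribed correlations
#'
#' Draws per-frame displacements independently per axis from the
#' multivariate normal with covariance sigma_i sigma_j rho_ij and adds them
#' to the helical rest trace. Deterministic given the spec's seed.
#'
#' @param spec an [ensemble_spec()].
#' @return list with `structure`, `trajectory` and `spec`.
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "allopath_ensemble_spec"))
  st <- make_ca_structure(spec$n_res, spec$chains, spec$resnames)
  Sig <- outer(spec$sigma, spec$sigma) * spec$correlation
  A <- psd_sqrt(Sig)
  base <- as.matrix(st$atoms[, c("x", "y", "z")])
  coords <- array(0, dim = c(spec$n_frames, spec$n_res, 3))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(spec$seed)
  for (ax in 1:3) {
    Z <- matrix(stats::rnorm(spec$n_frames * spec$n_res), spec$n_frames, spec$n_res)
    coords[, , ax] <- Z %*% A + matrix(base[, ax], spec$n_frames, spec$n_res, byrow = TRUE)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  list(structure = st, trajectory = new_trajectory(coords, st, spec$timestep),
       spec = spec)
}

#' Specification for a planted communication chain
#'
#' Defines a chain of residues (source, intermediates, target) whose
#' pairwise correlation is raised to `rho_on` while all other residue pairs
#' carry only weak background correlation (|rho| around `rho_off`), so the
#' chain is the unique low-weight route between the two end residues in the
#' fused residue graph.
#'
#' @param chain integer vector of chain residues in order (first = source,
#'   last = target); consecutive members must be in spatial contact on the
#'   base trace.
#' @param rho_on on-chain pairwise correlation (default 0.9).
#' @param rho_off background correlation scale for all other pairs
#'   (default 0.1; 0 disables background noise).
#' @param contact_radius Angstrom within which consecutive chain members
#'   must sit (default 10).
#' @return list of class `allopath_planted_spec`.
#' @export
planted_path_spec <- function(chain, rho_on = 0.9, rho_off = 0.1, contact_radius = 10) {
  chain <- as.integer(chain)
  if (length(chain) < 2 || anyDuplicated(chain))
    validation_error("planted chain needs >= 2 distinct residues")
  if (rho_on <= 0 || rho_on >= 1) validation_error("rho_on must be in (0, 1)")
  if (rho_off < 0 || rho_off >= rho_on)
    validation_error("rho_off must be in [0, rho_on)")
  structure(list(chain = chain, rho_on = rho_on, rho_off = rho_off,
                 contact_radius = contact_radius),
            class = "allopath_planted_spec")
}

#' Generate an ensemble containing a planted communication chain
#'
#' Builds a correlation matrix with a compound-symmetric `rho_on` block on
#' the chain residues over a weak random background (a Wishart-style random
#' correlation with off-diagonal scale `rho_off`), projects it to the
#' nearest unit-diagonal PSD matrix, and samples the ensemble. The returned
#' `truth` is the planted chain.
#'
#' @param spec a [planted_path_spec()].
#' @param base an [ensemble_spec()]; its `correlation` slot is ignored and
#'   replaced by the planted construction.
#' @return list with `structure`, `trajectory`, `truth` (chain residues) and
#'   `correlation` (the exact generating matrix).
#' @export
generate_planted_path <- function(spec, base) {
  stopifnot(inherits(spec, "allopath_planted_spec"),
            inherits(base, "allopath_ensemble_spec"))
  n <- base$n_res
  if (any(spec$chain < 1 | spec$chain > n))
    validation_error("chain residue outside 1..%d", n)
  trace <- ca_trace(n)
  steps <- sqrt(rowSums((trace[spec$chain[-1], , drop = FALSE] -
                           trace[spec$chain[-length(spec$chain)], , drop = FALSE])^2))
  if (any(steps > spec$contact_radius))
    validation_error("consecutive planted-chain residues %d A apart exceed contact radius %g",
                     ceiling(max(steps)), spec$contact_radius)

  # Background: a Gaussian kernel in the 3D distance of the rest trace,
  # rho_bg(i,j) = rho_off^((d_ij / 3.8)^2), so sequence neighbours carry the
  # stated background correlation and coupling decays with distance the way
  # protein DCCMs do. A Gaussian radial kernel is positive semidefinite by
  # construction. rho_off = 0 gives an identity background (no off-chain
  # coupling at all).
  if (spec$rho_off > 0) {
    d2 <- as.matrix(stats::dist(trace))^2
    R <- spec$rho_off^(d2 / 3.8^2)
  } else {
    R <- diag(n)
  }
  # Planted chain: Gaussian decay in hop count, rho(c_i, c_j) =
  # rho_on^((i-j)^2) (again a PSD kernel). The super-multiplicative decay
  # makes two consecutive hops strictly cheaper than one double hop under
  # -ln|C| weighting, so shortest paths traverse every chain member instead
  # of skipping alternate ones through i,i+2 contacts.
  pos <- seq_along(spec$chain)
  R[spec$chain, spec$chain] <- spec$rho_on^(outer(pos, pos, "-")^2)
  diag(R) <- 1
  # re-project: block overwrite can leave slightly negative eigenvalues
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 1e-8 * max(e$values))
  R <- stats::cov2cor(e$vectors %*% (lam * t(e$vectors)))

  base$correlation <- R
  gen <- generate_ensemble(base)
  list(structure = gen$structure, trajectory = gen$trajectory,
       truth = spec$chain, correlation = R)
}

#' Toy fixtures with controlled interaction geometry
#'
#' Emits a minimal structure (plus a one-frame trajectory) whose geometry is
#' parameterised so each detector criterion can be probed just inside and
#' just outside its threshold.
#'
#' @param kind one of `"hbond"`, `"hydrophobic"`, `"cation_pi"`, `"pi_pi"`.
#' @param distance the controlled distance, Angstrom: donor-acceptor for
#'   hbond, Calpha-Calpha for hydrophobic, min ring-atom to N for cation_pi,
#'   centroid-centroid for pi_pi.
#' @param angle D-H...A angle in degrees (hbond only, default 180).
#' @return list with `structure` and `trajectory` (1 frame).
#' @export
generate_interaction_fixture <- function(kind = c("hbond", "hydrophobic",
                                                  "cation_pi", "pi_pi"),
                                         distance, angle = 180) {
  kind <- match.arg(kind)
  mk <- function(df, chains = NULL) {
    df$serial <- seq_len(nrow(df))
    df$residue_index <- match(df$resno, sort(unique(df$resno)))
    df$mass <- element_mass(df$element)
    chains <- chains %||% data.frame(chain_id = "A", role = "protein",
                                     n_res = length(unique(df$resno)))
    map <- renumber_chains(stats::setNames(list(unique(df$resno)), chains$chain_id[1]))
    st <- new_structure(df[, c("serial", "name", "element", "resname", "chain",
                               "resno", "residue_index", "x", "y", "z", "mass")],
                        chains, map)
    coords <- array(as.matrix(df[, c("x", "y", "z")]), dim = c(1, nrow(df), 3))
    list(structure = st, trajectory = new_trajectory(coords, st))
  }
  if (kind == "hbond") {
    th <- angle * pi / 180
    disc <- cos(th)^2 - 1 + distance^2
    if (disc < 0) validation_error("no geometry with that distance/angle combination")
    t_len <- cos(th) + sqrt(disc)
    a_pos <- c(-cos(th), sin(th), 0) * t_len
    df <- data.frame(
      name = c("OG", "HG", "OG"), element = c("O", "H", "O"),
      resname = "SER", chain = "A", resno = c(1L, 1L, 2L),
      x = c(-1, 0, a_pos[1]), y = c(0, 0, a_pos[2]), z = c(0, 0, a_pos[3]),
      stringsAsFactors = FALSE
    )
    return(mk(df))
  }
  if (kind == "hydrophobic") {
    df <- data.frame(
      name = "CA", element = "C", resname = c("LEU", "GLY", "LEU"),
      chain = "A", resno = 1:3,
      x = c(0, distance / 2, distance), y = c(0, 8, 0), z = 0,
      stringsAsFactors = FALSE
    )
    return(mk(df))
  }
  hexagon <- function(center, z = 0) {
    ang <- (0:5) * pi / 3
    cbind(center[1] + 1.39 * cos(ang), center[2] + 1.39 * sin(ang), center[3] + z)
  }
  ring_names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  if (kind == "cation_pi") {
    ring <- hexagon(c(0, 0, 0))
    nearest <- ring[1, ]  # at (1.39, 0, 0)
    df <- data.frame(
      name = c(ring_names, "NZ"), element = c(rep("C", 6), "N"),
      resname = c(rep("PHE", 6), "LYS"), chain = "A",
      resno = c(rep(1L, 6), 3L),
      x = c(ring[, 1], nearest[1] + distance),
      y = c(ring[, 2], nearest[2]), z = c(ring[, 3], nearest[3]),
      stringsAsFactors = FALSE
    )
    return(mk(df))
  }
  ring1 <- hexagon(c(0, 0, 0))
  ring2 <- hexagon(c(0, 0, 0), z = distance)
  df <- data.frame(
    name = rep(ring_names, 2), element = "C", resname = "PHE", chain = "A",
    resno = rep(c(1L, 3L), each = 6),
    x = c(ring1[, 1], ring2[, 1]), y = c(ring1[, 2], ring2[, 2]),
    z = c(ring1[, 3], ring2[, 3]), stringsAsFactors = FALSE
  )
  mk(df)
}
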