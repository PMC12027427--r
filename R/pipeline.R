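#' Run configuration for the full analysis
#'
#' A single configuration drives the whole per-system workflow: backbone
#' metrics, correlation matrices, PCA/free-energy landscape, residue-graph
#' pathway mining and interaction occupancy. Inputs are either files
#' (`structure`/`trajectory` paths) or a synthetic system (`simulate`
#' block). Every analysis default is echoed into the run manifest so no
#' parameter stays implicit.
#'
#' @param structure path to a PDB structure (NULL when simulating).
#' @param trajectory path to a multi-model PDB / XYZ trajectory.
#' @param simulate NULL, or a list describing a synthetic system:
#'   `n_res`, `n_frames`, optional `chain` (planted communication chain),
#'   `rho_on`, `rho_off`, `sigma`.
#' @param chain_roles named character vector of chain roles.
#' @param sites named list of global residue index vectors (e.g.
#'   `orthosteric`, `allosteric`) used for occupancy and, when both are
#'   present, as source/target sets reported alongside the pathway map.
#' @param contact_cutoff,contact_mode residue contact matrix parameters.
#' @param f_min,c_min,importance_threshold residue-graph fusion and
#'   shortest-path-map parameters.
#' @param bins,temperature free-energy landscape parameters.
#' @param criteria an [interaction_criteria()] list.
#' @param hydrophobic_mode `"ca"` or `"sidechain"`.
#' @param timestep ps per frame.
#' @param output_dir where stage outputs and the manifest are written.
#' @param seed RNG seed for stochastic stages (simulation).
#' @return validated config list of class `allopath_config`.
#' @export
run_config <- function(structure = NULL, trajectory = NULL, simulate = NULL,
                       chain_roles = NULL, sites = list(),
                       contact_cutoff = 10, contact_mode = "min_heavy",
                       f_min = 0.5, c_min = 0.05, importance_threshold = 0.3,
                       bins = 50, temperature = 300,
                       criteria = interaction_criteria(),
                       hydrophobic_mode = "ca", timestep = 10,
                       output_dir = "allopath_out", seed = 1L) {
  if (is.null(simulate)) {
    if (is.null(structure) || is.null(trajectory))
      validation_error("config needs either structure+trajectory paths or a simulate block")
    if (!file.exists(structure)) validation_error("structure file not found: %s", structure)
    if (!file.exists(trajectory)) validation_error("trajectory file not found: %s", trajectory)
  }
  cfg <- list(structure = structure, trajectory = trajectory, simulate = simulate,
              chain_roles = chain_roles, sites = sites,
              contact_cutoff = contact_cutoff, contact_mode = contact_mode,
              f_min = f_min, c_min = c_min,
              importance_threshold = importance_threshold,
              bins = bins, temperature = temperature,
              criteria = unclass(criteria), hydrophobic_mode = hydrophobic_mode,
              timestep = timestep, output_dir = output_dir, seed = as.integer(seed))
  class(cfg) <- "allopath_config"
  cfg
}

#' Read a run configuration from a YAML file
#' @param path YAML file; keys as in [run_config()].
#' @return an `allopath_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  crit <- do.call(interaction_criteria, y$criteria %||% list())
  args <- y[setdiff(names(y), "criteria")]
  args$criteria <- crit
  if (!is.null(args$chain_roles)) args$chain_roles <- unlist(args$chain_roles)
  if (!is.null(args$sites)) args$sites <- lapply(args$sites, as.integer)
  do.call(run_config, args)
}

write_tsv <- function(d, path) {
  num <- vapply(d, is.double, logical(1))
  d[num] <- lapply(d[num], function(v) sprintf("%.10g", v))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the complete per-system analysis
#'
#' Stages: input (read or simulate), backbone metrics (RMSD, Rg, RMSF),
#' correlation (DCCM + contact matrix), ensemble (PCA + FEL), pathway
#' (fused residue graph + shortest-path map) and interactions (events +
#' occupancy). All outputs are plain text under `config$output_dir`; the
#' returned manifest lists every file with its MD5 hash, so two runs of the
#' same config and seed can be compared byte for byte. A stage failure
#' aborts with the stage name; files already written are retained and the
#' manifest records the failed stage.
#'
#' @param config an `allopath_config` (or a YAML path).
#' @return the run manifest (also written as `manifest.json`), invisibly.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "allopath_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(name) file.path(config$output_dir, name)
  written <- character(0)
  warnings <- character(0)
  manifest <- list(config = config[setdiff(names(config), "criteria")],
                   criteria = config$criteria,
                   version = as.character(utils::packageVersion("allopath")))
  truth <- NULL

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$failed_stage <- name
      manifest$error <- conditionMessage(e)
      manifest$files <- as.list(tools::md5sum(written))
      jsonlite::write_json(manifest, outfile("manifest.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # --- input ---------------------------------------------------------------
  sys <- stage("input", {
    if (!is.null(config$simulate)) {
      s <- config$simulate
      base <- ensemble_spec(n_res = s$n_res, sigma = s$sigma %||% 1,
                            n_frames = s$n_frames %||% 1000,
                            seed = config$seed, timestep = config$timestep,
                            resnames = s$resnames %||% "GLY")
      if (!is.null(s$chain)) {
        ps <- planted_path_spec(as.integer(s$chain), rho_on = s$rho_on %||% 0.9,
                                rho_off = s$rho_off %||% 0.1)
        g <- generate_planted_path(ps, base)
        truth <- g$truth
        g
      } else generate_ensemble(base)
    } else {
      st <- read_structure(config$structure, config$chain_roles)
      list(structure = st,
           trajectory = read_trajectory(config$trajectory, st, config$timestep))
    }
  })
  st <- sys$structure; traj <- sys$trajectory
  ca <- select_atoms(st, "ca")

  # --- backbone metrics ----------------------------------------------------
  stage("metrics", {
    written <- c(written, write_tsv(rmsd_series(traj, 1L, ca), outfile("rmsd.tsv")))
    written <- c(written, write_tsv(rg_series(traj, ca), outfile("rg.tsv")))
    written <- c(written, write_tsv(rmsf_profile(traj, ca), outfile("rmsf.tsv")))
  })

  # --- correlation ---------------------------------------------------------
  corr <- stage("correlation", {
    C <- dccm(covariance_matrix(traj, ca))
    rcm <- contact_matrix(traj, cutoff = config$contact_cutoff,
                          distance_mode = config$contact_mode)
    written <- c(written, write_matrix(unclass(C), outfile("dccm.tsv"),
                                        rownames(C)))
    written <- c(written, write_matrix(matrix(as.numeric(rcm), nrow(rcm)),
                                        outfile("rcm.tsv"), rownames(rcm)))
    list(C = C, rcm = rcm)
  })

  # --- ensemble ------------------------------------------------------------
  stage("ensemble", {
    p <- pca_ca(traj, ca)
    eigsum <- data.frame(pc = seq_along(p$eigenvalues),
                         eigenvalue = p$eigenvalues,
                         variance_fraction = p$variance_fraction,
                         cumulative = cumsum(p$variance_fraction))
    written <- c(written, write_tsv(eigsum, outfile("pca_summary.tsv")))
    fel <- free_energy_landscape(p, bins = config$bins,
                                 temperature = config$temperature)
    written <- c(written, write_tsv(fel_table(fel), outfile("fel.tsv")))
  })

  # --- pathway -------------------------------------------------------------
  spm <- stage("pathway", {
    g <- build_rdcm_graph(corr$C, corr$rcm, f_min = config$f_min,
                          c_min = config$c_min)
    spm <- extract_spm(g, importance_threshold = config$importance_threshold)
    written <- c(written, write_tsv(spm$edges, outfile("rdcm_edges.tsv")))
    written <- c(written, write_tsv(data.frame(residue = spm$hotspots),
                                     outfile("hotspots.tsv")))
    if (length(config$sites) >= 2) {
      sp <- shortest_paths(g, config$sites[[1]], config$sites[[2]])
      written <- c(written, write_tsv(sp, outfile("site_paths.tsv")))
    }
    spm
  })

  # --- interactions --------------------------------------------------------
  stage("interactions", {
    crit <- do.call(interaction_criteria, config$criteria)
    ev <- withCallingHandlers(
      detect_interactions(traj, crit, hydrophobic_mode = config$hydrophobic_mode),
      warning = function(w) {
        warnings <<- c(warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    written <- c(written, write_tsv(ev, outfile("events.tsv")))
    sites <- config$sites
    if (!length(sites))
      sites <- list(all = sort(unique(st$atoms$residue_index)))
    occ <- do.call(rbind, lapply(names(sites), function(nm) {
      occupancy_table(ev, traj$n_frames, sites[[nm]], label = nm)
    }))
    if (is.null(occ) || !nrow(occ))
      occ <- data.frame(site = character(), type = character(),
                        occupancy_pct = numeric(), min = numeric(),
                        max = numeric(), mean = numeric())
    written <- c(written, write_tsv(occ, outfile("occupancy.tsv")))
  })

  manifest$hotspots <- spm$hotspots
  if (!is.null(truth)) manifest$planted_chain <- truth
  manifest$warnings <- warnings
  manifest$files <- as.list(tools::md5sum(sort(unique(written))))
  jsonlite::write_json(manifest, outfile("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Cross-system consensus of pathway hotspots
#'
#' Collects the hotspot residues of several completed runs and intersects
#' them with [common_residues()], emitting the per-system lists plus a final
#' consensus row.
#'
#' @param manifests list of manifests returned by [run_all()] (or paths to
#'   `manifest.json` files).
#' @param window residue-position tolerance for the intersection (default 0).
#' @param path optional output TSV.
#' @return data.frame with columns `system` and `residues`
#'   (comma-separated); last row is the consensus.
#' @export
compare_systems <- function(manifests, window = 0, path = NULL) {
  if (length(manifests) < 2) validation_error("need at least two systems to compare")
  hot <- lapply(manifests, function(m) {
    if (is.character(m)) m <- jsonlite::read_json(m, simplifyVector = TRUE)
    as.integer(m$hotspots)
  })
  names(hot) <- names(manifests) %||% paste0("system", seq_along(hot))
  consensus <- common_residues(hot, window = window)
  out <- data.frame(
    system = c(names(hot), "common"),
    residues = c(vapply(hot, function(v) paste(v, collapse = ","), character(1)),
                 paste(consensus, collapse = ",")),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) write_tsv(out, path)
  out
}
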