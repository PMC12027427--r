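#' @title Structure and trajectory containers
#'
#' @description
#' A `Structure` holds atoms grouped into residues and chains together with a
#' continuous multi-chain residue renumbering map; a `Trajectory` holds the
#' per-frame coordinates of those atoms. All coordinates are in Angstrom.
#'
#' Global residue numbering is 1-based and continuous across chains in the
#' declared chain order (default: alternating light-heavy, L-H-L'-H'), so
#' residue identities remain unambiguous in multi-chain assemblies such as
#' full antibodies where the same author number recurs on every chain.
#' Ligand and glycan chains are appended after all protein chains so that
#' protein-only matrices stay dense and contiguous.
#'
#' @name structure-classes
NULL

new_structure <- function(atoms, chains, renumber_map) {
  stopifnot(is.data.frame(atoms), is.data.frame(chains), is.data.frame(renumber_map))
  structure(list(atoms = atoms, chains = chains, renumber_map = renumber_map),
            class = "allopath_structure")
}

new_trajectory <- function(coords, structure, timestep = 10) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    validation_error("trajectory coordinates must be an n_frames x n_atoms x 3 array")
  if (dim(coords)[2] != nrow(structure$atoms))
    validation_error("trajectory has %d atoms but structure has %d",
                     dim(coords)[2], nrow(structure$atoms))
  if (!all(is.finite(coords))) validation_error("trajectory contains non-finite coordinates")
  structure(list(coords = coords, structure = structure, timestep = timestep,
                 n_frames = dim(coords)[1]),
            class = "allopath_trajectory")
}

#' @export
print.allopath_structure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d residues, %d chains (%s)\n",
              nrow(x$atoms), max(x$atoms$residue_index), nrow(x$chains),
              paste(x$chains$chain_id, collapse = ",")))
  invisible(x)
}

#' @export
print.allopath_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, %.4g ps/frame\n",
              x$n_frames, dim(x$coords)[2], x$timestep))
  invisible(x)
}

#' Build a continuous multi-chain residue renumbering map
#'
#' Assigns 1-based global residue indices that run continuously across chains
#' in the order supplied by the caller (for an IgG: light, heavy, light',
#' heavy'). The map is a bijection: every (chain, author residue number) pair
#' maps to exactly one global index and back.
#'
#' @param chains either a data.frame with columns `chain_id` and `n_res`
#'   (author numbers then assumed 1..n per chain), or a named list giving,
#'   per chain and in order, the vector of author residue numbers.
#' @return data.frame with columns `chain_id`, `resno` (author number) and
#'   `residue_index` (global).
#' @export
renumber_chains <- function(chains) {
  if (is.data.frame(chains)) {
    if (!all(c("chain_id", "n_res") %in% names(chains)))
      validation_error("chains data.frame needs columns chain_id and n_res")
    if (any(chains$n_res < 1)) validation_error("empty chain in renumbering input")
    chains <- stats::setNames(lapply(chains$n_res, seq_len), chains$chain_id)
  }
  if (!length(chains)) validation_error("no chains to renumber")
  if (any(!lengths(chains))) validation_error("empty chain in renumbering input")
  map <- data.frame(
    chain_id = rep(names(chains), lengths(chains)),
    resno = unlist(chains, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  map$residue_index <- seq_len(nrow(map))
  dup <- duplicated(map[c("chain_id", "resno")])
  if (any(dup))
    validation_error("duplicate author residue number %s in chain %s",
                     map$resno[dup][1], map$chain_id[dup][1])
  map
}

#' Invert a renumbering map
#'
#' @param map a renumber map from [renumber_chains()].
#' @param residue_index global indices to look up.
#' @return data.frame rows of the map for the requested global indices.
#' @export
lookup_residue <- function(map, residue_index) {
  i <- match(residue_index, map$residue_index)
  if (anyNA(i)) validation_error("global residue index %s not in renumber map",
                                 residue_index[which(is.na(i))[1]])
  map[i, , drop = FALSE]
}

# ---- PDB parsing ------------------------------------------------------------

# Fixed-column PDB ATOM/HETATM fields per the wwPDB format; `lines` must be
# the raw record lines, `lineno` their 1-based file positions (for errors).
parse_pdb_atoms <- function(lines, lineno) {
  field <- function(from, to) trimws(substr(lines, from, to))
  xs <- suppressWarnings(as.numeric(field(31, 38)))
  ys <- suppressWarnings(as.numeric(field(39, 46)))
  zs <- suppressWarnings(as.numeric(field(47, 54)))
  bad <- which(!is.finite(xs) | !is.finite(ys) | !is.finite(zs))
  if (length(bad))
    format_error("malformed coordinate field at line %d: '%s'",
                 lineno[bad[1]], lines[bad[1]])
  serial <- suppressWarnings(as.integer(field(7, 11)))
  serial[is.na(serial)] <- seq_along(lines)[is.na(serial)]
  occ <- suppressWarnings(as.numeric(field(55, 60)))
  occ[is.na(occ)] <- 1
  elem <- field(77, 78)
  name <- field(13, 16)
  elem[elem == ""] <- infer_element(name[elem == ""])
  data.frame(
    record = field(1, 6), serial = serial, name = name,
    altloc = substr(lines, 17, 17),
    resname = field(18, 20), chain = field(22, 22),
    resno = suppressWarnings(as.integer(field(23, 26))),
    x = xs, y = ys, z = zs, occupancy = occ,
    element = toupper(elem), lineno = lineno,
    stringsAsFactors = FALSE
  )
}

# Keep the highest-occupancy alternate location per (chain, resno, atom name);
# ties resolved toward the alphabetically first altloc for determinism.
resolve_altloc <- function(at) {
  if (all(at$altloc %in% c("", " "))) return(at)
  key <- paste(at$chain, at$resno, at$name, sep = "\r")
  ord <- order(key, -at$occupancy, at$altloc)
  at <- at[ord, ]
  at <- at[!duplicated(paste(at$chain, at$resno, at$name, sep = "\r")), ]
  at[order(at$lineno), ]
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records (first MODEL only), resolves alternate
#' locations to the highest-occupancy conformer, infers missing element
#' symbols from atom names, and builds the continuous multi-chain renumber
#' map. Chains with role `ligand` or `glycan` are moved after all protein
#' chains in the global numbering.
#'
#' @param path PDB file path.
#' @param chain_roles named character vector mapping chain id to one of
#'   `light`, `heavy`, `ligand`, `glycan` (default: all chains `light`-like
#'   protein in file order).
#' @param chain_order optional explicit chain ordering for the renumbering
#'   (default: protein chains in file order, then ligand/glycan chains).
#' @return an `allopath_structure`.
#' @export
read_structure <- function(path, chain_roles = NULL, chain_order = NULL) {
  if (!file.exists(path)) validation_error("structure file not found: %s", path)
  raw <- readLines(path, warn = FALSE)
  end1 <- which(substr(raw, 1, 6) %in% c("ENDMDL"))[1]
  keep <- seq_len(if (is.na(end1)) length(raw) else end1)
  rec <- substr(raw[keep], 1, 6)
  sel <- which(trimws(rec) %in% c("ATOM", "HETATM"))
  if (!length(sel)) format_error("no ATOM/HETATM records in %s", path)
  at <- parse_pdb_atoms(raw[keep][sel], keep[sel])
  if (anyNA(at$resno))
    format_error("malformed residue number at line %d", at$lineno[which(is.na(at$resno))[1]])
  at <- resolve_altloc(at)
  dup <- duplicated(paste(at$chain, at$resno, at$name, sep = "\r"))
  if (any(dup))
    validation_error("duplicate atom (chain %s, residue %d, atom %s)",
                     at$chain[dup][1], at$resno[dup][1], at$name[dup][1])
  build_structure_from_atoms(at, chain_roles, chain_order)
}

# Shared finishing step: order chains, renumber residues, attach masses.
build_structure_from_atoms <- function(at, chain_roles = NULL, chain_order = NULL) {
  file_chains <- unique(at$chain)
  roles <- stats::setNames(rep("protein", length(file_chains)), file_chains)
  if (!is.null(chain_roles)) {
    unknown <- setdiff(names(chain_roles), file_chains)
    if (length(unknown))
      validation_error("chain_roles names chain '%s' not present in file", unknown[1])
    roles[names(chain_roles)] <- unname(chain_roles)
  }
  is_lig <- stats::setNames(roles %in% c("ligand", "glycan"), names(roles))
  ord <- chain_order %||% c(file_chains[!is_lig[file_chains]], file_chains[is_lig[file_chains]])
  if (!setequal(ord, file_chains))
    validation_error("chain_order must name exactly the chains present")

  per_chain <- lapply(ord, function(ch) unique(at$resno[at$chain == ch]))
  names(per_chain) <- ord
  map <- renumber_chains(per_chain)

  at$residue_index <- map$residue_index[match(paste(at$chain, at$resno),
                                              paste(map$chain_id, map$resno))]
  at <- at[order(at$residue_index, at$lineno), ]
  at$mass <- element_mass(at$element)
  chains <- data.frame(chain_id = ord, role = unname(roles[ord]),
                       n_res = lengths(per_chain), stringsAsFactors = FALSE)
  atoms <- at[, c("serial", "name", "element", "resname", "chain", "resno",
                  "residue_index", "x", "y", "z", "mass")]
  rownames(atoms) <- NULL
  new_structure(atoms, chains, map)
}

#' Read a trajectory
#'
#' Reads a multi-model PDB (MODEL/ENDMDL blocks) or a multi-frame XYZ file
#' into a Trajectory over a previously parsed Structure. Every frame must
#' contain the same number of atoms as the structure.
#'
#' @param path trajectory file path (`.pdb` or `.xyz` by extension).
#' @param structure the `allopath_structure` the frames instantiate.
#' @param timestep ps between saved frames (default 10, the usual MD save
#'   interval).
#' @return an `allopath_trajectory`.
#' @export
read_trajectory <- function(path, structure, timestep = 10) {
  if (!file.exists(path)) validation_error("trajectory file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  coords <- if (ext == "xyz") read_xyz_frames(path) else read_pdb_frames(path)
  n_at <- nrow(structure$atoms)
  for (f in seq_along(coords)) {
    if (nrow(coords[[f]]) != n_at)
      validation_error("frame %d has %d atoms, structure has %d",
                       f, nrow(coords[[f]]), n_at)
  }
  arr <- array(0, dim = c(length(coords), n_at, 3))
  for (f in seq_along(coords)) arr[f, , ] <- coords[[f]]
  new_trajectory(arr, structure, timestep)
}

read_pdb_frames <- function(path) {
  raw <- readLines(path, warn = FALSE)
  rec <- trimws(substr(raw, 1, 6))
  model_starts <- which(rec == "MODEL")
  is_atom <- rec %in% c("ATOM", "HETATM")
  if (!length(model_starts)) {
    at <- parse_pdb_atoms(raw[is_atom], which(is_atom))
    return(list(as.matrix(at[, c("x", "y", "z")])))
  }
  bounds <- c(model_starts, length(raw) + 1L)
  lapply(seq_along(model_starts), function(f) {
    idx <- which(is_atom & seq_along(raw) > bounds[f] & seq_along(raw) < bounds[f + 1])
    at <- parse_pdb_atoms(raw[idx], idx)
    as.matrix(at[, c("x", "y", "z")])
  })
}

read_xyz_frames <- function(path) {
  raw <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(raw)) {
    if (!nzchar(trimws(raw[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(raw[i])))
    if (is.na(n)) format_error("expected atom count at line %d of XYZ file", i)
    if (i + 1L + n > length(raw))
      format_error("truncated XYZ frame starting at line %d", i)
    block <- raw[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    xyz <- t(vapply(seq_along(parts), function(k) {
      p <- parts[[k]]
      if (length(p) < 4) format_error("malformed XYZ atom line %d", i + 1L + k)
      v <- suppressWarnings(as.numeric(p[2:4]))
      if (anyNA(v)) format_error("malformed coordinate field at line %d", i + 1L + k)
      v
    }, numeric(3)))
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  if (!length(frames)) format_error("no frames in XYZ file %s", path)
  frames
}

# ---- writers ----------------------------------------------------------------

pdb_atom_lines <- function(atoms, xyz) {
  # fixed wwPDB columns: name 13-16, resname 18-20, chain 22, resno 23-26,
  # coords 31-54, element 77-78
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$serial %% 100000L, substr(atoms$name, 1, 4),
          substr(atoms$resname, 1, 3), substr(atoms$chain, 1, 1),
          atoms$resno %% 10000L, xyz[, 1], xyz[, 2], xyz[, 3],
          1, 0, substr(atoms$element, 1, 2))
}

#' Write a structure (and optionally trajectory frames) as PDB
#'
#' @param x an `allopath_structure` or `allopath_trajectory`; trajectories
#'   are written as multi-model PDB (MODEL/ENDMDL per frame).
#' @param path output file.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "allopath_structure")) {
    writeLines(c(pdb_atom_lines(x$atoms, as.matrix(x$atoms[, c("x", "y", "z")])), "END"),
               path)
  } else if (inherits(x, "allopath_trajectory")) {
    at <- x$structure$atoms
    out <- unlist(lapply(seq_len(x$n_frames), function(f) {
      c(sprintf("MODEL     %4d", f), pdb_atom_lines(at, x$coords[f, , , drop = TRUE]), "ENDMDL")
    }))
    writeLines(c(out, "END"), path)
  } else validation_error("write_pdb expects a structure or trajectory")
  invisible(path)
}

#' Write a trajectory as multi-frame XYZ
#' @param traj an `allopath_trajectory`.
#' @param path output file.
#' @export
write_xyz <- function(traj, path) {
  at <- traj$structure$atoms
  out <- unlist(lapply(seq_len(traj$n_frames), function(f) {
    xyz <- traj$coords[f, , , drop = TRUE]
    c(sprintf("%d", nrow(at)), sprintf("frame %d", f),
      sprintf("%s %.10g %.10g %.10g", at$element, xyz[, 1], xyz[, 2], xyz[, 3]))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Write / read a labelled square matrix as TSV at full precision
#'
#' The text representation uses 17 significant digits so that
#' `read_matrix(write_matrix(M))` round-trips `M` exactly.
#'
#' @param m square numeric matrix.
#' @param path output file.
#' @param labels residue labels for rows/columns (default: 1..n).
#' @export
write_matrix <- function(m, path, labels = NULL) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    validation_error("write_matrix expects a square matrix")
  labels <- labels %||% seq_len(nrow(m))
  if (length(labels) != nrow(m))
    validation_error("label length %d does not match matrix dimension %d",
                     length(labels), nrow(m))
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(labels[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(paste(c("residue", labels), collapse = "\t"), body), path)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  dat <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(dat[, -1, drop = FALSE])
  dimnames(m) <- list(dat[[1]], colnames(dat)[-1])
  m
}

#' Write a renumber map as a JSON sidecar
#' @param structure an `allopath_structure`.
#' @param path output JSON path.
#' @export
write_renumber_map <- function(structure, path) {
  jsonlite::write_json(structure$renumber_map, path, dataframe = "columns")
  invisible(path)
}
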