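# Independent brute-force oracles and fixture builders used across tests.
# These deliberately avoid the package's own code paths: naive loops,
# exhaustive enumeration and closed forms only.

# Random rigid transform (rotation from QR of a Gaussian matrix + shift).
random_rigid <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 20))
}

apply_rigid <- function(coords, rigid) {
  sweep(coords %*% rigid$R, 2, rigid$t, FUN = "+")
}

apply_rigid_traj <- function(traj, rigid) {
  for (f in seq_len(traj$n_frames)) {
    traj$coords[f, , ] <- apply_rigid(traj$coords[f, , , drop = TRUE], rigid)
  }
  traj
}

# Brute-force minimised RMSD: dense random-quaternion search refined by
# Nelder-Mead over the quaternion components.
bf_min_rmsd <- function(P, Q, n_grid = 20000, seed = 1) {
  rot_from_quat <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  obj <- function(q) {
    R <- rot_from_quat(q)
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  set.seed(seed)
  best <- Inf; best_q <- c(1, 0, 0, 0)
  for (k in seq_len(n_grid)) {
    q <- rnorm(4)
    v <- obj(q)
    if (v < best) { best <- v; best_q <- q }
  }
  opt <- stats::optim(best_q, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# Exhaustive simple-path enumeration: minimum total weight between every
# vertex pair of a small weighted undirected graph (adjacency matrix with
# Inf for missing edges).
bf_all_pairs_shortest <- function(W) {
  n <- nrow(W)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  paths_from <- function(v, target, visited, acc) {
    if (v == target) {
      if (acc < best[cur_s, target]) best[cur_s, target] <<- acc
      return(invisible())
    }
    for (u in seq_len(n)) {
      if (!visited[u] && is.finite(W[v, u])) {
        visited[u] <- TRUE
        paths_from(u, target, visited, acc + W[v, u])
        visited[u] <- FALSE
      }
    }
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      cur_s <- s
      visited <- rep(FALSE, n); visited[s] <- TRUE
      paths_from(s, t, visited, 0)
      best[t, s] <- best[s, t]
    }
  }
  best
}

# Random weighted graph as adjacency matrix (NULL entries = no edge).
random_graph_adj <- function(n, p_edge = 0.5) {
  W <- matrix(Inf, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p_edge) W[i, j] <- W[j, i] <- runif(1, 0.1, 3)
    }
  }
  W
}

adj_to_igraph <- function(W) {
  n <- nrow(W)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n)))
  idx <- which(upper.tri(W) & is.finite(W), arr.ind = TRUE)
  if (nrow(idx)) {
    g <- igraph::add_edges(g, rbind(idx[, 1], idx[, 2]))
    g <- igraph::set_edge_attr(g, "weight", value = W[idx])
  }
  g
}

# Random interaction test frame: residues of known composition scattered in
# a box, with ground-truth donor/acceptor/ring/cation bookkeeping collected
# while building, so oracles need not re-derive chemistry.
random_interaction_frame <- function(seed, n_res = 40, box = 28) {
  set.seed(seed)
  pool <- c("LEU", "VAL", "GLY", "SER", "PHE", "TYR", "LYS", "ARG")
  rows <- list(); truth_donors <- list(); truth_rings <- list(); truth_cations <- list()
  add <- function(res, name, el, center, offset) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, element = el, resname = resname, chain = "A", resno = res,
      x = center[1] + offset[1], y = center[2] + offset[2], z = center[3] + offset[3],
      stringsAsFactors = FALSE)
    length(rows)
  }
  for (res in seq_len(n_res)) {
    resname <- sample(pool, 1)
    center <- runif(3, 0, box)
    add(res, "CA", "C", center, c(0, 0, 0))
    if (resname == "SER") {
      i_og <- add(res, "OG", "O", center, c(1.2, 0, 0))
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      i_hg <- add(res, "HG", "H", center, c(1.2, 0, 0) + u)
      truth_donors[[length(truth_donors) + 1L]] <- c(res = res)
    }
    if (resname %in% c("PHE", "TYR")) {
      ang <- (0:5) * pi / 3
      nm <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
      for (k in 1:6)
        add(res, nm[k], "C", center, c(1.39 * cos(ang[k]) + 2, 1.39 * sin(ang[k]), 0.5))
      truth_rings[[length(truth_rings) + 1L]] <- c(res = res)
    }
    if (resname == "LYS") {
      add(res, "NZ", "N", center, c(-1.5, 1, 0))
      truth_cations[[length(truth_cations) + 1L]] <- c(res = res)
    }
    if (resname == "ARG") {
      add(res, "NH1", "N", center, c(-1.2, -1, 0.4))
      add(res, "NH2", "N", center, c(-1.2, 1, 0.4))
      truth_cations[[length(truth_cations) + 1L]] <- c(res = res)
    }
  }
  df <- do.call(rbind, rows)
  df$serial <- seq_len(nrow(df))
  df$residue_index <- df$resno
  df$mass <- 12
  chains <- data.frame(chain_id = "A", role = "protein", n_res = n_res)
  map <- renumber_chains(stats::setNames(list(seq_len(n_res)), "A"))
  st <- allopath:::new_structure(
    df[, c("serial", "name", "element", "resname", "chain", "resno",
           "residue_index", "x", "y", "z", "mass")], chains, map)
  coords <- array(as.matrix(df[, c("x", "y", "z")]), dim = c(1, nrow(df), 3))
  list(structure = st,
       trajectory = allopath:::new_trajectory(coords, st),
       coords = as.matrix(df[, c("x", "y", "z")]))
}

# Naive O(n^2) interaction oracles over explicit atom tables.
oracle_events <- function(st, coords, criteria) {
  at <- st$atoms
  d <- function(i, j) sqrt(sum((coords[i, ] - coords[j, ])^2))
  out <- list()
  # hydrogen bonds: every N/O/S with an H within 1.3 A (same residue) as
  # donor, every N/O/S as acceptor
  nos <- which(at$element %in% c("N", "O", "S"))
  hs <- which(at$element == "H")
  for (h in hs) {
    dcand <- nos[vapply(nos, function(i) at$residue_index[i] == at$residue_index[h], logical(1))]
    if (!length(dcand)) next
    dd <- vapply(dcand, function(i) d(i, h), numeric(1))
    if (min(dd) >= 1.3) next
    don <- dcand[which.min(dd)]
    for (a in nos) {
      if (at$residue_index[a] == at$residue_index[don]) next
      if (d(don, a) >= criteria$hbond_max_dist) next
      v1 <- coords[don, ] - coords[h, ]; v2 <- coords[a, ] - coords[h, ]
      ang <- acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang > criteria$hbond_min_angle)
        out[[length(out) + 1L]] <- data.frame(type = "hbond",
                                              res_a = at$residue_index[don],
                                              res_b = at$residue_index[a])
    }
  }
  # hydrophobic: CA-CA between hydrophobic resnames, |i-j| > 1
  hres <- sort(unique(at$residue_index[at$resname %in%
                 c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP")]))
  cas <- vapply(hres, function(r) which(at$residue_index == r & at$name == "CA")[1],
                integer(1))
  if (length(hres) > 1) {
    for (a in seq_along(hres)[-length(hres)]) for (b in (a + 1):length(hres)) {
      if (abs(hres[b] - hres[a]) <= 1) next
      if (d(cas[a], cas[b]) < criteria$hydrophobic_max_dist)
        out[[length(out) + 1L]] <- data.frame(type = "hydrophobic",
                                              res_a = hres[a], res_b = hres[b])
    }
  }
  # rings by canonical names
  rings <- list()
  for (r in unique(at$residue_index)) {
    rn <- at$resname[at$residue_index == r][1]
    nm <- list(PHE = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
               TYR = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"))[[rn]] %||% NULL
    if (is.null(nm)) next
    idx <- which(at$residue_index == r & at$name %in% nm)
    if (length(idx) == 6) rings[[length(rings) + 1L]] <- list(res = r, idx = idx)
  }
  cats <- which(at$name %in% c("NZ", "NH1", "NH2", "NE") & at$element == "N")
  for (ring in rings) for (cN in cats) {
    if (at$residue_index[cN] == ring$res) next
    dd <- vapply(ring$idx, function(i) d(i, cN), numeric(1))
    if (min(dd) < criteria$cation_pi_max_dist)
      out[[length(out) + 1L]] <- data.frame(type = "cation_pi", res_a = ring$res,
                                            res_b = at$residue_index[cN])
  }
  if (length(rings) > 1) {
    for (a in seq_along(rings)[-length(rings)]) for (b in (a + 1):length(rings)) {
      if (rings[[a]]$res == rings[[b]]$res) next
      ca <- colMeans(coords[rings[[a]]$idx, ]); cb <- colMeans(coords[rings[[b]]$idx, ])
      if (sqrt(sum((ca - cb)^2)) < criteria$pi_pi_max_centroid_dist)
        out[[length(out) + 1L]] <- data.frame(type = "pi_pi", res_a = rings[[a]]$res,
                                              res_b = rings[[b]]$res)
    }
  }
  if (!length(out)) return(data.frame(type = character(), res_a = integer(),
                                      res_b = integer()))
  ev <- do.call(rbind, out)
  ev[order(ev$type, ev$res_a, ev$res_b), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical event key set for exact comparisons
event_keys <- function(ev) {
  if (!nrow(ev)) return(character(0))
  a <- pmin(ev$res_a, ev$res_b); b <- pmax(ev$res_a, ev$res_b)
  sort(paste(ev$type, a, b))
}

# small multi-chain PDB written as text, returned as a path
write_toy_pdb <- function(path, models = 1) {
  lines <- character(0)
  atom <- function(serial, name, resname, chain, resno, x, y, z, el) {
    sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, name, resname, chain, resno, x, y, z, el)
  }
  block <- function(shift) {
    c(atom(1, "N", "GLY", "L", 1, 0 + shift, 0, 0, "N"),
      atom(2, "CA", "GLY", "L", 1, 1.5 + shift, 0, 0, "C"),
      atom(3, "CA", "ALA", "L", 2, 5 + shift, 0, 0, "C"),
      atom(4, "CA", "SER", "L", 3, 9 + shift, 0, 0, "C"),
      atom(5, "CA", "GLY", "H", 1, 0 + shift, 6, 0, "C"),
      atom(6, "CA", "ALA", "H", 2, 4 + shift, 6, 0, "C"),
      atom(7, "CA", "LEU", "H", 3, 8 + shift, 6, 0, "C"))
  }
  if (models == 1) {
    lines <- c(block(0), "END")
  } else {
    for (m in seq_len(models)) {
      lines <- c(lines, sprintf("MODEL     %4d", m), block(m - 1), "ENDMDL")
    }
    lines <- c(lines, "END")
  }
  writeLines(lines, path)
  path
}
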