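#' Fuse contact and correlation matrices into a weighted residue graph
#'
#' The residue distance cross-correlation graph combines the contact matrix
#' (which gates edges: residues must actually touch for a direct
#' communication link) with the dynamic cross-correlation matrix (which
#' weights them: strongly coupled residues transmit with low cost). An edge
#' (i, j) exists iff i != j, contact frequency >= `f_min` and |C(i,j)| >=
#' `c_min`; its weight is -ln|C(i,j)|, so |C| = 1 gives a free link and weak
#' coupling a costly one. An alternative linear weighting 1 - |C| is
#' available via `weighting`.
#'
#' @param dccm an `allopath_dccm` (or plain symmetric matrix with residue
#'   dimnames).
#' @param contacts an `allopath_contact` frequency matrix on the same
#'   residues.
#' @param f_min minimum contact frequency for an edge (default 0.5).
#' @param c_min minimum |C| for an edge (default 0.05); must be > 0 so
#'   zero-correlation (infinite-weight) edges are excluded.
#' @param weighting `"neg_log"` (default, -ln|C|) or `"linear"` (1 - |C|).
#' @return an igraph graph; vertices carry the global residue index as
#'   `name`, edges carry `weight`, `abs_c` and `freq`.
#' @export
build_rdcm_graph <- function(dccm, contacts, f_min = 0.5, c_min = 0.05,
                             weighting = c("neg_log", "linear")) {
  weighting <- match.arg(weighting)
  if (!all(dim(dccm) == dim(contacts)))
    validation_error("DCCM (%d) and contact matrix (%d) dimensions differ",
                     nrow(dccm), nrow(contacts))
  if (!is.null(dimnames(dccm)) && !is.null(dimnames(contacts)) &&
      !identical(rownames(dccm), rownames(contacts)))
    validation_error("DCCM and contact matrix residue labels differ")
  if (c_min <= 0) validation_error("c_min must be positive")
  n <- nrow(dccm)
  labels <- rownames(dccm) %||% as.character(seq_len(n))
  ut <- which(upper.tri(dccm), arr.ind = TRUE)
  keep <- contacts[ut] >= f_min & abs(dccm[ut]) >= c_min
  ij <- ut[keep, , drop = FALSE]
  absc <- pmin(abs(dccm[ij]), 1)
  w <- if (weighting == "neg_log") -log(absc) else 1 - absc
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = labels)
  if (nrow(ij)) {
    g <- igraph::add_edges(g, rbind(ij[, 1], ij[, 2]))
    g <- igraph::set_edge_attr(g, "weight", value = w)
    g <- igraph::set_edge_attr(g, "abs_c", value = absc)
    g <- igraph::set_edge_attr(g, "freq", value = contacts[ij])
  }
  g
}

#' Shortest communication paths between residue sets
#'
#' Minimal total-weight (Dijkstra) path for every (source, target) pair on
#' the fused residue graph. Edge weights are non-negative by construction.
#'
#' @param graph an igraph graph from [build_rdcm_graph()].
#' @param sources,targets global residue indices (vertex names).
#' @return data.frame with one row per pair: `source`, `target`, `weight`
#'   (Inf if unreachable), `path` (dash-separated residue sequence, NA if
#'   unreachable).
#' @export
shortest_paths <- function(graph, sources, targets) {
  vn <- igraph::V(graph)$name
  missing <- setdiff(as.character(c(sources, targets)), vn)
  if (length(missing))
    validation_error("residue %s is not a node of the graph", missing[1])
  out <- expand.grid(source = as.character(sources), target = as.character(targets),
                     stringsAsFactors = FALSE)
  out$weight <- NA_real_
  out$path <- NA_character_
  for (k in seq_len(nrow(out))) {
    sp <- suppressWarnings(
      igraph::shortest_paths(graph, from = out$source[k], to = out$target[k],
                             weights = igraph::E(graph)$weight,
                             output = "vpath", algorithm = "dijkstra"))
    v <- sp$vpath[[1]]
    if (length(v) == 0 && out$source[k] != out$target[k]) {
      out$weight[k] <- Inf
    } else {
      out$path[k] <- paste(v$name, collapse = "-")
      out$weight[k] <- igraph::distances(graph, v = out$source[k], to = out$target[k],
                                         weights = igraph::E(graph)$weight,
                                         algorithm = "dijkstra")[1, 1]
    }
  }
  out
}

#' Shortest-path map: high-traffic edges and hotspot residues
#'
#' Counts, for every (source, target) residue pair (all pairs by default),
#' how many shortest paths traverse each edge, counting all co-optimal paths
#' when ties occur so the result does not depend on node order. Edge counts
#' are normalised by the maximum; edges with normalised importance >=
#' `importance_threshold` are retained and their endpoints reported as
#' hotspot residues in ascending global order.
#'
#' @param graph an igraph graph from [build_rdcm_graph()].
#' @param all_pairs use every vertex pair (default TRUE); otherwise supply
#'   `sources`/`targets`.
#' @param importance_threshold retain edges with importance >= this fraction
#'   of the maximum (default 0.3).
#' @param sources,targets residue names used when `all_pairs = FALSE`.
#' @return list of class `allopath_spm`: `edges` (data.frame i, j, weight,
#'   abs_c, freq, importance, retained), `hotspots` (integer residues),
#'   `threshold`.
#' @export
extract_spm <- function(graph, all_pairs = TRUE, importance_threshold = 0.3,
                        sources = NULL, targets = NULL) {
  if (igraph::gorder(graph) == 0 || igraph::gsize(graph) == 0)
    validation_error("cannot extract a pathway map from an empty graph")
  vn <- igraph::V(graph)$name
  if (all_pairs) {
    pairs <- utils::combn(seq_along(vn), 2)
  } else {
    if (is.null(sources) || is.null(targets))
      validation_error("sources and targets required when all_pairs = FALSE")
    pairs <- as.matrix(expand.grid(match(as.character(sources), vn),
                                   match(as.character(targets), vn)))
    if (anyNA(pairs)) validation_error("source/target not in graph")
    pairs <- t(pairs[pairs[, 1] != pairs[, 2], , drop = FALSE])
  }
  counts <- numeric(igraph::gsize(graph))
  w <- igraph::E(graph)$weight
  for (k in seq_len(ncol(pairs))) {
    asp <- suppressWarnings(
      igraph::all_shortest_paths(graph, from = pairs[1, k], to = pairs[2, k],
                                 weights = w))$vpaths
    for (p in asp) {
      vp <- as.integer(p)
      if (length(vp) < 2) next
      eids <- igraph::get_edge_ids(graph, as.vector(rbind(vp[-length(vp)], vp[-1])))
      counts[eids] <- counts[eids] + 1
    }
  }
  if (max(counts) == 0)
    validation_error("no connected residue pair: pathway map is empty")
  importance <- counts / max(counts)
  el <- igraph::as_edgelist(graph, names = TRUE)
  edges <- data.frame(i = as.integer(el[, 1]), j = as.integer(el[, 2]),
                      weight = w, abs_c = igraph::E(graph)$abs_c %||% exp(-w),
                      freq = igraph::E(graph)$freq %||% NA_real_,
                      importance = importance,
                      retained = importance >= importance_threshold)
  hot <- sort(unique(c(edges$i[edges$retained], edges$j[edges$retained])))
  structure(list(edges = edges, hotspots = hot, threshold = importance_threshold),
            class = "allopath_spm")
}

#' @export
print.allopath_spm <- function(x, ...) {
  cat(sprintf("Shortest-path map: %d/%d edges retained (threshold %.2f); %d hotspot residues\n",
              sum(x$edges$retained), nrow(x$edges), x$threshold, length(x$hotspots)))
  invisible(x)
}

#' Residues common to several pathway results
#'
#' A residue is common when every pathway result contains a hotspot within
#' `window` positions of it on the shared global numbering (window 0 = exact
#' intersection). Candidates closer than `window` to each other are collapsed
#' to the smallest index.
#'
#' @param pathways list of `allopath_spm` results (>= 2) or integer vectors.
#' @param window matching tolerance in residue positions (default 0).
#' @return sorted integer vector of common residues.
#' @export
common_residues <- function(pathways, window = 0) {
  if (length(pathways) < 2) validation_error("need at least two pathway results")
  sets <- lapply(pathways, function(p) {
    v <- if (inherits(p, "allopath_spm")) p$hotspots else as.integer(p)
    if (!length(v) || anyNA(v)) validation_error("pathway result with invalid hotspot set")
    sort(unique(v))
  })
  cand <- sort(unique(unlist(sets)))
  ok <- vapply(cand, function(r) {
    all(vapply(sets, function(s) any(abs(s - r) <= window), logical(1)))
  }, logical(1))
  cand <- cand[ok]
  if (!length(cand) || window == 0) return(cand)
  # collapse runs of candidates within `window` of each other to the smallest
  keep <- c(TRUE, diff(cand) > window)
  cand[keep]
}
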