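mk_dccm <- function(M) {
  dimnames(M) <- list(seq_len(nrow(M)), seq_len(nrow(M)))
  M
}

test_that("residue graph fuses contact gating with -ln|C| weights", {
  C <- mk_dccm(matrix(c(1, 1, 0.5, 0.02,
                        1, 1, 0.9, 0.4,
                        0.5, 0.9, 1, -0.6,
                        0.02, 0.4, -0.6, 1), 4, 4))
  Fq <- mk_dccm(matrix(c(1, 1, 1, 1,
                         1, 1, 0.2, 1,
                         1, 0.2, 1, 1,
                         1, 1, 1, 1), 4, 4))
  g <- build_rdcm_graph(C, Fq, f_min = 0.5, c_min = 0.05)
  el <- cbind(igraph::as_edgelist(g), igraph::E(g)$weight)
  # expected edges by hand: (1,2) |C|=1 w=0; (1,3) w=-ln 0.5; (2,4) w=-ln 0.4;
  # (3,4) w=-ln 0.6. Excluded: (1,4) |C|<c_min; (2,3) freq<f_min.
  expect_equal(nrow(el), 4)
  key <- paste(el[, 1], el[, 2])
  w <- as.numeric(el[, 3])
  expect_equal(w[key == "1 2"], 0)
  expect_equal(w[key == "1 3"], -log(0.5), tolerance = 1e-12)
  expect_equal(w[key == "2 4"], -log(0.4), tolerance = 1e-12)
  expect_equal(w[key == "3 4"], -log(0.6), tolerance = 1e-12)
  expect_false("1 4" %in% key)
  expect_false("2 3" %in% key)

  expect_error(build_rdcm_graph(C, Fq[1:3, 1:3]), class = "allopath_validation_error")
  expect_error(build_rdcm_graph(C, Fq, c_min = 0), class = "allopath_validation_error")
})

test_that("shortest paths follow Dijkstra arithmetic on toy graphs", {
  # two nodes, one edge
  C <- mk_dccm(matrix(c(1, 0.5, 0.5, 1), 2, 2))
  Fq <- mk_dccm(matrix(1, 2, 2))
  g <- build_rdcm_graph(C, Fq)
  sp <- shortest_paths(g, 1, 2)
  expect_equal(sp$path, "1-2")
  expect_equal(sp$weight, -log(0.5), tolerance = 1e-12)

  # triangle 1,1,3: two-hop route beats the direct edge
  W <- matrix(Inf, 3, 3)
  W[1, 2] <- W[2, 1] <- 1; W[2, 3] <- W[3, 2] <- 1; W[1, 3] <- W[3, 1] <- 3
  g3 <- adj_to_igraph(W)
  sp3 <- shortest_paths(g3, 1, 3)
  expect_equal(sp3$weight, 2)
  expect_equal(sp3$path, "1-2-3")

  # unreachable pairs flagged
  W2 <- matrix(Inf, 3, 3); W2[1, 2] <- W2[2, 1] <- 1
  sp4 <- shortest_paths(adj_to_igraph(W2), 1, 3)
  expect_true(is.infinite(sp4$weight))
  expect_true(is.na(sp4$path))

  expect_error(shortest_paths(g3, 1, 99), class = "allopath_validation_error")
})

test_that("Dijkstra equals exhaustive simple-path enumeration on random graphs", {
  set.seed(123)
  for (k in 1:100) {
    n <- sample(4:7, 1)
    W <- random_graph_adj(n, p_edge = 0.55)
    g <- adj_to_igraph(W)
    d_pkg <- igraph::distances(g, weights = igraph::E(g)$weight)
    d_bf <- bf_all_pairs_shortest(W)
    expect_equal(unname(d_pkg), d_bf, tolerance = 1e-9)
  }
  # and through the package surface on one instance
  W <- random_graph_adj(6, p_edge = 0.6)
  g <- adj_to_igraph(W)
  bf <- bf_all_pairs_shortest(W)
  sp <- shortest_paths(g, 1:6, 1:6)
  for (r in seq_len(nrow(sp))) {
    expect_equal(sp$weight[r],
                 bf[as.integer(sp$source[r]), as.integer(sp$target[r])],
                 tolerance = 1e-9)
  }
})

test_that("shortest-path map importance counts and thresholds behave as specified", {
  # path graph a-b-c: both edges carry two of the all-pairs shortest paths
  W <- matrix(Inf, 3, 3); W[1, 2] <- W[2, 1] <- 1; W[2, 3] <- W[3, 2] <- 1
  spm <- extract_spm(adj_to_igraph(W), importance_threshold = 0.3)
  expect_equal(spm$edges$importance, c(1, 1))
  expect_true(all(spm$edges$retained))
  expect_equal(spm$hotspots, 1:3)

  # star graph: symmetric leaves, all edges equal importance, all retained
  Ws <- matrix(Inf, 5, 5)
  for (leaf in 2:5) Ws[1, leaf] <- Ws[leaf, 1] <- 1
  spms <- extract_spm(adj_to_igraph(Ws))
  expect_equal(length(unique(spms$edges$importance)), 1)
  expect_true(all(spms$edges$retained))

  # planted backbone amid weak noise edges: retained set is the chain;
  # verified against brute-force shortest-path edge counting
  set.seed(9)
  n <- 9
  W <- matrix(Inf, n, n)
  for (i in 1:(n - 1)) W[i, i + 1] <- W[i + 1, i] <- 0.1         # cheap chain
  W[1, 5] <- W[5, 1] <- 3.0; W[3, 8] <- W[8, 3] <- 2.5           # costly noise
  g <- adj_to_igraph(W)
  spm2 <- extract_spm(g, importance_threshold = 0.3)
  # brute force: count, per edge, the shortest paths that use it
  bf_counts <- setNames(numeric(nrow(spm2$edges)),
                        paste(spm2$edges$i, spm2$edges$j))
  d_bf <- bf_all_pairs_shortest(W)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    # on this graph the chain route is the unique optimum; walk it
    route <- s:t
    for (k in seq_len(length(route) - 1)) {
      key <- paste(route[k], route[k + 1])
      bf_counts[key] <- bf_counts[key] + 1
    }
    expect_equal(d_bf[s, t], 0.1 * (t - s), tolerance = 1e-9)
  }
  bf_imp <- bf_counts / max(bf_counts)
  expect_equal(spm2$edges$importance, unname(bf_imp[paste(spm2$edges$i, spm2$edges$j)]))
  retained <- spm2$edges[spm2$edges$retained, c("i", "j")]
  expect_true(all(retained$j == retained$i + 1))  # only chain edges retained

  expect_error(extract_spm(igraph::make_empty_graph(0, directed = FALSE)),
               class = "allopath_validation_error")
})

test_that("co-optimal tied routes are both counted in importance", {
  # diamond: 1-2-4 and 1-3-4 tie exactly
  W <- matrix(Inf, 4, 4)
  W[1, 2] <- W[2, 1] <- 1; W[2, 4] <- W[4, 2] <- 1
  W[1, 3] <- W[3, 1] <- 1; W[3, 4] <- W[4, 3] <- 1
  spm <- extract_spm(adj_to_igraph(W), importance_threshold = 0)
  imp <- setNames(spm$edges$importance, paste(spm$edges$i, spm$edges$j))
  expect_equal(imp[["1 2"]], imp[["1 3"]])
  expect_equal(imp[["2 4"]], imp[["3 4"]])
  expect_true(all(c(2, 3) %in% spm$hotspots))
})

test_that("edge importance is invariant under order-preserving |C| relabeling", {
  set.seed(4)
  C <- diag(6)
  vals <- runif(15, 0.1, 0.95)
  C[upper.tri(C)] <- vals; C <- pmax(C, t(C)); diag(C) <- 1
  Fq <- mk_dccm(matrix(1, 6, 6))
  g1 <- build_rdcm_graph(mk_dccm(C), Fq, c_min = 0.05)
  # monotone relabeling toward 1: |C| -> |C|^0.5 preserves weight ordering
  C2 <- C; C2[upper.tri(C2)] <- sqrt(vals); C2 <- pmax(C2, t(C2)); diag(C2) <- 1
  g2 <- build_rdcm_graph(mk_dccm(C2), Fq, c_min = 0.05)
  s1 <- extract_spm(g1, importance_threshold = 0)
  s2 <- extract_spm(g2, importance_threshold = 0)
  expect_equal(nrow(s1$edges), nrow(s2$edges))
  expect_equal(s1$edges$importance, s2$edges$importance)
})

test_that("synthetic planted communication chains are recovered end to end", {
  ps <- planted_path_spec(13:18, rho_on = 0.9, rho_off = 0.2)
  gen <- generate_planted_path(ps, ensemble_spec(30, n_frames = 2000, seed = 11))
  C <- dccm(covariance_matrix(gen$trajectory))
  rcm <- contact_matrix(gen$trajectory, cutoff = 10)
  spm <- extract_spm(build_rdcm_graph(C, rcm))
  expect_gte(mean(gen$truth %in% spm$hotspots), 0.9)
})

test_that("common residues intersect hotspot sets with a position window", {
  a <- list(hotspots = c(10L, 50L, 70L))
  b <- list(hotspots = c(10L, 50L, 71L))
  class(a) <- class(b) <- "allopath_spm"
  expect_equal(common_residues(list(a, a)), a$hotspots)          # identical sets
  expect_equal(common_residues(list(c(1L, 2L), c(5L, 6L))), integer(0))
  expect_equal(common_residues(list(c(10L, 50L), c(11L, 50L)), window = 1),
               c(10L, 50L))                                       # tie -> smallest
  expect_equal(common_residues(list(a, b), window = 0), c(10L, 50L))
  expect_equal(common_residues(list(a, b), window = 1), c(10L, 50L, 70L))
  expect_error(common_residues(list(a)), class = "allopath_validation_error")
})
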