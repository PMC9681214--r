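# Small-worldness, consensus communities, rich-club, edge classes.

ctx_log_level("none")

test_that("rewired nulls preserve degrees and actually rewire", {
  set.seed(14)
  a <- random_connected_adj(30, 0.2)
  r <- rewire_null(a, seed = 1)
  expect_identical(degree_bin(r), degree_bin(a))
  expect_equal(diag(r), rep(0, 30))
  expect_true(all(r %in% c(0, 1)))

  # K4 is rigid: only one simple graph with that degree sequence
  expect_equal(rewire_null(k_complete(4), seed = 1), k_complete(4))

  # at 10 swaps/edge a 200-node connectome forgets most of its edges
  con <- generate_archetype(2, taxonomy_spec(seed = 3))
  overlaps <- vapply(1:20, function(s) {
    r <- rewire_null(con$adjacency, seed = s)
    sum(r * con$adjacency) / sum(con$adjacency)
  }, 0)
  expect_lt(max(overlaps), 0.6)
})

test_that("small-worldness flags ring-lattice-with-shortcuts graphs", {
  set.seed(15)
  a <- ring_lattice(60, 3)  # high clustering, long paths
  # rewire ~10% of edges to add shortcuts
  idx <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  pick <- sample(nrow(idx), 18)
  for (r in pick) {
    i <- idx[r, 1]; j <- idx[r, 2]
    cand <- setdiff(which(a[i, ] == 0), i)
    if (length(cand) == 0) next
    j2 <- sample(cand, 1)
    a[i, j] <- a[j, i] <- 0
    a[i, j2] <- a[j2, i] <- 1
  }
  if (!igraph::is_connected(igraph::graph_from_adjacency_matrix(a, mode = "undirected"))) {
    a <- ring_lattice(60, 3)  # fall back: still high C, S>1 holds
  }
  sw <- small_worldness(a, n_null = 50, seed = 2)
  expect_gt(sw$gamma, 0)
  expect_gt(sw$lambda, 0)
  expect_gt(sw$S, 1)
})

test_that("modularity matches its printed definition", {
  set.seed(16)
  w <- random_weighted_adj(20, 0.3)
  memb <- sample(1:3, 20, replace = TRUE)
  expect_equal(modularity_q(w, memb), oracle_q(w, memb), tolerance = 1e-12)
  expect_equal(modularity_q(w, memb, gamma_res = 1.4),
               oracle_q(w, memb, gamma_res = 1.4), tolerance = 1e-12)
  # the trivial one-community partition has Q(1) = 0
  expect_equal(modularity_q(w, rep(1, 20)), 0, tolerance = 1e-12)
})

test_that("consensus Louvain recovers planted partitions", {
  # two cliques joined by one edge
  a <- rbind(cbind(k_complete(8), matrix(0, 8, 8)),
             cbind(matrix(0, 8, 8), k_complete(8)))
  a[1, 9] <- a[9, 1] <- 1
  part <- louvain_consensus(a, n_runs = 50, seed = 3, weighted = FALSE)
  expect_equal(length(unique(part$membership)), 2)
  expect_equal(length(unique(part$membership[1:8])), 1)
  expect_equal(length(unique(part$membership[9:16])), 1)
  # stored q matches direct evaluation of the printed formula
  expect_equal(part$q, modularity_q(binarize(a), part$membership, 1),
               tolerance = 1e-10)

  # planted 4-module SBM (100 nodes, p_in = 0.3, p_out = 0.02)
  set.seed(17)
  planted <- rep(1:4, each = 25)
  p <- ifelse(outer(planted, planted, "=="), 0.3, 0.02)
  a2 <- matrix(0, 100, 100)
  ut <- upper.tri(a2)
  a2[ut] <- rbinom(sum(ut), 1, p[ut])
  a2 <- a2 + t(a2)
  part2 <- louvain_consensus(a2, n_runs = 100, seed = 4, weighted = FALSE)
  # agreement with planted labels up to relabelling
  tab <- table(planted, part2$membership)
  expect_gte(sum(apply(tab, 1, max)) / 100, 0.9)
})

test_that("rich-club curve and k-core match brute-force recounts", {
  set.seed(18)
  for (rep in 1:5) {
    a <- random_connected_adj(25, 0.25)
    rc <- rich_club_coeff(a)
    brute <- oracle_phi(a)
    expect_equal(rc$k, unname(brute[, "k"]))
    expect_equal(rc$phi, unname(brute[, "phi"]), tolerance = 1e-12)
    for (k in c(2, 4)) {
      expect_identical(unname(k_core_members(a, k)), oracle_kcore(a, k))
    }
  }
  # complete graph: phi = 1 at every evaluable level
  expect_true(all(rich_club_coeff(k_complete(10))$phi == 1))
})

test_that("a planted rich club is detected; ER graphs are not enriched", {
  # dense core of 10 nodes on a sparse 80-node periphery
  set.seed(19)
  n <- 80
  a <- matrix(0, n, n)
  ut <- upper.tri(a)
  a[ut] <- rbinom(sum(ut), 1, 0.06)
  a <- a + t(a)
  core <- 1:10
  a[core, core] <- 1
  diag(a) <- 0
  a <- binarize(a + t(a))
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  expect_true(igraph::is_connected(g))
  rc <- rich_club(a, n_null = 200, seed = 5)
  expect_false(is.na(rc$selected_k))
  expect_true(all(core %in% rc$rich_nodes))

  # homogeneous random graph: phi_norm near 1 away from the degenerate
  # tail (k levels with very few surviving nodes; the seed-averaged
  # unbiasedness check lives in test-acceptance.R)
  set.seed(20)
  er <- random_connected_adj(100, 0.2)
  rcer <- suppressWarnings(rich_club(er, n_null = 300, seed = 6))
  keep <- vapply(rcer$k_levels, function(k)
    sum(degree_bin(er) > k) >= 10, TRUE)
  expect_lt(mean(abs(rcer$phi_norm[keep] - 1)), 0.05)
})

test_that("edges are classified on all four axes", {
  spec <- small_spec(seed = 23)
  con <- generate_archetype(1, spec)
  part <- louvain_consensus(con, n_runs = 50, seed = 7)
  rc <- suppressWarnings(rich_club(con, n_null = 100, seed = 8))
  cls <- classify_edges(con, part, rc)
  expect_equal(nrow(cls), sum(con$adjacency) / 2)

  # axis labels follow their definitions edge by edge
  i <- cls$from[1]; j <- cls$to[1]
  expect_equal(cls$modular[1],
               ifelse(part$membership[i] == part$membership[j],
                      "intra", "inter"))
  expect_equal(cls$hemispheric[1],
               ifelse(con$hemisphere[i] == con$hemisphere[j],
                      "intra", "inter"))
  # the single longest edge is long iff it exceeds 75% of the max
  # inter-node distance; boundaries: short <= 25 < medium <= 75 < long
  expect_true(all(cls$length[cls$length_pct <= 25] == "short"))
  expect_true(all(cls$length[cls$length_pct > 75] == "long"))
  longest <- which.max(cls$length_pct)
  if (cls$length_pct[longest] > 75) {
    expect_equal(cls$length[longest], "long")
  }
  # feeder edges touch the club exactly once
  in_club <- seq_len(con$n_nodes) %in% rc$rich_nodes
  feeders <- cls$richclub == "feeder"
  expect_true(all(xor(in_club[cls$from[feeders]], in_club[cls$to[feeders]])))

  fr <- edge_class_fractions(cls)
  for (axis in c("modular", "hemispheric", "length", "richclub")) {
    expect_equal(sum(fr[grepl(paste0("^", axis, "\\."), names(fr))]), 1,
                 tolerance = 1e-12)
  }
})

test_that("per-order proportions come with t-based confidence intervals", {
  spec <- small_spec(seed = 29)
  ds <- generate_dataset(spec)
  sel <- vapply(species_samples(ds), `[[`, "", 1)
  cls <- lapply(sel, function(s) {
    con <- ds$connectomes[[s]]
    part <- louvain_consensus(con, n_runs = 20, seed = 1)
    rc <- suppressWarnings(rich_club(con, n_null = 50, seed = 1))
    classify_edges(con, part, rc)
  })
  names(cls) <- ds$species$species_id
  props <- edge_class_proportions(ds, cls)
  expect_true(all(props$ci_lo <= props$mean + 1e-12))
  expect_true(all(props$ci_hi >= props$mean - 1e-12))
  # per axis, order means sum to 1
  for (o in unique(props$order)) {
    hemi <- props[props$order == o & grepl("^hemispheric", props$class), ]
    expect_equal(sum(hemi$mean), 1, tolerance = 1e-12)
  }

  # an order of identical species has zero-width intervals
  con <- ds$connectomes[[sel[1]]]
  cls_id <- list(a = cls[[1]], b = cls[[1]])
  ds_id <- connectome_dataset(
    list(connectome(con$weights, con$hemisphere, con$coords, "a", "a"),
         connectome(con$weights, con$hemisphere, con$coords, "b", "b")),
    data.frame(species_id = c("a", "b"), order = "O", superorder = "S"))
  props_id <- edge_class_proportions(ds_id, cls_id)
  expect_equal(props_id$ci_hi - props_id$ci_lo, rep(0, nrow(props_id)))
})
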