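# Conserved global organization: small-worldness against rewired nulls,
# consensus Louvain communities, rich-club detection with permutation
# significance, and the four-way edge classification.

#' Degree-preserving rewired null graph
#'
#' Maslov-Sneppen double-edge swaps: preserves every node's degree
#' exactly, yields a simple graph, and retries (bounded) until the result
#' is connected when the input is.
#'
#' @param adjacency binary adjacency matrix.
#' @param n_swaps_per_edge swap attempts per edge (default 10).
#' @param seed optional RNG seed.
#' @param require_connected enforce connectivity of the null (default
#'   TRUE).
#' @param max_retries retry budget for the connectivity constraint.
#' @return a rewired binary adjacency matrix.
#' @export
rewire_null <- function(adjacency, n_swaps_per_edge = 10, seed = NULL,
                        require_connected = TRUE, max_retries = 20) {
  if (!is.null(seed)) set.seed(seed)
  a <- binarize(adjacency)
  g0 <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  ne <- igraph::ecount(g0)
  for (try in seq_len(max_retries)) {
    g <- igraph::rewire(g0, igraph::keeping_degseq(niter = n_swaps_per_edge * ne))
    if (!require_connected || igraph::is_connected(g)) {
      m <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
      dimnames(m) <- NULL
      return(m)
    }
  }
  stop("rewire_null: could not produce a connected rewired graph")
}

#' Small-worldness index
#'
#' Normalized clustering `gamma = C/C_rand` and path length
#' `lambda = L/L_rand` against an ensemble of degree-preserving rewired
#' null graphs, and their ratio `S = gamma/lambda`. C is the mean binary
#' clustering coefficient, L the binary characteristic path length.
#' `S >= 1` marks small-world architecture.
#'
#' @param con a [connectome] or binary adjacency matrix.
#' @param n_null number of rewired nulls (study setting: 1000).
#' @param seed RNG seed for the null ensemble.
#' @return object of class `small_world_result`: list with `gamma`,
#'   `lambda`, `S`, `C`, `L`, `C_rand`, `L_rand`, `n_null`.
#' @export
small_worldness <- function(con, n_null = 1000, seed = 1) {
  a <- if (inherits(con, "connectome")) con$adjacency else binarize(con)
  set.seed(seed)
  C <- mean(clustering_bin(a))
  L <- as.numeric(char_path_length(a, "binary"))
  cs <- numeric(n_null)
  ls <- numeric(n_null)
  for (i in seq_len(n_null)) {
    r <- rewire_null(a)
    cs[i] <- mean(clustering_bin(r))
    ls[i] <- as.numeric(char_path_length(r, "binary"))
  }
  gamma <- C / mean(cs)
  lambda <- L / mean(ls)
  structure(list(gamma = gamma, lambda = lambda, S = gamma / lambda,
                 C = C, L = L, C_rand = mean(cs), L_rand = mean(ls),
                 n_null = n_null),
            class = "small_world_result")
}

#' @export
print.small_world_result <- function(x, ...) {
  cat(sprintf("<small_world_result> gamma=%.3f lambda=%.3f S=%.3f (%d nulls)\n",
              x$gamma, x$lambda, x$S, x$n_null))
  invisible(x)
}

#' Modularity of a partition
#'
#' Direct evaluation of the resolution-parameterized modularity
#' `Q(gamma) = 1/2m * sum_ij [A_ij - gamma k_i k_j / 2m] delta(c_i, c_j)`
#' on a (binary or weighted) matrix.
#'
#' @param m adjacency or weight matrix.
#' @param membership per-node community ids.
#' @param gamma_res resolution parameter (default 1).
#' @return scalar Q.
#' @export
modularity_q <- function(m, membership, gamma_res = 1) {
  w <- as.matrix(m)
  diag(w) <- 0
  k <- rowSums(w)
  two_m <- sum(w)
  same <- outer(membership, membership, "==")
  sum((w - gamma_res * outer(k, k) / two_m) * same) / two_m
}

#' Consensus Louvain community detection
#'
#' Runs the Louvain algorithm `n_runs` times (weighted by default),
#' builds the module co-assignment (agreement) matrix, zeroes entries at
#' or below the permutation-null expected agreement, and re-clusters the
#' agreement matrix iteratively until all runs coincide.
#'
#' @param con a [connectome] or matrix.
#' @param gamma_res resolution parameter (default 1).
#' @param n_runs Louvain repetitions (study setting: 250).
#' @param seed RNG seed.
#' @param weighted run on weights (default) or on the binary adjacency.
#' @param max_consensus_iter bound on consensus iterations.
#' @return object of class `partition`: list with `membership` (ids
#'   contiguous from 1), `q` (modularity of the consensus partition on
#'   the analyzed matrix), `gamma_res`, `n_runs`.
#' @export
louvain_consensus <- function(con, gamma_res = 1.0, n_runs = 250, seed = 1,
                              weighted = TRUE, max_consensus_iter = 50) {
  w <- if (inherits(con, "connectome")) {
    if (weighted) con$weights else con$adjacency
  } else {
    m <- as.matrix(con)
    if (weighted) m else binarize(m)
  }
  set.seed(seed)
  run_louvain <- function(mat) {
    g <- igraph::graph_from_adjacency_matrix(mat, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    igraph::membership(igraph::cluster_louvain(g, resolution = gamma_res))
  }
  n <- nrow(w)
  mat <- w
  for (iter in seq_len(max_consensus_iter)) {
    runs <- replicate(n_runs, run_louvain(mat))
    if (all(apply(runs, 1, function(r) length(unique(r)) == 1))) {
      memb <- as.integer(factor(runs[, 1]))
      q <- modularity_q(w, memb, gamma_res)
      return(structure(list(membership = memb, q = q,
                            gamma_res = gamma_res, n_runs = n_runs),
                       class = "partition"))
    }
    agree <- matrix(0, n, n)
    for (r in seq_len(n_runs)) {
      agree <- agree + outer(runs[, r], runs[, r], "==")
    }
    agree <- agree / n_runs
    diag(agree) <- 0
    # permutation-null expected agreement: probability that two random
    # nodes share a community under each run's community-size profile
    null_agree <- mean(apply(runs, 2, function(r) {
      sz <- tabulate(factor(r))
      sum(sz * (sz - 1)) / (n * (n - 1))
    }))
    agree[agree <= null_agree] <- 0
    if (all(agree == 0)) {
      # no above-chance agreement: fall back to the best single run
      qs <- apply(runs, 2, function(r) modularity_q(w, r, gamma_res))
      memb <- as.integer(factor(runs[, which.max(qs)]))
      return(structure(list(membership = memb, q = max(qs),
                            gamma_res = gamma_res, n_runs = n_runs),
                       class = "partition"))
    }
    mat <- agree
  }
  stop("louvain_consensus: consensus did not converge")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d communities, Q(%.2f)=%.4f (%d runs)\n",
              length(unique(x$membership)), x$gamma_res, x$q, x$n_runs))
  invisible(x)
}

#' Rich-club coefficient curve
#'
#' For each degree level k, removes all nodes with degree <= k and
#' returns the density of the surviving subgraph:
#' `phi(k) = 2 E_>k / (N_>k (N_>k - 1))`, for all k with at least two
#' surviving nodes.
#'
#' @param adjacency binary adjacency matrix.
#' @return data.frame with columns `k`, `phi`, `n_nodes`, `n_edges`.
#' @export
rich_club_coeff <- function(adjacency) {
  a <- binarize(adjacency)
  deg <- rowSums(a)
  ks <- 0:(max(deg) - 1)
  rows <- lapply(ks, function(k) {
    keep <- deg > k
    nk <- sum(keep)
    if (nk < 2) return(NULL)
    ek <- sum(a[keep, keep]) / 2
    data.frame(k = k, phi = 2 * ek / (nk * (nk - 1)),
               n_nodes = nk, n_edges = ek)
  })
  do.call(rbind, rows)
}

#' k-core membership
#'
#' Nodes whose coreness (maximal subgraph degree under iterative pruning)
#' is at least `k`.
#'
#' @param adjacency binary adjacency matrix.
#' @param k core level.
#' @return logical vector, TRUE for members of the k-core.
#' @export
k_core_members <- function(adjacency, k) {
  g <- igraph::graph_from_adjacency_matrix(binarize(adjacency),
                                           mode = "undirected")
  igraph::coreness(g) >= k
}

#' Rich-club detection with permutation significance
#'
#' Computes phi(k) across degree levels, normalizes by the mean phi of
#' `n_null` degree-preserving rewired nulls, and tests each level
#' one-sided (observed phi against the null phi distribution). The
#' selected level is the k with the largest significant `phi_norm > 1`
#' (ties resolved toward larger k). Rich-club nodes are the hubs (degree
#' above mean + 1 SD, population SD) that belong to the core at the
#' selected level, with core membership at level k defined by degree >= k
#' (the convention used alongside the phi(k) curve; note that the
#' iterative-pruning k-core of [k_core_members()] can be empty at the
#' selected level even when a dense club exists, because a club of size c
#' has pruning-coreness at most c - 1 plus its peripheral degree). If no
#' level is significant the rich-club is empty (warning) and all edges
#' are peripheral downstream.
#'
#' @param con a [connectome] or binary adjacency matrix.
#' @param n_null null-ensemble size (study setting: 1000).
#' @param seed RNG seed.
#' @param alpha significance level for the permutation test.
#' @return object of class `rich_club_profile`: list with `k_levels`,
#'   `phi`, `phi_norm`, `p_values`, `n_null`, `selected_k` (NA when
#'   nothing is significant), `rich_nodes` (node indices), `hub_threshold`.
#' @export
rich_club <- function(con, n_null = 1000, seed = 1, alpha = 0.05) {
  a <- if (inherits(con, "connectome")) con$adjacency else binarize(con)
  set.seed(seed)
  obs <- rich_club_coeff(a)
  null_phi <- matrix(NA_real_, n_null, nrow(obs))
  for (i in seq_len(n_null)) {
    r <- rewire_null(a, require_connected = FALSE)
    nc <- rich_club_coeff(r)
    null_phi[i, ] <- nc$phi[match(obs$k, nc$k)]
  }
  phi_rand <- colMeans(null_phi, na.rm = TRUE)
  phi_norm <- obs$phi / phi_rand
  # one-sided permutation p: fraction of nulls with phi >= observed
  pvals <- vapply(seq_len(nrow(obs)), function(j) {
    nn <- null_phi[, j][!is.na(null_phi[, j])]
    (sum(nn >= obs$phi[j]) + 1) / (length(nn) + 1)
  }, 0)
  deg <- rowSums(a)
  hub_threshold <- mean(deg) + pop_sd(deg)
  sig <- which(phi_norm > 1 & pvals < alpha)
  if (length(sig) == 0) {
    warning("rich_club: no significant rich-club organization; empty club")
    selected_k <- NA_integer_
    rich_nodes <- integer(0)
  } else {
    best <- sig[phi_norm[sig] == max(phi_norm[sig])]
    selected_k <- obs$k[max(best)]  # tie -> larger k (denser club)
    rich_nodes <- which(deg > hub_threshold & deg >= selected_k)
  }
  structure(list(k_levels = obs$k, phi = obs$phi, phi_norm = phi_norm,
                 p_values = pvals, n_null = n_null,
                 selected_k = selected_k, rich_nodes = rich_nodes,
                 hub_threshold = hub_threshold),
            class = "rich_club_profile")
}

#' @export
print.rich_club_profile <- function(x, ...) {
  cat(sprintf("<rich_club_profile> %d levels, selected k=%s, %d rich nodes\n",
              length(x$k_levels),
              ifelse(is.na(x$selected_k), "none", x$selected_k),
              length(x$rich_nodes)))
  invisible(x)
}

#' Four-way edge classification
#'
#' Labels every edge on four independent axes:
#' * modular: intra- vs inter-modular (from a community partition),
#' * hemispheric: intra- vs inter-hemispheric,
#' * length: Euclidean distance between node centroids as a percentage of
#'   the maximum inter-node distance; short <= 25%, medium (25%, 75%],
#'   long > 75%,
#' * rich-club: rich-club (both endpoints in the club), feeder (one
#'   endpoint), peripheral (none).
#'
#' @param con a [connectome] (coordinates required for the length axis).
#' @param partition a `partition` from [louvain_consensus()].
#' @param rc a `rich_club_profile` from [rich_club()].
#' @return data.frame, one row per edge, with columns `from`, `to`,
#'   `modular`, `hemispheric`, `length`, `richclub`, `length_pct`.
#' @export
classify_edges <- function(con, partition, rc) {
  stopifnot(inherits(con, "connectome"), inherits(partition, "partition"),
            inherits(rc, "rich_club_profile"))
  a <- con$adjacency
  idx <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  dmax <- max(dist(con$coords))
  elen <- sqrt(rowSums((con$coords[i, , drop = FALSE] -
                          con$coords[j, , drop = FALSE])^2))
  pct <- 100 * elen / dmax
  len_class <- ifelse(pct <= 25, "short", ifelse(pct <= 75, "medium", "long"))
  in_club <- seq_len(con$n_nodes) %in% rc$rich_nodes
  n_club_ends <- in_club[i] + in_club[j]
  data.frame(
    from = i, to = j,
    modular = ifelse(partition$membership[i] == partition$membership[j],
                     "intra", "inter"),
    hemispheric = ifelse(con$hemisphere[i] == con$hemisphere[j],
                         "intra", "inter"),
    length = len_class,
    richclub = c("peripheral", "feeder", "rich-club")[n_club_ends + 1],
    length_pct = pct,
    stringsAsFactors = FALSE)
}

.edge_axes <- list(
  modular = c("intra", "inter"),
  hemispheric = c("intra", "inter"),
  length = c("short", "medium", "long"),
  richclub = c("rich-club", "feeder", "peripheral"))

#' Per-species edge-class proportions
#'
#' @param classification a data.frame from [classify_edges()].
#' @return named vector of proportions; per axis the proportions sum to 1.
#' @export
edge_class_fractions <- function(classification) {
  out <- unlist(lapply(names(.edge_axes), function(axis) {
    lv <- .edge_axes[[axis]]
    p <- table(factor(classification[[axis]], levels = lv)) /
      nrow(classification)
    setNames(as.numeric(p), paste0(axis, ".", lv))
  }))
  out
}

#' Per-order mean edge-class proportions with 95% confidence intervals
#'
#' Computes each species' edge-class proportions (one sampled connectome
#' per species, its consensus partition and rich-club), then summarizes
#' per order with the across-species mean and a t-based 95% CI.
#'
#' @param dataset a [connectome_dataset].
#' @param classifications named list of [classify_edges()] outputs, one
#'   per species (names = species_id).
#' @return data.frame with columns `order`, `class` (axis.level), `mean`,
#'   `ci_lo`, `ci_hi`, `n_species`.
#' @export
edge_class_proportions <- function(dataset, classifications) {
  sp <- dataset$species
  fr <- t(vapply(sp$species_id,
                 function(s) edge_class_fractions(classifications[[s]]),
                 edge_class_fractions(classifications[[sp$species_id[1]]])))
  rows <- list()
  for (o in unique(sp$order)) {
    sel <- fr[sp$order == o, , drop = FALSE]
    n <- nrow(sel)
    mu <- colMeans(sel)
    se <- apply(sel, 2, sd) / sqrt(n)
    half <- if (n > 1) qt(0.975, n - 1) * se else rep(0, length(mu))
    rows[[o]] <- data.frame(order = o, class = colnames(fr), mean = mu,
                            ci_lo = mu - half, ci_hi = mu + half,
                            n_species = n, row.names = NULL)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
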