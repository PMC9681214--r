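# Binary and weighted, local and global graph measures, and their
# assembly into the 22-entry topological feature vector:
#   2 x (4 local binary) + 2 x (4 local weighted) + 3 global binary
#   + 3 global weighted
# Local measures enter as their across-node mean and standard deviation.
#
# Conventions shared by the weighted measures:
#   * weight -> length map for shortest paths: f(w) = 1/w
#   * weighted clustering/transitivity rescale weights to [0,1] by the
#     global maximum before taking cube roots
#   * degrees (k_i) in weighted formulas always come from the binarized
#     matrix

as_igraph <- function(m, weighted = FALSE) {
  if (weighted) {
    igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                        weighted = TRUE, diag = FALSE)
  } else {
    igraph::graph_from_adjacency_matrix(binarize(m), mode = "undirected",
                                        diag = FALSE)
  }
}

#' Binary node degree
#' @param adjacency binary matrix.
#' @return per-node vector `k_i = sum_j a_ij`.
#' @export
degree_bin <- function(adjacency) {
  rowSums(binarize(adjacency))
}

#' Node strength (weighted degree)
#' @param weights weight matrix.
#' @return per-node vector `s_i = sum_j w_ij`.
#' @export
strength_wei <- function(weights) {
  w <- as.matrix(weights)
  diag(w) <- 0
  rowSums(w)
}

#' Binary clustering coefficient
#'
#' Fraction of a node's neighbour pairs that are themselves connected:
#' `c_i = (A^3)_ii / (k_i (k_i - 1))`; nodes with fewer than two
#' neighbours get 0.
#'
#' @param adjacency binary matrix.
#' @return per-node vector.
#' @export
clustering_bin <- function(adjacency) {
  a <- binarize(adjacency)
  k <- rowSums(a)
  tri <- diag(a %*% a %*% a)
  out <- numeric(length(k))
  ok <- k >= 2
  out[ok] <- tri[ok] / (k[ok] * (k[ok] - 1))
  out
}

#' Weighted clustering coefficient
#'
#' Mean intensity of triangles around a node (Onnela et al. variant):
#' cube-root weights, rescaled to \[0,1\] by the global maximum, with the
#' binary degree in the denominator.
#'
#' @param weights weight matrix.
#' @return per-node vector.
#' @export
clustering_wei <- function(weights) {
  w <- as.matrix(weights)
  diag(w) <- 0
  mx <- max(w)
  if (mx > 0) w <- w / mx
  k <- rowSums(w > 0)
  w3 <- w^(1 / 3)
  tri <- diag(w3 %*% w3 %*% w3)
  out <- numeric(length(k))
  ok <- k >= 2
  out[ok] <- tri[ok] / (k[ok] * (k[ok] - 1))
  out
}

#' Pairwise shortest-path lengths
#'
#' Binary mode counts hops; weighted mode runs Dijkstra on edge lengths
#' `1/w`. Disconnected pairs get `Inf`, the diagonal 0.
#'
#' @param m adjacency or weight matrix.
#' @param mode `"binary"` or `"weighted"`.
#' @return an N x N distance matrix.
#' @export
shortest_paths <- function(m, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  if (mode == "binary") {
    g <- as_igraph(m)
    d <- igraph::distances(g)
  } else {
    w <- as.matrix(m)
    if (any(w[w != 0] < 0)) stop("shortest_paths: negative weights")
    g <- as_igraph(w, weighted = TRUE)
    d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  }
  dimnames(d) <- NULL
  d
}

#' Normalized node betweenness centrality
#'
#' Fraction of shortest paths between other node pairs that pass through
#' each node, normalized by `(n-1)(n-2)` (ordered pairs). Weighted mode
#' uses edge lengths `1/w`.
#'
#' @inheritParams shortest_paths
#' @return per-node vector in \[0, 1\].
#' @export
node_betweenness <- function(m, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  n <- nrow(as.matrix(m))
  if (n < 3) return(numeric(n))
  if (mode == "binary") {
    g <- as_igraph(m)
    b <- igraph::betweenness(g, directed = FALSE)
  } else {
    g <- as_igraph(m, weighted = TRUE)
    b <- igraph::betweenness(g, directed = FALSE,
                             weights = 1 / igraph::E(g)$weight)
  }
  # igraph counts unordered pairs; the definition here sums ordered pairs
  unname(2 * b / ((n - 1) * (n - 2)))
}

#' Neighbourhood closeness (local-efficiency-style)
#'
#' For each node i with neighbours N_i, averages inverse shortest-path
#' lengths between pairs of neighbours computed on the subgraph induced by
#' N_i:
#' binary `e_i = sum_{j != h in N_i} 1/d_jh(N_i) / (k_i (k_i - 1))`;
#' weighted uses `(w_ij w_ih / d^w_jh(N_i))^(1/3)` terms. Pairs that are
#' disconnected within the neighbourhood contribute 0; nodes with fewer
#' than two neighbours get 0.
#'
#' @inheritParams shortest_paths
#' @return per-node vector.
#' @export
node_closeness <- function(m, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  w <- as.matrix(m)
  diag(w) <- 0
  a <- binarize(w)
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    sub <- w[nb, nb, drop = FALSE]
    d <- shortest_paths(sub, mode)
    inv <- 1 / d
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    if (mode == "binary") {
      out[i] <- sum(inv) / (k * (k - 1))
    } else {
      wi <- w[i, nb]
      terms <- (outer(wi, wi) * inv)^(1 / 3)
      diag(terms) <- 0
      out[i] <- sum(terms) / (k * (k - 1))
    }
  }
  out
}

#' Characteristic path length
#'
#' Mean shortest-path length over ordered node pairs. Disconnected pairs
#' are excluded from the mean; their presence is flagged in the
#' `"infinite_pairs"` attribute and logged.
#'
#' @inheritParams shortest_paths
#' @return scalar with attribute `infinite_pairs` (logical).
#' @export
char_path_length <- function(m, mode = c("binary", "weighted")) {
  d <- shortest_paths(m, mode)
  off <- d[row(d) != col(d)]
  fin <- off[is.finite(off)]
  if (length(fin) == 0) stop("char_path_length: no finite distances")
  has_inf <- any(!is.finite(off))
  if (has_inf) ctx_log("char_path_length: disconnected pairs excluded",
                       level = "warning")
  structure(mean(fin), infinite_pairs = has_inf)
}

#' Transitivity (global clustering)
#'
#' Ratio of observed to possible closed triangles,
#' `T = sum_i (A^3)_ii / sum_i k_i (k_i - 1)`; the weighted variant uses
#' max-normalized cube-root weights in the numerator and binary degrees in
#' the denominator.
#'
#' @inheritParams shortest_paths
#' @return scalar; 0 (with a warning) when no node has two neighbours.
#' @export
graph_transitivity <- function(m, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  w <- as.matrix(m)
  diag(w) <- 0
  a <- binarize(w)
  k <- rowSums(a)
  denom <- sum(k * (k - 1))
  if (denom == 0) {
    warning("graph_transitivity: no node with degree >= 2; returning 0")
    return(0)
  }
  if (mode == "binary") {
    num <- sum(diag(a %*% a %*% a))
  } else {
    mx <- max(w)
    wn <- if (mx > 0) w / mx else w
    w3 <- wn^(1 / 3)
    num <- sum(diag(w3 %*% w3 %*% w3))
  }
  num / denom
}

#' Degree (or strength) assortativity
#'
#' Edge-list correlation between endpoint degrees. The binary form is the
#' Newman assortativity coefficient; the weighted form correlates endpoint
#' strengths with `w_ij` weighting of each link (normalized by the link
#' count, following the printed per-link convention). Degree-regular
#' graphs have zero variance and return `NaN` with a warning.
#'
#' @inheritParams shortest_paths
#' @return scalar in \[-1, 1\], or `NaN` when undefined.
#' @export
graph_assortativity <- function(m, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  w <- as.matrix(m)
  diag(w) <- 0
  a <- binarize(w)
  idx <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  l <- nrow(idx)
  if (l < 2) stop("graph_assortativity: fewer than two edges")
  if (mode == "binary") {
    ki <- rowSums(a)[idx[, 1]]
    kj <- rowSums(a)[idx[, 2]]
    wij <- rep(1, l)
  } else {
    s <- rowSums(w)
    ki <- s[idx[, 1]]
    kj <- s[idx[, 2]]
    wij <- w[idx]
  }
  mu <- sum(wij * (ki + kj) / 2) / l
  num <- sum(wij * ki * kj) / l - mu^2
  den <- sum(wij * (ki^2 + kj^2) / 2) / l - mu^2
  if (abs(den) < 1e-15) {
    warning("graph_assortativity: zero degree variance (regular graph)")
    return(NaN)
  }
  num / den
}

# canonical feature order; "bin"/"wei" x "local"/"global" encoded in names
feature_names <- function() {
  loc <- c("degree", "clustering", "betweenness", "closeness")
  c(paste0("bin_local_", rep(loc, each = 2), c("_mean", "_sd")),
    paste0("wei_local_", rep(loc, each = 2), c("_mean", "_sd")),
    paste0("bin_global_", c("cpl", "transitivity", "assortativity")),
    paste0("wei_global_", c("cpl", "transitivity", "assortativity")))
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Topological feature vector of a connectome
#'
#' Assembles the 22-entry vector: mean and (population) SD of the four
#' local measures in binary and weighted form, plus the three global
#' measures in binary and weighted form. An undefined assortativity
#' (regular graph) is imputed as 0 so that cosine distances stay defined.
#'
#' @param con a [connectome] (or a bare weight matrix).
#' @param features `"all"`, `"local"` or `"global"`.
#' @param weighting `"all"`, `"binary"` or `"weighted"`.
#' @return named numeric vector (a subset of the 22 canonical entries,
#'   order preserved).
#' @export
feature_vector <- function(con, features = c("all", "local", "global"),
                           weighting = c("all", "binary", "weighted")) {
  features <- match.arg(features)
  weighting <- match.arg(weighting)
  w <- if (inherits(con, "connectome")) con$weights else as.matrix(con)
  a <- binarize(w)
  msd <- function(x) c(mean(x), pop_sd(x))
  assort <- function(m, mode) {
    r <- suppressWarnings(graph_assortativity(m, mode))
    if (!is.finite(r)) 0 else r
  }
  full <- c(
    msd(degree_bin(a)), msd(clustering_bin(a)),
    msd(node_betweenness(a, "binary")), msd(node_closeness(a, "binary")),
    msd(strength_wei(w)), msd(clustering_wei(w)),
    msd(node_betweenness(w, "weighted")), msd(node_closeness(w, "weighted")),
    as.numeric(char_path_length(a, "binary")),
    graph_transitivity(a, "binary"), assort(a, "binary"),
    as.numeric(char_path_length(w, "weighted")),
    graph_transitivity(w, "weighted"), assort(w, "weighted"))
  names(full) <- feature_names()
  feature_subset(full, features, weighting)
}

#' Select a feature subset by scope and weighting
#'
#' @param v named feature vector as returned by [feature_vector()].
#' @param features,weighting subset selectors (see [feature_vector()]).
#' @return the retained entries, original order preserved.
#' @export
feature_subset <- function(v, features = c("all", "local", "global"),
                           weighting = c("all", "binary", "weighted")) {
  features <- match.arg(features)
  weighting <- match.arg(weighting)
  keep <- rep(TRUE, length(v))
  nm <- names(v)
  if (features == "local") keep <- keep & grepl("_local_", nm)
  if (features == "global") keep <- keep & grepl("_global_", nm)
  if (weighting == "binary") keep <- keep & grepl("^bin_", nm)
  if (weighting == "weighted") keep <- keep & grepl("^wei_", nm)
  v[keep]
}

#' Feature table for a whole dataset
#'
#' @param dataset a [connectome_dataset].
#' @param features,weighting subset selectors passed to [feature_vector()].
#' @return matrix, one row per sample (rownames = sample_id), one column
#'   per feature.
#' @export
feature_table <- function(dataset, features = "all", weighting = "all") {
  rows <- lapply(dataset$connectomes, feature_vector,
                 features = features, weighting = weighting)
  do.call(rbind, rows)
}
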