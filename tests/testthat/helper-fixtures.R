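# Small graph fixtures and random-instance generators, built in code.

adj_from_edges <- function(n, edges) {
  a <- matrix(0, n, n)
  for (e in edges) {
    a[e[1], e[2]] <- a[e[2], e[1]] <- 1
  }
  a
}

k_complete <- function(n) {
  a <- matrix(1, n, n)
  diag(a) <- 0
  a
}

star_graph <- function(n) {
  a <- matrix(0, n, n)
  a[1, 2:n] <- a[2:n, 1] <- 1
  a
}

path_graph <- function(n) {
  adj_from_edges(n, lapply(seq_len(n - 1), function(i) c(i, i + 1)))
}

ring_lattice <- function(n, k_half = 2) {
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (s in seq_len(k_half)) {
      j <- ((i - 1 + s) %% n) + 1
      a[i, j] <- a[j, i] <- 1
    }
  }
  a
}

# random connected Erdos-Renyi adjacency (rejection-sampled)
random_connected_adj <- function(n, p, max_tries = 200) {
  for (t in seq_len(max_tries)) {
    a <- matrix(0, n, n)
    ut <- upper.tri(a)
    a[ut] <- rbinom(sum(ut), 1, p)
    a <- a + t(a)
    d <- oracle_shortest_paths(a, "binary")
    if (all(is.finite(d)) && all(rowSums(a) >= 1)) return(a)
  }
  stop("random_connected_adj: could not generate a connected graph")
}

# random connected weighted graph with continuous positive weights
random_weighted_adj <- function(n, p) {
  a <- random_connected_adj(n, p)
  w <- matrix(0, n, n)
  ut <- upper.tri(a) & a > 0
  w[ut] <- runif(sum(ut), 0.5, 5)
  w + t(w)
}

# wrap a bare weight matrix into a connectome with simple bilateral
# metadata (coordinates on a line so edge lengths are distinct)
toy_connectome <- function(w, species_id = "toy", sample_id = species_id) {
  n <- nrow(w)
  hemi <- rep(c("L", "R"), length.out = n)
  coords <- cbind(seq_len(n), (seq_len(n))^2 / n, 0)
  connectome(w, hemi, coords, species_id = species_id, sample_id = sample_id)
}

# small synthetic taxonomy used by several suites (kept light)
small_spec <- function(seed = 7, ...) {
  taxonomy_spec(n_orders = 3, species_per_order = 3, n_nodes = 60,
                density_range = c(0.12, 0.25), seed = seed, ...)
}
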