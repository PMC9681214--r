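# Synthetic taxonomy of connectomes.
#
# Stated world: each taxonomic order has one architectural archetype -- a
# bilateral stochastic block model (order-specific module count and
# density) with homotopic + random inter-hemispheric edges, lateralized
# Gaussian coordinate clouds, and log-normal edge weights that decay with
# Euclidean distance. Species within an order are degree-preserving
# rewirings of their order's archetype (local perturbation), replicas are
# much smaller rewirings plus weight jitter. Within-order perturbation is
# small relative to between-order architectural divergence by
# construction, which is what the intra- vs inter-order comparison
# assumes.

#' Specification of a synthetic taxonomy
#'
#' Defaults describe the reference world used across the test-suite:
#' 6 orders x 5 species, 200 bilateral nodes, order densities spanning
#' 0.08-0.25, 5% within-order edge rewiring, replicas with 2% rewiring and
#' 5% weight jitter.
#'
#' @param n_orders number of taxonomic orders.
#' @param species_per_order species per order (scalar or per-order vector).
#' @param n_nodes even number of nodes (two hemispheres of equal size).
#' @param density_range range of binary densities assigned (evenly spaced)
#'   across orders.
#' @param modules_per_hemisphere per-order module counts; default
#'   `1 + (1:n_orders)` so archetypes differ in modular structure.
#' @param module_contrast ratio of within- to between-module connection
#'   probability inside a hemisphere.
#' @param interhemispheric_fraction target fraction of edges crossing the
#'   midline.
#' @param homotopic_prob probability that a mirror-symmetric node pair is
#'   connected.
#' @param p_in,p_out,p_cross optional explicit block probabilities; when
#'   given they override the density-driven calibration (`p_cross` applies
#'   to non-homotopic inter-hemispheric pairs).
#' @param within_order_rewire fraction of archetype edges rewired
#'   (degree-preserving) to obtain each species.
#' @param species_weight_jitter log-scale SD of the multiplicative weight
#'   jitter applied per species.
#' @param replica_rewire,replica_jitter same two knobs for replica scans.
#' @param replicas replica count per species: a single integer for all
#'   species or a named vector keyed by species_id (see
#'   [generate_dataset()] for the id scheme); species not named get 1.
#' @param weight_meanlog,weight_sdlog,weight_distance_decay parameters of
#'   the distance-dependent log-normal edge weights
#'   (`meanlog = weight_meanlog - decay * d/d_max`).
#' @param coord_jitter SD of the per-species coordinate jitter.
#' @param max_retries bounded retries for connectivity-preserving steps.
#' @param seed master seed; every generated object derives its own
#'   substream from it.
#' @return a list of class `taxonomy_spec`.
#' @export
taxonomy_spec <- function(n_orders = 6,
                          species_per_order = 5,
                          n_nodes = 200,
                          density_range = c(0.08, 0.25),
                          modules_per_hemisphere = NULL,
                          module_contrast = 6,
                          interhemispheric_fraction = 0.12,
                          homotopic_prob = 0.75,
                          p_in = NULL, p_out = NULL, p_cross = NULL,
                          within_order_rewire = 0.05,
                          species_weight_jitter = 0.10,
                          replica_rewire = 0.02,
                          replica_jitter = 0.05,
                          replicas = 1L,
                          weight_meanlog = 3.0,
                          weight_sdlog = 0.5,
                          weight_distance_decay = 1.5,
                          coord_jitter = 0.2,
                          max_retries = 20,
                          seed = 1L) {
  if (n_nodes %% 2 != 0) stop("taxonomy_spec: n_nodes must be even")
  if (within_order_rewire < 0 || within_order_rewire > 1) {
    stop("taxonomy_spec: within_order_rewire must be in [0, 1]")
  }
  if (length(species_per_order) == 1) {
    species_per_order <- rep(species_per_order, n_orders)
  }
  stopifnot(length(species_per_order) == n_orders)
  if (is.null(modules_per_hemisphere)) {
    modules_per_hemisphere <- 1 + seq_len(n_orders)
  }
  if (length(modules_per_hemisphere) == 1) {
    modules_per_hemisphere <- rep(modules_per_hemisphere, n_orders)
  }
  structure(
    list(n_orders = as.integer(n_orders),
         species_per_order = as.integer(species_per_order),
         n_nodes = as.integer(n_nodes),
         density_range = density_range,
         modules_per_hemisphere = as.integer(modules_per_hemisphere),
         module_contrast = module_contrast,
         interhemispheric_fraction = interhemispheric_fraction,
         homotopic_prob = homotopic_prob,
         p_in = p_in, p_out = p_out, p_cross = p_cross,
         within_order_rewire = within_order_rewire,
         species_weight_jitter = species_weight_jitter,
         replica_rewire = replica_rewire,
         replica_jitter = replica_jitter,
         replicas = replicas,
         weight_meanlog = weight_meanlog,
         weight_sdlog = weight_sdlog,
         weight_distance_decay = weight_distance_decay,
         coord_jitter = coord_jitter,
         max_retries = as.integer(max_retries),
         seed = as.integer(seed)),
    class = "taxonomy_spec")
}

# per-order density targets, evenly spaced across the configured range
order_densities <- function(spec) {
  if (spec$n_orders == 1) return(mean(spec$density_range))
  seq(spec$density_range[1], spec$density_range[2],
      length.out = spec$n_orders)
}

# distance-dependent log-normal weights for the edges of `adj`
assign_weights <- function(adj, coords, spec) {
  n <- nrow(adj)
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  d <- sqrt(rowSums((coords[idx[, 1], , drop = FALSE] -
                       coords[idx[, 2], , drop = FALSE])^2))
  dmax <- max(dist(coords))
  wv <- rlnorm(nrow(idx),
               meanlog = spec$weight_meanlog -
                 spec$weight_distance_decay * d / dmax,
               sdlog = spec$weight_sdlog)
  w <- matrix(0, n, n)
  w[idx] <- wv
  w + t(w)
}

# add minimal bridging edges until the graph is connected
ensure_connected <- function(adj) {
  repeat {
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
    if (comp$no == 1) return(adj)
    small <- which.min(comp$csize)
    i <- sample(which(comp$membership == small), 1)
    j <- sample(which(comp$membership != small), 1)
    adj[i, j] <- adj[j, i] <- 1
  }
}

#' Generate an order archetype connectome
#'
#' Builds the bilateral stochastic-block-model archetype for one order:
#' intra-hemispheric edges from an order-specific SBM (module count and
#' density from the spec), homotopic plus random inter-hemispheric edges,
#' mirrored Gaussian coordinate clouds, and distance-decaying log-normal
#' weights. Connectivity is enforced by adding minimal bridging edges.
#'
#' @param order_index which order (1-based).
#' @param spec a [taxonomy_spec].
#' @param seed optional seed (defaults to a substream derived from
#'   `spec$seed` and the order index).
#' @return a [connectome] whose `species_id` marks it as the order
#'   archetype.
#' @export
generate_archetype <- function(order_index, spec,
                               seed = derive_seed(spec$seed,
                                                  paste0("archetype/", order_index))) {
  stopifnot(inherits(spec, "taxonomy_spec"),
            order_index >= 1, order_index <= spec$n_orders)
  set.seed(seed)
  n <- spec$n_nodes
  nh <- n %/% 2
  m <- spec$modules_per_hemisphere[order_index]
  rho <- order_densities(spec)[order_index]

  # modules mirrored across hemispheres; nodes 1..nh = left
  mods_h <- sort(rep_len(seq_len(m), nh))
  mods <- c(mods_h, mods_h)
  hemi <- rep(c("L", "R"), each = nh)

  # coordinates: mirrored module centres, lateral offset, nodal scatter
  centers <- matrix(rnorm(3 * m, sd = 4), m, 3)
  node_centers <- centers[mods_h, , drop = FALSE]
  left <- node_centers + matrix(rnorm(3 * nh, sd = 1.5), nh, 3)
  left[, 1] <- left[, 1] - 8
  right <- node_centers + matrix(rnorm(3 * nh, sd = 1.5), nh, 3)
  right[, 1] <- -right[, 1] + 8  # mirror of the left cloud about x = 0
  coords <- rbind(left, right)

  # edge budget: split target density between intra- and inter-hemispheric
  e_target <- rho * n * (n - 1) / 2
  e_cross <- spec$interhemispheric_fraction * e_target
  e_hemi <- (e_target - e_cross) / 2
  pairs_h <- nh * (nh - 1) / 2
  p_in_pairs <- sum(vapply(tabulate(mods_h, m),
                           function(sz) sz * (sz - 1) / 2, 0))
  p_out_pairs <- pairs_h - p_in_pairs
  if (!is.null(spec$p_in)) {
    p_in <- spec$p_in
    p_out <- if (is.null(spec$p_out)) spec$p_in else spec$p_out
  } else {
    p_out <- e_hemi / (p_in_pairs * spec$module_contrast + p_out_pairs)
    p_in <- spec$module_contrast * p_out
    if (p_in > 1) {  # saturated modules at high density: spill outward
      p_in <- 1
      p_out <- min(1, max(0, (e_hemi - p_in_pairs) / p_out_pairs))
    }
  }
  p_cross <- if (!is.null(spec$p_cross)) spec$p_cross else {
    n_hom <- nh * spec$homotopic_prob
    min(1, max(0, (e_cross - n_hom) / (nh * nh - nh)))
  }

  adj <- matrix(0, n, n)
  # intra-hemispheric SBM edges, both hemispheres at once
  ut <- which(upper.tri(adj), arr.ind = TRUE)
  same_h <- hemi[ut[, 1]] == hemi[ut[, 2]]
  same_m <- mods[ut[, 1]] == mods[ut[, 2]]
  homot <- abs(ut[, 1] - ut[, 2]) == nh  # mirror pairs (i, i + nh)
  p <- ifelse(same_h, ifelse(same_m, p_in, p_out),
              ifelse(homot, spec$homotopic_prob, p_cross))
  on <- runif(nrow(ut)) < p
  adj[ut[on, , drop = FALSE]] <- 1
  adj <- adj + t(adj)
  adj <- ensure_connected(adj)

  w <- assign_weights(adj, coords, spec)
  connectome(w, hemi, coords,
             species_id = sprintf("archetype_o%02d", order_index),
             sample_id = sprintf("archetype_o%02d", order_index))
}

# degree-preserving double-edge swaps on an adjacency matrix; returns the
# rewired adjacency or NULL if the swap budget could not be spent
swap_edges <- function(adj, n_swaps, max_attempts = 200 * max(n_swaps, 1)) {
  if (n_swaps == 0) return(adj)
  el <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  ne <- nrow(el)
  done <- 0
  attempts <- 0
  while (done < n_swaps && attempts < max_attempts) {
    attempts <- attempts + 1
    pick <- sample.int(ne, 2)
    a <- el[pick[1], 1]; b <- el[pick[1], 2]
    c_ <- el[pick[2], 1]; d <- el[pick[2], 2]
    if (runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
    if (length(unique(c(a, b, c_, d))) < 4) next
    if (adj[a, d] > 0 || adj[c_, b] > 0) next
    adj[a, b] <- adj[b, a] <- 0
    adj[c_, d] <- adj[d, c_] <- 0
    adj[a, d] <- adj[d, a] <- 1
    adj[c_, b] <- adj[b, c_] <- 1
    el[pick[1], ] <- sort(c(a, d))
    el[pick[2], ] <- sort(c(c_, b))
    done <- done + 1
  }
  if (done < n_swaps) return(NULL)
  adj
}

# shared species/replica perturbation: degree-preserving rewiring of a
# fraction of edges (connectivity enforced by retry), re-weighting of new
# edges by the archetype weight rule, multiplicative log-normal weight
# jitter, small coordinate jitter
perturb_connectome <- function(parent, spec, rewire_frac, jitter_sd,
                               species_id, sample_id) {
  if (rewire_frac < 0 || rewire_frac > 1) {
    stop("perturb_connectome: rewire fraction must be in [0, 1]")
  }
  ne <- sum(parent$adjacency) / 2
  n_swaps <- ceiling(rewire_frac * ne / 2)  # each swap moves two edges
  adj <- NULL
  for (try in seq_len(spec$max_retries)) {
    cand <- swap_edges(parent$adjacency, n_swaps)
    if (is.null(cand)) next
    g <- igraph::graph_from_adjacency_matrix(cand, mode = "undirected")
    if (igraph::is_connected(g)) { adj <- cand; break }
  }
  if (is.null(adj)) {
    stop("perturb_connectome: could not rewire while keeping connectivity")
  }
  coords <- parent$coords
  if (spec$coord_jitter > 0 && rewire_frac > 0) {
    coords <- coords + matrix(rnorm(length(coords), sd = spec$coord_jitter),
                              nrow(coords), 3)
  }
  w <- parent$weights * (adj * parent$adjacency)  # weights of kept edges
  new_e <- which(upper.tri(adj) & adj > 0 & w == 0, arr.ind = TRUE)
  if (nrow(new_e) > 0) {
    fresh <- assign_weights(adj, coords, spec)
    w[new_e] <- fresh[new_e]
    w[new_e[, c(2, 1), drop = FALSE]] <- fresh[new_e]
  }
  if (jitter_sd > 0) {
    jit <- matrix(0, nrow(w), ncol(w))
    ut <- upper.tri(w)
    jit[ut] <- rlnorm(sum(ut), 0, jitter_sd)
    jit <- jit + t(jit)
    w <- w * jit
  }
  connectome(w, parent$hemisphere, coords,
             species_id = species_id, sample_id = sample_id)
}

#' Generate a species connectome from its order archetype
#'
#' Rewires `within_order_rewire` of the archetype's edges with
#' degree-preserving swaps (the binary degree sequence is preserved
#' exactly), applies multiplicative log-normal weight jitter, and jitters
#' coordinates slightly. With zero rewiring and zero jitter the archetype
#' is returned unchanged (up to identifiers).
#'
#' @param archetype the order archetype [connectome].
#' @param spec a [taxonomy_spec].
#' @param species_id,sample_id identifiers for the new connectome.
#' @param seed optional seed.
#' @return a [connectome].
#' @export
generate_species <- function(archetype, spec,
                             species_id = paste0(archetype$species_id, "_sp"),
                             sample_id = species_id,
                             seed = NULL) {
  stopifnot(inherits(spec, "taxonomy_spec"))
  if (!is.null(seed)) set.seed(seed)
  perturb_connectome(archetype, spec, spec$within_order_rewire,
                     spec$species_weight_jitter, species_id, sample_id)
}

#' Generate a replica scan of a species connectome
#'
#' Same perturbation family as [generate_species()] but with the (much
#' smaller) replica noise: `replica_rewire` edge rewiring and
#' `replica_jitter` weight jitter, emulating scan-to-scan variability.
#'
#' @param con the species [connectome].
#' @param spec a [taxonomy_spec].
#' @param sample_id identifier of the replica scan.
#' @param seed optional seed.
#' @return a [connectome] with the same `species_id`.
#' @export
generate_replica <- function(con, spec, sample_id, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  perturb_connectome(con, spec, spec$replica_rewire, spec$replica_jitter,
                     con$species_id, sample_id)
}

#' Generate a full synthetic dataset
#'
#' Builds one archetype per order, derives the configured number of
#' species per order, and adds replica scans where requested. Species ids
#' follow `sp_o<order>_<species>`, sample ids append `_r<replica>`.
#' Orders are split into two superorders (first half / second half).
#' Deterministic given `spec$seed`: every connectome draws from a
#' substream derived by hashing (role, order, species, replica).
#'
#' @param spec a [taxonomy_spec].
#' @return a [connectome_dataset].
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "taxonomy_spec"))
  cons <- list()
  sp_rows <- list()
  for (o in seq_len(spec$n_orders)) {
    arch <- generate_archetype(o, spec)
    order_id <- sprintf("order_%02d", o)
    super_id <- if (o <= ceiling(spec$n_orders / 2)) "superorder_A" else "superorder_B"
    for (s in seq_len(spec$species_per_order[o])) {
      species_id <- sprintf("sp_o%02d_%02d", o, s)
      base <- generate_species(
        arch, spec, species_id = species_id,
        sample_id = paste0(species_id, "_r1"),
        seed = derive_seed(spec$seed, paste0("species/", o, "/", s)))
      cons[[length(cons) + 1]] <- base
      n_rep <- if (is.null(names(spec$replicas))) spec$replicas[[1]] else {
        r <- spec$replicas[species_id]
        if (is.na(r)) 1L else as.integer(r)
      }
      if (n_rep > 1) {
        for (r in 2:n_rep) {
          cons[[length(cons) + 1]] <- generate_replica(
            base, spec, sample_id = sprintf("%s_r%d", species_id, r),
            seed = derive_seed(spec$seed,
                               paste0("replica/", o, "/", s, "/", r)))
        }
      }
      sp_rows[[length(sp_rows) + 1]] <- data.frame(
        species_id = species_id, order = order_id, superorder = super_id)
    }
  }
  ds <- connectome_dataset(cons, do.call(rbind, sp_rows), spec$n_nodes)
  ctx_log(sprintf("generated %d connectomes (%d species, %d orders), seed %d",
                  length(ds$connectomes), nrow(ds$species), spec$n_orders,
                  spec$seed))
  ds
}
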