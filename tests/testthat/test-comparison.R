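# Distance matrices, replica resampling, intra/inter statistics, density
# control, embeddings.

ctx_log_level("none")

test_that("topological distance standardizes against its context", {
  set.seed(3)
  con <- toy_connectome(random_weighted_adj(15, 0.4))
  v <- feature_vector(con)
  ctx <- rbind(v, v * runif(22, 0.5, 2), v * runif(22, 0.5, 2))
  expect_equal(topological_distance(v, v, ctx), 0, tolerance = 1e-12)
  d12 <- topological_distance(v, ctx[2, ], ctx)
  expect_equal(topological_distance(ctx[2, ], v, ctx), d12)

  # with a 2-row context, z-scores are +/- the same magnitude: equal sign
  # patterns give 0, fully opposed ones give 2
  a <- setNames(c(1, 5, 2), c("f1", "f2", "f3"))
  b <- setNames(c(3, 9, 7), c("f1", "f2", "f3"))
  ctx2 <- rbind(a, b)
  expect_equal(topological_distance(a, a, ctx2, standardize = FALSE), 0)
  expect_equal(topological_distance(a, b, ctx2), 2, tolerance = 1e-12)
  # zero-variance columns are dropped with a warning
  ctx3 <- cbind(ctx2, f4 = c(1, 1))
  expect_warning(
    d <- topological_distance(c(a, f4 = 1), c(b, f4 = 1), ctx3),
    "zero-variance")
  expect_equal(d, 2, tolerance = 1e-12)
})

test_that("distance matrices are symmetric with zero diagonal", {
  ds <- generate_dataset(small_spec(seed = 41))
  for (metric in c("spectral", "topological")) {
    dm <- distance_matrix(ds, metric)
    expect_equal(as.vector(dm), as.vector(t(dm)), tolerance = 1e-12)
    expect_equal(unname(diag(dm)), rep(0, nrow(dm)))
    expect_true(all(dm >= 0))
    expect_equal(rownames(dm), ds$species$species_id)
  }
  # duplicated species (identical connectomes) sit at distance 0
  con <- ds$connectomes[[1]]
  twin <- connectome(con$weights, con$hemisphere, con$coords,
                     species_id = "twin", sample_id = "twin")
  ds2 <- connectome_dataset(
    c(ds$connectomes, list(twin)),
    rbind(ds$species, data.frame(species_id = "twin", order = "order_01",
                                 superorder = "superorder_A")))
  dm2 <- distance_matrix(ds2, "spectral")
  expect_equal(dm2[con$species_id, "twin"], 0, tolerance = 1e-12)
})

test_that("replica resampling reduces to the single-shot matrix and converges", {
  ds <- generate_dataset(small_spec(seed = 51))
  dm0 <- distance_matrix(ds, "spectral")
  dmr <- resample_replicas(ds, "spectral", n_iter = 50, seed = 2)
  expect_equal(as.vector(dmr), as.vector(dm0), tolerance = 1e-12)
  expect_identical(attr(dmr, "resampling")$n_iter, 50)

  # with replicas: deterministic given seed, and the average lies between
  # the two single-assignment extremes
  spec <- small_spec(seed = 52, replicas = c(sp_o01_01 = 2L),
                     replica_rewire = 0.2, replica_jitter = 0.2)
  dsr <- generate_dataset(spec)
  d1 <- resample_replicas(dsr, "spectral", n_iter = 200, seed = 7)
  d2 <- resample_replicas(dsr, "spectral", n_iter = 200, seed = 7)
  expect_identical(as.vector(d1), as.vector(d2))

  samples <- species_samples(dsr)
  keep_one <- function(which_rep) {
    sel <- vapply(samples, `[[`, "", 1)
    sel["sp_o01_01"] <- samples[["sp_o01_01"]][which_rep]
    connectome_dataset(dsr$connectomes[sel], dsr$species)
  }
  a <- distance_matrix(keep_one(1), "spectral")["sp_o01_01", "sp_o02_01"]
  b <- distance_matrix(keep_one(2), "spectral")["sp_o01_01", "sp_o02_01"]
  avg <- d1["sp_o01_01", "sp_o02_01"]
  expect_gte(avg, min(a, b) - 1e-12)
  expect_lte(avg, max(a, b) + 1e-12)
})

test_that("intra/inter comparison computes both test/effect-size pairs", {
  # hand-built distance matrix: two orders of two species; intra pairs
  # have distance 0.1, inter pairs 0.5
  labels <- c("a1", "a2", "b1", "b2")
  dm <- matrix(0.5, 4, 4, dimnames = list(labels, labels))
  dm[1, 2] <- dm[2, 1] <- dm[3, 4] <- dm[4, 3] <- 0.1
  diag(dm) <- 0
  sp <- data.frame(species_id = labels, order = c("A", "A", "B", "B"),
                   superorder = "S")
  cmp <- intra_inter_compare(dm, sp)
  expect_equal(sort(cmp$intra), c(0.1, 0.1))
  expect_length(cmp$inter, 4)
  expect_equal(cmp$mannwhitney$cles, 100)  # complete separation
  expect_true(is.infinite(cmp$welch$d))    # zero pooled variance

  # U and CLES against exhaustive pair counting with ties
  set.seed(8)
  ds <- generate_dataset(small_spec(seed = 61))
  cmp2 <- intra_inter_compare(distance_matrix(ds, "spectral"), ds$species)
  u_brute <- 0
  for (x in cmp2$inter) for (y in cmp2$intra) {
    u_brute <- u_brute + (x > y) + 0.5 * (x == y)
  }
  expect_equal(cmp2$mannwhitney$U, u_brute)
  expect_equal(cmp2$mannwhitney$cles,
               100 * u_brute / (length(cmp2$inter) * length(cmp2$intra)))
  expect_equal(length(cmp2$intra) + length(cmp2$inter),
               choose(nrow(ds$species), 2))
  # Cohen's d against its definition
  d_direct <- (mean(cmp2$inter) - mean(cmp2$intra)) /
    sqrt(((length(cmp2$inter) - 1) * var(cmp2$inter) +
            (length(cmp2$intra) - 1) * var(cmp2$intra)) /
           (length(cmp2$inter) + length(cmp2$intra) - 2))
  expect_equal(cmp2$welch$d, d_direct)
})

test_that("order block summary takes medians by block", {
  labels <- c("a1", "a2", "b1")
  dm <- matrix(0, 3, 3, dimnames = list(labels, labels))
  dm[1, 2] <- dm[2, 1] <- 0.2
  dm[1, 3] <- dm[3, 1] <- 0.6
  dm[2, 3] <- dm[3, 2] <- 0.8
  sp <- data.frame(species_id = labels, order = c("A", "A", "B"),
                   superorder = "S")
  blk <- order_block_summary(dm, sp)
  expect_equal(blk["A", "A"], 0.2)
  expect_equal(blk["A", "B"], median(c(0.6, 0.8)))
  expect_equal(blk, t(blk))

  ds <- generate_dataset(small_spec(seed = 71))
  blk2 <- order_block_summary(distance_matrix(ds, "spectral"), ds$species)
  expect_lt(mean(diag(blk2)), mean(blk2[upper.tri(blk2)]))
})

test_that("density control residualizes only density-driven features", {
  set.seed(10)
  n <- 50
  dens <- runif(n, 0.05, 0.4)
  lin <- 2 * dens + 1
  indep <- rnorm(n)
  expo <- exp(3 * dens) + rnorm(n, sd = 0.01)
  ft <- cbind(lin = lin, indep = indep, expo = expo)
  out <- density_control(ft, dens)
  info <- attr(out, "density_control")

  expect_true(info$controlled[info$feature == "lin"])
  expect_equal(info$model[info$feature == "lin"], "linear")
  expect_lt(max(abs(out[, "lin"])), 1e-10)

  expect_false(info$controlled[info$feature == "indep"])
  expect_identical(out[, "indep"], ft[, "indep"])

  expect_true(info$controlled[info$feature == "expo"])
  expect_equal(info$model[info$feature == "expo"], "exponential")
  expect_lt(sd(out[, "expo"]), 0.1 * sd(ft[, "expo"]))
  for (f in c("lin", "expo")) {
    expect_lt(abs(cor(out[, f], dens)), 0.1)
  }
})

test_that("network density matches counting", {
  expect_equal(network_density(k_complete(4)), 1)
  expect_equal(network_density(path_graph(4)), 0.5)
  expect_equal(network_density(matrix(0, 5, 5)), 0)
})

test_that("MDS embeds symmetric structures faithfully", {
  # three equidistant species -> equilateral triangle
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  em <- mds_embed(d3, 2, seed = 1)
  dd <- as.matrix(dist(em$coords))
  expect_equal(sd(dd[upper.tri(dd)]), 0, tolerance = 1e-6)
  expect_lt(em$stress, 1e-4)

  # duplicates coincide
  d4 <- matrix(1, 4, 4); diag(d4) <- 0
  d4[1, 2] <- d4[2, 1] <- 0
  em4 <- mds_embed(d4, 2, seed = 1)
  expect_lt(sqrt(sum((em4$coords[1, ] - em4$coords[2, ])^2)), 1e-6)

  # two well-separated clusters stay separated
  d8 <- matrix(1, 8, 8); diag(d8) <- 0
  d8[1:4, 1:4][d8[1:4, 1:4] > 0] <- 0.1
  d8[5:8, 5:8][d8[5:8, 5:8] > 0] <- 0.1
  em8 <- mds_embed(d8, 2, seed = 1)
  dd8 <- as.matrix(dist(em8$coords))
  within <- c(dd8[1:4, 1:4][upper.tri(diag(4))],
              dd8[5:8, 5:8][upper.tri(diag(4))])
  between <- as.vector(dd8[1:4, 5:8])
  expect_gt(min(between), max(within))
})

test_that("average-linkage clustering recovers planted blocks", {
  labels <- paste0("s", 1:6)
  d <- matrix(1, 6, 6, dimnames = list(labels, labels))
  diag(d) <- 0
  d[1:3, 1:3][d[1:3, 1:3] > 0] <- 0.1
  d[4:6, 4:6][d[4:6, 4:6] > 0] <- 0.1
  hc <- hierarchical_cluster(d)
  expect_true(all(diff(hc$height) >= -1e-12))
  k2 <- stats::cutree(hc, 2)
  expect_equal(length(unique(k2[1:3])), 1)
  expect_equal(length(unique(k2[4:6])), 1)
  expect_false(k2[1] == k2[4])

  # identical species merge at height 0
  d[1, 2] <- d[2, 1] <- 0
  expect_equal(min(hierarchical_cluster(d)$height), 0)
})
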