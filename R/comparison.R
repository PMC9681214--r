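# Inter-species distance matrices (spectral and topological), replica
# resampling, intra- vs inter-order statistics, density control, and
# low-dimensional embeddings of distance matrices.

# per-sample raw comparison vectors for a metric
comparison_vectors <- function(dataset, metric = c("spectral", "topological"),
                               features = "all", weighting = "all",
                               use_smoothed = FALSE) {
  metric <- match.arg(metric)
  if (metric == "spectral") {
    rows <- lapply(dataset$connectomes, function(con) {
      pr <- spectrum(con)
      if (use_smoothed) smooth_spectrum(pr)$smoothed$density else pr$eigenvalues
    })
  } else {
    rows <- lapply(dataset$connectomes, feature_vector,
                   features = features, weighting = weighting)
  }
  do.call(rbind, rows)
}

# distance matrix over rows of a vector table; topological vectors are
# z-scored per column across the table first (the standardization context)
dist_from_vectors <- function(x, standardize) {
  if (standardize) {
    sds <- apply(x, 2, sd)
    if (any(sds == 0)) {
      warning(sprintf("dropping %d zero-variance feature column(s)",
                      sum(sds == 0)))
      x <- x[, sds > 0, drop = FALSE]
      sds <- sds[sds > 0]
    }
    if (ncol(x) == 0) stop("no informative features left to compare")
    x <- scale(x)
  }
  cosine_distance_matrix(x)
}

#' Topological distance between two feature vectors
#'
#' One minus the cosine similarity of the two vectors after z-scoring
#' every feature across a standardization context (a feature table holding
#' all species' vectors for the current comparison). Without
#' standardization the raw vectors are compared, in which case
#' large-magnitude features dominate.
#'
#' @param a,b named feature vectors with identical feature sets.
#' @param context matrix of all species' feature vectors (one row per
#'   species) supplying the per-feature mean/SD; must contain the same
#'   columns as `a` and `b`.
#' @param standardize z-score features across the context first (default
#'   TRUE).
#' @return scalar distance (in \[0, 2\] for standardized vectors, \[0, 1\]
#'   for raw nonnegative ones).
#' @export
topological_distance <- function(a, b, context, standardize = TRUE) {
  stopifnot(identical(names(a), names(b)))
  if (standardize) {
    stopifnot(ncol(context) == length(a))
    mu <- colMeans(context)
    sds <- apply(context, 2, sd)
    keep <- sds > 0
    if (!all(keep)) {
      warning(sprintf("dropping %d zero-variance feature column(s)",
                      sum(!keep)))
    }
    a <- (a[keep] - mu[keep]) / sds[keep]
    b <- (b[keep] - mu[keep]) / sds[keep]
  }
  cosine_distance(a, b)
}

# pick one sample per species (the first listed), logging when replicas
# are being ignored
first_sample_per_species <- function(dataset) {
  samples <- species_samples(dataset)
  n_multi <- sum(lengths(samples) > 1)
  if (n_multi > 0) {
    ctx_log(sprintf(
      "distance_matrix: %d species have replicas; using first sample each (see resample_replicas)",
      n_multi), level = "warning")
  }
  vapply(samples, `[[`, "", 1)
}

new_distance_matrix <- function(values, labels, metric, features, weighting,
                                standardize, resampling = NULL) {
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("distance_matrix", "matrix"),
            metric = metric, features = features, weighting = weighting,
            standardize = standardize, resampling = resampling)
}

#' Inter-species distance matrix
#'
#' Computes all pairwise spectral or topological distances across the
#' species of a dataset, using one connectome per species (the first
#' sample; use [resample_replicas()] to handle replica scans properly).
#'
#' @param dataset a [connectome_dataset].
#' @param metric `"spectral"` or `"topological"`.
#' @param features,weighting feature subset for the topological metric
#'   (see [feature_vector()]).
#' @param standardize z-score topological features across species before
#'   the cosine (default TRUE; ignored for spectral).
#' @param use_smoothed for the spectral metric, compare Gaussian-smoothed
#'   eigenvalue densities instead of raw eigenvalues.
#' @return a symmetric `distance_matrix` (species x species, zero
#'   diagonal) with provenance attributes `metric`, `features`,
#'   `weighting`, `standardize`, `resampling`.
#' @export
distance_matrix <- function(dataset, metric = c("spectral", "topological"),
                            features = "all", weighting = "all",
                            standardize = TRUE, use_smoothed = FALSE) {
  metric <- match.arg(metric)
  sel <- first_sample_per_species(dataset)
  sub <- connectome_dataset(dataset$connectomes[sel], dataset$species,
                            dataset$parcellation_size)
  x <- comparison_vectors(sub, metric, features, weighting, use_smoothed)
  d <- dist_from_vectors(x, standardize = (metric == "topological") && standardize)
  new_distance_matrix(d, dataset$species$species_id, metric, features,
                      weighting, standardize)
}

#' Distance matrix from a precomputed feature table
#'
#' Builds the topological `distance_matrix` directly from a feature table
#' (as returned by [feature_table()], possibly subset via
#' [feature_subset()] column selection or residualized by
#' [density_control()]), avoiding recomputation of graph measures when
#' several feature subsets are compared.
#'
#' @param features matrix of per-species feature vectors (one row per
#'   species, rownames used as labels).
#' @param labels species labels (default: rownames of `features`).
#' @param standardize z-score features across rows first (default TRUE).
#' @return a `distance_matrix` with metric `"topological"`.
#' @export
feature_distance_matrix <- function(features, labels = rownames(features),
                                    standardize = TRUE) {
  d <- dist_from_vectors(as.matrix(features), standardize)
  new_distance_matrix(d, labels, "topological", "custom", "custom",
                      standardize)
}

#' Replica-controlled distance matrix
#'
#' Repeatedly samples one scan per species, computes the full distance
#' matrix, and averages element-wise across iterations, so species with
#' many replica scans do not dominate the distance distributions.
#' Species with a single scan contribute the same vector each iteration;
#' with no replicas anywhere the result equals [distance_matrix()]
#' exactly.
#'
#' @inheritParams distance_matrix
#' @param n_iter number of resampling iterations (study setting: 10000).
#' @param seed RNG seed (the result is deterministic given the seed).
#' @return an averaged `distance_matrix` with `resampling = list(n_iter,
#'   seed)`.
#' @export
resample_replicas <- function(dataset, metric = c("spectral", "topological"),
                              features = "all", weighting = "all",
                              standardize = TRUE, use_smoothed = FALSE,
                              n_iter = 10000, seed = 1) {
  metric <- match.arg(metric)
  stopifnot(n_iter >= 1)
  x <- comparison_vectors(dataset, metric, features, weighting, use_smoothed)
  samples <- species_samples(dataset)
  n_sp <- length(samples)
  set.seed(seed)
  acc <- matrix(0, n_sp, n_sp)
  std <- (metric == "topological") && standardize
  for (it in seq_len(n_iter)) {
    pick <- vapply(samples, function(s)
      if (length(s) == 1) s else s[sample.int(length(s), 1)], "")
    acc <- acc + suppressWarnings(dist_from_vectors(x[pick, , drop = FALSE], std))
  }
  new_distance_matrix(acc / n_iter, dataset$species$species_id, metric,
                      features, weighting, standardize,
                      resampling = list(n_iter = n_iter, seed = seed))
}

#' Intra- versus inter-order distance comparison
#'
#' Splits the unordered species pairs of a distance matrix into same-order
#' (intra) and different-order (inter) samples and compares them with the
#' two test/effect-size pairs: Welch's unequal-variance t-test with
#' Cohen's d (pooled-SD, positive when inter > intra) and the
#' Mann-Whitney U test with the common-language effect size
#' (`100 * U / (n1 n2)`, ties counted half).
#'
#' @param dm a `distance_matrix`.
#' @param species species table (`species_id`, `order`) covering the
#'   matrix labels.
#' @return object of class `taxon_comparison`: list with `intra`, `inter`
#'   (numeric samples), `welch` (`t`, `p`, `d`) and `mannwhitney` (`U`,
#'   `p`, `cles`).
#' @export
intra_inter_compare <- function(dm, species) {
  labels <- rownames(dm)
  ord <- species$order[match(labels, species$species_id)]
  if (any(is.na(ord))) stop("intra_inter_compare: unlabeled species")
  ut <- which(upper.tri(dm), arr.ind = TRUE)
  same <- ord[ut[, 1]] == ord[ut[, 2]]
  intra <- dm[ut[same, , drop = FALSE]]
  inter <- dm[ut[!same, , drop = FALSE]]
  if (length(intra) < 2 || length(inter) < 2) {
    stop("intra_inter_compare: need at least two distances in each group")
  }
  n1 <- length(inter); n2 <- length(intra)
  tt <- tryCatch(t.test(inter, intra, var.equal = FALSE),
                 error = function(e) {
                   # both groups (near-)constant: complete separation
                   delta <- mean(inter) - mean(intra)
                   list(statistic = c(t = sign(delta) * Inf),
                        p.value = if (delta == 0) 1 else 0)
                 })
  sp2 <- ((n1 - 1) * var(inter) + (n2 - 1) * var(intra)) / (n1 + n2 - 2)
  d <- if (sp2 <= 0) {
    sign(mean(inter) - mean(intra)) * Inf
  } else {
    (mean(inter) - mean(intra)) / sqrt(sp2)
  }
  u <- sum(outer(inter, intra, ">")) + 0.5 * sum(outer(inter, intra, "=="))
  wt <- suppressWarnings(wilcox.test(inter, intra, exact = FALSE))
  structure(
    list(intra = intra, inter = inter,
         welch = list(t = unname(tt$statistic), p = tt$p.value, d = d),
         mannwhitney = list(U = u, p = wt$p.value,
                            cles = 100 * u / (n1 * n2))),
    class = "taxon_comparison")
}

#' @export
print.taxon_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("<taxon_comparison> intra n=%d mean=%.3f median=%.3f | ",
           "inter n=%d mean=%.3f median=%.3f\n",
           "  Welch t=%.2f p=%.3g Cohen d=%.2f | Mann-Whitney U=%.0f ",
           "p=%.3g CLES=%.1f%%\n"),
    length(x$intra), mean(x$intra), median(x$intra),
    length(x$inter), mean(x$inter), median(x$inter),
    x$welch$t, x$welch$p, x$welch$d,
    x$mannwhitney$U, x$mannwhitney$p, x$mannwhitney$cles))
  invisible(x)
}

#' Order-by-order median distance blocks
#'
#' @param dm a `distance_matrix`.
#' @param species species table mapping species to orders.
#' @return symmetric order x order matrix; entry (o1, o2) is the median
#'   distance over species pairs spanning the two orders, the diagonal
#'   holds within-order medians.
#' @export
order_block_summary <- function(dm, species) {
  labels <- rownames(dm)
  ord <- species$order[match(labels, species$species_id)]
  orders <- unique(ord)
  k <- length(orders)
  out <- matrix(NA_real_, k, k, dimnames = list(orders, orders))
  for (i in seq_len(k)) {
    for (j in i:k) {
      ii <- which(ord == orders[i])
      jj <- which(ord == orders[j])
      vals <- if (i == j) {
        block <- dm[ii, ii, drop = FALSE]
        block[upper.tri(block)]
      } else {
        as.vector(dm[ii, jj, drop = FALSE])
      }
      out[i, j] <- out[j, i] <- median(vals)
    }
  }
  out
}

#' Residualize features against network density
#'
#' For each feature, fits a linear (`y = a x + b`) and an exponential
#' (`y = a exp(b x) + c`) model of the feature on density, keeps the model
#' with the larger R-squared, and replaces the feature by its residuals
#' when that R-squared exceeds `r2_threshold`; otherwise the feature
#' passes through unchanged. A non-converging exponential fit falls back
#' to the linear model (logged).
#'
#' @param features matrix of per-sample features (rows = samples).
#' @param densities per-sample binary densities.
#' @param r2_threshold variance-explained threshold above which a feature
#'   is controlled (default 0.1).
#' @return the feature matrix with controlled columns residualized;
#'   attribute `"density_control"` holds a data.frame of per-feature
#'   (model, r2, controlled).
#' @export
density_control <- function(features, densities, r2_threshold = 0.1) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(densities), nrow(features) >= 3)
  x <- densities
  info <- data.frame(feature = colnames(features), model = "none",
                     r2 = NA_real_, controlled = FALSE,
                     stringsAsFactors = FALSE)
  out <- features
  for (j in seq_len(ncol(features))) {
    y <- features[, j]
    if (sd(y) == 0) next
    fit_lin <- lm(y ~ x)
    res_lin <- unname(residuals(fit_lin))
    r2_lin <- 1 - sum(res_lin^2) / sum((y - mean(y))^2)
    fit_exp <- tryCatch({
      c0 <- min(y) - 0.1 * sd(y)
      z <- pmax(y - c0, 1e-12)
      init <- lm(log(z) ~ x)
      nls(y ~ a * exp(b * x) + cc,
          start = list(a = exp(coef(init)[[1]]), b = coef(init)[[2]],
                       cc = c0),
          control = list(maxiter = 200, warnOnly = FALSE))
    }, error = function(e) NULL)
    if (is.null(fit_exp)) {
      ctx_log(sprintf("density_control: exponential fit failed for %s; using linear",
                      colnames(features)[j]), level = "debug")
      r2_exp <- -Inf
    } else {
      r2_exp <- 1 - sum(residuals(fit_exp)^2) / sum((y - mean(y))^2)
    }
    if (r2_exp > r2_lin) {
      info$model[j] <- "exponential"
      info$r2[j] <- r2_exp
      res <- unname(residuals(fit_exp))
    } else {
      info$model[j] <- "linear"
      info$r2[j] <- r2_lin
      res <- res_lin
    }
    if (info$r2[j] > r2_threshold) {
      out[, j] <- res
      info$controlled[j] <- TRUE
    }
  }
  attr(out, "density_control") <- info
  out
}

#' Metric multidimensional scaling of a distance matrix
#'
#' Classical-scaling initialization followed by SMACOF stress
#' majorization. Deterministic given the seed (the seed only matters for
#' the tiny jitter used when the classical solution is rank-deficient).
#'
#' @param dm a `distance_matrix` (or any symmetric dissimilarity matrix).
#' @param n_dims embedding dimension (default 2).
#' @param seed RNG seed.
#' @param max_iter,tol majorization iteration controls.
#' @return list with `coords` (species x n_dims matrix) and `stress`
#'   (Kruskal stress-1 of the final configuration).
#' @export
mds_embed <- function(dm, n_dims = 2, seed = 1, max_iter = 500, tol = 1e-10) {
  d <- as.matrix(dm)
  n <- nrow(d)
  set.seed(seed)
  x <- suppressWarnings(cmdscale(d, k = n_dims))
  if (ncol(x) < n_dims) {
    x <- cbind(x, matrix(rnorm(n * (n_dims - ncol(x)), sd = 1e-6),
                         n, n_dims - ncol(x)))
  }
  raw_stress <- function(x) {
    dd <- as.matrix(dist(x))
    sum((d[upper.tri(d)] - dd[upper.tri(dd)])^2)
  }
  s_old <- raw_stress(x)
  for (it in seq_len(max_iter)) {
    dd <- as.matrix(dist(x))
    b <- ifelse(dd > 0, -d / pmax(dd, 1e-300), 0)
    diag(b) <- 0
    diag(b) <- -rowSums(b)
    x <- b %*% x / n
    s_new <- raw_stress(x)
    if (s_old - s_new < tol * max(s_old, 1e-300)) break
    s_old <- s_new
  }
  stress1 <- sqrt(raw_stress(x) / sum(d[upper.tri(d)]^2))
  rownames(x) <- rownames(d)
  list(coords = x, stress = stress1)
}

#' Average-linkage hierarchical clustering of a distance matrix
#'
#' @param dm a `distance_matrix`.
#' @param linkage agglomeration method (default `"average"`).
#' @return an [stats::hclust] object (merge list with non-decreasing
#'   heights).
#' @export
hierarchical_cluster <- function(dm, linkage = "average") {
  hclust(stats::as.dist(as.matrix(dm)), method = linkage)
}
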