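#' @keywords internal
"_PACKAGE"

#' @importFrom stats cmdscale cor dist hclust lm median nls coef predict
#'   qt rbinom rlnorm rnorm runif sd t.test var wilcox.test setNames
#'   residuals as.dist
#' @importFrom utils read.table write.table
NULL

# package-level logging: level in c("debug", "info", "warning", "none")
.ctx_env <- new.env(parent = emptyenv())
.ctx_env$log_level <- "info"

.log_levels <- c(debug = 1L, info = 2L, warning = 3L, none = 4L)

#' Set the package log level
#'
#' Controls the verbosity of pipeline log messages (emitted via
#' [message()]).
#'
#' @param level one of `"debug"`, `"info"`, `"warning"`, `"none"`.
#' @return the previous level, invisibly.
#' @export
ctx_log_level <- function(level = c("info", "debug", "warning", "none")) {
  level <- match.arg(level)
  old <- .ctx_env$log_level
  .ctx_env$log_level <- level
  invisible(old)
}

ctx_log <- function(..., level = "info") {
  if (.log_levels[[level]] >= .log_levels[[.ctx_env$log_level]]) {
    message(sprintf("[connectax] %s", paste0(...)))
  }
  invisible(NULL)
}

#' Cosine distance between two numeric vectors
#'
#' One minus the cosine similarity, the dissimilarity used for both the
#' spectral and the topological comparison of connectomes.
#'
#' @param a,b numeric vectors of equal length.
#' @return a scalar; 0 for proportional vectors, up to 2 for anti-parallel
#'   ones (at most 1 when both vectors are nonnegative).
#' @export
cosine_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    stop("cosine_distance: zero vector")
  }
  1 - sum(a * b) / (na * nb)
}

# pairwise cosine-distance matrix between rows of x (no zero rows allowed)
cosine_distance_matrix <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) stop("cosine_distance_matrix: zero row")
  s <- tcrossprod(x / nrm)
  d <- 1 - s
  d[d < 0] <- 0  # numerical guard for identical rows
  diag(d) <- 0
  d
}

# derive a deterministic 31-bit substream seed from a master seed and a
# string tag (stable across platforms; simple polynomial rolling hash)
derive_seed <- function(master_seed, tag) {
  h <- as.double(master_seed %% 2147483647L)
  for (ch in utf8ToInt(tag)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# symmetric test helper used by validators
is_symmetric_tol <- function(m, tol) {
  max(abs(m - t(m))) <= tol
}
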