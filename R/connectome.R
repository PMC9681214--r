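# Connectome data model and file I/O.
#
# A connectome is one species/scan: a symmetric nonnegative weight matrix
# (streamline-count-like units, zero diagonal), the derived binary
# adjacency, a per-node hemisphere label and a 3-D centroid per node.

#' Construct a connectome object
#'
#' Validates and assembles the per-scan data structure used throughout the
#' pipeline. The binary adjacency is derived from the weights
#' (`adjacency[i,j] = 1` iff `weights[i,j] > 0`).
#'
#' @param weights square, symmetric, nonnegative numeric matrix with zero
#'   diagonal. Mild asymmetry (below `sym_tol` relative to the largest
#'   weight) is silently symmetrized as `(M + t(M))/2`; anything larger is
#'   treated as corruption and errors.
#' @param hemisphere character vector, one of `"L"`/`"R"` per node.
#' @param coords numeric matrix with one row per node and columns x, y, z.
#' @param species_id,sample_id identifier strings.
#' @param sym_tol relative symmetry tolerance.
#' @return an object of class `connectome` with elements `weights`,
#'   `adjacency`, `hemisphere`, `coords`, `species_id`, `sample_id`,
#'   `n_nodes`.
#' @export
connectome <- function(weights, hemisphere, coords,
                       species_id = "unknown", sample_id = species_id,
                       sym_tol = 1e-8) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop("connectome: weight matrix must be square")
  }
  n <- nrow(weights)
  if (any(weights < 0)) stop("connectome: negative weight")
  mx <- max(abs(weights))
  if (mx > 0 && !is_symmetric_tol(weights, sym_tol * mx)) {
    stop("connectome: asymmetry above tolerance")
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  dimnames(weights) <- NULL
  adjacency <- binarize(weights)
  deg <- rowSums(adjacency)
  if (any(deg < 1)) {
    stop(sprintf("connectome: %d isolated node(s) (degree 0)", sum(deg < 1)))
  }
  hemisphere <- as.character(hemisphere)
  if (length(hemisphere) != n || !all(hemisphere %in% c("L", "R"))) {
    stop("connectome: hemisphere must be length-n with values in {L, R}")
  }
  coords <- as.matrix(coords)
  if (nrow(coords) != n || ncol(coords) != 3 || any(!is.finite(coords))) {
    stop("connectome: coords must be a finite n x 3 matrix")
  }
  dimnames(coords) <- NULL
  structure(
    list(species_id = as.character(species_id),
         sample_id = as.character(sample_id),
         weights = weights, adjacency = adjacency,
         hemisphere = hemisphere, coords = coords, n_nodes = n),
    class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %s (sample %s): %d nodes, %d edges, density %.3f\n",
              x$species_id, x$sample_id, x$n_nodes,
              sum(x$adjacency) / 2, network_density(x$adjacency)))
  invisible(x)
}

#' Binarize a weight matrix
#'
#' Entry-wise indicator of `weight > 0`; keeps the matrix symmetric with a
#' zero diagonal. Idempotent.
#'
#' @param weights nonnegative numeric matrix.
#' @return a 0/1 matrix of the same dimension.
#' @export
binarize <- function(weights) {
  a <- (as.matrix(weights) > 0) * 1
  diag(a) <- 0
  a
}

#' Read a connectome from a matrix file plus node metadata
#'
#' The matrix file is comma-separated, no header, one row per node. The
#' metadata file is tab-separated with a header and columns
#' `node_id`, `hemisphere` (L/R), `x`, `y`, `z`; rows are matched to matrix
#' rows by file order (node_id strings are free-form).
#'
#' @param matrix_path path to the N x N CSV weight matrix.
#' @param metadata_path path to the node metadata TSV.
#' @param species_id,sample_id identifiers attached to the result.
#' @return a [connectome] object.
#' @export
read_connectome <- function(matrix_path, metadata_path,
                            species_id = "unknown", sample_id = species_id) {
  w <- as.matrix(read.table(matrix_path, sep = ",", header = FALSE))
  storage.mode(w) <- "double"
  meta <- read.table(metadata_path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
  req <- c("node_id", "hemisphere", "x", "y", "z")
  if (!all(req %in% names(meta))) {
    stop("read_connectome: metadata must have columns ",
         paste(req, collapse = ", "))
  }
  if (nrow(meta) != nrow(w)) {
    stop("read_connectome: metadata rows do not cover all matrix nodes")
  }
  connectome(w, meta$hemisphere, as.matrix(meta[, c("x", "y", "z")]),
             species_id = species_id, sample_id = sample_id)
}

#' Write a connectome to the package file formats
#'
#' Inverse of [read_connectome()]: writes the weight matrix as headerless
#' CSV and the node metadata as TSV. Full-precision (`%.17g`) so a
#' write/read round trip reproduces weights bitwise.
#'
#' @param x a [connectome].
#' @param matrix_path,metadata_path output paths.
#' @return invisibly, `x`.
#' @export
write_connectome <- function(x, matrix_path, metadata_path) {
  stopifnot(inherits(x, "connectome"))
  lines <- apply(x$weights, 1, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(lines, matrix_path)
  meta <- data.frame(node_id = paste0("n", seq_len(x$n_nodes) - 1L),
                     hemisphere = x$hemisphere,
                     x = sprintf("%.17g", x$coords[, 1]),
                     y = sprintf("%.17g", x$coords[, 2]),
                     z = sprintf("%.17g", x$coords[, 3]))
  write.table(meta, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(x)
}

#' Binary network density
#'
#' Fraction of node pairs that are connected: `2E / (N (N - 1))`.
#'
#' @param adjacency binary (or weight) matrix; nonzero entries count as
#'   edges.
#' @return a scalar in \[0, 1\].
#' @export
network_density <- function(adjacency) {
  a <- binarize(adjacency)
  n <- nrow(a)
  sum(a) / (n * (n - 1))
}
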