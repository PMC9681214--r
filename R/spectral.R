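# Normalized Laplacian eigenspectrum and the spectral distance.
#
# The spectrum of L = I - D^{-1} A lies in [0, 2] and is a
# permutation-invariant fingerprint of the binary topology. L itself is
# not symmetric, but it is similar (hence equal in spectrum) to the
# symmetric normalized Laplacian I - D^{-1/2} A D^{-1/2}, which is what
# the eigensolver is run on for numerical stability.

#' Normalized graph Laplacian
#'
#' `L = I - D^{-1} A`: 1 on the diagonal, `-1/deg(i)` where i and j are
#' connected, 0 elsewhere.
#'
#' @param adjacency binary adjacency matrix without isolated nodes.
#' @return the (asymmetric) normalized Laplacian matrix.
#' @export
normalized_laplacian <- function(adjacency) {
  a <- binarize(adjacency)
  deg <- rowSums(a)
  if (any(deg == 0)) stop("normalized_laplacian: isolated node (degree 0)")
  diag(nrow(a)) - a / deg
}

#' Laplacian eigenspectrum of a connectome
#'
#' Eigenvalues of the normalized Laplacian of the binarized connectome,
#' computed on the symmetric form `I - D^{-1/2} A D^{-1/2}` and returned
#' in ascending order. The multiplicity of eigenvalue 0 equals the number
#' of connected components.
#'
#' @param con a [connectome], or a bare adjacency/weight matrix (weights
#'   are binarized).
#' @return object of class `spectral_profile`: list with `eigenvalues`
#'   (ascending, all in \[0, 2\] up to 1e-9) and `smoothed` (`NULL` until
#'   [smooth_spectrum()] is applied).
#' @export
spectrum <- function(con) {
  a <- if (inherits(con, "connectome")) con$adjacency else binarize(con)
  deg <- rowSums(a)
  if (any(deg == 0)) stop("spectrum: isolated node (degree 0)")
  dis <- 1 / sqrt(deg)
  lsym <- diag(nrow(a)) - a * outer(dis, dis)
  ev <- sort(eigen(lsym, symmetric = TRUE, only.values = TRUE)$values)
  if (min(ev) < -1e-9 || max(ev) > 2 + 1e-9) {
    stop("spectrum: eigenvalues outside [0, 2] beyond tolerance")
  }
  structure(list(eigenvalues = ev, smoothed = NULL),
            class = "spectral_profile")
}

#' @export
print.spectral_profile <- function(x, ...) {
  cat(sprintf("<spectral_profile> %d eigenvalues in [%.3g, %.3g]%s\n",
              length(x$eigenvalues), min(x$eigenvalues), max(x$eigenvalues),
              if (is.null(x$smoothed)) "" else
                sprintf(", smoothed on %d grid points", length(x$smoothed$grid))))
  invisible(x)
}

#' Gaussian-smoothed eigenvalue density
#'
#' Convolves the eigenvalue frequencies with a Gaussian kernel of width
#' `sigma`, evaluated on the half-open grid `[0, 2)` with the given step
#' (2000 points at the defaults), and renormalizes so the trapezoid area
#' under the curve is 1.
#'
#' @param profile a `spectral_profile` from [spectrum()].
#' @param sigma kernel standard deviation (default 0.015).
#' @param step grid step on \[0, 2) (default 0.001).
#' @return the profile with its `smoothed` field set: list with `grid`,
#'   `density`, `sigma`.
#' @export
smooth_spectrum <- function(profile, sigma = 0.015, step = 0.001) {
  stopifnot(inherits(profile, "spectral_profile"))
  if (sigma <= 0) stop("smooth_spectrum: sigma must be positive")
  if (step <= 0) stop("smooth_spectrum: step must be positive")
  grid <- seq(0, 2 - step, by = step)
  lam <- profile$eigenvalues
  dens <- vapply(grid, function(x) {
    sum(exp(-(x - lam)^2 / (2 * sigma^2))) / sqrt(2 * pi * sigma^2)
  }, 0)
  area <- sum((dens[-1] + dens[-length(dens)]) / 2) * step
  profile$smoothed <- list(grid = grid, density = dens / area, sigma = sigma)
  profile
}

#' Spectral distance between two connectomes
#'
#' One minus the cosine similarity of the two Laplacian eigenvalue
#' vectors (ascending eigenvalues by default; the Gaussian-smoothed
#' densities when `use_smoothed = TRUE`). Symmetric, nonnegative, 0 for
#' identical spectra; not a metric (no triangle inequality).
#'
#' @param a,b `spectral_profile` objects of equal length (same
#'   parcellation size; same grid when smoothed).
#' @param use_smoothed compare smoothed densities instead of raw
#'   eigenvalues.
#' @return scalar in \[0, 1\].
#' @export
spectral_distance <- function(a, b, use_smoothed = FALSE) {
  stopifnot(inherits(a, "spectral_profile"), inherits(b, "spectral_profile"))
  if (use_smoothed) {
    if (is.null(a$smoothed) || is.null(b$smoothed)) {
      stop("spectral_distance: profiles lack smoothed densities")
    }
    if (length(a$smoothed$density) != length(b$smoothed$density)) {
      stop("spectral_distance: smoothed grids differ")
    }
    cosine_distance(a$smoothed$density, b$smoothed$density)
  } else {
    if (length(a$eigenvalues) != length(b$eigenvalues)) {
      stop("spectral_distance: eigenvalue vectors differ in length")
    }
    cosine_distance(a$eigenvalues, b$eigenvalues)
  }
}
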