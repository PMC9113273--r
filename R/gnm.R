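#' Gaussian network model Kirchhoff (connectivity) matrix
#'
#' Builds the N x N Kirchhoff matrix of the coarse-grained GNM: residues i
#' and j are connected by a spring of force constant \code{gamma} when their
#' C-alpha distance is at most \code{cutoff} (inclusive boundary).
#' Off-diagonal entries are \code{-gamma} for connected pairs and 0
#' otherwise; diagonal entries are minus the row sums, i.e. gamma times the
#' contact degree.
#'
#' @param model A \code{"calpha_model"} with at least 2 residues.
#' @param cutoff Contact cutoff in Angstrom (default 7.0).
#' @param gamma Spring force constant (default 1.0).
#' @return N x N symmetric matrix with attributes \code{cutoff} and
#'   \code{gamma}.
#' @examples
#' m <- make_path_chain(3, spacing = 6)$model
#' kirchhoff(m)   # path-graph Laplacian
#' @export
kirchhoff <- function(model, cutoff = 7, gamma = 1) {
  stopifnot(inherits(model, "calpha_model"), cutoff > 0, gamma > 0)
  n <- n_residues(model)
  if (n < 2) stop("need at least 2 residues", call. = FALSE)
  d <- as.matrix(stats::dist(model$xyz))
  k <- -gamma * (d <= cutoff)
  diag(k) <- 0
  diag(k) <- -rowSums(k)
  dimnames(k) <- NULL
  attr(k, "cutoff") <- cutoff
  attr(k, "gamma") <- gamma
  k
}

#' Mode-truncated pseudoinverse of the Kirchhoff matrix
#'
#' Eigendecomposes the Kirchhoff matrix and forms its pseudoinverse from all
#' modes except the single zero mode, which corresponds to rigid-body
#' translation of the whole network.  The diagonal of the result is the
#' mean-square fluctuation profile of the residues (up to kT/gamma).
#'
#' A connected contact network has exactly one (numerically) zero
#' eigenvalue.  If more than one eigenvalue falls below the tolerance the
#' network is disconnected and the function stops, reporting the component
#' count, rather than silently dropping modes.
#'
#' @param k Kirchhoff matrix from \code{\link{kirchhoff}} (or any symmetric
#'   graph Laplacian).
#' @param zero_mode_tol Relative tolerance for zero eigenvalues, as a
#'   fraction of the largest eigenvalue (default 1e-8).
#' @return An object of class \code{"gnm_modes"}: list with \code{matrix}
#'   (the pseudoinverse), \code{eigenvalues} (all N, ascending),
#'   \code{eigenvectors} (matching columns, sign-fixed so the
#'   largest-magnitude component of each is positive) and
#'   \code{n_excluded_modes} (always 1).
#' @export
gnm_pseudoinverse <- function(k, zero_mode_tol = 1e-8) {
  stopifnot(is.matrix(k), nrow(k) == ncol(k))
  e <- eigen(k, symmetric = TRUE)
  ord <- rev(seq_along(e$values))           # ascending
  lambda <- e$values[ord]
  u <- e$vectors[, ord, drop = FALSE]
  # deterministic eigenvector sign: largest-magnitude component positive
  for (j in seq_len(ncol(u))) {
    i <- which.max(abs(u[, j]))
    if (u[i, j] < 0) u[, j] <- -u[, j]
  }
  lam_max <- max(abs(lambda))
  if (lam_max == 0)
    stop("disconnected contact network: ", length(lambda),
         " connected components; increase the cutoff or analyse components ",
         "separately", call. = FALSE)
  n_zero <- sum(abs(lambda) < zero_mode_tol * lam_max)
  if (n_zero > 1)
    stop("disconnected contact network: ", n_zero, " connected components; ",
         "increase the cutoff or analyse components separately",
         call. = FALSE)
  inv <- u[, -1, drop = FALSE] %*% (t(u[, -1, drop = FALSE]) / lambda[-1])
  inv <- (inv + t(inv)) / 2
  structure(list(matrix = inv, eigenvalues = lambda, eigenvectors = u,
                 n_excluded_modes = 1L),
            class = "gnm_modes")
}

#' @export
print.gnm_modes <- function(x, ...) {
  n <- nrow(x$matrix)
  cat("GNM mode decomposition: ", n, " residues, ", x$n_excluded_modes,
      " rigid-body mode excluded\n", sep = "")
  cat("slowest internal eigenvalues:",
      paste(signif(x$eigenvalues[2:min(6, n)], 4), collapse = " "), "\n")
  invisible(x)
}

#' Residue cross-correlation matrix
#'
#' Normalises the GNM pseudoinverse to the matrix of residue motion
#' cross-correlations, C_ij = G_ij / sqrt(G_ii G_jj) where G is the
#' pseudoinverse of the Kirchhoff matrix.  Entries are 1 for perfectly
#' correlated residue pairs and -1 for perfectly anticorrelated ones.
#'
#' @param cov A \code{"gnm_modes"} object, or the pseudoinverse matrix
#'   itself.
#' @return N x N symmetric correlation matrix with unit diagonal.
#' @export
cross_correlation <- function(cov) {
  m <- if (inherits(cov, "gnm_modes")) cov$matrix else cov
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  d <- diag(m)
  if (any(d <= 0))
    stop("numerical degeneracy: nonpositive mean-square fluctuation on the ",
         "diagonal", call. = FALSE)
  cc <- m / sqrt(outer(d, d))
  diag(cc) <- 1
  cc
}

#' Euclidean dynamic distance matrix
#'
#' Maps cross-correlations to distances via D_ij = sqrt(2 (1 - C_ij)):
#' perfectly correlated residues are at dynamic distance 0 and perfectly
#' anticorrelated ones at 2.  C is clipped to [-1, 1] first to absorb
#' rounding.  Because C is positive semidefinite, D is a Euclidean
#' embeddable metric, which is what licenses Ward clustering on it.
#'
#' @param c Cross-correlation matrix from \code{\link{cross_correlation}}.
#' @return N x N symmetric matrix with zero diagonal, entries in [0, 2].
#' @export
dynamic_distance <- function(c) {
  stopifnot(is.matrix(c), nrow(c) == ncol(c))
  cc <- pmin(pmax(c, -1), 1)
  d <- sqrt(2 * (1 - cc))
  diag(d) <- 0
  d
}
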