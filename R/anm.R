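#' Anisotropic network model Hessian
#'
#' Builds the 3N x 3N second-derivative matrix of the pairwise harmonic ANM
#' potential at the equilibrium structure.  For each connected pair (i, j)
#' (C-alpha distance at most \code{cutoff}) the off-diagonal 3 x 3
#' super-element is \code{-gamma * r r' / |r|^2} with r the equilibrium
#' inter-residue vector; diagonal super-elements are minus the sum of the
#' off-diagonal blocks in their row, so every 3-row band sums to zero
#' (translation invariance).
#'
#' @param model A \code{"calpha_model"} with at least 3 residues.
#' @param cutoff Contact cutoff in Angstrom (default 15.0).
#' @param gamma Spring force constant (default 1.0).
#' @return 3N x 3N symmetric matrix with attributes \code{cutoff},
#'   \code{gamma}.
#' @export
anm_hessian <- function(model, cutoff = 15, gamma = 1) {
  stopifnot(inherits(model, "calpha_model"), cutoff > 0)
  n <- n_residues(model)
  if (n < 3) stop("need at least 3 residues", call. = FALSE)
  xyz <- model$xyz
  d <- as.matrix(stats::dist(xyz))
  h <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] > cutoff) next
      if (d[i, j] == 0)
        stop("singular geometry: residues ", i, " and ", j,
             " are coincident", call. = FALSE)
      r <- xyz[j, ] - xyz[i, ]
      blk <- -gamma * tcrossprod(r) / sum(r^2)
      ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
      h[ii, jj] <- blk
      h[jj, ii] <- blk
      h[ii, ii] <- h[ii, ii] - blk
      h[jj, jj] <- h[jj, jj] - blk
    }
  }
  attr(h, "cutoff") <- cutoff
  attr(h, "gamma") <- gamma
  h
}

#' Internal normal modes of the ANM Hessian
#'
#' Eigendecomposes the Hessian and discards the six zero-eigenvalue modes
#' (rigid-body translations and rotations), keeping the 3N - 6 internal
#' modes in ascending eigenvalue order.  A connected, geometrically
#' non-degenerate structure has exactly six near-zero eigenvalues; any other
#' count indicates a disconnected network or collinear geometry and is an
#' error.
#'
#' @param h Hessian from \code{\link{anm_hessian}}.
#' @param zero_mode_tol Relative zero tolerance as a fraction of the largest
#'   eigenvalue (default 1e-8).
#' @return An object of class \code{"anm_modes"}: list with
#'   \code{eigenvalues} (internal, ascending), \code{vectors} (3N x (3N-6),
#'   unit columns) and \code{n_removed} (6).
#' @export
anm_modes <- function(h, zero_mode_tol = 1e-8) {
  stopifnot(is.matrix(h), nrow(h) == ncol(h))
  e <- eigen(h, symmetric = TRUE)
  ord <- rev(seq_along(e$values))
  lambda <- e$values[ord]
  v <- e$vectors[, ord, drop = FALSE]
  tol <- zero_mode_tol * max(abs(lambda))
  n_zero <- sum(abs(lambda) < tol)
  if (n_zero != 6)
    stop("degenerate geometry: found ", n_zero,
         " near-zero modes (expected 6); the contact network may be ",
         "disconnected or collinear", call. = FALSE)
  keep <- seq.int(7, length(lambda))
  for (j in keep) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  structure(list(eigenvalues = lambda[keep],
                 vectors = v[, keep, drop = FALSE],
                 n_removed = 6L),
            class = "anm_modes")
}

#' @export
print.anm_modes <- function(x, ...) {
  cat("ANM mode set: ", length(x$eigenvalues), " internal modes (",
      x$n_removed, " rigid-body modes removed)\n", sep = "")
  cat("slowest eigenvalues:",
      paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = " "), "\n")
  invisible(x)
}

#' Mode-displaced conformer trajectory
#'
#' Displaces the structure along one internal ANM eigenvector,
#' \code{R' = R + s v}, over a symmetric sweep of the amplification
#' parameter s in \code{[-s_max, +s_max]}.  The middle frame (s = 0) is the
#' input structure, bit for bit.  Mode indexing is 1-based over internal
#' modes: mode 1 is the lowest-frequency internal motion.
#'
#' @param model A \code{"calpha_model"}.
#' @param modes An \code{"anm_modes"} object for the same model.
#' @param mode Internal mode index (1-based).
#' @param s_max Maximum amplitude; \code{NULL} (default) picks s_max so the
#'   largest per-residue displacement at the sweep extreme is 2 Angstrom.
#' @param n_frames Odd number of frames >= 3, so that s = 0 is included
#'   (default 11).
#' @return An object of class \code{"motion_trajectory"}: list with
#'   \code{mode_index}, \code{amplitudes} and \code{frames} (list of N x 3
#'   matrices).
#' @export
anm_trajectory <- function(model, modes, mode = 1, s_max = NULL,
                           n_frames = 11) {
  stopifnot(inherits(model, "calpha_model"), inherits(modes, "anm_modes"))
  n <- n_residues(model)
  if (length(mode) != 1 || mode < 1 || mode > ncol(modes$vectors))
    stop("invalid mode index ", mode, ": have ", ncol(modes$vectors),
         " internal modes", call. = FALSE)
  if (nrow(modes$vectors) != 3 * n)
    stop("mode set does not match model size", call. = FALSE)
  if (n_frames < 3 || n_frames %% 2 == 0)
    stop("n_frames must be an odd number >= 3", call. = FALSE)
  v <- matrix(modes$vectors[, mode], ncol = 3, byrow = TRUE)
  if (is.null(s_max)) {
    per_res <- sqrt(rowSums(v^2))
    s_max <- 2 / max(per_res)
  }
  if (s_max <= 0) stop("s_max must be positive", call. = FALSE)
  s <- seq(-s_max, s_max, length.out = n_frames)
  frames <- lapply(s, function(si) model$xyz + si * v)
  frames[[(n_frames + 1) / 2]] <- model$xyz   # exact s = 0 frame
  structure(list(mode_index = mode, amplitudes = s, frames = frames),
            class = "motion_trajectory")
}

#' @export
print.motion_trajectory <- function(x, ...) {
  cat("ANM motion trajectory: mode ", x$mode_index, ", ",
      length(x$frames), " frames, |s| <= ",
      format(max(abs(x$amplitudes)), digits = 4), "\n", sep = "")
  invisible(x)
}
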