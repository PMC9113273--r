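# Deterministic structure generators with known network algebra and planted
# community structure, so the whole pipeline is testable without any
# deposited structure.

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister")
  code
}

synthetic_model <- function(xyz, source) {
  n <- nrow(xyz)
  new_calpha_model(
    residues = data.frame(chain = rep("A", n), resno = seq_len(n),
                          insert = rep("", n), resid = rep("ALA", n),
                          stringsAsFactors = FALSE),
    xyz = xyz, source = source)
}

#' Collinear C-alpha chain (analytic GNM fixture)
#'
#' Places n C-alpha atoms on a line at multiples of \code{spacing}.  With
#' spacing in (cutoff/2, cutoff] the GNM contact graph is the path graph,
#' whose Laplacian has a closed-form pseudoinverse — an analytic oracle for
#' the whole GNM algebra.
#'
#' @param n Number of residues (>= 2).
#' @param spacing Inter-residue spacing in Angstrom.
#' @return An object of class \code{"synthetic_structure"}: list with
#'   \code{model} (a \code{"calpha_model"}), \code{true_labels}
#'   (\code{NULL} here) and \code{seed} (\code{NA}).
#' @examples
#' kirchhoff(make_path_chain(3, 6)$model)
#' @export
make_path_chain <- function(n, spacing = 6) {
  stopifnot(n >= 2, spacing > 0)
  xyz <- cbind((seq_len(n) - 1) * spacing, 0, 0)
  structure(list(model = synthetic_model(xyz, "path_chain"),
                 true_labels = NULL, seed = NA_integer_),
            class = "synthetic_structure")
}

#' Two-domain dumbbell with planted community structure
#'
#' Builds two compact cubic-lattice blobs of C-alpha atoms (lattice constant
#' 4 Angstrom, so each blob is internally connected at the default 7
#' Angstrom GNM cutoff) joined by a 2-residue linker, with the blob faces
#' separated by \code{gap} so the only inter-domain contacts run through the
#' linker.  Coordinates are perturbed by uniform jitter from R's
#' Mersenne-Twister generator under the given seed, so fixtures reproduce
#' across platforms.
#'
#' Residue order is domain 1, linker, domain 2.  \code{true_labels} assigns
#' domain 1 and the first linker residue to community 1 and the rest to
#' community 2; the \code{linker} element records the two linker indices,
#' whose assignment is genuinely ambiguous (they sit on the hinge).
#'
#' @param n1,n2 Residues per domain (>= 5).
#' @param gap Face-to-face separation in Angstrom; must exceed the GNM
#'   cutoff you intend to use so that inter-domain contacts are sparse.
#' @param jitter Uniform jitter half-width in Angstrom (0 = exact lattice).
#' @param seed Integer seed for the jitter.
#' @return A \code{"synthetic_structure"} (see \code{\link{make_path_chain}})
#'   with \code{true_labels} and an extra \code{linker} element.
#' @export
make_two_domain <- function(n1 = 20, n2 = 20, gap = 12, jitter = 0.5,
                            seed = 1) {
  stopifnot(n1 >= 5, n2 >= 5, gap > 0, jitter >= 0)
  a <- 4                                  # lattice constant, Angstrom
  blob <- function(n) {
    side <- ceiling(n^(1 / 3))
    g <- expand.grid(x = 0:(side - 1), y = 0:(side - 1), z = 0:(side - 1))
    as.matrix(g[order(g$x, g$y, g$z)[seq_len(n)], c("x", "y", "z")]) * a
  }
  b1 <- blob(n1)
  b2 <- blob(n2)
  x_off <- max(b1[, 1]) + gap
  b2[, 1] <- b2[, 1] + x_off
  # 2-residue linker bridging the gap at thirds, on the lattice face line
  link <- rbind(c(max(b1[, 1]) + gap / 3, 0, 0),
                c(max(b1[, 1]) + 2 * gap / 3, 0, 0))
  xyz <- rbind(b1, link, b2)
  if (jitter > 0)
    xyz <- local_seed(seed,
      xyz + matrix(stats::runif(length(xyz), -jitter, jitter), ncol = 3))
  dimnames(xyz) <- NULL
  labels <- c(rep(1L, n1), 1L, 2L, rep(2L, n2))
  structure(list(model = synthetic_model(xyz, "two_domain"),
                 true_labels = labels, seed = as.integer(seed),
                 linker = c(n1 + 1L, n1 + 2L)),
            class = "synthetic_structure")
}

#' Block-constant correlation matrix (planted-partition fixture)
#'
#' Builds a correlation matrix with unit diagonal, \code{c_within} inside
#' each block and \code{c_between} across blocks, bypassing the network
#' model entirely so the clustering stage can be tested in isolation.  The
#' result must be a valid correlation matrix: \code{c_within > c_between}
#' and positive semidefinite (checked by eigendecomposition).
#'
#' @param sizes Integer vector of block sizes.
#' @param c_within,c_between Within- and between-block correlations.
#' @return N x N correlation matrix with attribute \code{block_labels}.
#' @export
make_block_correlation <- function(sizes, c_within = 0.9, c_between = -0.2) {
  stopifnot(length(sizes) >= 1, all(sizes >= 1))
  if (c_within <= c_between)
    stop("c_within must exceed c_between", call. = FALSE)
  labels <- rep(seq_along(sizes), sizes)
  same <- outer(labels, labels, "==")
  cc <- ifelse(same, c_within, c_between)
  diag(cc) <- 1
  ev <- eigen(cc, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("requested block correlations are not positive semidefinite ",
         "(min eigenvalue ", format(min(ev), digits = 3), ")", call. = FALSE)
  attr(cc, "block_labels") <- labels
  cc
}

#' @export
print.synthetic_structure <- function(x, ...) {
  cat("Synthetic structure '", x$model$source, "': ",
      n_residues(x$model), " residues",
      if (!is.null(x$true_labels))
        paste0(", ", max(x$true_labels), " planted communities"),
      "\n", sep = "")
  invisible(x)
}
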