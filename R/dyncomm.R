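#' Fit the dynamic community decomposition of a protein structure
#'
#' The main entry point of the package.  Runs the full pipeline on a
#' C-alpha model: GNM Kirchhoff matrix at the given contact cutoff,
#' mode-truncated pseudoinverse, residue cross-correlations, Euclidean
#' dynamic distance matrix, Ward clustering, and Calinski-Harabasz
#' selection of the number of communities over \code{k_min..k_max}.
#'
#' The defaults (7 Angstrom GNM cutoff, unit spring constant, k swept from
#' 2 to 20, all HETATM records excluded) are the standard operating point
#' for coarse-grained GNM community analysis.  \code{k_max} is clamped to
#' N - 1 for small structures, since the selection score is undefined at
#' k = N.
#'
#' @param structure Path to a PDB file, PDB text, a \code{"calpha_model"},
#'   or a \code{"synthetic_structure"}.
#' @param chains Optional chain selection (see \code{\link{read_calpha}}).
#' @param hetatm,het_include HETATM policy (see \code{\link{read_calpha}}).
#' @param cutoff GNM contact cutoff in Angstrom (default 7).
#' @param gamma Spring force constant (default 1).
#' @param k_min,k_max Community-count sweep range (defaults 2 and 20).
#' @param feature_mode Feature representation for Ward clustering and CH
#'   scoring: \code{"rows"} (rows of the dynamic distance matrix, default)
#'   or \code{"lw"} (Lance-Williams on the distances directly); see
#'   \code{\link{ward_tree}}.
#' @param zero_mode_tol Relative zero-eigenvalue tolerance for the GNM
#'   pseudoinverse.
#' @return An object of class \code{"dyncomm"}: list with \code{model},
#'   \code{gnm} (the \code{"gnm_modes"} decomposition), \code{correlation},
#'   \code{distance}, \code{sweep} (a \code{"community_sweep"}),
#'   \code{membership} (per-residue labels at the optimal k),
#'   \code{optimal_k}, \code{parameters} and \code{call}.
#' @examples
#' fit <- dyncomm(make_two_domain(n1 = 12, n2 = 12, seed = 1), k_max = 6)
#' fit$optimal_k
#' summary(fit)
#' @seealso \code{\link{select_communities}}, \code{\link{anm_modes}},
#'   \code{\link{write_labeled_pdb}}
#' @export
dyncomm <- function(structure, chains = NULL,
                    hetatm = c("exclude", "include"),
                    het_include = character(),
                    cutoff = 7, gamma = 1, k_min = 2, k_max = 20,
                    feature_mode = c("rows", "lw"),
                    zero_mode_tol = 1e-8) {
  feature_mode <- match.arg(feature_mode)
  hetatm <- match.arg(hetatm)
  model <- if (inherits(structure, "synthetic_structure")) structure$model
    else if (inherits(structure, "calpha_model")) structure
    else read_calpha(structure, chains = chains, hetatm = hetatm,
                     het_include = het_include)
  n <- n_residues(model)
  k_max_eff <- min(k_max, n - 1)
  if (k_max_eff < k_min)
    stop("structure too small for the requested sweep (N = ", n, ")",
         call. = FALSE)

  k <- kirchhoff(model, cutoff = cutoff, gamma = gamma)
  modes <- gnm_pseudoinverse(k, zero_mode_tol = zero_mode_tol)
  cc <- cross_correlation(modes)
  d <- dynamic_distance(cc)
  sweep <- select_communities(d, k_min = k_min, k_max = k_max_eff,
                              feature_mode = feature_mode)

  structure(list(model = model, gnm = modes, correlation = cc, distance = d,
                 sweep = sweep, membership = sweep$membership,
                 optimal_k = sweep$optimal_k,
                 parameters = list(cutoff = cutoff, gamma = gamma,
                                   k_min = k_min, k_max = k_max_eff,
                                   feature_mode = feature_mode,
                                   hetatm = hetatm, chains = chains),
                 call = match.call()),
            class = "dyncomm")
}

#' Extract community assignments from a fit
#'
#' @param fit A \code{"dyncomm"} object.
#' @param k Number of communities; defaults to the CH-optimal k.  Any k in
#'   1..N is available via the stored Ward tree.
#' @return Data frame with columns \code{chain}, \code{resnum},
#'   \code{icode}, \code{community}.
#' @export
community_assignments <- function(fit, k = NULL) {
  stopifnot(inherits(fit, "dyncomm"))
  labels <- if (is.null(k)) fit$membership
    else cut_communities(fit$sweep$tree, k)
  data.frame(chain = fit$model$residues$chain,
             resnum = fit$model$residues$resno,
             icode = fit$model$residues$insert,
             community = as.integer(labels),
             stringsAsFactors = FALSE)
}

#' @export
print.dyncomm <- function(x, ...) {
  cat("Dynamic community decomposition of '", x$model$source, "'\n",
      sep = "")
  cat("  ", n_residues(x$model), " residues; GNM cutoff ",
      x$parameters$cutoff, " A, gamma ", x$parameters$gamma, "\n", sep = "")
  cat("  optimal communities: k = ", x$optimal_k, "  (CH = ",
      format(x$sweep$ch_by_k[[as.character(x$optimal_k)]], digits = 6),
      ")\n", sep = "")
  invisible(x)
}

#' @export
summary.dyncomm <- function(object, ...) {
  sizes <- table(object$membership)
  out <- list(n = n_residues(object$model),
              parameters = object$parameters,
              optimal_k = object$optimal_k,
              community_sizes = sizes,
              ch_by_k = object$sweep$ch_by_k,
              ranked_peaks = object$sweep$ranked_peaks,
              mean_square_fluctuation = diag(object$gnm$matrix))
  class(out) <- "summary.dyncomm"
  out
}

#' @export
print.summary.dyncomm <- function(x, ...) {
  cat("Dynamic communities: N =", x$n, "residues, optimal k =",
      x$optimal_k, "\n")
  cat("community sizes:", paste(as.integer(x$community_sizes),
                                collapse = " "), "\n")
  cat("CH curve (k: score):\n")
  print(round(x$ch_by_k, 2))
  cat("top CH peaks:\n")
  print(utils::head(x$ranked_peaks, 5))
  invisible(x)
}

#' Plot the CH-vs-k model selection curve
#'
#' @param x A \code{"dyncomm"} object.
#' @param ... Passed to \code{\link[graphics]{plot}}.
#' @export
plot.dyncomm <- function(x, ...) {
  ks <- as.integer(names(x$sweep$ch_by_k))
  ch <- unname(x$sweep$ch_by_k)
  graphics::plot(ks, ch, type = "b", xlab = "number of communities k",
                 ylab = "Calinski-Harabasz score", ...)
  graphics::abline(v = x$optimal_k, lty = 2)
  graphics::points(x$optimal_k, x$sweep$ch_by_k[[as.character(x$optimal_k)]],
                   pch = 19)
  invisible(x)
}

#' JSON-ready report of a community fit
#'
#' Collects the parameters, CH curve, optimal k and ranked alternative
#' arrangements of a fit into a list that serialises to the package's
#' versioned JSON report schema.
#'
#' @param fit A \code{"dyncomm"} object.
#' @return A list; write it with \code{jsonlite::write_json(report, path,
#'   auto_unbox = TRUE, digits = NA)}.
#' @export
community_report <- function(fit) {
  stopifnot(inherits(fit, "dyncomm"))
  list(schema_version = 1L,
       structure = fit$model$source,
       n_residues = n_residues(fit$model),
       parameters = fit$parameters,
       optimal_k = fit$optimal_k,
       ch_by_k = as.list(fit$sweep$ch_by_k),
       ranked_peaks = fit$sweep$ranked_peaks,
       community_sizes = as.integer(table(fit$membership)))
}
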