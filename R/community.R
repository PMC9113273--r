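#' Ward tree over the dynamic distance matrix
#'
#' Agglomerative hierarchical clustering with the Ward minimum-variance
#' criterion.  Two representations of the dynamic distance matrix D are
#' supported:
#' \describe{
#'   \item{\code{"rows"}}{(default) residue i is represented by row i of D
#'     as a feature vector and Ward merging is applied to the Euclidean
#'     distances between those vectors.  This mirrors toolchains whose Ward
#'     implementation accepts only feature vectors.}
#'   \item{\code{"lw"}}{the Ward (Lance-Williams) recurrence is applied
#'     directly to D as pairwise distances.}
#' }
#'
#' @param d Dynamic distance matrix from \code{\link{dynamic_distance}}.
#' @param feature_mode \code{"rows"} or \code{"lw"}; see Details.
#' @return An \code{\link[stats]{hclust}} tree with an added
#'   \code{feature_mode} attribute.
#' @export
ward_tree <- function(d, feature_mode = c("rows", "lw")) {
  feature_mode <- match.arg(feature_mode)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (nrow(d) < 2) stop("need at least 2 residues to cluster", call. = FALSE)
  dd <- switch(feature_mode,
               rows = stats::dist(d),
               lw = stats::as.dist(d))
  tree <- stats::hclust(dd, method = "ward.D2")
  attr(tree, "feature_mode") <- feature_mode
  tree
}

#' Cut a Ward tree into k communities
#'
#' @param tree An \code{hclust} tree from \code{\link{ward_tree}}.
#' @param k Number of communities, between 1 and N.
#' @return Integer vector of labels in 1..k, renumbered by order of first
#'   residue occurrence.
#' @export
cut_communities <- function(tree, k) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  if (length(k) != 1 || k < 1 || k > n)
    stop("k must be between 1 and ", n, call. = FALSE)
  labs <- stats::cutree(tree, k = k)
  match(labs, unique(labs))
}

#' Calinski-Harabasz score of a labeling
#'
#' Ratio of between-cluster to within-cluster dispersion, each normalised by
#' its degrees of freedom: \code{[tr(B)/(k-1)] / [tr(W)/(N-k)]}, with B and W
#' measured about cluster centroids of the feature vectors.  Larger is
#' better; the score is used to select the number of dynamic communities.
#'
#' Degenerate cases follow sentinel conventions so that sweeps over k never
#' abort: zero total dispersion (all points identical) scores 0, and zero
#' within-cluster dispersion with positive between-cluster dispersion
#' ("perfect separation") scores the largest finite double.
#'
#' @param features N x M numeric matrix of feature vectors (rows of the
#'   dynamic distance matrix in the default pipeline).
#' @param labels Cluster labels of length N with k distinct values,
#'   2 <= k <= N-1, no empty cluster.
#' @return The CH score (single number).
#' @export
ch_score <- function(features, labels) {
  stopifnot(is.matrix(features) || is.data.frame(features))
  features <- as.matrix(features)
  n <- nrow(features)
  if (length(labels) != n) stop("labels length mismatch", call. = FALSE)
  labels <- match(labels, unique(labels))
  k <- max(labels)
  if (k < 2 || k > n - 1)
    stop("CH score is undefined for k = ", k, " with N = ", n, call. = FALSE)

  grand <- colMeans(features)
  w <- 0; b <- 0
  for (g in seq_len(k)) {
    xg <- features[labels == g, , drop = FALSE]
    mu <- colMeans(xg)
    w <- w + sum(sweep(xg, 2, mu)^2)
    b <- b + nrow(xg) * sum((mu - grand)^2)
  }
  if (b + w <= 0) return(0)
  if (w == 0) return(.Machine$double.xmax)
  (b / (k - 1)) / (w / (n - k))
}

#' Sweep community counts and select the best by CH score
#'
#' Cuts the Ward tree of the dynamic distance matrix at every k in
#' \code{[k_min, k_max]}, scores each partition with the Calinski-Harabasz
#' index (on the same feature representation used for clustering), and
#' selects the k with the highest score (ties broken towards fewer
#' communities).  Alternative arrangements are reported two ways: all k
#' ranked by CH, and the strict local maxima of the CH-vs-k curve
#' (endpoints included), supporting "second-best" readings of the curve.
#'
#' @param d Dynamic distance matrix.
#' @param k_min,k_max Sweep range (defaults 2 and 20); requires
#'   \code{2 <= k_min <= k_max <= N - 1}.
#' @param feature_mode Passed to \code{\link{ward_tree}}.
#' @return An object of class \code{"community_sweep"}: list with
#'   \code{labels_by_k} (named list of labelings), \code{ch_by_k} (named
#'   numeric), \code{optimal_k}, \code{membership} (labels at
#'   \code{optimal_k}), \code{ranked_all} and \code{ranked_peaks} (data
#'   frames with columns \code{k}, \code{ch}, CH-descending), \code{tree}
#'   and \code{feature_mode}.
#' @export
select_communities <- function(d, k_min = 2, k_max = 20,
                               feature_mode = c("rows", "lw")) {
  feature_mode <- match.arg(feature_mode)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (!(2 <= k_min && k_min <= k_max)) stop("need 2 <= k_min <= k_max",
                                            call. = FALSE)
  if (k_max > n - 1)
    stop("k_max must be at most N - 1 = ", n - 1, call. = FALSE)

  tree <- ward_tree(d, feature_mode)
  ks <- k_min:k_max
  labels_by_k <- lapply(ks, function(k) cut_communities(tree, k))
  names(labels_by_k) <- ks
  ch <- vapply(labels_by_k, function(l) ch_score(d, l), numeric(1))
  names(ch) <- ks

  opt <- ks[which.max(ch)]          # which.max: first maximum -> smallest k

  ranked_all <- data.frame(k = ks, ch = unname(ch))
  ranked_all <- ranked_all[order(-ranked_all$ch, ranked_all$k), ]
  rownames(ranked_all) <- NULL

  is_peak <- vapply(seq_along(ks), function(i) {
    left <- if (i == 1) TRUE else ch[i] > ch[i - 1]
    right <- if (i == length(ks)) TRUE else ch[i] > ch[i + 1]
    left && right
  }, logical(1))
  peaks <- data.frame(k = ks[is_peak], ch = unname(ch[is_peak]))
  peaks <- peaks[order(-peaks$ch, peaks$k), ]
  rownames(peaks) <- NULL

  structure(list(labels_by_k = labels_by_k, ch_by_k = ch, optimal_k = opt,
                 membership = labels_by_k[[as.character(opt)]],
                 ranked_all = ranked_all, ranked_peaks = peaks,
                 tree = tree, feature_mode = feature_mode),
            class = "community_sweep")
}

#' @export
print.community_sweep <- function(x, ...) {
  cat("Community sweep over k = ", names(x$ch_by_k)[1], "..",
      names(x$ch_by_k)[length(x$ch_by_k)], " (feature mode: ",
      x$feature_mode, ")\n", sep = "")
  cat("optimal k =", x$optimal_k, " (CH =",
      format(x$ch_by_k[[as.character(x$optimal_k)]], digits = 6), ")\n")
  top <- utils::head(x$ranked_peaks, 3)
  cat("CH peaks:", paste(sprintf("k=%d (%.4g)", top$k, top$ch),
                         collapse = ", "), "\n")
  invisible(x)
}
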