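#' Read a domain annotation table
#'
#' Reads a TSV with columns \code{domain_name}, \code{chain},
#' \code{start_resnum}, \code{end_resnum} (multiple rows per domain are
#' allowed and are unioned).
#'
#' @param file Path to the TSV.
#' @return A named list mapping each domain name to a data frame of
#'   (chain, start, end) ranges, in first-appearance order.
#' @export
read_domain_annotation <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("domain_name", "chain", "start_resnum", "end_resnum")
  if (!all(need %in% names(df)))
    stop("annotation must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  split(df[, c("chain", "start_resnum", "end_resnum")],
        factor(df$domain_name, levels = unique(df$domain_name)))
}

domain_index_sets <- function(model, annotation) {
  res <- model$residues
  skipped <- list()
  sets <- lapply(annotation, function(ranges) {
    idx <- integer(0)
    for (r in seq_len(nrow(ranges))) {
      hit <- which(res$chain == ranges$chain[r] &
                     res$resno >= ranges$start_resnum[r] &
                     res$resno <= ranges$end_resnum[r])
      idx <- union(idx, hit)
    }
    sort(idx)
  })
  n_expected <- vapply(annotation, function(ranges)
    sum(pmax(0, ranges$end_resnum - ranges$start_resnum + 1)), numeric(1))
  attr(sets, "n_missing") <- n_expected - vapply(sets, length, numeric(1))
  sets
}

#' Score recovery of annotated domains by dynamic communities
#'
#' Measures how well a community labeling reproduces an external domain
#' annotation.  Each domain reports its best-overlapping community and the
#' Jaccard index of that overlap.  Recovery is exclusive: communities are
#' claimed greedily in order of descending Jaccard (ties broken by domain
#' order, then by smaller community index), each community serving at most
#' one domain, and a domain counts as recovered when the community it
#' claims overlaps it with Jaccard at least \code{threshold}.  A community
#' spanning two domains can therefore recover only the domain it overlaps
#' better.
#'
#' Annotated residues absent from the model are not fatal: they are dropped
#' and counted in the \code{n_missing} attribute of the result.
#'
#' @param labels Per-residue community labels, length N, covering all
#'   annotated residues.
#' @param model The \code{"calpha_model"} the labels refer to.
#' @param annotation A named list of (chain, start, end) range tables as
#'   returned by \code{\link{read_domain_annotation}}.
#' @param threshold Jaccard threshold for recovery (default 0.5).
#' @return Data frame with one row per domain (input order): columns
#'   \code{domain}, \code{best_community}, \code{jaccard},
#'   \code{recovered}; attribute \code{n_missing} gives per-domain counts
#'   of annotated residues absent from the model.
#' @export
domain_recovery <- function(labels, model, annotation, threshold = 0.5) {
  stopifnot(inherits(model, "calpha_model"),
            length(labels) == n_residues(model),
            threshold >= 0, threshold <= 1)
  if (length(annotation) == 0)
    return(structure(data.frame(domain = character(0),
                                best_community = integer(0),
                                jaccard = numeric(0),
                                recovered = logical(0)),
                     n_missing = numeric(0)))
  sets <- domain_index_sets(model, annotation)
  comms <- sort(unique(labels))
  jac <- matrix(0, length(sets), length(comms),
                dimnames = list(names(sets), comms))
  for (d in seq_along(sets)) {
    for (ci in seq_along(comms)) {
      cset <- which(labels == comms[ci])
      inter <- length(intersect(sets[[d]], cset))
      un <- length(union(sets[[d]], cset))
      jac[d, ci] <- if (un == 0) 0 else inter / un
    }
  }
  # per-domain best match, regardless of competition (ties: smaller index)
  best_ci <- apply(jac, 1, which.max)
  best <- comms[best_ci]
  score <- jac[cbind(seq_along(sets), best_ci)]
  # greedy exclusive assignment: each community serves at most one domain,
  # claimed in order of descending Jaccard (ties: domain order, then
  # smaller community index)
  assigned <- rep(FALSE, length(sets))
  avail_d <- seq_along(sets)
  avail_c <- seq_along(comms)
  while (length(avail_d) > 0 && length(avail_c) > 0) {
    sub <- jac[avail_d, avail_c, drop = FALSE]
    m <- max(sub)
    if (m == 0) break
    hit <- which(sub == m, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    d <- avail_d[hit[1, 1]]
    ci <- avail_c[hit[1, 2]]
    assigned[d] <- jac[d, ci] >= threshold
    avail_d <- setdiff(avail_d, d)
    avail_c <- setdiff(avail_c, ci)
  }
  structure(data.frame(domain = names(sets),
                       best_community = best,
                       jaccard = score,
                       recovered = assigned,
                       stringsAsFactors = FALSE, row.names = NULL),
            n_missing = attr(sets, "n_missing"))
}
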