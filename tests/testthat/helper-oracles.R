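# Independent oracles and fixture builders shared across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical first-occurrence relabeling, for partition comparison
canon <- function(l) match(l, unique(l))

# Naive Ward on feature vectors: recompute every merge cost from scratch at
# each step (minimum-variance criterion).  Returns the list of partitions
# after each merge (n-1 entries, last = one cluster).
naive_ward_features <- function(X) {
  n <- nrow(X)
  clusters <- as.list(seq_len(n))
  parts <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(clusters)
    best <- NULL; bc <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      a <- clusters[[i]]; b <- clusters[[j]]
      mu_a <- colMeans(X[a, , drop = FALSE])
      mu_b <- colMeans(X[b, , drop = FALSE])
      cost <- length(a) * length(b) / (length(a) + length(b)) *
        sum((mu_a - mu_b)^2)
      if (cost < bc) { bc <- cost; best <- c(i, j) }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
    lab <- integer(n)
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    parts[[step]] <- canon(lab)
  }
  parts
}

# Naive Ward via the Lance-Williams recurrence applied directly to a
# pairwise dissimilarity matrix (squared internally), recomputed per step.
naive_ward_lw <- function(D) {
  n <- nrow(D)
  d2 <- D^2
  sizes <- rep(1, n)
  clusters <- as.list(seq_len(n))
  active <- seq_len(n)
  parts <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(active)
    best <- NULL; bc <- Inf
    for (ii in seq_len(m - 1)) for (jj in (ii + 1):m) {
      i <- active[ii]; j <- active[jj]
      if (d2[i, j] < bc) { bc <- d2[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    a <- sizes[i]; b <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      c_ <- sizes[k]
      d2[i, k] <- d2[k, i] <-
        ((a + c_) * d2[i, k] + (b + c_) * d2[j, k] - c_ * d2[i, j]) /
        (a + b + c_)
    }
    sizes[i] <- a + b
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    active <- setdiff(active, j)
    lab <- integer(n)
    for (ci in seq_along(active)) lab[clusters[[active[ci]]]] <- ci
    parts[[step]] <- canon(lab)
  }
  parts
}

# partitions at every k for an hclust tree, canonically labeled
tree_partitions <- function(tree) {
  n <- length(tree$order)
  lapply(seq_len(n - 1), function(step) canon(stats::cutree(tree, n - step)))
}

# random valid dynamic distance matrix from a random correlation matrix
random_dynamic_distance <- function(n, seed) {
  set.seed(seed)
  a <- matrix(rnorm(n * n), n)
  dynamic_distance(stats::cov2cor(crossprod(a) + diag(n) * 1e-6))
}

# random connected chain-like globule as a calpha_model (consecutive
# residues 3.8 A apart, so the 7 A contact graph is connected)
random_globule <- function(n, seed) {
  set.seed(seed)
  steps <- matrix(rnorm(3 * (n - 1)), ncol = 3)
  steps <- steps / sqrt(rowSums(steps^2)) * 3.8
  xyz <- rbind(0, apply(steps, 2, cumsum))
  dimnames(xyz) <- NULL
  dyncomm:::new_calpha_model(
    residues = data.frame(chain = rep("A", n), resno = seq_len(n),
                          insert = rep("", n), resid = rep("ALA", n),
                          stringsAsFactors = FALSE),
    xyz = xyz, source = paste0("globule", seed))
}

# fixed-column PDB ATOM/HETATM line builder for parser tests
pdb_line <- function(type = "ATOM", serial = 1, name = " CA ", alt = " ",
                     resid = "ALA", chain = "A", resno = 1, icode = " ",
                     x = 0, y = 0, z = 0, occ = 1, b = 0, element = " C") {
  sprintf("%-6s%5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, alt, resid, chain, resno, icode,
          x, y, z, occ, b, element)
}

# harmonic pairwise ANM potential, for finite-difference Hessian checks
anm_potential <- function(flat_xyz, xyz0, cutoff = 15, gamma = 1) {
  n <- nrow(xyz0)
  xyz <- matrix(flat_xyz, ncol = 3, byrow = TRUE)
  d0 <- as.matrix(stats::dist(xyz0))
  v <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (d0[i, j] > cutoff) next
    dij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    v <- v + 0.5 * gamma * (dij - d0[i, j])^2
  }
  v
}

numeric_hessian <- function(f, x, h = 1e-4) {
  n <- length(x)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    xpp <- x; xpp[i] <- xpp[i] + h; xpp[j] <- xpp[j] + h
    xpm <- x; xpm[i] <- xpm[i] + h; xpm[j] <- xpm[j] - h
    xmp <- x; xmp[i] <- xmp[i] - h; xmp[j] <- xmp[j] + h
    xmm <- x; xmm[i] <- xmm[i] - h; xmm[j] <- xmm[j] - h
    H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h^2)
  }
  H
}
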