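# Independent oracles used to validate the package implementations.
# These deliberately use different algorithms from the package code paths.

# ARI by brute-force pair counting over all C(n,2) pairs
brute_ari <- function(t, p) {
  n <- length(t)
  a <- b <- c_ <- d <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      st <- t[i] == t[j]
      sp <- p[i] == p[j]
      if (st && sp) a <- a + 1
      else if (st && !sp) b <- b + 1
      else if (!st && sp) c_ <- c_ + 1
      else d <- d + 1
    }
  }
  tot <- a + b + c_ + d
  exp_idx <- (a + b) * (a + c_) / tot
  max_idx <- ((a + b) + (a + c_)) / 2
  if (max_idx == exp_idx) return(1)
  (a - exp_idx) / (max_idx - exp_idx)
}

# NMI by direct plug-in entropies of the empirical joint distribution
brute_nmi <- function(t, p) {
  n <- length(t)
  jt <- table(t, p) / n
  pt <- rowSums(jt)
  pp <- colSums(jt)
  H <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  ht <- H(pt); hp <- H(pp)
  if (ht + hp == 0) return(1)
  mi <- 0
  for (i in seq_along(pt)) for (j in seq_along(pp)) {
    if (jt[i, j] > 0) mi <- mi + jt[i, j] * log(jt[i, j] / (pt[i] * pp[j]))
  }
  max(mi, 0) / ((ht + hp) / 2)
}

# connected components by union-find on an adjacency matrix
union_find_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && adj[i, j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

# largest principal angle (radians) between the column spaces of A and B
principal_angle <- function(A, B) {
  qa <- qr.Q(qr(as.matrix(A)))
  qb <- qr.Q(qr(as.matrix(B)))
  s <- svd(crossprod(qa, qb))$d
  acos(min(pmin(pmax(s, -1), 1)))
}

# edge set of an unweighted Laplacian as a sorted "i-j" character vector
laplacian_edges <- function(L) {
  idx <- which(L == -1 & upper.tri(L), arr.ind = TRUE)
  sort(paste0(idx[, 1], "-", idx[, 2]))
}

# quick labeled Gaussian blob data: list(points (cells x dims), labels)
make_blobs <- function(n_classes, per_class, dims, sep, seed, noise_sd = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(n_classes * dims, sd = sep), n_classes, dims)
  points <- do.call(rbind, lapply(seq_len(n_classes), function(cl) {
    matrix(rnorm(per_class * dims, sd = noise_sd), per_class, dims) +
      matrix(centers[cl, ], per_class, dims, byrow = TRUE)
  }))
  list(points = points,
       labels = rep(paste0("c", seq_len(n_classes)), each = per_class))
}

expect_valid_laplacian <- function(L, tol_row = 1e-10, tol_psd = 1e-8) {
  expect_equal(L, t(L))
  expect_lt(max(abs(rowSums(L))), tol_row)
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -tol_psd * max(1, max(ev)))
}
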