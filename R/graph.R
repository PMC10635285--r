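#' k-nearest-neighbor index
#'
#' For each point, the indices of its `k` nearest neighbors under the
#' Euclidean metric, self excluded. Distance ties are broken toward the
#' smaller point index, so the result is deterministic.
#'
#' @param points numeric matrix, one point per row (cells in rows when the
#'   points are cell expression profiles).
#' @param k number of neighbors, `1 <= k <= nrow(points) - 1`.
#' @return integer matrix N x k; row i holds the neighbor indices of point i
#'   in order of increasing distance.
#' @export
knn_index <- function(points, k, metric = "euclidean") {
  points <- as.matrix(points)
  n <- nrow(points)
  metric <- match.arg(metric, "euclidean")
  if (k < 1 || k >= n) {
    stop("k must satisfy 1 <= k <= N-1 (N = ", n, ", k = ", k, ")",
         call. = FALSE)
  }
  d2 <- squared_distances(points)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    di <- d2[i, ]
    di[i] <- Inf
    ord <- order(di, seq_len(n))     # ties -> smaller index first
    out[i, ] <- ord[seq_len(k)]
  }
  out
}

# dense squared Euclidean distance matrix, exact zero diagonal
squared_distances <- function(points) {
  g <- tcrossprod(points)
  sq <- diag(g)
  d2 <- outer(sq, sq, "+") - 2 * g
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  d2
}

# union-symmetrized kNN adjacency mask (logical N x N)
knn_union_mask <- function(nn) {
  n <- nrow(nn)
  mask <- matrix(FALSE, n, n)
  for (i in seq_len(n)) mask[i, nn[i, ]] <- TRUE
  mask | t(mask)
}

#' Gaussian-weighted kNN graph and its Laplacian
#'
#' Builds the union-symmetrized k-nearest-neighbor graph over the points and
#' weights its edges with the Gaussian kernel
#' \eqn{W_{ij} = \exp(-\|x_i - x_j\|^2 / \eta)}; non-edges get weight 0.
#' The graph Laplacian is `L = diag(degree) - W` with `degree = rowSums(W)`.
#'
#' @param points numeric matrix, one point (cell) per row.
#' @param k neighbor count (default 15, the conventional single-scale choice).
#' @param eta kernel scale in squared-distance units, or `"auto"`: the mean
#'   over points of the squared distance to the k-th nearest neighbor.
#' @return an object of class `neighbor_graph` with fields `W`, `degree`,
#'   `L`, `k`, `eta`, and the squared-distance matrix `d2`.
#' @export
gaussian_adjacency <- function(points, k = 15, eta = "auto") {
  points <- as.matrix(points)
  nn <- knn_index(points, k)
  d2 <- squared_distances(points)
  if (identical(eta, "auto")) {
    kth <- vapply(seq_len(nrow(points)),
                  function(i) d2[i, nn[i, k]], numeric(1))
    eta <- mean(kth)
    if (eta <= 0) eta <- 1  # all points coincident: any scale is equivalent
  }
  eta <- as.numeric(eta)
  if (!is.finite(eta) || eta <= 0) {
    stop("eta must be positive (got ", eta, ")", call. = FALSE)
  }
  mask <- knn_union_mask(nn)
  W <- ifelse(mask, exp(-d2 / eta), 0)
  diag(W) <- 0
  W <- (W + t(W)) / 2          # exact symmetry against rounding
  degree <- rowSums(W)
  L <- diag(degree) - W
  structure(
    list(W = W, degree = degree, L = L, k = k, eta = eta, d2 = d2),
    class = "neighbor_graph"
  )
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat("<neighbor_graph> N =", length(x$degree), " k =", x$k,
      " eta =", format(x$eta, digits = 4),
      " edges =", sum(x$W > 0) / 2, "\n")
  invisible(x)
}

new_filtration <- function(laplacians, mode, lmin = NA_real_,
                           lmax = NA_real_, d = NA_real_) {
  structure(
    list(laplacians = laplacians, p = length(laplacians), mode = mode,
         lmin = lmin, lmax = lmax, d = d),
    class = "filtration_sequence"
  )
}

#' @export
print.filtration_sequence <- function(x, ...) {
  cat("<filtration_sequence> mode =", x$mode, " p =", x$p,
      " N =", nrow(x$laplacians[[1]]), "\n")
  invisible(x)
}

unweighted_laplacian <- function(adj_mask) {
  Lt <- ifelse(adj_mask, -1, 0)
  diag(Lt) <- 0
  diag(Lt) <- -rowSums(Lt)
  Lt
}

#' Distance-threshold filtration of a weighted graph Laplacian
#'
#' Sweeps a threshold over the (negative-weight) off-diagonal entries of the
#' weighted kNN-graph Laplacian, in the Vietoris–Rips direction: at step t
#' (t = 1..p) an edge (i, j) is present iff it is kNN-supported
#' (`W_ij > 0`) and `l_ij <= (t/p) d + l_min`, where `l_ij = -W_ij`,
#' `l_min`/`l_max` are the extremes of the supported entries and
#' `d = l_max - l_min`. Heaviest edges (most negative `l_ij`) therefore
#' enter first and the step-p complex contains every supported edge, giving
#' a nested increasing sequence of unweighted graph Laplacians.
#'
#' @param graph a [gaussian_adjacency()] result (or any object with a `W`
#'   field of symmetric non-negative weights).
#' @param p number of filtration steps (default 7).
#' @param support `"knn"` (threshold only kNN-supported entries, default) or
#'   `"dense"` (threshold all pairs of the dense Gaussian kernel; requires
#'   the graph to carry `d2` and `eta`).
#' @param inverted if TRUE, use the opposite orientation (0 where `l_ij`
#'   is below threshold, -1 elsewhere over all pairs), which removes the
#'   closest pairs first and starts from a near-complete graph; provided
#'   for comparison only.
#' @return a `filtration_sequence` with integer-valued Laplacians `L^1..L^p`.
#' @export
distance_filtration <- function(graph, p = 7, support = c("knn", "dense"),
                                inverted = FALSE) {
  support <- match.arg(support)
  if (p < 1) stop("p must be >= 1", call. = FALSE)
  if (support == "dense") {
    if (is.null(graph$d2) || is.null(graph$eta)) {
      stop("dense support requires a graph with d2 and eta", call. = FALSE)
    }
    W <- exp(-graph$d2 / graph$eta)
    diag(W) <- 0
  } else {
    W <- graph$W
  }
  sup <- W > 0
  diag(sup) <- FALSE
  if (!any(sup)) stop("graph has no edges", call. = FALSE)
  l <- -W
  lvals <- l[sup]
  lmin <- min(lvals)
  lmax <- max(lvals)
  d <- lmax - lmin
  eps <- 1e-12 * max(1, abs(lmax), abs(lmin))
  laps <- vector("list", p)
  for (t in seq_len(p)) {
    thr <- if (t == p) lmax else (t / p) * d + lmin
    if (inverted) {
      adj <- (l > thr + eps)
      diag(adj) <- FALSE
    } else {
      adj <- sup & (l <= thr + eps)
    }
    laps[[t]] <- unweighted_laplacian(adj)
  }
  new_filtration(laps, mode = "distance", lmin = lmin, lmax = lmax, d = d)
}

#' kNN-induced filtration
#'
#' Varies the neighbor count k = 1..p and returns, for each k, the
#' unweighted Laplacian of the union-symmetrized kNN graph (edge iff
#' `j in N_k(i)` or `i in N_k(j)`). Since `N_k` grows with k the edge sets
#' are nested, and no distance threshold or kernel scale is involved.
#'
#' @param points numeric matrix, one point (cell) per row.
#' @param p number of filtration steps, `1 <= p <= N - 1` (default 8).
#' @return a `filtration_sequence` with mode `"knn"`.
#' @export
knn_filtration <- function(points, p = 8) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (p < 1 || p >= n) {
    stop("p must satisfy 1 <= p <= N-1 (N = ", n, ")", call. = FALSE)
  }
  nn <- knn_index(points, p)
  laps <- vector("list", p)
  for (k in seq_len(p)) {
    laps[[k]] <- unweighted_laplacian(knn_union_mask(nn[, seq_len(k),
                                                        drop = FALSE]))
  }
  new_filtration(laps, mode = "knn")
}

#' Accumulated persistent Laplacian
#'
#' Consolidates a filtration into a single regularizer
#' \eqn{PL = \sum_{t=1}^{p} \zeta_t L^t}. Non-negative weights keep PL
#' positive semidefinite; symmetry and zero row sums are inherited from the
#' per-step Laplacians.
#'
#' @param filtration a `filtration_sequence`.
#' @param zeta non-negative weight vector of length `p`. The conventional
#'   universal choice is `1/t` for step t.
#' @return an object of class `accumulated_laplacian` with fields `PL`,
#'   `zeta`, `p`, `mode`.
#' @export
accumulate_laplacian <- function(filtration, zeta = 1 / seq_len(filtration$p)) {
  stopifnot(inherits(filtration, "filtration_sequence"))
  zeta <- as.numeric(zeta)
  if (length(zeta) != filtration$p) {
    stop("zeta must have length p = ", filtration$p, " (got ",
         length(zeta), ")", call. = FALSE)
  }
  if (any(zeta < 0)) stop("zeta weights must be non-negative", call. = FALSE)
  if (all(zeta == 0)) {
    warning("all zeta weights are zero; PL is the zero matrix", call. = FALSE)
  }
  n <- nrow(filtration$laplacians[[1]])
  PL <- matrix(0, n, n)
  for (t in seq_len(filtration$p)) {
    if (zeta[t] != 0) PL <- PL + zeta[t] * filtration$laplacians[[t]]
  }
  structure(list(PL = PL, zeta = zeta, p = filtration$p,
                 mode = filtration$mode),
            class = "accumulated_laplacian")
}

#' Number of connected components from a Laplacian kernel
#'
#' Counts the (numerically) zero eigenvalues of a graph Laplacian — the
#' dimension of its kernel — which equals the number of connected components
#' of the underlying graph (the zeroth Betti number).
#'
#' @param laplacian symmetric matrix with zero row sums (weighted Laplacians
#'   are accepted).
#' @param tol relative kernel tolerance: eigenvalues below
#'   `tol * max(1, lambda_max)` count as zero.
#' @return integer component count.
#' @export
betti0 <- function(laplacian, tol = 1e-8) {
  laplacian <- as.matrix(laplacian)
  if (max(abs(laplacian - t(laplacian))) > 1e-8 * max(1, max(abs(laplacian)))) {
    stop("betti0 requires a symmetric matrix", call. = FALSE)
  }
  ev <- eigen((laplacian + t(laplacian)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  lam_max <- max(ev, 0)
  sum(ev < tol * max(1, lam_max))
}

#' Serialize a filtration sequence
#'
#' Writes each step's Laplacian as sparse Matrix Market (`L_1.mtx`, ...)
#' plus a JSON sidecar recording mode, p and construction constants.
#'
#' @param filtration a `filtration_sequence`.
#' @param dir output directory (created if needed).
#' @param zeta optional weights recorded in the sidecar.
#' @param eta,k optional graph constants recorded in the sidecar.
#' @return the sidecar path, invisibly.
#' @export
write_filtration <- function(filtration, dir, zeta = NULL, eta = NULL,
                             k = NULL) {
  stopifnot(inherits(filtration, "filtration_sequence"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in seq_len(filtration$p)) {
    Matrix::writeMM(Matrix::Matrix(filtration$laplacians[[t]], sparse = TRUE),
                    file.path(dir, sprintf("L_%d.mtx", t)))
  }
  sidecar <- file.path(dir, "filtration.json")
  jsonlite::write_json(
    list(mode = filtration$mode, p = filtration$p,
         lmin = filtration$lmin, lmax = filtration$lmax, d = filtration$d,
         zeta = zeta, eta = eta, k = k),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(sidecar)
}
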