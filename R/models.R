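#' Model configuration for the unified PCA-family solver
#'
#' One solver covers six named methods through the loss / regularizer
#' combination:
#'
#' | method      | loss      | laplacian_mode |
#' |-------------|-----------|----------------|
#' | `pca`       | frobenius | none (beta = gamma = 0) |
#' | `spca`      | frobenius | none (beta > 0) |
#' | `glspca`    | frobenius | graph |
#' | `rglspca`   | l21       | graph |
#' | `tpca`      | l21       | pl_distance |
#' | `knn_tpca`  | l21       | pl_knn |
#'
#' @param method optional preset name (above); fills loss, laplacian_mode
#'   and default beta/gamma. Individual arguments override the preset.
#' @param m target dimension (number of components).
#' @param beta sparsity weight on the row-wise L2,1 norm of Q (>= 0).
#' @param gamma Laplacian regularization weight (>= 0).
#' @param loss `"frobenius"` (squared Frobenius reconstruction) or `"l21"`
#'   (column-wise L2,1, robust to outlier cells).
#' @param laplacian_mode `"none"`, `"graph"` (single-scale Gaussian kNN
#'   Laplacian), `"pl_distance"` (accumulated distance-threshold persistent
#'   Laplacian) or `"pl_knn"` (accumulated kNN-induced persistent Laplacian).
#' @param p filtration steps; defaults to 8 for `pl_knn`, 7 for
#'   `pl_distance`.
#' @param zeta filtration weights, length p; default `1/t`.
#' @param k neighbor count for the graph construction (default 15).
#' @param eta Gaussian kernel scale or `"auto"`.
#' @param epsilon IRLS safeguard for vanishing norms (default 1e-8).
#' @param max_iter maximum outer iterations (default 300).
#' @param tol relative objective-change convergence tolerance (default 1e-6).
#' @param seed seed recorded for downstream stochastic consumers; the fit
#'   itself is deterministic (SVD initialization with a fixed sign
#'   convention).
#' @param simple_u_step if TRUE use `U = X Q` instead of the IRLS-weighted
#'   closed form in the U update.
#' @return an object of class `model_config`.
#' @export
model_config <- function(method = NULL, m = 2, beta = NULL, gamma = NULL,
                         loss = NULL, laplacian_mode = NULL, p = NULL,
                         zeta = NULL, k = 15, eta = "auto", epsilon = 1e-8,
                         max_iter = 300, tol = 1e-6, seed = 1,
                         simple_u_step = FALSE) {
  presets <- list(
    pca      = list(loss = "frobenius", laplacian_mode = "none",
                    beta = 0,   gamma = 0),
    spca     = list(loss = "frobenius", laplacian_mode = "none",
                    beta = 0.1, gamma = 0),
    glspca   = list(loss = "frobenius", laplacian_mode = "graph",
                    beta = 0.1, gamma = 1),
    rglspca  = list(loss = "l21", laplacian_mode = "graph",
                    beta = 0.1, gamma = 1),
    tpca     = list(loss = "l21", laplacian_mode = "pl_distance",
                    beta = 0.1, gamma = 1),
    knn_tpca = list(loss = "l21", laplacian_mode = "pl_knn",
                    beta = 0.1, gamma = 1)
  )
  if (!is.null(method)) {
    method <- gsub("-", "_", tolower(method))
    if (!method %in% names(presets)) {
      stop("unknown method '", method, "'; choose one of ",
           paste(names(presets), collapse = ", "), call. = FALSE)
    }
    pre <- presets[[method]]
    if (is.null(loss)) loss <- pre$loss
    if (is.null(laplacian_mode)) laplacian_mode <- pre$laplacian_mode
    if (is.null(beta)) beta <- pre$beta
    if (is.null(gamma)) gamma <- pre$gamma
  }
  if (is.null(loss)) loss <- "frobenius"
  if (is.null(laplacian_mode)) laplacian_mode <- "none"
  if (is.null(beta)) beta <- 0
  if (is.null(gamma)) gamma <- 0
  loss <- match.arg(loss, c("frobenius", "l21"))
  laplacian_mode <- match.arg(laplacian_mode,
                              c("none", "graph", "pl_distance", "pl_knn"))
  if (is.null(p)) p <- if (laplacian_mode == "pl_knn") 8 else 7
  if (is.null(zeta)) zeta <- 1 / seq_len(p)
  m <- suppressWarnings(as.integer(m))
  if (is.na(m) || m < 1) stop("m must be >= 1", call. = FALSE)
  if (beta < 0 || gamma < 0) stop("beta and gamma must be >= 0", call. = FALSE)
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  if (length(zeta) != p) stop("zeta must have length p", call. = FALSE)
  structure(
    list(method = method %||% "custom", m = as.integer(m), beta = beta,
         gamma = gamma, loss = loss, laplacian_mode = laplacian_mode,
         p = as.integer(p), zeta = as.numeric(zeta), k = as.integer(k),
         eta = eta, epsilon = epsilon, max_iter = as.integer(max_iter),
         tol = tol, seed = as.integer(seed),
         simple_u_step = isTRUE(simple_u_step)),
    class = "model_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>", x$method, "| m =", x$m, "loss =", x$loss,
      "laplacian =", x$laplacian_mode, "beta =", x$beta, "gamma =", x$gamma,
      "\n")
  invisible(x)
}

#' Objective value of the unified PCA family
#'
#' Reconstruction term (squared Frobenius or column-wise L2,1 of
#' `X - U Q^T`, per the configured loss) plus `beta * sum_j ||q_j||_2` over
#' the rows of Q plus `gamma * Tr(Q^T PL Q)`.
#'
#' @param X M x N data matrix. @param U M x m loadings. @param Q N x m
#'   embedding. @param config a [model_config()]. @param PL optional N x N
#'   regularizer matrix (required when gamma > 0 and mode != none).
#' @return a finite scalar.
#' @export
tpca_objective <- function(X, U, Q, config, PL = NULL) {
  if (nrow(U) != nrow(X) || nrow(Q) != ncol(X) || ncol(U) != ncol(Q)) {
    stop("shape mismatch: X is ", nrow(X), "x", ncol(X), ", U is ",
         nrow(U), "x", ncol(U), ", Q is ", nrow(Q), "x", ncol(Q),
         call. = FALSE)
  }
  E <- X - tcrossprod(U, Q)
  rec <- if (config$loss == "l21") {
    sum(sqrt(colSums(E^2)))
  } else {
    sum(E^2)
  }
  pen <- 0
  if (config$beta > 0) pen <- pen + config$beta * sum(sqrt(rowSums(Q^2)))
  reg <- 0
  if (config$gamma > 0 && !is.null(PL)) {
    reg <- config$gamma * sum(Q * (PL %*% Q))
  }
  val <- rec + pen + reg
  if (!is.finite(val)) stop("non-finite objective value", call. = FALSE)
  val
}

#' IRLS weights for an L2,1 term
#'
#' The standard majorization weights `d_j = 1 / (2 max(||e_j||, epsilon))`
#' turning a sum of norms into a weighted sum of squared norms that touches
#' it at the current iterate.
#'
#' @param residual_norms non-negative vector of column (or row) norms.
#' @param epsilon positive safeguard bounding the weights by
#'   `1 / (2 epsilon)`.
#' @return positive weight vector of the same length.
#' @export
irls_weights <- function(residual_norms, epsilon = 1e-8) {
  if (epsilon <= 0) stop("epsilon must be > 0", call. = FALSE)
  if (any(residual_norms < 0)) {
    stop("residual norms must be non-negative", call. = FALSE)
  }
  1 / (2 * pmax(residual_norms, epsilon))
}

#' Orthogonality-constrained quadratic minimization
#'
#' Solves `min_Q Tr(Q^T A Q) - 2 Tr(Q^T B)` subject to `Q^T Q = I_m` by
#' generalized power iteration: with `alpha >= lambda_max(A)`, repeat
#' `M <- 2 (alpha I - A) Q + 2 B`, `Q <- polar factor of M`. Each sweep is
#' non-increasing in the subproblem objective.
#'
#' @param A symmetric N x N matrix.
#' @param B N x m matrix.
#' @param Q0 N x m orthonormal starting point.
#' @param max_inner inner iteration cap (default 50).
#' @param alpha optional shift; defaults to a safe upper bound on
#'   `lambda_max(A)`.
#' @param tol inner relative-change stopping tolerance.
#' @return N x m matrix with orthonormal columns.
#' @export
stiefel_quadratic_minimize <- function(A, B, Q0, max_inner = 50,
                                       alpha = NULL, tol = 1e-12) {
  n <- nrow(Q0)
  if (is.null(alpha)) {
    # Gershgorin-type bound on lambda_max(A); cheap and always valid
    alpha <- max(abs(A) %*% rep(1, n))
  }
  alpha <- alpha * (1 + 1e-6) + 1e-12
  Q <- Q0
  obj_prev <- Inf
  for (it in seq_len(max_inner)) {
    M <- 2 * (alpha * Q - A %*% Q) + 2 * B
    Q <- polar_orthonormalize(M)
    obj <- sum(Q * (A %*% Q)) - 2 * sum(Q * B)
    if (is.finite(obj_prev) &&
        abs(obj_prev - obj) <= tol * max(1, abs(obj_prev))) break
    obj_prev <- obj
  }
  Q
}

# polar factor via SVD; handles rank deficiency (the deficient directions
# are completed deterministically by LAPACK's singular vectors)
polar_orthonormalize <- function(M) {
  sv <- svd(M)
  sv$u %*% t(sv$v)
}

# deterministic sign convention: largest-magnitude entry of each column >= 0
fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

# build the N x N regularizer for a config; returns NULL for mode "none"
build_regularizer <- function(X, config) {
  mode <- config$laplacian_mode
  if (mode == "none") return(NULL)
  points <- t(X)  # cells in rows
  if (mode == "graph") {
    g <- gaussian_adjacency(points, k = min(config$k, nrow(points) - 1),
                            eta = config$eta)
    return(g$L)
  }
  if (mode == "pl_distance") {
    g <- gaussian_adjacency(points, k = min(config$k, nrow(points) - 1),
                            eta = config$eta)
    filt <- distance_filtration(g, p = config$p)
  } else {
    filt <- knn_filtration(points, p = min(config$p, nrow(points) - 1))
  }
  zeta <- config$zeta[seq_len(filt$p)]
  accumulate_laplacian(filt, zeta)$PL
}

#' Fit a topological / regularized PCA model
#'
#' Alternating majorize–minimize solver shared by all six methods. The
#' embedding Q is initialized from the top-m right singular subspace of X
#' (fixed sign convention, hence deterministic), then the solver alternates:
#' IRLS residual weights (identity for the Frobenius loss), row-sparsity
#' weights for the beta term, the weighted closed-form U update
#' `U = X D Q (Q^T D Q)^{-1}`, and an orthogonality-constrained quadratic
#' Q update via [stiefel_quadratic_minimize()]. The objective trace is
#' non-increasing and iteration stops when its relative change drops below
#' `config$tol`.
#'
#' @param X M x N numeric matrix (genes x cells, z-scored upstream; the fit
#'   does not re-center), or an [expression_matrix()].
#' @param config a [model_config()].
#' @return an object of class `tpca_fit` with fields `U` (M x m loadings),
#'   `Q` (N x m embedding, orthonormal columns), `objective_trace`,
#'   `n_iter`, `converged`, `config`, and the regularizer `PL` used (NULL
#'   for unregularized fits).
#' @export
tpca_fit <- function(X, config = model_config("pca")) {
  xm <- NULL
  if (inherits(X, "expression_matrix")) {
    xm <- X
    X <- X$values
  }
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X must be finite", call. = FALSE)
  M <- nrow(X); N <- ncol(X); m <- config$m
  if (m > N) stop("m (", m, ") may not exceed the number of cells (", N, ")",
                  call. = FALSE)
  if (m > M) stop("m (", m, ") may not exceed the number of genes (", M, ")",
                  call. = FALSE)

  PL <- build_regularizer(X, config)
  use_reg <- !is.null(PL) && config$gamma > 0
  A_reg <- if (use_reg) config$gamma * PL else NULL
  lam_reg <- if (use_reg) max(abs(A_reg) %*% rep(1, N)) else 0

  sv <- svd(X, nu = 0, nv = m)
  Q <- fix_signs(sv$v[, seq_len(m), drop = FALSE])
  D <- rep(1, N)
  U <- u_step(X, Q, D, config$simple_u_step)

  trace <- tpca_objective(X, U, Q, config, PL)
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    E <- X - tcrossprod(U, Q)
    D <- if (config$loss == "l21") {
      irls_weights(sqrt(colSums(E^2)), config$epsilon)
    } else {
      rep(1, N)
    }
    S <- if (config$beta > 0) {
      config$beta * irls_weights(sqrt(rowSums(Q^2)), config$epsilon)
    } else {
      rep(0, N)
    }
    U <- u_step(X, Q, D, config$simple_u_step)

    UtU <- crossprod(U)
    lam_U <- max(eigen(UtU, symmetric = TRUE, only.values = TRUE)$values)
    # exact quadratic majorizer of sum_j d_j q_j' U'U q_j at the current Q:
    # lam_U * Tr(Q' D Q) plus the touching linear correction in B
    diag_part <- lam_U * D + S
    B <- D * (t(X) %*% U) + (D * Q) %*% (diag(lam_U, m) - UtU)
    alpha <- lam_reg + max(diag_part)
    Q_new <- if (use_reg) {
      Amul_minimize(A_reg, diag_part, B, Q, alpha)
    } else {
      Amul_minimize(NULL, diag_part, B, Q, alpha)
    }
    Q <- Q_new
    obj <- tpca_objective(X, U, Q, config, PL)
    trace <- c(trace, obj)
    prev <- trace[length(trace) - 1]
    if (abs(prev - obj) <= config$tol * max(1, abs(prev))) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(U = U, Q = Q, objective_trace = trace, n_iter = length(trace) - 1,
         converged = converged, config = config, PL = PL,
         gene_ids = if (!is.null(xm)) xm$gene_ids else rownames(X),
         cell_ids = if (!is.null(xm)) xm$cell_ids else colnames(X),
         labels = if (!is.null(xm)) xm$labels else NULL),
    class = "tpca_fit"
  )
}

# weighted closed-form U update (or the simple variant U = X Q)
u_step <- function(X, Q, D, simple) {
  if (simple) return(X %*% Q)
  DQ <- D * Q
  G <- crossprod(Q, DQ)
  XDQ <- X %*% DQ
  Ui <- tryCatch(XDQ %*% solve(G),
                 error = function(e) XDQ %*% MASS::ginv(G))
  Ui
}

# GPI sweep with A = diag(diag_part) [+ A_reg]; avoids forming diag(N) dense
Amul_minimize <- function(A_reg, diag_part, B, Q0, alpha, max_inner = 50,
                          tol = 1e-12) {
  Q <- Q0
  obj_prev <- Inf
  alpha <- alpha * (1 + 1e-6) + 1e-12
  for (it in seq_len(max_inner)) {
    AQ <- diag_part * Q
    if (!is.null(A_reg)) AQ <- AQ + A_reg %*% Q
    M <- 2 * (alpha * Q - AQ) + 2 * B
    Q <- polar_orthonormalize(M)
    AQ <- diag_part * Q
    if (!is.null(A_reg)) AQ <- AQ + A_reg %*% Q
    obj <- sum(Q * AQ) - 2 * sum(Q * B)
    if (is.finite(obj_prev) &&
        abs(obj_prev - obj) <= tol * max(1, abs(obj_prev))) break
    obj_prev <- obj
  }
  Q
}

#' @export
print.tpca_fit <- function(x, ...) {
  cat("<tpca_fit>", x$config$method, "| m =", x$config$m,
      "| iterations:", x$n_iter,
      "| converged:", x$converged,
      "| objective:", format(tail_obj(x), digits = 6), "\n")
  invisible(x)
}

tail_obj <- function(fit) fit$objective_trace[length(fit$objective_trace)]

#' Project new cells into a fitted basis
#'
#' Least-squares coordinates of new columns in the learned loading basis:
#' `X_new^T U (U^T U)^{-1}`.
#'
#' @param U M x m loading matrix (or a `tpca_fit`, whose `U` is used).
#' @param X_new M x N' matrix of new cells (same gene space).
#' @return N' x m coordinate matrix.
#' @export
tpca_transform <- function(U, X_new) {
  if (inherits(U, "tpca_fit")) U <- U$U
  U <- as.matrix(U)
  X_new <- as.matrix(X_new)
  if (nrow(X_new) != nrow(U)) {
    stop("X_new must have ", nrow(U), " rows (genes)", call. = FALSE)
  }
  G <- crossprod(U)
  Ginv <- tryCatch(solve(G), error = function(e) {
    warning("rank-deficient loadings; using pseudo-inverse", call. = FALSE)
    MASS::ginv(G)
  })
  t(X_new) %*% U %*% Ginv
}

#' @export
predict.tpca_fit <- function(object, newdata, ...) {
  tpca_transform(object$U, newdata)
}

#' Save a fitted model as a text archive
#'
#' Writes `U.csv`, `Q.csv`, `trace.csv` and a JSON manifest with the full
#' configuration into `dir`.
#'
#' @param fit a `tpca_fit`. @param dir output directory.
#' @return `dir`, invisibly.
#' @export
save_model <- function(fit, dir) {
  stopifnot(inherits(fit, "tpca_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(fit$U, file.path(dir, "U.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(fit$Q, file.path(dir, "Q.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(iter = seq_along(fit$objective_trace) - 1,
                                objective = fit$objective_trace),
                     file.path(dir, "trace.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  cfg <- fit$config
  cfg$eta <- if (identical(cfg$eta, "auto")) "auto" else as.numeric(cfg$eta)
  jsonlite::write_json(
    list(config = unclass(cfg), n_iter = fit$n_iter,
         converged = fit$converged),
    file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}
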