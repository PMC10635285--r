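test_that("model presets map onto the documented loss/regularizer identities", {
  expect_equal(model_config("pca")$loss, "frobenius")
  expect_equal(model_config("pca")$beta, 0)
  expect_equal(model_config("pca")$gamma, 0)
  expect_gt(model_config("spca")$beta, 0)
  expect_equal(model_config("glspca")$laplacian_mode, "graph")
  expect_equal(model_config("rglspca")$loss, "l21")
  expect_equal(model_config("rglspca")$laplacian_mode, "graph")
  expect_equal(model_config("tpca")$laplacian_mode, "pl_distance")
  expect_equal(model_config("tpca")$p, 7)
  expect_equal(model_config("knn-tpca")$laplacian_mode, "pl_knn")
  expect_equal(model_config("knn_tpca")$p, 8)
  expect_equal(model_config("knn_tpca")$zeta, 1 / (1:8))
  expect_error(model_config("umap"), "unknown method")
  expect_error(model_config("pca", m = 0), "m must")
  expect_error(model_config("pca", beta = -1), "beta")
})

test_that("objective evaluates the three terms as specified", {
  U <- matrix(c(1, 0), 2, 1)
  Q <- matrix(c(1, 0), 2, 1)
  X <- tcrossprod(U, Q)
  cfg <- model_config(loss = "frobenius", m = 1)
  expect_equal(tpca_objective(X, U, Q, cfg), 0)

  # l21 loss: residual columns (0, e2) give objective 1
  X2 <- diag(2)
  cfg21 <- model_config(loss = "l21", m = 1)
  expect_equal(tpca_objective(X2, U, Q, cfg21), 1)

  # beta term: ||I_2||_{2,1} = 2
  cfgb <- model_config(loss = "frobenius", m = 2, beta = 1)
  expect_equal(tpca_objective(diag(2), diag(2), diag(2), cfgb), 2)

  # gamma term is Tr(Q' PL Q)
  PL <- matrix(c(1, -1, -1, 1), 2, 2)
  cfgg <- model_config(loss = "frobenius", m = 1, gamma = 2,
                       laplacian_mode = "graph")
  q <- matrix(c(1, 0), 2, 1)
  expect_equal(tpca_objective(matrix(0, 2, 2), matrix(0, 2, 1), q, cfgg, PL),
               2 * 1)
  expect_error(tpca_objective(X, U, matrix(0, 3, 1), cfg), "shape mismatch")
})

test_that("irls_weights implements the safeguarded majorization weights", {
  expect_equal(irls_weights(1), 0.5)
  expect_equal(irls_weights(0, epsilon = 1e-8), 5e7)
  expect_equal(irls_weights(c(2, 2, 2)), rep(0.25, 3))
  expect_true(all(irls_weights(runif(10), 1e-8) <= 1 / (2e-8)))
  expect_error(irls_weights(1, epsilon = 0), "epsilon")
  expect_error(irls_weights(-1), "non-negative")
})

test_that("stiefel solver handles the closed-form and eigen oracle cases", {
  set.seed(17)
  n <- 20; m <- 2
  Q0 <- qr.Q(qr(matrix(rnorm(n * m), n, m)))

  # A = 0: optimum is the polar factor of B
  B <- matrix(rnorm(n * m), n, m)
  Q <- stiefel_quadratic_minimize(matrix(0, n, n), B, Q0, max_inner = 5)
  sv <- svd(B)
  expect_equal(Q, sv$u %*% t(sv$v), tolerance = 1e-10)

  # B = 0, A PSD: optimum spans the m smallest eigenvectors
  V <- qr.Q(qr(matrix(rnorm(n * n), n, n)))
  A <- V %*% diag(c(0.1, 0.2, 1, runif(n - 3, 2, 5))) %*% t(V)
  A <- (A + t(A)) / 2
  Qe <- stiefel_quadratic_minimize(A, matrix(0, n, m), Q0,
                                   max_inner = 5000, tol = 1e-16)
  expect_lt(principal_angle(Qe, V[, 1:2]), 1e-6)
  expect_lt(norm(crossprod(Qe) - diag(m), "F"), 1e-10)

  # A = alpha I: objective constant on the manifold; Q0 is already optimal
  Qc <- stiefel_quadratic_minimize(diag(3, n), matrix(0, n, m), Q0,
                                   max_inner = 10)
  expect_lt(norm(crossprod(Qc) - diag(m), "F"), 1e-10)
})

test_that("unregularized frobenius fit recovers the SVD subspace", {
  set.seed(23)
  for (trial in 1:5) {
    X <- matrix(rnorm(50 * 40), 50, 40)
    X <- X - rowMeans(X)
    m <- sample(2:5, 1)
    fit <- tpca_fit(X, model_config("pca", m = m))
    sv <- svd(X, nv = m)
    expect_lt(principal_angle(fit$Q, sv$v), 1e-6)
    expect_lt(norm(crossprod(fit$Q) - diag(m), "F"), 1e-8)
  }
})

test_that("objective trace is non-increasing for all six presets", {
  xm <- simulate_counts(synthetic_spec(cells_per_class = 20, n_genes = 120,
                                       n_informative_genes = 30, seed = 4))
  X <- zscore(suppressWarnings(preprocess(xm, min_class_size = 0)))$values
  for (method in c("pca", "spca", "glspca", "rglspca", "tpca", "knn_tpca")) {
    fit <- tpca_fit(X, model_config(method, m = 3, k = 10, p = 5))
    tr <- fit$objective_trace
    rel_inc <- diff(tr) / pmax(1, abs(tr[-length(tr)]))
    expect_true(all(rel_inc <= 1e-10),
                info = paste(method, "trace increased"))
    expect_lt(norm(crossprod(fit$Q) - diag(3), "F"), 1e-8)
  }
})

test_that("fits are deterministic", {
  xm <- simulate_counts(synthetic_spec(cells_per_class = 15, n_genes = 80,
                                       n_informative_genes = 20, seed = 9))
  X <- zscore(suppressWarnings(preprocess(xm, min_class_size = 0)))$values
  f1 <- tpca_fit(X, model_config("knn_tpca", m = 3, p = 4))
  f2 <- tpca_fit(X, model_config("knn_tpca", m = 3, p = 4))
  expect_identical(f1$Q, f2$Q)
  expect_identical(f1$U, f2$U)
  expect_identical(f1$objective_trace, f2$objective_trace)
})

test_that("large gamma drives Q to the smoothest eigenvectors of PL", {
  set.seed(7)
  pts <- matrix(rnorm(30 * 5), 30, 5)
  X <- t(pts) * 0.1
  filt <- knn_filtration(pts, p = 4)
  PL <- accumulate_laplacian(filt, 1 / (1:4))$PL
  expect_equal(betti0(filt$laplacians[[4]]), 1)   # connected filtration
  cfg <- model_config(loss = "l21", laplacian_mode = "pl_knn", m = 3,
                      p = 4, gamma = 1e6, beta = 0)
  fit <- tpca_fit(X, cfg)
  ev <- sort(eigen(PL, symmetric = TRUE, only.values = TRUE)$values)
  expect_lt(abs(sum(fit$Q * (PL %*% fit$Q)) - sum(ev[1:3])), 1e-6)
})

test_that("transform recovers training coordinates and handles edge cases", {
  set.seed(12)
  X <- matrix(rnorm(30 * 25), 30, 25)
  X <- X - rowMeans(X)
  fit <- tpca_fit(X, model_config("pca", m = 3))
  coords <- tpca_transform(fit$U, X)
  expect_lt(max(abs(coords - fit$Q)), 1e-6)

  # orthonormal U reduces to U' X_new transposed
  Uo <- qr.Q(qr(matrix(rnorm(30 * 3), 30, 3)))
  Xn <- matrix(rnorm(30 * 4), 30, 4)
  expect_equal(tpca_transform(Uo, Xn), t(crossprod(Uo, Xn)),
               tolerance = 1e-10)
  # zero column maps to the zero row
  Xz <- cbind(Xn[, 1:2], 0)
  expect_equal(unname(tpca_transform(Uo, Xz)[3, ]), rep(0, 3))
  # rank-deficient loadings fall back to the pseudo-inverse with a warning
  Ud <- cbind(Uo[, 1], Uo[, 1])
  expect_warning(tpca_transform(Ud, Xn), "pseudo-inverse")
})

test_that("robust graph fit does not degrade clustering on clean blobs", {
  aris <- matrix(NA_real_, 10, 2)
  for (s in 1:10) {
    blobs <- make_blobs(3, 15, 10, sep = 8, seed = 100 + s)
    X <- t(scale(blobs$points))   # genes x cells convention
    f_rob <- tpca_fit(X, model_config("rglspca", m = 3, k = 8))
    f_pca <- tpca_fit(X, model_config("pca", m = 3))
    set.seed(1)
    km1 <- kmeans(f_rob$Q, 3, nstart = 10)
    set.seed(1)
    km2 <- kmeans(f_pca$Q, 3, nstart = 10)
    aris[s, ] <- c(ari(blobs$labels, km1$cluster),
                   ari(blobs$labels, km2$cluster))
  }
  expect_true(all(aris[, 1] >= aris[, 2] - 0.05))
})

test_that("l21 loss is more robust to outlier cells than frobenius", {
  wins <- 0
  for (trial in 1:20) {
    set.seed(trial)
    M <- 40; N <- 100; m <- 3
    Uo <- qr.Q(qr(matrix(rnorm(M * m), M, m)))
    Xc <- Uo %*% matrix(rnorm(m * N, sd = 3), m, N) +
      matrix(rnorm(M * N, sd = 0.3), M, N)
    clean_V <- svd(Xc, nv = m)$v
    Xd <- Xc
    out <- sample(N, ceiling(0.05 * N))
    Xd[, out] <- Xd[, out] * 20
    a_l21 <- principal_angle(tpca_fit(Xd, model_config(loss = "l21",
                                                       m = m))$Q, clean_V)
    a_fro <- principal_angle(tpca_fit(Xd, model_config(loss = "frobenius",
                                                       m = m))$Q, clean_V)
    if (a_l21 <= a_fro) wins <- wins + 1
  }
  expect_gte(wins, 15)
})

test_that("fit validates its inputs", {
  X <- matrix(rnorm(20), 4, 5)
  expect_error(tpca_fit(X, model_config("pca", m = 6)), "may not exceed")
  Xb <- X; Xb[1, 1] <- NA
  expect_error(tpca_fit(Xb, model_config("pca", m = 2)), "finite")
})

test_that("model archives serialize config and factors as text", {
  X <- matrix(rnorm(40), 8, 5)
  fit <- tpca_fit(X, model_config("pca", m = 2))
  dir <- withr::local_tempdir()
  save_model(fit, dir)
  U <- as.matrix(utils::read.csv(file.path(dir, "U.csv"), header = FALSE))
  expect_equal(unname(U), unname(fit$U), tolerance = 1e-12)
  manifest <- jsonlite::read_json(file.path(dir, "model.json"))
  expect_equal(manifest$config$m, 2)
  expect_equal(manifest$config$loss, "frobenius")
})
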