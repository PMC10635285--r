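test_that("knn_index matches brute-force distances with index tie-breaks", {
  pts <- toy_geometries("line4")   # 0, 1, 3, 7
  nn <- knn_index(pts, k = 1)
  expect_equal(as.vector(nn), c(2L, 1L, 2L, 3L))

  # brute-force check on random points
  set.seed(11)
  P <- matrix(rnorm(15 * 3), 15, 3)
  nn3 <- knn_index(P, k = 3)
  d <- as.matrix(dist(P))
  for (i in 1:15) {
    di <- d[i, ]; di[i] <- Inf
    expect_setequal(nn3[i, ], order(di)[1:3])
  }

  # k = N-1: everyone else is a neighbor
  nnall <- knn_index(P, k = 14)
  expect_equal(sort(nnall[1, ]), 2:15)

  # coincident points are each other's nearest neighbor (index tie-break)
  co <- matrix(c(0, 0, 5), ncol = 1)
  nc <- knn_index(co, k = 1)
  expect_equal(as.vector(nc), c(2L, 1L, 1L))

  expect_error(knn_index(P, k = 15), "k must")
  expect_error(knn_index(P, k = 0), "k must")
})

test_that("gaussian_adjacency builds a valid weighted Laplacian", {
  set.seed(5)
  P <- matrix(rnorm(20 * 4), 20, 4)
  g <- gaussian_adjacency(P, k = 4, eta = 2)
  expect_equal(g$W, t(g$W))
  expect_true(all(diag(g$W) == 0))
  expect_true(all(g$W >= 0 & g$W <= 1))
  expect_equal(g$L, diag(g$degree) - g$W)
  expect_valid_laplacian(g$L)

  # analytic kernel values
  d2 <- as.matrix(dist(P))^2
  edges <- which(g$W > 0, arr.ind = TRUE)
  expect_equal(g$W[edges], exp(-d2[edges] / 2))

  # squared distance equal to eta gives weight exp(-1)
  two <- matrix(c(0, 1), ncol = 1)
  g2 <- gaussian_adjacency(two, k = 1, eta = 1)
  expect_equal(g2$W[1, 2], exp(-1))
  # coincident neighbors get weight 1
  g3 <- gaussian_adjacency(matrix(c(0, 0, 9), ncol = 1), k = 1, eta = 4)
  expect_equal(g3$W[1, 2], 1)

  expect_error(gaussian_adjacency(P, k = 4, eta = -1), "eta")
})

test_that("distance filtration thresholds reproduce hand-worked steps", {
  g <- toy_geometries("three_weights")    # l-values -0.9, -0.5, -0.2
  f <- distance_filtration(g, p = 3)
  counts <- vapply(f$laplacians,
                   function(L) sum(L == -1) / 2, numeric(1))
  expect_equal(counts, c(1, 2, 3))
  expect_equal(f$lmin, -0.9)
  expect_equal(f$lmax, -0.2)
  expect_equal(f$d, 0.7)
  # the first step admits only the heaviest edge (1,2)
  expect_equal(laplacian_edges(f$laplacians[[1]]), "1-2")
  # last step carries the full supported edge set
  expect_equal(laplacian_edges(f$laplacians[[3]]), c("1-2", "1-3", "2-3"))
  # p = 1 collapses to the unweighted kNN-graph Laplacian
  f1 <- distance_filtration(g, p = 1)
  expect_equal(f1$laplacians[[1]], unname(ifelse(g$W > 0, -1, 0) +
                                            diag(rowSums(g$W > 0))))
  # equal weights (d = 0): every step is the full graph
  geq <- toy_geometries("three_weights")
  geq$W[geq$W > 0] <- 0.5
  feq <- distance_filtration(geq, p = 3)
  for (L in feq$laplacians) expect_equal(sum(L == -1) / 2, 3)
})

test_that("knn filtration is nested with the expected endpoints", {
  pts <- toy_geometries("line4")
  f <- knn_filtration(pts, p = 1)
  expect_equal(laplacian_edges(f$laplacians[[1]]), c("1-2", "2-3", "3-4"))
  expect_equal(diag(f$laplacians[[1]]), c(1, 2, 2, 1))

  set.seed(21)
  P <- matrix(rnorm(12 * 2), 12, 2)
  fp <- knn_filtration(P, p = 11)
  # last step is the complete graph
  Lp <- fp$laplacians[[11]]
  expect_true(all(Lp[upper.tri(Lp)] == -1))
  expect_equal(diag(Lp), rep(11, 12))
  # nestedness in k
  for (k in 1:10) {
    e1 <- laplacian_edges(fp$laplacians[[k]])
    e2 <- laplacian_edges(fp$laplacians[[k + 1]])
    expect_true(all(e1 %in% e2))
  }
  # final knn step equals the support of the gaussian graph at the same k
  g <- gaussian_adjacency(P, k = 5)
  f5 <- knn_filtration(P, p = 5)
  expect_equal(f5$laplacians[[5]],
               unname(diag(rowSums(g$W > 0)) - (g$W > 0) * 1))

  expect_error(knn_filtration(P, p = 12), "p must")
})

test_that("accumulate_laplacian is the exact weighted sum", {
  set.seed(2)
  P <- matrix(rnorm(10 * 2), 10, 2)
  f <- knn_filtration(P, p = 3)
  # one-hot weights recover the individual Laplacian
  for (t in 1:3) {
    z <- rep(0, 3); z[t] <- 1
    acc <- suppressWarnings(accumulate_laplacian(f, z))
    expect_equal(acc$PL, f$laplacians[[t]])
  }
  # the universal 1/t weighting
  acc <- accumulate_laplacian(f, c(1, 1 / 2, 1 / 3))
  expect_equal(acc$PL, f$laplacians[[1]] + f$laplacians[[2]] / 2 +
                 f$laplacians[[3]] / 3)
  expect_valid_laplacian(acc$PL)
  # zero weights: warning and zero matrix
  expect_warning(z0 <- accumulate_laplacian(f, c(0, 0, 0)), "zero")
  expect_equal(z0$PL, matrix(0, 10, 10))
  expect_error(accumulate_laplacian(f, c(1, 2)), "length")
  expect_error(accumulate_laplacian(f, c(1, -1, 0)), "non-negative")
})

test_that("betti0 counts connected components", {
  expect_equal(betti0(toy_geometries("two_blocks")), 2)
  # complete graph is connected
  n <- 6
  Lc <- diag(n) * (n - 1) - (1 - diag(n))
  expect_equal(betti0(Lc), 1)
  # empty graph has N components
  expect_equal(betti0(matrix(0, 7, 7)), 7)
  expect_error(betti0(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("betti0 agrees with a union-find oracle on random graphs", {
  set.seed(99)
  for (trial in 1:100) {
    n <- sample(4:50, 1)
    adj <- matrix(runif(n * n) < 0.06, n, n)
    adj <- adj | t(adj)
    diag(adj) <- FALSE
    L <- diag(rowSums(adj)) - adj * 1
    expect_equal(betti0(L), union_find_components(adj))
  }
})

test_that("Laplacian invariants hold across random point clouds", {
  set.seed(31)
  for (trial in 1:25) {
    n <- sample(8:60, 1)
    P <- matrix(rnorm(n * 3), n, 3)
    k <- sample(2:min(8, n - 1), 1)
    g <- gaussian_adjacency(P, k = k)
    expect_valid_laplacian(g$L)
    p <- sample(2:5, 1)
    fd <- distance_filtration(g, p = p)
    fk <- knn_filtration(P, p = min(p, n - 1))
    for (L in c(fd$laplacians, fk$laplacians)) expect_valid_laplacian(L)
    # betti0 non-increasing along both filtrations
    b_d <- vapply(fd$laplacians, betti0, integer(1))
    b_k <- vapply(fk$laplacians, betti0, integer(1))
    expect_true(all(diff(b_d) <= 0))
    expect_true(all(diff(b_k) <= 0))
  }
})

test_that("inverted threshold orientation reverses the filtration", {
  g <- toy_geometries("three_weights")
  f <- distance_filtration(g, p = 3, inverted = TRUE)
  counts <- vapply(f$laplacians, function(L) sum(L == -1) / 2, numeric(1))
  # edges leave as the threshold sweeps up; the final complex is empty
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[3], 0)
})

test_that("filtration serialization round-trips through Matrix Market", {
  set.seed(13)
  P <- matrix(rnorm(8 * 2), 8, 2)
  f <- knn_filtration(P, p = 2)
  dir <- withr::local_tempdir()
  write_filtration(f, dir, zeta = c(1, 0.5))
  meta <- jsonlite::read_json(file.path(dir, "filtration.json"))
  expect_equal(meta$mode, "knn")
  expect_equal(meta$p, 2)
  L1 <- as.matrix(Matrix::readMM(file.path(dir, "L_1.mtx")))
  expect_equal(unname(L1), unname(f$laplacians[[1]]))
})
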