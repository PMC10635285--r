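#' Specification for a synthetic scRNA-seq count matrix
#'
#' Defines the study conditions for the generator: a log-normal count model
#' with cluster structure in a subset of informative genes, dropout-induced
#' sparsity, and optional magnitude-scaled outlier cells. The defaults are
#' the reference conditions used throughout the package's evaluation:
#' 3 classes of 100 cells over 1000 genes (100 informative), between-class
#' spread of 5 within-cluster standard deviations, 40% dropout, no
#' outliers.
#'
#' @param n_classes number of cell classes.
#' @param cells_per_class cells per class (scalar or length `n_classes`).
#' @param n_genes total genes.
#' @param n_informative_genes genes carrying class signal.
#' @param cluster_separation between-class standard deviation of the
#'   informative-gene log-means, in units of the within-cluster sd (= 1).
#' @param dropout_rate independent Bernoulli zeroing probability in [0, 1).
#' @param outlier_frac fraction of cells scaled x20 in magnitude, in [0, 1).
#' @param seed RNG seed; the generator is a pure function of the spec.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_classes = 3, cells_per_class = 100,
                           n_genes = 1000, n_informative_genes = 100,
                           cluster_separation = 5, dropout_rate = 0.4,
                           outlier_frac = 0, seed = 0) {
  if (n_classes < 1 || n_genes < 1 || any(cells_per_class < 1)) {
    stop("counts must be positive", call. = FALSE)
  }
  if (n_informative_genes > n_genes) {
    stop("n_informative_genes may not exceed n_genes", call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)", call. = FALSE)
  }
  if (outlier_frac < 0 || outlier_frac >= 1) {
    stop("outlier_frac must be in [0, 1)", call. = FALSE)
  }
  if (length(cells_per_class) == 1) {
    cells_per_class <- rep(cells_per_class, n_classes)
  }
  stopifnot(length(cells_per_class) == n_classes)
  structure(
    list(n_classes = as.integer(n_classes),
         cells_per_class = as.integer(cells_per_class),
         n_genes = as.integer(n_genes),
         n_informative_genes = as.integer(n_informative_genes),
         cluster_separation = cluster_separation,
         dropout_rate = dropout_rate, outlier_frac = outlier_frac,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Simulate a cluster-structured, dropout-sparse count matrix
#'
#' Per class, the informative genes get log-means drawn once from a
#' zero-mean Gaussian with sd `cluster_separation`; non-informative genes
#' have log-mean 0 for every class. Each cell's expression is
#' `round(exp(log-mean + N(0, 1)))`, dropout zeroes entries independently
#' at `dropout_rate`, and `floor(outlier_frac * N)` cells (spread over the
#' classes) are scaled x20. Deterministic given the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @return a labeled [expression_matrix()] of non-negative counts.
#' @export
simulate_counts <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(spec$seed)

  n_cells <- sum(spec$cells_per_class)
  labels <- rep(paste0("class_", seq_len(spec$n_classes)),
                times = spec$cells_per_class)
  mu <- matrix(0, spec$n_genes, spec$n_classes)
  if (spec$n_informative_genes > 0) {
    mu[seq_len(spec$n_informative_genes), ] <-
      stats::rnorm(spec$n_informative_genes * spec$n_classes,
                   sd = spec$cluster_separation)
  }
  class_idx <- rep(seq_len(spec$n_classes), times = spec$cells_per_class)
  logexpr <- mu[, class_idx] +
    matrix(stats::rnorm(spec$n_genes * n_cells), spec$n_genes, n_cells)
  counts <- round(exp(logexpr))

  if (spec$dropout_rate > 0) {
    keep <- matrix(stats::rbinom(length(counts), 1,
                                 1 - spec$dropout_rate),
                   nrow(counts), ncol(counts))
    counts <- counts * keep
  }
  n_out <- floor(spec$outlier_frac * n_cells)
  outliers <- integer(0)
  if (n_out > 0) {
    outliers <- sample.int(n_cells, n_out)
    counts[, outliers] <- counts[, outliers] * 20
  }
  expression_matrix(counts,
                    gene_ids = paste0("gene_", seq_len(spec$n_genes)),
                    cell_ids = paste0("cell_", seq_len(n_cells)),
                    labels = labels,
                    meta = list(spec = unclass(spec),
                                outlier_cells = outliers))
}

#' Deterministic toy geometries
#'
#' Small fixed inputs backing worked examples and tests:
#' * `line4` — the 1-D points 0, 1, 3, 7 (4 x 1 matrix);
#' * `two_blocks` — the Laplacian of the disjoint union of a 2-clique and a
#'   3-clique (two connected components);
#' * `three_weights` — a 3-node `neighbor_graph` with edge weights 0.9
#'   (1-2), 0.5 (1-3) and 0.2 (2-3).
#'
#' @param name one of `"line4"`, `"two_blocks"`, `"three_weights"`.
#' @return a matrix of points, a Laplacian matrix, or a `neighbor_graph`.
#' @export
toy_geometries <- function(name = c("line4", "two_blocks", "three_weights")) {
  name <- match.arg(name)
  if (name == "line4") {
    return(matrix(c(0, 1, 3, 7), ncol = 1))
  }
  if (name == "two_blocks") {
    blk <- function(n) diag(n) * (n - 1) - (1 - diag(n))
    L <- matrix(0, 5, 5)
    L[1:2, 1:2] <- blk(2)
    L[3:5, 3:5] <- blk(3)
    return(L)
  }
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.9
  W[1, 3] <- W[3, 1] <- 0.5
  W[2, 3] <- W[3, 2] <- 0.2
  degree <- rowSums(W)
  structure(list(W = W, degree = degree, L = diag(degree) - W,
                 k = 2, eta = NA_real_, d2 = NULL),
            class = "neighbor_graph")
}
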