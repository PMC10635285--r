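# k-means++ seeding (Arthur & Vassilvitskii); Lloyd iterations are done by
# stats::kmeans on the seeded centers
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  if (k > 1) {
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx <- sample.int(n, 1, prob = probs)
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
  }
  centers
}

# best-of-n_init Lloyd k-means with k-means++ seeding; deterministic given
# the RNG state
kmeans_best <- function(x, k, n_init, iter_max = 100) {
  best <- NULL
  for (r in seq_len(n_init)) {
    centers <- kmeanspp_centers(x, k)
    centers <- centers[!duplicated(centers), , drop = FALSE]
    km <- suppressWarnings(
      stats::kmeans(x, centers = centers, iter.max = iter_max,
                    algorithm = "Lloyd")
    )
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  best
}

# deterministic run seeds derived from a master seed by a fixed counter
derive_seeds <- function(seed, n) {
  (as.integer(seed) %% 1000003L) * 1000L + seq_len(n)
}

#' K-means clustering evaluation protocol
#'
#' Fits the configured model once (with the target dimension forced to the
#' number of distinct labels), then repeatedly clusters the embedding with
#' Lloyd's k-means (k-means++ seeding, `n_init` restarts keeping the best
#' inertia) and scores each run against the provided labels with ARI and
#' NMI.
#'
#' @param xm a preprocessed, labeled [expression_matrix()].
#' @param config a [model_config()]; its `m` is overridden by the number of
#'   classes.
#' @param n_runs number of independent clustering runs (default 30).
#' @param n_init k-means restarts per run (default 150).
#' @param seed master seed; run seeds are derived by a fixed counter.
#' @param fit optional pre-computed `tpca_fit` to reuse.
#' @return an object of class `cluster_eval_report`: a list with `method`,
#'   per-run vectors `ari`/`nmi`, `mean_ari`, `mean_nmi`, `config` and the
#'   underlying `fit`.
#' @export
cluster_eval <- function(xm, config, n_runs = 30, n_init = 150, seed = 1,
                         fit = NULL) {
  stopifnot(inherits(xm, "expression_matrix"))
  if (is.null(xm$labels)) stop("cluster_eval requires labels", call. = FALSE)
  k <- length(unique(xm$labels))
  if (ncol(xm$values) < k) {
    stop("fewer cells than clusters", call. = FALSE)
  }
  config$m <- as.integer(k)
  if (is.null(fit)) fit <- tpca_fit(xm$values, config)
  emb <- fit$Q
  seeds <- derive_seeds(seed, n_runs)
  ari_runs <- nmi_runs <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(seeds[r])
    km <- kmeans_best(emb, k, n_init)
    ari_runs[r] <- ari(xm$labels, km$cluster)
    nmi_runs[r] <- nmi(xm$labels, km$cluster)
  }
  structure(
    list(method = config$method, ari = ari_runs, nmi = nmi_runs,
         mean_ari = mean(ari_runs), mean_nmi = mean(nmi_runs),
         n_runs = n_runs, n_init = n_init, seed = seed,
         config = config, fit = fit),
    class = "cluster_eval_report"
  )
}

#' @export
print.cluster_eval_report <- function(x, ...) {
  cat("<cluster_eval_report>", x$method, "| runs:", x$n_runs,
      "| mean ARI:", format(x$mean_ari, digits = 4),
      "| mean NMI:", format(x$mean_nmi, digits = 4), "\n")
  invisible(x)
}

# deterministic majority-vote kNN classifier: ties in the vote are broken
# by the class of the nearest neighbor among the tied classes
knn_classify <- function(train_x, train_y, test_x, k) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  k <- min(k, nrow(train_x))
  preds <- character(nrow(test_x))
  cross <- tcrossprod(test_x, train_x)
  tn <- rowSums(train_x^2)
  sn <- rowSums(test_x^2)
  d2 <- outer(sn, tn, "+") - 2 * cross
  for (i in seq_len(nrow(test_x))) {
    ord <- order(d2[i, ], seq_len(ncol(d2)))[seq_len(k)]
    votes <- table(train_y[ord])
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) {
      preds[i] <- top
    } else {
      first_tied <- ord[train_y[ord] %in% top][1]
      preds[i] <- train_y[first_tied]
    }
  }
  preds
}

# stratified train index for a given fraction; deterministic given RNG state
stratified_split <- function(labels, train_frac) {
  idx <- integer(0)
  for (cl in unique(labels)) {
    members <- which(labels == cl)
    n_tr <- max(1L, round(train_frac * length(members)))
    idx <- c(idx, sample(members, n_tr))
  }
  sort(idx)
}

#' kNN classification evaluation across subspace dimensions
#'
#' For each target dimension m: repeatedly split the cells into stratified
#' train/test sets, fit the model on the training cells only, project the
#' test cells with the learned loadings, classify them by majority-vote kNN
#' in the embedding, and score with macro metrics. Scores are averaged over
#' `n_folds * n_repeats` splits per dimension, and grand means over the
#' dimension grid are reported.
#'
#' @param xm a labeled [expression_matrix()].
#' @param config a [model_config()].
#' @param dims dimension grid (default `100, 90, ..., 10, 1`, clipped to
#'   the data size).
#' @param train_frac training fraction per split (default 0.6).
#' @param n_folds,n_repeats splits per dimension = `n_folds * n_repeats`
#'   (defaults 5 and 5).
#' @param knn_k classifier neighbor count (default 5).
#' @param seed master seed.
#' @return an object of class `classify_eval_report` with a per-dimension
#'   tibble `per_dim` and `grand_means`.
#' @export
classify_eval <- function(xm, config, dims = c(seq(100, 10, by = -10), 1),
                          train_frac = 0.6, n_folds = 5, n_repeats = 5,
                          knn_k = 5, seed = 1) {
  stopifnot(inherits(xm, "expression_matrix"))
  if (is.null(xm$labels)) stop("classify_eval requires labels", call. = FALSE)
  labels <- xm$labels
  tab <- table(labels)
  small <- names(tab)[tab < n_folds]
  if (length(small) > 0) {
    warning("dropping ", length(small), " class(es) with fewer than ",
            n_folds, " members", call. = FALSE)
    keep <- which(!(labels %in% small))
    xm <- expression_matrix(xm$values[, keep, drop = FALSE],
                            gene_ids = xm$gene_ids,
                            cell_ids = xm$cell_ids[keep],
                            labels = labels[keep])
    labels <- xm$labels
  }
  X <- xm$values
  n <- ncol(X)
  max_m <- min(nrow(X), floor(train_frac * n) - 1)
  dims <- sort(unique(pmin(dims, max_m)), decreasing = TRUE)
  n_splits <- n_folds * n_repeats
  seeds <- derive_seeds(seed, n_splits)

  rows <- list()
  for (m in dims) {
    cfg <- config
    cfg$m <- as.integer(m)
    accs <- pres <- recs <- f1s <- numeric(n_splits)
    for (s in seq_len(n_splits)) {
      set.seed(seeds[s])
      tr <- stratified_split(labels, train_frac)
      te <- setdiff(seq_len(n), tr)
      fit <- tpca_fit(X[, tr, drop = FALSE], cfg)
      test_emb <- tpca_transform(fit$U, X[, te, drop = FALSE])
      preds <- knn_classify(fit$Q, labels[tr], test_emb, knn_k)
      mm <- macro_classification(labels[te], preds)
      accs[s] <- mm$acc; pres[s] <- mm$macro_pre
      recs[s] <- mm$macro_rec; f1s[s] <- mm$macro_f1
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      m = m, acc = mean(accs), macro_pre = mean(pres),
      macro_rec = mean(recs), macro_f1 = mean(f1s))
  }
  per_dim <- do.call(rbind, rows)
  structure(
    list(method = config$method, per_dim = per_dim,
         grand_means = list(acc = mean(per_dim$acc),
                            macro_pre = mean(per_dim$macro_pre),
                            macro_rec = mean(per_dim$macro_rec),
                            macro_f1 = mean(per_dim$macro_f1)),
         dims = dims, train_frac = train_frac, n_folds = n_folds,
         n_repeats = n_repeats, knn_k = knn_k, seed = seed, config = config),
    class = "classify_eval_report"
  )
}

#' @export
print.classify_eval_report <- function(x, ...) {
  cat("<classify_eval_report>", x$method, "| dims:",
      paste(x$dims, collapse = ","), "\n")
  g <- x$grand_means
  cat(sprintf("grand means  ACC %.4f  PRE %.4f  REC %.4f  F1 %.4f\n",
              g$acc, g$macro_pre, g$macro_rec, g$macro_f1))
  invisible(x)
}

#' Size of a filtration-weight parameter search
#'
#' Number of parameter combinations for the three search schemes over p
#' filtration steps and a gamma grid of size G: full search over the
#' (p+1)-candidate weight distribution gives `(p+1)^p * G`; the limited
#' scheme over `m_combos` connectivity combinations gives
#' `m_combos * (p+1)^3 * G`; the binary kNN scheme (each scale important or
#' not) gives `2^p * G`.
#'
#' @param scheme `"full"`, `"limited"` or `"knn"`.
#' @param p filtration steps.
#' @param m_combos connectivity combinations (limited scheme only).
#' @param gamma_grid_size size of the gamma grid G (default 1).
#' @return combination count (numeric, as counts overflow integers quickly).
#' @export
count_param_combinations <- function(scheme = c("full", "limited", "knn"),
                                     p, m_combos = NULL,
                                     gamma_grid_size = 1) {
  scheme <- match.arg(scheme)
  if (p < 1 || gamma_grid_size < 1) {
    stop("p and gamma_grid_size must be >= 1", call. = FALSE)
  }
  switch(scheme,
    full = (p + 1)^p * gamma_grid_size,
    limited = {
      if (is.null(m_combos)) {
        stop("m_combos required for the limited scheme", call. = FALSE)
      }
      m_combos * (p + 1)^3 * gamma_grid_size
    },
    knn = 2^p * gamma_grid_size
  )
}

#' Specify a filtration-weight search grid
#'
#' @param scheme `"full"` (every assignment of the candidate weights
#'   `{1, 1/2, ..., 1/p, 0}` to the p steps), `"limited"` (assignments over
#'   `m_combos` triples of active scales, the rest zero) or `"knn"` (each
#'   step weighted 0 or 1).
#' @param p filtration steps.
#' @param m_combos number of scale triples for the limited scheme
#'   (default 3; triples are spread evenly over the p scales).
#' @param gamma_grid gamma values crossed with the weight grid (default 1).
#' @param zeta_candidates override the candidate weight values.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(scheme = c("full", "limited", "knn"), p,
                      m_combos = 3, gamma_grid = 1,
                      zeta_candidates = NULL) {
  scheme <- match.arg(scheme)
  if (p < 1) stop("p must be >= 1", call. = FALSE)
  if (is.null(zeta_candidates)) {
    zeta_candidates <- if (scheme == "knn") c(0, 1) else c(1 / seq_len(p), 0)
  }
  structure(
    list(scheme = scheme, p = as.integer(p), m_combos = as.integer(m_combos),
         gamma_grid = as.numeric(gamma_grid),
         zeta_candidates = zeta_candidates),
    class = "grid_spec"
  )
}

# triples of (close, middle, long)-range scale indices for the limited
# scheme: combo i narrows in from both ends, i = 1..m_combos
limited_scale_triples <- function(p, m_combos) {
  if (p < 3) stop("limited scheme requires p >= 3", call. = FALSE)
  triples <- vector("list", m_combos)
  for (i in seq_len(m_combos)) {
    lo <- i
    hi <- p - i + 1
    if (hi - lo < 2) {
      stop("m_combos too large for p = ", p,
           " (need p >= 2*m_combos + 1)", call. = FALSE)
    }
    triples[[i]] <- c(lo, floor((lo + hi) / 2), hi)
  }
  triples
}

# materialize the zeta rows of a grid_spec as a matrix (one row per combo,
# gamma crossed afterwards)
build_zeta_grid <- function(spec) {
  p <- spec$p
  if (spec$scheme == "knn") {
    g <- as.matrix(expand.grid(rep(list(c(0, 1)), p),
                               KEEP.OUT.ATTRS = FALSE))
  } else if (spec$scheme == "full") {
    g <- as.matrix(expand.grid(rep(list(spec$zeta_candidates), p),
                               KEEP.OUT.ATTRS = FALSE))
  } else {
    triples <- limited_scale_triples(p, spec$m_combos)
    blocks <- lapply(triples, function(tr) {
      asn <- as.matrix(expand.grid(rep(list(spec$zeta_candidates), 3),
                                   KEEP.OUT.ATTRS = FALSE))
      out <- matrix(0, nrow(asn), p)
      out[, tr] <- asn
      out
    })
    g <- do.call(rbind, blocks)
  }
  colnames(g) <- paste0("zeta_", seq_len(p))
  g
}

#' Exhaustive search over filtration weights (and gamma)
#'
#' Evaluates [cluster_eval()] (with a reduced number of runs, default 5,
#' since the point of the schemes is search cost) for every weight
#' assignment in the grid crossed with every gamma value, and returns the
#' best configuration by the chosen metric together with the full
#' leaderboard. Ties are broken by the smaller grid index. The winner is
#' optionally re-scored under the full protocol.
#'
#' @param xm a labeled, preprocessed [expression_matrix()].
#' @param base_config a [model_config()] with a persistent-Laplacian mode;
#'   its `p` must match the grid's.
#' @param grid a [grid_spec()].
#' @param objective_metric `"ari"` or `"nmi"`.
#' @param seed master seed.
#' @param n_runs_search clustering runs per grid point (default 5).
#' @param n_init k-means restarts per run during search (default 10).
#' @param rescore_full re-run the winner with the full protocol
#'   (30 runs x 150 restarts)? Default FALSE.
#' @return a list with `best_config`, `best_score`, `leaderboard` (tibble,
#'   one row per grid point in grid order) and optionally `full_report`.
#' @export
zeta_grid_search <- function(xm, base_config, grid,
                             objective_metric = c("ari", "nmi"), seed = 1,
                             n_runs_search = 5, n_init = 10,
                             rescore_full = FALSE) {
  objective_metric <- match.arg(objective_metric)
  stopifnot(inherits(grid, "grid_spec"))
  if (is.null(xm$labels)) {
    stop("zeta_grid_search requires labels", call. = FALSE)
  }
  zg <- build_zeta_grid(grid)
  if (nrow(zg) == 0) stop("empty grid", call. = FALSE)
  combos <- expand.grid(zrow = seq_len(nrow(zg)),
                        gamma = grid$gamma_grid, KEEP.OUT.ATTRS = FALSE)
  n_combo <- nrow(combos)
  scores_ari <- scores_nmi <- numeric(n_combo)
  for (i in seq_len(n_combo)) {
    cfg <- base_config
    cfg$p <- grid$p
    cfg$zeta <- as.numeric(zg[combos$zrow[i], ])
    cfg$gamma <- combos$gamma[i]
    rep_i <- suppressWarnings(
      cluster_eval(xm, cfg, n_runs = n_runs_search, n_init = n_init,
                   seed = seed)
    )
    scores_ari[i] <- rep_i$mean_ari
    scores_nmi[i] <- rep_i$mean_nmi
  }
  score <- if (objective_metric == "ari") scores_ari else scores_nmi
  best_i <- which.max(score)  # which.max takes the first maximum: tie rule
  best_config <- base_config
  best_config$p <- grid$p
  best_config$zeta <- as.numeric(zg[combos$zrow[best_i], ])
  best_config$gamma <- combos$gamma[best_i]
  leaderboard <- tibble::tibble(
    grid_index = seq_len(n_combo),
    gamma = combos$gamma,
    as.data.frame(zg[combos$zrow, , drop = FALSE]),
    mean_ari = scores_ari,
    mean_nmi = scores_nmi
  )
  out <- list(best_config = best_config, best_score = score[best_i],
              leaderboard = leaderboard, objective_metric = objective_metric)
  if (rescore_full) {
    out$full_report <- cluster_eval(xm, best_config, seed = seed)
  }
  out
}
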