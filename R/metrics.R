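#' Contingency table between two labelings
#'
#' @param labels_true,labels_pred equal-length label vectors (any atomic
#'   type).
#' @return a list with the overlap matrix `a`, row sums `q`, column sums
#'   `p` and total `n`.
#' @export
contingency <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  a <- unclass(table(labels_true, labels_pred))
  list(a = a, q = rowSums(a), p = colSums(a), n = length(labels_true))
}

#' Adjusted Rand Index
#'
#' Chance-corrected pair-counting agreement between two partitions,
#' computed exactly from the contingency table in binomial-coefficient
#' form. 1 means identical partitions (up to relabeling), values near 0
#' mean chance-level agreement.
#'
#' @inheritParams contingency
#' @return a scalar in \eqn{[-1, 1]}.
#' @export
ari <- function(labels_true, labels_pred) {
  ct <- contingency(labels_true, labels_pred)
  if (ct$n < 2) stop("need at least 2 samples", call. = FALSE)
  sum_ij <- sum(choose(ct$a, 2))
  sum_q <- sum(choose(ct$q, 2))
  sum_p <- sum(choose(ct$p, 2))
  expected <- sum_q * sum_p / choose(ct$n, 2)
  denom <- (sum_q + sum_p) / 2 - expected
  if (abs(denom) < .Machine$double.eps) return(1)
  (sum_ij - expected) / denom
}

#' Normalized Mutual Information
#'
#' Mutual information of the two partitions divided by the arithmetic mean
#' of their entropies (natural logarithms; the ratio is base-invariant).
#' When both partitions are the trivial single-class partition the limit 1
#' is returned; when exactly one is trivial, MI is 0 and so is the score.
#'
#' @inheritParams contingency
#' @return a scalar in \eqn{[0, 1]}.
#' @export
nmi <- function(labels_true, labels_pred) {
  ct <- contingency(labels_true, labels_pred)
  if (ct$n < 2) stop("need at least 2 samples", call. = FALSE)
  pj <- ct$a / ct$n
  pt <- ct$q / ct$n
  pp <- ct$p / ct$n
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  et <- ent(pt)
  ep <- ent(pp)
  if (et + ep == 0) return(1)   # both partitions trivial
  mi <- 0
  for (i in seq_along(pt)) {
    for (j in seq_along(pp)) {
      if (pj[i, j] > 0) mi <- mi + pj[i, j] * log(pj[i, j] / (pt[i] * pp[j]))
    }
  }
  mi <- max(mi, 0)  # clamp tiny negative rounding
  mi / ((et + ep) / 2)
}

#' Macro-averaged classification metrics
#'
#' One-vs-rest precision and recall per class (classes taken from
#' `y_true`), arithmetically averaged into macro-precision and macro-recall;
#' the macro-F1 is the harmonic mean of those two macro averages (not the
#' mean of per-class F1 values). A class never predicted contributes
#' precision 0.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return a list with `acc`, `macro_pre`, `macro_rec`, `macro_f1`.
#' @export
macro_classification <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input", call. = FALSE)
  if (length(y_true) != length(y_pred)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  classes <- unique(y_true)
  pre <- rec <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    pre[ci] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[ci] <- if (tp + fn == 0) 0 else tp / (tp + fn)
  }
  mp <- mean(pre)
  mr <- mean(rec)
  f1 <- if (mp + mr == 0) 0 else 2 * mp * mr / (mp + mr)
  list(acc = mean(y_true == y_pred), macro_pre = mp, macro_rec = mr,
       macro_f1 = f1)
}

#' Residue and similarity scores
#'
#' Per-sample scores for multiclass separation visualization. The residue
#' score of sample i in class l is its summed Euclidean distance to all
#' points outside l, normalized by the maximum such sum within l (so each
#' class attains R = 1). The similarity score is the average over points in
#' the same class (including the sample itself, unless
#' `include_self = FALSE`) of `1 - d_ij / d_max`, with `d_max` the maximal
#' pairwise distance in the data; it lies in \eqn{[0, 1]}. Both scores are
#' invariant to global scaling of the points.
#'
#' @param points numeric matrix, one sample per row.
#' @param labels class labels, one per row.
#' @param include_self include the zero self-distance term in the
#'   similarity average (default TRUE).
#' @param global_rmax normalize residues by the global maximum instead of
#'   per class (default FALSE).
#' @return an object of class `rs_result`: a list with vectors `R`, `S`,
#'   per-class maxima `R_max`, and `d_max`.
#' @export
rs_scores <- function(points, labels, include_self = TRUE,
                      global_rmax = FALSE) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != n) stop("one label per row required", call. = FALSE)
  dm <- sqrt(squared_distances(points))
  d_max <- max(dm)
  classes <- unique(labels)

  single_class <- length(classes) < 2
  R_raw <- numeric(n)
  if (single_class) {
    warning("residue scores undefined with a single class; returning NaN",
            call. = FALSE)
    R <- rep(NaN, n)
    R_max <- stats::setNames(NaN, classes)
  } else {
    for (i in seq_len(n)) {
      R_raw[i] <- sum(dm[i, labels != labels[i]])
    }
    R_max <- vapply(classes, function(cl) max(R_raw[labels == cl]),
                    numeric(1))
    names(R_max) <- classes
    R <- if (global_rmax) {
      R_raw / max(R_max)
    } else {
      R_raw / R_max[labels]
    }
    R <- unname(R)
  }

  S <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(labels == labels[i])
    if (!include_self) same <- setdiff(same, i)
    if (length(same) == 0) {
      S[i] <- 1
    } else if (d_max == 0) {
      S[i] <- 1   # all points coincident
    } else {
      S[i] <- mean(1 - dm[i, same] / d_max)
    }
  }
  structure(list(R = R, S = S, R_max = R_max, d_max = d_max,
                 labels = labels),
            class = "rs_result")
}

#' @export
print.rs_result <- function(x, ...) {
  cat("<rs_result>", length(x$R), "samples,", length(x$R_max),
      "classes, d_max =", format(x$d_max, digits = 4), "\n")
  invisible(x)
}
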