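#' Tidy a fitted model into a per-cell tibble
#'
#' One row per cell with its embedding coordinates (`PC1..PCm`) and, when
#' available, its label.
#'
#' @param x a `tpca_fit`.
#' @param ... unused.
#' @return a tibble with columns `cell_id`, `PC*`, and optionally `label`.
#' @export
tidy.tpca_fit <- function(x, ...) {
  m <- ncol(x$Q)
  emb <- as.data.frame(x$Q)
  colnames(emb) <- paste0("PC", seq_len(m))
  out <- tibble::tibble(
    cell_id = x$cell_ids %||% paste0("cell_", seq_len(nrow(x$Q))))
  out <- cbind(out, emb)
  if (!is.null(x$labels)) out$label <- x$labels
  tibble::as_tibble(out)
}

#' One-row fit summary
#'
#' @param x a `tpca_fit`.
#' @param ... unused.
#' @return a one-row tibble with the method, dimensions, final objective,
#'   iteration count, convergence flag and orthonormality error.
#' @export
glance.tpca_fit <- function(x, ...) {
  m <- ncol(x$Q)
  tibble::tibble(
    method = x$config$method,
    m = m,
    n_cells = nrow(x$Q),
    n_genes = nrow(x$U),
    objective = tail_obj(x),
    n_iter = x$n_iter,
    converged = x$converged,
    orthonormality_error = norm(crossprod(x$Q) - diag(m), "F")
  )
}

#' @export
tidy.cluster_eval_report <- function(x, ...) {
  tibble::tibble(run = seq_along(x$ari), ari = x$ari, nmi = x$nmi)
}

#' @export
glance.cluster_eval_report <- function(x, ...) {
  tibble::tibble(method = x$method, n_runs = x$n_runs,
                 mean_ari = x$mean_ari, mean_nmi = x$mean_nmi)
}

#' @export
tidy.classify_eval_report <- function(x, ...) {
  tibble::as_tibble(x$per_dim)
}

#' @export
glance.classify_eval_report <- function(x, ...) {
  g <- x$grand_means
  tibble::tibble(method = x$method, acc = g$acc, macro_pre = g$macro_pre,
                 macro_rec = g$macro_rec, macro_f1 = g$macro_f1)
}

#' @export
tidy.rs_result <- function(x, ...) {
  tibble::tibble(sample = seq_along(x$R), label = x$labels,
                 residue = x$R, similarity = x$S)
}

#' Export residue-similarity scores as CSV
#'
#' @param rs an [rs_scores()] result.
#' @param path output CSV path.
#' @param cell_ids optional identifiers (defaults to `sample_1..n`).
#' @return `path`, invisibly.
#' @export
write_rs_csv <- function(rs, path, cell_ids = NULL) {
  stopifnot(inherits(rs, "rs_result"))
  df <- data.frame(
    cell_id = cell_ids %||% paste0("sample_", seq_along(rs$R)),
    class = rs$labels, R = rs$R, S = rs$S)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
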