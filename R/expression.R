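#' Construct an expression matrix object
#'
#' The container used throughout the package: a dense genes-by-cells value
#' matrix with unique gene and cell identifiers and optional per-cell class
#' labels (cell types).
#'
#' @param values numeric matrix, genes in rows, cells in columns.
#' @param gene_ids character vector of row identifiers (defaults to existing
#'   rownames or `gene_1..gene_M`).
#' @param cell_ids character vector of column identifiers.
#' @param labels optional character vector of per-cell class labels, length
#'   `ncol(values)`.
#' @param meta list of bookkeeping entries (preprocessing reports etc.).
#' @return An object of class `expression_matrix` with fields `values`,
#'   `gene_ids`, `cell_ids`, `labels`, `meta`.
#' @export
expression_matrix <- function(values, gene_ids = NULL, cell_ids = NULL,
                              labels = NULL, meta = list()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values))) {
    stop("expression values contain NA/NaN/Inf entries", call. = FALSE)
  }
  if (is.null(gene_ids)) {
    gene_ids <- rownames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  }
  if (is.null(cell_ids)) {
    cell_ids <- colnames(values)
    if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(ncol(values)))
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("gene_ids length (", length(gene_ids), ") does not match row count (",
         nrow(values), ")", call. = FALSE)
  }
  if (length(cell_ids) != ncol(values)) {
    stop("cell_ids length (", length(cell_ids), ") does not match column count (",
         ncol(values), ")", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("gene_ids are not unique", call. = FALSE)
  if (anyDuplicated(cell_ids)) stop("cell_ids are not unique", call. = FALSE)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != ncol(values)) {
      stop("labels must have one entry per cell (", ncol(values), "), got ",
           length(labels), call. = FALSE)
    }
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(
    list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
         labels = labels, meta = meta),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " cells", sep = "")
  if (!is.null(x$labels)) {
    cat(", ", length(unique(x$labels)), " classes", sep = "")
  }
  cat("\n")
  if (length(x$meta)) cat("meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix from disk
#'
#' Supports dense CSV/TSV (first column = gene ids, header = cell ids) and
#' Matrix Market MTX with companion `genes.txt` / `barcodes.txt` identifier
#' files (one id per line). Whatever the on-disk orientation, the returned
#' object always has genes in rows and cells in columns.
#'
#' @param path file to read.
#' @param format one of `"auto"`, `"csv"`, `"tsv"`, `"mtx"`; `"auto"` guesses
#'   from the file extension.
#' @param cells_in `"columns"` (default, matrix on disk is genes x cells) or
#'   `"rows"` (transposed on disk).
#' @param genes_file,barcodes_file identifier files for MTX input; default to
#'   `genes.txt` / `barcodes.txt` next to `path`. If absent, synthetic ids
#'   are generated.
#' @param labels_file optional CSV with columns `cell_id,label`.
#' @return an [expression_matrix()].
#' @export
load_expression <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                            cells_in = c("columns", "rows"),
                            genes_file = NULL, barcodes_file = NULL,
                            labels_file = NULL) {
  format <- match.arg(format)
  cells_in <- match.arg(cells_in)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot guess format from extension '", ext, "'",
                          call. = FALSE))
  }

  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- tryCatch(
      utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                        check.names = FALSE, stringsAsFactors = FALSE),
      error = function(e) stop("parse error reading ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    )
    vals <- as.matrix(df)
    if (!is.numeric(vals)) {
      bad <- which(!vapply(df, is.numeric, logical(1)))[1]
      stop("parse error in ", path, ": non-numeric values in column '",
           colnames(df)[bad], "'", call. = FALSE)
    }
    if (anyNA(vals)) {
      bad_rows <- which(rowSums(is.na(vals)) > 0)
      stop("parse error in ", path, ": missing value near line ",
           bad_rows[1] + 1L, call. = FALSE)
    }
    row_ids <- rownames(vals)
    col_ids <- colnames(vals)
  } else {
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop("parse error reading ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
    vals <- as.matrix(m)
    dirn <- dirname(path)
    if (is.null(genes_file)) {
      cand <- file.path(dirn, "genes.txt")
      genes_file <- if (file.exists(cand)) cand else NA
    }
    if (is.null(barcodes_file)) {
      cand <- file.path(dirn, "barcodes.txt")
      barcodes_file <- if (file.exists(cand)) cand else NA
    }
    read_ids <- function(f, n, prefix) {
      if (is.na(f) || is.null(f)) return(paste0(prefix, seq_len(n)))
      ids <- readLines(f)
      ids <- ids[nzchar(ids)]
      if (length(ids) != n) {
        stop("shape error: ", f, " has ", length(ids),
             " ids but matrix dimension is ", n, call. = FALSE)
      }
      ids
    }
    row_ids <- read_ids(genes_file, nrow(vals), "gene_")
    col_ids <- read_ids(barcodes_file, ncol(vals), "cell_")
    rownames(vals) <- row_ids
    colnames(vals) <- col_ids
  }

  if (cells_in == "rows") {
    vals <- t(vals)
    tmp <- row_ids; row_ids <- col_ids; col_ids <- tmp
  }

  labels <- NULL
  if (!is.null(labels_file)) {
    labels <- load_labels(labels_file, col_ids)
  }
  expression_matrix(vals, gene_ids = row_ids, cell_ids = col_ids,
                    labels = labels)
}

#' Read a per-cell label file
#'
#' @param path CSV file with columns `cell_id,label`.
#' @param cell_ids cell identifiers to align labels against.
#' @return character vector of labels ordered as `cell_ids`.
#' @export
load_labels <- function(path, cell_ids) {
  df <- utils::read.table(path, sep = ",", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("cell_id", "label") %in% colnames(df))) {
    stop("label file must have columns cell_id,label", call. = FALSE)
  }
  idx <- match(cell_ids, as.character(df$cell_id))
  if (anyNA(idx)) {
    stop("shape error: ", sum(is.na(idx)), " cells missing from label file",
         call. = FALSE)
  }
  as.character(df$label)[idx]
}

#' Write an expression matrix to disk
#'
#' @param xm an [expression_matrix()].
#' @param path output file (for MTX, `genes.txt`/`barcodes.txt` are written
#'   alongside).
#' @param format `"csv"`, `"tsv"` or `"mtx"`.
#' @param labels_file optional path for a `cell_id,label` CSV when labels are
#'   present.
#' @return `path`, invisibly.
#' @export
write_expression <- function(xm, path, format = c("csv", "tsv", "mtx"),
                             labels_file = NULL) {
  stopifnot(inherits(xm, "expression_matrix"))
  format <- match.arg(format)
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(gene_id = xm$gene_ids, xm$values, check.names = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(unname(xm$values), sparse = TRUE), path)
    dirn <- dirname(path)
    writeLines(xm$gene_ids, file.path(dirn, "genes.txt"))
    writeLines(xm$cell_ids, file.path(dirn, "barcodes.txt"))
  }
  if (!is.null(labels_file) && !is.null(xm$labels)) {
    utils::write.table(
      data.frame(cell_id = xm$cell_ids, label = xm$labels),
      labels_file, sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Standard preprocessing chain for count-like expression data
#'
#' Applies, in this fixed order: (1) elementwise `log1p`; (2) entries below
#' `floor` set to 0; (3) the lowest-variance genes dropped — `floor(frac * M)`
#' of them, ranked by per-gene variance across cells with ties broken toward
#' keeping the smaller row index; (4) if labels are present, cells belonging
#' to classes with fewer than `min_class_size` members removed. Counts
#' removed at each step are recorded in `meta$preprocess`.
#'
#' @param xm an [expression_matrix()] with non-negative values.
#' @param variance_drop_frac fraction of lowest-variance genes to drop
#'   (default 0.20).
#' @param min_class_size minimum class size; smaller classes are removed
#'   (default 15). Set to 0 to disable.
#' @param floor values below this (after log transform) are zeroed
#'   (default 1e-6).
#' @return a new [expression_matrix()].
#' @export
preprocess <- function(xm, variance_drop_frac = 0.20, min_class_size = 15,
                       floor = 1e-6) {
  stopifnot(inherits(xm, "expression_matrix"))
  if (variance_drop_frac < 0 || variance_drop_frac > 1) {
    stop("variance_drop_frac must be in [0, 1]", call. = FALSE)
  }
  if (any(xm$values < 0)) {
    stop("preprocess expects non-negative values", call. = FALSE)
  }
  v <- log1p(xm$values)
  n_zeroed <- sum(v < floor & v != 0)
  v[v < floor] <- 0

  m_total <- nrow(v)
  n_drop <- base::floor(variance_drop_frac * m_total)
  if (n_drop >= m_total) {
    stop("degenerate input: all genes would be dropped", call. = FALSE)
  }
  keep_genes <- seq_len(m_total)
  if (n_drop > 0) {
    mu <- rowMeans(v)
    vars <- rowMeans((v - mu)^2)
    # ties at the drop boundary keep the smaller row index (drop the larger)
    ord <- order(vars, -seq_along(vars))
    drop_idx <- ord[seq_len(n_drop)]
    keep_genes <- setdiff(seq_len(m_total), drop_idx)
    v <- v[keep_genes, , drop = FALSE]
  }

  labels <- xm$labels
  cell_keep <- seq_len(ncol(v))
  n_cells_dropped <- 0L
  n_classes_dropped <- 0L
  if (min_class_size > 0) {
    if (is.null(labels)) {
      warning("no labels present; class-size filtering skipped", call. = FALSE)
    } else {
      tab <- table(labels)
      small <- names(tab)[tab < min_class_size]
      n_classes_dropped <- length(small)
      cell_keep <- which(!(labels %in% small))
      n_cells_dropped <- ncol(v) - length(cell_keep)
      if (length(cell_keep) == 0) {
        stop("degenerate input: all cells removed by class-size filter",
             call. = FALSE)
      }
      v <- v[, cell_keep, drop = FALSE]
      labels <- labels[cell_keep]
    }
  }

  meta <- xm$meta
  meta$preprocess <- list(
    n_genes_in = m_total,
    n_cells_in = length(xm$cell_ids),
    n_entries_zeroed = n_zeroed,
    n_genes_dropped = n_drop,
    n_cells_dropped = n_cells_dropped,
    n_classes_dropped = n_classes_dropped,
    variance_drop_frac = variance_drop_frac,
    min_class_size = min_class_size,
    floor = floor
  )
  expression_matrix(v, gene_ids = xm$gene_ids[keep_genes],
                    cell_ids = xm$cell_ids[cell_keep],
                    labels = labels, meta = meta)
}

#' Gene-wise z-scoring
#'
#' Demeans each gene row and scales it by its population (ddof = 0) standard
#' deviation. Zero-variance rows are left at 0 and their indices flagged in
#' `meta$zero_variance_genes`. Idempotent up to numerical precision.
#'
#' @param xm an [expression_matrix()].
#' @return a new [expression_matrix()] whose non-constant rows have mean 0
#'   and population standard deviation 1.
#' @export
zscore <- function(xm) {
  stopifnot(inherits(xm, "expression_matrix"))
  v <- xm$values
  mu <- rowMeans(v)
  sdev <- sqrt(rowMeans((v - mu)^2))
  flat <- sdev <= 0
  sdev[flat] <- 1
  v <- (v - mu) / sdev
  v[flat, ] <- 0
  meta <- xm$meta
  meta$zero_variance_genes <- unname(which(flat))
  expression_matrix(v, gene_ids = xm$gene_ids, cell_ids = xm$cell_ids,
                    labels = xm$labels, meta = meta)
}
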