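#' Read a 10x-style matrix directory
#'
#' Reads `matrix.mtx` (+ `features.tsv`, `barcodes.tsv`, and optionally
#' `cells.tsv`) as written by [write_10x()]. Gzipped variants
#' (`matrix.mtx.gz`, ...) are accepted transparently.
#'
#' @param dir directory containing the triplet.
#' @return list with `counts` (dgCMatrix, genes x cells), `cells`
#'   (data.frame; minimal cell_id table when no metadata file is present) and
#'   `annotation` (data.frame from the features file).
#' @export
read_10x <- function(dir) {
  find <- function(base, required = TRUE) {
    for (f in c(file.path(dir, base), file.path(dir, paste0(base, ".gz")))) {
      if (file.exists(f)) return(f)
    }
    if (required) stop("missing file '", base, "' (or .gz) in ", dir)
    NULL
  }
  mtx <- find("matrix.mtx")
  counts <- read_mtx(mtx)
  feats <- utils::read.table(find("features.tsv"), sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = c(chromosome = "character"))
  barcodes <- readLines(find("barcodes.tsv"))
  if (nrow(feats) != nrow(counts)) {
    stop("features file lists ", nrow(feats), " genes but matrix has ",
         nrow(counts), " rows")
  }
  if (length(barcodes) != ncol(counts)) {
    stop("barcodes file lists ", length(barcodes), " cells but matrix has ",
         ncol(counts), " columns")
  }
  dimnames(counts) <- list(feats$gene_id, barcodes)
  cellf <- find("cells.tsv", required = FALSE)
  cells <- if (!is.null(cellf)) {
    utils::read.table(cellf, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  } else {
    data.frame(cell_id = barcodes, stringsAsFactors = FALSE)
  }
  if (nrow(cells) != ncol(counts)) {
    stop("cell metadata lists ", nrow(cells), " cells but matrix has ",
         ncol(counts), " columns")
  }
  list(counts = counts, cells = cells, annotation = feats)
}

# Minimal MatrixMarket coordinate reader (integer or real, general).
read_mtx <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  header <- readLines(con, n = 1)
  if (!grepl("^%%MatrixMarket +matrix +coordinate", header)) {
    stop("malformed MatrixMarket header at line 1: '", header, "'")
  }
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("malformed MatrixMarket file: missing size line")
    if (!startsWith(line, "%")) break
  }
  dims <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
  if (length(dims) != 3 || anyNA(dims)) {
    stop("malformed MatrixMarket size line: '", line, "'")
  }
  body <- readLines(con)
  body <- body[nzchar(trimws(body))]
  if (length(body) != dims[3]) {
    stop("MatrixMarket body has ", length(body), " entries, header declares ",
         dims[3])
  }
  if (length(body) > 0) {
    parts <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
                    ncol = 3, byrow = TRUE)
    m <- Matrix::sparseMatrix(i = parts[, 1], j = parts[, 2], x = parts[, 3],
                              dims = dims[1:2])
  } else {
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = dims[1:2])
  }
  methods::as(m, "CsparseMatrix")
}

#' Per-cell QC statistics
#'
#' Computes detected-gene counts and mitochondrial read fractions from raw
#' counts (before any gene filtering, since the fraction describes reads
#' mapped to the mitochondrial genome).
#'
#' @param counts genes x cells raw counts.
#' @param annotation gene annotation with `gene_id` and `is_mito`.
#' @return data.frame with cell_id, n_genes_detected, mito_fraction.
#' @export
cell_qc_stats <- function(counts, annotation) {
  mito <- intersect(rownames(counts), annotation$gene_id[annotation$is_mito])
  total <- Matrix::colSums(counts)
  mt <- if (length(mito) > 0) Matrix::colSums(counts[mito, , drop = FALSE]) else 0
  data.frame(cell_id = colnames(counts),
             n_genes_detected = Matrix::colSums(counts > 0),
             mito_fraction = ifelse(total > 0, mt / total, 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter cells on detected genes and mitochondrial fraction
#'
#' Keeps exactly the cells with more than `min_genes` detected genes
#' (strict inequality) and mitochondrial fraction inside `mito_range`
#' (inclusive on both ends). Cell order is preserved.
#'
#' @param counts genes x cells raw counts.
#' @param cells per-cell metadata (first column = cell id).
#' @param annotation gene annotation with the mitochondrial flag.
#' @param min_genes detected-gene threshold (kept if strictly greater).
#' @param mito_range inclusive `[low, high]` mitochondrial-fraction window.
#' @return list with filtered `counts`, `cells` (with QC columns appended)
#'   and a `report` (class `qc_report`) of per-filter removal counts.
#' @export
filter_cells <- function(counts, cells, annotation, min_genes = 1000,
                         mito_range = c(0.01, 0.10)) {
  stopifnot(ncol(counts) == nrow(cells))
  qc <- cell_qc_stats(counts, annotation)
  pass_genes <- qc$n_genes_detected > min_genes
  pass_mito <- qc$mito_fraction >= mito_range[1] & qc$mito_fraction <= mito_range[2]
  keep <- pass_genes & pass_mito
  report <- structure(list(
    cells_in = ncol(counts),
    cells_kept = sum(keep),
    fail_low_genes = sum(!pass_genes),
    fail_mito_low = sum(qc$mito_fraction < mito_range[1]),
    fail_mito_high = sum(qc$mito_fraction > mito_range[2]),
    min_genes = min_genes, mito_range = mito_range), class = "qc_report")
  if (sum(keep) == 0) warning("no cells pass QC")
  cells_out <- cbind(cells[keep, , drop = FALSE], qc[keep, -1, drop = FALSE])
  rownames(cells_out) <- NULL
  list(counts = counts[, keep, drop = FALSE], cells = cells_out,
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("cells in: %d, kept: %d\n", x$cells_in, x$cells_kept))
  cat(sprintf("  failing detected-genes > %g: %d\n", x$min_genes, x$fail_low_genes))
  cat(sprintf("  mito fraction < %g: %d; > %g: %d\n", x$mito_range[1],
              x$fail_mito_low, x$mito_range[2], x$fail_mito_high))
  invisible(x)
}

#' Retain protein-coding, non-mitochondrial genes
#'
#' Mitochondrial removal takes precedence: a mitochondrially encoded
#' protein-coding gene is dropped.
#'
#' @param counts genes x cells counts.
#' @param annotation annotation covering all genes in `counts`.
#' @return the filtered count matrix.
#' @export
filter_genes <- function(counts, annotation) {
  missing <- setdiff(rownames(counts), annotation$gene_id)
  if (length(missing) > 0) {
    stop("genes missing from annotation: ", paste(missing, collapse = ", "))
  }
  ann <- annotation[match(rownames(counts), annotation$gene_id), ]
  keep <- ann$biotype == "protein_coding" & !ann$is_mito
  counts[keep, , drop = FALSE]
}

#' Log-normalize counts
#'
#' Per cell: `ln(1 + count * scale_factor / total)`. Zeros map to zero, so
#' sparsity is preserved; per cell, `sum(expm1(value))` equals
#' `scale_factor`.
#'
#' @param counts genes x cells raw counts (sparse or dense).
#' @param scale_factor library-size target (default 10,000).
#' @return dgCMatrix of normalized expression.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  totals <- Matrix::colSums(m)
  if (any(totals <= 0)) {
    stop("cells with zero total counts cannot be normalized: ",
         paste(utils::head(colnames(m)[totals <= 0], 5), collapse = ", "))
  }
  percol <- rep.int(totals, diff(m@p))
  m@x <- log1p(m@x * scale_factor / percol)
  m
}
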