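# Shared fixture builders; everything is generated in code at test time.

# Minimal annotation for hand-built count fixtures.
toy_annotation <- function(gene_ids, chromosome = "1",
                           biotype = "protein_coding", is_mito = FALSE,
                           start = NULL) {
  n <- length(gene_ids)
  if (is.null(start)) start <- seq(1e5, by = 1e5, length.out = n)
  data.frame(gene_id = gene_ids, gene_name = gene_ids,
             chromosome = rep_len(chromosome, n),
             start = start, end = start + 1e3,
             biotype = rep_len(biotype, n),
             is_mito = rep_len(is_mito, n), stringsAsFactors = FALSE)
}

# Dense random normalized-expression fixture with dimnames.
random_norm <- function(n_genes, n_cells, seed = 1, lambda = 2) {
  set.seed(seed)
  counts <- matrix(rpois(n_genes * n_cells, lambda), nrow = n_genes,
                   dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                   sprintf("c%04d", seq_len(n_cells))))
  log_normalize(Matrix::Matrix(counts, sparse = TRUE))
}

# A cell-level count fixture where detection counts and mitochondrial
# fractions are set exactly per cell: each cell detects `n_nonmito` distinct
# nuclear genes (count 1 each) plus the single MT gene with count `mt`.
qc_fixture <- function(n_nonmito, mt, n_genes = 1600) {
  stopifnot(length(n_nonmito) == length(mt), n_genes > max(n_nonmito))
  n_cells <- length(n_nonmito)
  i <- unlist(lapply(n_nonmito, function(k) seq_len(k) + 1L))  # gene 1 is MT
  j <- rep(seq_len(n_cells), n_nonmito)
  x <- rep(1, length(i))
  i <- c(i, rep(1L, n_cells))
  j <- c(j, seq_len(n_cells))
  x <- c(x, mt)
  counts <- Matrix::sparseMatrix(i = i, j = j, x = x,
                                 dims = c(n_genes, n_cells))
  rownames(counts) <- c("MT01", sprintf("g%04d", seq_len(n_genes - 1)))
  colnames(counts) <- sprintf("cell%02d", seq_len(n_cells))
  ann <- toy_annotation(rownames(counts))
  ann$chromosome[1] <- "MT"
  ann$is_mito[1] <- TRUE
  cells <- data.frame(cell_id = colnames(counts),
                      sample = "s1", genotype = "euploid",
                      stringsAsFactors = FALSE)
  list(counts = counts, cells = cells, annotation = ann)
}

# Two separated Gaussian blobs in 2D with truth labels.
blob_coords <- function(n_per = 100, gap = 20, sd = 1, seed = 1) {
  set.seed(seed)
  xy <- rbind(cbind(rnorm(n_per, 0, sd), rnorm(n_per, 0, sd)),
              cbind(rnorm(n_per, gap, sd), rnorm(n_per, 0, sd)))
  rownames(xy) <- sprintf("c%03d", seq_len(2 * n_per))
  list(coords = xy, truth = rep(c(1L, 2L), each = n_per))
}
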