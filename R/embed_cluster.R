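#' Select highly variable genes by binned standardized dispersion
#'
#' Ranks genes by the z-score of their dispersion (variance/mean) within 20
#' equal-frequency mean bins and returns the top `n`. Zero-variance genes are
#' never selected; ties are broken by gene id so the selection is
#' deterministic.
#'
#' @param normexpr genes x cells normalized expression.
#' @param n number of genes to return (default 2000).
#' @param n_bins number of equal-frequency mean bins.
#' @return character vector of gene ids, ranked.
#' @export
select_hvg <- function(normexpr, n = 2000, n_bins = 20) {
  mu <- Matrix::rowMeans(normexpr)
  ex2 <- Matrix::rowMeans(normexpr^2)
  nc <- ncol(normexpr)
  v <- (ex2 - mu^2) * nc / max(nc - 1, 1)
  ok <- v > 0 & mu > 0
  if (sum(ok) < n) {
    warning("only ", sum(ok), " genes with nonzero variance; returning all")
  }
  mu <- mu[ok]; v <- v[ok]
  disp <- v / mu
  # equal-frequency bins on the mean; duplicate quantiles collapse bins
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(mu, breaks = br, include.lowest = TRUE)
  z <- disp
  for (b in levels(bin)) {
    sel <- bin == b
    s <- stats::sd(disp[sel])
    z[sel] <- if (is.na(s) || s == 0) 0 else (disp[sel] - mean(disp[sel])) / s
  }
  ids <- names(z)[order(-z, names(z))]
  utils::head(ids, n)
}

#' Scale gene rows and run PCA
#'
#' Gene rows (HVGs) are z-scored across cells and clipped at +/- `clip`
#' before a dense SVD. The sign of each component is fixed so that the
#' largest-magnitude gene loading is positive.
#'
#' @param normexpr genes x cells normalized expression.
#' @param hvgs gene ids to use (rows of `normexpr`).
#' @param n_pcs number of components (default 10).
#' @param clip z-score clipping bound.
#' @return list with `scores` (cells x n_pcs), `loadings` (genes x n_pcs),
#'   `sdev` (component standard deviations, non-increasing).
#' @export
run_pca <- function(normexpr, hvgs, n_pcs = 10, clip = 10) {
  x <- as.matrix(normexpr[hvgs, , drop = FALSE])
  if (n_pcs > min(dim(x))) {
    stop("n_pcs = ", n_pcs, " exceeds matrix rank bound ", min(dim(x)))
  }
  mu <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  s[s == 0] <- 1
  z <- (x - mu) / s
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  y <- t(z)  # cells x genes
  sv <- svd(y, nu = n_pcs, nv = n_pcs)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs, n_pcs)
  loadings <- sv$v
  for (j in seq_len(n_pcs)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- colnames(normexpr)
  rownames(loadings) <- hvgs
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(n_pcs))
  list(scores = scores, loadings = loadings,
       sdev = sv$d[seq_len(n_pcs)] / sqrt(max(nrow(y) - 1, 1)))
}

#' 2D embedding of PCA scores
#'
#' Thin, seeded wrapper around UMAP (uwot) producing a deterministic
#' two-column embedding.
#'
#' @param pca_scores cells x PCs matrix.
#' @param seed integer seed.
#' @param n_neighbors,min_dist UMAP parameters.
#' @return cells x 2 coordinate matrix.
#' @export
embed_2d <- function(pca_scores, seed = 42, n_neighbors = 30, min_dist = 0.3) {
  n <- nrow(pca_scores)
  n_neighbors <- min(n_neighbors, n - 1)
  set.seed(seed)
  xy <- uwot::umap(as.matrix(pca_scores), n_neighbors = n_neighbors,
                   min_dist = min_dist, n_threads = 1, n_sgd_threads = 0,
                   verbose = FALSE)
  rownames(xy) <- rownames(pca_scores)
  colnames(xy) <- c("UMAP1", "UMAP2")
  xy
}

#' Graph clustering on 2D coordinates
#'
#' Builds a k-nearest-neighbour graph on the 2D embedding, weights edges by
#' shared-neighbour (Jaccard) overlap, and runs Louvain modularity
#' optimization at the given resolution. Cluster labels are 0..C-1, ordered
#' by decreasing size.
#'
#' @param proj2d cells x 2 coordinates.
#' @param k neighbourhood size (default 15).
#' @param resolution modularity resolution (default 0.15).
#' @param seed integer seed for the community search.
#' @param prune drop shared-neighbour edges with Jaccard below this value.
#' @return integer vector of cluster labels (named by cell).
#' @export
cluster_cells <- function(proj2d, k = 15, resolution = 0.15, seed = 0,
                          prune = 1 / 15) {
  n <- nrow(proj2d)
  if (k >= n) stop("k = ", k, " must be smaller than the number of cells (", n, ")")
  if (stats::sd(as.matrix(proj2d)) == 0) {
    return(stats::setNames(rep(0L, n), rownames(proj2d)))
  }
  idx <- cbind(seq_len(n), knn_index(as.matrix(proj2d), k))  # include self
  memb <- Matrix::sparseMatrix(i = rep(seq_len(n), ncol(idx)),
                               j = as.vector(idx), x = 1, dims = c(n, n))
  inter <- Matrix::tcrossprod(memb)  # shared-neighbour counts
  inter <- methods::as(inter, "TsparseMatrix")
  jac <- inter@x / (2 * (k + 1) - inter@x)
  keep <- jac >= prune & inter@i != inter@j
  g <- igraph::graph_from_data_frame(
    data.frame(from = inter@i[keep] + 1L, to = inter@j[keep] + 1L,
               weight = jac[keep]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
  g <- igraph::simplify(g, edge.attr.comb = "mean")
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  raw <- igraph::membership(cl)[as.character(seq_len(n))]
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  stats::setNames(as.integer(relabel[as.character(raw)]), rownames(proj2d))
}

#' Assign cell types to clusters from a marker panel
#'
#' Scores each cluster by the mean z-scored expression of each type's marker
#' genes and labels the cluster with the arg-max type. Ties are broken
#' alphabetically with a warning; panel genes absent from the matrix are
#' warned about and skipped.
#'
#' @param normexpr genes x cells normalized expression.
#' @param clusters per-cell cluster labels.
#' @param panel named list mapping cell-type label to marker gene ids.
#' @return character vector of per-cell type labels.
#' @export
assign_cell_types <- function(normexpr, clusters, panel) {
  if (length(panel) == 0) stop("empty marker panel")
  if (any(lengths(panel) == 0)) stop("marker panel has empty gene lists")
  x <- as.matrix(normexpr)
  mu <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  s[s == 0] <- 1
  z <- (x - mu) / s
  type_score <- sapply(names(panel), function(ty) {
    genes <- intersect(panel[[ty]], rownames(z))
    if (length(genes) < length(panel[[ty]])) {
      warning("markers missing from matrix for '", ty, "': ",
              paste(setdiff(panel[[ty]], rownames(z)), collapse = ", "))
    }
    if (length(genes) == 0) return(rep(-Inf, ncol(z)))
    colMeans(z[genes, , drop = FALSE])
  })  # cells x types
  labels <- character(length(clusters))
  for (cl in unique(clusters)) {
    sel <- clusters == cl
    sc <- colMeans(type_score[sel, , drop = FALSE])
    best <- names(sc)[sc == max(sc)]
    if (length(best) > 1) {
      warning("cluster ", cl, ": marker-score tie between ",
              paste(best, collapse = ", "), "; using alphabetical order")
      best <- sort(best)
    }
    labels[sel] <- best[1]
  }
  stats::setNames(labels, names(clusters) %||% colnames(normexpr))
}
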