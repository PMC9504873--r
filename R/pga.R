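#' Symmetrized k-nearest-neighbour weight matrix
#'
#' Binary, symmetric (union of directed kNN), zero diagonal.
#'
#' @param coords cells x dims coordinates.
#' @param k neighbour count (> 0, < n).
#' @return sparse symmetric dgCMatrix.
#' @export
knn_weights <- function(coords, k) {
  if (k <= 0) stop("k must be positive")
  w <- knn_adjacency(as.matrix(coords), k)
  rownames(w) <- colnames(w) <- rownames(coords)
  w
}

#' Moran's I spatial autocorrelation on a weighted graph
#'
#' `I = (N / sum(W)) * sum_ij w_ij z_i z_j / sum_i z_i^2` with
#' `z = x - mean(x)`; computed exactly.
#'
#' @param x per-cell values.
#' @param w weight matrix (sparse or dense), zero diagonal.
#' @return Moran's I.
#' @export
morans_i <- function(x, w) {
  if (stats::var(x) == 0) stop("Moran's I is undefined for constant input")
  z <- x - mean(x)
  n <- length(z)
  s0 <- sum(w)
  num <- as.numeric(z %*% (w %*% z))
  (n / s0) * num / sum(z^2)
}

#' Gene association with diffusion-map structure (Moran's I screen)
#'
#' Computes Moran's I for each gene over a kNN graph on the embedding
#' coordinates, with an upper-tail permutation p-value (values shuffled over
#' cells) and BH adjustment across genes. Genes with `I > I_min` and
#' adjusted p below `alpha_adj` are flagged as associated; if genotype
#' labels are supplied, associated genes are further labelled trisomic or
#' euploid by point-biserial correlation (see [genotype_direction()]).
#'
#' @param normexpr genes x cells normalized expression.
#' @param coords cells x dims embedding coordinates.
#' @param k kNN graph size (default 15).
#' @param I_min Moran's I threshold (default 0.3).
#' @param alpha_adj adjusted-p threshold (default 0.01).
#' @param n_perm number of permutations (default 999; < 99 warns).
#' @param seed integer seed.
#' @param genotype optional per-cell genotype labels.
#' @param r_min correlation threshold for the direction call.
#' @return data.frame: gene, moran_i, p_value, p_adj, associated, direction.
#' @export
graph_association <- function(normexpr, coords, k = 15, I_min = 0.3,
                              alpha_adj = 0.01, n_perm = 999, seed = 1,
                              genotype = NULL, r_min = 0.1) {
  if (n_perm < 99) warning("n_perm < 99 gives unstable permutation p-values")
  w <- knn_weights(coords, k)
  x <- as.matrix(normexpr)
  n <- ncol(x)
  stopifnot(n == nrow(coords))
  zc <- x - rowMeans(x)
  den <- rowSums(zc^2)
  testable <- den > 0
  s0 <- sum(w)
  obs <- rep(NA_real_, nrow(x))
  moran_num <- function(z) rowSums(as.matrix(z %*% w) * z)
  obs[testable] <- (n / s0) * moran_num(zc[testable, , drop = FALSE]) /
    den[testable]

  set.seed(seed)
  exceed <- integer(sum(testable))
  zt <- zc[testable, , drop = FALSE]
  it <- obs[testable]
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    ib <- (n / s0) * moran_num(zt[, perm, drop = FALSE]) / den[testable]
    exceed <- exceed + (ib >= it)
  }
  p <- rep(NA_real_, nrow(x))
  p[testable] <- (1 + exceed) / (n_perm + 1)
  padj <- rep(NA_real_, nrow(x))
  padj[testable] <- stats::p.adjust(p[testable], method = "BH")
  res <- data.frame(gene = rownames(x), moran_i = obs, p_value = p,
                    p_adj = padj,
                    associated = !is.na(obs) & obs > I_min &
                      !is.na(padj) & padj < alpha_adj,
                    stringsAsFactors = FALSE)
  if (!is.null(genotype)) {
    res$direction <- "none"
    for (i in which(res$associated)) {
      res$direction[i] <- genotype_direction(x[i, ], genotype, r_min = r_min)
    }
  }
  rownames(res) <- NULL
  res
}

#' Genotype direction of an associated gene
#'
#' Point-biserial correlation between a gene's expression and the trisomic
#' indicator: `"trisomic"` if r > r_min, `"euploid"` if r < -r_min, else
#' `"none"`.
#'
#' @param x per-cell expression values.
#' @param genotype per-cell labels.
#' @param r_min correlation threshold (default 0.1).
#' @return one of `"trisomic"`, `"euploid"`, `"none"`.
#' @export
genotype_direction <- function(x, genotype, r_min = 0.1) {
  ind <- as.numeric(genotype == "trisomic")
  if (stats::sd(x) == 0 || stats::sd(ind) == 0) return("none")
  r <- stats::cor(x, ind)
  if (r > r_min) "trisomic" else if (r < -r_min) "euploid" else "none"
}
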