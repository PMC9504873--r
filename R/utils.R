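#' @importFrom Matrix colSums rowSums rowMeans colMeans t sparseMatrix Diagonal
#' @importFrom methods as is
#' @importFrom stats dist prcomp quantile rnbinom runif rbeta rlnorm var sd
#'   pchisq phyper pnorm p.adjust ks.test cor qlnorm plogis setNames
#'   binom.test aggregate
#' @importFrom utils combn write.table read.table
NULL

# Euclidean distances between two coordinate sets (rows), via the
# tcrossprod expansion; clamps tiny negative values from roundoff.
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Full symmetric pairwise distance matrix.
pairwise_dist <- function(x) {
  d <- cross_dist(x, x)
  diag(d) <- 0
  d
}

# k nearest neighbours (excluding self) for each row of x.
# Returns an n x k index matrix.
knn_index <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the number of cells")
  nn <- RANN::nn2(x, k = k + 1L)$nn.idx
  # drop the self column (first hit is the point itself except under ties)
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    row <- nn[i, ]
    row <- row[row != i]
    idx[i, ] <- row[seq_len(k)]
  }
  idx
}

# Symmetrized (union) binary kNN adjacency as a sparse matrix, zero diagonal.
knn_adjacency <- function(x, k) {
  idx <- knn_index(x, k)
  n <- nrow(idx)
  i <- rep(seq_len(n), ncol(idx))
  j <- as.vector(idx)
  a <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  a <- (a + Matrix::t(a) > 0) * 1
  a <- methods::as(a, "CsparseMatrix")
  diag(a) <- 0
  Matrix::drop0(a)
}

# Adjusted Rand index between two labelings.
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Deterministic per-stage seed derived from a global seed; stays well below
# .Machine$integer.max.
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, qc = 211L, embed = 307L, cluster = 401L,
               dex = 503L, dosage = 601L, trajectory = 701L, igd = 809L,
               pga = 907L, report = 1009L)
  if (!stage %in% names(offsets)) {
    stop("unknown stage '", stage, "'; valid stages: ",
         paste(names(offsets), collapse = ", "))
  }
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
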