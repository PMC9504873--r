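#' Estimate the diffusion kernel width
#'
#' Evaluates the dimensionality curve
#' `S(sigma) = mean_i log( (1/n) sum_j exp(-d_ij^2 / (2 sigma^2)) )`
#' over a log-spaced sigma grid spanning the 1st-99th percentile of pairwise
#' distances and returns the sigma at which the discrete derivative
#' `dS / d log(sigma)` is maximal (the steepest point of the curve).
#'
#' @param pcs cells x dims coordinate matrix.
#' @param n_grid grid resolution (default 30).
#' @return the selected sigma (positive scalar).
#' @export
find_sigma <- function(pcs, n_grid = 30) {
  d <- pairwise_dist(as.matrix(pcs))
  find_sigma_d(d, n_grid)
}

find_sigma_d <- function(d, n_grid = 30) {
  dv <- d[upper.tri(d)]
  dv <- dv[dv > 0]
  if (length(dv) == 0) stop("degenerate input: all points are identical")
  lo <- stats::quantile(dv, 0.01)
  hi <- stats::quantile(dv, 0.99)
  if (lo <= 0) lo <- min(dv)
  sig <- exp(seq(log(lo), log(hi), length.out = n_grid))
  d2 <- d^2
  n <- nrow(d)
  s_curve <- vapply(sig, function(s)
    mean(log(rowMeans(exp(-d2 / (2 * s^2))))), numeric(1))
  dS <- diff(s_curve) / diff(log(sig))
  k <- which.max(dS)
  # geometric midpoint of the steepest grid interval
  sqrt(sig[k] * sig[k + 1])
}

#' Diffusion-map embedding
#'
#' Builds a Gaussian kernel `w_ij = exp(-d_ij^2 / (2 (scale_multiplier *
#' sigma)^2))` restricted to the symmetrized k-nearest-neighbour graph,
#' applies density normalization `w_ij / (q_i q_j)` with `q` the kernel row
#' sums, row-normalizes to a Markov matrix, and eigendecomposes via the
#' symmetric conjugate. The leading (constant, eigenvalue 1) component is
#' dropped and the remaining components are scaled by their eigenvalues.
#'
#' If the neighbour graph is disconnected, the largest component is embedded
#' and the remaining cells get NA coordinates (with a warning).
#'
#' @param pcs cells x dims coordinates (typically PCA scores).
#' @param sigma kernel width; estimated with [find_sigma()] when NULL.
#' @param k neighbour count (default 100 for a global map; 25 is the
#'   per-cell-type convention).
#' @param n_components number of non-trivial components to return.
#' @param scale_multiplier kernel width multiplier (default 2).
#' @return list of class `diffusion_map` with `components` (cells x
#'   n_components, eigenvalue-scaled), `eigenvalues`, `lambda0` and `psi0`
#'   (the pre-drop trivial eigenpair), `graph` (sparse symmetric kernel
#'   weights), `sigma`, `k`, and `in_largest_component`.
#' @export
diffusion_map <- function(pcs, sigma = NULL, k = 100, n_components = 20,
                          scale_multiplier = 2) {
  x <- as.matrix(pcs)
  n <- nrow(x)
  if (k >= n) stop("k = ", k, " must be smaller than the number of cells (", n, ")")
  d <- pairwise_dist(x)
  if (is.null(sigma)) sigma <- find_sigma_d(d)
  stopifnot(sigma > 0)
  eps <- scale_multiplier * sigma

  adj <- knn_adjacency(x, k)
  w <- adj * exp(-d^2 / (2 * eps^2))
  w <- methods::as(Matrix::Matrix(w, sparse = TRUE), "CsparseMatrix")
  dimnames(w) <- list(rownames(x), rownames(x))

  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    adj, mode = "undirected"))
  in_main <- comp$membership == which.max(comp$csize)
  if (comp$no > 1) {
    warning("neighbour graph has ", comp$no, " components; embedding the ",
            "largest (", sum(in_main), " of ", n, " cells)")
  }
  wm <- w[in_main, in_main, drop = FALSE]
  q <- Matrix::rowSums(wm)
  q[q == 0] <- 1
  wt <- wm / outer(q, q)            # density normalization (alpha = 1)
  dd <- Matrix::rowSums(wt)
  dsq <- 1 / sqrt(dd)
  s <- methods::as(Matrix::Matrix(wt * outer(dsq, dsq), sparse = TRUE),
                   "CsparseMatrix")  # symmetric conjugate of the Markov matrix

  m <- sum(in_main)
  n_eig <- min(n_components + 1, m)
  if (m <= 400) {
    es <- eigen(as.matrix(s), symmetric = TRUE)
    vals <- es$values[seq_len(n_eig)]
    vecs <- es$vectors[, seq_len(n_eig), drop = FALSE]
  } else {
    ar <- igraph::arpack(function(v, extra) as.numeric(s %*% v),
                         sym = TRUE,
                         options = list(n = m, nev = n_eig,
                                        ncv = min(m, max(3 * n_eig, 30)),
                                        which = "LA", maxiter = 5000))
    ord <- order(ar$values, decreasing = TRUE)
    vals <- ar$values[ord]
    vecs <- ar$vectors[, ord, drop = FALSE]
  }
  # Markov eigenvectors: psi = D^{-1/2} u, scaled so the trivial one is 1
  psi <- vecs * dsq
  psi <- sweep(psi, 2, psi[1, 1] / abs(psi[1, 1]) * sqrt(sum(psi[, 1]^2) / m), "/")
  psi0 <- psi[, 1]
  comps <- sweep(psi[, -1, drop = FALSE], 2, vals[-1], "*")

  components <- matrix(NA_real_, n, ncol(comps),
                       dimnames = list(rownames(x),
                                       paste0("DC", seq_len(ncol(comps)))))
  components[in_main, ] <- comps
  structure(list(components = components,
                 eigenvalues = vals[-1],
                 lambda0 = vals[1], psi0 = psi0,
                 graph = w, sigma = sigma, k = k,
                 scale_multiplier = scale_multiplier,
                 in_largest_component = stats::setNames(in_main, rownames(x))),
            class = "diffusion_map")
}

#' Flood pseudotime from root cells
#'
#' Repeats a stochastic graph "flood" `n_floods` times: each flood starts
#' from a random half of the root cells (step 0); at every subsequent step
#' an unvisited cell becomes visited when at least `min(m, degree)` of its
#' neighbours in the diffusion transition graph are visited. A cell's
#' per-flood time is its visit step divided by the flood's last step;
#' pseudotime is the mean over floods (cells unreached in every flood get
#' NA). Root cells are assigned pseudotime 0.
#'
#' @param dm a [diffusion_map()] result (its `graph` is used), or a sparse
#'   symmetric adjacency/weight matrix.
#' @param roots cell ids (or indices) of the root population.
#' @param n_floods number of floods (default 100).
#' @param m visited-neighbour threshold (default 2).
#' @param root_frac fraction of roots seeding each flood (default 0.5).
#' @param seed integer seed.
#' @return list of class `pseudotime` with `pseudotime` (named, in [0, 1]),
#'   `n_floods`, `roots`.
#' @export
flood_pseudotime <- function(dm, roots, n_floods = 100, m = 2,
                             root_frac = 0.5, seed = 1) {
  g <- if (inherits(dm, "diffusion_map")) dm$graph else dm
  a <- methods::as(Matrix::Matrix(g != 0, sparse = TRUE) * 1, "CsparseMatrix")
  n <- nrow(a)
  ids <- rownames(a) %||% as.character(seq_len(n))
  rownames(a) <- colnames(a) <- ids
  if (is.numeric(roots)) roots <- ids[roots]
  roots <- intersect(as.character(roots), ids)
  if (length(roots) == 0) stop("no root cells found in the graph")
  deg <- Matrix::colSums(a)
  thresh <- pmin(m, pmax(deg, 1))
  root_idx <- match(roots, ids)

  set.seed(seed)
  sum_t <- numeric(n)
  n_reached <- integer(n)
  n_seed <- max(1, round(root_frac * length(root_idx)))
  for (f in seq_len(n_floods)) {
    visited <- logical(n)
    step_at <- rep(NA_integer_, n)
    seeds <- if (length(root_idx) == 1) root_idx else sample(root_idx, n_seed)
    visited[seeds] <- TRUE
    step_at[seeds] <- 0L
    step <- 0L
    repeat {
      cnt <- as.numeric(a %*% visited)
      new <- !visited & cnt >= thresh & cnt > 0
      if (!any(new)) break
      step <- step + 1L
      visited[new] <- TRUE
      step_at[new] <- step
    }
    if (step > 0) {
      t_f <- step_at / step
      got <- !is.na(t_f)
      sum_t[got] <- sum_t[got] + t_f[got]
      n_reached[got] <- n_reached[got] + 1L
    } else {
      got <- !is.na(step_at)
      sum_t[got] <- sum_t[got] + 0
      n_reached[got] <- n_reached[got] + 1L
    }
  }
  if (all(n_reached[-root_idx] == 0) && n > length(root_idx)) {
    stop("no cell outside the roots is reachable; check the graph and m")
  }
  pt <- ifelse(n_reached > 0, sum_t / pmax(n_reached, 1), NA_real_)
  pt[root_idx] <- 0
  structure(list(pseudotime = stats::setNames(pt, ids),
                 n_floods = n_floods, roots = roots, m = m,
                 root_frac = root_frac),
            class = "pseudotime")
}

#' Select root cells near the centre of a cell type's diffusion map
#'
#' Cells of the designated root type whose distance to that type's centroid
#' (on the diffusion components) is within the `frac` quantile.
#'
#' @param dm_components cells x components matrix.
#' @param types per-cell type labels (aligned with rows).
#' @param root_type label of the root population.
#' @param frac distance quantile (default 0.25).
#' @return character vector of root cell ids.
#' @export
root_cells <- function(dm_components, types, root_type, frac = 0.25) {
  sel <- which(types == root_type & !is.na(dm_components[, 1]))
  if (length(sel) == 0) stop("no cells of root type '", root_type, "'")
  x <- dm_components[sel, , drop = FALSE]
  centroid <- colMeans(x)
  d <- sqrt(rowSums(sweep(x, 2, centroid)^2))
  rownames(dm_components)[sel[d <= stats::quantile(d, frac)]]
}

#' Kolmogorov-Smirnov comparison of genotype pseudotime distributions
#'
#' @param pt per-cell pseudotime (NAs dropped).
#' @param genotype per-cell genotype labels (`euploid`/`trisomic`).
#' @return list with `statistic` (D) and `p_value`.
#' @export
ks_pseudotime <- function(pt, genotype) {
  x <- pt[genotype == "euploid"]
  y <- pt[genotype == "trisomic"]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3) {
    stop("need at least 3 non-missing pseudotime values per genotype")
  }
  kt <- suppressWarnings(stats::ks.test(x, y))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}
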