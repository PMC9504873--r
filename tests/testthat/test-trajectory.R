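test_that("kernel width selection is deterministic, scale-equivariant, and sane", {
  set.seed(13)
  x <- matrix(rnorm(200 * 3), ncol = 3)
  s1 <- find_sigma(x)
  expect_identical(s1, find_sigma(x))
  # scale equivariance (up to one log-grid step)
  s3 <- find_sigma(3 * x)
  expect_lt(abs(log(s3 / (3 * s1))), log(1.3))
  # isotropic Gaussian cloud of scale s: selected sigma within [s/2, 2s]
  for (s in c(0.5, 2)) {
    xs <- matrix(rnorm(150 * 3, sd = s), ncol = 3)
    sig <- find_sigma(xs)
    expect_gt(sig, s / 2); expect_lt(sig, 2 * s)
  }
  expect_error(find_sigma(matrix(1, 60, 3)), "degenerate")
})

test_that("diffusion map matches a dense eigendecomposition oracle", {
  set.seed(14)
  x <- matrix(rnorm(60 * 5), ncol = 5)
  rownames(x) <- sprintf("c%02d", 1:60)
  dm <- diffusion_map(x, k = 12, n_components = 6)

  expect_equal(dm$lambda0, 1, tolerance = 1e-10)
  expect_lt(sd(dm$psi0), 1e-10)         # constant trivial eigenvector
  expect_true(all(diff(dm$eigenvalues) <= 1e-12))
  expect_true(all(dm$eigenvalues > 0 & dm$eigenvalues <= 1 + 1e-10))

  # dense oracle built directly from the returned kernel graph
  w <- as.matrix(dm$graph)
  q <- rowSums(w); wt <- w / outer(q, q); p <- wt / rowSums(wt)
  ev <- eigen(p)
  ord <- order(Re(ev$values), decreasing = TRUE)
  vals <- Re(ev$values)[ord]; vecs <- Re(ev$vectors)[, ord]
  expect_equal(dm$eigenvalues, vals[2:7], tolerance = 1e-8)
  for (j in 1:6) {
    v <- vecs[, j + 1]; u <- dm$components[, j]
    v <- v / sqrt(sum(v^2)); u <- u / sqrt(sum(u^2))
    expect_lt(min(max(abs(u - v)), max(abs(u + v))), 1e-8)
  }
})

test_that("iterative and dense eigen solvers agree on larger graphs", {
  set.seed(15)
  x <- matrix(rnorm(450 * 4), ncol = 4)
  rownames(x) <- sprintf("c%03d", 1:450)
  dm <- diffusion_map(x, k = 30, n_components = 5)   # iterative path
  w <- as.matrix(dm$graph)
  q <- rowSums(w); wt <- w / outer(q, q); p <- wt / rowSums(wt)
  ev <- eigen(p)
  vals <- sort(Re(ev$values), decreasing = TRUE)
  expect_equal(dm$eigenvalues, vals[2:6], tolerance = 1e-8)
})

test_that("disconnected graphs embed the largest component with a warning", {
  set.seed(16)
  x <- rbind(matrix(rnorm(50 * 3), ncol = 3),
             matrix(rnorm(10 * 3, mean = 1e4), ncol = 3))
  rownames(x) <- sprintf("c%02d", 1:60)
  expect_warning(dm <- diffusion_map(x, k = 5, n_components = 3,
                                     sigma = 1), "components")
  expect_true(all(is.na(dm$components[51:60, 1])))
  expect_true(all(!is.na(dm$components[1:50, 1])))
})

test_that("flood pseudotime is monotone along a chain and zero at roots", {
  n <- 15
  a <- Matrix::sparseMatrix(i = c(1:(n - 1), 2:n), j = c(2:n, 1:(n - 1)),
                            x = 1, dims = c(n, n))
  rownames(a) <- colnames(a) <- paste0("v", seq_len(n))
  pt <- flood_pseudotime(a, roots = "v1", n_floods = 3, m = 1, seed = 2)
  v <- pt$pseudotime
  expect_equal(unname(v["v1"]), 0)
  expect_true(all(diff(v) > 0))
  expect_equal(unname(v["v15"]), 1)
  expect_error(flood_pseudotime(a, roots = "zz"), "root")
})

test_that("flood pseudotime recovers simulated latent time", {
  cfg <- sim_config(n_genes = 250, n_cells_per_sample = 75, n_cell_types = 3,
                    divergent_types = "type3", divergence_shift = 0,
                    dosage_factor = 1, n_de_genes_per_type = 0,
                    n_marker_genes_per_type = 0, mito_gene_count = 0,
                    low_quality_fraction = 0, seed = 42)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)
  norm <- log_normalize(sim$counts)
  hv <- suppressWarnings(select_hvg(norm, 200))
  pca <- run_pca(norm, hv, n_pcs = 10)
  dm <- diffusion_map(pca$scores, k = 50, n_components = 10)
  roots <- root_cells(dm$components, sim$truth$true_type, "type1")
  pt <- flood_pseudotime(dm, roots, n_floods = 50, seed = 3)
  rho <- cor(pt$pseudotime, sim$truth$latent_time[names(pt$pseudotime)],
             method = "spearman", use = "complete.obs")
  expect_gt(abs(rho), 0.8)
  expect_true(all(pt$pseudotime[roots] == 0))
  expect_true(all(pt$pseudotime >= 0 & pt$pseudotime <= 1, na.rm = TRUE))

  # the average over floods stabilizes across seeds
  pt2 <- flood_pseudotime(dm, roots, n_floods = 50, seed = 99)
  d <- abs(pt$pseudotime - pt2$pseudotime)
  expect_lt(stats::median(d, na.rm = TRUE), 0.05)
})

test_that("KS comparison matches the ECDF-supremum oracle", {
  # disjoint supports give the maximal statistic
  disj <- ks_pseudotime(c(0.1, 0.2, 0.15, 0.8, 0.9, 0.85),
                        rep(c("euploid", "trisomic"), each = 3))
  expect_equal(disj$statistic, 1)

  same <- ks_pseudotime(rep(c(0.3, 0.5, 0.7), 2),
                        rep(c("euploid", "trisomic"), each = 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # brute-force sup|ECDF1 - ECDF2| on random instances
  set.seed(17)
  for (r in 1:25) {
    x <- runif(sample(5:40, 1)); y <- runif(sample(5:40, 1))
    res <- ks_pseudotime(c(x, y), rep(c("euploid", "trisomic"),
                                      c(length(x), length(y))))
    grid <- sort(c(x, y))
    oracle <- max(abs(ecdf(x)(grid) - ecdf(y)(grid)))
    expect_equal(res$statistic, oracle, tolerance = 1e-12)
  }
  expect_error(ks_pseudotime(c(0.1, 0.2, NA, 0.3),
                             c("euploid", "euploid", "euploid", "trisomic")),
               "at least 3")
})
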