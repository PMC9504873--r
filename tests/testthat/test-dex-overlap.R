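# Brute-force BH step-up oracle used against the package's adjusted p-values.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

make_detection_fixture <- function(d1, n1, d2, n2, gene = "gX") {
  # one gene, one cluster; detection counts set exactly
  x <- c(rep(1, d1), rep(0, n1 - d1), rep(1, d2), rep(0, n2 - d2))
  m <- Matrix::Matrix(matrix(x, nrow = 1,
                             dimnames = list(gene,
                                             sprintf("c%03d", seq_along(x)))),
                      sparse = TRUE)
  cells <- data.frame(cell_id = colnames(m),
                      genotype = rep(c("trisomic", "euploid"), c(n1, n2)))
  list(norm = m, cells = cells, clusters = rep("k0", n1 + n2))
}

test_that("binomial detection LRT matches direct log-likelihood evaluation", {
  fx <- make_detection_fixture(9, 10, 1, 10)
  res <- binomial_dex(fx$norm, fx$cells, fx$clusters, min_pct = 0.25)
  # oracle: evaluate the binomial log-likelihoods explicitly
  ll <- function(d, n, p) d * log(p) + (n - d) * log(1 - p)
  oracle <- 2 * (ll(9, 10, 0.9) + ll(1, 10, 0.1) - ll(9, 10, 0.5) -
                   ll(1, 10, 0.5))
  expect_equal(res$lrt_stat, oracle, tolerance = 1e-12)
  expect_equal(res$lrt_stat, 14.7224, tolerance = 1e-3)
  expect_lt(res$p_value, 2e-4)
  expect_gt(res$log2fc, 0)
  expect_identical(res$direction, "up")

  # equal detection rates -> statistic 0, p 1
  fx2 <- make_detection_fixture(5, 10, 5, 10)
  res2 <- binomial_dex(fx2$norm, fx2$cells, fx2$clusters)
  expect_equal(res2$lrt_stat, 0)
  expect_equal(res2$p_value, 1)

  # below the detection floor in both genotypes -> not tested
  fx3 <- make_detection_fixture(2, 10, 2, 10)
  expect_identical(nrow(binomial_dex(fx3$norm, fx3$cells, fx3$clusters)), 0L)

  # too few cells in one genotype -> cluster skipped with a warning
  fx4 <- make_detection_fixture(2, 2, 5, 10)
  expect_warning(binomial_dex(fx4$norm, fx4$cells, fx4$clusters), "skipped")
})

test_that("binomial test is calibrated and BH matches the step-up oracle", {
  set.seed(21)
  n_genes <- 120; n1 <- n2 <- 40
  counts <- matrix(rpois(n_genes * (n1 + n2), 1.2), nrow = n_genes,
                   dimnames = list(sprintf("g%03d", 1:n_genes),
                                   sprintf("c%03d", 1:(n1 + n2))))
  norm <- log_normalize(Matrix::Matrix(counts + rbinom(length(counts), 1, 0.05),
                                       sparse = TRUE))
  cells <- data.frame(cell_id = colnames(norm),
                      genotype = rep(c("trisomic", "euploid"), c(n1, n2)))
  res <- binomial_dex(norm, cells, rep("k0", n1 + n2), min_pct = 0.25)
  expect_gt(nrow(res), 50)
  # null data: raw rejections near nominal, BH equals the oracle
  expect_lt(mean(res$p_value < 0.05), 0.12)
  expect_equal(res$p_adj, bh_oracle(res$p_value), tolerance = 1e-12)

  # type-I error across replicates stays near the chi-square nominal level
  set.seed(22)
  rates <- replicate(30, {
    d1 <- rbinom(50, 40, 0.5); d2 <- rbinom(50, 40, 0.5)
    stat <- scDivergence:::binom_lrt_stat(d1, 40, d2, 40)
    mean(pchisq(stat, 1, lower.tail = FALSE) < 0.05)
  })
  expect_lt(mean(rates), 0.08)
})

test_that("hypergeometric enrichment reports exact fold enrichment", {
  universe <- sprintf("u%02d", 1:20)
  query <- universe[1:10]
  sets <- list(same = query, other = universe[11:20],
               half = universe[6:15])
  res <- enrichment_hypergeom(query, sets, universe, fdr = 0.05)
  expect_equal(res$fold_enrichment[res$set == "same"], 2)
  expect_equal(res$fold_enrichment[res$set == "other"], 0)
  expect_equal(res$p_value[res$set == "other"], 1)
  expect_identical(res$set[1], "same")  # sorted by fold enrichment
  expect_true(res$enriched[res$set == "same"])
  expect_error(enrichment_hypergeom(c("zz"), sets, universe), "universe")
  expect_error(enrichment_hypergeom(query, sets, character(0)), "empty")
})

test_that("overlap test reproduces exact enumeration and resampling", {
  u <- sprintf("u%02d", 1:10)
  res <- overlap_test(u[1:5], u[1:5], u)
  expect_equal(res$p_value, 1 / 252, tolerance = 1e-12)
  expect_identical(res$overlap, 5L)

  # zero overlap has upper-tail probability 1
  res0 <- overlap_test(u[1:5], u[6:10], u)
  expect_equal(res0$p_value, 1)

  # Monte-Carlo resampling oracle on random instances
  set.seed(31)
  for (r in 1:5) {
    nu <- 30; na <- sample(5:15, 1); nb <- sample(5:15, 1)
    uni <- sprintf("x%02d", 1:nu)
    a <- sample(uni, na); b <- sample(uni, nb)
    res <- overlap_test(a, b, uni)
    draws <- replicate(4000, length(intersect(sample(uni, na), b)))
    mc <- mean(draws >= res$overlap)
    se <- sqrt(mc * (1 - mc) / 4000)
    expect_lt(abs(res$p_value - mc), 3 * se + 1e-8)
  }
  expect_error(overlap_test(c("nope"), u[1:2], u), "universe")
})

test_that("venn region counts reconcile with list sizes", {
  vc <- venn_counts(list(A = c("x", "y"), B = c("y", "z")))
  expect_identical(vc$count[vc$region == "A"], 1L)
  expect_identical(vc$count[vc$region == "B"], 1L)
  expect_identical(vc$count[vc$region == "A&B"], 1L)

  same <- replicate(4, sprintf("g%d", 1:7), simplify = FALSE)
  names(same) <- LETTERS[1:4]
  vc4 <- venn_counts(same)
  expect_identical(nrow(vc4), 1L)
  expect_identical(vc4$region, "A&B&C&D")
  expect_identical(vc4$count, 7L)

  # per-list conservation
  set.seed(5)
  lists <- list(A = sample(letters, 10), B = sample(letters, 12),
                C = sample(letters, 8))
  vc3 <- venn_counts(lists)
  for (nm in names(lists)) {
    in_region <- grepl(paste0("(^|&)", nm, "($|&)"), vc3$region)
    expect_identical(sum(vc3$count[in_region]), length(unique(lists[[nm]])))
  }
})
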