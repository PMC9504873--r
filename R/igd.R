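#' Observed inter-genotype distance
#'
#' Mean Euclidean distance over all trisomic x euploid cell pairs in the
#' given coordinate space (typically diffusion components of one cell type).
#'
#' @param coords cells x components coordinate matrix.
#' @param genotype per-cell labels (`euploid`/`trisomic`), aligned to rows.
#' @return the oIGD (non-negative scalar).
#' @export
observed_igd <- function(coords, genotype) {
  coords <- as.matrix(coords)
  tri <- genotype == "trisomic"
  eu <- genotype == "euploid"
  if (!any(tri) || !any(eu)) {
    stop("both genotypes must be present to compute an inter-genotype distance")
  }
  mean(cross_dist(coords[tri, , drop = FALSE], coords[eu, , drop = FALSE]))
}

# oIGD from a precomputed full distance matrix and a logical trisomic mask.
igd_from_dist <- function(d, tri) {
  mean(d[tri, !tri, drop = FALSE])
}

#' Permutation null for the inter-genotype distance
#'
#' Shuffles genotype labels (preserving group sizes) and recomputes the IGD
#' to form the expected-IGD (eIGD) null sample. When the number of distinct
#' labelings `choose(n, n_trisomic)` is at most `exhaustive_limit`, all
#' labelings are enumerated and the p-value is the exact proportion of
#' labelings with eIGD >= oIGD; otherwise `B` Monte-Carlo shuffles are drawn
#' and the add-one estimator `(1 + #{eIGD >= oIGD}) / (B + 1)` is used.
#'
#' @param coords cells x components coordinates.
#' @param genotype per-cell labels.
#' @param B number of Monte-Carlo permutations (default 1000).
#' @param seed integer seed.
#' @param exhaustive_limit labeling-count bound for exact enumeration.
#' @return list with `oigd`, `eigd` (null sample), `p_value`, `method`
#'   (`"exhaustive"` or `"monte-carlo"`), `B`, `seed`.
#' @export
permutation_null <- function(coords, genotype, B = 1000, seed = 1,
                             exhaustive_limit = 10000) {
  if (B < 1) stop("B must be at least 1")
  coords <- as.matrix(coords)
  n <- nrow(coords)
  tri <- genotype == "trisomic"
  eu <- genotype == "euploid"
  if (!any(tri) || !any(eu)) stop("both genotypes must be present")
  d <- pairwise_dist(coords)
  oigd <- igd_from_dist(d, tri)
  n_tri <- sum(tri)
  if (choose(n, n_tri) <= exhaustive_limit) {
    labelings <- utils::combn(n, n_tri)
    eigd <- apply(labelings, 2, function(ix) {
      mask <- logical(n); mask[ix] <- TRUE
      igd_from_dist(d, mask)
    })
    p <- sum(eigd >= oigd - 1e-12) / length(eigd)
    method <- "exhaustive"
  } else {
    set.seed(seed)
    eigd <- vapply(seq_len(B), function(b) {
      mask <- logical(n); mask[sample.int(n, n_tri)] <- TRUE
      igd_from_dist(d, mask)
    }, numeric(1))
    p <- (1 + sum(eigd >= oigd)) / (B + 1)
    method <- "monte-carlo"
  }
  list(oigd = oigd, eigd = eigd, p_value = p, method = method, B = B,
       seed = seed)
}

#' Normalize IGD values by the euploid-pair distance
#'
#' The normalizer is the mean Euclidean distance over all unique euploid
#' cell pairs; it is applied to the observed IGD and to every null eIGD,
#' making values comparable across cell types.
#'
#' @param oigd observed IGD.
#' @param eigd null eIGD sample (may be NULL).
#' @param coords,genotype the coordinates and labels the IGD was computed on.
#' @return list with `normalizer`, `normalized_oigd`, `normalized_eigd`.
#' @export
normalize_igd <- function(oigd, eigd, coords, genotype) {
  coords <- as.matrix(coords)
  eu <- which(genotype == "euploid")
  if (length(eu) < 2) stop("need at least 2 euploid cells to normalize")
  d <- cross_dist(coords[eu, , drop = FALSE], coords[eu, , drop = FALSE])
  normalizer <- mean(d[upper.tri(d)])
  if (normalizer == 0) stop("all euploid cells are coincident; normalizer is 0")
  list(normalizer = normalizer, normalized_oigd = oigd / normalizer,
       normalized_eigd = if (is.null(eigd)) NULL else eigd / normalizer)
}

#' Full IGD test for one cell population
#'
#' Convenience wrapper: observed IGD, permutation null, p-value, and
#' euploid-pair normalization.
#'
#' @inheritParams permutation_null
#' @return list of class `igd_result`.
#' @export
igd_test <- function(coords, genotype, B = 1000, seed = 1) {
  pn <- permutation_null(coords, genotype, B = B, seed = seed)
  nz <- normalize_igd(pn$oigd, pn$eigd, coords, genotype)
  structure(c(pn, nz,
              list(n_trisomic = sum(genotype == "trisomic"),
                   n_euploid = sum(genotype == "euploid"))),
            class = "igd_result")
}

#' Rank cell types by inter-genotype divergence
#'
#' Runs [igd_test()] on each cell type's coordinates and orders the results
#' by p-value (ascending), breaking ties by normalized oIGD (descending).
#' Types missing a genotype are skipped with a warning. The significance
#' flag uses p < 0.001.
#'
#' @param coords_by_type named list of per-type coordinate matrices.
#' @param genotype_by_type named list of matching genotype label vectors.
#' @param B permutations per type.
#' @param seed integer seed (per-type seeds are derived from it).
#' @param p_signif significance threshold for the flag (default 0.001).
#' @return data.frame: cell_type, n_euploid, n_trisomic, oigd, normalizer,
#'   normalized_oigd, p_value, significant; attribute `details` holds the
#'   per-type `igd_result` objects.
#' @export
rank_cell_types <- function(coords_by_type, genotype_by_type, B = 1000,
                            seed = 1, p_signif = 0.001) {
  stopifnot(identical(names(coords_by_type), names(genotype_by_type)))
  details <- list()
  rows <- list()
  for (i in seq_along(coords_by_type)) {
    ty <- names(coords_by_type)[i]
    gt <- genotype_by_type[[i]]
    if (!any(gt == "trisomic") || !any(gt == "euploid")) {
      warning("cell type '", ty, "' skipped: one genotype is missing")
      next
    }
    res <- igd_test(coords_by_type[[i]], gt, B = B,
                    seed = seed + i)
    details[[ty]] <- res
    rows[[ty]] <- data.frame(cell_type = ty, n_euploid = res$n_euploid,
                             n_trisomic = res$n_trisomic, oigd = res$oigd,
                             normalizer = res$normalizer,
                             normalized_oigd = res$normalized_oigd,
                             p_value = res$p_value,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no cell type had both genotypes")
  out <- out[order(out$p_value, -out$normalized_oigd), ]
  out$significant <- out$p_value < p_signif
  rownames(out) <- NULL
  attr(out, "details") <- details
  out
}

#' Per-cell-type diffusion maps and IGD ranking
#'
#' For each cell type: select HVGs within the type, run PCA, fit a diffusion
#' map (per-type neighbour convention k = 25), and compute the IGD
#' permutation test on the diffusion components. Types with fewer than
#' `min_cells` cells, or with a missing genotype, are skipped with a
#' warning.
#'
#' @param normexpr genes x cells normalized expression.
#' @param cells metadata with `genotype`.
#' @param cell_types per-cell type labels.
#' @param n_hvg HVGs per type (default 500).
#' @param n_pcs PCs per type (default 20).
#' @param k diffusion neighbour count within type (default 25).
#' @param n_components diffusion components retained (default 20).
#' @param B,seed permutation settings.
#' @param min_cells minimum cells per type.
#' @return the [rank_cell_types()] table; attribute `dms` holds the
#'   per-type diffusion maps.
#' @export
celltype_igd <- function(normexpr, cells, cell_types, n_hvg = 500,
                         n_pcs = 20, k = 25, n_components = 20, B = 1000,
                         seed = 1, min_cells = 20) {
  coords <- list(); gts <- list(); dms <- list()
  for (ty in sort(unique(cell_types))) {
    sel <- which(cell_types == ty)
    if (length(sel) < min_cells) {
      warning("cell type '", ty, "' skipped: fewer than ", min_cells, " cells")
      next
    }
    sub <- normexpr[, sel, drop = FALSE]
    hv <- suppressWarnings(select_hvg(sub, n = n_hvg))
    npc <- min(n_pcs, length(hv), length(sel) - 1)
    pca <- run_pca(sub, hv, n_pcs = npc)
    dm <- suppressWarnings(diffusion_map(pca$scores,
                                         k = min(k, length(sel) - 1),
                                         n_components = n_components))
    ok <- dm$in_largest_component
    coords[[ty]] <- dm$components[ok, , drop = FALSE]
    gts[[ty]] <- cells$genotype[sel][ok]
    dms[[ty]] <- dm
  }
  if (length(coords) == 0) stop("no cell type large enough for IGD analysis")
  out <- rank_cell_types(coords, gts, B = B, seed = seed)
  attr(out, "dms") <- dms
  out
}
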