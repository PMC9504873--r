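#' Per-cluster genotype differential expression (binomial detection test)
#'
#' Within each cluster, compares the per-gene detection rate (fraction of
#' cells with nonzero expression) between trisomic and euploid cells with a
#' likelihood-ratio test of equal binomial proportions (chi-squared with one
#' degree of freedom). Only genes detected in at least `min_pct` of cells in
#' either genotype are tested; BH adjustment is applied within each
#' cluster's tested genes. The reported log2 fold change is computed on
#' normalized expression: `log2((mean(expm1(x_tri)) + 1) /
#' (mean(expm1(x_eu)) + 1))`.
#'
#' @param normexpr genes x cells log-normalized expression.
#' @param cells metadata with a `genotype` column (`euploid`/`trisomic`).
#' @param clusters per-cell cluster (or cell-type) labels.
#' @param min_pct detection floor (default 0.25).
#' @param alpha_adj adjusted-p significance threshold (default 0.1).
#' @param min_cells minimum cells per genotype within a cluster; clusters
#'   below it are skipped with a warning.
#' @return data.frame of per-gene results across clusters.
#' @export
binomial_dex <- function(normexpr, cells, clusters, min_pct = 0.25,
                         alpha_adj = 0.1, min_cells = 3) {
  stopifnot(ncol(normexpr) == nrow(cells), length(clusters) == nrow(cells))
  out <- list()
  for (cl in sort(unique(clusters))) {
    sel <- clusters == cl
    tri <- sel & cells$genotype == "trisomic"
    eu <- sel & cells$genotype == "euploid"
    if (sum(tri) < min_cells || sum(eu) < min_cells) {
      warning("cluster '", cl, "' skipped: fewer than ", min_cells,
              " cells in one genotype")
      next
    }
    n1 <- sum(tri); n2 <- sum(eu)
    d1 <- Matrix::rowSums(normexpr[, tri, drop = FALSE] > 0)
    d2 <- Matrix::rowSums(normexpr[, eu, drop = FALSE] > 0)
    p1 <- d1 / n1; p2 <- d2 / n2
    test <- pmax(p1, p2) >= min_pct
    if (!any(test)) next
    stat <- binom_lrt_stat(d1[test], n1, d2[test], n2)
    pval <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    m1 <- Matrix::rowMeans(expm1(normexpr[test, tri, drop = FALSE]))
    m2 <- Matrix::rowMeans(expm1(normexpr[test, eu, drop = FALSE]))
    lfc <- log2((m1 + 1) / (m2 + 1))
    out[[as.character(cl)]] <- data.frame(
      gene = rownames(normexpr)[test], cluster = cl,
      pct_trisomic = p1[test], pct_euploid = p2[test],
      log2fc = lfc, lrt_stat = stat, p_value = pval,
      p_adj = stats::p.adjust(pval, method = "BH"),
      direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none")),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene = character(0), cluster = character(0),
                      pct_trisomic = numeric(0), pct_euploid = numeric(0),
                      log2fc = numeric(0), lrt_stat = numeric(0),
                      p_value = numeric(0), p_adj = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE)
  }
  res$significant <- res$p_adj < alpha_adj
  rownames(res) <- NULL
  res
}

# Likelihood-ratio statistic for equal binomial detection probabilities;
# 0 * log(0) terms are defined as 0.
binom_lrt_stat <- function(d1, n1, d2, n2) {
  ll <- function(d, n, p) {
    t1 <- ifelse(d == 0, 0, d * log(p))
    t2 <- ifelse(n - d == 0, 0, (n - d) * log(1 - p))
    t1 + t2
  }
  p1 <- d1 / n1; p2 <- d2 / n2; pp <- (d1 + d2) / (n1 + n2)
  2 * (ll(d1, n1, p1) + ll(d2, n2, p2) - ll(d1, n1, pp) - ll(d2, n2, pp))
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of each gene set against a query list,
#' with BH adjustment across sets. Fold enrichment is the ratio of the hit
#' fraction in the query to the set's fraction of the universe; results are
#' sorted by fold enrichment.
#'
#' @param genes query gene list (must be a subset of `universe`).
#' @param gene_sets named list of gene sets.
#' @param universe background gene list.
#' @param fdr BH threshold for the `enriched` flag (default 0.05).
#' @return data.frame: set, set_size, hits, fold_enrichment, p_value, p_adj,
#'   enriched.
#' @export
enrichment_hypergeom <- function(genes, gene_sets, universe, fdr = 0.05) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  bad <- setdiff(genes, universe)
  if (length(bad) > 0) {
    stop("query genes outside the universe: ", paste(utils::head(bad, 5),
                                                     collapse = ", "))
  }
  genes <- unique(genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    hits <- length(intersect(genes, set))
    p <- stats::phyper(hits - 1, length(set), length(universe) - length(set),
                       length(genes), lower.tail = FALSE)
    fold <- if (length(set) == 0 || length(genes) == 0) 0 else
      (hits / length(genes)) / (length(set) / length(universe))
    data.frame(set = nm, set_size = length(set), hits = hits,
               fold_enrichment = fold, p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
  res$enriched <- res$p_adj < fdr
  res <- res[order(-res$fold_enrichment, res$p_value), ]
  rownames(res) <- NULL
  res
}

#' Exact hypergeometric overlap test for two gene lists
#'
#' Upper-tail probability of observing at least the given overlap between
#' two lists drawn from a common universe.
#'
#' @param list_a,list_b gene lists (subsets of `universe`).
#' @param universe background gene list.
#' @return list with n_universe, n_a, n_b, overlap, p_value.
#' @export
overlap_test <- function(list_a, list_b, universe) {
  universe <- unique(universe)
  list_a <- unique(list_a); list_b <- unique(list_b)
  bad <- c(setdiff(list_a, universe), setdiff(list_b, universe))
  if (length(bad) > 0) {
    stop("list members outside the universe: ",
         paste(utils::head(unique(bad), 5), collapse = ", "))
  }
  ov <- length(intersect(list_a, list_b))
  p <- stats::phyper(ov - 1, length(list_a),
                     length(universe) - length(list_a), length(list_b),
                     lower.tail = FALSE)
  list(n_universe = length(universe), n_a = length(list_a),
       n_b = length(list_b), overlap = ov, p_value = p)
}

#' Region counts for a Venn diagram of gene lists
#'
#' @param lists named list (>= 2) of gene vectors.
#' @return data.frame with one row per non-empty membership pattern:
#'   `region` (names joined by `&`) and `count` of elements belonging to
#'   exactly those lists.
#' @export
venn_counts <- function(lists) {
  stopifnot(length(lists) >= 2, !is.null(names(lists)))
  lists <- lapply(lists, unique)
  all_genes <- unique(unlist(lists))
  memb <- sapply(lists, function(l) all_genes %in% l)
  if (length(all_genes) == 1) memb <- matrix(memb, nrow = 1,
                                             dimnames = list(NULL, names(lists)))
  pattern <- apply(memb, 1, function(r) paste(names(lists)[r], collapse = "&"))
  tab <- table(pattern)
  data.frame(region = names(tab), count = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}
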