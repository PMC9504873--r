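#' Binned genomic coverage of expression per sample
#'
#' Assigns each positioned gene to the fixed-width genomic window containing
#' its start (windows `[w*W+1, (w+1)*W]`, 0-based index `w`) and sums raw
#' counts per sample within each window. Totals are also reported as counts
#' per million of the sample's positioned-gene total, so coverage profiles
#' are comparable across sequencing depths.
#'
#' @param counts genes x cells raw counts.
#' @param cells per-cell metadata with a `sample` column.
#' @param annotation gene annotation with chromosome and start.
#' @param window_bp window width in bp (default 5e6).
#' @param chrom_lengths optional named vector of chromosome lengths; genes
#'   starting beyond the declared length are warned about and clamped into
#'   the last window.
#' @return data.frame with chromosome, window (0-based), sample, total, cpm.
#' @export
bin_coverage <- function(counts, cells, annotation, window_bp = 5e6,
                         chrom_lengths = NULL) {
  ann <- annotation[match(rownames(counts), annotation$gene_id), ]
  if (anyNA(ann$start)) stop("annotation lacks positions for some genes")
  win <- (ann$start - 1) %/% window_bp
  if (!is.null(chrom_lengths)) {
    last_win <- (chrom_lengths[ann$chromosome] - 1) %/% window_bp
    over <- !is.na(last_win) & win > last_win
    if (any(over)) {
      warning(sum(over), " gene(s) start beyond the declared chromosome ",
              "length; clamped to the last window")
      win[over] <- last_win[over]
    }
  }
  samples <- unique(cells$sample)
  pb <- sapply(samples, function(s)
    Matrix::rowSums(counts[, cells$sample == s, drop = FALSE]))
  key <- paste(ann$chromosome, win, sep = ":")
  out <- do.call(rbind, lapply(seq_along(samples), function(j) {
    tot <- tapply(pb[, j], key, sum)
    parts <- do.call(rbind, strsplit(names(tot), ":", fixed = TRUE))
    data.frame(chromosome = parts[, 1], window = as.integer(parts[, 2]),
               sample = samples[j], total = as.numeric(tot),
               cpm = as.numeric(tot) / sum(pb[, j]) * 1e6,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chromosome, out$window, out$sample), ]
  rownames(out) <- NULL
  out
}

#' Per-window trisomic/euploid coverage ratio
#'
#' @param profile output of [bin_coverage()].
#' @param sample_genotypes named character vector mapping sample to genotype
#'   (`"euploid"` / `"trisomic"`).
#' @return data.frame with chromosome, window, ratio (mean trisomic CPM over
#'   mean euploid CPM).
#' @export
coverage_ratio <- function(profile, sample_genotypes) {
  gt <- sample_genotypes[profile$sample]
  key <- paste(profile$chromosome, profile$window, sep = ":")
  mean_by <- function(sel) tapply(profile$cpm[sel], key[sel], mean)
  tri <- mean_by(gt == "trisomic")
  eu <- mean_by(gt == "euploid")
  common <- intersect(names(tri), names(eu))
  parts <- do.call(rbind, strsplit(common, ":", fixed = TRUE))
  out <- data.frame(chromosome = parts[, 1], window = as.integer(parts[, 2]),
                    ratio = as.numeric(tri[common] / eu[common]),
                    stringsAsFactors = FALSE)
  out[order(out$chromosome, out$window), ]
}

#' Pseudobulk per-chromosome differential-expression tallies
#'
#' Sums counts per sample, then tests each gene for a genotype difference
#' with a simplified negative-binomial Wald test: per-group means are
#' estimated on depth-normalized (CPM) counts, a common dispersion is
#' estimated across genes by the method of moments, and the Wald statistic
#' compares the log ratio of group means. BH-adjusted significant genes are
#' tallied per chromosome as up- (higher trisomic mean) or downregulated.
#'
#' @param counts genes x cells raw counts.
#' @param cells metadata with `sample` and `genotype` columns.
#' @param annotation annotation giving each gene's chromosome.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @return list with `genes` (per-gene table) and `summary`
#'   (per-chromosome up/down tallies), plus the dispersion used.
#' @export
pseudobulk_chrom_dex <- function(counts, cells, annotation, alpha = 0.05) {
  samples <- unique(cells$sample)
  gt <- vapply(samples, function(s)
    unique(cells$genotype[cells$sample == s])[1], character(1))
  if (sum(gt == "trisomic") < 2 || sum(gt == "euploid") < 2) {
    stop("need at least 2 samples per genotype for pseudobulk testing")
  }
  pb <- sapply(samples, function(s)
    Matrix::rowSums(counts[, cells$sample == s, drop = FALSE]))
  nonzero <- rowSums(pb) > 0
  pb <- pb[nonzero, , drop = FALSE]
  depth <- colSums(pb) / 1e6  # CPM scale: mu_ij = q_g(group) * depth_j
  tri <- which(gt == "trisomic"); eu <- which(gt == "euploid")

  q_hat <- function(cols) rowSums(pb[, cols, drop = FALSE]) / sum(depth[cols])
  q1 <- q_hat(tri); q0 <- q_hat(eu)

  # method-of-moments common dispersion from within-group residuals;
  # the n/(n-1) factor undoes the df lost to the fitted group mean
  resid2 <- function(cols, q) {
    mu <- outer(q, depth[cols])
    n_s <- length(cols)
    list(r2 = n_s / (n_s - 1) * rowSums((pb[, cols, drop = FALSE] - mu)^2) -
           rowSums(mu),
         m2 = rowSums(mu^2))
  }
  a <- resid2(tri, q1); b <- resid2(eu, q0)
  # unweighted mean of per-gene estimates: robust to a few very
  # high-expression genes dominating a pooled (mu^2-weighted) estimate
  u <- (a$r2 + b$r2) / (a$m2 + b$m2)
  u <- u[is.finite(u)]
  phi <- max(mean(u), 0)

  # score-type test: the difference of group means standardized by its
  # NB variance evaluated at the pooled (null) mean, which keeps the
  # statistic calibrated with few samples per group
  q_pool <- q_hat(c(tri, eu))
  var_q0 <- function(cols) {
    mu <- outer(q_pool, depth[cols])
    rowSums(mu + phi * mu^2) / sum(depth[cols])^2
  }
  v1 <- var_q0(tri); v0 <- var_q0(eu)
  ok <- q_pool > 0
  lfc <- log2(q1 / q0)
  z <- ifelse(ok, (q1 - q0) / sqrt(v1 + v0), NA)
  p <- 2 * stats::pnorm(-abs(z))
  padj <- rep(NA_real_, length(p))
  padj[ok] <- stats::p.adjust(p[ok], method = "BH")

  chrom <- annotation$chromosome[match(rownames(pb), annotation$gene_id)]
  genes <- data.frame(gene_id = rownames(pb), chromosome = chrom,
                      mean_trisomic_cpm = q1, mean_euploid_cpm = q0,
                      log2fc = lfc, p_value = p, p_adj = padj,
                      row.names = NULL, stringsAsFactors = FALSE)
  sig <- !is.na(genes$p_adj) & genes$p_adj < alpha
  up <- sig & genes$log2fc > 0
  down <- sig & genes$log2fc < 0
  summary <- data.frame(chromosome = sort(unique(chrom)),
                        stringsAsFactors = FALSE)
  summary$n_tested <- as.integer(table(chrom)[summary$chromosome])
  summary$n_up <- vapply(summary$chromosome, function(ch)
    sum(up & chrom == ch), integer(1))
  summary$n_down <- vapply(summary$chromosome, function(ch)
    sum(down & chrom == ch), integer(1))
  list(genes = genes, summary = summary, dispersion = phi, alpha = alpha)
}
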