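#' Configuration for the two-genotype scRNA-seq simulator
#'
#' Builds and validates the parameter set that drives [simulate_annotation()]
#' and [simulate_counts()]. The defaults emulate a two-genotype (euploid vs
#' trisomic), two-samples-per-genotype cortical differentiation experiment:
#' seven cell types ordered along a latent differentiation axis, a 1.5x
#' expression dosage on genes of one designated "trisomic" chromosome, one
#' divergent cell type whose trisomic cells lag along the latent axis, a small
#' set of per-type differentially expressed genes, and per-cell mitochondrial
#' read fractions mostly inside 1-10% with outlier tails so that quality
#' control has something to remove.
#'
#' @param n_genes number of nuclear genes (mitochondrial genes are extra).
#' @param n_cells_per_sample cells simulated per sample.
#' @param n_samples_per_genotype samples per genotype (>= 1).
#' @param n_cell_types number of cell types placed along the latent axis.
#'   With 7 types the canonical labels aRGC, IPC, ExN1..ExN4, InN are used;
#'   otherwise labels are type1..typeN.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param trisomic_chrom label of the triplicated chromosome; must be one of
#'   `names(chrom_lengths)`.
#' @param dosage_factor multiplicative dosage on trisomic-chromosome genes in
#'   trisomic cells (1.5 for a triplication).
#' @param divergent_types cell types whose trisomic cells are shifted along
#'   the latent axis.
#' @param divergence_shift latent-time lag (in [0, 1]) applied to trisomic
#'   cells of divergent types.
#' @param n_de_genes_per_type number of genes per cell type given an extra
#'   genotype effect in that type.
#' @param de_log2fc log2 fold change applied to those genes in trisomic cells.
#' @param mito_gene_count number of genes on the dedicated "MT" contig.
#' @param nb_dispersion negative-binomial dispersion phi (variance
#'   mu + phi * mu^2) shared across genes.
#' @param library_size_mean mean library size (total counts) per good cell.
#' @param library_size_sdlog log-scale SD of library sizes.
#' @param low_quality_fraction fraction of cells given very small libraries
#'   (they fall below the detected-gene QC threshold).
#' @param n_marker_genes_per_type marker genes upregulated in each type.
#' @param marker_log2fc log2 fold change of marker genes in their own type.
#' @param n_traj_genes genes whose expression follows a smooth (sigmoidal)
#'   program along the latent axis.
#' @param seed integer seed; identical configurations give identical data.
#'
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_cells_per_sample = 250L,
                       n_samples_per_genotype = 2L,
                       n_cell_types = 7L,
                       chrom_lengths = c("1" = 120e6, "2" = 100e6, "3" = 80e6,
                                         "4" = 60e6, "5" = 40e6, "21" = 20e6),
                       trisomic_chrom = "21",
                       dosage_factor = 1.5,
                       divergent_types = "ExN4",
                       divergence_shift = 0.3,
                       n_de_genes_per_type = 20L,
                       de_log2fc = 1,
                       mito_gene_count = 13L,
                       nb_dispersion = 0.1,
                       library_size_mean = 10000,
                       library_size_sdlog = 0.3,
                       low_quality_fraction = 0.08,
                       n_marker_genes_per_type = 25L,
                       marker_log2fc = 2,
                       n_traj_genes = 300L,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_cells_per_sample = as.integer(n_cells_per_sample),
              n_samples_per_genotype = as.integer(n_samples_per_genotype),
              n_cell_types = as.integer(n_cell_types),
              chrom_lengths = chrom_lengths,
              trisomic_chrom = as.character(trisomic_chrom),
              dosage_factor = dosage_factor,
              divergent_types = as.character(divergent_types),
              divergence_shift = divergence_shift,
              n_de_genes_per_type = as.integer(n_de_genes_per_type),
              de_log2fc = de_log2fc,
              mito_gene_count = as.integer(mito_gene_count),
              nb_dispersion = nb_dispersion,
              library_size_mean = library_size_mean,
              library_size_sdlog = library_size_sdlog,
              low_quality_fraction = low_quality_fraction,
              n_marker_genes_per_type = as.integer(n_marker_genes_per_type),
              marker_log2fc = marker_log2fc,
              n_traj_genes = as.integer(n_traj_genes),
              seed = as.integer(seed))
  if (is.null(names(cfg$chrom_lengths)) || any(names(cfg$chrom_lengths) == "")) {
    stop("chrom_lengths must be a named vector")
  }
  if (length(cfg$chrom_lengths) == 0) stop("chrom_lengths must be non-empty")
  if (any(cfg$chrom_lengths < 1)) {
    stop("invalid configuration: every chromosome must be at least 1 bp long")
  }
  if (!cfg$trisomic_chrom %in% names(cfg$chrom_lengths)) {
    stop("invalid configuration: trisomic_chrom '", cfg$trisomic_chrom,
         "' is not among chrom_lengths labels")
  }
  if (cfg$dosage_factor <= 0) stop("invalid configuration: dosage_factor must be > 0")
  if (cfg$divergence_shift < 0 || cfg$divergence_shift > 1) {
    stop("invalid configuration: divergence_shift must lie in [0, 1]")
  }
  with(cfg, {
    if (n_genes < 1 || n_cells_per_sample < 1 || n_samples_per_genotype < 1 ||
        n_cell_types < 1) {
      stop("invalid configuration: counts must be >= 1")
    }
  })
  types <- sim_type_names(cfg$n_cell_types)
  bad <- setdiff(cfg$divergent_types, types)
  if (length(bad) > 0) {
    stop("invalid configuration: divergent_types not among cell types: ",
         paste(bad, collapse = ", "))
  }
  class(cfg) <- "sim_config"
  cfg
}

sim_type_names <- function(n) {
  if (n == 7L) c("aRGC", "IPC", "ExN1", "ExN2", "ExN3", "ExN4", "InN")
  else paste0("type", seq_len(n))
}

# Latent-time window [start, start + width] occupied by each type. Types tile
# the axis in order with overlapping windows (so the trajectory is
# continuous); the first type is the root population.
sim_type_windows <- function(n) {
  if (n == 1L) {
    data.frame(type = sim_type_names(1), start = 0, width = 1,
               stringsAsFactors = FALSE)
  } else {
    width <- max(0.3, 1.2 / n)
    data.frame(type = sim_type_names(n),
               start = (1 - width) * (seq_len(n) - 1) / (n - 1),
               width = width, stringsAsFactors = FALSE)
  }
}

#' Simulate a gene annotation table
#'
#' Places `n_genes` protein-coding genes uniformly at random along the
#' configured chromosomes (gene count per chromosome proportional to its
#' length) and adds `mito_gene_count` mitochondrial genes on a dedicated
#' "MT" contig. Intervals are 1-based and closed.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns gene_id, gene_name, chromosome, start,
#'   end, biotype, is_mito.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "simulate"))
  lens <- config$chrom_lengths
  n <- config$n_genes
  # deterministic proportional allocation (largest remainder)
  raw <- n * lens / sum(lens)
  n_per <- floor(raw)
  rem <- n - sum(n_per)
  if (rem > 0) {
    extra <- order(raw - n_per, decreasing = TRUE)[seq_len(rem)]
    n_per[extra] <- n_per[extra] + 1L
  }
  rows <- lapply(names(lens), function(ch) {
    m <- n_per[[ch]]
    if (m == 0) return(NULL)
    glen <- pmin(pmax(round(stats::rlnorm(m, log(20000), 0.8)), 200), lens[[ch]])
    start <- floor(stats::runif(m, 1, lens[[ch]] - glen + 1))
    start <- pmax(1, pmin(start, lens[[ch]]))
    end <- pmin(start + glen - 1, lens[[ch]])
    data.frame(chromosome = ch, start = sort(start),
               end = end[order(start)], stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, rows)
  ann$gene_id <- sprintf("G%05d", seq_len(nrow(ann)))
  ann$gene_name <- ann$gene_id
  ann$biotype <- "protein_coding"
  ann$is_mito <- FALSE
  if (config$mito_gene_count > 0) {
    m <- config$mito_gene_count
    mt_len <- 16569
    glen <- pmin(pmax(round(stats::runif(m, 300, 1800)), 100), mt_len)
    start <- floor(stats::runif(m, 1, mt_len - glen + 1))
    mt <- data.frame(chromosome = "MT", start = sort(start),
                     end = pmin(start[order(start)] + glen[order(start)] - 1, mt_len),
                     gene_id = sprintf("MT%02d", seq_len(m)),
                     gene_name = sprintf("MT%02d", seq_len(m)),
                     biotype = "protein_coding", is_mito = TRUE,
                     stringsAsFactors = FALSE)
    ann <- rbind(ann, mt[, names(ann)])
  }
  ann <- ann[, c("gene_id", "gene_name", "chromosome", "start", "end",
                 "biotype", "is_mito")]
  rownames(ann) <- NULL
  stopifnot(all(ann$start >= 1), all(ann$start <= ann$end))
  ann
}

#' Simulate two-genotype single-cell counts with known structure
#'
#' Draws negative-binomial counts whose means encode (i) a per-gene baseline
#' on a log-normal grid, (ii) cell-type marker programs, (iii) a smooth
#' sigmoidal trajectory program along a per-cell latent time in [0, 1],
#' (iv) a dosage factor on trisomic-chromosome genes in trisomic cells,
#' (v) extra per-type differential expression in trisomic cells, and (vi)
#' mitochondrial counts targeting a per-cell mitochondrial read fraction.
#' In divergent cell types, the latent time of trisomic cells is shifted
#' down by `divergence_shift` (truncated at 0), modelling developmental lag.
#'
#' Library scale factors are computed from pre-dosage baseline means, so the
#' expected trisomic/euploid mean-count ratio for trisomic-chromosome genes
#' is exactly `dosage_factor` (trisomic cells carry proportionally more
#' total RNA, as in a real triplication).
#'
#' @param config a [sim_config()].
#' @param annotation output of [simulate_annotation()] for the same config.
#' @return list with elements `counts` (sparse genes x cells dgCMatrix),
#'   `cells` (data.frame: cell_id, sample, genotype), and `truth` (list:
#'   latent_time, true_type, de_genes, marker_genes, traj_genes,
#'   divergent_types, type_windows).
#' @export
simulate_counts <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"))
  if (config$divergence_shift < 0 || config$divergence_shift > 1) {
    stop("invalid configuration: divergence_shift must lie in [0, 1]")
  }
  set.seed(derive_seed(config$seed, "simulate") + 1L)

  nuclear <- annotation$gene_id[!annotation$is_mito]
  mito <- annotation$gene_id[annotation$is_mito]
  n_gene <- length(nuclear)
  types <- sim_type_names(config$n_cell_types)
  windows <- sim_type_windows(config$n_cell_types)

  samples <- c(paste0("eu", seq_len(config$n_samples_per_genotype)),
               paste0("tri", seq_len(config$n_samples_per_genotype)))
  genotype_of <- c(rep("euploid", config$n_samples_per_genotype),
                   rep("trisomic", config$n_samples_per_genotype))
  n_cells <- config$n_cells_per_sample * length(samples)

  cells <- data.frame(
    cell_id = unlist(lapply(samples, function(s)
      sprintf("%s-%04d", s, seq_len(config$n_cells_per_sample)))),
    sample = rep(samples, each = config$n_cells_per_sample),
    genotype = rep(genotype_of, each = config$n_cells_per_sample),
    stringsAsFactors = FALSE)

  # cell types round-robin within sample so every sample has all types
  cells$true_type <- unlist(lapply(seq_along(samples), function(i)
    rep_len(types, config$n_cells_per_sample)))

  # latent time uniform within the type window; trisomic cells of divergent
  # types are shifted down (developmental lag), truncated at 0
  wstart <- stats::setNames(windows$start, windows$type)
  wwidth <- stats::setNames(windows$width, windows$type)
  t_lat <- stats::runif(n_cells, wstart[cells$true_type],
                        wstart[cells$true_type] + wwidth[cells$true_type])
  shift_me <- cells$genotype == "trisomic" & cells$true_type %in% config$divergent_types
  t_lat[shift_me] <- pmax(0, t_lat[shift_me] - config$divergence_shift)
  t_lat <- pmin(pmax(t_lat, 0), 1)

  # gene programs -----------------------------------------------------------
  base <- stats::qlnorm(seq(0.02, 0.98, length.out = n_gene), meanlog = 0, sdlog = 1)
  base <- sample(base)  # shuffle so the grid is not ordered along the genome
  names(base) <- nuclear

  pick <- function(pool, k) if (k <= 0) character(0) else sample(pool, min(k, length(pool)))
  remaining <- nuclear
  marker_genes <- list()
  for (ty in types) {
    marker_genes[[ty]] <- pick(remaining, config$n_marker_genes_per_type)
    remaining <- setdiff(remaining, marker_genes[[ty]])
  }
  de_genes <- list()
  for (ty in types) {
    de_genes[[ty]] <- pick(remaining, config$n_de_genes_per_type)
    remaining <- setdiff(remaining, de_genes[[ty]])
  }
  traj_genes <- pick(remaining, config$n_traj_genes)

  # relative (pre-dosage) mean matrix: genes x cells
  mu <- matrix(base, nrow = n_gene, ncol = n_cells,
               dimnames = list(nuclear, cells$cell_id))
  mfac <- 2^config$marker_log2fc
  for (ty in types) {
    sel <- cells$true_type == ty
    if (length(marker_genes[[ty]]) > 0 && any(sel)) {
      mu[marker_genes[[ty]], sel] <- mu[marker_genes[[ty]], sel] * mfac
    }
  }
  if (length(traj_genes) > 0) {
    centre <- stats::runif(length(traj_genes), 0.1, 0.9)
    slope <- sample(c(-1, 1), length(traj_genes), replace = TRUE) *
      stats::runif(length(traj_genes), 1.0, 2.0)
    sig <- stats::plogis(outer(-centre, t_lat, "+") / 0.1)  # genes x cells
    mu[traj_genes, ] <- mu[traj_genes, ] * exp(slope * (sig - 0.5))
  }

  # library scaling from the baseline (pre-dosage) totals
  lib <- stats::rlnorm(n_cells, log(config$library_size_mean),
                       config$library_size_sdlog)
  n_low <- round(config$low_quality_fraction * n_cells)
  if (n_low > 0) {
    low <- sample(n_cells, n_low)
    lib[low] <- stats::rlnorm(n_low, log(config$library_size_mean * 0.08),
                              config$library_size_sdlog)
  }
  scale_c <- lib / colSums(mu)
  mu <- sweep(mu, 2, scale_c, "*")

  # genotype effects applied after scaling, so the trisomic/euploid mean
  # ratio equals the configured factors exactly
  tri_cells <- cells$genotype == "trisomic"
  chrom <- stats::setNames(annotation$chromosome, annotation$gene_id)
  on_tri_chrom <- nuclear[chrom[nuclear] == config$trisomic_chrom]
  if (length(on_tri_chrom) > 0 && any(tri_cells)) {
    mu[on_tri_chrom, tri_cells] <- mu[on_tri_chrom, tri_cells] * config$dosage_factor
  }
  for (ty in types) {
    sel <- tri_cells & cells$true_type == ty
    if (length(de_genes[[ty]]) > 0 && any(sel)) {
      mu[de_genes[[ty]], sel] <- mu[de_genes[[ty]], sel] * 2^config$de_log2fc
    }
  }

  # mitochondrial counts: target per-cell fraction mostly in [1%, 10%] with
  # outlier tails on both sides
  if (length(mito) > 0) {
    mt_frac <- stats::rbeta(n_cells, 2.5, 45)
    hi <- stats::runif(n_cells) < 0.04
    lo <- !hi & stats::runif(n_cells) < 0.03
    mt_frac[hi] <- stats::runif(sum(hi), 0.12, 0.30)
    mt_frac[lo] <- stats::runif(sum(lo), 0.0005, 0.008)
    mt_total <- colSums(mu) * mt_frac / (1 - mt_frac)
    mt_w <- stats::runif(length(mito), 0.5, 1.5)
    mt_w <- mt_w / sum(mt_w)
    mu_mt <- outer(mt_w, mt_total)
    dimnames(mu_mt) <- list(mito, cells$cell_id)
    mu <- rbind(mu, mu_mt)
  }

  size <- 1 / config$nb_dispersion
  counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu), size = size),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  # restore annotation gene order
  counts <- counts[annotation$gene_id, , drop = FALSE]
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")

  truth <- list(latent_time = stats::setNames(t_lat, cells$cell_id),
                true_type = stats::setNames(cells$true_type, cells$cell_id),
                de_genes = de_genes,
                marker_genes = marker_genes,
                traj_genes = traj_genes,
                divergent_types = config$divergent_types,
                type_windows = windows)
  list(counts = counts, cells = cells[, c("cell_id", "sample", "genotype")],
       truth = truth)
}

#' Write a 10x-style matrix directory
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate integer, genes as rows),
#' `features.tsv` (gene_id, gene_name, chromosome, start, end, biotype,
#' is_mito), `barcodes.tsv`, and `cells.tsv` (per-cell metadata). The layout
#' round-trips losslessly through [read_10x()].
#'
#' @param counts genes x cells count matrix (sparse or dense).
#' @param cells data.frame of per-cell metadata; first column must be the
#'   cell id matching `colnames(counts)`.
#' @param annotation gene annotation data.frame covering `rownames(counts)`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_10x <- function(counts, cells, annotation, dir) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (ncol(counts) != nrow(cells)) {
    stop("IO error: counts has ", ncol(counts), " cells but metadata has ",
         nrow(cells), " rows")
  }
  if (!all(rownames(counts) %in% annotation$gene_id)) {
    stop("IO error: counts contains genes missing from the annotation")
  }
  if (nrow(cells) > 0 && !identical(colnames(counts), as.character(cells[[1]]))) {
    stop("IO error: column names of counts do not match the cell metadata")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- annotation[match(rownames(counts), annotation$gene_id), , drop = FALSE]
  write_mtx_integer(counts, file.path(dir, "matrix.mtx"))
  utils::write.table(ann, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(colnames(counts) %||% character(0), file.path(dir, "barcodes.tsv"))
  utils::write.table(cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv",
                             "cells.tsv")))
}

# MatrixMarket coordinate-integer writer for a sparse count matrix.
write_mtx_integer <- function(m, path) {
  tm <- methods::as(m, "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate integer general", con)
  writeLines(paste(nrow(m), ncol(m), length(tm@x)), con)
  if (length(tm@x) > 0) {
    writeLines(paste(tm@i + 1L, tm@j + 1L, format(tm@x, scientific = FALSE,
                                                  trim = TRUE)), con)
  }
  invisible(path)
}
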