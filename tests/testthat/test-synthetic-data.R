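test_that("annotation places genes inside chromosomes and flags mitochondria", {
  cfg <- sim_config(n_genes = 300, chrom_lengths = c("1" = 1e7),
                    trisomic_chrom = "1", mito_gene_count = 7,
                    n_cell_types = 3, divergent_types = "type3")
  ann <- simulate_annotation(cfg)
  nuc <- ann[!ann$is_mito, ]
  expect_true(all(nuc$chromosome == "1"))
  expect_true(all(nuc$start >= 1 & nuc$start <= 1e7))
  expect_true(all(nuc$start <= nuc$end & nuc$end <= 1e7))
  expect_identical(sum(ann$is_mito), 7L)
  expect_true(all(ann$chromosome[ann$is_mito] == "MT"))
  expect_true(all(ann$biotype == "protein_coding"))
  expect_false(any(duplicated(ann$gene_id)))

  cfg0 <- sim_config(n_genes = 50, chrom_lengths = c("1" = 1e6),
                     trisomic_chrom = "1", mito_gene_count = 0,
                     n_cell_types = 2, divergent_types = "type2")
  expect_identical(sum(simulate_annotation(cfg0)$is_mito), 0L)
})

test_that("simulation is seeded-deterministic and validates its config", {
  cfg <- sim_config(n_genes = 150, n_cells_per_sample = 20,
                    n_cell_types = 3, divergent_types = "type3", seed = 9)
  a1 <- simulate_annotation(cfg); a2 <- simulate_annotation(cfg)
  expect_identical(a1, a2)
  s1 <- simulate_counts(cfg, a1); s2 <- simulate_counts(cfg, a2)
  expect_identical(as.matrix(s1$counts), as.matrix(s2$counts))
  expect_identical(s1$truth$latent_time, s2$truth$latent_time)

  expect_error(sim_config(chrom_lengths = c("1" = 0.5)), "at least 1 bp")
  expect_error(sim_config(trisomic_chrom = "99"), "trisomic_chrom")
  expect_error(sim_config(divergence_shift = 1.2), "divergence_shift")
  expect_error(sim_config(dosage_factor = 0), "dosage_factor")
  expect_error(sim_config(divergent_types = "nope"), "divergent_types")
})

test_that("counts encode the configured dosage and latent-time lag", {
  cfg <- sim_config(n_genes = 600, n_cells_per_sample = 150,
                    n_cell_types = 3, divergent_types = "type3",
                    divergence_shift = 0.25, n_de_genes_per_type = 0,
                    low_quality_fraction = 0, seed = 4)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)
  tri <- sim$cells$genotype == "trisomic"
  chr21 <- ann$gene_id[ann$chromosome == "21" & !ann$is_mito]
  off <- ann$gene_id[!ann$is_mito & ann$chromosome != "21"]
  r21 <- mean(Matrix::rowMeans(sim$counts[chr21, tri])) /
    mean(Matrix::rowMeans(sim$counts[chr21, !tri]))
  roff <- mean(Matrix::rowMeans(sim$counts[off, tri])) /
    mean(Matrix::rowMeans(sim$counts[off, !tri]))
  expect_gt(r21, 1.35); expect_lt(r21, 1.65)
  expect_gt(roff, 0.93); expect_lt(roff, 1.07)

  lt <- sim$truth$latent_time
  div <- sim$truth$true_type == "type3"
  expect_lt(mean(lt[div & tri]) - mean(lt[div & !tri]), -0.15)
  other <- sim$truth$true_type == "type1"
  expect_lt(abs(mean(lt[other & tri]) - mean(lt[other & !tri])), 0.05)
  expect_true(all(lt >= 0 & lt <= 1))

  # mitochondrial fractions mostly inside the QC window, tails on both sides
  st <- cell_qc_stats(sim$counts, ann)
  inside <- mean(st$mito_fraction >= 0.01 & st$mito_fraction <= 0.10)
  expect_gt(inside, 0.7)
  expect_gt(sum(st$mito_fraction < 0.01), 0)
  expect_gt(sum(st$mito_fraction > 0.10), 0)
})

test_that("10x round trip is lossless", {
  cfg <- sim_config(n_genes = 120, n_cells_per_sample = 15,
                    n_cell_types = 2, divergent_types = "type2", seed = 2)
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(cfg, ann)
  dir <- withr::local_tempdir()
  write_10x(sim$counts, sim$cells, ann, dir)
  back <- read_10x(dir)
  expect_identical(as.matrix(back$counts), as.matrix(sim$counts))
  expect_identical(colnames(back$counts), sim$cells$cell_id)
  expect_identical(back$cells$genotype, sim$cells$genotype)
  expect_identical(back$annotation$chromosome,
                   ann$chromosome[match(rownames(sim$counts), ann$gene_id)])

  # gzipped variant accepted
  for (f in c("matrix.mtx", "features.tsv", "barcodes.tsv", "cells.tsv")) {
    p <- file.path(dir, f)
    con <- gzfile(paste0(p, ".gz"), "wb")
    writeLines(readLines(p), con); close(con)
    unlink(p)
  }
  gz <- read_10x(dir)
  expect_identical(as.matrix(gz$counts), as.matrix(sim$counts))
})

test_that("10x writer handles degenerate matrices and rejects mismatches", {
  ann <- toy_annotation(c("gA", "gB", "gC"))
  empty <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(3, 0))
  rownames(empty) <- ann$gene_id
  dir <- withr::local_tempdir()
  write_10x(empty, data.frame(cell_id = character(0)), ann, dir)
  back <- read_10x(dir)
  expect_identical(ncol(back$counts), 0L)

  toy <- Matrix::sparseMatrix(i = 1, j = 1, x = 5, dims = c(3, 2))
  dimnames(toy) <- list(ann$gene_id, c("c1", "c2"))
  dir2 <- withr::local_tempdir()
  write_10x(toy, data.frame(cell_id = c("c1", "c2")), ann, dir2)
  body <- readLines(file.path(dir2, "matrix.mtx"))
  expect_match(body[1], "coordinate integer")
  expect_identical(length(body), 3L)  # header + size + one triple
  expect_identical(body[3], "1 1 5")

  expect_error(write_10x(toy, data.frame(cell_id = "c1"), ann, dir2),
               "IO error")
  # corrupt barcodes -> reader errors
  writeLines(c("c1", "c2", "c3"), file.path(dir2, "barcodes.tsv"))
  expect_error(read_10x(dir2), "barcodes")
})
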