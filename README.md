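# scDivergence

Quantifying genotype-driven developmental divergence in single-cell RNA-seq.

Isogenic designs — for example a euploid/trisomic (trisomy 21) iPSC pair
differentiated into cortical spheroids — ask a specific question of
scRNA-seq data: *within each cell type, how far apart are the two genotypes
along the differentiation trajectory, and which genes travel with that
divergence?* `scDivergence` implements the full analysis path for that
question, from raw 10x-style counts to a permutation-tested divergence
statistic, for computational biologists working with two-condition
single-cell experiments.

## What it computes

The core statistic is the **inter-genotype distance (IGD)**. Within one cell
type, cells are embedded with a diffusion map (Gaussian kernel of width
2σ on a symmetrized kNN graph, density-normalized, eigenvalue-scaled
components). The observed IGD is

oIGD = (1 / n_tri·n_eu) · Σ_i Σ_j ‖x_i − x_j‖

the mean Euclidean distance over all trisomic × euploid cell pairs on the
diffusion components. Genotype labels are permuted within the cell type
(B = 1,000; exact enumeration when the labeling count is small) to form the
null sample of expected IGDs (eIGD), giving p = (1 + #{eIGD ≥ oIGD}) / (B+1).
For comparison across cell types, oIGD and eIGDs are divided by the mean
pairwise distance among euploid cells of that type (normalized oIGD).

Around this statistic the package provides:

- **Synthetic data**: a seeded two-genotype generator with known cell types,
  latent differentiation times, chromosome dosage (1.5× triplication),
  per-type DE genes, a divergent cell type shifted along the trajectory, and
  mitochondrial/library-size variation that exercises QC.
- **IO / QC**: 10x-style MTX round-trip; cell filter (detected genes
  > 1,000, mitochondrial fraction in [1%, 10%]); protein-coding non-mito
  gene filter; log-normalization `ln(1 + 10,000·c/total)`.
- **Embedding / clustering**: binned-dispersion HVGs (2,000), scaled PCA
  (10 PCs), seeded UMAP, shared-neighbour Louvain clustering (k = 15,
  resolution 0.15) on the 2D coordinates, marker-panel cell-type labels.
- **Dosage detection**: expression coverage in 5 Mb genomic windows with
  cross-genotype CPM ratios, plus a pseudobulk negative-binomial score test
  tallying up/down-regulated genes per chromosome.
- **Per-cluster DE**: binomial detection-rate likelihood-ratio test
  (detection floor 25%, BH-adjusted p < 0.1), hypergeometric gene-set
  enrichment and exact hypergeometric list-overlap tests, Venn counts.
- **Trajectory**: diffusion maps with automatic σ selection, flood
  pseudotime (100 stochastic floods from root cells), Kolmogorov–Smirnov
  comparison of genotype pseudotime distributions.
- **Graph association**: Moran's I per gene on the diffusion-map kNN graph
  (I > 0.3, adjusted p < 0.01, permutation p-values), with a point-biserial
  genotype direction call.

## Worked example

```r
library(scDivergence)

res <- suppressWarnings(run_pipeline(pipeline_config(seed = 1)))
pipeline_report(res)
```

```
cells: 1000 in, 771 kept after QC; 2000 genes kept
clusters: 13 (ARI vs simulated types: 1.000)
per-cluster DE: 52 significant gene hits
per-type IGD (ordered by significance):
 cell_type n_euploid n_trisomic     oigd normalizer normalized_oigd     p_value
      ExN4        56         55 2.090715   1.330889        1.570916 0.000999001
       InN        56         52 1.739920   1.474022        1.180390 0.000999001
      aRGC        55         54 1.730488   1.501498        1.152508 0.000999001
      ExN2        53         63 1.810273   1.601530        1.130340 0.000999001
      ExN3        54         55 1.728582   1.559399        1.108492 0.000999001
      ExN1        61         49 1.732824   1.566316        1.106306 0.000999001
       IPC        54         54 1.711168   1.588809        1.077013 0.000999001
top divergent type: ExN4
```

Reading this: QC kept 771 of 1,000 simulated cells (the rest fail the
detected-gene or mitochondrial-fraction filters). Clustering recovers the
seven simulated cell types exactly (adjusted Rand index 1.0). The planted
divergent type ExN4 tops the IGD ranking with the largest normalized oIGD
(1.57: trisomic–euploid pairs are 57% farther apart than euploid–euploid
pairs) at the smallest attainable permutation p (1/1001 < 0.001). All types
reach small p here because the simulation also plants chromosome-21 dosage
and per-type DE genes — real genotype signal — in every type; the *ranking*
is what separates the trajectory-divergent type.

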