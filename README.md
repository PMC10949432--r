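# imodulome

Reconstruction of bacterial transcriptional regulatory networks (TRNs)
from RNA-seq expression compendia using independent component analysis.

Microbial transcriptomes respond to their environment through a modest
number of regulators acting on overlapping gene sets. Given a compendium
of logTPM expression profiles spanning many conditions, ICA factors the
genes x samples matrix as

    X ~ M A

where the columns of `M` are independent, sparse gene-weight vectors and
`A` holds per-sample activities. Thresholding a column of `M` yields an
**iModulon** — an independently modulated gene set that frequently
coincides with a known regulon — and its activity row tracks regulatory
engagement across conditions. The package is aimed at microbial systems
biologists who have a processed expression compendium (plus, optionally,
a draft TRN, a genome annotation, and aligned transcription-factor
binding sites) and want a reproducible route from that matrix to
candidate regulons, differential activities, and sequence-level evidence.

The pipeline covers:

* **Compendium QC** — read-count/FASTQC exclusion, replicate-correlation
  filtering with group averaging (any within-group Pearson r below 0.80
  collapses the group to its mean; sweep over 0.80/0.85/0.90/0.95
  available), reference-condition centering per project.
* **Robust ICA** — fixed-point algorithm (log-cosh contrast, SVD
  whitening) over many restarts; components clustered across restarts on
  `1 - |r|`, clusters supported by at least half the restarts yield
  centrotype components; dimensionality selected from a sweep as the
  largest dimension at which every robust component is still a multi-gene
  component.
* **iModulon extraction** — iterative D'Agostino K-squared thresholding
  of gene weights, explained variance `1 - ||X - M_S A_S||_F^2 /
  ||X||_F^2`, single-gene detection, Spearman activity clustering, and
  differential iModulon activity (DIMA) with a replicate-fitted
  log-normal null and BH-FDR.
* **TRN enrichment** — hypergeometric enrichment against a draft
  regulator-to-gene table, iModulon/regulon recall metrics, and the
  four-quadrant classification (well matched / regulon subset / regulon
  discovery / poorly matched).
* **Sequence arm** — intergenic-distance operon clustering from GFF3,
  PSSM log-odds motif scanning of operon promoters (bits, both strands),
  and an elastic-net logistic classifier of regulon membership with
  SMOTE+Tomek rebalancing and fivefold operon-grouped stratified
  cross-validation against a 0.8 AUC-ROC benchmark.
* **Synthetic generators** — compendia with planted modules and
  controlled replicate correlation, genomes with known operon structure
  and planted promoter motifs, and TRN tables with controlled overlap, so
  every stage has a parameter-recovery test against known ground truth.

## Worked example

```r
library(imodulome)

# a synthetic compendium with 5 planted modules: 200 genes,
# 20 conditions x 3 replicates, logTPM noise sd 0.3, replicate r ~ 0.9
sim <- generate_compendium(n_genes = 200, n_conditions = 20,
                           replicates_per_condition = 3, k_modules = 5,
                           noise_sd = 0.3, replicate_rho = 0.9, seed = 7)

# QC: correlation filter at 0.80, then reference-condition centering
x <- center_to_reference(
  replicate_correlation_filter(sim$compendium)$compendium)

# robust ICA, 10 restarts
dec <- run_ica(x, dimension = 5, n_restarts = 10, seed = 42)
dec
#> <ica_decomposition> 5 robust components (dimension 5, 10 restarts)

# thresholded iModulons
ims <- extract_imodulons(x, dec)
ims
#> <imodulon_set> 5 iModulons (0 single-gene), total EV 0.963

# enrichment against a draft TRN covering 80% of each planted module
trn <- generate_trn_table(sim$truth, 0.8, extra_genes = 2, seed = 1)
en <- enrich_regulons(ims, trn, background = rownames(x$values))
subset(en$table, q_value < 0.05,
       select = c(imodulon, regulator, overlap,
                  imodulon_recall, regulon_recall, quadrant))
#>    imodulon regulator overlap imodulon_recall regulon_recall     quadrant
#> 5      IC01     Reg05      16             0.8      0.8888889 well_matched
#> 6      IC02     Reg01      16             0.8      0.8888889 well_matched
#> 12     IC03     Reg02      16             0.8      0.8888889 well_matched
#> 18     IC04     Reg03      16             0.8      0.8888889 well_matched
#> 24     IC05     Reg04      16             0.8      0.8888889 well_matched
```

Each planted module is recovered as one robust component; each iModulon
holds 20 genes of which 16 overlap its 18-gene draft regulon (80% of the
module plus 2 random genes), giving iModulon recall 0.8 and regulon
recall 0.89 — the well-matched quadrant. The five components together
explain 96.3% of the variance in this low-noise synthetic matrix.

A full run — QC through classifier — is driven by `run_pipeline()` from
a YAML/JSON config, or from the shell via the thin CLI:

```sh
Rscript inst/cli/imodulome.R simulate --seed 5 --outdir bundle
Rscript inst/cli/imodulome.R run-all --expression bundle/expression.tsv \
    --metadata bundle/metadata.tsv --trn bundle/trn.tsv \
    --gff3 bundle/genes.gff3 --dimension 5 --seed 5 --outdir out
```

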