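# mirtss

Identification of active promoters and transcription start sites (TSSs) of
intergenic microRNAs from genome-wide RNA polymerase II (RPol II) ChIP-seq
binding patterns.

Primary microRNA transcripts are poorly annotated, so the promoters that
drive microRNA expression — and how they respond to treatment — are usually
unknown. RPol II occupancy peaks at active TSSs, stays elevated through the
transcribed region and decays to background in intergenic DNA. `mirtss`
learns that signature from expressed protein-coding genes and then scans
upstream of annotated microRNAs for it, calling active promoters per
biological condition so transcriptional activity can be compared across
conditions (e.g. hormone-treated versus resistant breast-cancer lines).

## The model

Fragment counts in 200-bp bins around a TSS (25 bins per side plus the
central bin) are Poisson, `X_ij ~ Poisson(lambda_ij)`, with

```
lambda_ij = B_i + (S_i - B_i) exp(-Kp_i |D_j|)   upstream   (D_j < 0)
lambda_ij = S_i                                  TSS bin    (D_j = 0)
lambda_ij = T_i + (S_i - T_i) exp(-Kt_i  D_j)    downstream (D_j > 0)
```

where `S` is the TSS-bin level, `B` the intergenic background, `T` the
steady transcript level and `Kp`, `Kt` the upstream/downstream decay rates
per bin. The five parameters are gene-specific latent variables, each
Gamma-distributed genome-wide; the ten Gamma parameters `Phi` are estimated
from expressed training genes by EM with deterministic quadrature over the
latent parameters (compiled kernel, log-space throughout).

Candidate bins upstream of a microRNA are scored with the marginal
likelihood ratio

```
dF = log P(x | TSS model, Phi) - log P(x | background-only; alpha_B, beta_B)
```

(the background marginal is the closed-form Gamma–Poisson with one shared
`B`). The best bin within 10 kb upstream of the pre-miRNA 5' end is the
putative TSS; an empirical FDR referenced to unexpressed-gene promoter loci
decides whether the promoter is active (default threshold 0.2), and the
"90% decay" rule around the called TSS delineates its regulatory region.
See `vignettes/mirtss-methods.Rmd` for the full account, tunable
parameters and limitations.

## Worked example

All inputs are plain text (BED fragments, refFlat genes, an expression-call
table, miRBase-style GFF3); the bundled generator writes a complete
synthetic study so the pipeline can be exercised without any download:

```r
library(mirtss)

fxdir <- tempfile("mirtss_demo")
cfg <- sim_config(n_expressed = 60, n_unexpressed = 40,
                  n_mirna_active = 10, n_mirna_silent = 10, seed = 7)
fx <- simulate_genome_fixture(cfg, fxdir)

frags <- read_fragments_bed(fx$paths$fragments, fx$layout)
genes <- merge(read_genes(fx$paths$genes, "refFlat"),
               read_expression(fx$paths$expression), by = "gene_id")

## long, isolated genes; Present -> expressed pool, Absent -> background
gold <- select_gold_standard(genes, seed = 1)
#> <gold_standard> train 15 / test 45 expressed, 40 unexpressed (seed 1)

train <- genes[genes$gene_id %in% gold$train_expressed, ]
counts <- profile_counts_matrix(frags, data.frame(chrom = train$chrom,
  pos = train$tss, strand = train$strand), -25:25)
profiles <- lapply(seq_len(nrow(counts)), function(i)
  binned_profile(counts[i, ], -25:25, anchor_id = train$gene_id[i]))
fit <- fit_hyperparams(profiles)
#> <fit_result> 7 iterations (converged), objective -1800.84
#> <hyper_params>
#>   gS   shape=4.347 rate=0.06778  (mean 64.13)
#>   gB   shape=2.497 rate=1.258  (mean 1.985)
#>   gT   shape=3.49 rate=0.323  (mean 10.81)
#>   gKp  shape=18.08 rate=23.92  (mean 0.7556)
#>   gKt  shape=36.13 rate=79.44  (mean 0.4548)
```

The fitted laws recover the generator's structure: background near 2
fragments/bin, a TSS peak more than an order of magnitude above it, higher
occupancy in the transcript region than the intergenic background
(`mean(T) > mean(B)`), and faster upstream than downstream decay
(`mean(Kp) > mean(Kt)`).

```r
mirnas <- classify_mirnas(read_mirnas(fx$paths$mirnas, "GFF3"), genes)
scans <- lapply(seq_len(nrow(mirnas)), function(i)
  scan_mirna_upstream(frags, mirnas[i, ], fit$phi, layout = fx$layout))
bg_genes <- genes[genes$gene_id %in% gold$unexpressed, ]
bg <- vapply(seq_len(nrow(bg_genes)), function(i) {
  g <- bg_genes[i, ]
  scan_mirna_upstream(frags, list(mirna_id = g$gene_id, chrom = g$chrom,
    strand = g$strand, pre_start = g$tss, pre_end = g$tss),
    fit$phi, layout = fx$layout)$best_score
}, numeric(1))
calls <- call_promoters(scans, bg, frags, fit$phi, method = "exceedance",
                        layout = fx$layout)
calls[[1]]
#> <scan_result> mir0001 best dF=182.58 at 23 bins upstream (fdr=0)
```

`mir0001`'s promoter is called active: the best-scoring bin sits 23 bins
(4.6 kb) upstream of the pre-miRNA, its FDR against the unexpressed-gene
background is 0, the called TSS is `chrS2:15401` and the fitted decay rates
give a 2,000-bp regulatory region (`14701-16700`). Across the fixture, the
10 loci with a planted TSS are called active and the 10 background-only
loci are not.

The same chain is scriptable from a shell via the installed CLI
(`simulate`, `fit`, `scan`, `evaluate`, `profile` subcommands):

```sh
mirtss simulate --out fx --seed 7
mirtss fit      --fixture fx --out phi.tsv --seed 1
mirtss scan     --fixture fx --phi phi.tsv --out scan --seed 1
mirtss evaluate --fixture fx --phi phi.tsv --out eval --seed 1
```

Outputs are BED6+ predictions, tab-delimited score/AUC tables and a JSON
run manifest per output directory; a fixed `--seed` reproduces every output
byte for byte.

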