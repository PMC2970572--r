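# Lazily-built shared pipeline objects for the heavier end-to-end tests.
# Built once per test run; every builder is fully seeded.

.pipe_cache <- new.env(parent = emptyenv())

pipe_get <- function(name, builder) {
  if (!exists(name, envir = .pipe_cache)) {
    assign(name, builder(), envir = .pipe_cache)
  }
  get(name, envir = .pipe_cache)
}

# The reference synthetic study: expressed/unexpressed genes for training and
# evaluation plus planted-TSS microRNA loci, with hyperparameters fitted on
# the training split of its own expressed genes.
study_fixture <- function() {
  pipe_get("study", function() {
    cfg <- sim_config(n_expressed = 150, n_unexpressed = 80,
                      n_mirna_active = 40, n_mirna_silent = 0, seed = 20260901)
    fx <- simulate_genome_fixture(cfg, file.path(tempdir(), "mirtss_study"))
    frags <- read_fragments_bed(fx$paths$fragments, fx$layout)
    genes <- merge(read_genes(fx$paths$genes, "refFlat"),
                   read_expression(fx$paths$expression), by = "gene_id")
    gold <- select_gold_standard(genes, seed = 7)
    train <- genes[genes$gene_id %in% gold$train_expressed, , drop = FALSE]
    offsets <- -25:25
    counts <- profile_counts_matrix(
      frags, data.frame(chrom = train$chrom, pos = train$tss,
                        strand = train$strand), offsets)
    profiles <- lapply(seq_len(nrow(counts)), function(i)
      binned_profile(counts[i, ], offsets, anchor_id = train$gene_id[i]))
    fit <- fit_hyperparams(profiles, settings = fit_settings(max_iter = 60))
    list(cfg = cfg, fx = fx, frags = frags, genes = genes, gold = gold,
         fit = fit, phi = fit$phi)
  })
}

# Best upstream-scan scores at unexpressed gold-standard gene promoters --
# the empirical-FDR background for promoter calling.
study_background_scores <- function() {
  pipe_get("study_bg", function() {
    st <- study_fixture()
    bg_genes <- st$genes[st$genes$gene_id %in% st$gold$unexpressed, ,
                         drop = FALSE]
    vapply(seq_len(nrow(bg_genes)), function(i) {
      g <- bg_genes[i, ]
      scan_mirna_upstream(st$frags,
                          list(mirna_id = g$gene_id, chrom = g$chrom,
                               strand = g$strand, pre_start = g$tss,
                               pre_end = g$tss),
                          st$phi, layout = st$fx$layout)$best_score
    }, numeric(1))
  })
}

study_mirna_scans <- function() {
  pipe_get("study_scans", function() {
    st <- study_fixture()
    lapply(seq_len(nrow(st$fx$mirnas)), function(i)
      scan_mirna_upstream(st$frags, st$fx$mirnas[i, ], st$phi,
                          layout = st$fx$layout))
  })
}
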