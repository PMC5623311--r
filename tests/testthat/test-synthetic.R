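# a small, fast world for unit tests (the acceptance suite runs the full
# stated benchmark configuration)
small_config <- function(seed = 7, ...) {
  synth_config(seed = seed, n_chroms = 4, chrom_length = 2e6, n_genes = 80,
               n_enhancers = 40, ...)
}

test_that("generation is deterministic: same seed, identical bundle", {
  b1 <- synth_generate(small_config())
  b2 <- synth_generate(small_config())
  expect_identical(b1$genes, b2$genes)
  expect_identical(b1$enhancers, b2$enhancers)
  expect_identical(b1$counts$enh$ER$matrix, b2$counts$enh$ER$matrix)
  expect_identical(b1$truth, b2$truth)
  b3 <- synth_generate(small_config(seed = 8))
  expect_false(identical(b1$enhancers, b3$enhancers))
})

test_that("bundle invariants: links, geometry, observed subset", {
  b <- synth_generate(small_config())
  # every truth link connects emitted elements on the same chromosome
  expect_true(all(b$truth$enhancer_id %in% b$enhancers$name))
  expect_true(all(b$truth$gene_id %in% b$genes$name))
  ec <- b$enhancers$chrom[match(b$truth$enhancer_id, b$enhancers$name)]
  gc <- b$genes$chrom[match(b$truth$gene_id, b$genes$name)]
  expect_equal(ec, gc)
  # enhancers are intergenic and pairwise non-overlapping
  expect_false(any(overlaps_any(b$enhancers, promoter_extended(b$genes, 300))))
  for (ch in unique(b$enhancers$chrom)) {
    e <- b$enhancers[b$enhancers$chrom == ch, ]
    e <- e[order(e$start), ]
    if (nrow(e) > 1) expect_true(all(e$start[-1] >= e$end[-nrow(e)]))
  }
  # observed truth is a subset of the complete truth
  obs_enh <- sprintf("%s:%d-%d", b$observed$chrom_a,
                     as.integer(b$observed$start_a),
                     as.integer(b$observed$end_a))
  expect_true(all(obs_enh %in% b$truth$enhancer_id))
  expect_lte(nrow(b$observed), nrow(b$truth))
})

test_that("observed sensitivity matches the configured rate", {
  # binomial check pooled over seeds: 3 * 50 links at sensitivity 0.6
  tot <- 0; obs <- 0
  for (s in 1:3) {
    b <- synth_generate(synth_config(seed = s, n_chroms = 2,
                                     chrom_length = 5e6, n_genes = 100,
                                     n_enhancers = 100))
    tot <- tot + nrow(b$truth); obs <- obs + nrow(b$observed)
  }
  expect_gt(obs / tot, 0.6 - 3 * sqrt(0.6 * 0.4 / tot))
  expect_lt(obs / tot, 0.6 + 3 * sqrt(0.6 * 0.4 / tot))
})

test_that("noiseless full-strength links correlate perfectly; no links when fraction is zero", {
  b <- synth_generate(small_config(noise_sd = 0,
                                   signal_strength = c(ER = 1, PolII_rep1 = 1,
                                                       PolII_rep2 = 1,
                                                       H2AZ = 1, H3K4me3 = 1),
                                   library_sizes = rep(1e6, 8)))
  norm_e <- normalize_timeseries(b$counts$enh$ER)
  norm_g <- normalize_timeseries(b$counts$gene$ER)
  for (i in seq_len(nrow(b$truth))) {
    r <- pearson_cor(
      norm_e$matrix[match(b$truth$enhancer_id[i], norm_e$region_ids), ],
      norm_g$matrix[match(b$truth$gene_id[i], norm_g$region_ids), ])
    expect_gt(r, 0.999)  # equal up to count rounding
  }
  b0 <- synth_generate(small_config(fraction_linked = 0))
  expect_equal(nrow(b0$truth), 0)
  expect_equal(nrow(b0$observed), 0)
})

test_that("consensus reconstruction recovers the planted enhancers exactly", {
  b <- synth_generate(small_config())
  cons <- persistent_union(b$peaks)
  distal <- filter_distal(cons, b$genes)
  expect_setequal(distal$name, b$enhancers$name)
  # genic decoy peaks survive the support filter but fall to the distal
  # filter, so the raw consensus is strictly larger
  expect_gt(nrow(cons), nrow(distal))
})

test_that("linked-pair correlations stochastically dominate unlinked for strong assays", {
  b <- synth_generate(small_config())
  cfg <- pipeline_config()
  res <- analyze_bundle(b, cfg)
  feats <- res$features
  key <- paste(b$truth$enhancer_id, b$truth$gene_id)
  linked <- paste(feats$enhancer_id, feats$gene_id) %in% key
  ks <- suppressWarnings(
    stats::ks.test(feats$c_ER[linked], feats$c_ER[!linked],
                   alternative = "less"))
  expect_lt(ks$p.value, 1e-6)
  expect_gt(mean(feats$c_ER[linked]), mean(feats$c_ER[!linked]))
})

test_that("feature table has the full candidate-universe row count", {
  b <- synth_generate(small_config())
  res <- analyze_bundle(b)
  per_chrom <- table(b$genes$chrom)
  expected <- sum(per_chrom[b$enhancers$chrom])
  expect_equal(nrow(res$features), expected)
})

test_that("bundles round-trip to disk in the standard formats", {
  b <- synth_generate(small_config())
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  genes <- read_genes(file.path(dir, "genes.tsv"))
  expect_equal(genes$name, b$genes$name)
  expect_equal(genes$tss, b$genes$tss)
  obs <- read_bedpe(file.path(dir, "observed.bedpe"))
  expect_equal(nrow(obs), nrow(b$observed))
  cnt <- read_count_table(file.path(dir, "counts", "ER_enhancers.tsv"))
  expect_equal(cnt$matrix, b$counts$enh$ER$matrix)
  peaks <- read_bed(file.path(dir, "peaks", "t5.bed"))
  expect_equal(peaks[, c("chrom", "start", "end")],
               b$peaks[["5"]][, c("chrom", "start", "end")])
  tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  expect_equal(tr$enhancer_id, b$truth$enhancer_id)
})
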