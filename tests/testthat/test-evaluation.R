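test_that("split_chromosomes parses numeric suffixes, excludes the rest", {
  s <- split_chromosomes(c("chr2", "chr1", "chr3", "chr10", "chrX", "chrM"))
  expect_equal(s$train, c("chr1", "chr3"))
  expect_equal(s$test, c("chr10", "chr2"))
  expect_equal(s$excluded, c("chrM", "chrX"))
  expect_equal(split_chromosomes(c("1", "2"))$train, "1")
})

test_that("precision_at_tpr: worked example, edge cases, tie blocks", {
  p <- precision_at_tpr(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 0), 0.5)
  expect_equal(unname(p), 1.0)          # prefix {0.9} reaches recall 1/2
  # tau = 1 with the weakest item positive: prefix is the entire set, so
  # precision equals the overall positive fraction
  expect_equal(unname(precision_at_tpr(c(0.9, 0.5, 0.8, 0.4),
                                       c(1, 0, 0, 1), 1.0)), 0.5)
  # perfect separation and all-positive cases
  expect_true(all(precision_at_tpr(4:1, c(1, 1, 0, 0), c(0.1, 0.5, 1)) == 1))
  expect_true(all(precision_at_tpr(runif(5), rep(1, 5), c(0.1, 0.9)) == 1))
  expect_error(precision_at_tpr(1:3, c(0, 0, 0), 0.1), "no positive")
  # tied scores enter as a whole block
  p <- precision_at_tpr(c(0.9, 0.9, 0.9), c(1, 0, 0), 0.5)
  expect_equal(unname(p), 1 / 3)
})

test_that("precision_at_tpr and fdr_cutoff match exhaustive scans", {
  set.seed(81)
  for (i in 1:30) {
    n <- sample(10:50, 1)
    scores <- round(runif(n), 2)           # duplicates exercise tie logic
    labels <- rbinom(n, 1, 0.4)
    if (!any(labels)) labels[1] <- 1
    for (tau in c(0.1, 0.3, 0.7, 1)) {
      expect_equal(unname(precision_at_tpr(scores, labels, tau)),
                   oracle_precision_at_tpr(scores, labels == 1, tau))
    }
    for (f in c(0, 0.25, 0.5, 0.9)) {
      got <- fdr_cutoff(scores, labels, f)
      orc <- oracle_fdr_cutoff(scores, labels == 1, f)
      expect_equal(got$threshold, orc$threshold)
      expect_equal(got$tpr, orc$tpr)
    }
  }
})

test_that("fdr_cutoff: perfect separation, alternating labels, f = 0", {
  got <- fdr_cutoff(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0), 0.1)
  expect_equal(got$threshold, 0.8)       # lowest qualifying cutoff
  expect_equal(got$tpr, 1.0)
  # top item mislabeled and f = 0 -> undefined
  und <- fdr_cutoff(c(0.9, 0.8), c(0, 1), 0)
  expect_true(is.na(und$threshold))
  # TPR non-increasing as f decreases
  set.seed(82)
  scores <- runif(60); labels <- rbinom(60, 1, 0.5)
  cuts <- fdr_cutoff(scores, labels, c(0.5, 0.3, 0.1))
  tpr <- cuts$tpr[!is.na(cuts$tpr)]
  expect_true(all(diff(tpr) <= 0))
})

test_that("map_accuracy counts membership in per-enhancer truth sets", {
  map_df <- data.frame(enhancer_id = c("E1", "E2", "E3"),
                       map_gene = c("gA", "gB", "gZ"))
  truth <- data.frame(enhancer_id = c("E1", "E2", "E2", "E3"),
                      gene_id = c("gA", "gB", "gC", "gQ"))
  expect_equal(map_accuracy(map_df, truth), 100 * 2 / 3)
  # multi-target enhancer: either target counts
  truth2 <- data.frame(enhancer_id = c("E3", "E3"), gene_id = c("gZ", "gY"))
  expect_equal(map_accuracy(map_df, truth2), 100)
  expect_equal(map_accuracy(map_df, truth[1:2, ]), 100)
})

test_that("stratify_by_tad partitions pairs with the stated fallback", {
  tads <- regions(rep("chr1", 3), c(0, 1e6, 2e6), c(1e6, 2e6, 3e6))
  pairs <- data.frame(
    chrom = "chr1",
    enh_center = c(5e5, 5e5, 3.5e6, 1.5e6),
    tss_shifted = c(9e5, 1.5e6, 3.6e6, 1.9e6))
  intra <- stratify_by_tad(pairs, tads)
  expect_equal(intra, c(TRUE, FALSE, FALSE, TRUE))  # outside-all -> inter
  expect_equal(sum(intra) + sum(!intra), nrow(pairs))
  bad <- regions(rep("chr1", 2), c(0, 5e5), c(1e6, 1.5e6))
  expect_error(stratify_by_tad(pairs, bad), "overlapping TADs")
})

test_that("de_gene_validation follows the prefix-scan oracle", {
  gs <- data.frame(gene_id = paste0("g", 1:10),
                   regulation_prob = seq(1, 0.1, by = -0.1))
  # DE set anti-correlated with the score ranking
  de <- paste0("g", 6:10)
  pr <- de_gene_validation(gs, de)
  # brute-force prefix computation
  labels <- gs$gene_id %in% de
  for (i in seq_len(nrow(pr))) {
    sel <- gs$regulation_prob >= pr$threshold[i]
    expect_equal(pr$precision[i], sum(labels[sel]) / sum(sel))
    expect_equal(pr$recall[i], sum(labels[sel]) / length(de))
  }
  # degenerate: all scored genes DE / none DE
  expect_true(all(de_gene_validation(gs, gs$gene_id)$precision == 1))
  expect_true(all(de_gene_validation(gs, "absent")$precision == 0))
  expect_error(de_gene_validation(gs, character()), "empty")
})

test_that("evaluate_predictions assembles the report on labeled pairs only", {
  set.seed(83)
  k <- 40
  post <- data.frame(
    enhancer_id = rep(c("E1", "E2"), each = k / 2),
    gene_id = paste0("g", 1:k), chrom = "chr2",
    enh_center = rep(c(2e5, 1.2e6), each = k / 2),
    tss_shifted = runif(k, 0, 2.4e6),
    log10_dist = runif(k, 4, 6),
    posterior = runif(k),
    label = sample(c("positive", "negative", "unknown"), k, replace = TRUE,
                   prob = c(0.2, 0.6, 0.2)))
  post$posterior[post$label == "positive"] <-
    post$posterior[post$label == "positive"] + 1  # separable
  tads <- regions(rep("chr2", 2), c(0, 1.2e6), c(1.2e6, 2.4e6))
  rep <- evaluate_predictions(post, tads = tads)
  expect_equal(rep$n_positive + rep$n_negative, sum(post$label != "unknown"))
  expect_true(all(rep$precision_at_tpr == 1))
  expect_true(rep$map_accuracy >= 0 && rep$map_accuracy <= 100)
  expect_equal(rep$intra_tad$n_positive + rep$inter_tad$n_positive,
               rep$n_positive)
})
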