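test_that("pearson_cor matches the textbook formula and its guards", {
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_cor(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(pearson_cor(c(5, 5, 5), c(1, 2, 3)), 0)  # zero variance
  expect_error(pearson_cor(1:3, 1:4), "length mismatch")
  # affine invariance (positive slope) and antisymmetry under negation
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    r <- pearson_cor(x, y)
    expect_equal(pearson_cor(2.5 * x + 3, y), r)
    expect_equal(pearson_cor(x, -y), -r)
  }
})

# two enhancers on chr1, genes on chr1 and chr2; hand-set time series
feature_fixture <- function() {
  g <- tiny_genes()
  enh <- regions("chr1", c(100000, 200000), c(100800, 201000))
  enh$center <- floor((enh$start + enh$end) / 2)
  tp <- c(0, 5, 10, 20)
  set.seed(77)
  mk_ts <- function(ids, n) {
    function(assay) ts_set(matrix(abs(rnorm(n * 4, 50, 10)), nrow = n),
                           tp, ids, rep(1e6, 4), assay = assay,
                           normalized = TRUE)
  }
  assays <- c("ER", "PolII_rep1", "PolII_rep2", "H2AZ", "H3K4me3")
  enh_ts <- setNames(lapply(assays, mk_ts(enh$name, 2)), assays)
  gene_ts <- setNames(lapply(assays, mk_ts(g$name, 3)), assays)
  list(genes = g, enh = enh, enh_ts = enh_ts, gene_ts = gene_ts)
}

test_that("build_features constructs the candidate universe and distance", {
  fx <- feature_fixture()
  feats <- build_features(fx$enh_ts, fx$gene_ts, fx$enh, fx$genes)
  # same-chromosome universe only: 2 enhancers x 2 chr1 genes
  expect_equal(nrow(feats), 4)
  expect_false("gC" %in% feats$gene_id)
  expect_setequal(names(feats)[grepl("^c_", names(feats))],
                  c("c_ER", "c_PolII", c("c_H2AZ", "c_H3K4me3")))
  # distance: |shifted TSS - centre|, log10
  r1 <- feats[feats$enhancer_id == fx$enh$name[1] & feats$gene_id == "gA", ]
  expect_equal(r1$log10_dist, log10(abs((10000 - 300) - 100400)))
  # PolII feature is the average of the two replicate correlations
  rep1 <- fx$enh_ts$PolII_rep1$matrix[1, ]
  rep2 <- fx$enh_ts$PolII_rep2$matrix[1, ]
  gA1 <- fx$gene_ts$PolII_rep1$matrix[1, ]
  gA2 <- fx$gene_ts$PolII_rep2$matrix[1, ]
  expect_equal(r1$c_PolII, (pearson_cor(rep1, gA1) + pearson_cor(rep2, gA2)) / 2)
  expect_equal(r1$c_ER, pearson_cor(fx$enh_ts$ER$matrix[1, ],
                                    fx$gene_ts$ER$matrix[1, ]))
  expect_true(all(abs(feats[, grepl("^c_", names(feats))]) <= 1))
  expect_true(all(feats$label == "unknown"))
})

test_that("build_features errors on zero separation and caps distance", {
  fx <- feature_fixture()
  enh0 <- fx$enh
  enh0$center[1] <- 10000 - 300  # exactly the shifted TSS of gA
  expect_error(build_features(fx$enh_ts, fx$gene_ts, enh0, fx$genes),
               "zero separation")
  capped <- build_features(fx$enh_ts, fx$gene_ts, fx$enh, fx$genes,
                           max_distance = 95000)
  expect_true(all(10^capped$log10_dist <= 95000))
  expect_lt(nrow(capped), 4)
})

test_that("feature construction is deterministic", {
  fx <- feature_fixture()
  a <- build_features(fx$enh_ts, fx$gene_ts, fx$enh, fx$genes)
  b <- build_features(fx$enh_ts, fx$gene_ts, fx$enh, fx$genes)
  expect_identical(a, b)
})

test_that("label_pairs implements positive/negative/unknown semantics", {
  fx <- feature_fixture()
  feats <- build_features(fx$enh_ts, fx$gene_ts, fx$enh, fx$genes)
  e1 <- fx$enh[1, ]
  # one anchor overlaps enhancer 1, mate overlaps gA's promoter extension
  truth <- data.frame(chrom_a = "chr1", start_a = e1$start, end_a = e1$end,
                      chrom_b = "chr1", start_b = 9700, end_b = 9800,
                      score = NA, stringsAsFactors = FALSE)
  lab <- label_pairs(feats, truth, fx$enh, fx$genes)
  get <- function(e, g) lab$label[lab$enhancer_id == e & lab$gene_id == g]
  expect_equal(get(e1$name, "gA"), "positive")
  expect_equal(get(e1$name, "gB"), "negative")   # same enhancer, other gene
  expect_equal(get(fx$enh$name[2], "gA"), "unknown")  # enhancer never anchored
  expect_equal(get(fx$enh$name[2], "gB"), "unknown")
  # swapped anchor orientation gives the same labels
  truth_sw <- truth[, c(4:6, 1:3, 7)]
  names(truth_sw) <- names(truth)
  expect_identical(label_pairs(feats, truth_sw, fx$enh, fx$genes)$label,
                   lab$label)
  # positive-pair enhancers never appear among unknowns
  pos_enh <- unique(lab$enhancer_id[lab$label == "positive"])
  expect_false(any(lab$enhancer_id %in% pos_enh & lab$label == "unknown"))
  # empty truth: everything unknown
  expect_true(all(label_pairs(feats, truth[0, ], fx$enh,
                              fx$genes)$label == "unknown"))
})

test_that("feature tables round-trip through TSV", {
  fx <- feature_fixture()
  feats <- build_features(fx$enh_ts, fx$gene_ts, fx$enh, fx$genes)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_features(feats, p)
  back <- read_features(p)
  expect_equal(back$c_ER, feats$c_ER)
  expect_equal(back$log10_dist, feats$log10_dist)
  expect_identical(back$label, feats$label)
})
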