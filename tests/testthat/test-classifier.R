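mk_pairs <- function(k, features = c("c_ER", "log10_dist"),
                     enhancer_id = "E1") {
  df <- data.frame(enhancer_id = enhancer_id,
                   gene_id = sprintf("g%02d", seq_len(k)),
                   chrom = "chr2", stringsAsFactors = FALSE)
  for (f in features) df[[f]] <- rnorm(k)
  df$log10_dist <- abs(df$log10_dist) + 3
  df$label <- "unknown"
  df
}

test_that("pair_log_ratio reduces to known closed cases", {
  set.seed(71)
  pairs <- mk_pairs(4)
  # identical positive and negative densities -> ratio 0 everywhere
  same <- random_densities(c("c_ER", "log10_dist"))
  for (f in same$features) same$densities[[f]]$negative <- same$densities[[f]]$positive
  expect_equal(pair_log_ratio(pairs, same), rep(0, 4))
  # feature subset {distance} with P(d|1) = 2 P(d|0): ratio log 2
  dens <- random_densities("log10_dist", m = 1)
  dens$densities$log10_dist$positive <- kde_density(5, 1)
  dens$densities$log10_dist$negative <- kde_density(5 + sqrt(2 * log(2)), 1)
  expect_equal(pair_log_ratio(data.frame(log10_dist = 5), dens,
                              "log10_dist"), log(2))
  expect_error(pair_log_ratio(pairs, dens, "c_H2AZ"), "no fitted density")
})

test_that("pair_log_ratio equals the naive per-feature product oracle", {
  set.seed(72)
  for (i in 1:10) {
    feats <- c("c_ER", "c_PolII", "log10_dist")
    pairs <- mk_pairs(6, feats)
    dens <- random_densities(feats)
    lr <- pair_log_ratio(pairs, dens, feats)
    oracle <- vapply(seq_len(6), function(j) {
      tot <- 0
      for (f in feats) {
        dp <- dens$densities[[f]]$positive
        dn <- dens$densities[[f]]$negative
        tot <- tot + oracle_kde_logpdf(dp$values, dp$bandwidth, pairs[[f]][j]) -
          oracle_kde_logpdf(dn$values, dn$bandwidth, pairs[[f]][j])
      }
      tot
    }, numeric(1))
    expect_equal(lr, oracle, tolerance = 1e-12)
  }
})

test_that("posterior_over_genes: closed cases and normalization", {
  expect_equal(posterior_over_genes(c(log(3), 0)), c(0.75, 0.25))
  expect_equal(posterior_over_genes(rep(2.2, 5)), rep(0.2, 5))
  expect_equal(posterior_over_genes(0), 1)
  expect_error(posterior_over_genes(c(-Inf, -Inf)), "degenerate")
  set.seed(73)
  for (i in 1:50) {
    p <- posterior_over_genes(rnorm(sample(1:12, 1), sd = 5))
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("cancellation-based posterior equals the full-product oracle", {
  set.seed(74)
  feats <- c("c_ER", "c_PolII", "c_H2AZ", "c_H3K4me3", "log10_dist")
  for (i in 1:25) {
    k <- sample(2:10, 1)
    pairs <- mk_pairs(k, feats)
    dens <- random_densities(feats)
    post <- posterior_table(pairs, dens, feats)
    fm <- as.matrix(pairs[, feats])
    colnames(fm) <- feats
    expect_equal(post$posterior, oracle_posterior(fm, dens$densities),
                 tolerance = 1e-9)
  }
})

test_that("posterior obeys prior odds and log-ratio monotonicity", {
  set.seed(75)
  lr <- rnorm(5)
  uni <- posterior_over_genes(lr)
  pri <- c(0.4, 0.3, 0.1, 0.1, 0.1)
  wp <- posterior_over_genes(lr, pri)
  # posterior odds change by exactly the prior odds
  expect_equal((wp[1] / wp[2]) / (uni[1] / uni[2]), pri[1] / pri[2])
  # increasing one ratio strictly raises its posterior, lowers the rest
  lr2 <- lr; lr2[3] <- lr2[3] + 1
  up <- posterior_over_genes(lr2)
  expect_gt(up[3], uni[3])
  expect_true(all(up[-3] < uni[-3]))
  # uninformative features: posterior equals the prior
  pairs <- mk_pairs(5)
  same <- random_densities(c("c_ER", "log10_dist"))
  for (f in same$features) same$densities[[f]]$negative <- same$densities[[f]]$positive
  post <- posterior_table(pairs, same, prior = list(E1 = pri))
  expect_equal(post$posterior, pri)
})

test_that("map_target breaks ties by distance then gene id", {
  post <- data.frame(enhancer_id = "E1", gene_id = c("gB", "gA", "gC"),
                     posterior = c(0.4, 0.4, 0.2),
                     log10_dist = c(log10(50000), log10(10000), 4))
  m <- map_target(post)
  expect_equal(m$map_gene, "gA")     # tie -> nearer gene
  expect_equal(m$map_prob, 0.4)
  post$log10_dist <- 4               # full tie -> lexicographic
  expect_equal(map_target(post[1:2, ])$map_gene, "gA")
  one <- data.frame(enhancer_id = "E2", gene_id = "gZ", posterior = 1,
                    log10_dist = 5)
  expect_equal(map_target(one)$map_prob, 1)
})

test_that("gene_regulation_score implements the no-regulator complement", {
  post <- data.frame(enhancer_id = c("E1", "E2", "E3"),
                     gene_id = c("gA", "gA", "gB"),
                     posterior = c(0.5, 0.5, 0.3),
                     log10_dist = 4)
  gs <- gene_regulation_score(post)
  expect_equal(gs$regulation_prob[gs$gene_id == "gA"], 0.75)  # 1 - 0.25
  expect_equal(gs$regulation_prob[gs$gene_id == "gB"], 0.3)   # single enhancer
  expect_equal(gs$n_enhancers[gs$gene_id == "gA"], 2)
  # absorbing posterior of 1
  post$posterior[1] <- 1
  expect_equal(gene_regulation_score(post)$regulation_prob[1], 1)
  # monotone in each contributing posterior and in contributor count
  s1 <- 1 - (1 - 0.2) * (1 - 0.3)
  s2 <- 1 - (1 - 0.2) * (1 - 0.4)
  s3 <- 1 - (1 - 0.2) * (1 - 0.3) * (1 - 0.1)
  expect_gt(s2, s1)
  expect_gt(s3, s1)
})
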