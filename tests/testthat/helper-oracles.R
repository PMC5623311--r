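# Independent brute-force oracles used to check the implementation.
# These are deliberately naive (loops, full products, exhaustive scans)
# and share no code with the package internals they verify.

# transitive merge of overlapping intervals by explicit adjacency closure
oracle_merge <- function(df) {
  n <- nrow(df)
  if (n == 0) return(df)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- df$chrom[i] == df$chrom[j] &&
        df$start[i] < df$end[j] && df$start[j] < df$end[i]
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (adj[i, j] && comp[j] != comp[i]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(comp), function(cid) {
    sel <- df[comp == cid, , drop = FALSE]
    data.frame(chrom = sel$chrom[1], start = min(sel$start),
               end = max(sel$end), stringsAsFactors = FALSE)
  }))
  out[order(out$chrom, out$start), , drop = FALSE]
}

oracle_kde_logpdf <- function(values, h, q) {
  vapply(q, function(x) {
    log(mean(stats::dnorm((x - values) / h)) / h)
  }, numeric(1))
}

oracle_cv_bandwidth <- function(values, labels, grid) {
  score <- vapply(grid, function(h) {
    tot <- 0
    for (ch in unique(labels)) {
      train <- values[labels != ch]
      test <- values[labels == ch]
      if (!length(train) || !length(test)) next
      tot <- tot + sum(oracle_kde_logpdf(train, h, test))
    }
    tot
  }, numeric(1))
  sort(grid)[which.max(score[order(grid)])]
}

# full single-target posterior: per candidate structure, the product of
# the target pair's positive densities and every other pair's negative
# densities over all features -- no cancellation shortcut
oracle_posterior <- function(feat_mat, dens, prior = NULL) {
  k <- nrow(feat_mat)
  if (is.null(prior)) prior <- rep(1 / k, k)
  lp <- function(cls) {
    m <- matrix(0, k, ncol(feat_mat))
    for (f in seq_len(ncol(feat_mat))) {
      d <- dens[[colnames(feat_mat)[f]]][[cls]]
      m[, f] <- oracle_kde_logpdf(d$values, d$bandwidth, feat_mat[, f])
    }
    rowSums(m)
  }
  lpos <- lp("positive")
  lneg <- lp("negative")
  # full per-structure likelihood: the target pair's positive term times
  # every other pair's negative term (no cancellation shortcut)
  lik <- vapply(seq_len(k), function(target) {
    lpos[target] + sum(lneg[-target])
  }, numeric(1))
  w <- prior * exp(lik - max(lik))
  w / sum(w)
}

oracle_precision_at_tpr <- function(scores, labels, tau) {
  n_pos <- sum(labels)
  best <- NA_real_
  for (thr in sort(unique(scores), decreasing = TRUE)) {
    sel <- scores >= thr
    recall <- sum(labels[sel]) / n_pos
    if (recall >= tau) {
      best <- sum(labels[sel]) / sum(sel)
      break
    }
  }
  best
}

oracle_fdr_cutoff <- function(scores, labels, f) {
  n_pos <- sum(labels)
  best_thr <- NA_real_
  best_tpr <- -1
  for (thr in sort(unique(scores), decreasing = TRUE)) {
    sel <- scores >= thr
    prec <- sum(labels[sel]) / sum(sel)
    tpr <- sum(labels[sel]) / n_pos
    if (prec >= 1 - f && tpr > best_tpr) {
      best_tpr <- tpr
      best_thr <- thr
    }
  }
  list(threshold = best_thr, tpr = if (best_tpr < 0) NA_real_ else best_tpr)
}

# random KDE densities over a feature set, for classifier oracle tests
random_densities <- function(features, m = 8) {
  dens <- lapply(features, function(f) {
    lapply(c(positive = "positive", negative = "negative"), function(cl) {
      kde_density(stats::rnorm(m, mean = stats::runif(1, -1, 1)),
                  bandwidth = stats::runif(1, 0.2, 1.5),
                  feature = f, class = cl)
    })
  })
  names(dens) <- features
  structure(list(densities = dens, features = features, chroms = "chrS",
                 n_positive = m, n_negative = m),
            class = "class_densities")
}

tiny_genes <- function() {
  g <- regions(c("chr1", "chr1", "chr2"), c(10000, 50000, 20000),
               c(15000, 58000, 26000), name = c("gA", "gB", "gC"),
               strand = c("+", "-", "+"))
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1)
  g
}
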