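#' Gaussian kernel density estimate
#'
#' Stores the training values and bandwidth; evaluation is exact (sum over
#' all training points), not binned, because class-conditional likelihoods
#' feed straight into the Naive Bayes log-ratio and binning error would
#' bias posteriors.
#'
#' @param values numeric training values (non-empty, finite).
#' @param bandwidth positive kernel bandwidth.
#' @param feature feature name (e.g. `"c_ER"`, `"log10_dist"`).
#' @param class `"positive"` or `"negative"`.
#' @return object of class `kde_density`.
#' @export
kde_density <- function(values, bandwidth, feature = "feature",
                        class = "positive") {
  values <- as.numeric(values)
  stopifnot(length(values) >= 1, all(is.finite(values)),
            is.finite(bandwidth), bandwidth > 0)
  structure(list(values = values, bandwidth = bandwidth,
                 feature = feature, class = class),
            class = "kde_density")
}

#' @export
print.kde_density <- function(x, ...) {
  cat(sprintf("<kde_density> %s|%s: m=%d, h=%.6g\n", x$feature, x$class,
              length(x$values), x$bandwidth))
  invisible(x)
}

#' Log density of a Gaussian KDE
#'
#' `log (1/(m h)) sum_i phi((q - v_i)/h)`, computed with log-sum-exp so
#' that far-out queries return a large negative finite value instead of
#' `-Inf` (up to underflow of the largest summand).
#'
#' @param density a [kde_density()].
#' @param query numeric vector of evaluation points.
#' @param chunk internal block size for memory control.
#' @return numeric vector of log densities.
#' @export
kde_logpdf <- function(density, query, chunk = 4096L) {
  stopifnot(inherits(density, "kde_density"))
  v <- density$values
  h <- density$bandwidth
  m <- length(v)
  const <- -log(m) - log(h) - 0.5 * log(2 * pi)
  out <- numeric(length(query))
  for (from in seq(1, length(query), by = chunk)) {
    to <- min(from + chunk - 1L, length(query))
    q <- query[from:to]
    e <- -0.5 * (outer(q, v, "-") / h)^2   # nq x m
    mx <- e[cbind(seq_along(q), max.col(e, ties.method = "first"))]
    out[from:to] <- mx + log(rowSums(exp(e - mx))) + const
  }
  out
}

#' Scott's rule bandwidth
#'
#' One-dimensional plug-in rule `h = sd(values) * n^(-1/5)` with the
#' (n-1)-denominator sample standard deviation. Used for the background
#' (negative) class, where the sample is large enough that plug-in
#' selection suffices.
#'
#' @param values numeric vector, length >= 2, positive variance.
#' @return positive bandwidth.
#' @export
scott_bandwidth <- function(values) {
  n <- length(values)
  if (n < 2) stop("scott_bandwidth needs n >= 2")
  s <- stats::sd(values)
  if (s == 0) stop("scott_bandwidth: zero variance")
  s * n^(-1 / 5)
}

#' Leave-one-chromosome-out cross-validated bandwidth
#'
#' For each candidate bandwidth, every chromosome's values are held out in
#' turn, the KDE is fitted on the remaining values, and the held-out
#' log-likelihood is accumulated; the grid value with the highest total
#' wins. This keeps positive-class bandwidths honest despite the small
#' positive sample. Ties on the objective go to the smaller bandwidth.
#'
#' @param values numeric training values.
#' @param chrom_labels chromosome label per value (>= 2 distinct).
#' @param grid candidate bandwidths; default 30 log-spaced values spanning
#'   `scott/10 .. scott*10` around the Scott's-rule pilot.
#' @return the selected bandwidth.
#' @export
cv_bandwidth <- function(values, chrom_labels, grid = NULL) {
  stopifnot(length(values) == length(chrom_labels), length(values) >= 2)
  chroms <- unique(chrom_labels)
  if (length(chroms) < 2) {
    stop("cv_bandwidth needs values from >= 2 chromosomes")
  }
  if (is.null(grid)) {
    pilot <- scott_bandwidth(values)
    grid <- exp(seq(log(pilot / 10), log(pilot * 10), length.out = 30))
  }
  stopifnot(length(grid) >= 1, all(grid > 0))
  grid <- sort(grid)
  total <- numeric(length(grid))
  for (ch in chroms) {
    test <- values[chrom_labels == ch]
    train <- values[chrom_labels != ch]
    if (!length(train)) {
      warning(sprintf("cv_bandwidth: empty training set for fold %s; skipped", ch))
      next
    }
    if (!length(test)) next
    d <- outer(test, train, "-")  # reused across the whole grid
    for (i in seq_along(grid)) {
      e <- -0.5 * (d / grid[i])^2
      mx <- e[cbind(seq_len(nrow(e)), max.col(e, ties.method = "first"))]
      ll <- mx + log(rowSums(exp(e - mx))) -
        log(length(train)) - log(grid[i]) - 0.5 * log(2 * pi)
      total[i] <- total[i] + sum(ll)
    }
  }
  grid[which.max(total)]
}

#' Fit class-conditional densities for every feature
#'
#' Positive-class densities get leave-one-chromosome-out cross-validated
#' bandwidths; negative-class densities use Scott's rule (the background
#' set is large, making CV both unnecessary and expensive).
#'
#' @param pairs labeled feature table (from [label_pairs()]).
#' @param feature_cols feature column names; default every `c_*` column
#'   plus `log10_dist`.
#' @param grid optional CV bandwidth grid passed to [cv_bandwidth()].
#' @return object of class `class_densities`: list
#'   `densities[[feature]][[class]]` plus provenance (`chroms`, counts).
#' @export
fit_class_densities <- function(pairs, feature_cols = NULL, grid = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- c(grep("^c_", names(pairs), value = TRUE), "log10_dist")
  }
  stopifnot(all(feature_cols %in% names(pairs)),
            all(c("label", "chrom") %in% names(pairs)))
  pos <- pairs[pairs$label == "positive", , drop = FALSE]
  neg <- pairs[pairs$label == "negative", , drop = FALSE]
  if (nrow(pos) < 2 || nrow(neg) < 2) {
    stop("need >= 2 positive and >= 2 negative pairs to fit densities")
  }
  cv_ok <- length(unique(pos$chrom)) >= 2
  if (!cv_ok) {
    warning("positive pairs span a single chromosome: ",
            "falling back to Scott's rule for positive bandwidths")
  }
  dens <- lapply(feature_cols, function(fc) {
    h_pos <- if (cv_ok) cv_bandwidth(pos[[fc]], pos$chrom, grid = grid) else
      scott_bandwidth(pos[[fc]])
    h_neg <- scott_bandwidth(neg[[fc]])
    list(positive = kde_density(pos[[fc]], h_pos, feature = fc,
                                class = "positive"),
         negative = kde_density(neg[[fc]], h_neg, feature = fc,
                                class = "negative"))
  })
  names(dens) <- feature_cols
  structure(list(densities = dens, features = feature_cols,
                 chroms = sort(unique(pos$chrom)),
                 n_positive = nrow(pos), n_negative = nrow(neg)),
            class = "class_densities")
}

#' @export
print.class_densities <- function(x, ...) {
  cat(sprintf("<class_densities> %d features, %d pos / %d neg pairs (chroms: %s)\n",
              length(x$features), x$n_positive, x$n_negative,
              paste(x$chroms, collapse = ",")))
  invisible(x)
}

#' Serialize / restore fitted densities as portable JSON
#' @param model a `class_densities` object.
#' @param path file path.
#' @export
write_densities <- function(model, path) {
  obj <- list(features = model$features, chroms = model$chroms,
              n_positive = model$n_positive, n_negative = model$n_negative,
              densities = lapply(model$densities, function(fc) {
                lapply(fc, function(d) list(values = d$values,
                                            bandwidth = d$bandwidth))
              }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_densities
#' @export
read_densities <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- obj$features
  dens <- lapply(feats, function(fc) {
    lapply(stats::setNames(c("positive", "negative"),
                           c("positive", "negative")), function(cl) {
      d <- obj$densities[[fc]][[cl]]
      kde_density(d$values, d$bandwidth, feature = fc, class = cl)
    })
  })
  names(dens) <- feats
  structure(list(densities = dens, features = feats, chroms = obj$chroms,
                 n_positive = obj$n_positive, n_negative = obj$n_negative),
            class = "class_densities")
}
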