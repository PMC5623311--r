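#' Per-pair Naive Bayes log density ratio
#'
#' For each candidate pair, the log ratio of interacting to background
#' class-conditional likelihoods under conditional independence of the
#' attributes:
#' `log r = sum_f [ log P(f | interacting) - log P(f | background) ]`
#' over the configured feature subset. Distance-alone, data-alone and any
#' combination are obtained by choosing `feature_subset`.
#'
#' @param pairs feature table.
#' @param model fitted [fit_class_densities()] object.
#' @param feature_subset feature columns to use; default all fitted.
#' @return numeric vector of log ratios, one per row of `pairs`.
#' @export
pair_log_ratio <- function(pairs, model, feature_subset = NULL) {
  stopifnot(inherits(model, "class_densities"))
  if (is.null(feature_subset)) feature_subset <- model$features
  missing <- setdiff(feature_subset, model$features)
  if (length(missing)) {
    stop("no fitted density for feature(s): ", paste(missing, collapse = ", "))
  }
  missing <- setdiff(feature_subset, names(pairs))
  if (length(missing)) {
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  }
  lr <- numeric(nrow(pairs))
  for (fc in feature_subset) {
    d <- model$densities[[fc]]
    lr <- lr + kde_logpdf(d$positive, pairs[[fc]]) -
      kde_logpdf(d$negative, pairs[[fc]])
  }
  lr
}

#' Posterior over one enhancer's candidate genes
#'
#' Under the single-target restriction, the posterior of "this enhancer's
#' target is gene k" is `prior_k * r_k / sum_l prior_l * r_l`: the product
#' of background densities over non-target pairs is common to every
#' candidate structure and cancels, leaving only the per-pair ratios.
#' Computed in log space with log-sum-exp.
#'
#' @param log_ratios per-candidate log density ratios.
#' @param prior per-candidate prior; default uniform `1/K`. Must sum to 1.
#' @return posterior probability vector (sums to 1).
#' @export
posterior_over_genes <- function(log_ratios, prior = NULL) {
  k <- length(log_ratios)
  stopifnot(k >= 1)
  if (is.null(prior)) prior <- rep(1 / k, k)
  stopifnot(length(prior) == k, all(prior >= 0),
            abs(sum(prior) - 1) < 1e-6)
  lp <- log_ratios + log(prior)
  mx <- max(lp)
  if (!is.finite(mx)) {
    stop("all candidate log ratios are -Inf: degenerate densities")
  }
  w <- exp(lp - mx)
  w / sum(w)
}

#' Score every enhancer's candidates and take posteriors
#'
#' Groups the feature table by enhancer, computes per-pair log ratios and
#' per-enhancer posteriors. Row order within an enhancer follows the
#' feature table.
#'
#' @param pairs feature table.
#' @param model fitted densities.
#' @param feature_subset feature columns to use (default all fitted).
#' @param prior optional named list: enhancer_id -> prior vector; default
#'   uniform per enhancer.
#' @return `pairs` plus columns `log_ratio` and `posterior`, of class
#'   `posterior_table`.
#' @export
posterior_table <- function(pairs, model, feature_subset = NULL,
                            prior = NULL) {
  pairs$log_ratio <- pair_log_ratio(pairs, model, feature_subset)
  pairs$posterior <- NA_real_
  for (idx in split(seq_len(nrow(pairs)), pairs$enhancer_id)) {
    p <- if (!is.null(prior)) prior[[pairs$enhancer_id[idx[1]]]] else NULL
    pairs$posterior[idx] <- posterior_over_genes(pairs$log_ratio[idx], p)
  }
  class(pairs) <- c("posterior_table", class(pairs))
  pairs
}

#' Maximum a posteriori target gene per enhancer
#'
#' The gene with the largest posterior; exact ties are broken by smaller
#' genomic separation, then lexicographically by gene id, so the result
#' is deterministic.
#'
#' @param post a [posterior_table()] (needs `log10_dist`).
#' @return data.frame: `enhancer_id`, `map_gene`, `map_prob`, `n_candidates`.
#' @export
map_target <- function(post) {
  stopifnot(all(c("enhancer_id", "gene_id", "posterior") %in% names(post)))
  groups <- split(seq_len(nrow(post)), post$enhancer_id)
  out <- lapply(names(groups), function(eid) {
    idx <- groups[[eid]]
    ord <- order(-post$posterior[idx], post$log10_dist[idx],
                 post$gene_id[idx])
    best <- idx[ord[1]]
    data.frame(enhancer_id = eid, map_gene = post$gene_id[best],
               map_prob = post$posterior[best], n_candidates = length(idx),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gene-level regulation scores
#'
#' The probability that a gene has at least one regulating enhancer:
#' `1 - prod_j (1 - P_j(gene))` over every enhancer whose candidate set
#' contains the gene. Enhancers with unknown truth status contribute too:
#' target-gene prediction uses all enhancers, not just the labeled ones.
#'
#' @param post a [posterior_table()].
#' @return data.frame: `gene_id`, `regulation_prob`, `n_enhancers`,
#'   sorted by decreasing score.
#' @export
gene_regulation_score <- function(post) {
  groups <- split(post$posterior, post$gene_id)
  score <- vapply(groups, function(p) 1 - prod(1 - p), numeric(1))
  res <- data.frame(gene_id = names(groups),
                    regulation_prob = unname(score),
                    n_enhancers = unname(lengths(groups)),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$regulation_prob, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Export predicted links as BEDPE
#'
#' One line per pair with posterior at or above `min_posterior`; the
#' posterior goes in the score column.
#'
#' @param post a [posterior_table()].
#' @param enhancers consensus enhancer table.
#' @param genes gene table.
#' @param path output path.
#' @param min_posterior threshold (default 0: all pairs).
#' @param promoter_ext promoter extension for the gene anchor.
#' @export
export_links_bedpe <- function(post, enhancers, genes, path,
                               min_posterior = 0, promoter_ext = 300) {
  keep <- post$posterior >= min_posterior
  sel <- post[keep, , drop = FALSE]
  ei <- match(sel$enhancer_id, enhancers$name)
  ext <- promoter_extended(genes, promoter_ext)
  gi <- match(sel$gene_id, ext$name)
  df <- data.frame(chrom_a = enhancers$chrom[ei],
                   start_a = enhancers$start[ei], end_a = enhancers$end[ei],
                   chrom_b = ext$chrom[gi], start_b = ext$start[gi],
                   end_b = ext$end[gi], score = sel$posterior,
                   stringsAsFactors = FALSE)
  write_bedpe(df, path)
}
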