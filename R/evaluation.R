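#' Odd/even chromosome split
#'
#' Parses the trailing integer of each chromosome name (`chr1` .. `chr22`
#' or bare `1` .. `22`); odd numbers train, even numbers test. Names
#' without a trailing integer (chrX, chrY, chrM) are excluded by default.
#'
#' @param chroms character vector of chromosome names.
#' @param include_nonnumeric put non-numeric chromosomes in neither set
#'   (FALSE, default) or error (TRUE is not supported; they are simply
#'   reported in `excluded`).
#' @return list with `train`, `test`, `excluded` chromosome name vectors.
#' @export
split_chromosomes <- function(chroms, include_nonnumeric = FALSE) {
  chroms <- unique(chroms)
  num <- suppressWarnings(as.integer(sub("^.*?([0-9]+)$", "\\1", chroms)))
  num[!grepl("[0-9]+$", chroms)] <- NA
  list(train = sort(chroms[!is.na(num) & num %% 2 == 1]),
       test = sort(chroms[!is.na(num) & num %% 2 == 0]),
       excluded = sort(chroms[is.na(num)]))
}

# Block-wise prefix scan over scores sorted descending; tied scores are
# always taken as a whole block. Returns one row per distinct threshold.
.prefix_table <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ord <- order(-scores)
  s <- scores[ord]
  l <- as.integer(labels[ord])
  n_pos <- sum(l)
  block_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[block_end]
  taken <- block_end
  data.frame(threshold = s[block_end], taken = taken, tp = tp,
             precision = tp / taken,
             recall = if (n_pos > 0) tp / n_pos else NA_real_)
}

#' Precision at fixed recall levels
#'
#' Pairs are ranked by score (descending); for each recall level the
#' smallest prefix whose recall reaches the level is taken (tied scores
#' enter as a whole block) and its precision TP/(TP+FP) reported.
#'
#' @param scores numeric prediction scores.
#' @param labels binary truth labels (1/TRUE = positive); at least one
#'   positive required.
#' @param tpr_levels recall levels (default 0.10, 0.20, 0.30).
#' @return named numeric vector of precisions, one per level (NA when the
#'   level is unreachable, which only happens with zero positives).
#' @export
precision_at_tpr <- function(scores, labels, tpr_levels = c(0.1, 0.2, 0.3)) {
  labels <- as.logical(labels)
  if (!any(labels)) stop("precision_at_tpr: no positive labels")
  pt <- .prefix_table(scores, labels)
  out <- vapply(tpr_levels, function(tau) {
    i <- which(pt$recall >= tau)
    if (!length(i)) return(NA_real_)
    pt$precision[i[1]]
  }, numeric(1))
  names(out) <- sprintf("tpr_%g", tpr_levels)
  out
}

#' Posterior cutoffs indexed by FDR
#'
#' For each FDR level f, among all score thresholds whose prefix precision
#' is at least 1 - f, returns the one with the largest TPR (the lowest
#' qualifying threshold). Undefined levels (no threshold qualifies) are
#' reported as NA.
#'
#' @param scores,labels as in [precision_at_tpr()].
#' @param fdr_levels FDR levels (default 0.20, 0.25, 0.30).
#' @return data.frame: `fdr`, `threshold`, `tpr`, `precision`.
#' @export
fdr_cutoff <- function(scores, labels, fdr_levels = c(0.2, 0.25, 0.3)) {
  labels <- as.logical(labels)
  if (!any(labels)) stop("fdr_cutoff: no positive labels")
  pt <- .prefix_table(scores, labels)
  rows <- lapply(fdr_levels, function(f) {
    ok <- which(pt$precision >= 1 - f)
    if (!length(ok)) {
      return(data.frame(fdr = f, threshold = NA_real_, tpr = NA_real_,
                        precision = NA_real_))
    }
    best <- ok[which.max(pt$recall[ok])]
    data.frame(fdr = f, threshold = pt$threshold[best], tpr = pt$recall[best],
               precision = pt$precision[best])
  })
  do.call(rbind, rows)
}

#' MAP accuracy against ground-truth targets
#'
#' Percentage of evaluated enhancers whose MAP gene is among that
#' enhancer's confirmed targets. Only enhancers present in `truth` are
#' evaluated.
#'
#' @param map_df output of [map_target()].
#' @param truth data.frame with columns `enhancer_id`, `gene_id` (one row
#'   per confirmed link; an enhancer may have several).
#' @return percentage in `[0, 100]`.
#' @export
map_accuracy <- function(map_df, truth) {
  targets <- split(truth$gene_id, truth$enhancer_id)
  eval_ids <- intersect(map_df$enhancer_id, names(targets))
  if (!length(eval_ids)) stop("map_accuracy: no enhancer with ground truth")
  sub <- map_df[match(eval_ids, map_df$enhancer_id), ]
  correct <- mapply(function(g, eid) g %in% targets[[eid]],
                    sub$map_gene, sub$enhancer_id)
  100 * mean(correct)
}

#' Partition pairs into intra- and inter-TAD
#'
#' A pair is intra iff the enhancer centre and the shifted TSS fall
#' inside the same TAD interval; pairs in different TADs, or with either
#' element outside every TAD, are inter. TADs must be non-overlapping
#' within each chromosome.
#'
#' @param pairs feature table (needs `chrom`, `enh_center`, `tss_shifted`).
#' @param tads region table of TAD intervals.
#' @return logical vector `intra` along rows of `pairs`.
#' @export
stratify_by_tad <- function(pairs, tads) {
  validate_regions(tads, "TAD")
  # overlap validation per chromosome
  for (ch in unique(tads$chrom)) {
    t <- tads[tads$chrom == ch, , drop = FALSE]
    t <- t[order(t$start), , drop = FALSE]
    if (nrow(t) > 1 && any(t$start[-1] < t$end[-nrow(t)])) {
      stop(sprintf("overlapping TADs on %s", ch))
    }
  }
  tad_of <- function(chrom, pos) {
    out <- rep(NA_integer_, length(pos))
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      t <- tads[tads$chrom == ch, , drop = FALSE]
      if (!nrow(t)) next
      t <- t[order(t$start), , drop = FALSE]
      i <- findInterval(pos[sel], t$start)
      inside <- i >= 1 & pos[sel] < t$end[pmax(i, 1)]
      ids <- which(tads$chrom == ch)[order(tads$start[tads$chrom == ch])]
      out[sel][inside] <- ids[i[inside]]
    }
    out
  }
  te <- tad_of(pairs$chrom, pairs$enh_center)
  tg <- tad_of(pairs$chrom, pairs$tss_shifted)
  !is.na(te) & !is.na(tg) & te == tg
}

#' Precision-recall of predicted target genes against a DE gene list
#'
#' Genes are ranked by regulation score (descending, tied scores as a
#' block); precision and recall of membership in the externally supplied
#' differentially-expressed gene list are computed along the ranking.
#'
#' @param gene_scores output of [gene_regulation_score()].
#' @param de_genes character vector of DE gene ids (non-empty).
#' @return data.frame: `threshold`, `n_predicted`, `precision`, `recall`.
#' @export
de_gene_validation <- function(gene_scores, de_genes) {
  if (!length(de_genes)) stop("de_gene_validation: empty DE gene list")
  labels <- gene_scores$gene_id %in% de_genes
  pt <- .prefix_table(gene_scores$regulation_prob, labels)
  if (!any(labels)) pt$recall <- 0
  data.frame(threshold = pt$threshold, n_predicted = pt$taken,
             precision = pt$precision, recall = pt$recall)
}

#' Full evaluation report for one feature subset
#'
#' Scores the labeled pairs, computes precision at the requested recall
#' levels, FDR-indexed posterior cutoffs, MAP accuracy, and (when TADs
#' are given) the intra/inter-TAD stratification of the same metrics.
#' Unknown-label pairs are excluded from the evaluation universe.
#'
#' @param post a [posterior_table()] with labels filled in.
#' @param tpr_levels recall levels.
#' @param fdr_levels FDR levels.
#' @param tads optional TAD region table.
#' @return list of class `eval_report`.
#' @export
evaluate_predictions <- function(post, tpr_levels = c(0.1, 0.2, 0.3),
                                 fdr_levels = c(0.2, 0.25, 0.3),
                                 tads = NULL) {
  lab <- post[post$label != "unknown", , drop = FALSE]
  if (!nrow(lab)) stop("no labeled pairs to evaluate")
  is_pos <- lab$label == "positive"
  truth <- data.frame(enhancer_id = lab$enhancer_id[is_pos],
                      gene_id = lab$gene_id[is_pos],
                      stringsAsFactors = FALSE)
  res <- list(
    n_positive = sum(is_pos), n_negative = sum(!is_pos),
    precision_at_tpr = precision_at_tpr(lab$posterior, is_pos, tpr_levels),
    fdr_cutoffs = fdr_cutoff(lab$posterior, is_pos, fdr_levels),
    map_accuracy = map_accuracy(map_target(lab), truth))
  if (!is.null(tads)) {
    intra <- stratify_by_tad(lab, tads)
    strat <- function(sel) {
      if (!any(lab$label[sel] == "positive")) {
        return(list(n_positive = 0, n_negative = sum(sel),
                    precision_at_tpr = NULL))
      }
      list(n_positive = sum(sel & is_pos), n_negative = sum(sel & !is_pos),
           precision_at_tpr = precision_at_tpr(lab$posterior[sel],
                                               is_pos[sel], tpr_levels))
    }
    res$intra_tad <- strat(intra)
    res$inter_tad <- strat(!intra)
  }
  class(res) <- "eval_report"
  res
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d positives / %d negatives\n",
              x$n_positive, x$n_negative))
  cat("precision at recall:\n")
  print(round(x$precision_at_tpr, 4))
  cat(sprintf("MAP accuracy: %.2f%%\n", x$map_accuracy))
  invisible(x)
}
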