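#' Sample Pearson correlation with a zero-variance guard
#'
#' Identical to the textbook estimator except that a zero-variance input
#' yields 0 (uninformative) instead of NaN, so pairs are never silently
#' dropped at the feature stage.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch in pearson_cor")
  if (length(x) < 2) stop("pearson_cor needs length >= 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

# Row-standardize to (x - mean) / (sd * sqrt(T-1)) so that tcrossprod gives
# the full Pearson correlation matrix in one shot; zero-variance rows are
# zeroed (-> correlation 0 against anything).
.std_rows <- function(m) {
  mu <- rowMeans(m)
  cen <- m - mu
  ss <- sqrt(rowSums(cen^2))
  zero <- ss == 0
  ss[zero] <- 1
  out <- cen / ss
  out[zero, ] <- 0
  out
}

#' Build the per-pair attribute table
#'
#' For every same-chromosome (enhancer, gene) pair: one Pearson
#' correlation per assay between the enhancer and gene occupancy time
#' series -- Pol II replicates are correlated separately and the two
#' values averaged into a single `c_PolII` -- plus the log10 genomic
#' separation between the enhancer centre and the upstream-shifted
#' canonical TSS.
#'
#' @param enh_ts named list of normalized `ts_set`s over enhancers; names
#'   are assay labels. Pol II replicates must be named
#'   `<prefix>_rep<i>` (e.g. `PolII_rep1`, `PolII_rep2`).
#' @param gene_ts matching named list of `ts_set`s over promoter-extended
#'   genes (same assay names).
#' @param enhancers consensus enhancer table (needs `name`, `center`).
#' @param genes gene table (needs `name`, `tss`, `strand`).
#' @param promoter_ext upstream TSS shift in bp (default 300).
#' @param max_distance optional cap in bp on the candidate universe
#'   (default `Inf`: all same-chromosome genes per enhancer).
#' @return data.frame with one row per candidate pair: `enhancer_id`,
#'   `gene_id`, `chrom`, one `c_<assay>` column per collapsed assay,
#'   `log10_dist`, `enh_center`, `tss_shifted`, `label` (initialized
#'   `"unknown"`).
#' @export
build_features <- function(enh_ts, gene_ts, enhancers, genes,
                           promoter_ext = 300, max_distance = Inf) {
  stopifnot(identical(sort(names(enh_ts)), sort(names(gene_ts))),
            length(enh_ts) >= 1)
  validate_regions(enhancers, "enhancer")
  if (is.null(enhancers$center)) {
    enhancers$center <- floor((enhancers$start + enhancers$end) / 2)
  }
  check_shared_chroms(enhancers, genes, "enhancers and genes")
  assays <- names(enh_ts)
  # collapse replicate assays: "PolII_rep1"/"PolII_rep2" -> "PolII"
  groups <- sub("_rep[0-9]+$", "", assays)
  feature_names <- unique(groups)
  genes$tss_shifted <- shifted_tss(genes, promoter_ext)

  out <- list()
  for (chrom in sort(intersect(unique(enhancers$chrom), unique(genes$chrom)))) {
    e <- enhancers[enhancers$chrom == chrom, , drop = FALSE]
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    if (!nrow(e) || !nrow(g)) next
    ne <- nrow(e); ng <- nrow(g)
    pair_e <- rep(seq_len(ne), each = ng)
    pair_g <- rep(seq_len(ng), times = ne)
    dist_bp <- abs(g$tss_shifted[pair_g] - e$center[pair_e])
    if (any(dist_bp == 0)) {
      stop(sprintf("zero separation for pair (%s, %s): non-distal pair",
                   e$name[pair_e[which(dist_bp == 0)[1]]],
                   g$name[pair_g[which(dist_bp == 0)[1]]]))
    }
    df <- data.frame(enhancer_id = e$name[pair_e], gene_id = g$name[pair_g],
                     chrom = chrom, stringsAsFactors = FALSE)
    cors <- matrix(0, nrow(df), length(feature_names),
                   dimnames = list(NULL, feature_names))
    for (fn in feature_names) {
      reps <- assays[groups == fn]
      acc <- 0
      for (a in reps) {
        em <- enh_ts[[a]]$matrix[match(e$name, enh_ts[[a]]$region_ids), ,
                                 drop = FALSE]
        gm <- gene_ts[[a]]$matrix[match(g$name, gene_ts[[a]]$region_ids), ,
                                  drop = FALSE]
        if (anyNA(em) || anyNA(gm)) {
          stop(sprintf("assay %s lacks time series for some regions on %s",
                       a, chrom))
        }
        cmat <- tcrossprod(.std_rows(em), .std_rows(gm))  # ne x ng
        acc <- acc + cmat[cbind(pair_e, pair_g)]
      }
      cors[, fn] <- pmin(1, pmax(-1, acc / length(reps)))
    }
    colnames(cors) <- paste0("c_", feature_names)
    df <- cbind(df, cors)
    df$log10_dist <- log10(pmax(1, dist_bp))
    df$enh_center <- e$center[pair_e]
    df$tss_shifted <- g$tss_shifted[pair_g]
    keep <- dist_bp <= max_distance
    out[[chrom]] <- df[keep, , drop = FALSE]
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(enhancer_id = character(), gene_id = character(),
               chrom = character(), log10_dist = numeric(),
               enh_center = numeric(), tss_shifted = numeric())
  }
  res$label <- "unknown"
  rownames(res) <- NULL
  res
}

#' Label candidate pairs against interaction ground truth
#'
#' A pair is `positive` iff some anchor pair has one anchor overlapping
#' the enhancer and the mate anchor overlapping the promoter-extended
#' gene (both orientations tried; when an anchor overlaps both element
#' kinds, every consistent assignment is used). A pair is `negative` iff
#' its enhancer has at least one positive pair but this gene is not among
#' its confirmed targets. Pairs whose enhancer has no confirmed
#' interaction stay `unknown` and are excluded from training and testing.
#'
#' @param pairs feature table from [build_features()].
#' @param truth anchor-pair table ([read_bedpe()] format).
#' @param enhancers consensus enhancer table.
#' @param genes gene table.
#' @param promoter_ext upstream extension used for gene anchors.
#' @param min_overlap minimum anchor overlap in bp (default 1).
#' @return `pairs` with `label` filled in.
#' @export
label_pairs <- function(pairs, truth, enhancers, genes, promoter_ext = 300,
                        min_overlap = 1) {
  if (nrow(truth) == 0) {
    pairs$label <- "unknown"
    return(pairs)
  }
  ext <- promoter_extended(genes, promoter_ext)
  gr_enh <- regions_to_gr(enhancers)
  gr_gene <- regions_to_gr(ext)
  anchor_a <- regions_to_gr(regions(truth$chrom_a, truth$start_a, truth$end_a))
  anchor_b <- regions_to_gr(regions(truth$chrom_b, truth$start_b, truth$end_b))
  hit_pairs <- function(anch_e, anch_g) {
    he <- GenomicRanges::findOverlaps(anch_e, gr_enh, minoverlap = min_overlap)
    hg <- GenomicRanges::findOverlaps(anch_g, gr_gene, minoverlap = min_overlap)
    e_by_link <- split(S4Vectors::subjectHits(he), S4Vectors::queryHits(he))
    g_by_link <- split(S4Vectors::subjectHits(hg), S4Vectors::queryHits(hg))
    links <- intersect(names(e_by_link), names(g_by_link))
    if (!length(links)) return(NULL)
    do.call(rbind, lapply(links, function(l) {
      expand.grid(e = e_by_link[[l]], g = g_by_link[[l]])
    }))
  }
  pos <- rbind(hit_pairs(anchor_a, anchor_b), hit_pairs(anchor_b, anchor_a))
  key <- character(0)
  if (!is.null(pos) && nrow(pos)) {
    key <- unique(paste(enhancers$name[pos$e], ext$name[pos$g], sep = "\r"))
  }
  pair_key <- paste(pairs$enhancer_id, pairs$gene_id, sep = "\r")
  is_pos <- pair_key %in% key
  linked_enh <- unique(pairs$enhancer_id[is_pos])
  pairs$label <- ifelse(is_pos, "positive",
                        ifelse(pairs$enhancer_id %in% linked_enh,
                               "negative", "unknown"))
  pairs
}

#' Write / read the feature table
#' @param pairs feature table.
#' @param path file path.
#' @export
write_features <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(enhancer_id = "character",
                                   gene_id = "character",
                                   chrom = "character", label = "character"))
}
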