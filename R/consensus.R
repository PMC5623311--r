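#' Merge per-timepoint peaks into time-persistent consensus sites
#'
#' Peaks from all post-stimulation timepoints are pooled and transitively
#' merged into connected components by half-open overlap (mergeBED-style
#' union). A component is kept as a consensus site only when peaks from at
#' least `min_support` distinct timepoints contribute; components seen at a
#' single timepoint are discarded. The baseline (t = 0) peak set is
#' excluded from support counting by default, since consensus sites are
#' meant to capture stimulation-induced persistent binding.
#'
#' @param peaks named list: timepoint label (minutes, e.g. `"0"`, `"5"`)
#'   -> region table of peak calls for that timepoint.
#' @param min_support minimum number of distinct contributing timepoints
#'   (default 2).
#' @param include_t0 count the t = 0 set toward support (default FALSE).
#' @return region table with columns `chrom,start,end,name,strand` plus
#'   `support` (distinct contributing timepoints) and `center`
#'   (`floor((start+end)/2)`). Regions are pairwise non-overlapping.
#' @export
persistent_union <- function(peaks, min_support = 2, include_t0 = FALSE) {
  stopifnot(is.list(peaks), min_support >= 1)
  tp_labels <- names(peaks)
  if (is.null(tp_labels) || any(!nzchar(tp_labels))) {
    stop("peaks must be a named list keyed by timepoint (minutes)")
  }
  tp_num <- suppressWarnings(as.numeric(tp_labels))
  if (any(is.na(tp_num))) stop("timepoint labels must be numeric minutes")
  if (is.unsorted(tp_num, strictly = TRUE)) {
    stop("timepoints must be strictly increasing")
  }
  if (!include_t0) peaks <- peaks[tp_num != 0]
  empty <- {
    out <- regions(character(), numeric(), numeric())
    out$support <- integer()
    out$center <- numeric()
    out
  }
  peaks <- Filter(function(p) nrow(p) > 0, peaks)
  if (!length(peaks)) return(empty)
  for (p in peaks) validate_regions(p, "peak")
  pooled <- do.call(rbind, lapply(names(peaks), function(tp) {
    data.frame(chrom = peaks[[tp]]$chrom, start = peaks[[tp]]$start,
               end = peaks[[tp]]$end, timepoint = tp,
               stringsAsFactors = FALSE)
  }))
  gr <- regions_to_gr(pooled)
  # min.gapwidth = 0: merge only truly overlapping ranges; abutting
  # half-open intervals stay separate, matching region_overlaps().
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(merged, gr)
  support <- vapply(split(pooled$timepoint[S4Vectors::subjectHits(hits)],
                          factor(S4Vectors::queryHits(hits),
                                 levels = seq_along(merged))),
                    function(tps) length(unique(tps)), integer(1))
  keep <- support >= min_support
  if (!any(keep)) return(empty)
  out <- gr_to_regions(merged[keep])
  out$support <- as.integer(support[keep])
  out$center <- floor((out$start + out$end) / 2)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict consensus sites to distal (intergenic) enhancers
#'
#' Drops every consensus region that overlaps a gene body or its upstream
#' promoter extension; what remains are the distal enhancers the model
#' scores.
#'
#' @param consensus consensus region table (from [persistent_union()]).
#' @param genes gene table.
#' @param promoter_ext upstream extension in bp (default 300).
#' @param min_overlap minimum bp overlap that counts (default 1).
#' @return the retained rows of `consensus`.
#' @export
filter_distal <- function(consensus, genes, promoter_ext = 300,
                          min_overlap = 1) {
  validate_regions(consensus, "consensus")
  if (nrow(genes) == 0 || nrow(consensus) == 0) return(consensus)
  ext <- promoter_extended(genes, promoter_ext)
  hit <- overlaps_any(consensus, ext, min_overlap = min_overlap)
  out <- consensus[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}
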