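#' Construct a time-series set
#'
#' One set per assay: a region x timepoint count matrix with its
#' per-timepoint library sizes (total mapped, non-duplicate reads).
#'
#' @param matrix numeric matrix, rows = regions, columns = timepoints.
#' @param timepoints numeric minutes, one per column, strictly increasing.
#' @param region_ids row labels.
#' @param library_sizes per-timepoint totals (positive).
#' @param assay assay label (e.g. `"ER"`, `"PolII_rep1"`).
#' @param normalized has depth normalization been applied?
#' @return an object of class `ts_set`.
#' @export
ts_set <- function(matrix, timepoints, region_ids, library_sizes,
                   assay = "assay", normalized = FALSE) {
  matrix <- as.matrix(matrix)
  stopifnot(ncol(matrix) == length(timepoints),
            nrow(matrix) == length(region_ids),
            length(library_sizes) == length(timepoints),
            !is.unsorted(timepoints, strictly = TRUE),
            all(matrix >= 0))
  dimnames(matrix) <- list(region_ids, paste0("t", timepoints))
  structure(list(assay = assay, timepoints = as.numeric(timepoints),
                 matrix = matrix, region_ids = as.character(region_ids),
                 library_sizes = as.numeric(library_sizes),
                 normalized = isTRUE(normalized)),
            class = "ts_set")
}

#' @export
print.ts_set <- function(x, ...) {
  cat(sprintf("<ts_set> assay=%s: %d regions x %d timepoints (%s)\n",
              x$assay, nrow(x$matrix), ncol(x$matrix),
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Count reads over regions, per timepoint
#'
#' Cell (j, t) is the number of reads at timepoint t whose interval
#' overlaps region j (half-open, >= 1 bp). A read spanning two regions is
#' counted in both.
#'
#' @param regions region table (must be non-empty).
#' @param reads named list: timepoint label -> region table of read
#'   intervals (a timepoint with zero reads gives a zero column).
#' @param library_sizes per-timepoint totals, same order as `reads`.
#' @param assay assay label.
#' @return a raw (unnormalized) [ts_set()].
#' @export
count_over_regions <- function(regions, reads, library_sizes,
                               assay = "assay") {
  validate_regions(regions)
  if (nrow(regions) == 0) stop("region list is empty")
  tp <- suppressWarnings(as.numeric(names(reads)))
  if (any(is.na(tp))) stop("reads must be keyed by numeric timepoint")
  stopifnot(length(library_sizes) == length(reads), all(library_sizes > 0))
  gr <- regions_to_gr(regions)
  counts <- vapply(reads, function(rd) {
    if (is.null(rd) || nrow(rd) == 0) return(integer(length(gr)))
    GenomicRanges::countOverlaps(gr, regions_to_gr(rd), minoverlap = 1L)
  }, integer(nrow(regions)))
  counts <- matrix(counts, nrow = nrow(regions))
  ts_set(counts, tp, regions$name, library_sizes, assay = assay,
         normalized = FALSE)
}

#' Depth-normalize a raw time-series set
#'
#' Each column is divided by its timepoint's library size and rescaled to
#' the baseline (t = 0) depth: `norm(j,t) = raw(j,t) / L_t * L_0`. The
#' t = 0 column is unchanged, and equal library sizes leave the matrix
#' untouched.
#'
#' @param ts a raw [ts_set()]; t = 0 must be present.
#' @return normalized `ts_set`.
#' @export
normalize_timeseries <- function(ts) {
  stopifnot(inherits(ts, "ts_set"))
  if (ts$normalized) stop("time series already normalized")
  i0 <- which(ts$timepoints == 0)
  if (!length(i0)) stop("t = 0 timepoint required for normalization")
  if (any(ts$library_sizes == 0)) {
    stop(sprintf("library size is zero at timepoint t=%g",
                 ts$timepoints[which(ts$library_sizes == 0)[1]]))
  }
  factors <- ts$library_sizes[i0] / ts$library_sizes
  out <- ts
  out$matrix <- sweep(ts$matrix, 2, factors, `*`)
  out$normalized <- TRUE
  out
}

#' Drop regions with insufficient total raw coverage
#'
#' A region is retained iff the sum of its raw counts over all timepoints
#' and all assays is at least `min_total` (default 30, i.e. "less than 30"
#' is dropped). Dropped regions are removed from every set.
#'
#' @param ts_list list of raw `ts_set` objects sharing `region_ids`.
#' @param min_total minimum total raw read count (default 30).
#' @return list with `retained` (character ids) and `ts_list` (filtered
#'   sets, original order preserved).
#' @export
filter_low_coverage <- function(ts_list, min_total = 30) {
  stopifnot(length(ts_list) >= 1)
  ids <- ts_list[[1]]$region_ids
  for (ts in ts_list) {
    stopifnot(inherits(ts, "ts_set"))
    if (!identical(ts$region_ids, ids)) {
      stop("all time-series sets must share region_ids")
    }
  }
  totals <- Reduce(`+`, lapply(ts_list, function(ts) rowSums(ts$matrix)))
  keep <- totals >= min_total
  list(retained = ids[keep],
       ts_list = lapply(ts_list, function(ts) {
         ts$matrix <- ts$matrix[keep, , drop = FALSE]
         ts$region_ids <- ids[keep]
         ts
       }))
}

#' Write a count table as TSV
#'
#' First column `region_id`, then one column per timepoint (`t0`, `t5`,
#' ...). Library sizes are stored in a `# library_sizes:` header comment.
#'
#' @param ts a `ts_set`.
#' @param path output path.
#' @export
write_count_table <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# assay: %s", ts$assay), con)
  writeLines(sprintf("# library_sizes: %s",
                     paste(ts$library_sizes, collapse = ",")), con)
  writeLines(sprintf("# normalized: %s", ts$normalized), con)
  df <- data.frame(region_id = ts$region_ids, ts$matrix, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count table written by [write_count_table()]
#' @param path file path.
#' @return a `ts_set`.
#' @export
read_count_table <- function(path) {
  header <- readLines(path, n = 10)
  meta <- header[grepl("^#", header)]
  get <- function(key) sub(sprintf("^# %s: ", key), "",
                           grep(sprintf("^# %s:", key), meta, value = TRUE)[1])
  assay <- get("assay")
  lib <- as.numeric(strsplit(get("library_sizes"), ",")[[1]])
  normalized <- identical(get("normalized"), "TRUE")
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE,
                          colClasses = c(region_id = "character"))
  tp <- as.numeric(sub("^t", "", setdiff(names(df), "region_id")))
  ts_set(as.matrix(df[, -1, drop = FALSE]), tp, df$region_id, lib,
         assay = assay, normalized = normalized)
}
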