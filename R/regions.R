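#' Construct a table of genomic regions
#'
#' Regions are plain data frames in the BED convention: 0-based,
#' half-open `[start, end)` intervals. This constructor validates the
#' coordinates and fills in optional columns.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, exclusive; must satisfy `end > start`.
#' @param name optional region labels; defaults to `chrom:start-end`.
#' @param strand optional strand, one of `"+"`, `"-"` or `NA`.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `strand`.
#' @export
regions <- function(chrom, start, end, name = NULL, strand = NA_character_) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  if (any(!lengths(list(chrom, start, end)) %in% c(if (n > 0) 1L, n))) {
    stop("chrom, start and end must have equal length (or length 1)")
  }
  if (n > 0) {
    chrom <- rep_len(chrom, n)
    start <- rep_len(start, n)
    end <- rep_len(end, n)
  }
  if (is.null(name)) name <- region_id(chrom, start, end)
  strand <- rep_len(as.character(strand), n)
  df <- data.frame(chrom = chrom, start = start, end = end,
                   name = as.character(rep_len(name, max(n, 0L))),
                   strand = strand, stringsAsFactors = FALSE)
  validate_regions(df)
  df
}

region_id <- function(chrom, start, end) {
  sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
}

#' Validate a region table
#'
#' @param df data frame with at least `chrom`, `start`, `end`.
#' @param what label used in error messages.
#' @return `df`, invisibly, if valid; otherwise an error.
#' @export
validate_regions <- function(df, what = "region") {
  stopifnot(is.data.frame(df))
  req <- c("chrom", "start", "end")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop(sprintf("%s table lacks column(s): %s", what,
                 paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(!nzchar(df$chrom) | is.na(df$chrom))
  if (length(bad)) stop(sprintf("%s %d has empty chrom", what, bad[1]))
  bad <- which(df$start < 0)
  if (length(bad)) stop(sprintf("%s %d has negative start", what, bad[1]))
  bad <- which(df$end <= df$start)
  if (length(bad)) {
    stop(sprintf("%s %d has end <= start (%s:%s-%s)", what, bad[1],
                 df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]))
  }
  invisible(df)
}

# 0-based half-open -> 1-based closed GRanges (strand ignored: features are
# strand-agnostic; strand only matters for TSS location).
regions_to_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1, end = df$end))
}

gr_to_regions <- function(gr, name = NULL, strand = NA_character_) {
  regions(as.character(GenomicRanges::seqnames(gr)),
          GenomicRanges::start(gr) - 1,
          GenomicRanges::end(gr),
          name = name, strand = strand)
}

#' Read a BED file into a region table
#'
#' Accepts BED3+ (tab-separated). `track`, `browser` and `#` comment lines
#' are skipped. Coordinates are taken verbatim (BED is already 0-based
#' half-open). Column 4 becomes `name`, column 5 `score`, column 6 `strand`
#' when present.
#'
#' @param path file path.
#' @return region `data.frame` (possibly 0 rows), with a `score` column if
#'   the file had one.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    return(regions(character(), numeric(), numeric()))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3)) {
    stop(sprintf("BED parse error at line %d: fewer than 3 columns",
                 idx[which(ncols < 3)[1]]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf("BED parse error at line %d: non-integer coordinates",
                 idx[bad[1]]))
  }
  bad <- which(end <= start | start < 0)
  if (length(bad)) {
    stop(sprintf("BED parse error at line %d: invalid interval (end <= start)",
                 idx[bad[1]]))
  }
  name <- vapply(fields, function(f) if (length(f) >= 4) f[4L] else NA_character_, "")
  name[is.na(name)] <- region_id(chrom, start, end)[is.na(name)]
  strand <- vapply(fields, function(f) if (length(f) >= 6) f[6L] else NA_character_, "")
  strand[!strand %in% c("+", "-")] <- NA_character_
  df <- regions(chrom, start, end, name = name, strand = strand)
  if (any(ncols >= 5)) {
    score <- suppressWarnings(as.numeric(
      vapply(fields, function(f) if (length(f) >= 5) f[5L] else NA_character_, "")))
    df$score <- score
  }
  df
}

#' Write a region table as BED
#'
#' Emits BED6 when `name`/`score`/`strand` information is present, BED3
#' otherwise. Round-trips coordinates bit-exactly with [read_bed()].
#'
#' @param df region table.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  validate_regions(df)
  out <- data.frame(df$chrom, as.integer(df$start), as.integer(df$end),
                    stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  if (!is.null(df$name)) {
    score <- if (!is.null(df$score)) df$score else 0
    strand <- if (!is.null(df$strand)) ifelse(is.na(df$strand), ".", df$strand) else "."
    out <- cbind(out, df$name, score, strand)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read interaction anchor pairs (BEDPE)
#'
#' One anchor pair per line, >= 6 tab-separated columns
#' (chromA, startA, endA, chromB, startB, endB[, score]). Column 7, when
#' present, is stored as `score`.
#'
#' @param path file path.
#' @return `data.frame` with columns `chrom_a,start_a,end_a,chrom_b,
#'   start_b,end_b,score`.
#' @export
read_bedpe <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  empty <- data.frame(chrom_a = character(), start_a = numeric(),
                      end_a = numeric(), chrom_b = character(),
                      start_b = numeric(), end_b = numeric(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (!length(idx)) return(empty)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 6)) {
    stop(sprintf("BEDPE parse error at line %d: fewer than 6 columns",
                 idx[which(ncols < 6)[1]]))
  }
  num <- function(k) suppressWarnings(as.numeric(vapply(fields, `[[`, "", k)))
  df <- data.frame(
    chrom_a = vapply(fields, `[[`, "", 1L), start_a = num(2L), end_a = num(3L),
    chrom_b = vapply(fields, `[[`, "", 4L), start_b = num(5L), end_b = num(6L),
    stringsAsFactors = FALSE)
  df$score <- ifelse(ncols >= 7,
                     suppressWarnings(as.numeric(vapply(
                       fields, function(f) if (length(f) >= 7) f[7L] else NA_character_, ""))),
                     NA_real_)
  bad <- which(is.na(df$start_a) | is.na(df$end_a) | is.na(df$start_b) |
                 is.na(df$end_b))
  if (length(bad)) {
    stop(sprintf("BEDPE parse error at line %d: non-integer coordinates",
                 idx[bad[1]]))
  }
  validate_regions(data.frame(chrom = df$chrom_a, start = df$start_a,
                              end = df$end_a), "BEDPE anchor A")
  validate_regions(data.frame(chrom = df$chrom_b, start = df$start_b,
                              end = df$end_b), "BEDPE anchor B")
  df
}

#' Write anchor pairs as BEDPE
#' @param df anchor-pair table as returned by [read_bedpe()].
#' @param path output path.
#' @export
write_bedpe <- function(df, path) {
  out <- data.frame(df$chrom_a, as.integer(df$start_a), as.integer(df$end_a),
                    df$chrom_b, as.integer(df$start_b), as.integer(df$end_b),
                    stringsAsFactors = FALSE)
  if (!is.null(df$score) && any(!is.na(df$score))) {
    out <- cbind(out, ifelse(is.na(df$score), ".", df$score))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Tab-separated with a header and columns `chrom`, `start`, `end`, `name`,
#' `strand`. Coordinates are interpreted according to `convention`: BED
#' (0-based half-open, the internal standard) or `"one_based"` (1-based
#' closed, converted at this boundary).
#'
#' The canonical TSS is `start` for `+` genes and `end - 1` for `-` genes
#' (in the internal 0-based convention).
#'
#' @param path file path.
#' @param convention `"bed"` (default) or `"one_based"`.
#' @return gene table: region columns plus `tss`.
#' @export
read_genes <- function(path, convention = c("bed", "one_based")) {
  convention <- match.arg(convention)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character", name = "character",
                                         strand = "character"))
  req <- c("chrom", "start", "end", "name", "strand")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("gene table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (convention == "one_based") {
    df$start <- df$start - 1
  }
  if (nrow(df) && any(!df$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  validate_regions(df, "gene")
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1)
  df
}

#' Write a gene table (BED-convention TSV with header)
#' @param genes gene table.
#' @param path output path.
#' @export
write_genes <- function(genes, path) {
  utils::write.table(genes[, c("chrom", "start", "end", "name", "strand")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Do two intervals overlap?
#'
#' Half-open semantics: `[0,10)` and `[10,20)` abut but do not overlap.
#' Vectorized over rows; recycles length-1 arguments.
#'
#' @param a,b region tables (or single rows).
#' @param min_overlap minimum overlap in bp (default 1).
#' @return logical vector.
#' @export
region_overlaps <- function(a, b, min_overlap = 1) {
  ov <- pmin(a$end, b$end) - pmax(a$start, b$start)
  a$chrom == b$chrom & ov >= min_overlap
}

#' Which query regions overlap any subject region?
#'
#' @param query,subject region tables.
#' @param min_overlap minimum overlap in bp.
#' @return logical vector along `query` rows.
#' @export
overlaps_any <- function(query, subject, min_overlap = 1) {
  if (nrow(subject) == 0 || nrow(query) == 0) {
    return(rep(FALSE, nrow(query)))
  }
  GenomicRanges::countOverlaps(regions_to_gr(query), regions_to_gr(subject),
                               minoverlap = min_overlap) > 0
}

#' Promoter-extended gene regions
#'
#' Grows each gene body by `ext` bp on the TSS side (upstream): start-ext
#' for `+` genes, end+ext for `-` genes, clipped at 0. Used both to call
#' an enhancer "distal" and as the counting window for gene time series.
#'
#' @param genes gene table (needs `strand`).
#' @param ext upstream extension in bp (default 300).
#' @return region table with the same `name` order as `genes`.
#' @export
promoter_extended <- function(genes, ext = 300) {
  stopifnot(ext >= 0)
  if (nrow(genes) == 0) return(genes[, c("chrom", "start", "end", "name", "strand")])
  start <- ifelse(genes$strand == "+", pmax(0, genes$start - ext), genes$start)
  end <- ifelse(genes$strand == "-", genes$end + ext, genes$end)
  regions(genes$chrom, start, end, name = genes$name, strand = genes$strand)
}

#' Upstream-shifted TSS positions
#'
#' The distance feature is measured from the enhancer centre to the
#' canonical TSS moved `ext` bp upstream (matching the promoter
#' extension).
#'
#' @param genes gene table.
#' @param ext shift in bp (default 300).
#' @return numeric vector of positions (0-based), clipped at 0.
#' @export
shifted_tss <- function(genes, ext = 300) {
  ifelse(genes$strand == "+", pmax(0, genes$tss - ext), genes$tss + ext)
}

#' Warn when two inputs share no chromosome names
#'
#' Chromosome matching is exact string equality; this guard catches
#' "chr1" vs "1" style mismatches early.
#'
#' @param a,b region tables.
#' @param what description for the warning message.
#' @return TRUE (invisibly) iff at least one name is shared.
#' @export
check_shared_chroms <- function(a, b, what = "inputs") {
  shared <- intersect(unique(a$chrom), unique(b$chrom))
  if (nrow(a) && nrow(b) && !length(shared)) {
    warning(sprintf("%s share zero chromosome names (exact matching)", what))
    return(invisible(FALSE))
  }
  invisible(TRUE)
}
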