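#' Configuration for the synthetic-data generator
#'
#' The defaults describe the stated benchmark world: 4 chromosomes of
#' 10 Mb, 400 genes, 200 enhancers, 8 timepoints on the real sampling
#' grid (0..320 min), five assays with strong TF/polymerase signal
#' (0.9) and weak histone signal (0.2), observation noise 0.3, linked
#' pairs at log-normally distributed separations (median 50 kb), and a
#' ground-truth assay that reports only 60% of true links (emulating
#' interaction-capture false negatives).
#'
#' @param seed RNG seed.
#' @param n_chroms number of chromosomes (`chr1` ...).
#' @param chrom_length chromosome length in bp.
#' @param n_genes,n_enhancers element counts (split across chromosomes).
#' @param timepoints minutes, must start at 0.
#' @param assays assay labels; `_rep<i>` suffixes mark replicates.
#' @param fraction_linked fraction of enhancers with a planted target.
#' @param signal_strength named per-assay latent-profile mixing weight in
#'   `[0, 1]`.
#' @param noise_sd per-timepoint observation noise (latent profile has
#'   unit variance).
#' @param link_dist_meanlog,link_dist_sdlog log-normal parameters of the
#'   planted enhancer-TSS separation in bp.
#' @param min_link_dist smallest planted separation (self-ligation-style
#'   short links are absent from real interaction data).
#' @param sensitivity fraction of true links emitted into the observed
#'   (BEDPE) truth.
#' @param library_sizes per-timepoint totals; defaults vary around 1e6 so
#'   depth normalization is exercised.
#' @param tad_width TAD tile width in bp.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1, n_chroms = 4, chrom_length = 1e7,
                         n_genes = 400, n_enhancers = 200,
                         timepoints = c(0, 5, 10, 20, 40, 80, 160, 320),
                         assays = c("ER", "PolII_rep1", "PolII_rep2",
                                    "H2AZ", "H3K4me3"),
                         fraction_linked = 0.5,
                         signal_strength = c(ER = 0.9, PolII_rep1 = 0.9,
                                             PolII_rep2 = 0.9, H2AZ = 0.2,
                                             H3K4me3 = 0.2),
                         noise_sd = 0.3,
                         link_dist_meanlog = log(5e4),
                         link_dist_sdlog = 1.0,
                         min_link_dist = 5000,
                         sensitivity = 0.6,
                         library_sizes = NULL,
                         tad_width = 1e6) {
  if (is.null(library_sizes)) {
    library_sizes <- 1e6 * rep_len(c(1, 0.9, 1.1, 0.95, 1.05, 0.85, 1.15, 1),
                                   length(timepoints))
  }
  cfg <- list(seed = seed, n_chroms = n_chroms, chrom_length = chrom_length,
              n_genes = n_genes, n_enhancers = n_enhancers,
              timepoints = timepoints, assays = assays,
              fraction_linked = fraction_linked,
              signal_strength = signal_strength, noise_sd = noise_sd,
              link_dist_meanlog = link_dist_meanlog,
              link_dist_sdlog = link_dist_sdlog,
              min_link_dist = min_link_dist, sensitivity = sensitivity,
              library_sizes = library_sizes, tad_width = tad_width)
  stopifnot(n_chroms >= 1, chrom_length > 0, n_genes >= 1, n_enhancers >= 1,
            timepoints[1] == 0, !is.unsorted(timepoints, strictly = TRUE),
            fraction_linked >= 0, fraction_linked <= 1,
            all(signal_strength >= 0), all(signal_strength <= 1),
            all(assays %in% names(signal_strength)) || is.null(names(signal_strength)),
            noise_sd >= 0, sensitivity >= 0, sensitivity <= 1,
            length(library_sizes) == length(timepoints),
            all(library_sizes > 0))
  if (is.null(names(signal_strength))) {
    names(signal_strength) <- assays
    cfg$signal_strength <- signal_strength
  }
  class(cfg) <- "synth_config"
  cfg
}

# cubic-interpolated random walk over the timepoint grid, standardized to
# mean 0 / sd 1 -- a smooth "response profile" without committing to any
# particular cluster shape
.latent_profile <- function(n_tp) {
  k <- max(3, min(4, n_tp - 1))
  y <- cumsum(stats::rnorm(k))
  prof <- stats::spline(seq(1, n_tp, length.out = k), y, xout = seq_len(n_tp),
                        method = "natural")$y
  s <- stats::sd(prof)
  if (s < 1e-8) prof <- prof + stats::rnorm(n_tp, sd = 0.1)
  (prof - mean(prof)) / stats::sd(prof)
}

# does [start, end) stay >= margin bp away from every occupied interval?
.is_free <- function(start, end, occ, margin = 0) {
  if (!nrow(occ)) return(TRUE)
  !any(occ$start < end + margin & start < occ$end + margin)
}

#' Generate a synthetic benchmark bundle
#'
#' Places genes and intergenic enhancers on artificial chromosomes,
#' plants enhancer-gene links whose occupancy time series share a latent
#' response profile, emits per-timepoint peak calls whose
#' persistent-union reconstruction equals the planted enhancers (plus
#' single-timepoint and genic decoy peaks that the consensus and distal
#' filters must remove), per-assay raw count tables at realistic varying
#' sequencing depths, the complete planted truth, a sensitivity-thinned
#' observed truth (BEDPE), and a TAD tiling. Fully reproducible from the
#' seed.
#'
#' @param config a [synth_config()].
#' @return list of class `synth_bundle` with elements `config`, `genes`,
#'   `enhancers`, `peaks`, `counts` (`$enh[[assay]]`, `$gene[[assay]]`,
#'   raw `ts_set`s), `truth`, `observed`, `tads`.
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  tp <- config$timepoints
  n_tp <- length(tp)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  per_gene <- diff(floor(seq(0, config$n_genes, length.out = config$n_chroms + 1)))
  per_enh <- diff(floor(seq(0, config$n_enhancers, length.out = config$n_chroms + 1)))

  genes_list <- list(); enh_list <- list(); truth_list <- list()
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    ng <- per_gene[ci]; ne <- per_enh[ci]
    slot <- config$chrom_length / ng
    if (slot < 40000) stop("infeasible placement: too many genes for chrom_length")
    glen <- round(stats::runif(ng, 2000, 10000))
    goff <- round(stats::runif(ng, 10000, slot - 10000 - glen))
    gstart <- (seq_len(ng) - 1) * slot + goff
    gstrand <- sample(c("+", "-"), ng, replace = TRUE)
    g <- regions(rep(ch, ng), gstart, gstart + glen,
                 name = sprintf("%s_g%03d", ch, seq_len(ng)),
                 strand = gstrand)
    g$tss <- ifelse(g$strand == "+", g$start, g$end - 1)
    g$tss_shifted <- shifted_tss(g, 300)
    genes_list[[ch]] <- g

    occ <- promoter_extended(g, 300)[, c("start", "end")]
    n_linked <- round(config$fraction_linked * ne)
    targets <- sample(seq_len(ng), n_linked)
    estart <- numeric(0); eend <- numeric(0)
    elinked <- character(0)
    place_enh <- function(center_fun, label) {
      for (try in seq_len(500)) {
        center <- center_fun()
        len <- round(stats::runif(1, 500, 1500))
        s <- round(center - len / 2); e <- s + len
        if (s < 0 || e > config$chrom_length) next
        if (!.is_free(s, e, occ, margin = 0)) next
        if (length(estart) &&
            !.is_free(s, e, data.frame(start = estart, end = eend),
                      margin = 1000)) next
        cc <- floor((s + e) / 2)
        if (any(abs(g$tss_shifted - cc) == 0)) next
        return(c(s, e))
      }
      stop(sprintf("infeasible placement: could not place %s enhancer on %s",
                   label, ch))
    }
    for (ti in seq_len(n_linked)) {
      anchor <- g$tss_shifted[targets[ti]]
      se <- place_enh(function() {
        d <- max(config$min_link_dist,
                 stats::rlnorm(1, config$link_dist_meanlog,
                               config$link_dist_sdlog))
        d <- min(d, config$chrom_length / 4)
        round(anchor + sample(c(-1, 1), 1) * d)
      }, "linked")
      estart <- c(estart, se[1]); eend <- c(eend, se[2])
      elinked <- c(elinked, g$name[targets[ti]])
    }
    for (ui in seq_len(ne - n_linked)) {
      se <- place_enh(function() {
        round(stats::runif(1, 2000, config$chrom_length - 2000))
      }, "unlinked")
      estart <- c(estart, se[1]); eend <- c(eend, se[2])
      elinked <- c(elinked, NA_character_)
    }
    ord <- order(estart)
    e <- regions(rep(ch, ne), estart[ord], eend[ord])
    e$center <- floor((e$start + e$end) / 2)
    e$target <- elinked[ord]
    enh_list[[ch]] <- e
    tr <- e[!is.na(e$target), c("name", "target")]
    if (nrow(tr)) {
      truth_list[[ch]] <- data.frame(enhancer_id = tr$name,
                                     gene_id = tr$target, chrom = ch,
                                     stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, genes_list); rownames(genes) <- NULL
  enhancers <- do.call(rbind, enh_list); rownames(enhancers) <- NULL
  truth <- if (length(truth_list)) {
    do.call(rbind, truth_list)
  } else {
    data.frame(enhancer_id = character(), gene_id = character(),
               chrom = character(), stringsAsFactors = FALSE)
  }
  rownames(truth) <- NULL

  # --- per-timepoint peaks: union over chosen timepoints reconstructs the
  # enhancer exactly; decoys exercise the support and distal filters
  post0 <- as.character(tp[tp != 0])
  peaks <- stats::setNames(
    lapply(seq_len(n_tp), function(i) list()), as.character(tp))
  add_peak <- function(tp_label, ch, s, e) {
    peaks[[tp_label]][[length(peaks[[tp_label]]) + 1]] <<-
      data.frame(chrom = ch, start = s, end = e, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(enhancers))) {
    s <- enhancers$start[i]; e <- enhancers$end[i]; L <- e - s
    w <- ceiling(0.6 * L)
    supp <- sample(2:min(7, length(post0)), 1)
    tps <- sort(sample(post0, supp))
    for (k in seq_along(tps)) {
      if (k == 1) { ps <- s; pe <- s + w }
      else if (k == length(tps)) { ps <- e - w; pe <- e }
      else {
        r <- floor(stats::runif(1, 0, L - w))
        ps <- s + r; pe <- ps + w
      }
      add_peak(tps[k], enhancers$chrom[i], ps, pe)
    }
  }
  # decoys: single-timepoint intergenic peaks (dropped by support filter)
  # and persistent genic peaks (dropped by the distal filter)
  for (ch in chroms) {
    g <- genes_list[[ch]]
    occ <- rbind(promoter_extended(g, 300)[, c("start", "end")],
                 enh_list[[ch]][, c("start", "end")])
    for (d in seq_len(10)) {
      for (try in seq_len(200)) {
        s <- round(stats::runif(1, 0, config$chrom_length - 800))
        if (.is_free(s, s + 800, occ, margin = 2000)) break
        s <- NA
      }
      if (is.na(s)) next
      occ <- rbind(occ, data.frame(start = s, end = s + 800))
      add_peak(sample(post0, 1), ch, s, s + 800)
    }
    for (d in seq_len(5)) {
      gi <- sample(nrow(g), 1)
      if (g$end[gi] - g$start[gi] < 1200) next
      s <- g$start[gi] + 100
      for (k in sample(post0, 2)) add_peak(k, ch, s, s + 1000)
    }
  }
  peaks <- lapply(peaks, function(pl) {
    if (!length(pl)) {
      regions(character(), numeric(), numeric())
    } else {
      df <- do.call(rbind, pl)
      regions(df$chrom, df$start, df$end)
    }
  })

  # --- time series: linked pairs share a latent profile per pair
  n_enh <- nrow(enhancers); n_gen <- nrow(genes)
  enh_latent <- t(vapply(seq_len(n_enh), function(i) .latent_profile(n_tp),
                         numeric(n_tp)))
  gene_latent <- t(vapply(seq_len(n_gen), function(i) .latent_profile(n_tp),
                          numeric(n_tp)))
  li <- match(truth$gene_id, genes$name)
  ei <- match(truth$enhancer_id, enhancers$name)
  gene_latent[li, ] <- enh_latent[ei, ]  # shared profile for planted links

  lib <- config$library_sizes
  depth <- lib / lib[1]
  make_counts <- function(latent, ids, assay) {
    s_a <- config$signal_strength[[assay]]
    signal <- s_a * latent +
      matrix(stats::rnorm(length(latent), 0, config$noise_sd),
             nrow = nrow(latent))
    ideal <- pmax(150 + 40 * signal, 0)
    raw <- round(sweep(ideal, 2, depth, `*`))
    ts_set(raw, tp, ids, lib, assay = assay, normalized = FALSE)
  }
  counts <- list(
    enh = stats::setNames(lapply(config$assays, function(a)
      make_counts(enh_latent, enhancers$name, a)), config$assays),
    gene = stats::setNames(lapply(config$assays, function(a)
      make_counts(gene_latent, genes$name, a)), config$assays))

  # --- observed truth: sensitivity-thinned BEDPE over element anchors
  keep <- stats::runif(nrow(truth)) < config$sensitivity
  obs <- truth[keep, , drop = FALSE]
  ext <- promoter_extended(genes, 300)
  oe <- match(obs$enhancer_id, enhancers$name)
  og <- match(obs$gene_id, ext$name)
  observed <- data.frame(
    chrom_a = enhancers$chrom[oe], start_a = enhancers$start[oe],
    end_a = enhancers$end[oe], chrom_b = ext$chrom[og],
    start_b = ext$start[og], end_b = ext$end[og],
    score = rep(1, length(oe)), stringsAsFactors = FALSE)
  rownames(observed) <- NULL

  n_tads <- max(1, floor(config$chrom_length / config$tad_width))
  tads <- do.call(rbind, lapply(chroms, function(ch) {
    s <- (seq_len(n_tads) - 1) * config$tad_width
    regions(rep(ch, n_tads), s, pmin(s + config$tad_width, config$chrom_length),
            name = sprintf("%s_tad%02d", ch, seq_len(n_tads)))
  }))
  rownames(tads) <- NULL

  structure(list(config = config, genes = genes, enhancers = enhancers,
                 peaks = peaks, counts = counts, truth = truth,
                 observed = observed, tads = tads),
            class = "synth_bundle")
}

#' @export
print.synth_bundle <- function(x, ...) {
  cat(sprintf(
    "<synth_bundle> %d chroms, %d genes, %d enhancers (%d linked, %d observed)\n",
    x$config$n_chroms, nrow(x$genes), nrow(x$enhancers), nrow(x$truth),
    nrow(x$observed)))
  invisible(x)
}

#' Write a synthetic bundle to disk in pipeline-standard formats
#'
#' Emits exactly what the real pipeline consumes: per-timepoint peak BEDs,
#' a gene TSV, per-assay raw count tables for enhancers and genes, the
#' observed truth BEDPE, a TAD BED, plus the complete truth as JSON.
#'
#' @param bundle a `synth_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synth_bundle"))
  dir.create(file.path(dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "counts"), showWarnings = FALSE)
  write_genes(bundle$genes, file.path(dir, "genes.tsv"))
  for (tp in names(bundle$peaks)) {
    write_bed(bundle$peaks[[tp]], file.path(dir, "peaks",
                                            sprintf("t%s.bed", tp)))
  }
  for (a in names(bundle$counts$enh)) {
    write_count_table(bundle$counts$enh[[a]],
                      file.path(dir, "counts", sprintf("%s_enhancers.tsv", a)))
    write_count_table(bundle$counts$gene[[a]],
                      file.path(dir, "counts", sprintf("%s_genes.tsv", a)))
  }
  write_bedpe(bundle$observed, file.path(dir, "observed.bedpe"))
  write_bed(bundle$tads, file.path(dir, "tads.bed"))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       digits = NA)
  jsonlite::write_json(unclass(bundle$config), file.path(dir, "config.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Recovery of planted links by a fitted classifier
#'
#' Scores recovery against the complete planted truth (not the thinned
#' observed set): MAP accuracy over truly linked enhancers present in the
#' posterior table, and precision at fixed recall over all candidate
#' pairs of those enhancers (a pair is a true positive iff it is a
#' planted link).
#'
#' @param truth complete truth table (`enhancer_id`, `gene_id`).
#' @param post a [posterior_table()].
#' @param tpr_levels recall levels.
#' @return list: `map_accuracy` (percent), `precision_at_tpr`,
#'   `n_enhancers_evaluated`, `n_true_links`.
#' @export
truth_recovery_report <- function(truth, post, tpr_levels = c(0.1, 0.2, 0.3)) {
  linked <- intersect(unique(truth$enhancer_id), unique(post$enhancer_id))
  if (!length(linked)) stop("no truly linked enhancer in the posterior table")
  sub <- post[post$enhancer_id %in% linked, , drop = FALSE]
  key <- paste(truth$enhancer_id, truth$gene_id, sep = "\r")
  is_true <- paste(sub$enhancer_id, sub$gene_id, sep = "\r") %in% key
  list(map_accuracy = map_accuracy(map_target(sub), truth),
       precision_at_tpr = precision_at_tpr(sub$posterior, is_true,
                                           tpr_levels),
       n_enhancers_evaluated = length(linked),
       n_true_links = sum(is_true))
}
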