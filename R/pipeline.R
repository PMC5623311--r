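#' Default pipeline configuration
#'
#' Parameter home for the whole workflow. Everything is overridable from
#' a JSON config file and, through the bundled CLI script, from the
#' command line (precedence: CLI > file > defaults).
#'
#' @param ... overrides of the defaults below.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    promoter_ext = 300,        # bp upstream promoter extension
    min_support = 2,           # distinct timepoints for a consensus site
    min_total_reads = 30,      # raw-count floor across all assays/timepoints
    include_t0 = FALSE,        # count t=0 peaks toward consensus support
    feature_subset = NULL,     # NULL = all fitted features
    max_distance = Inf,        # candidate-universe cap in bp
    tpr_levels = c(0.10, 0.20, 0.30),
    fdr_levels = c(0.20, 0.25, 0.30),
    seed = 1,
    synth = list())            # overrides passed to synth_config()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  lv <- c(cfg$tpr_levels, cfg$fdr_levels)
  if (any(lv <= 0 | lv > 1)) stop("tpr/fdr levels must lie in (0, 1]")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline config from JSON
#' @param path JSON file with any subset of the [pipeline_config()] fields.
#' @export
read_pipeline_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, obj)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg)[order(names(cfg))], tmp, digits = NA,
                       auto_unbox = TRUE, null = "null")
  unname(tools::md5sum(tmp))
}

.manifest_path <- function(outdir) file.path(outdir, "run_manifest.json")

.read_manifest <- function(outdir) {
  p <- .manifest_path(outdir)
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else
    list(config_hash = NULL, stages = list())
}

.record_stage <- function(outdir, stage, outputs, cfg) {
  m <- .read_manifest(outdir)
  m$config_hash <- config_hash(cfg)
  m$package_version <- as.character(utils::packageVersion("epbayes"))
  m$stages[[stage]] <- list(outputs = outputs,
                            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(m, .manifest_path(outdir), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(m)
}

.require_artifact <- function(path, produced_by) {
  if (!file.exists(path)) {
    stop(sprintf("missing artifact '%s': run the '%s' stage first",
                 basename(path), produced_by))
  }
  path
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (write a synthetic bundle), `consensus`
#' (persistent-union peaks, distal filter), `counts` (normalize and
#' coverage-filter count tables), `features` (pair attributes + truth
#' labels), `train` (fit class densities on odd chromosomes), `predict`
#' (posteriors, MAP targets, gene scores over all enhancers), `evaluate`
#' (held-out report on even chromosomes). Existing outputs are reused
#' unless `force = TRUE`; every output is recorded in
#' `run_manifest.json` together with a hash of the config.
#'
#' @param stage stage name (see above).
#' @param config a [pipeline_config()], or path to a JSON config.
#' @param outdir output/working directory (also where upstream artifacts
#'   are looked up).
#' @param force recompute even when outputs exist.
#' @param quiet suppress progress messages.
#' @return invisible character vector of this stage's output paths.
#' @export
run_pipeline <- function(stage = c("simulate", "consensus", "counts",
                                   "features", "train", "predict",
                                   "evaluate"),
                         config = pipeline_config(), outdir, force = FALSE,
                         quiet = FALSE) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  outputs <- switch(
    stage,
    simulate = {
      bdir <- file.path(outdir, "bundle")
      if (!force && file.exists(file.path(bdir, "genes.tsv"))) {
        say("[simulate] bundle exists; skipping (use force = TRUE)")
        return(invisible(bdir))
      }
      scfg <- do.call(synth_config, c(list(seed = config$seed), config$synth))
      write_bundle(synth_generate(scfg), bdir)
      say("[simulate] wrote bundle to %s", bdir)
      bdir
    },
    consensus = {
      out <- file.path(outdir, "consensus.bed")
      if (!force && file.exists(out)) {
        say("[consensus] exists; skipping"); return(invisible(out))
      }
      bdir <- file.path(outdir, "bundle")
      .require_artifact(file.path(bdir, "genes.tsv"), "simulate")
      peak_files <- list.files(file.path(bdir, "peaks"), full.names = TRUE)
      tps <- sub("^t(.*)\\.bed$", "\\1", basename(peak_files))
      ord <- order(as.numeric(tps))
      peaks <- stats::setNames(lapply(peak_files[ord], read_bed), tps[ord])
      genes <- read_genes(file.path(bdir, "genes.tsv"))
      cons <- persistent_union(peaks, min_support = config$min_support,
                               include_t0 = config$include_t0)
      distal <- filter_distal(cons, genes, config$promoter_ext)
      distal$score <- distal$support
      write_bed(distal, out)
      say("[consensus] %d consensus sites, %d distal", nrow(cons), nrow(distal))
      out
    },
    counts = {
      out <- file.path(outdir, "counts_normalized")
      done <- file.path(out, ".done")
      if (!force && file.exists(done)) {
        say("[counts] exists; skipping"); return(invisible(out))
      }
      bdir <- file.path(outdir, "bundle")
      cons <- read_bed(.require_artifact(file.path(outdir, "consensus.bed"),
                                         "consensus"))
      files <- list.files(file.path(bdir, "counts"), full.names = TRUE)
      .require_artifact(file.path(bdir, "counts"), "simulate")
      dir.create(out, showWarnings = FALSE)
      load_side <- function(suffix, ids) {
        fs <- files[grepl(suffix, files)]
        raw <- lapply(fs, read_count_table)
        names(raw) <- sub(suffix, "", basename(fs))
        raw <- lapply(raw, function(ts) {
          i <- match(ids, ts$region_ids)
          if (anyNA(i)) stop("count table lacks rows for some regions")
          ts$matrix <- ts$matrix[i, , drop = FALSE]
          ts$region_ids <- ids
          ts
        })
        filt <- filter_low_coverage(raw, config$min_total_reads)
        lapply(filt$ts_list, normalize_timeseries)
      }
      enh_norm <- load_side("_enhancers\\.tsv$", cons$name)
      gene_norm <- load_side("_genes\\.tsv$",
                             read_genes(file.path(bdir, "genes.tsv"))$name)
      for (a in names(enh_norm)) {
        write_count_table(enh_norm[[a]],
                          file.path(out, sprintf("%s_enhancers.tsv", a)))
        write_count_table(gene_norm[[a]],
                          file.path(out, sprintf("%s_genes.tsv", a)))
      }
      writeLines(format(Sys.time()), done)
      say("[counts] normalized %d assays", length(enh_norm))
      out
    },
    features = {
      out <- file.path(outdir, "features.tsv")
      if (!force && file.exists(out)) {
        say("[features] exists; skipping"); return(invisible(out))
      }
      bdir <- file.path(outdir, "bundle")
      cdir <- .require_artifact(file.path(outdir, "counts_normalized"), "counts")
      cons <- read_bed(.require_artifact(file.path(outdir, "consensus.bed"),
                                         "consensus"))
      genes <- read_genes(file.path(bdir, "genes.tsv"))
      read_side <- function(suffix) {
        fs <- list.files(cdir, pattern = suffix, full.names = TRUE)
        stats::setNames(lapply(fs, read_count_table),
                        sub(suffix, "", basename(fs)))
      }
      enh_ts <- read_side("_enhancers\\.tsv$")
      gene_ts <- read_side("_genes\\.tsv$")
      cons <- cons[cons$name %in% enh_ts[[1]]$region_ids, , drop = FALSE]
      genes <- genes[genes$name %in% gene_ts[[1]]$region_ids, , drop = FALSE]
      cons$center <- floor((cons$start + cons$end) / 2)
      feats <- build_features(enh_ts, gene_ts, cons, genes,
                              promoter_ext = config$promoter_ext,
                              max_distance = config$max_distance)
      truth <- read_bedpe(file.path(bdir, "observed.bedpe"))
      feats <- label_pairs(feats, truth, cons, genes, config$promoter_ext)
      write_features(feats, out)
      say("[features] %d pairs (%d positive, %d negative)",
          nrow(feats), sum(feats$label == "positive"),
          sum(feats$label == "negative"))
      out
    },
    train = {
      out <- file.path(outdir, "model.json")
      if (!force && file.exists(out)) {
        say("[train] exists; skipping"); return(invisible(out))
      }
      feats <- read_features(.require_artifact(
        file.path(outdir, "features.tsv"), "features"))
      split <- split_chromosomes(unique(feats$chrom))
      train <- feats[feats$chrom %in% split$train & feats$label != "unknown", ]
      model <- fit_class_densities(train)
      write_densities(model, out)
      say("[train] fitted on %s (%d pos / %d neg)",
          paste(split$train, collapse = ","), model$n_positive,
          model$n_negative)
      out
    },
    predict = {
      outs <- file.path(outdir, c("posteriors.tsv", "map_targets.tsv",
                                  "gene_scores.tsv"))
      if (!force && all(file.exists(outs))) {
        say("[predict] exists; skipping"); return(invisible(outs))
      }
      feats <- read_features(.require_artifact(
        file.path(outdir, "features.tsv"), "features"))
      model <- read_densities(.require_artifact(
        file.path(outdir, "model.json"), "train"))
      post <- posterior_table(feats, model, config$feature_subset)
      write_features(post, outs[1])
      utils::write.table(map_target(post), outs[2], sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(gene_regulation_score(post), outs[3], sep = "\t",
                         quote = FALSE, row.names = FALSE)
      say("[predict] scored %d pairs over %d enhancers", nrow(post),
          length(unique(post$enhancer_id)))
      outs
    },
    evaluate = {
      out <- file.path(outdir, "eval_report.json")
      if (!force && file.exists(out)) {
        say("[evaluate] exists; skipping"); return(invisible(out))
      }
      post <- read_features(.require_artifact(
        file.path(outdir, "posteriors.tsv"), "predict"))
      split <- split_chromosomes(unique(post$chrom))
      test <- post[post$chrom %in% split$test, , drop = FALSE]
      tad_path <- file.path(outdir, "bundle", "tads.bed")
      tads <- if (file.exists(tad_path)) read_bed(tad_path) else NULL
      rep <- evaluate_predictions(test, config$tpr_levels,
                                  config$fdr_levels, tads)
      jsonlite::write_json(
        list(test_chroms = split$test,
             feature_subset = if (is.null(config$feature_subset)) "all"
                              else config$feature_subset,
             tpr_levels = config$tpr_levels, fdr_levels = config$fdr_levels,
             n_positive = rep$n_positive, n_negative = rep$n_negative,
             precision_at_tpr = as.list(rep$precision_at_tpr),
             fdr_cutoffs = rep$fdr_cutoffs,
             map_accuracy = rep$map_accuracy,
             intra_tad = rep$intra_tad, inter_tad = rep$inter_tad),
        out, auto_unbox = TRUE, digits = NA, null = "null")
      say("[evaluate] MAP accuracy %.1f%% on %s", rep$map_accuracy,
          paste(split$test, collapse = ","))
      out
    })
  .record_stage(outdir, stage, outputs, config)
  invisible(outputs)
}

#' End-to-end analysis of an in-memory bundle
#'
#' Convenience wrapper used by the tests and the acceptance suite:
#' consensus construction, count normalization and filtering, feature
#' building, labelling against the observed truth, density fitting on
#' the training chromosomes and posterior scoring of the test
#' chromosomes.
#'
#' @param bundle a [synth_generate()] bundle (or an equivalent list).
#' @param config a [pipeline_config()].
#' @param feature_subset feature columns for scoring (default all).
#' @return list: `features` (labeled, all chroms), `post_test`
#'   (posterior table on test chromosomes), `model`, `split`,
#'   `enhancers`, `genes`.
#' @export
analyze_bundle <- function(bundle, config = pipeline_config(),
                           feature_subset = NULL) {
  cons <- persistent_union(bundle$peaks, min_support = config$min_support,
                           include_t0 = config$include_t0)
  distal <- filter_distal(cons, bundle$genes, config$promoter_ext)
  subset_ts <- function(ts_list, ids) {
    lapply(ts_list, function(ts) {
      i <- match(ids, ts$region_ids)
      if (anyNA(i)) stop("count table lacks rows for some consensus regions")
      ts$matrix <- ts$matrix[i, , drop = FALSE]
      ts$region_ids <- ids
      ts
    })
  }
  enh_raw <- subset_ts(bundle$counts$enh, distal$name)
  gene_raw <- bundle$counts$gene
  enh_f <- filter_low_coverage(enh_raw, config$min_total_reads)
  gene_f <- filter_low_coverage(gene_raw, config$min_total_reads)
  enh_norm <- lapply(enh_f$ts_list, normalize_timeseries)
  gene_norm <- lapply(gene_f$ts_list, normalize_timeseries)
  distal <- distal[distal$name %in% enh_f$retained, , drop = FALSE]
  genes <- bundle$genes[bundle$genes$name %in% gene_f$retained, , drop = FALSE]
  feats <- build_features(enh_norm, gene_norm, distal, genes,
                          promoter_ext = config$promoter_ext,
                          max_distance = config$max_distance)
  feats <- label_pairs(feats, bundle$observed, distal, genes,
                       config$promoter_ext)
  split <- split_chromosomes(unique(feats$chrom))
  train <- feats[feats$chrom %in% split$train & feats$label != "unknown", ]
  model <- fit_class_densities(train)
  test <- feats[feats$chrom %in% split$test, , drop = FALSE]
  post <- posterior_table(test, model, feature_subset)
  list(features = feats, post_test = post, model = model, split = split,
       enhancers = distal, genes = genes)
}
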