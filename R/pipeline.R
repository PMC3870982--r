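#' Default run configuration
#'
#' All fixed constants of the method live here, each overridable: the
#' detection floor (log2(FPKM) >= -15), the activity threshold
#' (zFPKM >= -3), the binning size (500 genes), the promoter windows
#' (2 kb active, containment for repressed, 1 kb for H3K4me3), the KDE
#' settings, and the seed. The resolved configuration is echoed into the
#' output directory of every run so no default stays hidden.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    fpkm = NULL, dialect = "plain_tsv",
    segments_bed = NULL, gtf = NULL, peaks_bed = NULL,
    bandwidth = "scott", grid_points = 4096L, min_detected = 30L,
    floor = -15, threshold = -3, bin_size = 500L,
    window_active = 2000L, window_repressed = 0L, window_h3k4me3 = 1000L,
    active_states = c(1L, 2L), repressed_states = c(12L, 13L),
    exclude_samples = character(0), gene_whitelist = NULL,
    seed = 1L, out_dir = NULL, plots = FALSE
  )
}

resolve_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  resolved <- default_config()
  unknown <- setdiff(names(config), names(resolved))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  resolved[names(config)] <- config
  resolved
}

#' Run the full zFPKM workflow
#'
#' Sequences the method end to end: read the FPKM matrix, fit the zFPKM
#' model and call active genes; then, when chromatin inputs (`segments_bed`
#' + `gtf`) are present, classify promoters, build the binned fraction
#' curves, locate each sample's active/repressed crossover, and summarize
#' the thresholds across samples; optionally flag H3K4me3-proximal genes
#' when `peaks_bed` is given. All tables are written as TSV into `out_dir`
#' together with the resolved configuration (YAML) and a run log with
#' per-stage row counts. Reruns with the same configuration produce
#' identical numeric tables.
#'
#' @param config Named list of options (see [default_config()]) or path to
#'   a YAML file with the same fields. `fpkm` and `out_dir` are required.
#' @return Invisibly, a list of class `"zfpkm_run"`: the fitted model,
#'   promoter calls, crossover results, threshold summary, and a manifest
#'   of written files with per-stage completion status.
#' @export
run_pipeline <- function(config) {
  cfg <- resolve_config(config)
  if (is.null(cfg$fpkm)) stop("config must name an fpkm input file")
  if (is.null(cfg$out_dir)) stop("config must name an out_dir")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  logf <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, log_con)
    message(msg)
  }
  manifest <- list()
  result <- list(config = cfg)
  class(result) <- "zfpkm_run"

  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))],
                   file.path(cfg$out_dir, "resolved_config.yaml"))
  manifest$resolved_config <- "resolved_config.yaml"

  # --- stage: expression input -------------------------------------------
  fpkm <- read_fpkm_matrix(cfg$fpkm, cfg$dialect)
  logf("stage read: %d genes x %d samples from %s",
       nrow(fpkm), ncol(fpkm), cfg$fpkm)
  if (!is.null(cfg$gene_whitelist)) {
    keep <- rownames(fpkm) %in% cfg$gene_whitelist
    logf("stage whitelist: %d of %d genes kept", sum(keep), nrow(fpkm))
    fpkm <- fpkm[keep, , drop = FALSE]
  }

  # --- stage: zFPKM fit ---------------------------------------------------
  fit <- zfpkm(fpkm, floor = cfg$floor, bandwidth = cfg$bandwidth,
               grid_points = cfg$grid_points, min_detected = cfg$min_detected)
  result$fit <- fit
  write_fit_table(fit, file.path(cfg$out_dir, "fit_table.tsv"))
  write_matrix(fit$zfpkm, file.path(cfg$out_dir, "zfpkm_matrix.tsv"))
  active <- call_active(fit, cfg$threshold)
  storage.mode(active) <- "integer"
  write_matrix(active, file.path(cfg$out_dir, "active_calls.tsv"))
  manifest$fit_table <- "fit_table.tsv"
  manifest$zfpkm_matrix <- "zfpkm_matrix.tsv"
  manifest$active_calls <- "active_calls.tsv"
  logf("stage fit: %d sample(s); active gene counts: %s",
       ncol(fpkm), paste(colSums(active), collapse = ", "))

  if (isTRUE(cfg$plots)) {
    grDevices::png(file.path(cfg$out_dir, "fit_%02d.png"),
                   width = 800, height = 600)
    for (s in fit$fits$sample_id) plot(fit, sample = s,
                                       threshold = cfg$threshold)
    grDevices::dev.off()
    manifest$fit_plots <- "fit_*.png"
  }

  # --- stage: chromatin validation (optional) ----------------------------
  if (!is.null(cfg$segments_bed) && !is.null(cfg$gtf)) {
    segments <- parse_chromhmm_bed(cfg$segments_bed,
                                   keep_states = c(cfg$active_states,
                                                   cfg$repressed_states))
    tss <- extract_tss(cfg$gtf)
    logf("stage chromatin: %d segments, %d TSS records",
         nrow(segments), nrow(tss))
    calls <- classify_promoters(tss, segments, window = cfg$window_active,
                                repressed_window = cfg$window_repressed,
                                active_states = cfg$active_states,
                                repressed_states = cfg$repressed_states)
    result$promoter_calls <- calls
    utils::write.table(calls, file.path(cfg$out_dir, "promoter_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$promoter_calls <- "promoter_calls.tsv"

    if (!is.null(cfg$peaks_bed)) {
      k4 <- h3k4me3_overlap(tss, cfg$peaks_bed, window = cfg$window_h3k4me3)
      result$h3k4me3 <- k4
      utils::write.table(k4, file.path(cfg$out_dir, "h3k4me3_flags.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$h3k4me3 <- "h3k4me3_flags.tsv"
      logf("stage h3k4me3: %d of %d genes flagged", sum(k4$h3k4me3), nrow(k4))
    }

    crossovers <- list()
    for (s in fit$fits$sample_id) {
      lg <- fit$log2_fpkm[, s]
      curve <- bin_by_expression(lg[!is.na(lg)], calls,
                                 bin_size = cfg$bin_size)
      res <- tryCatch(
        find_crossover(curve, fit = fit$fits[fit$fits$sample_id == s, ]),
        error = function(e) {
          logf("stage crossover [%s]: %s", s, conditionMessage(e))
          NULL
        })
      if (!is.null(res)) crossovers[[s]] <- res
      utils::write.table(curve,
                         file.path(cfg$out_dir,
                                   paste0("fraction_curve_", s, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest$fraction_curves <- "fraction_curve_<sample>.tsv"
    if (length(crossovers)) {
      result$crossovers <- crossovers
      xo <- do.call(rbind, lapply(crossovers, function(r) {
        data.frame(sample_id = r$sample_id,
                   threshold_log2fpkm = r$threshold_log2fpkm,
                   threshold_zfpkm = r$threshold_zfpkm,
                   threshold_fpkm = r$threshold_fpkm)
      }))
      utils::write.table(xo, file.path(cfg$out_dir, "crossover.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$crossover <- "crossover.tsv"
      logf("stage crossover: thresholds found for %d sample(s)",
           nrow(xo))
      summary <- summarize_thresholds(xo, exclude = cfg$exclude_samples)
      result$threshold_summary <- summary
      sink(file.path(cfg$out_dir, "threshold_summary.txt"))
      print(summary)
      sink()
      manifest$threshold_summary <- "threshold_summary.txt"
    }
  } else {
    logf("stage chromatin: skipped (no segments_bed/gtf in config)")
  }

  result$manifest <- manifest
  logf("run complete: %d artifact(s) in %s", length(manifest), cfg$out_dir)
  invisible(result)
}

#' @export
print.zfpkm_run <- function(x, ...) {
  cat("zFPKM pipeline run:", x$config$out_dir, "\n")
  cat("artifacts:", paste(unlist(x$manifest), collapse = ", "), "\n")
  invisible(x)
}
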