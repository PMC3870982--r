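#' Bin genes by expression and compute promoter-state fractions
#'
#' Rank-orders detected genes by log2(FPKM) (ascending; ties keep input
#' order) and cuts them into consecutive bins of `bin_size` genes (the
#' highest-expression tail bin may be smaller). For each bin it reports the
#' mean expression and the fraction of genes with active and with repressed
#' promoters. Genes without a promoter call stay in the bin and in the
#' denominator — the fractions are fractions of genes in the bin, not of
#' labelled genes.
#'
#' @param log_values Named numeric vector of log2(FPKM) for detected genes,
#'   or a data frame from [log2_with_floor()] (not-detected rows dropped).
#' @param calls Promoter call table from [classify_promoters()].
#' @param bin_size Genes per bin (default 500).
#' @return Data frame of class `"binned_fraction_curve"`: one row per bin
#'   with `bin`, `mean_log2_fpkm`, `count`, `fraction_active`,
#'   `fraction_repressed`, ordered by ascending expression.
#' @export
bin_by_expression <- function(log_values, calls, bin_size = 500L) {
  stopifnot(bin_size >= 1)
  if (is.data.frame(log_values)) {
    log_values <- stats::setNames(log_values$log2_fpkm,
                                  log_values$gene_id)[log_values$detected]
  }
  log_values <- log_values[!is.na(log_values)]
  if (length(log_values) == 0L) {
    stop("no detected genes to bin")
  }
  ord <- order(log_values)  # stable: ties keep input order
  x <- log_values[ord]
  ids <- names(x)
  active <- stats::setNames(calls$active, calls$gene_id)[ids]
  repressed <- stats::setNames(calls$repressed, calls$gene_id)[ids]
  active[is.na(active)] <- FALSE
  repressed[is.na(repressed)] <- FALSE
  bin <- ceiling(seq_along(x) / bin_size)
  out <- data.frame(
    bin = unique(bin),
    mean_log2_fpkm = as.numeric(tapply(x, bin, mean)),
    count = as.integer(tapply(x, bin, length)),
    fraction_active = as.numeric(tapply(active, bin, mean)),
    fraction_repressed = as.numeric(tapply(repressed, bin, mean)),
    row.names = NULL
  )
  class(out) <- c("binned_fraction_curve", "data.frame")
  out
}

#' Locate the active/repressed crossover of a binned fraction curve
#'
#' Scans the curve from the highest-expression bin downward and takes the
#' first adjacent bin pair where the difference
#' `d = fraction_active - fraction_repressed` changes sign (from >= 0 to
#' < 0); the expression level where d = 0 is found by linear interpolation
#' between the two bins' mean expressions. This is the level below which
#' repressed promoters outnumber active ones — the boundary between active
#' transcription and background. Additional sign changes further down the
#' curve (noise in sparse low-expression bins) are reported as a warning.
#'
#' @param curve A `binned_fraction_curve` from [bin_by_expression()].
#' @param fit Optional `half_gaussian_fit` (or one row of a `zfpkm_fit`'s
#'   `fits` table) used to express the threshold on the zFPKM scale.
#' @param sample_id Optional sample label carried into the result.
#' @return List of class `"crossover_result"`: `threshold_log2fpkm`,
#'   `threshold_zfpkm` (`NA` without a fit), `threshold_fpkm` (linear
#'   scale), `bracket` (indices of the bracketing bins, low then high) and
#'   `sample_id`.
#' @export
find_crossover <- function(curve, fit = NULL, sample_id = NA_character_) {
  stopifnot(is.data.frame(curve), nrow(curve) >= 2)
  d <- curve$fraction_active - curve$fraction_repressed
  x <- curve$mean_log2_fpkm
  n <- length(d)
  # walk downward from the top bin; bracket = (hi = i+1, lo = i)
  crossings <- integer(0)
  for (i in (n - 1):1) {
    if (d[i + 1] >= 0 && d[i] < 0) crossings <- c(crossings, i)
  }
  if (length(crossings) == 0L) {
    stop("no active/repressed crossover: the fraction curves never cross")
  }
  if (length(crossings) > 1L) {
    warning("multiple active/repressed crossings; using the ",
            "highest-expression one (bins ",
            paste(crossings, collapse = ", "), ")")
  }
  lo <- crossings[1]
  hi <- lo + 1L
  thr <- x[hi] + (x[lo] - x[hi]) * d[hi] / (d[hi] - d[lo])
  z <- NA_real_
  if (!is.null(fit)) {
    if (is.data.frame(fit)) fit <- as.list(fit[1, ])
    z <- (thr - fit$mu) / fit$sigma
    if (is.na(sample_id) && !is.null(fit$sample_id)) sample_id <- fit$sample_id
  }
  structure(
    list(threshold_log2fpkm = thr, threshold_zfpkm = z,
         threshold_fpkm = 2^thr, bracket = c(lo, hi), sample_id = sample_id),
    class = "crossover_result"
  )
}

#' @export
print.crossover_result <- function(x, ...) {
  cat(sprintf(
    "Active/repressed crossover%s: log2(FPKM) = %.3f (FPKM %.3f)%s\n",
    if (is.na(x$sample_id)) "" else paste0(" [", x$sample_id, "]"),
    x$threshold_log2fpkm, x$threshold_fpkm,
    if (is.na(x$threshold_zfpkm)) ""
    else sprintf(", zFPKM = %.3f", x$threshold_zfpkm)))
  invisible(x)
}

#' Summarize crossover thresholds across samples
#'
#' Computes the arithmetic mean and standard deviation of per-sample
#' crossover thresholds, on the log2(FPKM) and/or zFPKM scale, optionally
#' excluding outlier samples. The population (n-divisor) standard deviation
#' is the default; the sample (n-1) form is available via `sd_type`. The
#' included thresholds' range is also reported on the linear FPKM scale.
#'
#' @param results Either a list of `crossover_result` objects, a data frame
#'   with `sample_id` and `threshold_log2fpkm` / `threshold_zfpkm` columns,
#'   or a (optionally named) numeric vector of thresholds together with
#'   `scale`.
#' @param exclude Character vector of sample ids to exclude.
#' @param scale For numeric-vector input: `"zfpkm"` or `"log2fpkm"`.
#' @param sd_type `"population"` (n divisor, default) or `"sample"` (n-1).
#' @return List of class `"threshold_summary"` with per-scale `mean`, `sd`
#'   and `n`, plus `fpkm_range` (linear FPKM of the extreme included log2
#'   thresholds) and `excluded`.
#' @export
summarize_thresholds <- function(results, exclude = character(0),
                                 scale = c("zfpkm", "log2fpkm"),
                                 sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (is.numeric(results)) {
    scale <- match.arg(scale)
    df <- data.frame(sample_id = names(results) %||%
                       as.character(seq_along(results)))
    df[[paste0("threshold_", scale)]] <- as.numeric(results)
  } else if (is.data.frame(results)) {
    df <- results
  } else {
    df <- do.call(rbind, lapply(results, function(r) {
      data.frame(sample_id = r$sample_id,
                 threshold_log2fpkm = r$threshold_log2fpkm,
                 threshold_zfpkm = r$threshold_zfpkm,
                 stringsAsFactors = FALSE)
    }))
  }
  keep <- !(df$sample_id %in% exclude)
  if (!any(keep)) stop("all samples excluded")
  df <- df[keep, , drop = FALSE]
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  stat <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NULL)
    list(mean = mean(v),
         sd = if (sd_type == "population") pop_sd(v) else stats::sd(v),
         n = length(v))
  }
  out <- list(
    log2fpkm = if ("threshold_log2fpkm" %in% names(df))
      stat(df$threshold_log2fpkm) else NULL,
    zfpkm = if ("threshold_zfpkm" %in% names(df))
      stat(df$threshold_zfpkm) else NULL,
    excluded = exclude, sd_type = sd_type
  )
  if (!is.null(out$log2fpkm)) {
    lg <- df$threshold_log2fpkm[!is.na(df$threshold_log2fpkm)]
    out$fpkm_range <- 2^range(lg)
  }
  class(out) <- "threshold_summary"
  out
}

#' @export
print.threshold_summary <- function(x, ...) {
  fmt <- function(s, label) {
    if (!is.null(s)) {
      cat(sprintf("  %s: %.2f +/- %.2f (n = %d)\n", label, s$mean, s$sd, s$n))
    }
  }
  cat("Crossover threshold summary",
      if (length(x$excluded))
        paste0(" (excluding ", paste(x$excluded, collapse = ", "), ")"),
      "\n", sep = "")
  fmt(x$log2fpkm, "log2(FPKM)")
  fmt(x$zfpkm, "zFPKM")
  if (!is.null(x$fpkm_range)) {
    cat(sprintf("  linear FPKM range: %.2f - %.2f\n",
                x$fpkm_range[1], x$fpkm_range[2]))
  }
  invisible(x)
}

#' Plot a binned fraction curve
#'
#' @param x A `binned_fraction_curve`.
#' @param crossover Optional `crossover_result` whose threshold to mark.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.binned_fraction_curve <- function(x, crossover = NULL, ...) {
  graphics::plot(x$mean_log2_fpkm, x$fraction_active, type = "l",
                 col = "forestgreen", lwd = 2, ylim = c(0, 1),
                 xlab = expression(log[2] * "(FPKM)"),
                 ylab = "fraction of genes in bin", ...)
  graphics::lines(x$mean_log2_fpkm, x$fraction_repressed, col = "black",
                  lwd = 2)
  if (!is.null(crossover)) {
    graphics::abline(v = crossover$threshold_log2fpkm, col = "grey50",
                     lty = 2)
  }
  graphics::legend("left", bty = "n", lwd = 2,
                   col = c("forestgreen", "black"),
                   legend = c("active promoter", "repressed promoter"))
  invisible(x)
}
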