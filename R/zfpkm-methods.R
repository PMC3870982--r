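#' @export
print.zfpkm_fit <- function(x, ...) {
  cat("zFPKM normalization fit\n")
  cat(sprintf("  %d genes x %d sample(s); detection floor log2(FPKM) >= %g\n",
              nrow(x$zfpkm), ncol(x$zfpkm), x$floor))
  print(x$fits, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Per-sample Gaussian parameters of a zFPKM fit
#'
#' @param object A `zfpkm_fit`.
#' @param ... Ignored.
#' @return Numeric matrix with one row per sample and columns `mu`, `sigma`.
#' @export
coef.zfpkm_fit <- function(object, ...) {
  m <- as.matrix(object$fits[, c("mu", "sigma")])
  rownames(m) <- object$fits$sample_id
  m
}

#' @export
summary.zfpkm_fit <- function(object, threshold = -3, ...) {
  active <- call_active(object, threshold)
  s <- object$fits
  s$active <- colSums(active)
  s$not_detected <- colSums(is.na(object$zfpkm))
  structure(list(fits = s, threshold = threshold, n_genes = nrow(object$zfpkm)),
            class = "summary.zfpkm_fit")
}

#' @export
print.summary.zfpkm_fit <- function(x, ...) {
  cat(sprintf("zFPKM fit summary (%d genes; active = zFPKM >= %g)\n",
              x$n_genes, x$threshold))
  print(x$fits, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Transform new expression values with a fitted zFPKM model
#'
#' @param object A `zfpkm_fit`.
#' @param newdata Numeric vector or gene-by-sample matrix of linear FPKM
#'   values; when `NULL`, the fitted zFPKM matrix is returned.
#' @param sample Sample whose (mu, sigma) to apply (name or index);
#'   required when `newdata` has no column names matching fitted samples
#'   and the fit has more than one sample.
#' @param type `"zfpkm"` (default) to transform FPKM to zFPKM, or
#'   `"log2fpkm"` to invert zFPKM values back to log2(FPKM).
#' @param ... Ignored.
#' @return Numeric vector or matrix matching `newdata`.
#' @export
predict.zfpkm_fit <- function(object, newdata = NULL, sample = NULL,
                              type = c("zfpkm", "log2fpkm"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) return(object$zfpkm)
  pick_fit <- function(s) {
    i <- if (is.character(s)) match(s, object$fits$sample_id) else as.integer(s)
    if (is.na(i) || i < 1 || i > nrow(object$fits)) {
      stop("unknown sample: ", s)
    }
    object$fits[i, ]
  }
  one <- function(values, s) {
    f <- pick_fit(s)
    if (type == "zfpkm") {
      zfpkm_transform(log2_with_floor(values, floor = object$floor), f)
    } else {
      values * f$sigma + f$mu
    }
  }
  if (is.matrix(newdata)) {
    samples <- colnames(newdata) %||% object$fits$sample_id[seq_len(ncol(newdata))]
    out <- vapply(seq_len(ncol(newdata)),
                  function(j) one(stats::setNames(newdata[, j],
                                                  rownames(newdata)),
                                  samples[j]),
                  numeric(nrow(newdata)))
    dimnames(out) <- list(rownames(newdata), samples)
    out
  } else {
    if (is.null(sample)) {
      if (nrow(object$fits) != 1L) {
        stop("specify `sample` when the fit has multiple samples")
      }
      sample <- 1L
    }
    one(newdata, sample)
  }
}

#' Fitted zFPKM values
#'
#' @param object A `zfpkm_fit`.
#' @param ... Ignored.
#' @return The gene-by-sample zFPKM matrix (`NA` = not detected).
#' @export
fitted.zfpkm_fit <- function(object, ...) object$zfpkm

#' Plot a zFPKM fit
#'
#' Draws, for one sample, the kernel density estimate of log2(FPKM) together
#' with the mirrored Gaussian N(mu, sigma) implied by the half-Gaussian fit,
#' and marks mu and the active-gene threshold.
#'
#' @param x A `zfpkm_fit`.
#' @param sample Sample to plot (name or index; default first).
#' @param threshold Threshold to mark, on the zFPKM scale (default -3).
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.zfpkm_fit <- function(x, sample = 1L, threshold = -3, ...) {
  i <- if (is.character(sample)) match(sample, x$fits$sample_id) else sample
  if (is.na(i)) stop("unknown sample: ", sample)
  dens <- x$densities[[i]]
  f <- x$fits[i, ]
  gauss <- stats::dnorm(dens$grid, f$mu, f$sigma)
  graphics::plot(dens$grid, dens$density, type = "l", col = "steelblue",
                 lwd = 2, xlab = expression(log[2] * "(FPKM)"),
                 ylab = "density",
                 main = paste0(f$sample_id, ": zFPKM fit"), ...)
  graphics::lines(dens$grid, gauss, col = "firebrick", lwd = 2, lty = 2)
  graphics::abline(v = f$mu, col = "grey40", lty = 3)
  graphics::abline(v = f$mu + threshold * f$sigma, col = "grey40", lty = 2)
  graphics::legend("topleft", bty = "n", lwd = 2, lty = c(1, 2),
                   col = c("steelblue", "firebrick"),
                   legend = c("KDE", sprintf("N(%.2f, %.2f)", f$mu, f$sigma)))
  invisible(x)
}

#' Export the per-sample fit parameters as TSV
#'
#' @param fit A `zfpkm_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_table <- function(fit, path) {
  stopifnot(inherits(fit, "zfpkm_fit"))
  utils::write.table(fit$fits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
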