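#' Floor-aware log2 transform of FPKM values
#'
#' Converts linear-scale FPKM to log2 and applies the detection floor: genes
#' with FPKM of zero, missing FPKM, or log2(FPKM) below `floor` are marked
#' not-detected and carry no numeric value downstream. The default floor of
#' -15 log2 units sits far below any biologically plausible expression level
#' and exists only to remove numerical noise from near-zero quantitation.
#'
#' @param fpkm Numeric vector of nonnegative linear-scale FPKM values,
#'   optionally named by gene.
#' @param floor Detection floor on the log2 scale (default -15).
#' @return A data frame with columns `gene_id`, `log2_fpkm`, `detected`.
#'   `log2_fpkm` is `NA` where `detected` is `FALSE`.
#' @export
#' @examples
#' log2_with_floor(c(a = 1, b = 0, c = 8))
log2_with_floor <- function(fpkm, floor = -15) {
  if (!is.numeric(fpkm)) stop("fpkm must be numeric")
  if (any(fpkm < 0, na.rm = TRUE)) {
    stop("negative FPKM value: FPKM is nonnegative by definition")
  }
  ids <- names(fpkm)
  if (is.null(ids)) ids <- as.character(seq_along(fpkm))
  lg <- suppressWarnings(log2(fpkm))
  detected <- !is.na(fpkm) & fpkm > 0 & lg >= floor
  lg[!detected] <- NA_real_
  data.frame(gene_id = ids, log2_fpkm = lg, detected = detected,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Scott's rule as used by scipy's gaussian_kde: sd(x) * n^(-1/5).
# R's bw.nrd is the 1.06-factor variant, so the factor is computed here.
scott_bandwidth <- function(x) {
  stats::sd(x) * length(x)^(-1 / 5)
}

#' Gaussian kernel density estimate of a log2 expression distribution
#'
#' Evaluates a Gaussian-kernel KDE on an even grid spanning the data range
#' plus three bandwidths on either side. The mode of this curve anchors the
#' half-Gaussian fit in [fit_half_gaussian()].
#'
#' @param values Numeric vector of detected log2(FPKM) values (no `NA`).
#' @param bandwidth Either the string `"scott"` (default; `sd(x) * n^(-1/5)`)
#'   or an explicit positive bandwidth on the log2 scale.
#' @param grid_points Number of evenly spaced grid points (default 4096,
#'   giving a resolution of roughly 0.01 log2 units on typical data).
#' @param min_values Minimum number of values required for a meaningful
#'   density (default 30).
#' @return A data frame with columns `grid` and `density`; the trapezoidal
#'   integral of `density` over `grid` is 1 up to truncation error. The
#'   bandwidth used is attached as the `"bandwidth"` attribute.
#' @export
estimate_density <- function(values, bandwidth = "scott",
                             grid_points = 4096L, min_values = 30L) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("values must not contain NA; filter to detected genes")
  if (length(values) < min_values) {
    stop("density estimation infeasible: ", length(values),
         " values, need at least ", min_values)
  }
  if (identical(bandwidth, "scott")) {
    bw <- scott_bandwidth(values)
  } else {
    bw <- as.numeric(bandwidth)
  }
  if (!is.finite(bw) || bw <= 0) {
    stop("density estimation infeasible: bandwidth must be positive ",
         "(zero-variance input?)")
  }
  d <- stats::density(values, bw = bw, kernel = "gaussian", n = grid_points,
                      from = min(values) - 3 * bw, to = max(values) + 3 * bw)
  out <- data.frame(grid = d$x, density = d$y)
  attr(out, "bandwidth") <- bw
  out
}

#' Fit a half-Gaussian to the high-expression peak
#'
#' Models the right flank of the main expression peak as half of a Gaussian:
#' mu is placed at the KDE mode, and sigma follows from the half-normal
#' identity `E[X - mu | X > mu] = sigma * sqrt(2/pi)`, i.e.
#' `sigma = (U - mu) * sqrt(pi/2)` where U is the mean of all values
#' strictly above mu. Mirroring that half-Gaussian around mu yields the full
#' Gaussian N(mu, sigma) that describes the active-gene population.
#'
#' Ties at the density mode are broken toward the larger log2 value (the
#' right-most grid point of a plateau), which keeps the fit deterministic.
#'
#' @param values Numeric vector of detected log2(FPKM) values.
#' @param density Density curve from [estimate_density()]; computed from
#'   `values` when `NULL`.
#' @param ... Passed on to [estimate_density()] when `density` is `NULL`.
#' @return A list of class `"half_gaussian_fit"` with elements `mu`, `sigma`,
#'   `u`, `n_detected`, `n_above`, and `bandwidth`.
#' @export
fit_half_gaussian <- function(values, density = NULL, ...) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("values must not contain NA; filter to detected genes")
  if (is.null(density)) {
    density <- estimate_density(values, ...)
  }
  stopifnot(is.data.frame(density), all(c("grid", "density") %in% names(density)))
  peak <- max(density$density)
  mu <- max(density$grid[density$density == peak])  # right-most mode of a plateau
  above <- values[values > mu]
  if (length(unique(above)) < 2L) {
    stop("half-Gaussian fit infeasible: fewer than two distinct values above ",
         "the density mode ", format(mu, digits = 4))
  }
  u <- mean(above)
  sigma <- (u - mu) * sqrt(pi / 2)
  structure(
    list(mu = mu, sigma = sigma, u = u,
         n_detected = length(values), n_above = length(above),
         bandwidth = attr(density, "bandwidth")),
    class = "half_gaussian_fit"
  )
}

#' @export
print.half_gaussian_fit <- function(x, ...) {
  cat(sprintf(
    "Half-Gaussian fit: mu = %.4f, sigma = %.4f (U = %.4f, n = %d)\n",
    x$mu, x$sigma, x$u, x$n_detected))
  invisible(x)
}

#' zFPKM transform of log2 expression values
#'
#' Applies the affine transform `zFPKM = (log2(FPKM) - mu) / sigma` to the
#' detected genes of a sample; not-detected genes stay `NA`. The transform is
#' invertible: `log2(FPKM) = zFPKM * sigma + mu`.
#'
#' @param log_values Data frame from [log2_with_floor()], or a numeric vector
#'   of log2(FPKM) with `NA` for not-detected genes.
#' @param fit A `half_gaussian_fit` (or any list with `mu` and `sigma`).
#' @return Numeric vector of zFPKM values, named by gene where names are
#'   available; `NA` where the input was not detected.
#' @export
zfpkm_transform <- function(log_values, fit) {
  if (is.data.frame(log_values)) {
    lg <- stats::setNames(log_values$log2_fpkm, log_values$gene_id)
  } else {
    lg <- log_values
  }
  if (!is.numeric(fit$sigma) || fit$sigma <= 0) {
    stop("fit sigma must be positive")
  }
  (lg - fit$mu) / fit$sigma
}

#' Fit the zFPKM normalization model to an expression matrix
#'
#' The central fitting function. For every sample (column) it: (1) takes
#' log2(FPKM) with the detection floor ([log2_with_floor()]); (2) estimates
#' the density of detected values ([estimate_density()]); (3) fits the
#' half-Gaussian to the main peak ([fit_half_gaussian()]); and (4) transforms
#' the sample to zFPKM ([zfpkm_transform()]). The result is a fitted-model
#' object carrying the per-sample (mu, sigma) parameters, the zFPKM matrix,
#' and the density curves.
#'
#' The model assumes each sample's log2(FPKM) distribution has a dominant
#' high-expression peak whose right flank is approximately Gaussian; the
#' low-expression left shoulder (background transcription, mapping noise)
#' is deliberately ignored by fitting only values above the mode.
#'
#' @param x Numeric gene-by-sample matrix of linear FPKM values (rows named
#'   by gene, columns by sample), e.g. from [read_fpkm_matrix()]. A single
#'   unnamed numeric vector is treated as a one-sample matrix.
#' @param floor Detection floor on the log2 scale (default -15).
#' @param bandwidth `"scott"` or an explicit positive KDE bandwidth.
#' @param grid_points KDE grid size (default 4096).
#' @param min_detected Minimum detected genes per sample for a fit.
#' @return An object of class `"zfpkm_fit"` with components
#'   \describe{
#'     \item{fits}{data frame with `sample_id`, `mu`, `sigma`, `u`,
#'       `n_detected`}
#'     \item{zfpkm}{gene-by-sample matrix of zFPKM values (`NA` =
#'       not detected)}
#'     \item{log2_fpkm}{gene-by-sample matrix of floored log2(FPKM)}
#'     \item{densities}{named list of density curves, one per sample}
#'   }
#' @seealso [call_active()], [predict.zfpkm_fit()], [plot.zfpkm_fit()]
#' @export
#' @examples
#' set.seed(1)
#' fpkm <- matrix(2^rnorm(2000, mean = 3.7, sd = 2), ncol = 2,
#'                dimnames = list(paste0("g", 1:1000), c("s1", "s2")))
#' fit <- zfpkm(fpkm)
#' coef(fit)
zfpkm <- function(x, floor = -15, bandwidth = "scott",
                  grid_points = 4096L, min_detected = 30L) {
  if (is.numeric(x) && is.null(dim(x))) {
    x <- matrix(x, ncol = 1,
                dimnames = list(names(x) %||% as.character(seq_along(x)),
                                "sample_1"))
  }
  validate_fpkm_matrix(x, allow_missing = TRUE)
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("sample_", seq_len(ncol(x)))
  }
  samples <- colnames(x)
  genes <- rownames(x)

  log2m <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
  zm <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
  fits <- vector("list", length(samples))
  densities <- vector("list", length(samples))
  names(densities) <- samples

  for (j in seq_along(samples)) {
    lv <- log2_with_floor(stats::setNames(x[, j], genes), floor = floor)
    log2m[, j] <- lv$log2_fpkm
    dens <- estimate_density(lv$log2_fpkm[lv$detected], bandwidth = bandwidth,
                             grid_points = grid_points,
                             min_values = min_detected)
    fit <- fit_half_gaussian(lv$log2_fpkm[lv$detected], density = dens)
    zm[, j] <- zfpkm_transform(lv, fit)
    fits[[j]] <- data.frame(sample_id = samples[j], mu = fit$mu,
                            sigma = fit$sigma, u = fit$u,
                            n_detected = fit$n_detected,
                            stringsAsFactors = FALSE)
    densities[[j]] <- dens
  }

  structure(
    list(fits = do.call(rbind, fits), zfpkm = zm, log2_fpkm = log2m,
         densities = densities, floor = floor, bandwidth = bandwidth,
         grid_points = grid_points, call = match.call()),
    class = "zfpkm_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call active genes from a fitted zFPKM model
#'
#' A gene is active in a sample when it is detected and its zFPKM is at or
#' above the threshold. The default threshold of -3 (inclusive) deliberately
#' errs toward keeping borderline genes rather than discarding active ones.
#'
#' @param fit A `zfpkm_fit` object, or a numeric zFPKM matrix.
#' @param threshold Activity threshold on the zFPKM scale (default -3).
#' @return Logical gene-by-sample matrix; `FALSE` for not-detected genes.
#' @export
call_active <- function(fit, threshold = -3) {
  zm <- if (inherits(fit, "zfpkm_fit")) fit$zfpkm else fit
  if (!is.numeric(zm) || is.null(dim(zm))) {
    stop("fit must be a zfpkm_fit or a numeric zFPKM matrix")
  }
  active <- !is.na(zm) & zm >= threshold
  dimnames(active) <- dimnames(zm)
  active
}

#' Per-sample active gene sets
#'
#' @param fit A `zfpkm_fit` object or zFPKM matrix.
#' @param threshold Activity threshold on the zFPKM scale (default -3).
#' @return Named list of character vectors of active gene identifiers.
#' @export
active_genes <- function(fit, threshold = -3) {
  active <- call_active(fit, threshold)
  lapply(stats::setNames(seq_len(ncol(active)), colnames(active)),
         function(j) rownames(active)[active[, j]])
}
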