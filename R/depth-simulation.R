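# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Simulate mapped-read counts from a ground-truth transcriptome
#'
#' Draws per-gene read counts multinomially: the probability that a read
#' maps to a gene is proportional to `true_fpkm * length / 1000`, i.e. the
#' expected fragment mass of that gene. Sampling is at the gene level —
#' fragment placement within a transcript does not affect gene-level FPKM.
#'
#' @param truth A `synthetic_truth` from [generate_expression_profile()], or
#'   any list with numeric `true_fpkm` and `lengths` (and optionally
#'   `gene_ids`).
#' @param depth Total mapped reads to draw (>= 1).
#' @param seed Integer seed; the same (truth, depth, seed) always yields the
#'   same counts.
#' @return Integer vector of per-gene counts summing to `depth`, named by
#'   gene.
#' @export
simulate_read_counts <- function(truth, depth, seed) {
  stopifnot(depth >= 1)
  fpkm <- truth$true_fpkm
  lengths <- truth$lengths
  if (any(lengths <= 0)) stop("transcript lengths must be positive")
  w <- fpkm * lengths / 1000
  if (all(w == 0)) stop("all-zero truth: no gene can emit reads")
  counts <- with_seed(seed,
                      as.integer(stats::rmultinom(1, size = depth,
                                                  prob = w)))
  names(counts) <- truth$gene_ids %||% names(fpkm)
  counts
}

#' Convert read counts to FPKM
#'
#' `FPKM = count / (length / 1000) / (depth / 1e6)` — fragments per kilobase
#' of gene model per million mapped reads.
#'
#' @param counts Integer vector of per-gene read counts.
#' @param lengths Transcript lengths in bases (> 0).
#' @param depth Total mapped reads (>= 1).
#' @return Numeric vector of FPKM values, named like `counts`.
#' @export
counts_to_fpkm <- function(counts, lengths, depth) {
  stopifnot(depth >= 1)
  if (any(lengths <= 0)) stop("transcript lengths must be positive")
  counts / (lengths / 1000) / (depth / 1e6)
}

# Thin a count vector to a smaller depth without replacement (multivariate
# hypergeometric): equivalent to keeping a uniform subset of the deeper
# sample's reads, so the thinned sample is nested within the deeper one.
thin_counts <- function(counts, target_depth) {
  total <- sum(counts)
  stopifnot(target_depth <= total)
  if (target_depth == total) return(counts)
  out <- integer(length(counts))
  remaining <- target_depth
  left <- total
  for (i in seq_along(counts)) {
    if (remaining == 0L) break
    k <- stats::rhyper(1, counts[i], left - counts[i], remaining)
    out[i] <- k
    remaining <- remaining - k
    left <- left - counts[i]
  }
  names(out) <- names(counts)
  out
}

#' Read-depth series analysis of detection and active-gene stability
#'
#' Emulates sequencing the same library at several depths: counts are drawn
#' once at the deepest depth and thinned to each shallower depth (nested
#' subsampling, so detected gene sets grow monotonically with depth). At
#' each depth, FPKM is recomputed, the zFPKM model refitted, and detected
#' (count >= 1) and active (zFPKM >= `threshold`) genes counted. The
#' stability of the active-gene count across depths is summarized by its
#' coefficient of variation (population SD / mean).
#'
#' @param truth A `synthetic_truth` (see [generate_expression_profile()]).
#' @param depths Ascending vector of mapped-read depths (>= 2 depths).
#' @param threshold Activity threshold on the zFPKM scale (default -3).
#' @param seed Integer seed for the read sampling.
#' @param ... Passed to [zfpkm()] (e.g. `min_detected`).
#' @return Object of class `"depth_series"`: a list with `table` (data frame
#'   with `depth`, `detected`, `active`, `newly_detected`,
#'   `newly_detected_active`, `mu`, `sigma`, `fit_ok`) and `cv_active`.
#' @export
depth_series_analysis <- function(truth, depths, threshold = -3, seed = 1L,
                                  ...) {
  stopifnot(length(depths) >= 2)
  depths <- as.numeric(depths)
  if (is.unsorted(depths)) stop("depths must be sorted ascending")
  deepest <- simulate_read_counts(truth, max(depths), seed)
  lengths <- truth$lengths

  counts_at <- vector("list", length(depths))
  # thin from the deepest down so every shallower sample nests in the deeper
  with_seed(seed + 1L, {
    prev <- deepest
    for (i in rev(seq_along(depths))) {
      prev <- thin_counts(prev, depths[i])
      counts_at[[i]] <- prev
    }
  })

  rows <- vector("list", length(depths))
  active_sets <- vector("list", length(depths))
  detected_sets <- vector("list", length(depths))
  for (i in seq_along(depths)) {
    counts <- counts_at[[i]]
    fpkm <- counts_to_fpkm(counts, lengths, depths[i])
    detected_sets[[i]] <- names(counts)[counts >= 1L]
    mu <- sigma <- NA_real_
    active <- NA_integer_
    fit_ok <- TRUE
    active_sets[[i]] <- character(0)
    tryCatch({
      fit <- zfpkm(matrix(fpkm, ncol = 1,
                          dimnames = list(names(counts), "depth_sample")),
                   ...)
      mu <- fit$fits$mu
      sigma <- fit$fits$sigma
      active_sets[[i]] <- active_genes(fit, threshold)[[1]]
      active <- length(active_sets[[i]])
    }, error = function(e) {
      fit_ok <<- FALSE
      warning("fit failed at depth ", depths[i], ": ", conditionMessage(e))
    })
    rows[[i]] <- data.frame(
      depth = depths[i], detected = length(detected_sets[[i]]),
      active = active, mu = mu, sigma = sigma, fit_ok = fit_ok
    )
  }
  tab <- do.call(rbind, rows)
  tab$newly_detected <- c(NA_integer_, vapply(seq_along(depths)[-1],
    function(i) length(setdiff(detected_sets[[i]], detected_sets[[i - 1]])),
    integer(1)))
  tab$newly_detected_active <- c(NA_integer_, vapply(seq_along(depths)[-1],
    function(i) length(intersect(
      setdiff(detected_sets[[i]], detected_sets[[i - 1]]),
      active_sets[[i]])),
    integer(1)))
  act <- tab$active[tab$fit_ok & !is.na(tab$active)]
  cv <- if (length(act) >= 2) sqrt(mean((act - mean(act))^2)) / mean(act)
        else NA_real_
  structure(list(table = tab, cv_active = cv, threshold = threshold,
                 seed = seed),
            class = "depth_series")
}

#' @export
print.depth_series <- function(x, ...) {
  cat(sprintf("Read-depth series (active = zFPKM >= %g)\n", x$threshold))
  print(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("CV of active-gene count across depths: %.4f\n", x$cv_active))
  invisible(x)
}

#' Export a depth series table as TSV
#'
#' @param series A `depth_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_series <- function(series, path) {
  stopifnot(inherits(series, "depth_series"))
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(series$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(sprintf("# cv_active\t%.6g", series$cv_active), con)
  invisible(path)
}
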