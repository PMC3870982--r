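#' Parameters for the synthetic expression generator
#'
#' Describes the two-component mixture the zFPKM model assumes: a Gaussian
#' main peak of active genes in log2(FPKM) space and a lower Gaussian
#' background component (the "left shoulder" of leaky transcription and
#' mapping noise). Promoter labels are tied to true expression through a
#' logistic curve, so active-promoter fractions rise and repressed-promoter
#' fractions fall with expression, crossing at `label_midpoint`.
#'
#' Defaults describe a typical deeply sequenced human cell line: ~15,000
#' quantified protein-coding genes, about two thirds actively transcribed,
#' active peak N(3.7, 2.0) and background N(-6, 2.5) on the log2 scale, and
#' a label crossover near log2(FPKM) = -2.2.
#'
#' @param n_genes Number of genes.
#' @param p_active Probability that a gene belongs to the active component.
#' @param mu_a,sigma_a Mean and SD of the active component (log2 scale).
#' @param mu_b,sigma_b Mean and SD of the background component (log2 scale);
#'   a warning is issued unless `mu_b + 3 * sigma_b < mu_a` (modes
#'   well separated).
#' @param label_midpoint Log2 expression at which active and repressed
#'   promoter-label probabilities are equal.
#' @param label_steepness Logistic slope per log2 unit.
#' @param length_meanlog,length_sdlog Log-normal parameters of transcript
#'   length in bases; lengths are clamped at `min_length`.
#' @param min_length Minimum transcript length (default 200 b).
#' @param seed Integer seed; all randomness flows from it.
#' @return List of class `"synthetic_params"`.
#' @export
synthetic_params <- function(n_genes = 15000L, p_active = 0.65,
                             mu_a = 3.7, sigma_a = 2.0,
                             mu_b = -6, sigma_b = 2.5,
                             label_midpoint = -2.2, label_steepness = 1.5,
                             length_meanlog = log(2500), length_sdlog = 0.6,
                             min_length = 200L, seed = 1L) {
  if (p_active <= 0 || p_active >= 1) {
    if (p_active != 1) stop("p_active must lie in (0, 1]")
  }
  if (sigma_a <= 0 || sigma_b <= 0) stop("component SDs must be positive")
  if (mu_b + 3 * sigma_b >= mu_a) {
    warning("background and active components overlap substantially ",
            "(mu_b + 3*sigma_b >= mu_a); the fitted peak may be biased")
  }
  structure(
    list(n_genes = as.integer(n_genes), p_active = p_active,
         mu_a = mu_a, sigma_a = sigma_a, mu_b = mu_b, sigma_b = sigma_b,
         label_midpoint = label_midpoint, label_steepness = label_steepness,
         length_meanlog = length_meanlog, length_sdlog = length_sdlog,
         min_length = as.integer(min_length), seed = as.integer(seed)),
    class = "synthetic_params"
  )
}

#' Generate a synthetic expression profile with known ground truth
#'
#' Draws each gene's true log2 expression from the active component (with
#' probability `p_active`) or the background component, exponentiates to
#' linear FPKM, and attaches promoter labels: the active flag is Bernoulli
#' with probability `plogis(steepness * (x - midpoint))` in the true log2
#' expression, the repressed flag Bernoulli with the complementary
#' probability, drawn independently — so a small fraction of genes carries
#' both labels, as observed in real chromatin segmentations. Transcript
#' lengths are log-normal.
#'
#' The output is reproducible bit-for-bit from the parameter object (which
#' includes the seed).
#'
#' @param params A [synthetic_params()] object.
#' @return List of class `"synthetic_truth"`: `fpkm` (one-column matrix of
#'   linear FPKM), `true_fpkm`, `true_log2` (numeric vectors), `gene_ids`,
#'   `latent_label` (`"active"`/`"background"`), `promoter_calls` (data
#'   frame as from [classify_promoters()]), `lengths`, and `params`.
#' @export
generate_expression_profile <- function(params = synthetic_params()) {
  stopifnot(inherits(params, "synthetic_params"))
  p <- params
  with_seed(p$seed, {
    gene_ids <- sprintf("SYNG%05d", seq_len(p$n_genes))
    is_active <- stats::runif(p$n_genes) < p$p_active
    x <- numeric(p$n_genes)
    x[is_active] <- stats::rnorm(sum(is_active), p$mu_a, p$sigma_a)
    x[!is_active] <- stats::rnorm(sum(!is_active), p$mu_b, p$sigma_b)
    p_act_label <- stats::plogis(p$label_steepness * (x - p$label_midpoint))
    active_label <- stats::runif(p$n_genes) < p_act_label
    repressed_label <- stats::runif(p$n_genes) < (1 - p_act_label)
    lengths <- pmax(p$min_length,
                    round(stats::rlnorm(p$n_genes, p$length_meanlog,
                                        p$length_sdlog)))
    fpkm <- 2^x
    truth <- list(
      fpkm = matrix(fpkm, ncol = 1,
                    dimnames = list(gene_ids, "synthetic_1")),
      true_fpkm = stats::setNames(fpkm, gene_ids),
      true_log2 = stats::setNames(x, gene_ids),
      gene_ids = gene_ids,
      latent_label = stats::setNames(
        ifelse(is_active, "active", "background"), gene_ids),
      promoter_calls = data.frame(gene_id = gene_ids,
                                  active = active_label,
                                  repressed = repressed_label,
                                  stringsAsFactors = FALSE),
      lengths = stats::setNames(as.numeric(lengths), gene_ids),
      params = p
    )
    class(truth) <- "synthetic_truth"
    truth
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Synthetic truth: %d genes (p_active = %.2f), active N(%.2f, %.2f), background N(%.2f, %.2f), seed %d\n",
    p$n_genes, p$p_active, p$mu_a, p$sigma_a, p$mu_b, p$sigma_b, p$seed))
  invisible(x)
}

#' Write fixture files for a synthetic truth
#'
#' Materializes a synthetic profile as the on-disk formats the rest of the
#' package consumes: an FPKM matrix TSV, a Cufflinks-tracking-dialect file,
#' a toy GTF (one contig, one transcript per gene, >= 10 kb apart, strands
#' alternating), and a chromHMM-style BED with a state-1 segment spanning
#' each active-labelled promoter and a state-13 segment spanning each
#' repressed-labelled promoter (each segment covers TSS +/- 500 b, so the
#' labels are exactly recoverable by [classify_promoters()] at its
#' defaults).
#'
#' @param truth A `synthetic_truth`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the written file paths (`matrix`,
#'   `tracking`, `gtf`, `bed`), invisibly.
#' @export
write_fixture_files <- function(truth, out_dir) {
  stopifnot(inherits(truth, "synthetic_truth"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(out_dir, "fpkm_matrix.tsv"),
             tracking = file.path(out_dir, "genes.fpkm_tracking"),
             gtf = file.path(out_dir, "genes.gtf"),
             bed = file.path(out_dir, "chromhmm_states.bed"))

  write_matrix(truth$fpkm, paths["matrix"])

  n <- length(truth$gene_ids)
  fpkm <- as.numeric(truth$fpkm[, 1])
  tracking <- data.frame(
    tracking_id = truth$gene_ids,
    gene_short_name = paste0("SYN", seq_len(n)),
    locus = "chrSyn:0-0",
    length = as.integer(truth$lengths),
    FPKM = format(fpkm, digits = 15, trim = TRUE, scientific = FALSE),
    FPKM_status = "OK",
    stringsAsFactors = FALSE
  )
  utils::write.table(tracking, paths["tracking"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # deterministic layout: transcript i on chrSyn, starts spaced >= 10 kb
  # beyond the previous transcript's end, strands alternating
  lengths <- as.integer(truth$lengths)
  starts <- integer(n)
  pos <- 10000L
  for (i in seq_len(n)) {
    starts[i] <- pos
    pos <- pos + lengths[i] + 10000L
  }
  ends <- starts + lengths - 1L
  strands <- rep(c("+", "-"), length.out = n)
  tss <- ifelse(strands == "+", starts, ends)
  gtf <- sprintf(
    'chrSyn\tsynthetic\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t1";',
    starts, ends, strands, truth$gene_ids, truth$gene_ids)
  writeLines(gtf, paths["gtf"])

  calls <- truth$promoter_calls
  bed <- character(0)
  half <- 500L
  act <- which(calls$active)
  if (length(act)) {
    bed <- c(bed, sprintf("chrSyn\t%d\t%d\t1_Active_Promoter",
                          pmax(0L, tss[act] - half), tss[act] + half))
  }
  rep_i <- which(calls$repressed)
  if (length(rep_i)) {
    bed <- c(bed, sprintf("chrSyn\t%d\t%d\t13_Heterochromatin",
                          pmax(0L, tss[rep_i] - half), tss[rep_i] + half))
  }
  writeLines(bed, paths["bed"])
  invisible(paths)
}
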