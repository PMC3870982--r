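#' Parse a chromHMM-style BED segmentation
#'
#' Reads a BED file of chromatin-state segments whose name field begins with
#' an integer state number (e.g. `1_Active_Promoter`, `13_Heterochromatin`)
#' and returns the segments as a data frame with 0-based half-open
#' coordinates, optionally filtered to a set of states of interest.
#'
#' @param path Path to a BED file with at least 4 columns.
#' @param keep_states Optional integer vector of state numbers to keep
#'   (e.g. `c(1, 2, 12, 13)` for active/weak promoter and
#'   Polycomb-repressed/heterochromatin states); `NULL` keeps all.
#' @return Data frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open) and `state` (integer).
#' @export
parse_chromhmm_bed <- function(path, keep_states = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm) || anyNA(nm)) {
    stop("BED file must carry a name field with chromHMM-style state labels")
  }
  state_str <- sub("_.*$", "", nm)
  state <- suppressWarnings(as.integer(state_str))
  if (anyNA(state)) {
    bad <- which(is.na(state))[1]
    stop("unparseable state name '", nm[bad], "' at segment ", bad,
         ": expected an integer state prefix like '1_Active_Promoter'")
  }
  seg <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to BED 0-based half-open
    end = GenomicRanges::end(gr),
    state = state,
    stringsAsFactors = FALSE
  )
  if (any(seg$start >= seg$end)) {
    bad <- which(seg$start >= seg$end)[1]
    stop("malformed segment at line ", bad, ": start >= end")
  }
  if (!is.null(keep_states)) {
    seg <- seg[seg$state %in% keep_states, , drop = FALSE]
    rownames(seg) <- NULL
  }
  seg
}

#' Extract transcription start sites from a GTF file
#'
#' Returns one record per annotated transcript, with the TSS taken
#' strand-aware: the start coordinate on the + strand, the end coordinate on
#' the - strand (both 1-based, as in GTF).
#'
#' @param gtf_path Path to a GTF file containing `transcript` features with
#'   `gene_id` and `transcript_id` attributes.
#' @return Data frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `position` (1-based TSS coordinate) and `strand`.
#' @export
extract_tss <- function(gtf_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[gr$type == "transcript"]
  if (length(gr) == 0L) {
    stop("GTF file contains no transcript features")
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    bad <- which(strand == "*")[1]
    stop("transcript without strand at record ", bad,
         ": strand is required for TSS extraction")
  }
  if (is.null(gr$gene_id) || anyNA(gr$gene_id) ||
      is.null(gr$transcript_id) || anyNA(gr$transcript_id)) {
    stop("every transcript must carry gene_id and transcript_id attributes")
  }
  data.frame(
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    position = ifelse(strand == "+", GenomicRanges::start(gr),
                      GenomicRanges::end(gr)),
    strand = strand,
    stringsAsFactors = FALSE
  )
}

# Distance convention between a 1-based TSS position p and a 0-based
# half-open segment [s, e): 0 if s < p <= e (containment in 1-based terms),
# otherwise min(|p - (s+1)|, |p - e|) -- the distance to the nearest segment
# base in 1-based coordinates. "Within w bp" is inclusive (distance <= w).
# With IRanges (segments as 1-based [s+1, e]): distance <= w  <=>  overlap
# with maxgap = w - 1 for w >= 1, plain overlap for w = 0.
tss_within_window <- function(tss, intervals, window) {
  stopifnot(window >= 0)
  hit <- logical(nrow(tss))
  if (nrow(intervals) == 0L) return(hit)
  missing_chroms <- setdiff(unique(tss$chrom), unique(intervals$chrom))
  for (chrom in missing_chroms) {
    message("no segments on chromosome '", chrom,
            "'; its genes get no calls from this track")
  }
  common <- intersect(unique(tss$chrom), unique(intervals$chrom))
  for (chrom in common) {
    ti <- which(tss$chrom == chrom)
    iv <- intervals[intervals$chrom == chrom, , drop = FALSE]
    q <- IRanges::IRanges(start = tss$position[ti], width = 1L)
    s <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
    maxgap <- if (window >= 1) window - 1L else -1L
    ov <- IRanges::overlapsAny(q, s, maxgap = maxgap)
    hit[ti] <- ov
  }
  hit
}

#' Classify gene promoters as active and/or repressed from chromatin state
#'
#' A gene is labelled *active* when any of its TSSs lies within `window` bp
#' of any segment in an active-promoter state (chromHMM states 1 "Active
#' Promoter" or 2 "Weak Promoter" by default). It is labelled *repressed*
#' when any TSS lies within `repressed_window` bp of a repressed-state
#' segment (states 12 "Polycomb-repressed" or 13 "Heterochromatin"); the
#' default `repressed_window = 0` requires the TSS to fall inside the
#' segment, reflecting the stricter containment reading for repressed loci.
#' The two flags are independent: a gene with one TSS in an active segment
#' and another in a heterochromatic segment carries both labels.
#'
#' Distances use 1-based TSS coordinates against 0-based half-open segments:
#' distance 0 means containment, otherwise the distance to the nearest
#' segment base; "within w bp" is inclusive (distance <= w).
#'
#' @param tss Data frame from [extract_tss()].
#' @param segments Data frame from [parse_chromhmm_bed()].
#' @param window Window around the TSS for the active label, in bp
#'   (default 2000).
#' @param repressed_window Window for the repressed label (default 0 =
#'   strict containment).
#' @param active_states,repressed_states Integer state numbers counting as
#'   active / repressed.
#' @return Data frame with one row per gene: `gene_id`, `active`,
#'   `repressed` (logical). Window settings are attached as attributes
#'   `"window"` and `"repressed_window"`.
#' @export
classify_promoters <- function(tss, segments, window = 2000,
                               repressed_window = 0,
                               active_states = c(1L, 2L),
                               repressed_states = c(12L, 13L)) {
  stopifnot(is.data.frame(tss), is.data.frame(segments))
  act_seg <- segments[segments$state %in% active_states, , drop = FALSE]
  rep_seg <- segments[segments$state %in% repressed_states, , drop = FALSE]
  act_hit <- tss_within_window(tss, act_seg, window)
  rep_hit <- tss_within_window(tss, rep_seg, repressed_window)
  genes <- unique(tss$gene_id)
  out <- data.frame(
    gene_id = genes,
    active = as.logical(tapply(act_hit, factor(tss$gene_id, levels = genes),
                               any)),
    repressed = as.logical(tapply(rep_hit, factor(tss$gene_id, levels = genes),
                                  any)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "window") <- window
  attr(out, "repressed_window") <- repressed_window
  out
}

#' Flag genes with an H3K4me3 peak near a TSS
#'
#' H3K4me3 (histone H3 lysine-4 trimethylation) marks active promoters; a
#' gene is flagged when any of its TSSs lies within `window` bp of any peak
#' interval, under the same distance convention as [classify_promoters()].
#'
#' @param tss Data frame from [extract_tss()].
#' @param peaks Peak intervals: a data frame with `chrom`, `start`, `end`
#'   (0-based half-open), or a path to a BED file.
#' @param window Window in bp (default 1000).
#' @return Data frame with columns `gene_id` and `h3k4me3` (logical).
#' @export
h3k4me3_overlap <- function(tss, peaks, window = 1000) {
  if (is.character(peaks)) {
    gr <- rtracklayer::import(peaks, format = "BED")
    peaks <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE
    )
  }
  hit <- tss_within_window(tss, peaks, window)
  genes <- unique(tss$gene_id)
  data.frame(
    gene_id = genes,
    h3k4me3 = as.logical(tapply(hit, factor(tss$gene_id, levels = genes),
                                any)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
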