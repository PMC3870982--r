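# Shared helpers: brute-force oracles and small fixture builders.

# Distance from a 1-based TSS position p to a 0-based half-open segment
# [s, e): 0 on containment, else distance to the nearest segment base in
# 1-based coordinates. Used as the quadratic oracle for window queries.
oracle_distance <- function(p, s, e) {
  if (s < p && p <= e) return(0)
  min(abs(p - (s + 1)), abs(p - e))
}

# O(n * m) all-pairs window query: for every TSS row, is any interval on the
# same chromosome within `window` bp?
oracle_within_window <- function(tss, intervals, window) {
  vapply(seq_len(nrow(tss)), function(i) {
    iv <- intervals[intervals$chrom == tss$chrom[i], , drop = FALSE]
    if (nrow(iv) == 0L) return(FALSE)
    any(vapply(seq_len(nrow(iv)), function(j) {
      oracle_distance(tss$position[i], iv$start[j], iv$end[j]) <= window
    }, logical(1)))
  }, logical(1))
}

# Per-gene reduction of a per-TSS logical, matching classify_promoters.
oracle_by_gene <- function(tss, hit) {
  genes <- unique(tss$gene_id)
  as.logical(tapply(hit, factor(tss$gene_id, levels = genes), any))
}

write_tsv_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Minimal GTF with one transcript per row of `df` (chrom, start, end,
# strand, gene_id, transcript_id).
write_gtf_fixture <- function(df) {
  write_tsv_fixture(sprintf(
    '%s\ttest\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    df$chrom, df$start, df$end, df$strand, df$gene_id, df$transcript_id),
    ext = ".gtf")
}

write_bed_fixture <- function(df) {
  write_tsv_fixture(sprintf("%s\t%d\t%d\t%s",
                            df$chrom, df$start, df$end, df$name),
                    ext = ".bed")
}
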