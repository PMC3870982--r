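test_that("chromHMM BED parsing extracts and filters state numbers", {
  path <- write_bed_fixture(data.frame(
    chrom = "chr1",
    start = c(1000L, 3000L, 5000L, 7000L, 9000L, 11000L, 13000L, 15000L,
              17000L, 19000L),
    end = c(2000L, 4000L, 6000L, 8000L, 10000L, 12000L, 14000L, 16000L,
            18000L, 20000L),
    name = c("1_Active_Promoter", "2_Weak_Promoter", "5_Strong_Enhancer",
             "12_Repressed", "13_Heterochromatin", "15_Repetitive",
             "1_Active_Promoter", "5_Strong_Enhancer", "2_Weak_Promoter",
             "13_Heterochromatin")))
  all_seg <- parse_chromhmm_bed(path)
  expect_identical(nrow(all_seg), 10L)
  expect_identical(all_seg$start[1], 1000L)
  expect_identical(all_seg$end[1], 2000L)
  expect_identical(all_seg$state[1], 1L)

  kept <- parse_chromhmm_bed(path, keep_states = c(1, 2, 12, 13))
  expect_identical(nrow(kept), 7L)  # hand count: rows 1,2,4,5,7,9,10
  expect_false(any(kept$state %in% c(5L, 15L)))

  bad <- write_bed_fixture(data.frame(chrom = "chr1", start = 0L, end = 10L,
                                      name = "Heterochromatin"))
  expect_error(parse_chromhmm_bed(bad), "state")
})

test_that("TSS extraction is strand-aware and per-transcript", {
  gtf <- write_gtf_fixture(data.frame(
    chrom = "chr1", start = c(100L, 100L, 900L), end = c(500L, 450L, 1200L),
    strand = c("+", "-", "+"),
    gene_id = c("gA", "gA", "gA"),
    transcript_id = c("tA1", "tA2", "tA3")))
  tss <- extract_tss(gtf)
  expect_identical(nrow(tss), 3L)
  expect_identical(unique(tss$gene_id), "gA")
  expect_identical(tss$position[tss$transcript_id == "tA1"], 100L)  # + strand
  expect_identical(tss$position[tss$transcript_id == "tA2"], 450L)  # - strand
  expect_identical(tss$position[tss$transcript_id == "tA3"], 900L)

  unstranded <- write_gtf_fixture(data.frame(
    chrom = "chr1", start = 1L, end = 10L, strand = ".",
    gene_id = "g", transcript_id = "t"))
  expect_error(extract_tss(unstranded), "strand")
})

test_that("promoter classification honours the window boundary exactly", {
  segments <- data.frame(chrom = "chr1", start = 4000L, end = 6000L,
                         state = 1L)
  tss_at <- function(p) data.frame(gene_id = "g", transcript_id = "t",
                                   chrom = "chr1", position = p,
                                   strand = "+")
  # containment: distance 0
  expect_true(classify_promoters(tss_at(5000L), segments)$active)
  # nearest 1-based segment base is 6000: position 8000 -> distance 2000
  # (inclusive boundary, active), 8001 -> 2001 (not active)
  expect_true(classify_promoters(tss_at(8000L), segments)$active)
  expect_false(classify_promoters(tss_at(8001L), segments)$active)
  # left flank: first 1-based base is 4001
  expect_true(classify_promoters(tss_at(2001L), segments)$active)
  expect_false(classify_promoters(tss_at(2000L), segments)$active)
})

test_that("a gene can carry both active and repressed labels", {
  segments <- data.frame(chrom = "chr1",
                         start = c(1000L, 50000L),
                         end = c(2000L, 52000L),
                         state = c(2L, 13L))
  tss <- data.frame(gene_id = "g", transcript_id = c("t1", "t2"),
                    chrom = "chr1", position = c(1500L, 51000L),
                    strand = "+")
  calls <- classify_promoters(tss, segments)
  expect_true(calls$active)
  expect_true(calls$repressed)
})

test_that("window 0 with full coverage marks every gene active", {
  segments <- data.frame(chrom = "chr1", start = 0L, end = 100000L,
                         state = 1L)
  tss <- data.frame(gene_id = paste0("g", 1:20), transcript_id = paste0("t", 1:20),
                    chrom = "chr1", position = seq(500L, 99000L, length.out = 20),
                    strand = "+")
  tss$position <- as.integer(tss$position)
  calls <- classify_promoters(tss, segments, window = 0)
  expect_true(all(calls$active))
})

test_that("classification matches the brute-force distance oracle", {
  set.seed(21)
  chroms <- c("chr1", "chr2")
  segments <- data.frame(
    chrom = sample(chroms, 400, replace = TRUE),
    start = as.integer(sample.int(500000L, 400)),
    state = sample(c(1L, 2L, 12L, 13L), 400, replace = TRUE))
  segments$end <- segments$start + as.integer(sample.int(3000L, 400))
  tss <- data.frame(
    gene_id = rep(sprintf("g%03d", 1:100), each = 2),
    transcript_id = sprintf("t%03d", 1:200),
    chrom = sample(c(chroms, "chr3"), 200, replace = TRUE),
    position = as.integer(sample.int(520000L, 200)),
    strand = sample(c("+", "-"), 200, replace = TRUE))

  calls <- suppressMessages(
    classify_promoters(tss, segments, window = 2000, repressed_window = 0))
  act_seg <- segments[segments$state %in% c(1L, 2L), ]
  rep_seg <- segments[segments$state %in% c(12L, 13L), ]
  expect_identical(calls$active, oracle_by_gene(tss,
    oracle_within_window(tss, act_seg, 2000)))
  expect_identical(calls$repressed, oracle_by_gene(tss,
    oracle_within_window(tss, rep_seg, 0)))

  # order invariance: shuffling segments and TSS records changes nothing
  perm_seg <- segments[sample.int(nrow(segments)), ]
  perm_tss <- tss[sample.int(nrow(tss)), ]
  calls2 <- suppressMessages(
    classify_promoters(perm_tss, perm_seg, window = 2000,
                       repressed_window = 0))
  calls2 <- calls2[match(calls$gene_id, calls2$gene_id), ]
  rownames(calls2) <- NULL
  attributes(calls2) <- attributes(calls)
  expect_identical(calls2, calls)
})

test_that("H3K4me3 proximity flags match the 1 kb window and the oracle", {
  tss <- data.frame(gene_id = c("g1", "g2"), transcript_id = c("t1", "t2"),
                    chrom = "chr1", position = c(10000L, 10000L),
                    strand = "+")
  near <- data.frame(chrom = "chr1", start = 9500L, end = 9700L)
  far <- data.frame(chrom = "chr1", start = 11100L, end = 11300L)
  expect_true(all(h3k4me3_overlap(tss, near)$h3k4me3))
  expect_false(any(h3k4me3_overlap(tss, far)$h3k4me3))

  set.seed(22)
  tss50 <- data.frame(
    gene_id = sprintf("g%02d", 1:50), transcript_id = sprintf("t%02d", 1:50),
    chrom = "chr1", position = as.integer(sample.int(200000L, 50)),
    strand = "+")
  peaks <- data.frame(chrom = "chr1",
                      start = as.integer(sample.int(200000L, 30)))
  peaks$end <- peaks$start + 400L
  flags <- h3k4me3_overlap(tss50, peaks, window = 1000)
  expect_identical(flags$h3k4me3,
                   oracle_by_gene(tss50,
                                  oracle_within_window(tss50, peaks, 1000)))
})
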