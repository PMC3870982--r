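make_calls <- function(ids, active, repressed = !active) {
  data.frame(gene_id = ids, active = active, repressed = repressed,
             stringsAsFactors = FALSE)
}

test_that("binning cuts rank-ordered genes into bins of bin_size", {
  x <- setNames(sort(rnorm(1000)), sprintf("g%04d", 1:1000))
  calls <- make_calls(names(x), active = rep(TRUE, 1000))
  curve <- bin_by_expression(x, calls, bin_size = 500)
  expect_identical(curve$count, c(500L, 500L))
  expect_true(all(diff(curve$mean_log2_fpkm) >= 0))
  expect_equal(curve$fraction_active, c(1, 1))
  expect_equal(curve$fraction_repressed, c(0, 0))

  x2 <- setNames(rnorm(1234), sprintf("g%04d", 1:1234))
  curve2 <- bin_by_expression(x2, make_calls(names(x2), rep(TRUE, 1234)),
                              bin_size = 500)
  expect_identical(curve2$count, c(500L, 500L, 234L))
})

test_that("genes without a promoter call stay in the denominator", {
  x <- setNames(1:10 / 10, paste0("g", 1:10))
  calls <- make_calls(paste0("g", 1:5), active = rep(TRUE, 5),
                      repressed = rep(FALSE, 5))
  curve <- bin_by_expression(x, calls, bin_size = 10)
  expect_identical(curve$count, 10L)
  expect_equal(curve$fraction_active, 0.5)  # 5 labelled of 10 binned
  expect_error(bin_by_expression(setNames(numeric(0), character(0)), calls),
               "no detected")
})

test_that("crossover interpolation matches hand-computed values", {
  curve2 <- data.frame(bin = 1:2, mean_log2_fpkm = c(-3, -1), count = 500L,
                       fraction_active = c(0.25, 0.75),
                       fraction_repressed = c(0.75, 0.25))
  res <- find_crossover(curve2)
  expect_equal(res$threshold_log2fpkm, -2)      # symmetric midpoint
  expect_identical(res$bracket, c(1L, 2L))

  curve4 <- data.frame(bin = 1:4, mean_log2_fpkm = c(-4, -2, 0, 2),
                       count = 500L,
                       fraction_active = c(0.1, 0.3, 0.6, 0.95),
                       fraction_repressed = c(0.8, 0.4, 0.3, 0.05))
  # d = {-0.7, -0.1, +0.3, +0.9}: interpolate between means 0 and -2
  res4 <- find_crossover(curve4)
  expect_equal(res4$threshold_log2fpkm, 0 + (-2 - 0) * (0.3 / (0.3 + 0.1)))
  expect_equal(res4$threshold_log2fpkm, -1.5)

  # zFPKM scale via a sample fit
  res_z <- find_crossover(curve4, fit = list(mu = 3.5, sigma = 2,
                                             sample_id = "s1"))
  expect_equal(res_z$threshold_zfpkm, (-1.5 - 3.5) / 2)
  expect_identical(res_z$sample_id, "s1")

  none <- data.frame(bin = 1:3, mean_log2_fpkm = c(-3, -1, 1), count = 500L,
                     fraction_active = c(0.6, 0.7, 0.9),
                     fraction_repressed = c(0.2, 0.1, 0.05))
  expect_error(find_crossover(none), "no active/repressed crossover")
})

test_that("crossover shifts with the expression axis and warns on recrossings", {
  curve <- data.frame(bin = 1:4, mean_log2_fpkm = c(-4, -2, 0, 2),
                      count = 500L,
                      fraction_active = c(0.1, 0.3, 0.6, 0.95),
                      fraction_repressed = c(0.8, 0.4, 0.3, 0.05))
  base <- find_crossover(curve)$threshold_log2fpkm
  shifted <- curve
  shifted$mean_log2_fpkm <- curve$mean_log2_fpkm + 5.5
  expect_equal(find_crossover(shifted)$threshold_log2fpkm, base + 5.5)

  noisy <- data.frame(bin = 1:4, mean_log2_fpkm = c(-6, -4, -2, 0),
                      count = 500L,
                      fraction_active = c(0.3, 0.5, 0.3, 0.9),
                      fraction_repressed = c(0.5, 0.4, 0.6, 0.0))
  # d = {-0.2, +0.1, -0.3, +0.9}: upward crossings at bins 3-4 and 1-2;
  # the highest-expression one wins
  expect_warning(res <- find_crossover(noisy), "multiple")
  expect_identical(res$bracket, c(3L, 4L))
})

test_that("interpolated threshold converges to the analytic intersection", {
  # active and repressed fractions follow two logistic curves crossing at
  # x = -2.2 exactly; finer bins must pin the interpolated crossover down
  # to less than one bin spacing
  midpoint <- -2.2
  fa <- function(x) plogis(1.5 * (x - midpoint))
  fr <- function(x) 1 - fa(x)
  err_for <- function(n_bins) {
    x <- seq(-10, 8, length.out = n_bins)
    curve <- data.frame(bin = seq_along(x), mean_log2_fpkm = x,
                        count = 500L, fraction_active = fa(x),
                        fraction_repressed = fr(x))
    abs(find_crossover(curve)$threshold_log2fpkm - midpoint)
  }
  spacing <- function(n_bins) 18 / (n_bins - 1)
  for (n_bins in c(10, 40, 160)) {
    expect_lt(err_for(n_bins), spacing(n_bins))
  }
  expect_lt(err_for(160), err_for(10))
})

test_that("threshold summaries use the population standard deviation", {
  log2_thresholds <- c(GM12878 = -2.18, `H1-eSC` = -1.20, HMEC = -2.37,
                       HSMM = -2.41, HUVEC = -1.85, HepG2 = -2.79,
                       K562 = -2.19, NHEK = -1.96, NHLF = -2.06)
  s <- summarize_thresholds(log2_thresholds, scale = "log2fpkm")
  expect_equal(round(s$log2fpkm$mean, 2), -2.11)
  expect_equal(round(s$log2fpkm$sd, 2), 0.42)
  expect_equal(s$log2fpkm$n, 9L)

  # single sample: sd 0, mean = the threshold
  one <- summarize_thresholds(c(only = -2.5), scale = "zfpkm")
  expect_equal(one$zfpkm$mean, -2.5)
  expect_equal(one$zfpkm$sd, 0)

  # n-1 form available but not the default
  s_n1 <- summarize_thresholds(log2_thresholds, scale = "log2fpkm",
                               sd_type = "sample")
  expect_gt(s_n1$log2fpkm$sd, s$log2fpkm$sd)
  expect_error(summarize_thresholds(c(a = 1), exclude = "a"), "excluded")
})
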