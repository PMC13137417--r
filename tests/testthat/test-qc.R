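test_that("Gaussian DIMAPD threshold matches the closed-form quantile", {
  # scores rescaled to exact sample mean 1.0 and SD 0.1
  set.seed(1)
  x <- rnorm(200)
  x <- (x - mean(x)) / sd(x) * 0.1 + 1.0
  fit <- fit_dimapd_threshold(x, p_cut = 0.1)
  expect_equal(fit$threshold, 1.0 + qnorm(0.9) * 0.1, tolerance = 1e-12)
  expect_equal(fit$threshold, 1.1282, tolerance = 1e-4)
  # p_cut = 0.5: threshold is the mean
  expect_equal(fit_dimapd_threshold(x, p_cut = 0.5)$threshold, 1.0,
               tolerance = 1e-12)
  # degenerate inputs
  expect_error(fit_dimapd_threshold(rep(1, 50)), "degenerate")
  expect_error(fit_dimapd_threshold(c(1, 2)), ">= 10")
})

test_that("noisy-cell filter applies both criteria and keeps an audit trail", {
  cells <- cell_table(paste0("c", 1:4),
                      dimapd = c(1.0, 1.5, 1.0, 1.5),
                      ploidy_confidence_low = c(FALSE, FALSE, TRUE, TRUE))
  fit <- structure(list(mu = 1, sigma = 0.1, p_cut = 0.1, threshold = 1.2),
                   class = "dimapd_fit")
  out <- filter_noisy_cells(cells, fit)
  # low ploidy confidence alone flags a cell even below the DIMAPD threshold
  expect_equal(out$status, c("unlabeled", "noisy", "noisy", "noisy"))
  expect_equal(nrow(out), 4L)  # flagged cells stay in the table
  # idempotent
  expect_identical(filter_noisy_cells(out, fit), out)
  # empty table passes through
  expect_equal(nrow(filter_noisy_cells(cell_table(character(0)), fit)), 0L)
})

test_that("flagged fraction on one Gaussian converges to the tail probability", {
  set.seed(42)
  fr <- replicate(5, {
    cells <- cell_table(paste0("c", 1:5000), dimapd = rnorm(5000, 1, 0.1))
    out <- filter_noisy_cells(cells, fit_dimapd_threshold(cells$dimapd))
    mean(out$status == "noisy")
  })
  expect_lt(abs(mean(fr) - 0.1), 0.015)
})

test_that("call filter uses strict quality and mappability boundaries", {
  # one cell, qualities 0..30: retained calls are exactly those >= 15
  g <- toy_genome(1, 31)
  cn <- matrix(2L, 1, 31, dimnames = list("c1", NULL))
  q <- matrix(0:30, 1, 31)
  m <- cn_matrix(cn, g, quality = q)
  f <- filter_calls(m)
  expect_identical(unname(which(is.na(f$cn[1, ]))), 1:15)  # qualities 0..14 removed
  expect_true(all(!is.na(f$cn[1, 16:31])))         # quality 15 kept (strict <)

  # bin with mappability 0.85 is dropped from the genome for all cells
  g2 <- bin_genome(rep("chr1", 3), c(0, 2e4, 4e4), c(2e4, 4e4, 6e4),
                   mappability = c(1, 0.85, 0.95))
  m2 <- cn_matrix(matrix(2L, 2, 3, dimnames = list(c("a", "b"), NULL)), g2,
                  quality = matrix(20L, 2, 3))
  f2 <- filter_calls(m2)
  expect_equal(nrow(f2$genome), 2L)
  expect_equal(f2$genome$start, c(0L, 40000L))
  # boundary: mappability exactly 0.90 is kept
  g3 <- bin_genome("chr1", 0, 2e4, mappability = 0.90)
  m3 <- cn_matrix(matrix(2L, 1, 1, dimnames = list("a", NULL)), g3,
                  quality = matrix(20L, 1, 1))
  expect_equal(ncol(filter_calls(m3)$cn), 1L)

  # idempotent; aggregated input rejected
  expect_identical(filter_calls(f)$cn, f$cn)
  agg <- aggregate_bins(m, factor = 31L)
  expect_error(filter_calls(agg), "raw")
})

test_that("bin aggregation averages runs of 500 bins and respects chromosomes", {
  g <- toy_genome(1, 500)
  m <- cn_matrix(matrix(2L, 1, 500, dimnames = list("c1", NULL)), g)
  a <- aggregate_bins(m, factor = 500L)
  expect_equal(ncol(a$cn), 1L)
  expect_equal(unname(a$cn[1, 1]), 2.0)
  expect_equal(a$resolution, "aggregated")
  expect_equal(attr(a$genome, "bin_width"), 500L * 20000L)  # 20 kb -> 10 Mb

  # mean of mixed values
  m2 <- cn_matrix(matrix(rep(c(2L, 3L), each = 250), 1, 500,
                         dimnames = list("c1", NULL)), g)
  expect_equal(unname(aggregate_bins(m2, 500L)$cn[1, 1]), 2.5)

  # missing calls are skipped, not imputed
  cn3 <- matrix(2L, 1, 500, dimnames = list("c1", NULL))
  cn3[1, 17] <- NA
  expect_equal(unname(aggregate_bins(cn_matrix(cn3, g), 500L)$cn[1, 1]), 2.0)
  # all-missing input yields a missing aggregated bin
  cn4 <- matrix(NA_integer_, 1, 500, dimnames = list("c1", NULL))
  cn4[1, 1] <- 2L  # keep one call so the matrix is valid, then drop it
  m4 <- cn_matrix(cn4, g)
  m4$cn[1, 1] <- NA
  expect_true(is.na(aggregate_bins(m4, 500L)$cn[1, 1]))

  # chromosome-end remainders form a final short bin; chromosomes never mix
  g5 <- toy_genome(2, 7)
  m5 <- cn_matrix(matrix(rep(c(2L, 4L), each = 7), 1, 14,
                         dimnames = list("c1", NULL)), g5)
  a5 <- aggregate_bins(m5, factor = 5L)
  expect_equal(a5$genome$chrom, c("chr1", "chr1", "chr2", "chr2"))
  expect_equal(unname(a5$cn[1, ]), c(2, 2, 4, 4))
})

test_that("aggregation commutes with cell subsetting and preserves mean ploidy", {
  spec <- clone_spec(list(A = list(parent = NULL, n_cells = 12L, events = list(
    cn_event("gain", "chr1", haplotype = "A"),
    cn_event("loss", "chr3", haplotype = "B")
  ))), flip_rate = 0.05, genome = toy_genome(3, 20), seed = 2)
  sim <- sample_cells(spec)
  sub_then_agg <- aggregate_bins(subset_cells(sim$cn, c("cell_0003", "cell_0010")),
                                 factor = 10L)
  agg_then_sub <- subset_cells(aggregate_bins(sim$cn, factor = 10L),
                               c("cell_0003", "cell_0010"))
  expect_equal(sub_then_agg$cn, agg_then_sub$cn)
  # with no missing calls and equal-sized groups, mean ploidy is unchanged
  expect_equal(unname(mean_ploidy(aggregate_bins(sim$cn, 10L))),
               unname(mean_ploidy(sim$cn)))
})
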