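test_that("allele CN estimation rounds BAF against total CN", {
  g <- toy_genome(1, 3)
  tot <- matrix(c(2L, 2L, 3L), 1, 3, dimnames = list("c1", NULL))
  baf <- matrix(c(0.5, 0.0, 0.33), 1, 3, dimnames = list("c1", NULL))
  x <- estimate_allele_cn(tot, baf, g)
  expect_equal(unname(x$a_cn[1, ]), c(1, 2, 2))
  expect_equal(unname(x$b_cn[1, ]), c(1, 0, 1))
  # missing BAF leaves allele CN undefined
  baf[1, 2] <- NA
  x2 <- estimate_allele_cn(tot, baf, g)
  expect_true(is.na(x2$a_cn[1, 2]) && is.na(x2$b_cn[1, 2]))
  # identity a + b = total wherever defined, for random inputs
  set.seed(1)
  tot_r <- matrix(sample(0:6, 300, replace = TRUE), 10, 30,
                  dimnames = list(paste0("c", 1:10), NULL))
  baf_r <- matrix(runif(300), 10, 30)
  xr <- estimate_allele_cn(tot_r, baf_r, toy_genome(1, 30))
  expect_equal(xr$a_cn + xr$b_cn, tot_r + 0, ignore_attr = TRUE)
})

test_that("LOH covers all three manifestations and excludes homozygous loss", {
  g <- toy_genome(1, 5)
  a <- matrix(c(1L, 2L, 3L, 1L, 0L), 1, 5, dimnames = list("c1", NULL))
  b <- matrix(c(0L, 0L, 0L, 1L, 0L), 1, 5, dimnames = list("c1", NULL))
  x <- allele_cn_matrix(a, b, g)
  loh <- call_loh(x, min_run = 1L)
  # hemizygous (1,0), copy-neutral (2,0), gain of remaining (3,0) are LOH;
  # balanced (1,1) and homozygous deletion (0,0) are not
  expect_equal(unname(loh$mask[1, ]), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  # monotone under allele-preserving gain: (a,0) -> (2a,0) stays LOH
  x2 <- allele_cn_matrix(2L * a, b, g)
  loh2 <- call_loh(x2, min_run = 1L)
  expect_true(all(loh2$mask[1, loh$mask[1, ] & a[1, ] > 0]))
})

test_that("LOH segments respect the minimum run and chromosome boundaries", {
  g <- toy_genome(2, 5)
  a <- matrix(1L, 2, 10, dimnames = list(c("c1", "c2"), NULL))
  b <- a
  b[1, 3:5] <- 0L   # 3-bin run at the end of chr1
  b[1, 6:7] <- 0L   # 2-bin run at the start of chr2: below min_run
  b[2, 3:5] <- 0L
  loh <- call_loh(allele_cn_matrix(a, b, g), min_run = 3L,
                  assignments = setNames(c(1L, 1L), c("c1", "c2")))
  expect_equal(nrow(loh$segments), 2L)  # per-cell chr1 runs only
  expect_true(all(loh$segments$chrom == "chr1"))
  expect_equal(loh$segments$n_bins, c(3L, 3L))
  # cluster consensus (both cells LOH on chr1 bins 3..5)
  expect_equal(nrow(loh$cluster_segments), 1L)
  expect_equal(loh$cluster_segments$start, 2L * 20000L)
})

test_that("WGD calls sit strictly above the half-genome threshold", {
  g <- toy_genome(1, 100)
  mk <- function(frac) {
    n2 <- round(frac * 100)
    a <- matrix(c(rep(2L, n2), rep(1L, 100 - n2)), 1, 100,
                dimnames = list("c1", NULL))
    b <- matrix(1L, 1, 100, dimnames = list("c1", NULL))
    allele_cn_matrix(a, b, g)
  }
  expect_false(call_wgd(mk(0))$is_wgd)     # (1,1) genome-wide: fraction 0
  w1 <- call_wgd(mk(1))
  expect_true(w1$is_wgd)                   # fraction 1
  expect_equal(w1$wgd_fraction, 1)
  w06 <- call_wgd(mk(0.6))
  expect_equal(w06$wgd_fraction, 0.6)
  expect_true(w06$is_wgd)
  expect_false(call_wgd(mk(0.5))$is_wgd)   # exactly 0.5 is not WGD
  # undefined when too little of the genome is assessed
  x <- mk(1)
  x$a_cn[1, 1:60] <- NA; x$b_cn[1, 1:60] <- NA
  expect_true(is.na(call_wgd(x)$is_wgd))
})

test_that("RDR normalizes depth against the diploid reference", {
  counts <- matrix(100, 2, 10, dimnames = list(c("c1", "c2"), NULL))
  ref <- rep(100, 10)
  expect_true(all(abs(compute_rdr(counts, ref) - 1) < 1e-12))
  counts[2, 4] <- 200  # double relative depth in one bin
  r <- compute_rdr(counts, ref)
  expect_equal(unname(r[2, 4] / r[2, 1]), 2)
  ref[7] <- 0
  expect_true(all(is.na(compute_rdr(counts, ref)[, 7])))
})

test_that("cluster BAF blocks recover allelic balance and LOH poles", {
  g <- toy_genome(1, 30)
  a <- matrix(rep(c(1L, 2L, 0L), each = 10), 4, 30, byrow = TRUE,
              dimnames = list(paste0("c", 1:4), NULL))
  b <- matrix(rep(c(1L, 0L, 2L), each = 10), 4, 30, byrow = TRUE,
              dimnames = list(paste0("c", 1:4), NULL))
  x <- allele_cn_matrix(a, b, g)
  baf <- sample_snp_counts(x, lambda = 60, snps_per_bin = 4, seed = 9)
  blocks <- cluster_baf_blocks(baf, setNames(rep(1L, 4), paste0("c", 1:4)),
                               block = 100000L)
  mid <- function(lo, hi) blocks$baf[blocks$start >= lo & blocks$end <= hi]
  expect_lt(max(abs(mid(0, 2e5) - 0.5)), 0.1)   # (1,1): balance
  expect_true(all(mid(2e5, 4e5) == 0))          # (2,0): BAF 0
  expect_true(all(mid(4e5, 6e5) == 1))          # (0,2): BAF 1
})

test_that("BAF block noise shrinks with the number of SNPs per block", {
  g <- toy_genome(1, 200)
  a <- matrix(1L, 1, 200, dimnames = list("c1", NULL))
  x <- allele_cn_matrix(a, a, g)
  sd_at <- function(spb) {
    baf <- sample_snp_counts(x, lambda = 30, snps_per_bin = spb, seed = 4)
    blocks <- cluster_baf_blocks(baf, setNames(1L, "c1"), block = 20000L)
    sd(blocks$baf)
  }
  s1 <- sd_at(1L); s16 <- sd_at(16L)
  # sampling theory: SD ~ 1/sqrt(SNPs per block), so 16x SNPs ~ 4x shrink
  expect_lt(s16, s1 / 2.5)
  expect_gt(s16, s1 / 6.5)
})

test_that("mirrored allelic imbalance is detected only for opposite major haplotypes", {
  g <- toy_genome(2, 10)
  mk <- function(a, b) list(a = a, b = b)
  a1 <- rep(1L, 20); b1 <- rep(1L, 20)
  a2 <- a1; b2 <- b1
  # chr2 bins 11..16: (2,1) in cluster 1 vs (1,2) in cluster 2
  a1[11:16] <- 2L
  b2[11:16] <- 2L
  res <- detect_mirrored_imbalance(mk(a1, b1), mk(a2, b2), g)
  expect_equal(nrow(res), 1L)
  expect_equal(res$chrom, "chr2")
  expect_equal(res$n_bins, 6L)
  expect_equal(c(res$a1, res$b1, res$a2, res$b2), c(2L, 1L, 1L, 2L))
  # same imbalance on the same haplotype: no call
  res2 <- detect_mirrored_imbalance(mk(a1, b1), mk(a1, b1), g)
  expect_equal(nrow(res2), 0L)
  # mirrored LOH (2,0) vs (0,2) is reported; shared LOH is not
  a3 <- rep(1L, 20); b3 <- rep(1L, 20); a4 <- a3; b4 <- b3
  a3[1:5] <- 2L; b3[1:5] <- 0L
  b4[1:5] <- 2L; a4[1:5] <- 0L
  res3 <- detect_mirrored_imbalance(mk(a3, b3), mk(a4, b4), g)
  expect_equal(nrow(res3), 1L)
  expect_equal(res3$n_bins, 5L)
  res4 <- detect_mirrored_imbalance(mk(a3, b3), mk(a3, b3), g)
  expect_equal(nrow(res4), 0L)
})

test_that("allele CN estimated from simulated SNP counts matches truth", {
  g <- toy_genome(2, 25)
  spec <- clone_spec(list(A = list(parent = NULL, n_cells = 3L, events = list(
    cn_event("gain", "chr1", haplotype = "A"),
    cn_event("cnloh", "chr2", haplotype = "B")
  ))), flip_rate = 0, genome = g, seed = 6)
  sim <- sample_cells(spec)
  baf <- sample_snp_counts(sim$allele, lambda = 100, snps_per_bin = 20,
                           seed = 6)
  # per-cell, per-bin BAF (block = bin width aligns blocks with bins)
  for (bc in barcodes(sim$cn)) {
    blocks <- cluster_baf_blocks(baf[baf$cell == bc, ],
                                 setNames(bc, bc), block = 20000L)
    key <- sprintf("%s:%d-%d", blocks$chrom, blocks$start, blocks$end)
    baf_vec <- setNames(blocks$baf, key)[bin_ids(g)]
    est <- estimate_allele_cn(sim$cn$cn[bc, , drop = FALSE],
                              matrix(baf_vec, 1, dimnames = list(bc, NULL)),
                              g)
    agree <- mean(est$a_cn[1, ] == sim$allele$a_cn[bc, ] &
                    est$b_cn[1, ] == sim$allele$b_cn[bc, ])
    expect_gte(agree, 0.99)
  }
})
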