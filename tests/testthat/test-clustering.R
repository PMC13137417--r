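test_that("three planted clones are recovered exactly without noise", {
  sim <- sample_cells(spec_3clones(eps = 0, seed = 1))
  r <- ml_cluster(aggregate_bins(sim$cn), seed = 1)
  expect_equal(r$selected_k, 3L)
  expect_equal(ari(r$assignments, sim$truth$clone), 1.0)
  # AIC and BIC come from the same WSS (identity over evaluated k)
  cr <- r$criteria[!is.na(r$criteria$wss), ]
  expect_equal(cr$bic - cr$aic, cr$k * (log(300) - 2))
})

test_that("identical cells collapse to a single cluster", {
  g <- toy_genome(2, 10)
  m <- cn_matrix(matrix(2L, 20, 20,
                        dimnames = list(paste0("c", 1:20), NULL)), g)
  r <- ml_cluster(aggregate_bins(m, 10L), seed = 1)
  expect_equal(r$selected_k, 1L)
  expect_equal(r$criteria$wss[1], 0)
})

test_that("clone recovery is robust to flip noise and to the seed", {
  aris <- sapply(1:3, function(s) {
    sim <- sample_cells(spec_3clones(eps = 0.01, seed = s))
    r <- ml_cluster(aggregate_bins(sim$cn), seed = 1)
    ari(r$assignments, sim$truth$clone)
  })
  expect_true(all(aris >= 0.95))
  # determinism under a fixed seed; high agreement between seeds
  sim <- sample_cells(spec_3clones(eps = 0.01, seed = 4))
  agg <- aggregate_bins(sim$cn)
  r1 <- ml_cluster(agg, seed = 7)
  r2 <- ml_cluster(agg, seed = 7)
  expect_identical(r1$assignments, r2$assignments)
  r3 <- ml_cluster(agg, seed = 8)
  expect_gte(ari(r1$assignments, r3$assignments), 0.95)
})

test_that("WSS is monotone non-increasing in k", {
  sim <- sample_cells(default_clone_spec(seed = 5))
  r <- ml_cluster(aggregate_bins(sim$cn), seed = 1)
  w <- r$criteria$wss
  w <- w[!is.na(w)]
  expect_true(all(diff(w) <= 1e-8))
})

test_that("BIC never selects more clusters than AIC on multiclonal data", {
  hits <- sapply(1:10, function(s) {
    sim <- sample_cells(default_clone_spec(seed = s))
    r <- ml_cluster(aggregate_bins(sim$cn), seed = 1)
    r$selected_k_bic <= r$selected_k
  })
  expect_gte(mean(hits), 0.8)
})

test_that("subclustering splits planted sub-lineages and formats labels", {
  # one cluster with two sub-lineages differing by a single chromosome
  clones <- list(
    A = list(parent = NULL, n_cells = 40L, events = list(
      cn_event("gain", "chr1", haplotype = "A"),
      cn_event("gain", "chr2", haplotype = "A"),
      cn_event("gain", "chr3", haplotype = "A"),
      cn_event("gain", "chr4", haplotype = "A"),
      cn_event("gain", "chr5", haplotype = "A")
    )),
    A2 = list(parent = "A", n_cells = 40L, events = list(
      cn_event("gain", "chr8", haplotype = "A")
    ))
  )
  spec <- clone_spec(clones, n_diploid = 40L, flip_rate = 0, seed = 2)
  sim <- sample_cells(spec)
  agg <- aggregate_bins(sim$cn)

  # force one parent cluster over all tumor cells, subclustering must split
  # the two sub-lineages and label them "1.1"/"1.2"
  tum <- sim$truth$barcode[sim$truth$class == "tumor"]
  parent <- structure(
    list(assignments = setNames(rep(1L, length(tum)), tum)),
    class = "clustering_result")
  sub <- subcluster(parent, subset_cells(agg, tum), seed = 1)
  expect_true(all(grepl("^[0-9]+\\.[0-9]+$", sub$labels)))
  expect_equal(length(unique(sub$labels)), 2L)
  expect_equal(ari(sub$labels[tum],
                   sim$truth$clone[match(tum, sim$truth$barcode)]), 1.0)

  # homogeneous cluster stays a single subcluster
  dip <- sim$truth$barcode[sim$truth$class == "diploid"]
  parent_d <- structure(
    list(assignments = setNames(rep(1L, length(dip)), dip)),
    class = "clustering_result")
  sub_d <- subcluster(parent_d, subset_cells(agg, dip), seed = 1)
  expect_equal(unique(sub_d$labels), "1.1")
})

test_that("discriminant analysis separates groups along their true axis", {
  g <- toy_genome(4, 5)
  set.seed(9)
  base <- matrix(rnorm(40 * 20, 2, 0.05), 40, 20,
                 dimnames = list(paste0("c", 1:40), NULL))
  base[21:40, 6:10] <- base[21:40, 6:10] + 1  # group 2 gains chr2
  m <- cn_matrix(round(pmax(base, 0)), g, resolution = "raw")
  m$cn <- pmax(base, 0)  # keep fractional values
  m$resolution <- "aggregated"
  labels <- setNames(rep(c("g1", "g2"), each = 20), rownames(base))
  d <- discriminant_analysis(m, labels)
  expect_equal(ncol(d$coords), 1L)  # two groups -> one discriminant function
  # DF1 loadings peak in chr2 bins
  peak <- which.max(abs(d$loadings[, 1]))
  expect_true(peak %in% 6:10)
  # group separation on DF1
  expect_gt(abs(mean(d$coords[1:20, 1]) - mean(d$coords[21:40, 1])),
            3 * (sd(d$coords[1:20, 1]) + sd(d$coords[21:40, 1])))
})

test_that("identical groups give near-zero discriminant eigenvalues", {
  g <- toy_genome(2, 5)
  set.seed(3)
  base <- matrix(rnorm(10 * 10, 2, 0.1), 10, 10)
  x <- base[rep(1:10, 3), ]  # three groups with identical member profiles
  rownames(x) <- paste0("c", 1:30)
  m <- structure(list(cn = x, quality = NULL, genome = g,
                      resolution = "aggregated"), class = "cn_matrix")
  labels <- setNames(rep(c("a", "b", "c"), each = 10), rownames(x))
  d <- suppressWarnings(discriminant_analysis(m, labels))
  expect_true(all(abs(d$eigenvalues) < 1e-6))
})

test_that("diploid cluster identification picks the CN-2 cluster or errors", {
  sim <- sample_cells(default_clone_spec(seed = 3))
  agg <- aggregate_bins(sim$cn)
  act <- sim$truth$barcode[sim$truth$class %in% c("tumor", "diploid")]
  r <- ml_cluster(subset_cells(agg, act), seed = 1)
  dip <- identify_diploid_cluster(r, agg)
  dip_bc <- names(r$assignments)[r$assignments == dip]
  truth_dip <- sim$truth$barcode[sim$truth$class == "diploid"]
  expect_true(length(intersect(dip_bc, truth_dip)) / length(truth_dip) > 0.95)

  # tetraploid-only data has no diploid cluster
  g <- toy_genome(2, 10)
  m4 <- cn_matrix(matrix(4L, 10, 20, dimnames = list(paste0("c", 1:10), NULL)),
                  g)
  a4 <- aggregate_bins(m4, 10L)
  r4 <- ml_cluster(a4, seed = 1)
  expect_error(identify_diploid_cluster(r4, a4), "no diploid cluster")
})

test_that("pseudodiploid flagging needs three deviating bins and scores overlap", {
  g <- toy_genome(6, 5)
  prof <- matrix(2, 4, 30, dimnames = list(paste0("c", 1:4), NULL))
  prof[2, c(1, 6)] <- 3        # two deviating aggregated bins: not flagged
  prof[3, c(1, 6, 11)] <- 3    # three: flagged
  prof[4, c(16, 21, 26)] <- 3  # three, but disjoint from tumor gains
  m <- structure(list(cn = prof, quality = NULL, genome = aggregate_bins(
    cn_matrix(matrix(2L, 1, 30, dimnames = list("x", NULL)), g), 5L)$genome,
    resolution = "aggregated"), class = "cn_matrix")
  res <- detect_pseudodiploid(m, paste0("c", 1:4),
                              tumor_gain_bins = c(1, 6, 11))
  expect_equal(res$pseudodiploid, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(res$overlap[3], 1.0)
  expect_equal(res$overlap[4], 0.0)  # disjoint gain sets -> Jaccard 0
  expect_equal(res$n_dev, c(0L, 2L, 3L, 3L))
})
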