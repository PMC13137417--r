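#' Pairwise CN distance matrix
#'
#' Manhattan (for phylogenies) or Euclidean (for intracluster diversity)
#' distance between CN profiles. For each pair, only bins defined in both
#' profiles contribute, and by default the distance is normalized per
#' shared bin (mean absolute difference, or root-mean-square difference),
#' so differing missing-call loads do not bias pairs; `normalize = FALSE`
#' gives the raw sums for strict replication.
#'
#' @param profiles numeric matrix, rows = cells/clusters (labeled), columns
#'   = bins; `NA` allowed.
#' @param metric `"manhattan"` or `"euclidean"`.
#' @param normalize divide by the number of shared bins.
#' @return a symmetric matrix of class `dist_cn` with a `metric` attribute.
#' @export
cn_distance_matrix <- function(profiles, metric = c("manhattan", "euclidean"),
                               normalize = TRUE) {
  metric <- match.arg(metric)
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n < 2L) stop("cn_distance_matrix: need >= 2 profiles")
  if (is.null(rownames(profiles))) {
    rownames(profiles) <- paste0("p", seq_len(n))
  }
  d <- matrix(0, n, n, dimnames = list(rownames(profiles), rownames(profiles)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(profiles[i, ]) & !is.na(profiles[j, ])
      if (!any(ok)) {
        stop(sprintf("cn_distance_matrix: no shared bins for %s / %s",
                     rownames(profiles)[i], rownames(profiles)[j]))
      }
      diff <- profiles[i, ok] - profiles[j, ok]
      v <- if (metric == "manhattan") {
        s <- sum(abs(diff)); if (normalize) s / sum(ok) else s
      } else {
        if (normalize) sqrt(mean(diff^2)) else sqrt(sum(diff^2))
      }
      d[i, j] <- d[j, i] <- v
    }
  }
  attr(d, "metric") <- metric
  class(d) <- c("dist_cn", "matrix")
  d
}

#' Balanced minimum evolution tree from a distance matrix
#'
#' Builds the CN phylogeny with the balanced minimum evolution (BME)
#' criterion — the fastme-style heuristic of a greedy start refined by
#' topology rearrangements (NNI and SPR) on the balanced tree-length
#' objective — and optionally roots it at a designated diploid outgroup.
#' Negative branch lengths, a bookkeeping artifact of distance-based
#' reconstruction, are clamped to 0 after the topology is fixed.
#'
#' @param d symmetric distance matrix with labels (e.g. from
#'   [cn_distance_matrix()]); >= 3 taxa, nonnegative entries.
#' @param outgroup optional leaf label to root at (see
#'   [root_at_outgroup()]).
#' @return an [ape::phylo] tree.
#' @export
bme_tree <- function(d, outgroup = NULL) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("bme_tree: need >= 3 taxa")
  if (any(d < 0)) stop("bme_tree: negative distances")
  tree <- ape::fastme.bal(stats::as.dist(d), nni = TRUE, spr = TRUE)
  tree$edge.length[tree$edge.length < 0] <- 0
  if (!is.null(outgroup)) tree <- root_at_outgroup(tree, outgroup)
  tree
}

#' Root a tree on its outgroup's pendant edge
#'
#' Inserts the root at the midpoint of the outgroup leaf's pendant edge, so
#' the outgroup (a diploid cell or cluster) is sister to all tumor clades.
#'
#' @param tree an unrooted `phylo`.
#' @param outgroup a leaf label present in the tree.
#' @return a rooted `phylo`.
#' @export
root_at_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label) {
    stop("root_at_outgroup: unknown label ", outgroup)
  }
  r <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  root_node <- ape::Ntip(r) + 1L
  ch <- which(r$edge[, 1L] == root_node)
  if (length(ch) == 2L) {
    tot <- sum(r$edge.length[ch])
    r$edge.length[ch] <- tot / 2
  }
  r
}

#' Balanced (Pauplin) tree length of a topology under a distance matrix
#'
#' The BME objective: `sum over pairs (i<j) of d_ij * 2^(1 - p_ij)` where
#' `p_ij` is the number of edges on the tree path between leaves i and j.
#' Depends only on the topology, which makes it the natural score for
#' comparing candidate topologies (it is also what [bme_tree()] minimizes).
#'
#' @param d labeled symmetric distance matrix.
#' @param tree a `phylo` over the same labels (rooted trees are unrooted
#'   first).
#' @return the balanced tree length (numeric scalar).
#' @export
balanced_tree_length <- function(d, tree) {
  d <- as.matrix(d)
  t2 <- ape::unroot(tree)
  t2$edge.length <- rep(1, nrow(t2$edge))
  p <- stats::cophenetic(t2)  # topological path lengths
  lab <- t2$tip.label
  p <- p[lab, lab]
  dd <- d[lab, lab]
  sum(dd[upper.tri(dd)] * 2^(1 - p[upper.tri(p)]))
}

#' All unique pairwise distances within each cluster
#'
#' For each cluster of n cells, the n(n-1)/2 pairwise Euclidean distances
#' between its cells' CN profiles — the intracluster diversity statistic.
#' Singleton clusters yield an empty vector.
#'
#' @param profiles numeric matrix, cells x bins.
#' @param assignments named cluster labels for the rows.
#' @param normalize per-shared-bin normalization (see
#'   [cn_distance_matrix()]).
#' @return named list of numeric vectors, one per cluster.
#' @export
intracluster_distances <- function(profiles, assignments, normalize = TRUE) {
  assignments <- assignments[rownames(profiles)]
  out <- list()
  for (cl in sort(unique(assignments))) {
    bcs <- names(assignments)[assignments == cl]
    if (length(bcs) < 2L) {
      out[[as.character(cl)]] <- numeric(0)
      next
    }
    d <- cn_distance_matrix(profiles[bcs, , drop = FALSE],
                            metric = "euclidean", normalize = normalize)
    out[[as.character(cl)]] <- d[upper.tri(d)]
  }
  out
}

#' Regression of per-bin CN standard deviation on mean within a cluster
#'
#' For each bin, the mean and SD of CN across the cluster's cells; then
#' ordinary least squares of SD on mean. A positive slope indicates that
#' intracluster variability concentrates in gained regions.
#'
#' @param profiles numeric matrix (cells x bins) of one cluster's cells.
#' @return list: `slope`, `intercept`, `table` (per-bin mean/sd), `fit`
#'   (the `lm` object).
#' @export
mean_sd_regression <- function(profiles) {
  if (nrow(profiles) < 2L) stop("mean_sd_regression: need >= 2 cells")
  if (ncol(profiles) < 3L) stop("mean_sd_regression: need >= 3 bins")
  mu <- colMeans(profiles, na.rm = TRUE)
  sdv <- apply(profiles, 2L, stats::sd, na.rm = TRUE)
  if (stats::sd(mu) == 0) stop("mean_sd_regression: zero variance in bin means")
  fit <- stats::lm(sdv ~ mu)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       table = data.frame(mean = mu, sd = sdv),
       fit = fit)
}
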