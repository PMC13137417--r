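#' Fit the Gaussian DIMAPD threshold
#'
#' DIMAPD (depth-independent median absolute deviation of pairwise
#' differences) measures a cell's bin-to-bin CN noisiness; actively
#' replicating (S-phase) and low-quality cells inflate it. A Gaussian is fit
#' to the per-cell scores by sample mean and SD, and the threshold is the
#' upper-tail quantile at probability `p_cut` (default 0.1):
#' `threshold = mu + qnorm(1 - p_cut) * sigma`.
#'
#' By default the fit uses all scores; `trim` drops the given upper fraction
#' before fitting for robustness to extreme outliers.
#'
#' @param scores numeric vector of per-cell DIMAPD scores (>= 10 finite).
#' @param p_cut upper-tail probability defining the cutoff.
#' @param trim upper fraction of scores removed before fitting (0 = none).
#' @return list of class `dimapd_fit` with `mu`, `sigma`, `p_cut`,
#'   `threshold`.
#' @export
fit_dimapd_threshold <- function(scores, p_cut = 0.1, trim = 0) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 10L) stop("fit_dimapd_threshold: need >= 10 finite scores")
  if (trim > 0) {
    scores <- sort(scores)[seq_len(floor(length(scores) * (1 - trim)))]
  }
  mu <- mean(scores)
  sigma <- stats::sd(scores)
  if (!is.finite(sigma) || sigma <= 0) {
    stop("fit_dimapd_threshold: degenerate fit (zero variance)")
  }
  structure(list(mu = mu, sigma = sigma, p_cut = p_cut,
                 threshold = mu + stats::qnorm(1 - p_cut) * sigma),
            class = "dimapd_fit")
}

#' @export
print.dimapd_fit <- function(x, ...) {
  cat(sprintf("dimapd_fit: mu=%.4f sigma=%.4f p_cut=%.3f threshold=%.4f\n",
              x$mu, x$sigma, x$p_cut, x$threshold))
  invisible(x)
}

#' Flag noisy cells
#'
#' A cell is noisy if either (i) its ploidy confidence is low, or (ii) its
#' DIMAPD score exceeds the Gaussian-fit threshold. Flagged cells stay in
#' the table with `status = "noisy"` (audit trail); they are excluded from
#' downstream stages via [active_barcodes()].
#'
#' @param cells a [cell_table()] with `dimapd` and `ploidy_confidence_low`.
#' @param fit a `dimapd_fit` from [fit_dimapd_threshold()].
#' @return the updated `cell_table`.
#' @export
filter_noisy_cells <- function(cells, fit) {
  if (nrow(cells) == 0L) return(cells)
  noisy <- cells$ploidy_confidence_low | (cells$dimapd > fit$threshold)
  noisy[is.na(noisy)] <- FALSE
  set_status(cells, noisy, "noisy")
}

#' Filter CN calls by quality and bins by mappability
#'
#' Calls with quality score below `q_min` (strict `<`, default 15) are set
#' missing for that cell only; bins with mappability below `map_min`
#' (strict `<`, default 0.90) are dropped from the genome for all cells.
#' Raw-resolution matrices only.
#'
#' @param m a raw [cn_matrix()] with a quality matrix.
#' @param q_min minimum retained call quality.
#' @param map_min minimum retained bin mappability.
#' @return a filtered `cn_matrix`.
#' @export
filter_calls <- function(m, q_min = 15L, map_min = 0.90) {
  if (m$resolution != "raw") {
    stop("filter_calls: expects a raw-resolution matrix")
  }
  cn <- m$cn
  q <- m$quality
  if (!is.null(q)) cn[!is.na(q) & q < q_min] <- NA
  keep <- m$genome$mappability >= map_min
  g <- m$genome[keep, , drop = FALSE]
  attr(g, "bin_width") <- attr(m$genome, "bin_width")
  class(g) <- class(m$genome)
  rownames(g) <- NULL
  cn_matrix(cn[, keep, drop = FALSE], g,
            quality = if (!is.null(q)) q[, keep, drop = FALSE],
            resolution = "raw")
}

#' Aggregate raw 20 kb CN calls into mean-ploidy bins
#'
#' Runs of `factor` consecutive bins (default 500, i.e. 20 kb -> 10 Mb)
#' within one chromosome collapse to a single bin whose value is the mean of
#' the non-missing calls; an aggregated bin is missing only when every input
#' call is. Chromosome-end remainders form a final short bin — aggregated
#' bins never straddle a chromosome boundary.
#'
#' @param m a raw [cn_matrix()].
#' @param factor number of consecutive bins per aggregated bin (>= 1).
#' @return an aggregated `cn_matrix` (fractional mean-ploidy values, no
#'   quality matrix).
#' @export
aggregate_bins <- function(m, factor = 500L) {
  stopifnot(factor >= 1L)
  g <- m$genome
  chrom_rle <- rle(g$chrom)
  group <- integer(nrow(g))
  gstart <- integer(0); gend <- integer(0); gchrom <- character(0)
  off <- 0L; gid <- 0L
  for (ci in seq_along(chrom_rle$values)) {
    len <- chrom_rle$lengths[ci]
    idx <- off + seq_len(len)
    grp_local <- (seq_len(len) - 1L) %/% factor
    group[idx] <- gid + grp_local + 1L
    for (gg in unique(grp_local)) {
      sel <- idx[grp_local == gg]
      gchrom <- c(gchrom, chrom_rle$values[ci])
      gstart <- c(gstart, g$start[sel[1L]])
      gend <- c(gend, g$end[sel[length(sel)]])
    }
    gid <- gid + max(grp_local) + 1L
    off <- off + len
  }
  n_grp <- gid
  # group means skipping missing calls
  cnt <- t(rowsum(t(!is.na(m$cn)) * 1, group))
  sums <- t(rowsum(t(ifelse(is.na(m$cn), 0, m$cn)), group))
  agg <- sums / cnt
  agg[cnt == 0] <- NA
  mapp <- as.vector(rowsum(g$mappability, group) / rowsum(rep(1, nrow(g)), group))
  ga <- bin_genome(gchrom, gstart, gend, mappability = mapp,
                   bin_width = attr(g, "bin_width") * factor)
  rownames(agg) <- rownames(m$cn)
  cn_matrix(agg, ga, resolution = "aggregated")
}
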