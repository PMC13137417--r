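# maximal TRUE-runs of a per-bin mask, never crossing a chromosome boundary
mask_runs <- function(mask, genome, min_run = 1L) {
  mask[is.na(mask)] <- FALSE
  chrom_id <- match(genome$chrom, unique(genome$chrom))
  # encode chromosome in the run value so runs stop at boundaries
  r <- rle(ifelse(mask, chrom_id, 0L))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values > 0L & r$lengths >= min_run
  data.frame(
    chrom = genome$chrom[starts[keep]],
    start = genome$start[starts[keep]],
    end = genome$end[ends[keep]],
    n_bins = r$lengths[keep],
    stringsAsFactors = FALSE
  )
}

#' Read-depth ratio per cell and bin
#'
#' RDR normalizes a cell's per-bin read counts against a diploid reference:
#' `RDR = (cell count / cell total) / (reference count / reference total)`,
#' so RDR is proportional to total CN / 2. Bins with zero reference counts
#' are returned missing.
#'
#' @param cell_counts numeric matrix, cells x bins, of read counts.
#' @param ref_counts numeric vector of diploid-reference counts per bin.
#' @return numeric matrix of RDR values (same dimnames as `cell_counts`).
#' @export
compute_rdr <- function(cell_counts, ref_counts) {
  cell_counts <- as.matrix(cell_counts)
  stopifnot(ncol(cell_counts) == length(ref_counts))
  ref_frac <- ref_counts / sum(ref_counts)
  rdr <- sweep(cell_counts / rowSums(cell_counts), 2L, ref_frac, "/")
  rdr[, ref_counts <= 0] <- NA_real_
  rdr
}

#' Estimate allele-specific CN from total CN and BAF
#'
#' The per-bin rounding estimator: `b_cn = round(baf * total_cn)`,
#' `a_cn = total_cn - b_cn`. Bins with missing BAF get undefined allele CN.
#' The identity `a_cn + b_cn = total_cn` holds wherever defined.
#'
#' @param total_cn integer matrix (cells x bins) of total CN.
#' @param baf matrix of B-allele frequencies in \[0,1\] (same shape), `NA`
#'   where BAF is unobserved.
#' @param genome the `bin_genome` of the columns.
#' @return an [allele_cn_matrix()].
#' @export
estimate_allele_cn <- function(total_cn, baf, genome) {
  total_cn <- as.matrix(total_cn); baf <- as.matrix(baf)
  stopifnot(all(dim(total_cn) == dim(baf)))
  b <- floor(baf * total_cn + 0.5)
  a <- total_cn - b
  und <- is.na(baf) | is.na(total_cn)
  a[und] <- NA; b[und] <- NA
  dimnames(a) <- dimnames(b) <- dimnames(total_cn)
  allele_cn_matrix(a, b, genome)
}

#' Call loss of heterozygosity from allele-specific CN
#'
#' LOH is any region lacking representation of one allele: a bin is LOH iff
#' `min(a, b) = 0` and `a + b > 0`. This covers all three manifestations —
#' hemizygous loss (1,0), copy-neutral LOH (2,0), and LOH with gain of the
#' remaining allele (3,0)+ — while excluding homozygous deletion (0,0).
#' Per-cell segments are maximal runs of at least `min_run` bins; with
#' cluster assignments, a cluster-consensus mask (bins LOH in at least
#' `consensus` of the cluster's informative cells) is segmented the same
#' way.
#'
#' @param allele an [allele_cn_matrix()].
#' @param min_run minimum bins per reported segment.
#' @param assignments optional named cluster labels for consensus calls.
#' @param consensus fraction of informative cells required for a consensus
#'   LOH bin.
#' @return list: `mask` (cells x bins logical), `segments` (per-cell
#'   data.frame), and with assignments `cluster_mask` / `cluster_segments`.
#' @export
call_loh <- function(allele, min_run = 3L, assignments = NULL,
                     consensus = 0.8) {
  a <- allele$a_cn; b <- allele$b_cn
  mask <- (pmin(a, b) == 0) & (a + b > 0)
  segs <- lapply(rownames(mask), function(bc) {
    s <- mask_runs(mask[bc, ], allele$genome, min_run)
    if (nrow(s)) cbind(cell = bc, s, stringsAsFactors = FALSE) else NULL
  })
  segs <- do.call(rbind, segs)
  if (is.null(segs)) {
    segs <- data.frame(cell = character(), chrom = character(),
                       start = integer(), end = integer(), n_bins = integer())
  }
  rownames(segs) <- NULL
  out <- list(mask = mask, segments = segs)
  if (!is.null(assignments)) {
    assignments <- assignments[rownames(mask)]
    cl_levels <- sort(unique(assignments))
    cmask <- t(vapply(cl_levels, function(cl) {
      sub <- mask[names(assignments)[assignments == cl], , drop = FALSE]
      frac <- colMeans(sub, na.rm = TRUE)
      !is.na(frac) & frac >= consensus
    }, logical(ncol(mask))))
    rownames(cmask) <- as.character(cl_levels)
    csegs <- lapply(rownames(cmask), function(cl) {
      s <- mask_runs(cmask[cl, ], allele$genome, min_run)
      if (nrow(s)) cbind(cluster = cl, s, stringsAsFactors = FALSE) else NULL
    })
    csegs <- do.call(rbind, csegs)
    if (!is.null(csegs)) rownames(csegs) <- NULL
    out$cluster_mask <- cmask
    out$cluster_segments <- csegs
  }
  out
}

#' Call whole-genome doubling per cell
#'
#' Computes, per cell, the fraction of the assessed genome (length-weighted
#' over bins with defined allele CN) whose major allele CN — the larger of
#' the two haplotype copy numbers — is at least 2. A fraction strictly
#' greater than 0.5 calls WGD. Cells with allele CN defined on less than
#' `min_defined` of the genome get an undefined call.
#'
#' @param allele an [allele_cn_matrix()].
#' @param min_defined minimum assessed genome fraction for a valid call.
#' @return data.frame: barcode, `wgd_fraction`, `is_wgd`.
#' @export
call_wgd <- function(allele, min_defined = 0.5) {
  w <- bin_lengths(allele$genome)
  mcn <- pmax(allele$a_cn, allele$b_cn)
  res <- lapply(rownames(mcn), function(bc) {
    v <- mcn[bc, ]
    ok <- !is.na(v)
    assessed <- sum(w[ok])
    if (assessed < min_defined * sum(w)) {
      return(data.frame(barcode = bc, wgd_fraction = NA_real_, is_wgd = NA))
    }
    frac <- sum(w[ok][v[ok] >= 2]) / assessed
    data.frame(barcode = bc, wgd_fraction = frac, is_wgd = frac > 0.5,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Cluster-level BAF smoothed into fixed blocks
#'
#' Pools SNP-level allele counts over the cells of each cluster and bins
#' them into `block` bp blocks (default 100 kb): per block, BAF = sum of
#' B-allele reads / sum of total reads. Blocks with no covered SNP are
#' omitted. BAF near 0.5 reflects allelic balance; values approaching 0 or
#' 1 reflect LOH.
#'
#' @param baf a `baf_track` of per-SNP counts (`cell` column holds cell
#'   barcodes).
#' @param assignments named cluster labels per barcode.
#' @param block block width in bp.
#' @return data.frame: cluster, chrom, start, end, baf, n_snps.
#' @export
cluster_baf_blocks <- function(baf, assignments, block = 100000L) {
  cl <- assignments[baf$cell]
  keep <- !is.na(cl)
  d <- baf[keep, , drop = FALSE]
  cl <- cl[keep]
  blk <- (d$pos %/% block) * block
  key <- paste(cl, d$chrom, blk, sep = "\r")
  bsum <- rowsum(d$b_count, key)
  tsum <- rowsum(d$total, key)
  nsnp <- rowsum(rep(1L, nrow(d)), key)
  parts <- do.call(rbind, strsplit(rownames(bsum), "\r", fixed = TRUE))
  out <- data.frame(
    cluster = parts[, 1L], chrom = parts[, 2L],
    start = as.integer(parts[, 3L]),
    end = as.integer(parts[, 3L]) + as.integer(block),
    baf = as.vector(bsum / tsum), n_snps = as.vector(nsnp),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$cluster, match(out$chrom, unique(baf$chrom)), out$start), ]
  rownames(out) <- NULL
  out
}

#' Consensus allele-specific profile of a set of cells
#' @param allele an [allele_cn_matrix()].
#' @param cells barcodes to summarize.
#' @return list with integer vectors `a` and `b` (per-bin medians).
#' @export
allele_consensus <- function(allele, cells) {
  med <- function(m) {
    v <- apply(m[cells, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
    as.integer(floor(v + 0.5))
  }
  list(a = med(allele$a_cn), b = med(allele$b_cn))
}

#' Detect mirrored allelic imbalance between two clusters
#'
#' Reports maximal runs (at least `min_run` bins) where the two clusters'
#' consensus total CN is equal, both are allelically imbalanced (a != b),
#' and the major haplotype differs — e.g. (2,1) against (1,2). Such regions
#' are the signature of convergent, independently acquired gains. Regions
#' of shared LOH or shared imbalance on the same haplotype are not
#' reported.
#'
#' @param cons1,cons2 consensus profiles (`list(a =, b =)`) of the two
#'   clusters, as from [allele_consensus()].
#' @param genome the shared `bin_genome`.
#' @param min_run minimum bins per reported region.
#' @return data.frame: chrom, start, end, n_bins, a1, b1, a2, b2, total
#'   (consensus values at the region's first bin).
#' @export
detect_mirrored_imbalance <- function(cons1, cons2, genome, min_run = 3L) {
  a1 <- cons1$a; b1 <- cons1$b; a2 <- cons2$a; b2 <- cons2$b
  mask <- (a1 + b1 == a2 + b2) & (a1 != b1) & (a2 != b2) &
    ((a1 > b1) != (a2 > b2))
  regs <- mask_runs(mask, genome, min_run)
  if (!nrow(regs)) {
    return(cbind(regs, data.frame(a1 = integer(), b1 = integer(),
                                  a2 = integer(), b2 = integer(),
                                  total = integer())))
  }
  first_bin <- vapply(seq_len(nrow(regs)), function(i) {
    which(genome$chrom == regs$chrom[i] & genome$start == regs$start[i])[1L]
  }, 0L)
  cbind(regs, data.frame(
    a1 = a1[first_bin], b1 = b1[first_bin],
    a2 = a2[first_bin], b2 = b2[first_bin],
    total = a1[first_bin] + b1[first_bin]
  ))
}
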