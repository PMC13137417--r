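#' Baseline (pre-WGD) consensus CN profiles per tumor cluster
#'
#' The per-bin median over a cluster's cells, rounded to integer copies.
#' Baselines should be taken from tumor clusters representing a pre-WGD
#' profile when one exists; post-WGD clusters would double every expected
#' doublet profile.
#'
#' @param m aggregated [cn_matrix()].
#' @param assignments named cluster vector (from [ml_cluster()]).
#' @param clusters cluster ids to build baselines for.
#' @return named list of integer per-bin profiles (names = cluster ids).
#' @export
baseline_profiles <- function(m, assignments, clusters) {
  out <- lapply(clusters, function(cl) {
    bcs <- names(assignments)[assignments == cl]
    as.integer(floor(consensus_profile(m, bcs) + 0.5))
  })
  names(out) <- as.character(clusters)
  out
}

#' Synthesize expected doublet CN profiles from baselines
#'
#' For each baseline clone profile b, the expected diploid-tumor doublet is
#' `b + 2` per bin (a diploid genome co-encapsulated with the tumor cell);
#' for each unordered pair of baselines, the expected tumor-tumor doublet
#' is their per-bin sum.
#'
#' @param baselines named list of per-bin integer profiles.
#' @return named list of doublet profiles; names are `dt_<clone>` and
#'   `tt_<clone1>_<clone2>`.
#' @export
synthesize_doublet_profiles <- function(baselines) {
  if (!length(baselines)) stop("synthesize_doublet_profiles: need >= 1 baseline")
  out <- list()
  for (nm in names(baselines)) {
    out[[paste0("dt_", nm)]] <- baselines[[nm]] + 2L
  }
  nms <- names(baselines)
  if (length(nms) >= 2L) {
    prs <- utils::combn(nms, 2L)
    for (j in seq_len(ncol(prs))) {
      out[[paste0("tt_", prs[1L, j], "_", prs[2L, j])]] <-
        baselines[[prs[1L, j]]] + baselines[[prs[2L, j]]]
    }
  }
  out
}

#' Classify cells against singlet and doublet reference profiles
#'
#' Each cell's aggregated profile is matched to the nearest reference by
#' mean per-bin Manhattan distance. Singlet references comprise a constant
#' diploid profile (CN 2), the pre-WGD clone baselines, and any additional
#' cluster consensus profiles passed as `singlets` (post-WGD clusters must
#' be represented here, or their cells would only have doublet profiles to
#' match). Doublet references are synthesized from the baselines. A cell is
#' called a doublet only when its nearest reference is a doublet profile
#' *and* the margin to the best singlet reference exceeds `margin` mean
#' copies per bin — an exact tie favors the singlet.
#'
#' @param m aggregated [cn_matrix()].
#' @param baselines named list from [baseline_profiles()] (pre-WGD clones).
#' @param singlets optional named list of additional singlet reference
#'   profiles (e.g. consensus of WGD tumor clusters).
#' @param margin required distance margin (mean copies/bin).
#' @param barcodes cells to classify (default all).
#' @return data.frame: barcode, nearest reference, singlet/doublet
#'   distances, `is_doublet`.
#' @export
classify_doublets <- function(m, baselines, singlets = NULL, margin = 0.3,
                              barcodes = NULL) {
  if (!length(baselines)) stop("classify_doublets: references empty")
  if (is.null(barcodes)) barcodes <- rownames(m$cn)
  dbl <- synthesize_doublet_profiles(baselines)
  refs <- c(
    list(diploid = rep(2L, ncol(m$cn))),
    baselines[setdiff(names(baselines), names(singlets))],
    singlets,
    dbl
  )
  is_dbl <- names(refs) %in% names(dbl)
  x <- m$cn[barcodes, , drop = FALSE]
  d <- sapply(refs, function(r) {
    rowMeans(abs(sweep(x, 2L, r)), na.rm = TRUE)
  })
  if (is.null(dim(d))) d <- matrix(d, nrow = 1L, dimnames = list(barcodes, names(refs)))
  best_s <- apply(d[, !is_dbl, drop = FALSE], 1L, min)
  best_d <- apply(d[, is_dbl, drop = FALSE], 1L, min)
  nearest <- colnames(d)[apply(d, 1L, which.min)]
  data.frame(
    barcode = barcodes,
    nearest = nearest,
    dist_singlet = best_s,
    dist_doublet = best_d,
    is_doublet = (best_d < best_s) & (best_s - best_d > margin),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Odd-copy-number artifact filter
#'
#' Cells produced by CN overfitting tend to have profiles that are a pure
#' scaling of the diploid genome; genuine aneuploid tumor cells virtually
#' always carry at least one 10 Mb region at odd copy number. A non-exempt
#' cell is flagged as an artifact iff no aggregated bin rounds to an odd CN.
#' The diploid cluster is exempt (an all-even CN-2 profile is its normal
#' state), as are clusters legitimately all-even after WGD.
#'
#' @param m aggregated [cn_matrix()].
#' @param exempt barcodes exempt from the filter (diploid cluster and,
#'   optionally, WGD clusters).
#' @param barcodes cells to test (default all).
#' @return named logical vector: TRUE = artifact.
#' @export
odd_cn_filter <- function(m, exempt = character(0), barcodes = NULL) {
  if (is.null(barcodes)) barcodes <- rownames(m$cn)
  x <- m$cn[barcodes, , drop = FALSE]
  rounded <- floor(x + 0.5)
  has_odd <- apply(rounded %% 2 == 1, 1L, any, na.rm = TRUE)
  flag <- !has_odd
  flag[barcodes %in% exempt] <- FALSE
  names(flag) <- barcodes
  flag
}
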