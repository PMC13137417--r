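#' Cells-by-bins copy-number matrix
#'
#' Wraps an integer CN matrix (rows = cell barcodes, columns = genomic bins)
#' with its [bin_genome()] and, at raw resolution, a per-call quality matrix.
#' Missing calls are carried explicitly as `NA` and are never imputed at this
#' layer; downstream means skip them (calls are removed per cell, bins are
#' only dropped genome-wide by the mappability filter).
#'
#' Two resolutions exist:
#' * `"raw"`: integer CN per 20 kb bin plus integer call quality;
#' * `"aggregated"`: fractional mean-ploidy values after [aggregate_bins()],
#'   with no quality matrix.
#'
#' @param cn numeric matrix, cells x bins; rownames are barcodes.
#' @param genome a `bin_genome` whose rows match the columns of `cn`.
#' @param quality optional integer matrix of per-call quality scores, same
#'   shape as `cn`; required semantics only at raw resolution.
#' @param resolution `"raw"` or `"aggregated"`.
#' @return an object of class `cn_matrix`.
#' @export
cn_matrix <- function(cn, genome, quality = NULL, resolution = c("raw", "aggregated")) {
  resolution <- match.arg(resolution)
  cn <- as.matrix(cn)
  if (is.null(rownames(cn))) stop("cn_matrix: cn must have barcode rownames")
  if (ncol(cn) != nrow(genome)) {
    stop(sprintf("cn_matrix: %d matrix columns but %d genome bins",
                 ncol(cn), nrow(genome)))
  }
  if (any(cn < 0, na.rm = TRUE)) stop("cn_matrix: negative CN values")
  if (resolution == "raw" && any(cn != round(cn), na.rm = TRUE)) {
    stop("cn_matrix: raw-resolution CN must be integer")
  }
  if (!is.null(quality)) {
    quality <- as.matrix(quality)
    if (!all(dim(quality) == dim(cn))) stop("cn_matrix: quality shape mismatch")
    if (any(quality < 0, na.rm = TRUE)) stop("cn_matrix: negative quality scores")
    rownames(quality) <- rownames(cn)
  }
  colnames(cn) <- bin_ids(genome)
  if (!is.null(quality)) colnames(quality) <- colnames(cn)
  structure(
    list(cn = cn, quality = quality, genome = genome, resolution = resolution),
    class = "cn_matrix"
  )
}

#' @export
print.cn_matrix <- function(x, ...) {
  cat(sprintf("cn_matrix [%s]: %d cells x %d bins (%d missing calls)\n",
              x$resolution, nrow(x$cn), ncol(x$cn), sum(is.na(x$cn))))
  invisible(x)
}

#' @export
dim.cn_matrix <- function(x) dim(x$cn)

#' Barcodes of a cn_matrix.
#' @param m a `cn_matrix`.
#' @return character vector of cell barcodes.
#' @export
barcodes <- function(m) rownames(m$cn)

#' Subset a cn_matrix by cells (and optionally bins), preserving order.
#' @param m a `cn_matrix`.
#' @param cells barcode character vector or row index.
#' @param bins optional bin index.
#' @return a `cn_matrix`.
#' @export
subset_cells <- function(m, cells, bins = NULL) {
  if (is.null(bins)) bins <- seq_len(ncol(m$cn))
  g <- m$genome[bins, , drop = FALSE]
  attr(g, "bin_width") <- attr(m$genome, "bin_width")
  class(g) <- class(m$genome)
  rownames(g) <- NULL
  cn_matrix(
    m$cn[cells, bins, drop = FALSE], g,
    quality = if (!is.null(m$quality)) m$quality[cells, bins, drop = FALSE],
    resolution = m$resolution
  )
}

#' Per-cell mean ploidy, skipping missing calls.
#' @param m a `cn_matrix`.
#' @return named numeric vector, one value per barcode.
#' @export
mean_ploidy <- function(m) rowMeans(m$cn, na.rm = TRUE)

#' Allele-specific copy-number matrix
#'
#' Per-cell haplotype copy numbers (A = reference haplotype 1) on a shared
#' bin grid. The LOH mask is derived, not stored: a bin is LOH when one
#' haplotype has zero copies while total CN is positive (see [call_loh()]).
#'
#' @param a_cn,b_cn nonnegative integer matrices, cells x bins, identical
#'   dimnames; `NA` marks bins with undefined allele CN.
#' @param genome a `bin_genome` matching the columns.
#' @return an object of class `allele_cn`.
#' @export
allele_cn_matrix <- function(a_cn, b_cn, genome) {
  a_cn <- as.matrix(a_cn); b_cn <- as.matrix(b_cn)
  stopifnot(all(dim(a_cn) == dim(b_cn)))
  if (is.null(rownames(a_cn))) stop("allele_cn: barcode rownames required")
  if (ncol(a_cn) != nrow(genome)) stop("allele_cn: column/bin count mismatch")
  if (any(a_cn < 0, na.rm = TRUE) || any(b_cn < 0, na.rm = TRUE)) {
    stop("allele_cn: negative haplotype copy numbers")
  }
  if (!identical(unname(is.na(a_cn)), unname(is.na(b_cn)))) {
    stop("allele_cn: a_cn and b_cn must share the same missing mask")
  }
  colnames(a_cn) <- colnames(b_cn) <- bin_ids(genome)
  rownames(b_cn) <- rownames(a_cn)
  structure(list(a_cn = a_cn, b_cn = b_cn, genome = genome),
            class = "allele_cn")
}

#' @export
print.allele_cn <- function(x, ...) {
  cat(sprintf("allele_cn: %d cells x %d bins\n", nrow(x$a_cn), ncol(x$a_cn)))
  invisible(x)
}

#' Per-cell table of QC metrics and pipeline status labels
#'
#' One row per input barcode. `status` starts at `"unlabeled"` and only
#' moves forward as stages label cells (noisy, apoptotic, doublet, artifact,
#' diploid, tumor, pseudodiploid); cells are labeled, never deleted, so the
#' table is a complete audit trail.
#'
#' @param barcode character vector of cell barcodes.
#' @param dimapd nonnegative per-cell DIMAPD score.
#' @param ploidy_confidence_low logical flag from the upstream caller.
#' @param mean_ploidy per-cell mean ploidy.
#' @return a data.frame of class `cell_table` with status/cluster columns.
#' @export
cell_table <- function(barcode, dimapd = NA_real_,
                       ploidy_confidence_low = FALSE,
                       mean_ploidy = NA_real_) {
  n <- length(barcode)
  d <- data.frame(
    barcode = as.character(barcode),
    dimapd = rep_len(as.numeric(dimapd), n),
    ploidy_confidence_low = rep_len(as.logical(ploidy_confidence_low), n),
    mean_ploidy = rep_len(as.numeric(mean_ploidy), n),
    status = rep_len("unlabeled", n),
    cluster = rep_len(NA_integer_, n),
    subcluster = rep_len(NA_character_, n),
    wgd_fraction = rep_len(NA_real_, n),
    is_wgd = rep_len(NA, n),
    stringsAsFactors = FALSE
  )
  class(d) <- c("cell_table", "data.frame")
  d
}

.cell_statuses <- c("unlabeled", "diploid", "tumor", "noisy", "apoptotic",
                    "doublet", "artifact", "pseudodiploid")

#' Label cells, enforcing forward-only status transitions
#'
#' A cell already carrying a terminal removal label (noisy, apoptotic,
#' doublet, artifact) is never relabeled; `unlabeled`, `diploid` and `tumor`
#' may advance.
#'
#' @param cells a `cell_table`.
#' @param which logical or index vector of rows to label.
#' @param status new status, one of the recognized labels.
#' @return the updated `cell_table`.
#' @export
set_status <- function(cells, which, status) {
  status <- match.arg(status, .cell_statuses)
  idx <- if (is.logical(which)) which(which) else which
  movable <- cells$status[idx] %in% c("unlabeled", "diploid", "tumor")
  cells$status[idx[movable]] <- status
  cells
}

#' Barcodes still active for downstream stages
#' @param cells a `cell_table`.
#' @return barcodes with status unlabeled, diploid, tumor or pseudodiploid.
#' @export
active_barcodes <- function(cells) {
  cells$barcode[cells$status %in% c("unlabeled", "diploid", "tumor", "pseudodiploid")]
}
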