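#' Read a bins BED file
#'
#' BED with columns chrom, start, end and an optional 4th column holding the
#' bin mappability fraction (a 5th column, if present, is ignored).
#'
#' @param path BED file path (no header).
#' @param bin_width nominal bin width recorded on the result.
#' @return a [bin_genome()].
#' @export
read_bins_bed <- function(path, bin_width = 20000L) {
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(b) < 3L) stop("bins BED: need at least chrom/start/end columns")
  mapp <- if (ncol(b) >= 4L) as.numeric(b[[4L]]) else rep(1, nrow(b))
  bin_genome(b[[1L]], b[[2L]], b[[3L]], mappability = mapp, bin_width = bin_width)
}

#' Write a bin_genome as BED4
#' @param g a `bin_genome`.
#' @param path output path.
#' @export
write_bins_bed <- function(g, path) {
  utils::write.table(
    data.frame(g$chrom, g$start, g$end, g$mappability),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a wide CN matrix with its bin definition
#'
#' The matrix file is TSV with a header row of bin labels, one row per cell:
#' first column the barcode, remaining columns integer CN calls in the BED
#' order of `path_bins`. Missing calls are empty fields or `NA`. An optional
#' quality file of identical layout supplies per-call quality scores.
#'
#' @param path_matrix TSV of CN calls.
#' @param path_bins BED file of bins (see [read_bins_bed()]).
#' @param path_quality optional TSV of quality scores, same layout.
#' @param resolution resolution tag for the result.
#' @param bin_width nominal bin width of the BED bins.
#' @return a [cn_matrix()].
#' @export
read_cn_matrix <- function(path_matrix, path_bins, path_quality = NULL,
                           resolution = "raw", bin_width = 20000L) {
  g <- read_bins_bed(path_bins, bin_width = bin_width)
  read_wide <- function(p) {
    d <- utils::read.table(p, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
    m <- as.matrix(d[, -1L, drop = FALSE])
    mode(m) <- "numeric"
    rownames(m) <- as.character(d[[1L]])
    m
  }
  cn <- read_wide(path_matrix)
  if (ncol(cn) != nrow(g)) {
    stop(sprintf("CN matrix format error: %d data columns but %d bins in BED",
                 ncol(cn), nrow(g)))
  }
  q <- if (!is.null(path_quality)) {
    qm <- read_wide(path_quality)
    if (!all(dim(qm) == dim(cn))) stop("quality matrix shape mismatch")
    qm
  }
  cn_matrix(cn, g, quality = q, resolution = resolution)
}

#' Write a cn_matrix (and its bins) to TSV/BED
#'
#' Round-trip safe: values and the missing mask are reproduced exactly by
#' [read_cn_matrix()]. Missing calls are written as `NA`.
#'
#' @param m a `cn_matrix`.
#' @param path_matrix output TSV for CN values.
#' @param path_bins optional output BED for the bins.
#' @param path_quality optional output TSV for quality scores.
#' @export
write_cn_matrix <- function(m, path_matrix, path_bins = NULL, path_quality = NULL) {
  write_wide <- function(mat, p) {
    d <- data.frame(barcode = rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_wide(m$cn, path_matrix)
  if (!is.null(path_bins)) write_bins_bed(m$genome, path_bins)
  if (!is.null(path_quality) && !is.null(m$quality)) write_wide(m$quality, path_quality)
  invisible(path_matrix)
}

#' Read an allele-specific CN table (long format)
#'
#' TSV with header `barcode, chrom, start, end, a_cn, b_cn` — the layout of
#' haplotype-specific CN callers' per-cell output. Bins are taken from the
#' union of (chrom, start, end) rows, sorted; cells missing a bin get `NA`.
#'
#' @param path TSV path.
#' @param bin_width nominal bin width recorded on the genome.
#' @return an [allele_cn_matrix()].
#' @export
read_allele_cn <- function(path, bin_width = 20000L) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("barcode", "chrom", "start", "end", "a_cn", "b_cn")
  if (!all(need %in% names(d))) stop("allele CN TSV: missing required columns")
  ub <- unique(d[, c("chrom", "start", "end")])
  ub <- ub[order(ub$chrom, ub$start), , drop = FALSE]
  g <- bin_genome(ub$chrom, ub$start, ub$end, bin_width = bin_width)
  ids <- bin_ids(g)
  key <- sprintf("%s:%d-%d", d$chrom, d$start, d$end)
  bc <- unique(d$barcode)
  a <- matrix(NA_real_, length(bc), length(ids), dimnames = list(bc, ids))
  b <- a
  i <- cbind(match(d$barcode, bc), match(key, ids))
  a[i] <- d$a_cn
  b[i] <- d$b_cn
  allele_cn_matrix(a, b, g)
}

#' Write an allele_cn matrix as a long TSV
#' @param x an `allele_cn`.
#' @param path output path.
#' @export
write_allele_cn <- function(x, path) {
  g <- x$genome
  n_bin <- nrow(g)
  bc <- rownames(x$a_cn)
  d <- data.frame(
    barcode = rep(bc, each = n_bin),
    chrom = rep(g$chrom, length(bc)),
    start = rep(g$start, length(bc)),
    end = rep(g$end, length(bc)),
    a_cn = as.vector(t(x$a_cn)),
    b_cn = as.vector(t(x$b_cn)),
    stringsAsFactors = FALSE
  )
  d <- d[!is.na(d$a_cn), , drop = FALSE]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-SNP B-allele counts
#'
#' TSV with header `cell, chrom, pos, b_count, total` (`cell` may hold a
#' cluster label when counts are pooled).
#'
#' @param path TSV path.
#' @return a data.frame of class `baf_track`.
#' @export
read_baf_track <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("cell", "chrom", "pos", "b_count", "total")
  if (!all(need %in% names(d))) stop("BAF TSV: missing required columns")
  if (any(d$b_count > d$total)) stop("BAF TSV: b_count exceeds total")
  class(d) <- c("baf_track", "data.frame")
  d
}

#' @rdname read_baf_track
#' @param x a `baf_track`.
#' @export
write_baf_track <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the pipeline report: JSON summary plus per-cell assignment table
#'
#' The JSON records the stage parameters, per-status cell counts and final
#' cluster sizes; the TSV has one row per input barcode with its final
#' status and (sub)cluster assignment, mirroring the per-sample barcode
#' retention tables such pipelines publish.
#'
#' @param cells a `cell_table` after the pipeline ran.
#' @param params named list of the parameters the run used.
#' @param dir output directory (created if needed).
#' @param extra optional named list merged into the JSON (e.g. per-k AIC).
#' @return invisibly, the list written as JSON.
#' @export
write_report <- function(cells, params = list(), dir, extra = list()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  status_counts <- as.list(table(factor(cells$status, levels = .cell_statuses)))
  cl <- cells$cluster[!is.na(cells$cluster)]
  cluster_sizes <- if (length(cl)) as.list(table(cl)) else list()
  report <- c(list(
    n_cells = nrow(cells),
    params = params,
    status_counts = lapply(status_counts, as.integer),
    cluster_sizes = lapply(cluster_sizes, as.integer)
  ), extra)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(as.data.frame(cells), file.path(dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}
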