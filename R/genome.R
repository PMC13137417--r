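#' Binned genome
#'
#' An ordered set of fixed-width genomic bins with a per-bin mappability
#' fraction. This is the coordinate backbone shared by every matrix in the
#' package: the columns of a [cn_matrix()] are exactly the rows of its
#' `bin_genome`.
#'
#' Coordinates are 0-based, half-open (BED convention). Bins must be
#' non-overlapping and sorted by (chrom, start); chromosomes appear as
#' contiguous blocks.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors of bin boundaries (0-based half-open).
#' @param mappability numeric in \[0, 1\]; defaults to 1 for every bin.
#' @param bin_width nominal bin width in bp (the base resolution is 20 kb;
#'   chromosome-end bins may be shorter).
#'
#' @return A data.frame of class `bin_genome` with columns `chrom`, `start`,
#'   `end`, `mappability` and attribute `bin_width`.
#' @export
bin_genome <- function(chrom, start, end, mappability = NULL, bin_width = 20000L) {
  if (is.null(mappability)) mappability <- rep(1, length(chrom))
  g <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    mappability = as.numeric(mappability),
    stringsAsFactors = FALSE
  )
  attr(g, "bin_width") <- as.integer(bin_width)
  class(g) <- c("bin_genome", "data.frame")
  validate_bin_genome(g)
  g
}

validate_bin_genome <- function(g) {
  stopifnot(is.data.frame(g), all(c("chrom", "start", "end", "mappability") %in% names(g)))
  if (nrow(g) == 0L) return(invisible(g))
  if (any(g$end <= g$start)) {
    stop("bin_genome: all bins must satisfy end > start")
  }
  if (any(g$mappability < 0 | g$mappability > 1)) {
    stop("bin_genome: mappability must lie in [0, 1]")
  }
  # chromosomes must form contiguous, internally sorted, non-overlapping blocks
  blocks <- rle(g$chrom)$values
  if (anyDuplicated(blocks)) {
    stop("bin_genome: bins of one chromosome must be contiguous")
  }
  for (ch in blocks) {
    i <- which(g$chrom == ch)
    s <- g$start[i]; e <- g$end[i]
    if (is.unsorted(s, strictly = TRUE)) {
      stop("bin_genome: bins must be sorted by start within chromosome")
    }
    if (length(i) > 1L && any(s[-1L] < e[-length(e)])) {
      stop("bin_genome: bins must not overlap")
    }
  }
  invisible(g)
}

#' @export
print.bin_genome <- function(x, ...) {
  cat(sprintf(
    "bin_genome: %d bins on %d chromosome(s), bin width %s bp\n",
    nrow(x), length(unique(x$chrom)), format(attr(x, "bin_width"), big.mark = ",")
  ))
  invisible(x)
}

#' Bin identifiers `chrom:start-end` used as matrix column names.
#' @param g a `bin_genome`.
#' @return character vector, one id per bin.
#' @export
bin_ids <- function(g) sprintf("%s:%d-%d", g$chrom, g$start, g$end)

#' Bin lengths in bp.
#' @param g a `bin_genome`.
#' @return integer vector of `end - start`.
#' @export
bin_lengths <- function(g) g$end - g$start

#' Scaled human-like genome for desk-scale runs
#'
#' 22 autosomes plus X with lengths 1/`scale` of the GRCh38 chromosome
#' lengths, tiled with `bin_width` bins (default 20 kb). At the default
#' `scale = 30` this yields roughly 5,100 bins, so a full simulated pipeline
#' run takes seconds while preserving per-chromosome structure (whole-
#' chromosome and arm-scale events remain expressible).
#'
#' @param scale divisor applied to the GRCh38 chromosome lengths.
#' @param bin_width bin width in bp.
#' @param mappability constant mappability assigned to every bin.
#' @return a [bin_genome()].
#' @export
default_genome <- function(scale = 30, bin_width = 20000L, mappability = 1) {
  # GRCh38 chromosome lengths, Mb-rounded; adequate for a scaled test genome
  len <- c(
    chr1 = 248956422, chr2 = 242193529, chr3 = 198295559, chr4 = 190214555,
    chr5 = 181538259, chr6 = 170805979, chr7 = 159345973, chr8 = 145138636,
    chr9 = 138394717, chr10 = 133797422, chr11 = 135086622, chr12 = 133275309,
    chr13 = 114364328, chr14 = 107043718, chr15 = 101991189, chr16 = 90338345,
    chr17 = 83257441, chr18 = 80373285, chr19 = 58617616, chr20 = 64444167,
    chr21 = 46709983, chr22 = 50818468, chrX = 156040895
  )
  len <- floor(len / scale)
  pieces <- lapply(names(len), function(ch) {
    n <- max(1L, floor(len[[ch]] / bin_width))
    start <- (seq_len(n) - 1L) * bin_width
    data.frame(chrom = ch, start = start, end = start + bin_width,
               stringsAsFactors = FALSE)
  })
  b <- do.call(rbind, pieces)
  bin_genome(b$chrom, b$start, b$end,
             mappability = rep(mappability, nrow(b)), bin_width = bin_width)
}
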