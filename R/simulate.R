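#' Copy-number event specification
#'
#' One mutational event on a clone's haplotype-specific CN profile. Events
#' apply cumulatively along the path from the diploid root to the clone, so
#' order matters: copy-neutral LOH followed by WGD yields (4,0) — absolute
#' CN 2 pre-doubling, 4 post — while the reverse yields (4,0) only via a
#' different history.
#'
#' Kinds:
#' * `gain` / `loss`: add `delta` (positive / negative) copies of a
#'   haplotype over a region;
#' * `wgd`: whole-genome doubling, doubles both haplotypes everywhere
#'   (no region or haplotype);
#' * `cnloh`: copy-neutral LOH — the kept haplotype absorbs the other's
#'   copies, the other drops to 0; total CN unchanged;
#' * `hemizygous_del`: one haplotype drops to 0 over the region;
#' * `focal_amp`: high-level gain (`delta` copies) of one haplotype over a
#'   (typically small) region.
#'
#' @param kind event kind, see above.
#' @param chrom chromosome name (omit for `wgd`).
#' @param start,end region in bp (0-based half-open); omit both for a
#'   whole-chromosome event.
#' @param haplotype `"A"`, `"B"` or `"both"`; for `cnloh` the haplotype that
#'   is *kept*.
#' @param delta signed copies for `gain`/`loss`/`focal_amp`.
#' @return a list of class `cn_event`.
#' @export
cn_event <- function(kind = c("gain", "loss", "wgd", "cnloh",
                              "hemizygous_del", "focal_amp"),
                     chrom = NULL, start = NULL, end = NULL,
                     haplotype = "A", delta = 1L) {
  kind <- match.arg(kind)
  if (kind == "wgd") {
    chrom <- start <- end <- haplotype <- NULL
  } else {
    if (is.null(chrom)) stop("cn_event: non-WGD events need a chromosome")
    haplotype <- match.arg(haplotype, c("A", "B", "both"))
  }
  if (kind == "loss" && delta > 0) delta <- -delta
  structure(list(kind = kind, chrom = chrom, start = start, end = end,
                 haplotype = haplotype, delta = as.integer(delta)),
            class = "cn_event")
}

#' Bin indices overlapped by a region (whole chromosome when start is NULL).
#' @param genome a `bin_genome`.
#' @param chrom chromosome name.
#' @param start,end optional region in bp.
#' @return integer vector of bin indices.
#' @export
region_bins <- function(genome, chrom, start = NULL, end = NULL) {
  i <- genome$chrom == chrom
  if (!is.null(start)) i <- i & genome$end > start & genome$start < end
  which(i)
}

#' Clone specification for the synthetic-data generator
#'
#' Defines the full ground truth of a simulated scDNA-seq sample: a clone
#' tree rooted at a diploid ancestor, per-clone event lists (applied
#' cumulatively along the root path), per-clone cell counts, counts of every
#' contaminant cell class the pipeline must handle, and the noise model.
#' Replaying a spec with the same seed is bit-identical.
#'
#' @param clones named list; each element a list with `parent` (clone name
#'   or `NULL` for children of the diploid root), `n_cells`, and `events`
#'   (list of [cn_event()]).
#' @param n_diploid,n_noisy,n_apoptotic,n_doublet_dt,n_doublet_tt,n_pseudodiploid
#'   contaminant cell counts: normal diploid cells; S-phase/noisy cells
#'   (inflated DIMAPD); degraded apoptotic cells; diploid-tumor doublets;
#'   tumor-tumor doublets; pseudodiploid cells (diploid background plus a
#'   random subset of truncal gains at +1).
#' @param flip_rate per-bin probability of a +/-1 copy flip on a haplotype
#'   (the CN noise epsilon, in \[0, 0.5)).
#' @param cn_noise_scaling when TRUE the flip probability scales with the
#'   bin's total CN (`flip_rate * cn/2`), emulating read-sampling noise
#'   that grows with copy number; default FALSE (uniform flips).
#' @param dimapd_mu,dimapd_sd Gaussian DIMAPD for clean cells.
#' @param dimapd_shift_sd shift (in SD units) of the noisy-cell DIMAPD mean.
#' @param pseudodiploid_p probability each truncal gain region is present in
#'   a pseudodiploid cell.
#' @param q_low_rate fraction of calls given a low quality score (< 15).
#' @param lambda mean reads per SNP for [sample_snp_counts()].
#' @param genome a [bin_genome()]; defaults to [default_genome()].
#' @param seed integer seed governing all randomness of the spec.
#' @return a list of class `clone_spec`.
#' @export
clone_spec <- function(clones,
                       n_diploid = 0L, n_noisy = 0L, n_apoptotic = 0L,
                       n_doublet_dt = 0L, n_doublet_tt = 0L,
                       n_pseudodiploid = 0L,
                       flip_rate = 0.01,
                       cn_noise_scaling = FALSE,
                       dimapd_mu = 1.0, dimapd_sd = 0.1, dimapd_shift_sd = 5,
                       pseudodiploid_p = 0.5,
                       q_low_rate = 0.02,
                       lambda = 30,
                       genome = default_genome(),
                       seed = 1L) {
  if (is.null(names(clones)) || any(names(clones) == "")) {
    stop("clone_spec: clones must be a named list")
  }
  counts <- c(n_diploid, n_noisy, n_apoptotic, n_doublet_dt, n_doublet_tt,
              n_pseudodiploid, vapply(clones, function(cl) cl$n_cells, 0))
  if (any(counts < 0)) stop("clone_spec: cell counts must be >= 0")
  if (flip_rate < 0 || flip_rate >= 0.5) stop("clone_spec: flip_rate in [0, 0.5)")
  if (n_doublet_tt > 0 && length(clones) < 2L) {
    stop("clone_spec: tumor-tumor doublets require at least 2 clones")
  }
  structure(list(
    clones = clones, n_diploid = n_diploid, n_noisy = n_noisy,
    n_apoptotic = n_apoptotic, n_doublet_dt = n_doublet_dt,
    n_doublet_tt = n_doublet_tt, n_pseudodiploid = n_pseudodiploid,
    flip_rate = flip_rate, cn_noise_scaling = isTRUE(cn_noise_scaling),
    dimapd_mu = dimapd_mu, dimapd_sd = dimapd_sd,
    dimapd_shift_sd = dimapd_shift_sd, pseudodiploid_p = pseudodiploid_p,
    q_low_rate = q_low_rate, lambda = lambda, genome = genome,
    seed = as.integer(seed)
  ), class = "clone_spec")
}

#' Expand per-clone haplotype CN profiles from a clone spec
#'
#' Walks the clone tree from the diploid root, applying each clone's events
#' in order on top of its parent's profile. The root profile is (1,1)
#' everywhere.
#'
#' @param spec a [clone_spec()].
#' @return named list, one element per clone: `list(a = , b = )` integer
#'   vectors over the genome's bins.
#' @export
expand_clone_profiles <- function(spec) {
  g <- spec$genome
  n <- nrow(g)
  apply_event <- function(prof, ev) {
    if (ev$kind == "wgd") {
      prof$a <- prof$a * 2L; prof$b <- prof$b * 2L
      return(prof)
    }
    idx <- region_bins(g, ev$chrom, ev$start, ev$end)
    if (!length(idx)) stop("cn_event region matches no bins: ", ev$chrom)
    switch(ev$kind,
      gain = , loss = , focal_amp = {
        h <- if (ev$haplotype == "both") c("a", "b")
             else if (ev$haplotype == "A") "a" else "b"
        for (hh in h) prof[[hh]][idx] <- prof[[hh]][idx] + ev$delta
      },
      cnloh = {
        keep <- if (ev$haplotype == "A") "a" else "b"
        drop <- if (keep == "a") "b" else "a"
        prof[[keep]][idx] <- prof[[keep]][idx] + prof[[drop]][idx]
        prof[[drop]][idx] <- 0L
      },
      hemizygous_del = {
        h <- if (ev$haplotype == "A") "a" else "b"
        prof[[h]][idx] <- 0L
      }
    )
    if (any(prof$a < 0) || any(prof$b < 0)) {
      stop("cn_event drives a haplotype CN below 0 (", ev$kind, " ", ev$chrom, ")")
    }
    prof
  }
  profiles <- list()
  expand <- function(name) {
    if (!is.null(profiles[[name]])) return(profiles[[name]])
    cl <- spec$clones[[name]]
    base <- if (is.null(cl$parent)) {
      list(a = rep(1L, n), b = rep(1L, n))
    } else {
      expand(cl$parent)
    }
    for (ev in cl$events) base <- apply_event(base, ev)
    profiles[[name]] <<- base
    base
  }
  for (name in names(spec$clones)) expand(name)
  profiles[names(spec$clones)]
}

# gain-type regions carried by every tumor clone (events of clones that are
# ancestors of, or equal to, all clones) -- the truncal gains pseudodiploid
# cells sample from
truncal_gain_bins <- function(spec) {
  anc <- function(name) {
    path <- character()
    while (!is.null(name)) { path <- c(path, name); name <- spec$clones[[name]]$parent }
    path
  }
  paths <- lapply(names(spec$clones), anc)
  common <- Reduce(intersect, paths)
  regions <- list()
  for (name in common) {
    for (ev in spec$clones[[name]]$events) {
      if (ev$kind %in% c("gain", "focal_amp") && ev$delta > 0) {
        regions[[length(regions) + 1L]] <- region_bins(spec$genome, ev$chrom,
                                                       ev$start, ev$end)
      }
    }
  }
  regions
}

# per-cell noise: each bin flips with prob eps (optionally scaled by
# total CN / 2, emulating read-sampling noise that grows with copy number);
# the flip hits one haplotype (+1 or -1, clamped at 0), so total CN always
# equals a + b
.flip_noise <- function(a, b, eps, scale_by_cn = FALSE) {
  if (eps <= 0) return(list(a = a, b = b))
  n <- length(a)
  p <- if (scale_by_cn) pmin(eps * (a + b) / 2, 0.49) else eps
  hit <- which(stats::runif(n) < p)
  if (length(hit)) {
    which_h <- stats::runif(length(hit)) < 0.5
    dir <- ifelse(stats::runif(length(hit)) < 0.5, 1L, -1L)
    ai <- hit[which_h]; bi <- hit[!which_h]
    a[ai] <- pmax(0L, a[ai] + dir[which_h])
    b[bi] <- pmax(0L, b[bi] + dir[!which_h])
  }
  list(a = a, b = b)
}

#' Sample a full synthetic cell population from a clone spec
#'
#' Generates every cell class: tumor cells per clone and normal diploid
#' cells (clone profile plus independent per-bin flip noise), diploid-tumor
#' doublets (clone total profile plus two), tumor-tumor doublets (sum of two
#' clone profiles), pseudodiploid cells (diploid background plus a random
#' subset of truncal gain regions at +1), apoptotic cells (a random 30-70%
#' of bins degraded to CN 0 or 1), and S-phase/noisy cells whose DIMAPD is
#' drawn from the inflated distribution. Haplotype-level noise keeps the
#' invariant total CN = A + B exact for every cell.
#'
#' @param spec a [clone_spec()].
#' @return list with elements `cn` ([cn_matrix()], raw 20 kb with quality),
#'   `allele` ([allele_cn_matrix()]), `cells` ([cell_table()]), and `truth`
#'   (data.frame barcode / class / clone).
#' @export
sample_cells <- function(spec) {
  set.seed(spec$seed)
  g <- spec$genome
  n_bin <- nrow(g)
  profiles <- expand_clone_profiles(spec)
  clone_names <- names(profiles)
  trunc_bins <- truncal_gain_bins(spec)

  rows_a <- list(); rows_b <- list(); truth <- list(); dimapd <- c()
  add_cell <- function(a, b, class, clone = NA_character_, noisy_dimapd = FALSE) {
    i <- length(rows_a) + 1L
    rows_a[[i]] <<- a; rows_b[[i]] <<- b
    truth[[i]] <<- data.frame(class = class, clone = clone,
                              stringsAsFactors = FALSE)
    mu <- spec$dimapd_mu + if (noisy_dimapd) spec$dimapd_shift_sd * spec$dimapd_sd else 0
    dimapd[i] <<- stats::rnorm(1, mu, spec$dimapd_sd)
  }

  for (cl in clone_names) {
    p <- profiles[[cl]]
    for (j in seq_len(spec$clones[[cl]]$n_cells)) {
      x <- .flip_noise(p$a, p$b, spec$flip_rate, spec$cn_noise_scaling)
      add_cell(x$a, x$b, "tumor", cl)
    }
  }
  for (j in seq_len(spec$n_diploid)) {
    x <- .flip_noise(rep(1L, n_bin), rep(1L, n_bin), spec$flip_rate, spec$cn_noise_scaling)
    add_cell(x$a, x$b, "diploid")
  }
  for (j in seq_len(spec$n_pseudodiploid)) {
    a <- rep(1L, n_bin); b <- rep(1L, n_bin)
    for (reg in trunc_bins) {
      if (stats::runif(1) < spec$pseudodiploid_p) a[reg] <- a[reg] + 1L
    }
    x <- .flip_noise(a, b, spec$flip_rate, spec$cn_noise_scaling)
    add_cell(x$a, x$b, "pseudodiploid")
  }
  for (j in seq_len(spec$n_doublet_dt)) {
    cl <- clone_names[1L + (j - 1L) %% length(clone_names)]
    p <- profiles[[cl]]
    x <- .flip_noise(p$a + 1L, p$b + 1L, spec$flip_rate, spec$cn_noise_scaling)
    add_cell(x$a, x$b, "doublet_dt", cl)
  }
  if (spec$n_doublet_tt > 0) {
    prs <- utils::combn(clone_names, 2L)
    for (j in seq_len(spec$n_doublet_tt)) {
      k <- 1L + (j - 1L) %% ncol(prs)
      p1 <- profiles[[prs[1L, k]]]; p2 <- profiles[[prs[2L, k]]]
      x <- .flip_noise(p1$a + p2$a, p1$b + p2$b, spec$flip_rate, spec$cn_noise_scaling)
      add_cell(x$a, x$b, "doublet_tt", paste(prs[, k], collapse = "+"))
    }
  }
  for (j in seq_len(spec$n_apoptotic)) {
    a <- rep(1L, n_bin); b <- rep(1L, n_bin)
    frac <- stats::runif(1, 0.3, 0.7)
    hit <- sample.int(n_bin, round(frac * n_bin))
    tot <- sample(0:1, length(hit), replace = TRUE)
    a[hit] <- tot; b[hit] <- 0L
    add_cell(a, b, "apoptotic")
  }
  for (j in seq_len(spec$n_noisy)) {
    cl <- clone_names[1L + (j - 1L) %% length(clone_names)]
    p <- profiles[[cl]]
    x <- .flip_noise(p$a, p$b, spec$flip_rate, spec$cn_noise_scaling)
    add_cell(x$a, x$b, "noisy", cl, noisy_dimapd = TRUE)
  }

  n_cell <- length(rows_a)
  bc <- sprintf("cell_%04d", seq_len(n_cell))
  a_mat <- do.call(rbind, rows_a); b_mat <- do.call(rbind, rows_b)
  rownames(a_mat) <- rownames(b_mat) <- bc
  cn <- a_mat + b_mat

  quality <- matrix(
    sample(15:40, n_cell * n_bin, replace = TRUE), n_cell, n_bin
  )
  low <- which(stats::runif(n_cell * n_bin) < spec$q_low_rate)
  quality[low] <- sample(0:14, length(low), replace = TRUE)
  rownames(quality) <- bc

  truth <- do.call(rbind, truth)
  truth <- data.frame(barcode = bc, truth, stringsAsFactors = FALSE)
  m <- cn_matrix(cn, g, quality = quality, resolution = "raw")
  cells <- cell_table(bc, dimapd = dimapd,
                      ploidy_confidence_low = FALSE,
                      mean_ploidy = rowMeans(cn))
  list(cn = m, allele = allele_cn_matrix(a_mat, b_mat, g),
       cells = cells, truth = truth)
}

#' Sample per-SNP allele read counts from haplotype CN profiles
#'
#' For each cell and bin, places `snps_per_bin` heterozygous SNPs at evenly
#' spaced positions; each SNP's total read count is Poisson(`lambda`) and
#' its B-allele count Binomial(total, b/(a+b)). Bins with total CN 0 emit
#' no reads.
#'
#' @param allele an [allele_cn_matrix()].
#' @param lambda mean reads per SNP (> 0).
#' @param snps_per_bin SNPs simulated per bin.
#' @param cells optional subset of barcodes.
#' @param seed integer seed.
#' @return a `baf_track` data.frame (`cell, chrom, pos, b_count, total`).
#' @export
sample_snp_counts <- function(allele, lambda, snps_per_bin = 1L,
                              cells = NULL, seed = 1L) {
  stopifnot(lambda > 0)
  set.seed(seed)
  g <- allele$genome
  if (is.null(cells)) cells <- rownames(allele$a_cn)
  w <- bin_lengths(g)
  pos_off <- lapply(seq_len(snps_per_bin), function(k) {
    g$start + floor(w * k / (snps_per_bin + 1))
  })
  out <- list()
  for (bc in cells) {
    a <- allele$a_cn[bc, ]; b <- allele$b_cn[bc, ]
    tot_cn <- a + b
    ok <- !is.na(tot_cn) & tot_cn > 0
    p_b <- b[ok] / tot_cn[ok]
    if (!any(ok)) next
    for (k in seq_len(snps_per_bin)) {
      tot <- stats::rpois(sum(ok), lambda)
      bc_count <- stats::rbinom(sum(ok), tot, p_b)
      keep <- tot > 0
      out[[length(out) + 1L]] <- data.frame(
        cell = rep(bc, sum(keep)), chrom = g$chrom[ok][keep],
        pos = pos_off[[k]][ok][keep],
        b_count = bc_count[keep], total = tot[keep],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    d <- data.frame(cell = character(), chrom = character(),
                    pos = integer(), b_count = integer(), total = integer())
    class(d) <- c("baf_track", "data.frame")
    return(d)
  }
  d <- do.call(rbind, out)
  d <- d[order(match(d$cell, cells), match(d$chrom, unique(g$chrom)), d$pos), ]
  rownames(d) <- NULL
  class(d) <- c("baf_track", "data.frame")
  d
}

#' Default synthetic sample: diploid cells plus a multiclonal tumor
#'
#' The stock study conditions used throughout the package's tests and
#' examples: a heavily aneuploid founder clone A (truncal gains of
#' chr1/chr8/chr9/chr16/chr20, loss of chr2, copy-neutral LOH of chr17 and
#' hemizygous loss of chr13 — founder-level aneuploidy is what makes a WGD
#' descendant distinguishable from diploid-tumor doublets); a post-WGD
#' descendant B with an extra chr4 loss; and two pre-WGD siblings C and D
#' with distinct private gains/losses that include a mirrored chr10
#' imbalance — C gains the B haplotype, D the A haplotype, both reaching
#' total CN 3. Contaminants cover every class the pipeline filters: diploid
#' cells, pseudodiploids, both doublet types, apoptotic debris and S-phase
#' cells.
#'
#' @param seed integer seed.
#' @param genome a [bin_genome()].
#' @param flip_rate per-bin CN flip probability.
#' @param ... further arguments passed to [clone_spec()].
#' @return a [clone_spec()].
#' @export
default_clone_spec <- function(seed = 1L, genome = default_genome(),
                               flip_rate = 0.01, ...) {
  clones <- list(
    A = list(parent = NULL, n_cells = 80L, events = list(
      cn_event("gain", "chr1", haplotype = "A"),
      cn_event("gain", "chr8", haplotype = "A"),
      cn_event("gain", "chr9", haplotype = "A"),
      cn_event("gain", "chr16", haplotype = "A", delta = 2L),
      cn_event("gain", "chr20", haplotype = "A"),
      cn_event("loss", "chr2", haplotype = "B"),
      cn_event("cnloh", "chr17", haplotype = "A"),
      cn_event("hemizygous_del", "chr13", haplotype = "B")
    )),
    B = list(parent = "A", n_cells = 80L, events = list(
      cn_event("wgd"),
      cn_event("loss", "chr4", haplotype = "B")
    )),
    C = list(parent = "A", n_cells = 60L, events = list(
      cn_event("gain", "chr3", haplotype = "B"),
      cn_event("gain", "chr10", haplotype = "B"),
      cn_event("loss", "chr5", haplotype = "B"),
      cn_event("gain", "chr12", haplotype = "B"),
      cn_event("gain", "chr15", haplotype = "A")
    )),
    D = list(parent = "A", n_cells = 50L, events = list(
      cn_event("gain", "chr10", haplotype = "A"),
      cn_event("loss", "chr14", haplotype = "B"),
      cn_event("gain", "chr21", haplotype = "A"),
      cn_event("gain", "chr22", haplotype = "A"),
      cn_event("gain", "chr6", haplotype = "A")
    ))
  )
  clone_spec(clones,
             n_diploid = 60L, n_noisy = 12L, n_apoptotic = 10L,
             n_doublet_dt = 8L, n_doublet_tt = 6L, n_pseudodiploid = 10L,
             flip_rate = flip_rate, genome = genome, seed = seed, ...)
}
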