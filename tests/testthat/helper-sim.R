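# shared fixtures: small genomes and clone specs built in code

toy_genome <- function(n_chr = 3L, bins_per_chr = 10L, bin_width = 20000L) {
  chrom <- rep(paste0("chr", seq_len(n_chr)), each = bins_per_chr)
  start <- rep((seq_len(bins_per_chr) - 1L) * bin_width, n_chr)
  bin_genome(chrom, start, start + bin_width, bin_width = bin_width)
}

# three well-separated clones, >= 5 whole-chromosome differences apart
spec_3clones <- function(eps = 0, seed = 1L, n = 100L,
                         genome = default_genome()) {
  clones <- list(
    A = list(parent = NULL, n_cells = n, events = list(
      cn_event("gain", "chr1", haplotype = "A"),
      cn_event("gain", "chr2", haplotype = "A"),
      cn_event("gain", "chr3", haplotype = "A"),
      cn_event("loss", "chr4", haplotype = "B"),
      cn_event("gain", "chr5", haplotype = "A")
    )),
    B = list(parent = "A", n_cells = n, events = list(
      cn_event("gain", "chr6", haplotype = "A"),
      cn_event("gain", "chr7", haplotype = "A"),
      cn_event("loss", "chr8", haplotype = "B"),
      cn_event("gain", "chr9", haplotype = "A"),
      cn_event("gain", "chr10", haplotype = "A")
    )),
    C = list(parent = "A", n_cells = n, events = list(
      cn_event("gain", "chr11", haplotype = "A"),
      cn_event("gain", "chr12", haplotype = "A"),
      cn_event("loss", "chr13", haplotype = "B"),
      cn_event("gain", "chr14", haplotype = "A"),
      cn_event("gain", "chr15", haplotype = "A")
    ))
  )
  clone_spec(clones, flip_rate = eps, genome = genome, seed = seed)
}

# two aneuploid pre-WGD clones plus diploid cells and injected doublets;
# every doublet type is synthesizable from the baselines
spec_doublets <- function(eps = 0, seed = 1L, n = 60L, n_dbl = 20L,
                          genome = default_genome()) {
  clones <- list(
    A = list(parent = NULL, n_cells = n, events = list(
      cn_event("gain", "chr1", haplotype = "A"),
      cn_event("gain", "chr3", haplotype = "A"),
      cn_event("loss", "chr4", haplotype = "B"),
      cn_event("gain", "chr8", haplotype = "A"),
      cn_event("loss", "chr13", haplotype = "B")
    )),
    B = list(parent = "A", n_cells = n, events = list(
      cn_event("gain", "chr6", haplotype = "A"),
      cn_event("gain", "chr9", haplotype = "A"),
      cn_event("loss", "chr2", haplotype = "B"),
      cn_event("gain", "chr12", haplotype = "A", delta = 2L),
      cn_event("gain", "chr20", haplotype = "A")
    ))
  )
  clone_spec(clones, n_diploid = n, n_doublet_dt = n_dbl,
             n_doublet_tt = n_dbl, flip_rate = eps, genome = genome,
             seed = seed)
}

# per-bin truth LOH mask for a clone profile
profile_loh_mask <- function(profile) {
  pmin(profile$a, profile$b) == 0 & (profile$a + profile$b) > 0
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
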