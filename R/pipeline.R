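#' Pipeline configuration
#'
#' Collects every tunable of the post-processing pipeline with its default.
#' Unknown names are rejected.
#'
#' @param q_min minimum retained call quality (strict `<` removes).
#' @param map_min minimum retained bin mappability.
#' @param dimapd_p upper-tail probability of the DIMAPD Gaussian threshold.
#' @param factor bins aggregated per mean-ploidy bin (20 kb -> 10 Mb).
#' @param k_max largest k tried in clustering.
#' @param doublet_margin required singlet-doublet distance margin
#'   (mean copies/bin).
#' @param min_loh_run minimum bins per LOH / mirrored segment.
#' @param consensus cluster-consensus fraction for LOH bins.
#' @param diploid_max_dev largest mean |CN-2| accepted for the diploid
#'   cluster.
#' @param apoptotic_low_frac drop clusters whose median per-cell fraction
#'   of bins at CN <= 1 exceeds this.
#' @param pseudodiploid_min_bins deviating aggregated bins to flag a
#'   pseudodiploid.
#' @param pseudodiploid_dev per-bin deviation (copies) counting as
#'   non-diploid.
#' @param wgd_ploidy_cut mean-ploidy proxy separating pre- from post-WGD
#'   clusters when allele data are absent.
#' @param min_clone_cells smallest cluster treated as a clone when deciding
#'   whether a doublet-like cluster with consensus LOH is a genuine
#'   (post-WGD) clone rather than a doublet cluster.
#' @param seed integer seed for all stochastic steps.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(q_min = 15L, map_min = 0.90, dimapd_p = 0.10,
                            factor = 500L, k_max = 20L,
                            doublet_margin = 0.3, min_loh_run = 3L,
                            consensus = 0.8, diploid_max_dev = 0.25,
                            apoptotic_low_frac = 0.3,
                            pseudodiploid_min_bins = 3L,
                            pseudodiploid_dev = 0.5,
                            wgd_ploidy_cut = 3.0,
                            min_clone_cells = 10L,
                            seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

# median per-cell fraction of aggregated bins at CN <= 1, per cluster:
# clusters of degraded/apoptotic DNA stand out by pervasive low CN
.apoptotic_clusters <- function(m, assignments, cutoff) {
  low_frac <- rowMeans(m$cn < 1.5, na.rm = TRUE)
  cls <- sort(unique(assignments))
  flagged <- cls[vapply(cls, function(cl) {
    stats::median(low_frac[names(assignments)[assignments == cl]]) > cutoff
  }, FALSE)]
  flagged
}

#' Run the full post-processing and clonal-inference pipeline
#'
#' Stage order: (1) flag noisy cells (ploidy confidence / DIMAPD Gaussian
#' threshold) and filter calls by quality and mappability; (2) aggregate to
#' mean-ploidy bins; (3) first clustering; (4) remove apoptotic/degraded
#' clusters; (5) identify the diploid cluster; (6) synthesize doublet
#' profiles from pre-WGD baselines, remove matching cells, apply the
#' odd-CN artifact filter; (7) final clustering and subclustering of the
#' retained cells, with pseudodiploid flagging in the diploid cluster;
#' (8) allele-specific statistics (LOH, WGD, mirrored imbalance) when an
#' allele matrix is supplied; (9) subcluster-level BME phylogeny rooted at
#' the diploid outgroup. Cells are labeled, never dropped from the table.
#'
#' @param cn raw [cn_matrix()] with quality scores.
#' @param cells a [cell_table()] for the same barcodes.
#' @param allele optional [allele_cn_matrix()] on the raw bins.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for the JSON/TSV report.
#' @return list of class `pipeline_result`: the updated `cells` table,
#'   stage log, clustering results, consensus profiles, allele statistics,
#'   tree, and the report list.
#' @export
run_pipeline <- function(cn, cells, allele = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  note <- function(stage, ...) {
    log[[stage]] <<- list(...)
  }

  ## 1. cell and call filters
  if (any(is.finite(cells$dimapd)) && config$dimapd_p > 0) {
    fit <- fit_dimapd_threshold(cells$dimapd, p_cut = config$dimapd_p)
    cells <- filter_noisy_cells(cells, fit)
  } else {
    fit <- NULL
  }
  note("noisy_filter", n_noisy = sum(cells$status == "noisy"),
       threshold = if (!is.null(fit)) fit$threshold else NA)
  cn_f <- filter_calls(cn, q_min = config$q_min, map_min = config$map_min)
  note("call_filter", bins_kept = ncol(cn_f$cn),
       calls_removed = sum(is.na(cn_f$cn)) - sum(is.na(cn$cn)))

  ## 2. aggregate
  agg <- aggregate_bins(cn_f, factor = config$factor)

  ## 3. first clustering on active cells
  act <- active_barcodes(cells)
  cl1 <- ml_cluster(subset_cells(agg, act), k_max = config$k_max,
                    seed = config$seed)
  note("clustering_1", k = cl1$selected_k, n_cells = length(act))

  ## 4. apoptotic/degraded clusters
  apo <- .apoptotic_clusters(subset_cells(agg, act), cl1$assignments,
                             config$apoptotic_low_frac)
  if (length(apo)) {
    apo_bc <- names(cl1$assignments)[cl1$assignments %in% apo]
    cells <- set_status(cells, cells$barcode %in% apo_bc, "apoptotic")
  }
  note("apoptotic_filter", clusters_dropped = length(apo),
       n_apoptotic = sum(cells$status == "apoptotic"))

  ## 5. diploid cluster (on post-apoptotic clustering)
  act <- active_barcodes(cells)
  asn <- cl1$assignments[act]
  dip_cl <- identify_diploid_cluster(
    structure(list(assignments = asn), class = "clustering_result"),
    agg, max_dev = config$diploid_max_dev
  )
  dip_bc <- names(asn)[asn == dip_cl]
  cells <- set_status(cells, cells$barcode %in% dip_bc, "diploid")
  cells <- set_status(cells, cells$barcode %in% setdiff(act, dip_bc), "tumor")
  note("diploid_cluster", cluster = dip_cl, n_diploid = length(dip_bc))

  ## 6a. WGD calls (needed to choose pre-WGD baselines)
  wgd <- NULL
  if (!is.null(allele)) {
    wgd <- call_wgd(allele)
    i <- match(wgd$barcode, cells$barcode)
    cells$wgd_fraction[i] <- wgd$wgd_fraction
    cells$is_wgd[i] <- wgd$is_wgd
  }
  tumor_cls <- setdiff(sort(unique(asn)), dip_cl)
  cluster_wgd <- vapply(tumor_cls, function(cl) {
    bcs <- names(asn)[asn == cl]
    if (!is.null(wgd)) {
      mean(cells$is_wgd[match(bcs, cells$barcode)], na.rm = TRUE) > 0.5
    } else {
      mean(mean_ploidy(subset_cells(agg, bcs))) > config$wgd_ploidy_cut
    }
  }, FALSE)
  baseline_cls <- tumor_cls[!cluster_wgd]
  if (!length(baseline_cls)) baseline_cls <- tumor_cls
  note("wgd", n_wgd_clusters = sum(cluster_wgd),
       baseline_clusters = baseline_cls)

  ## 6b. doublets and artifacts
  bl <- baseline_profiles(agg, asn, baseline_cls)
  # Non-baseline tumor clusters (e.g. post-WGD clones) also serve as singlet
  # references -- unless a cluster's own consensus matches a doublet profile,
  # in which case it is a doublet cluster and must not shelter its cells.
  # A WGD clone is *always* nearer the founder+2 doublet profile than any
  # singlet (|2A - (A+2)| = |A - 2|), so profile geometry alone cannot
  # protect it; but a doublet containing a diploid genome has both alleles
  # >= 1 everywhere and therefore no LOH, whereas a genuine clone inherits
  # its founder's LOH. Population-sized candidates with consensus LOH are
  # kept as clones.
  singlet_refs <- list()
  other_cls <- setdiff(tumor_cls, baseline_cls)
  if (length(other_cls)) {
    cand <- baseline_profiles(agg, asn, other_cls)
    dbl <- synthesize_doublet_profiles(bl)
    keep <- vapply(other_cls, function(cl) {
      p <- cand[[as.character(cl)]]
      d_dbl <- min(vapply(dbl, function(r) mean(abs(p - r)), 0))
      d_sing <- min(mean(abs(p - 2)),
                    vapply(bl, function(r) mean(abs(p - r)), 0))
      doublet_like <- d_dbl < d_sing && d_sing - d_dbl > config$doublet_margin
      if (doublet_like && !is.null(allele)) {
        bcs <- intersect(names(asn)[asn == cl], rownames(allele$a_cn))
        if (length(bcs) >= config$min_clone_cells) {
          cons <- allele_consensus(allele, bcs)
          loh_mask <- pmin(cons$a, cons$b) == 0 & (cons$a + cons$b) > 0
          if (nrow(mask_runs(loh_mask, allele$genome,
                             config$min_loh_run)) > 0) {
            doublet_like <- FALSE
          }
        }
      }
      !doublet_like
    }, FALSE)
    singlet_refs <- cand[keep]
  }
  dres <- classify_doublets(agg, bl, singlets = singlet_refs,
                            margin = config$doublet_margin,
                            barcodes = active_barcodes(cells))
  cells <- set_status(cells, cells$barcode %in%
                        dres$barcode[dres$is_doublet], "doublet")
  wgd_exempt_bc <- names(asn)[asn %in% tumor_cls[cluster_wgd]]
  art <- odd_cn_filter(agg, exempt = c(dip_bc, wgd_exempt_bc),
                       barcodes = active_barcodes(cells))
  cells <- set_status(cells, cells$barcode %in% names(art)[art], "artifact")
  note("doublet_artifact", n_doublet = sum(cells$status == "doublet"),
       n_artifact = sum(cells$status == "artifact"))

  ## 7. final clustering + subclustering
  act <- active_barcodes(cells)
  agg_act <- subset_cells(agg, act)
  cl2 <- ml_cluster(agg_act, k_max = config$k_max, seed = config$seed)
  sub <- subcluster(cl2, agg_act, k_max = config$k_max, seed = config$seed)
  i <- match(names(cl2$assignments), cells$barcode)
  cells$cluster[i] <- cl2$assignments
  cells$subcluster[i] <- sub$labels
  dip_cl2 <- identify_diploid_cluster(cl2, agg,
                                      max_dev = config$diploid_max_dev)
  note("clustering_final", k = cl2$selected_k,
       n_subclusters = length(unique(sub$labels)))

  ## pseudodiploid flagging within the final diploid cluster
  dip_bc2 <- names(cl2$assignments)[cl2$assignments == dip_cl2]
  tum_bc2 <- setdiff(act, dip_bc2)
  pseudo <- NULL
  if (length(dip_bc2) && length(tum_bc2)) {
    tumor_cons <- consensus_profile(agg, tum_bc2)
    gain_bins <- which(tumor_cons > 2.5)
    pseudo <- detect_pseudodiploid(agg, dip_bc2, gain_bins,
                                   min_bins = config$pseudodiploid_min_bins,
                                   dev = config$pseudodiploid_dev)
    cells <- set_status(cells, cells$barcode %in%
                          pseudo$barcode[pseudo$pseudodiploid],
                        "pseudodiploid")
  }
  note("pseudodiploid", n = sum(cells$status == "pseudodiploid"))

  ## 8. allele statistics on retained cells
  loh <- mirrored <- NULL
  if (!is.null(allele)) {
    keep <- intersect(act, rownames(allele$a_cn))
    al <- allele_cn_matrix(allele$a_cn[keep, , drop = FALSE],
                           allele$b_cn[keep, , drop = FALSE], allele$genome)
    asn2 <- cl2$assignments[keep]
    loh <- call_loh(al, min_run = config$min_loh_run,
                    assignments = asn2, consensus = config$consensus)
    tum_cls2 <- setdiff(sort(unique(asn2)), dip_cl2)
    if (length(tum_cls2) >= 2L) {
      prs <- utils::combn(tum_cls2, 2L)
      mirrored <- do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
        c1 <- allele_consensus(al, names(asn2)[asn2 == prs[1L, j]])
        c2 <- allele_consensus(al, names(asn2)[asn2 == prs[2L, j]])
        r <- detect_mirrored_imbalance(c1, c2, al$genome,
                                       min_run = config$min_loh_run)
        if (nrow(r)) cbind(cluster1 = prs[1L, j], cluster2 = prs[2L, j], r)
      }))
    }
    note("allele", n_loh_segments = nrow(loh$segments),
         n_mirrored = if (is.null(mirrored)) 0L else nrow(mirrored))
  }

  ## 9. subcluster-level phylogeny rooted at the diploid outgroup
  tree <- NULL
  sub_labels <- sub$labels
  if (length(unique(sub_labels)) >= 3L) {
    prof <- do.call(rbind, lapply(split(names(sub_labels), sub_labels),
                                  function(bcs) colMeans(cn_f$cn[bcs, , drop = FALSE],
                                                         na.rm = TRUE)))
    dmat <- cn_distance_matrix(prof, metric = "manhattan")
    outg <- sprintf("%d.1", dip_cl2)
    if (!outg %in% rownames(prof)) outg <- NULL
    tree <- bme_tree(dmat, outgroup = outg)
  }

  params <- unclass(config)
  report <- if (!is.null(out_dir)) {
    write_report(cells, params = params, dir = out_dir,
                 extra = list(stages = log))
  } else {
    NULL
  }
  structure(list(
    cells = cells, log = log, config = config,
    clustering = cl2, subclusters = sub, first_clustering = cl1,
    diploid_cluster = dip_cl2, baselines = bl,
    aggregated = agg, filtered = cn_f,
    pseudodiploid = pseudo, wgd = wgd, loh = loh, mirrored = mirrored,
    tree = tree, report = report
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  print(table(x$cells$status))
  cat(sprintf("final k = %d, diploid cluster = %d\n",
              x$clustering$selected_k, x$diploid_cluster))
  invisible(x)
}
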