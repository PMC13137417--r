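# select k from an information-criterion curve: zero-WSS shortcut, then
# elbow by maximal distance below the endpoint chord, then arg-min
.select_k <- function(ks, crit, wss) {
  ok <- which(!is.na(wss))
  if (!length(ok)) stop("ml_cluster: no k could be evaluated")
  tol <- max(wss[ok][1L] * 1e-10, 1e-12)
  zero <- ok[wss[ok] <= tol]
  if (length(zero)) return(ks[zero[1L]])
  if (length(ok) == 1L) return(ks[ok])
  k_ok <- ks[ok]; c_ok <- crit[ok]
  m <- length(ok)
  chord <- c_ok[1L] + (c_ok[m] - c_ok[1L]) * (k_ok - k_ok[1L]) / (k_ok[m] - k_ok[1L])
  below <- chord - c_ok
  if (max(below) > 0) {
    cand <- which(below >= 0.95 * max(below))  # smallest k near the elbow
    return(k_ok[cand[1L]])
  }
  k_ok[which.min(c_ok)]
}

#' Maximum-likelihood clustering of aggregated CN profiles
#'
#' Mirrors the find-clusters strategy standard in genetic clustering of CN
#' profiles: center/scale the aggregated mean-ploidy matrix, reduce by PCA
#' (components kept up to `var_explained` cumulative variance, capped at
#' `pc_cap` and n-1), run k-means for every k up to `k_max` with `nstart`
#' restarts, and score each solution by information criteria computed from
#' the within-group sum of squares:
#' `AIC(k) = n * ln(WSS(k)/n) + 2k`, `BIC(k) = n * ln(WSS(k)/n) + k * ln(n)`.
#'
#' k is selected from the AIC curve. When some k reaches (numerically) zero
#' WSS the smallest such k is taken — the data are then exactly k point
#' clusters. Otherwise the curve's elbow is selected: the smallest k whose
#' AIC lies maximally below the chord joining the curve's endpoints, the
#' automatic version of reading the bend off the criterion plot that is
#' standard for this clustering strategy. A raw arg-min is used only when
#' the curve has no bend below the chord. (On profiles whose within-clone
#' spread is small relative to between-clone distances, `n ln WSS` keeps
#' rewarding splits of pure noise by more than the +2 penalty all the way
#' to `k_max`, so a literal arg-min overclusters; the elbow is where the
#' criterion stops improving materially.) BIC is evaluated on the same WSS
#' and reported alongside (`selected_k_bic`); it tends to undercluster
#' heterogeneous tumor populations, which is why AIC drives the choice.
#'
#' Missing aggregated values are imputed to the cell's own mean ploidy
#' before PCA (complete data is required; imputed entries carry no signal).
#'
#' @param m an aggregated [cn_matrix()] with >= 2 cells.
#' @param k_max largest number of clusters tried.
#' @param var_explained cumulative variance retained by PCA.
#' @param pc_cap hard cap on retained components.
#' @param nstart k-means restarts per k.
#' @param seed integer seed (clustering is deterministic given it).
#' @return list of class `clustering_result`: `criteria` (per-k WSS/AIC/
#'   BIC), `selected_k`, `assignments` (named integer vector), `pc_scores`,
#'   `centers`, and the PCA transform used.
#' @export
ml_cluster <- function(m, k_max = 20L, var_explained = 0.95, pc_cap = 50L,
                       nstart = 10L, seed = 1L) {
  x <- m$cn
  n <- nrow(x)
  if (n < 2L) stop("ml_cluster: need >= 2 cells")
  # impute missing aggregated bins to the cell's mean ploidy
  if (anyNA(x)) {
    mp <- rowMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mp[idx[, 1L]]
  }
  sds <- apply(x, 2L, stats::sd)
  x_sc <- scale(x, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  pca <- stats::prcomp(x_sc, center = FALSE, scale. = FALSE)
  ev <- pca$sdev^2
  if (sum(ev) == 0) {
    n_pc <- 1L
  } else {
    n_pc <- which(cumsum(ev) / sum(ev) >= var_explained)[1L]
  }
  n_pc <- min(n_pc, pc_cap, n - 1L, ncol(pca$x))
  n_pc <- max(n_pc, 1L)
  scores <- pca$x[, seq_len(n_pc), drop = FALSE]

  set.seed(seed)
  ks <- seq_len(k_max)
  wss <- rep(NA_real_, k_max)
  fits <- vector("list", k_max)
  tot_center <- colMeans(scores)
  km <- function(centers) {
    tryCatch(
      suppressWarnings(
        stats::kmeans(scores, centers = centers, nstart = if (length(centers) == 1L) nstart else 1L,
                      iter.max = 100L)
      ),
      error = function(e) NULL
    )
  }
  for (k in ks) {
    if (k > n) next
    if (k == 1L) {
      wss[k] <- sum(sweep(scores, 2L, tot_center)^2)
      fits[[k]] <- list(cluster = rep(1L, n),
                        centers = matrix(tot_center, 1L, ncol(scores)))
      next
    }
    fit <- km(k)  # random restarts
    # cascade start: previous best centers plus the farthest point, which
    # makes WSS(k) monotone non-increasing and finds rare-cell clusters
    # that random restarts miss
    prev <- fits[[k - 1L]]
    if (!is.null(prev)) {
      cen <- prev$centers
      resid <- rowSums((scores - cen[prev$cluster, , drop = FALSE])^2)
      cand <- rbind(cen, scores[which.max(resid), ])
      if (!anyDuplicated(cand)) {
        fit2 <- km(cand)
        if (!is.null(fit2) && (is.null(fit) || fit2$tot.withinss < fit$tot.withinss)) {
          fit <- fit2
        }
      }
    }
    if (is.null(fit)) next  # e.g. more centers than distinct points
    wss[k] <- fit$tot.withinss
    fits[[k]] <- fit
  }
  aic <- n * log(wss / n) + 2 * ks
  bic <- n * log(wss / n) + ks * log(n)
  selected_k <- .select_k(ks, aic, wss)
  selected_k_bic <- .select_k(ks, bic, wss)
  assign_raw <- fits[[selected_k]]$cluster
  # renumber clusters by order of first appearance for stable labels
  relab <- match(assign_raw, unique(assign_raw))
  names(relab) <- rownames(x)
  structure(list(
    k_max = k_max,
    criteria = data.frame(k = ks, wss = wss, aic = aic, bic = bic),
    selected_k = selected_k,
    selected_k_bic = selected_k_bic,
    assignments = relab,
    pc_scores = scores,
    centers = fits[[selected_k]]$centers[unique(assign_raw), , drop = FALSE],
    pca = list(rotation = pca$rotation[, seq_len(n_pc), drop = FALSE],
               center = attr(x_sc, "scaled:center"),
               scale = attr(x_sc, "scaled:scale")),
    n_pc = n_pc,
    seed = seed
  ), class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result: selected k = %d (AIC), %d cells, %d PCs\n",
              x$selected_k, length(x$assignments), x$n_pc))
  print(table(x$assignments))
  invisible(x)
}

#' Subcluster each cluster by a second clustering round
#'
#' Cells of each cluster are re-clustered with [ml_cluster()] under the same
#' settings; subcluster labels take the conventional `"<cluster>.<sub>"`
#' form (e.g. `"1.2"`). Clusters with fewer than 3 cells are kept as a
#' single subcluster.
#'
#' @param result a `clustering_result`.
#' @param m the aggregated [cn_matrix()] the result was computed on.
#' @param ... passed through to [ml_cluster()].
#' @return list: `labels` (named character vector of `"c.s"` labels) and
#'   `per_cluster` (the child `clustering_result`s).
#' @export
subcluster <- function(result, m, ...) {
  labels <- character(length(result$assignments))
  names(labels) <- names(result$assignments)
  per_cluster <- list()
  for (cl in sort(unique(result$assignments))) {
    bcs <- names(result$assignments)[result$assignments == cl]
    if (length(bcs) < 3L) {
      labels[bcs] <- sprintf("%d.1", cl)
      next
    }
    sub <- ml_cluster(subset_cells(m, bcs), ...)
    labels[bcs] <- sprintf("%d.%d", cl, sub$assignments[bcs])
    per_cluster[[as.character(cl)]] <- sub
  }
  list(labels = labels, per_cluster = per_cluster)
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Linear discriminant functions computed on the PCA-reduced CN profiles,
#' to display between-cluster structure. The generalized eigenproblem
#' between/within is solved on the retained components; when the
#' within-group scatter is singular it is ridge-regularized
#' (`lambda = 1e-6` times its mean diagonal) with a warning. Discriminant
#' loadings are back-projected to bins through the PCA rotation.
#'
#' @param m an aggregated [cn_matrix()].
#' @param labels named cluster labels covering the matrix's barcodes.
#' @param var_explained,pc_cap PCA retention as in [ml_cluster()].
#' @return list of class `dapc_result`: `coords` (cells x functions),
#'   `loadings` (bins x functions), `eigenvalues`, `groups`.
#' @export
discriminant_analysis <- function(m, labels, var_explained = 0.95,
                                  pc_cap = 50L) {
  labels <- labels[rownames(m$cn)]
  grp <- factor(labels)
  if (nlevels(grp) < 2L) stop("discriminant_analysis: need >= 2 groups")
  if (any(table(grp) < 2L)) stop("discriminant_analysis: each group needs >= 2 cells")
  x <- m$cn
  if (anyNA(x)) {
    mp <- rowMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mp[idx[, 1L]]
  }
  sds <- apply(x, 2L, stats::sd)
  x_sc <- scale(x, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  pca <- stats::prcomp(x_sc, center = FALSE, scale. = FALSE)
  ev <- pca$sdev^2
  n_pc <- if (sum(ev) > 0) which(cumsum(ev) / sum(ev) >= var_explained)[1L] else 1L
  n_pc <- max(1L, min(n_pc, pc_cap, nrow(x) - 1L))
  s <- pca$x[, seq_len(n_pc), drop = FALSE]

  mu <- colMeans(s)
  W <- matrix(0, n_pc, n_pc)
  B <- matrix(0, n_pc, n_pc)
  for (g in levels(grp)) {
    sg <- s[grp == g, , drop = FALSE]
    mg <- colMeans(sg)
    W <- W + crossprod(sweep(sg, 2L, mg))
    B <- B + nrow(sg) * tcrossprod(mg - mu)
  }
  Winv <- tryCatch({
    if (rcond(W) < 1e-12) stop("singular")
    solve(W)
  }, error = function(e) {
    warning("discriminant_analysis: singular within-group scatter; ridge-regularized")
    solve(W + diag(1e-6 * max(mean(diag(W)), 1), n_pc))
  })
  eg <- eigen(Winv %*% B)
  n_df <- min(nlevels(grp) - 1L, n_pc)
  vec <- Re(eg$vectors[, seq_len(n_df), drop = FALSE])
  val <- Re(eg$values[seq_len(n_df)])
  coords <- s %*% vec
  colnames(coords) <- paste0("DF", seq_len(n_df))
  loadings <- pca$rotation[, seq_len(n_pc), drop = FALSE] %*% vec
  colnames(loadings) <- colnames(coords)
  rownames(loadings) <- colnames(m$cn)
  structure(list(coords = coords, loadings = loadings,
                 eigenvalues = val, groups = grp),
            class = "dapc_result")
}

#' Identify the diploid cluster
#'
#' Returns the cluster whose cells' mean absolute deviation from CN 2 is
#' smallest; errors if even that cluster deviates by more than `max_dev`
#' mean copies (no diploid population present).
#'
#' @param result a `clustering_result`.
#' @param m the aggregated [cn_matrix()].
#' @param max_dev largest acceptable mean |CN - 2| for a diploid cluster.
#' @return the diploid cluster id (integer).
#' @export
identify_diploid_cluster <- function(result, m, max_dev = 0.25) {
  devs <- vapply(sort(unique(result$assignments)), function(cl) {
    bcs <- names(result$assignments)[result$assignments == cl]
    mean(abs(m$cn[bcs, , drop = FALSE] - 2), na.rm = TRUE)
  }, 0)
  names(devs) <- sort(unique(result$assignments))
  best <- which.min(devs)
  if (devs[best] > max_dev) {
    stop(sprintf("no diploid cluster: smallest mean |CN-2| is %.3f > %.3f",
                 devs[best], max_dev))
  }
  as.integer(names(devs)[best])
}

#' Flag pseudodiploid cells within the diploid cluster
#'
#' A diploid-cluster cell is called pseudodiploid when at least `min_bins`
#' aggregated bins deviate from CN 2 by more than `dev` copies — sparse,
#' low-amplitude gains in an otherwise diploid profile. Each flagged cell's
#' gained bins are scored by Jaccard overlap against the bins gained in the
#' tumor consensus, quantifying whether its gains sit at sites further
#' amplified in the malignant clone (the premalignant-cell signature).
#'
#' @param m aggregated [cn_matrix()].
#' @param diploid_barcodes barcodes of the diploid cluster.
#' @param tumor_gain_bins integer indices of aggregated bins gained in the
#'   tumor consensus profile.
#' @param min_bins minimum deviating bins to flag a cell.
#' @param dev deviation (copies) for a bin to count as non-diploid.
#' @return data.frame: barcode, n_dev, overlap (Jaccard), pseudodiploid.
#' @export
detect_pseudodiploid <- function(m, diploid_barcodes, tumor_gain_bins,
                                 min_bins = 3L, dev = 0.5) {
  x <- m$cn[diploid_barcodes, , drop = FALSE]
  out <- lapply(seq_along(diploid_barcodes), function(i) {
    v <- x[i, ]
    devia <- which(!is.na(v) & abs(v - 2) > dev)
    gained <- which(!is.na(v) & v - 2 > dev)
    un <- union(gained, tumor_gain_bins)
    ov <- if (length(un)) length(intersect(gained, tumor_gain_bins)) / length(un) else 0
    data.frame(barcode = diploid_barcodes[i], n_dev = length(devia),
               overlap = ov, pseudodiploid = length(devia) >= min_bins,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-bin consensus profile over a set of cells
#' @param m a [cn_matrix()].
#' @param cells barcodes to summarize.
#' @param fun summary function (default median, robust to outlier cells).
#' @return numeric vector over the matrix's bins.
#' @export
consensus_profile <- function(m, cells, fun = stats::median) {
  apply(m$cn[cells, , drop = FALSE], 2L, fun, na.rm = TRUE)
}
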