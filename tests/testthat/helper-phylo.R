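# independent brute-force oracle for balanced minimum evolution:
# exhaustive topology enumeration (phangorn::allTrees) scored by a
# from-scratch Pauplin length (BFS path counts on the edge list)

oracle_pauplin <- function(d, tree) {
  n_tip <- length(tree$tip.label)
  edge <- tree$edge
  n_node <- max(edge)
  adj <- vector("list", n_node)
  for (i in seq_len(nrow(edge))) {
    a <- edge[i, 1L]; b <- edge[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  # BFS from each tip -> number of edges to every other tip
  total <- 0
  for (i in seq_len(n_tip - 1L)) {
    dist <- rep(NA_integer_, n_node)
    dist[i] <- 0L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    for (j in (i + 1L):n_tip) {
      total <- total +
        d[tree$tip.label[i], tree$tip.label[j]] * 2^(1 - dist[j])
    }
  }
  total
}

oracle_best_balanced <- function(d) {
  labs <- rownames(d)
  trees <- phangorn::allTrees(length(labs), rooted = FALSE, tip.label = labs)
  lens <- vapply(trees, oracle_pauplin, 0, d = d)
  list(min_length = min(lens), tree = trees[[which.min(lens)]])
}

# metric matrix from random points (triangle inequality guaranteed)
random_metric_matrix <- function(n, seed) {
  set.seed(seed)
  pts <- matrix(stats::rnorm(n * 5), n)
  d <- as.matrix(stats::dist(pts))
  dimnames(d) <- list(paste0("t", seq_len(n)), paste0("t", seq_len(n)))
  d
}

# additive matrix from a random tree with known topology
additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.5, 2)
  list(d = stats::cophenetic(tr)[tr$tip.label, tr$tip.label], tree = tr)
}
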