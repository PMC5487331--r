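# Fixtures are generated in code; nothing is stored on disk beyond the
# karate club edge list shipped in inst/extdata.

# uniform random label ensemble (no structure), node ids n01, n02, ...
random_ensemble <- function(n_nodes, runs, max_labels = 4, seed = 1) {
  set.seed(seed)
  labels <- matrix(as.character(sample.int(max_labels, n_nodes * runs,
                                           replace = TRUE)),
                   n_nodes, runs)
  rownames(labels) <- sprintf("n%02d", seq_len(n_nodes))
  partition_ensemble(labels)
}

# the hand-counted 2-run toy over nodes 1..3: run1 = {1,2 | 3},
# run2 = {1 | 2,3}; p(1,2) = p(2,3) = 1/2, p(1,3) = 0
toy_ensemble <- function() {
  partition_ensemble(list(c(`1` = "a", `2` = "a", `3` = "b"),
                          c(`1` = "a", `2` = "b", `3` = "b")))
}

# two disconnected k-cliques; Louvain at gamma = 1 recovers them exactly
two_cliques_graph <- function(k = 5) {
  g <- igraph::disjoint_union(igraph::make_full_graph(k),
                              igraph::make_full_graph(k))
  igraph::V(g)$name <- sprintf("v%02d", seq_len(2 * k))
  g
}

# bootstrap standard error of one node's versatility under run resampling;
# works from the node's co-membership indicators only, so it stays cheap
# at 10^4 runs
indicator_versatility_se <- function(ensemble, node, n_boot = 200,
                                     seed = 1) {
  l <- ensemble$labels
  r <- ncol(l)
  m <- (l == matrix(l[node, ], nrow(l), r, byrow = TRUE)) * 1
  set.seed(seed)
  w <- vapply(seq_len(n_boot),
              function(b) tabulate(sample.int(r, r, replace = TRUE), r),
              integer(r))
  p <- (m %*% w) / r
  p[node, ] <- 1
  v <- colSums(sinpi(p)) / colSums(p)
  sd(v)
}

# random weighted directed graph with planted groups, as an edge-list file
write_random_directed_tsv <- function(path, n_groups = 3, per_group = 8,
                                      seed = 99) {
  set.seed(seed)
  n <- n_groups * per_group
  grp <- rep(seq_len(n_groups), each = per_group)
  lines <- character(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      pr <- if (grp[i] == grp[j]) 0.6 else 0.05
      if (runif(1) < pr) {
        lines <- c(lines, sprintf("r%02d\tr%02d\t%.3f", i, j, runif(1, 0.5, 2)))
      }
    }
  }
  writeLines(lines, path)
  path
}
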