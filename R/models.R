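# Idealised model networks: the n-split and n-clusters cases.
#
# Both models describe how an *idealised* stochastic community-detection
# algorithm would behave, so each comes in three forms: a partition sampler
# (the source of truth), an exact closed-form versatility oracle for the
# indicator node, and a concrete graph constructor. No claim is made that
# any real algorithm reproduces the samplers; Louvain, for instance, is
# deterministic on the n-split graph unless node order is randomised.
#
# Node id scheme (stable, shared by samplers and graph builders):
#   indicator node          "ind"          (n-split only)
#   cluster k, member m     "c<k>_<m>"     k = 1..n, m = 1..c
#   extra node j            "x<j>"         j = 1..x
# In the n-clusters model the indicator cluster is cluster 1 and the
# indicator node is "c1_1".

#' Specify an n-split model network
#'
#' A single indicator node has one connection to each of `n` identical
#' tightly-interconnected clusters of `c` nodes; on each run of the
#' idealised algorithm the indicator joins exactly one cluster's community,
#' each with probability 1/n. `x` extra nodes enlarge the network without
#' affecting the decomposition; total size is `n * c + x + 1`.
#'
#' @param n number of clusters (>= 1).
#' @param c nodes per cluster (>= 1).
#' @param x extra nodes (>= 0).
#' @return Object of class `nsplit_spec`.
#' @export
nsplit_spec <- function(n, c, x = 0) {
  stopifnot(n >= 1, c >= 1, x >= 0,
            n == round(n), c == round(c), x == round(x))
  structure(list(n = as.integer(n), c = as.integer(c), x = as.integer(x)),
            class = "nsplit_spec")
}

#' Specify an n-clusters model network
#'
#' `n` identical clusters of `c` nodes, tightly connected within and loosely
#' between. On each run each of the other `n - 1` clusters independently
#' merges into the indicator cluster's community with probability `p`
#' (star-merge around the indicator cluster, so the pairwise co-assignment
#' probability between the indicator cluster and every other cluster is
#' exactly `p`). Total size is `n * c + x`.
#'
#' @param n number of clusters (>= 1).
#' @param c nodes per cluster (>= 1).
#' @param x extra nodes (>= 0).
#' @param p merge probability in \[0, 1\].
#' @return Object of class `ncluster_spec`.
#' @export
ncluster_spec <- function(n, c, x = 0, p) {
  stopifnot(n >= 1, c >= 1, x >= 0, p >= 0, p <= 1,
            n == round(n), c == round(c), x == round(x))
  structure(list(n = as.integer(n), c = as.integer(c), x = as.integer(x),
                 p = as.numeric(p)),
            class = "ncluster_spec")
}

.model_ids <- function(spec) {
  cl <- as.vector(outer(seq_len(spec$c), seq_len(spec$n),
                        function(m, k) sprintf("c%d_%d", k, m)))
  ex <- if (spec$x > 0) sprintf("x%d", seq_len(spec$x)) else character(0)
  if (inherits(spec, "nsplit_spec")) c("ind", cl, ex) else c(cl, ex)
}

#' Sample one idealised partition of the n-split model
#'
#' Each cluster is its own community and each extra node its own singleton;
#' the indicator node joins one cluster chosen uniformly at random.
#'
#' @param spec an [nsplit_spec()].
#' @param seed optional integer seed (`set.seed` is called when given).
#' @return Community labels named by node id.
#' @export
sample_nsplit_partition <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "nsplit_spec"))
  if (!is.null(seed)) set.seed(seed)
  pick <- sample.int(spec$n, 1L)
  labels <- c(sprintf("k%d", pick),                       # indicator
              rep(sprintf("k%d", seq_len(spec$n)), each = spec$c),
              if (spec$x > 0) sprintf("s%d", seq_len(spec$x)))
  setNames(labels, .model_ids(spec))
}

#' Sample one idealised partition of the n-clusters model
#'
#' Cluster 1 is the indicator cluster; each of the other clusters merges
#' into its community independently with probability `p`. Unmerged clusters
#' and extra nodes keep their own communities.
#'
#' @param spec an [ncluster_spec()].
#' @param seed optional integer seed.
#' @return Community labels named by node id.
#' @export
sample_ncluster_partition <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "ncluster_spec"))
  if (!is.null(seed)) set.seed(seed)
  merged <- if (spec$n > 1) runif(spec$n - 1) < spec$p else logical(0)
  comm <- c("k1", ifelse(merged, "k1", sprintf("k%d", seq_len(spec$n)[-1])))
  labels <- c(rep(comm, each = spec$c),
              if (spec$x > 0) sprintf("s%d", seq_len(spec$x)))
  setNames(labels, .model_ids(spec))
}

#' Sample a whole ensemble from a model specification
#'
#' Convenience wrapper: `runs` independent idealised partitions with seeds
#' derived deterministically from `base_seed` via [derive_seed()].
#'
#' @param spec an [nsplit_spec()] or [ncluster_spec()].
#' @param runs number of partitions.
#' @param base_seed integer seed for the whole ensemble.
#' @return A [partition_ensemble()].
#' @export
sample_model_ensemble <- function(spec, runs, base_seed = 1) {
  sampler <- if (inherits(spec, "nsplit_spec")) {
    sample_nsplit_partition
  } else {
    sample_ncluster_partition
  }
  ids <- .model_ids(spec)
  labels <- matrix(NA_character_, length(ids), runs,
                   dimnames = list(ids, NULL))
  for (k in seq_len(runs)) {
    labels[, k] <- sampler(spec, seed = derive_seed(base_seed, 0L, k))
  }
  partition_ensemble(labels,
                     provenance = sprintf("idealised %s sampler, base_seed=%d",
                                          class(spec), base_seed))
}

#' Exact versatility of the n-split indicator node
#'
#' Closed form of the estimator applied to the model's expected association
#' matrix. For community-size normalisation (codes ending in C),
#' \deqn{V = \frac{n\,c\,f(1/n)}{1 + c},} and for network-size
#' normalisation the denominator is instead `n*c + x + 1`. With the sine
#' transform this is 0 at n = 1, increases in both n and c, and tends to 2
#' for n = 2 as c grows — the landmark value for a node split evenly
#' between two large communities.
#'
#' @param spec an [nsplit_spec()].
#' @param estimator one of [estimator_codes()].
#' @return A single number.
#' @export
#' @examples
#' analytic_versatility_nsplit(nsplit_spec(2, 3))  # 1.5
analytic_versatility_nsplit <- function(spec, estimator = "SC") {
  stopifnot(inherits(spec, "nsplit_spec"))
  estimator <- .check_estimator(estimator)
  f <- .transform_fun(substr(estimator, 1, 1))
  num <- spec$n * spec$c * f(1 / spec$n)
  den <- if (substr(estimator, 2, 2) == "C") 1 + spec$c
         else spec$n * spec$c + spec$x + 1
  num / den
}

#' Exact versatility of a node in the indicator cluster (n-clusters model)
#'
#' For community-size normalisation,
#' \deqn{V = \frac{(n-1)\,f(p)}{1 + (n-1)\,p},} independent of the cluster
#' size c; for network-size normalisation the numerator `(n-1) c f(p)` is
#' divided by `n*c + x`. Zero at p = 0 and p = 1, increasing in n.
#'
#' @param spec an [ncluster_spec()].
#' @param estimator one of [estimator_codes()].
#' @return A single number.
#' @export
analytic_versatility_ncluster <- function(spec, estimator = "SC") {
  stopifnot(inherits(spec, "ncluster_spec"))
  estimator <- .check_estimator(estimator)
  f <- .transform_fun(substr(estimator, 1, 1))
  num <- (spec$n - 1) * spec$c * f(spec$p)
  den <- if (substr(estimator, 2, 2) == "C") {
    spec$c * (1 + (spec$n - 1) * spec$p)
  } else {
    spec$n * spec$c + spec$x
  }
  num / den
}

#' Expected association matrix of a model network
#'
#' The idealised algorithm's exact co-assignment probabilities, useful as a
#' ground-truth reference for the Monte-Carlo pipeline. `run_count` is `NA`
#' (expected values, not sample frequencies).
#'
#' @param spec an [nsplit_spec()] or [ncluster_spec()].
#' @return An [association_matrix()].
#' @export
idealised_association <- function(spec) {
  ids <- .model_ids(spec)
  p <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  cluster_of <- function(id) as.integer(sub("^c(\\d+)_.*$", "\\1", id))
  is_cl <- grepl("^c", ids)
  k <- ifelse(is_cl, NA_integer_, NA_integer_)
  k[is_cl] <- cluster_of(ids[is_cl])
  same <- outer(k, k, "==")
  same[is.na(same)] <- FALSE
  p[same] <- 1
  if (inherits(spec, "nsplit_spec")) {
    p["ind", is_cl] <- 1 / spec$n
    p[is_cl, "ind"] <- 1 / spec$n
  } else {
    # indicator cluster co-assigns with any other cluster w.p. p; two
    # non-indicator clusters co-assign only via the star centre: p^2
    other <- is_cl & k != 1L
    ind_cl <- is_cl & k == 1L
    p[ind_cl, other] <- spec$p
    p[other, ind_cl] <- spec$p
    cross <- outer(k, k, function(a, b) !is.na(a) & !is.na(b) & a != b & a != 1 & b != 1)
    p[cross] <- spec$p^2
  }
  diag(p) <- 1
  association_matrix(p, run_count = NA_integer_)
}

#' Build the n-split graph
#'
#' Each cluster is a c-clique; the indicator node has exactly one edge to
#' the lowest-indexed node of each cluster; extra nodes form an isolated
#' x-clique so they do not disturb modularity-style detection.
#'
#' @param spec an [nsplit_spec()].
#' @return An undirected, unweighted igraph with named vertices.
#' @export
build_nsplit_graph <- function(spec) {
  stopifnot(inherits(spec, "nsplit_spec"))
  edges <- character(0)
  for (k in seq_len(spec$n)) {
    members <- sprintf("c%d_%d", k, seq_len(spec$c))
    edges <- c(edges, .clique_edges(members), "ind", members[1L])
  }
  if (spec$x > 1) {
    edges <- c(edges, .clique_edges(sprintf("x%d", seq_len(spec$x))))
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(.model_ids(spec)),
                            name = .model_ids(spec))
  igraph::add_edges(g, edges)
}

#' Build the n-clusters graph
#'
#' `n` unit-weight c-cliques; one inter-cluster edge of weight
#' `inter_weight` between the lowest-indexed representatives of every pair
#' of clusters (fully symmetric); extra nodes form an isolated clique.
#'
#' @param spec an [ncluster_spec()].
#' @param inter_weight non-negative weight of the inter-cluster edges.
#' @return An undirected, weighted igraph with named vertices.
#' @export
build_ncluster_graph <- function(spec, inter_weight = 0.1) {
  stopifnot(inherits(spec, "ncluster_spec"), inter_weight >= 0)
  edges <- character(0)
  weights <- numeric(0)
  for (k in seq_len(spec$n)) {
    ce <- .clique_edges(sprintf("c%d_%d", k, seq_len(spec$c)))
    edges <- c(edges, ce)
    weights <- c(weights, rep(1, length(ce) / 2))
  }
  if (spec$n > 1 && inter_weight > 0) {
    for (a in seq_len(spec$n - 1)) {
      for (b in seq(a + 1, spec$n)) {
        edges <- c(edges, sprintf("c%d_1", a), sprintf("c%d_1", b))
        weights <- c(weights, inter_weight)
      }
    }
  }
  if (spec$x > 1) {
    ce <- .clique_edges(sprintf("x%d", seq_len(spec$x)))
    edges <- c(edges, ce)
    weights <- c(weights, rep(1, length(ce) / 2))
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(.model_ids(spec)),
                            name = .model_ids(spec))
  g <- igraph::add_edges(g, edges)
  igraph::E(g)$weight <- weights
  g
}

.clique_edges <- function(members) {
  if (length(members) < 2) return(character(0))
  pairs <- utils::combn(members, 2)
  as.vector(pairs)
}

#' Maximum attainable SC versatility in a network of given size
#'
#' Exhaustive search over all integer n-split configurations (n clusters of
#' c nodes, n*c <= network_size - 1) of the closed-form SC versatility of
#' the indicator node. The result is non-decreasing in network size and
#' strictly below \eqn{\pi}; the bound is approached only as the size grows
#' without limit.
#'
#' @param network_size total node count (>= 2).
#' @return A single number in \[0, \eqn{\pi}).
#' @export
max_versatility <- function(network_size) {
  stopifnot(network_size >= 2, network_size == round(network_size))
  budget <- network_size - 1
  n <- seq_len(budget)
  c <- budget %/% n
  max(n * c * sinpi(1 / n) / (1 + c))
}
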