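# Versatility estimators and the participation coefficient.
#
# An estimator is a two-letter code: a concave transform f applied to each
# co-assignment probability (S sine, E binary entropy, T triangle wave, all
# with f(0) = f(1) = 0 and f(1/2) = 1) and a normalisation g (U network
# size, C expected community size). "SC" is canonical versatility: for node
# j it is sum_i f(p_ij) / sum_i p_ij, both sums over all i including i = j.
# The self term adds 0 to the numerator and 1 to the denominator, so the
# denominator is the expected size (counting j) of j's community.

#' The six estimator codes
#'
#' @return Character vector `c("SU","EU","TU","SC","EC","TC")`. The first
#'   letter selects the transform (S sine, E entropy, T triangle), the
#'   second the normalisation (U network size, C mean community size).
#' @export
estimator_codes <- function() {
  c("SU", "EU", "TU", "SC", "EC", "TC")
}

# Transforms are exact at 0 and 1 (sinpi, and continuous extension for the
# entropy), so deterministic ensembles give versatility exactly 0.
.transform_fun <- function(code) {
  switch(code,
    S = function(x) sinpi(x),
    E = function(x) {
      y <- numeric(length(x))
      inner <- x > 0 & x < 1
      xi <- x[inner]
      y[inner] <- -xi * log2(xi) - (1 - xi) * log2(1 - xi)
      dim(y) <- dim(x)
      y
    },
    T = function(x) 2 * pmin(x, 1 - x),
    stop(sprintf("unknown transform '%s'", code)))
}

.check_estimator <- function(estimator) {
  estimator <- toupper(estimator)
  if (!estimator %in% estimator_codes()) {
    stop(sprintf("unknown estimator '%s'; valid codes: %s", estimator,
                 paste(estimator_codes(), collapse = ", ")))
  }
  estimator
}

#' Per-node versatility from an association matrix
#'
#' Versatility of node j measures how ambiguously the ensemble assigns j to
#' a community: 0 when every co-assignment probability involving j is 0 or
#' 1, maximal when probabilities sit at one half. It depends only on the
#' association matrix — never on the graph or on node degree.
#'
#' Under the default estimator `"SC"`,
#' \deqn{V(j) = \frac{\sum_i \sin(\pi p_{ij})}{\sum_i p_{ij}},}
#' with both sums over all nodes i (the i = j term contributes 0 above and
#' 1 below, making the denominator the expected size of j's community,
#' including j itself). SC values are non-negative and strictly below
#' \eqn{\pi}; the bound is approached only as the network grows without
#' limit, and a value of 2 marks a node split evenly between two large
#' equally-sized communities.
#'
#' @param assoc an [association_matrix()] (at least 2 nodes).
#' @param estimator one of [estimator_codes()]; default `"SC"`.
#' @return Object of class `versatility_result`: `node_ids`, named numeric
#'   `values`, `estimator`, `run_count`.
#' @export
#' @examples
#' pe <- partition_ensemble(list(c(`1` = "a", `2` = "a", `3` = "b"),
#'                               c(`1` = "a", `2` = "b", `3` = "b")))
#' versatility(accumulate(pe))$values
versatility <- function(assoc, estimator = "SC") {
  if (!inherits(assoc, "association_matrix")) {
    stop("`assoc` must be an association_matrix")
  }
  estimator <- .check_estimator(estimator)
  p <- assoc$p
  n <- nrow(p)
  if (n < 2L) stop("versatility needs at least 2 nodes")
  if (any(p < 0 | p > 1)) stop("association probabilities must lie in [0, 1]")
  f <- .transform_fun(substr(estimator, 1, 1))
  num <- colSums(f(p))
  den <- if (substr(estimator, 2, 2) == "C") colSums(p) else rep(n, n)
  structure(
    list(node_ids = assoc$node_ids,
         values = setNames(num / den, assoc$node_ids),
         estimator = estimator, run_count = assoc$run_count),
    class = "versatility_result")
}

#' @export
print.versatility_result <- function(x, ...) {
  cat(sprintf("Versatility (%s) over %d nodes%s\n", x$estimator,
              length(x$values),
              ifelse(is.na(x$run_count), "",
                     sprintf(", %d runs", x$run_count))))
  print(summary(x$values))
  invisible(x)
}

#' @export
as.data.frame.versatility_result <- function(x, ...) {
  data.frame(node = x$node_ids, versatility = unname(x$values),
             stringsAsFactors = FALSE)
}

#' Global mean versatility
#'
#' The arithmetic mean of per-node versatility; used as the objective that
#' [sweep_resolution()] minimises over the resolution parameter.
#'
#' @param result a `versatility_result` or a numeric vector of values.
#' @return A single number.
#' @export
mean_versatility <- function(result) {
  v <- if (inherits(result, "versatility_result")) result$values else result
  if (length(v) == 0L) stop("empty versatility result")
  mean(v)
}

#' Participation coefficient of each node
#'
#' The classical degree-based contrast to versatility: how evenly a node's
#' edge weight spreads over communities of one fixed partition,
#' \deqn{PC(i) = 1 - \sum_s (k_{i,s}/k_i)^2,}
#' where \eqn{k_i} is the (weighted) degree of i and \eqn{k_{i,s}} its
#' weight into community s. PC is 0 when all of i's edges stay inside one
#' community and approaches 1 when the weight is spread over many. Unlike
#' versatility it depends on the graph's edges and on a single partition.
#'
#' @param graph an igraph object (weights used when present; directed
#'   graphs use total in+out strength).
#' @param partition community labels named by node id, covering every
#'   vertex of `graph`.
#' @return Object of class `participation_result` with `node_ids` and named
#'   `values` in \[0, 1\]; isolated nodes get 0 by convention.
#' @export
participation_coefficient <- function(graph, partition) {
  ids <- igraph::V(graph)$name %||% as.character(seq_len(igraph::vcount(graph)))
  nm <- names(partition) %||% ids
  missing <- setdiff(ids, nm)
  if (length(missing) > 0L) {
    stop(sprintf("partition is missing graph node(s): %s",
                 paste(head(missing, 5), collapse = ", ")))
  }
  labels <- as.character(partition)[match(ids, nm)]
  a <- igraph::as_adjacency_matrix(
    graph, sparse = TRUE,
    attr = if ("weight" %in% igraph::edge_attr_names(graph)) "weight" else NULL)
  if (igraph::is_directed(graph)) a <- a + Matrix::t(a)
  memb <- Matrix::sparseMatrix(i = seq_along(ids),
                               j = match(labels, unique(labels)),
                               x = 1,
                               dims = c(length(ids), length(unique(labels))))
  w <- as.matrix(a %*% memb)     # weight from node i into community s
  k <- rowSums(w)
  pc <- 1 - rowSums((w / ifelse(k > 0, k, 1))^2)
  pc[k == 0] <- 0
  structure(list(node_ids = ids, values = setNames(pc, ids)),
            class = "participation_result")
}

#' @export
print.participation_result <- function(x, ...) {
  cat(sprintf("Participation coefficient over %d nodes\n", length(x$values)))
  print(summary(x$values))
  invisible(x)
}

#' @export
as.data.frame.participation_result <- function(x, ...) {
  data.frame(node = x$node_ids, participation = unname(x$values),
             stringsAsFactors = FALSE)
}
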