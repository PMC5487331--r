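# Partition ensembles and the association matrix.
#
# A "partition" is one run's assignment of every node to exactly one
# community: a vector of labels named by node id. Labels are opaque; only
# equality within a single run matters, and no alignment of labels across
# runs is ever attempted — the association matrix needs only the
# co-assignment indicator.

#' Bundle partitions from repeated algorithm runs into an ensemble
#'
#' All partitions must cover the same node set; they are stored column-wise
#' over a common node ordering taken from the first partition.
#'
#' @param partitions either a list of partitions (vectors of community
#'   labels named by node id; unnamed vectors are matched positionally), or
#'   a node-by-run matrix of labels with node ids as row names.
#' @param provenance free-text description of the generating algorithm, its
#'   parameters and seeds; carried along into downstream results.
#' @return An object of class `partition_ensemble` with elements `labels`
#'   (node-by-run character matrix), `node_ids`, `run_count`, `provenance`.
#' @seealso [accumulate()], [run_ensemble()]
#' @export
#' @examples
#' pe <- partition_ensemble(list(c(a = 1, b = 1, c = 2), c(a = 1, b = 2, c = 2)))
#' pe$run_count
partition_ensemble <- function(partitions, provenance = "") {
  if (is.matrix(partitions)) {
    labels <- matrix(as.character(partitions), nrow(partitions), ncol(partitions))
    rownames(labels) <- rownames(partitions) %||% as.character(seq_len(nrow(partitions)))
  } else if (is.list(partitions)) {
    if (length(partitions) == 0L) {
      stop("empty ensemble: at least one partition is required")
    }
    ref <- names(partitions[[1L]]) %||% as.character(seq_along(partitions[[1L]]))
    labels <- matrix(NA_character_, length(ref), length(partitions),
                     dimnames = list(ref, NULL))
    for (r in seq_along(partitions)) {
      p <- partitions[[r]]
      nm <- names(p) %||% as.character(seq_along(p))
      if (length(p) != length(ref) || !setequal(nm, ref)) {
        stop(sprintf("run %d covers a different node set than run 1", r))
      }
      labels[, r] <- as.character(p)[match(ref, nm)]
    }
  } else {
    stop("`partitions` must be a list of labelled vectors or a label matrix")
  }
  if (anyDuplicated(rownames(labels))) stop("node ids must be unique")
  if (anyNA(labels)) stop("partitions may not contain missing labels")
  colnames(labels) <- sprintf("run_%04d", seq_len(ncol(labels)))
  structure(
    list(labels = labels, node_ids = rownames(labels),
         run_count = ncol(labels), provenance = provenance),
    class = "partition_ensemble")
}

#' @export
print.partition_ensemble <- function(x, ...) {
  cat(sprintf("Partition ensemble: %d nodes x %d runs\n",
              length(x$node_ids), x$run_count))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Construct an association matrix object
#'
#' Low-level constructor; most users obtain association matrices from
#' [accumulate()]. Entry (i, j) is the sample probability that nodes i and j
#' were assigned to the same community across the ensemble. The diagonal is
#' fixed at 1: a node trivially shares a community with itself, which makes
#' the community-size normalisation in [versatility()] count the node
#' itself.
#'
#' @param p square numeric matrix of co-assignment probabilities in
#'   \[0, 1\], with node ids as dimnames.
#' @param run_count number of runs the probabilities were estimated from;
#'   `NA` for idealised (expected-value) matrices.
#' @return Object of class `association_matrix`.
#' @export
association_matrix <- function(p, run_count = NA_integer_) {
  if (!is.matrix(p) || nrow(p) != ncol(p)) stop("`p` must be a square matrix")
  if (is.null(rownames(p))) {
    dimnames(p) <- list(as.character(seq_len(nrow(p))),
                        as.character(seq_len(nrow(p))))
  }
  if (!identical(rownames(p), colnames(p))) stop("row and column ids differ")
  if (any(p < 0 | p > 1)) stop("association probabilities must lie in [0, 1]")
  if (max(abs(p - t(p))) > 1e-12) stop("association matrix must be symmetric")
  if (any(abs(diag(p) - 1) > 1e-12)) stop("association diagonal must equal 1")
  if (!is.na(run_count)) {
    counts <- p * run_count
    if (max(abs(counts - round(counts))) > 1e-6) {
      stop("off-diagonal entries must be multiples of 1/run_count")
    }
  }
  structure(list(p = p, node_ids = rownames(p), run_count = run_count),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("Association matrix: %d nodes, %s runs\n", length(x$node_ids),
              ifelse(is.na(x$run_count), "idealised (expected-value)",
                     as.character(x$run_count))))
  invisible(x)
}

# Sparse node-by-community incidence over all runs. Column k is one
# community of one run; tcrossprod of this matrix counts co-assignments.
# Returns S plus the run index owning each column (used by the bootstrap).
.coassign_sparse <- function(labels) {
  n <- nrow(labels)
  r <- ncol(labels)
  jj <- vector("list", r)
  ncomm <- integer(r)
  for (k in seq_len(r)) {
    f <- match(labels[, k], unique(labels[, k]))
    ncomm[k] <- max(f)
    jj[[k]] <- f
  }
  offsets <- c(0L, cumsum(ncomm))
  j <- unlist(jj, use.names = FALSE) +
    rep(offsets[seq_len(r)], each = n)
  s <- Matrix::sparseMatrix(i = rep(seq_len(n), times = r), j = j, x = 1,
                            dims = c(n, offsets[r + 1L]))
  list(S = s, run_of_col = rep(seq_len(r), times = ncomm))
}

#' Accumulate an ensemble into the association matrix
#'
#' Counts, for every pair of nodes, the number of runs in which the two
#' nodes share a community label, and divides once by the run count.
#' Integer counts are accumulated first, so the result is independent of
#' accumulation order.
#'
#' @param ensemble a [partition_ensemble()].
#' @return An [association_matrix()].
#' @export
#' @examples
#' pe <- partition_ensemble(list(c(`1` = "a", `2` = "a", `3` = "b"),
#'                               c(`1` = "a", `2` = "b", `3` = "b")))
#' accumulate(pe)$p
accumulate <- function(ensemble) {
  if (!inherits(ensemble, "partition_ensemble")) {
    stop("`ensemble` must be a partition_ensemble")
  }
  counts <- as.matrix(Matrix::tcrossprod(.coassign_sparse(ensemble$labels)$S))
  p <- counts / ensemble$run_count
  diag(p) <- 1
  dimnames(p) <- list(ensemble$node_ids, ensemble$node_ids)
  association_matrix(p, run_count = ensemble$run_count)
}

#' Accumulate partitions one at a time
#'
#' Identical result to [accumulate()] without materialising the ensemble:
#' memory is bounded by one node-by-node count matrix. Useful when the
#' partitions come from a long-running external process.
#'
#' @param partition_source a function that returns the next partition
#'   (labels named by node id) on each call and `NULL` when exhausted, or a
#'   list of partitions for convenience.
#' @return An [association_matrix()].
#' @export
accumulate_streaming <- function(partition_source) {
  if (is.list(partition_source)) {
    parts <- partition_source
    k <- 0L
    partition_source <- function() {
      if (k >= length(parts)) return(NULL)
      k <<- k + 1L
      parts[[k]]
    }
  }
  if (!is.function(partition_source)) {
    stop("`partition_source` must be a function or a list of partitions")
  }
  counts <- NULL
  ref <- NULL
  r <- 0L
  repeat {
    part <- partition_source()
    if (is.null(part)) break
    r <- r + 1L
    nm <- names(part) %||% as.character(seq_along(part))
    if (r == 1L) {
      ref <- nm
      counts <- matrix(0L, length(ref), length(ref), dimnames = list(ref, ref))
    } else if (length(part) != length(ref) || !setequal(nm, ref)) {
      stop(sprintf("run %d covers a different node set than run 1", r))
    }
    l <- as.character(part)[match(ref, nm)]
    counts <- counts + outer(l, l, "==")
  }
  if (r == 0L) stop("empty ensemble: at least one partition is required")
  p <- counts / r
  diag(p) <- 1
  association_matrix(p, run_count = r)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
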