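# Resolution-parameter sweep: seeded Louvain ensembles, the global mean
# versatility curve, and selection of optimal resolution values.

#' Deterministic seed derivation
#'
#' Every source of randomness in an ensemble or sweep draws its seed from
#' this function, so identical inputs give bit-identical results. The rule
#' is `(base_seed * 1000003 + gamma_index * 100003 + run) mod (2^31 - 1)`,
#' computed in double precision (exact for the sizes involved), which keeps
#' seeds distinct across grid points for ensembles of up to 100003 runs.
#'
#' @param base_seed user-facing integer seed.
#' @param gamma_index zero-based index of the grid point (0 for a single
#'   ensemble).
#' @param run one-based run number within the ensemble.
#' @return An integer seed in \[0, 2^31 - 1).
#' @export
derive_seed <- function(base_seed, gamma_index, run) {
  as.integer((as.numeric(base_seed) * 1000003 +
              as.numeric(gamma_index) * 100003 +
              as.numeric(run)) %% 2147483647)
}

#' One seeded Louvain run with a resolution parameter
#'
#' Greedy modularity maximisation of the quality
#' \deqn{Q_\gamma = \frac{1}{2m}\sum_{ij}\left[A_{ij} - \gamma\frac{k_i k_j}{2m}\right]\delta(c_i,c_j),}
#' with weighted degrees for weighted graphs. The node visitation order is
#' randomly permuted per seed — Louvain is otherwise biased by adjacency
#' order and can behave deterministically — so distinct seeds explore
#' distinct local optima while the same seed always returns the same
#' partition. Directed graphs are symmetrised to (A + t(A))/2 first, with a
#' message.
#'
#' @param graph an igraph object; non-negative weights.
#' @param gamma resolution parameter (>= 0): low values favour few large
#'   communities, high values many small ones.
#' @param seed integer seed.
#' @return Community labels (integers) named by node id.
#' @export
louvain_gamma <- function(graph, gamma, seed) {
  stopifnot(igraph::vcount(graph) > 0, gamma >= 0)
  graph <- .symmetrise(graph)
  w <- igraph::E(graph)$weight
  if (!is.null(w) && any(w < 0)) {
    stop("negative edge weights: modularity is undefined")
  }
  ids <- igraph::V(graph)$name %||% as.character(seq_len(igraph::vcount(graph)))
  set.seed(seed)
  perm <- sample.int(igraph::vcount(graph))
  shuffled <- igraph::permute(graph, perm)
  memb <- igraph::membership(igraph::cluster_louvain(shuffled,
                                                     resolution = gamma))
  setNames(as.integer(memb[perm]), ids)
}

.symmetrise <- function(graph) {
  if (!igraph::is_directed(graph)) return(graph)
  message("directed graph symmetrised as (A + t(A))/2 before Louvain")
  und <- igraph::as_undirected(graph, mode = "collapse",
                               edge.attr.comb = list(weight = "sum", "ignore"))
  if ("weight" %in% igraph::edge_attr_names(und)) {
    igraph::E(und)$weight <- igraph::E(und)$weight / 2
  }
  und
}

#' Wrap a community-detection routine as a detector adapter
#'
#' A detector adapter is the contract [run_ensemble()] works against: given
#' (graph, seed) it returns one partition, and the same seed always returns
#' the same partition.
#'
#' @param name short detector name (recorded in provenance).
#' @param fn function of `(graph, seed)` returning labels named by node id.
#' @param parameters named list of parameters (recorded in provenance).
#' @return Object of class `detector_adapter`.
#' @export
detector_adapter <- function(name, fn, parameters = list()) {
  stopifnot(is.character(name), is.function(fn))
  structure(list(name = name, fn = fn, parameters = parameters),
            class = "detector_adapter")
}

#' The bundled Louvain detector at a fixed resolution
#'
#' @param gamma resolution parameter.
#' @return A [detector_adapter()] calling [louvain_gamma()].
#' @export
detector_louvain <- function(gamma = 1) {
  detector_adapter("louvain", function(graph, seed) {
    louvain_gamma(graph, gamma, seed)
  }, parameters = list(resolution = gamma))
}

#' Run a detector many times to build a partition ensemble
#'
#' Around 1000 runs give a reliable association matrix for typical networks
#' (see [convergence_diagnostic()] to check a particular case). Run k uses
#' seed `derive_seed(base_seed, gamma_index, k)`.
#'
#' @param graph an igraph object.
#' @param detector a [detector_adapter()].
#' @param runs number of runs (>= 1).
#' @param base_seed integer seed for the whole ensemble.
#' @param gamma_index zero-based grid index used in seed derivation (so
#'   ensembles at different grid points are independent).
#' @return A [partition_ensemble()] with provenance recorded.
#' @export
run_ensemble <- function(graph, detector, runs, base_seed = 1,
                         gamma_index = 0L) {
  stopifnot(inherits(detector, "detector_adapter"), runs >= 1)
  ids <- igraph::V(graph)$name %||% as.character(seq_len(igraph::vcount(graph)))
  labels <- matrix(NA_character_, length(ids), runs,
                   dimnames = list(ids, NULL))
  for (k in seq_len(runs)) {
    seed <- derive_seed(base_seed, gamma_index, k)
    part <- tryCatch(detector$fn(graph, seed), error = function(e) {
      stop(sprintf("detector '%s' failed on run %d (seed %d): %s",
                   detector$name, k, seed, conditionMessage(e)), call. = FALSE)
    })
    nm <- names(part) %||% ids
    if (!setequal(nm, ids)) {
      stop(sprintf("detector '%s' run %d returned a different node set",
                   detector$name, k))
    }
    labels[, k] <- as.character(part)[match(ids, nm)]
  }
  partition_ensemble(labels, provenance = sprintf(
    "%s(%s), runs=%d, base_seed=%d, gamma_index=%d",
    detector$name,
    paste(names(detector$parameters), unlist(detector$parameters),
          sep = "=", collapse = ", "),
    runs, base_seed, gamma_index))
}

# Bootstrap standard error of the global mean versatility: resample the
# ensemble's runs with replacement and recompute association + mean
# versatility, using the sparse incidence so no detector is re-run.
.bootstrap_sem <- function(ensemble, estimator = "SC", n_boot = 100,
                           seed = 1) {
  cs <- .coassign_sparse(ensemble$labels)
  n <- nrow(ensemble$labels)
  r <- ensemble$run_count
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    w <- tabulate(sample.int(r, r, replace = TRUE), nbins = r)
    counts <- as.matrix(cs$S %*% Matrix::Diagonal(x = w[cs$run_of_col]) %*%
                          Matrix::t(cs$S))
    p <- counts / r
    diag(p) <- 1
    dimnames(p) <- list(ensemble$node_ids, ensemble$node_ids)
    mean_versatility(versatility(association_matrix(p, run_count = r),
                                 estimator))
  }, numeric(1))
  stats::sd(reps)
}

#' Sweep the resolution parameter and trace mean versatility
#'
#' For each value of the grid: run the detector `runs_per_gamma` times,
#' accumulate the association matrix, compute per-node versatility and
#' average it. The uncertainty attached to each point is a bootstrap
#' standard error (runs resampled with replacement, default 100 resamples —
#' no extra detector calls). Grid points whose median run is degenerate
#' (one community spanning the network, or >= N-1 communities) are flagged
#' trivial: versatility vanishes there for the wrong reason and such points
#' are excluded when selecting an optimum.
#'
#' @param graph an igraph object.
#' @param gammas ascending grid of resolution values (default 0.1 to 3 in
#'   steps of 0.1).
#' @param runs_per_gamma detector runs per grid point (>= 2; default 1000).
#' @param base_seed integer seed.
#' @param estimator estimator code for the versatility values.
#' @param n_boot bootstrap resamples for the SEM.
#' @param detector_factory function mapping a gamma value to a
#'   [detector_adapter()]; defaults to [detector_louvain()].
#' @return Object of class `sweep_result`, a data frame with columns
#'   `gamma`, `mean_versatility`, `sem`, `mean_n_communities`, `trivial`,
#'   plus attributes `runs_per_gamma`, `base_seed`, `estimator`,
#'   `node_versatility` (node-by-gamma matrix).
#' @seealso [find_optima()], [plot.sweep_result()]
#' @export
sweep_resolution <- function(graph, gammas = seq(0.1, 3, 0.1),
                             runs_per_gamma = 1000, base_seed = 1,
                             estimator = "SC", n_boot = 100,
                             detector_factory = detector_louvain) {
  stopifnot(length(gammas) > 0, !is.unsorted(gammas), runs_per_gamma >= 2)
  estimator <- .check_estimator(estimator)
  graph <- .symmetrise(graph)
  n <- igraph::vcount(graph)
  mv <- sem <- mnc <- numeric(length(gammas))
  triv <- logical(length(gammas))
  vmat <- NULL
  for (g in seq_along(gammas)) {
    ens <- tryCatch(
      run_ensemble(graph, detector_factory(gammas[g]), runs_per_gamma,
                   base_seed = base_seed, gamma_index = g - 1L),
      error = function(e) stop(sprintf("gamma=%g: %s", gammas[g],
                                       conditionMessage(e)), call. = FALSE))
    v <- versatility(accumulate(ens), estimator)
    if (is.null(vmat)) {
      vmat <- matrix(NA_real_, n, length(gammas),
                     dimnames = list(v$node_ids, NULL))
    }
    vmat[, g] <- v$values
    mv[g] <- mean_versatility(v)
    sem[g] <- .bootstrap_sem(ens, estimator, n_boot,
                             seed = derive_seed(base_seed, g - 1L, 0L))
    ncomm <- apply(ens$labels, 2, function(x) length(unique(x)))
    mnc[g] <- mean(ncomm)
    med <- stats::median(ncomm)
    triv[g] <- med == 1 || med >= n - 1
  }
  out <- data.frame(gamma = gammas, mean_versatility = mv, sem = sem,
                    mean_n_communities = mnc, trivial = triv)
  attr(out, "runs_per_gamma") <- runs_per_gamma
  attr(out, "base_seed") <- base_seed
  attr(out, "estimator") <- estimator
  attr(out, "node_versatility") <- vmat
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Select optimal resolution values from a sweep
#'
#' Returns the non-trivial discrete local minima of the mean-versatility
#' curve (strictly lower than their non-trivial neighbours; over a flat run
#' of equal values the lowest gamma is reported), sorted by mean
#' versatility, followed by low-versatility plateaus: maximal stretches of
#' at least `plateau_len` consecutive non-trivial grid points that all lie
#' within one SEM of the stretch's minimum. Plateaus prioritise stability
#' of the decomposition under small perturbations of the resolution over
#' the global minimum itself.
#'
#' @param result a [sweep_resolution()] result.
#' @param plateau_len minimum number of grid points forming a plateau.
#' @return Data frame with columns `gamma`, `kind` ("minimum" or
#'   "plateau"), `mean_versatility`, `gamma_lo`, `gamma_hi` (plateau
#'   extent; equal to `gamma` for minima). Empty, with a warning, if every
#'   grid point is trivial.
#' @export
find_optima <- function(result, plateau_len = 3) {
  stopifnot(inherits(result, "sweep_result"))
  empty <- data.frame(gamma = numeric(0), kind = character(0),
                      mean_versatility = numeric(0),
                      gamma_lo = numeric(0), gamma_hi = numeric(0))
  keep <- !result$trivial
  if (!any(keep)) {
    warning("every grid point is trivial; no optimum to report")
    return(empty)
  }
  segs <- split(which(keep), cumsum(c(1, diff(which(keep)) != 1)))
  minima <- data.frame()
  plateaus <- data.frame()
  for (idx in segs) {
    v <- result$mean_versatility[idx]
    # run-length collapse so ties break toward lower gamma
    rl <- rle(v)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    for (q in seq_along(rl$values)) {
      lower_left <- q == 1 || rl$values[q] < rl$values[q - 1]
      lower_right <- q == length(rl$values) || rl$values[q] < rl$values[q + 1]
      if (lower_left && lower_right) {
        i <- idx[starts[q]]
        minima <- rbind(minima, data.frame(
          gamma = result$gamma[i], kind = "minimum",
          mean_versatility = result$mean_versatility[i],
          gamma_lo = result$gamma[i], gamma_hi = result$gamma[i]))
      }
    }
    # plateaus: maximal windows within 1 SEM of their own minimum
    nseg <- length(idx)
    if (nseg >= plateau_len) {
      wins <- list()
      for (a in seq_len(nseg - plateau_len + 1)) {
        b_best <- NA
        for (b in seq(a + plateau_len - 1, nseg)) {
          m <- which.min(v[a:b]) + a - 1
          if (max(v[a:b]) <= v[m] + result$sem[idx[m]]) b_best <- b
        }
        if (!is.na(b_best)) wins[[length(wins) + 1]] <- c(a, b_best)
      }
      # keep only windows not contained in another
      for (w in wins) {
        contained <- any(vapply(wins, function(u) {
          (u[1] < w[1] && u[2] >= w[2]) || (u[1] <= w[1] && u[2] > w[2])
        }, logical(1)))
        if (!contained) {
          m <- which.min(v[w[1]:w[2]]) + w[1] - 1
          plateaus <- rbind(plateaus, data.frame(
            gamma = result$gamma[idx[m]], kind = "plateau",
            mean_versatility = result$mean_versatility[idx[m]],
            gamma_lo = result$gamma[idx[w[1]]],
            gamma_hi = result$gamma[idx[w[2]]]))
        }
      }
    }
  }
  if (nrow(minima) > 0) {
    minima <- minima[order(minima$mean_versatility), ]
  }
  plateaus <- unique(plateaus)
  out <- rbind(minima, plateaus)
  if (nrow(out) == 0) return(empty)
  rownames(out) <- NULL
  out
}

#' How many runs are enough? Variance of the mean-versatility estimate
#'
#' For a ladder of ensemble sizes, builds `n_replicates` independent
#' ensembles of each size and reports the standard deviation of the global
#' mean versatility across replicates. The sd shrinks roughly as
#' 1/sqrt(runs); pick the smallest ladder step whose sd is acceptable.
#'
#' @param graph an igraph object.
#' @param detector a [detector_adapter()].
#' @param max_runs largest ensemble size (>= 10).
#' @param n_replicates independent ensembles per ladder step (>= 3).
#' @param base_seed integer seed.
#' @param ladder candidate ensemble sizes; capped at `max_runs`, which is
#'   always included as the last step.
#' @param estimator estimator code.
#' @return Data frame with columns `runs` and `sd_mean_versatility`.
#' @export
convergence_diagnostic <- function(graph, detector, max_runs = 1000,
                                   n_replicates = 5, base_seed = 1,
                                   ladder = c(10, 30, 100, 300, 1000),
                                   estimator = "SC") {
  stopifnot(max_runs >= 10, n_replicates >= 3)
  ladder <- sort(unique(c(ladder[ladder < max_runs], max_runs)))
  sds <- vapply(seq_along(ladder), function(li) {
    mv <- vapply(seq_len(n_replicates), function(rep) {
      ens <- run_ensemble(graph, detector, ladder[li],
                          base_seed = derive_seed(base_seed, li, rep),
                          gamma_index = 0L)
      mean_versatility(versatility(accumulate(ens), estimator))
    }, numeric(1))
    stats::sd(mv)
  }, numeric(1))
  data.frame(runs = ladder, sd_mean_versatility = sds)
}

#' Plot the mean-versatility curve of a sweep
#'
#' Mean versatility against the resolution parameter with SEM error bars;
#' trivial grid points are drawn hollow. A secondary axis shows the mean
#' number of communities, the quantity older resolution-selection
#' heuristics track.
#'
#' @param x a [sweep_resolution()] result.
#' @param ... further arguments passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.sweep_result <- function(x, ...) {
  graphics::plot(x$gamma, x$mean_versatility, type = "b",
                 pch = ifelse(x$trivial, 1, 16),
                 xlab = expression(gamma), ylab = "mean versatility", ...)
  up <- x$mean_versatility + x$sem
  lo <- x$mean_versatility - x$sem
  ok <- x$sem > 0
  if (any(ok)) {
    graphics::arrows(x$gamma[ok], lo[ok], x$gamma[ok], up[ok],
                     angle = 90, code = 3, length = 0.03)
  }
  op <- graphics::par(new = TRUE)
  on.exit(graphics::par(op))
  graphics::plot(x$gamma, x$mean_n_communities, type = "l", lty = 3,
                 axes = FALSE, xlab = "", ylab = "", col = "grey40")
  graphics::axis(4, col = "grey40", col.axis = "grey40")
  graphics::mtext("mean communities", side = 4, line = 2, col = "grey40",
                  cex = 0.8)
  invisible(x)
}
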