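# Readers and writers: graphs (edge list TSV, adjacency CSV, GraphML),
# partition ensembles (CSV, one column per run), association matrices
# (CSV) and per-node result tables (TSV + JSON sidecar).
#
# Node ids are opaque strings throughout — numeric-looking ids are never
# coerced, so "01" and "1" stay distinct — and vertices are kept in sorted
# id order for stable, reproducible output.

#' Read a graph from a file
#'
#' Supported formats:
#' \describe{
#'   \item{edgelist}{whitespace/tab-delimited lines `from to [weight]`;
#'     missing weights default to 1; lines starting with `#` are ignored.}
#'   \item{adjacency}{square CSV with node ids as header row and first
#'     column; nonzero entries become edge weights.}
#'   \item{graphml}{parsed by igraph.}
#' }
#' In every format duplicate edges are summed, self-loops are dropped with
#' a warning, negative weights are an error, and vertices are sorted by id.
#'
#' @param path file path.
#' @param format one of "auto" (by extension: .graphml, .csv, else edge
#'   list), "edgelist", "adjacency", "graphml".
#' @param directed read the graph as directed.
#' @return An igraph object with character vertex names and a `weight` edge
#'   attribute.
#' @export
read_graph_file <- function(path, format = c("auto", "edgelist", "adjacency",
                                             "graphml"),
                            directed = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml"
              else if (grepl("\\.csv$", path, ignore.case = TRUE)) "adjacency"
              else "edgelist"
  }
  g <- switch(format,
    edgelist = .read_edgelist(path, directed),
    adjacency = .read_adjacency(path, directed),
    graphml = {
      gg <- igraph::read_graph(path, format = "graphml")
      if (directed && !igraph::is_directed(gg)) {
        gg <- igraph::as_directed(gg, mode = "arbitrary")
      }
      gg
    })
  .normalise_graph(g)
}

.read_edgelist <- function(path, directed) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop(sprintf("%s: no edges found", path))
  from <- to <- character(length(keep))
  w <- numeric(length(keep))
  for (k in seq_along(keep)) {
    tok <- strsplit(trimws(lines[keep[k]]), "\\s+")[[1L]]
    if (!length(tok) %in% c(2L, 3L)) {
      stop(sprintf("%s line %d: expected 'from to [weight]', got %d field(s)",
                   path, keep[k], length(tok)))
    }
    wt <- if (length(tok) == 3L) suppressWarnings(as.numeric(tok[3L])) else 1
    if (is.na(wt)) {
      stop(sprintf("%s line %d: weight '%s' is not a number",
                   path, keep[k], tok[3L]))
    }
    from[k] <- tok[1L]; to[k] <- tok[2L]; w[k] <- wt
  }
  if (any(w < 0)) {
    stop(sprintf("%s line %d: negative edge weight",
                 path, keep[which(w < 0)[1L]]))
  }
  ids <- sort(unique(c(from, to)))
  g <- igraph::make_empty_graph(n = length(ids), directed = directed)
  igraph::V(g)$name <- ids
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  g
}

.read_adjacency <- function(path, directed) {
  a <- tryCatch(as.matrix(read.csv(path, row.names = 1, check.names = FALSE)),
                error = function(e) stop(sprintf("%s: %s", path,
                                                 conditionMessage(e))))
  if (nrow(a) != ncol(a)) {
    stop(sprintf("%s: adjacency matrix is %d x %d, not square",
                 path, nrow(a), ncol(a)))
  }
  if (!identical(rownames(a), colnames(a))) {
    stop(sprintf("%s: row and column ids differ", path))
  }
  if (any(a < 0)) stop(sprintf("%s: negative edge weight", path))
  mode(a) <- "numeric"
  igraph::graph_from_adjacency_matrix(
    a, mode = if (directed) "directed" else "undirected", weighted = TRUE)
}

.normalise_graph <- function(g) {
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  igraph::V(g)$name <- as.character(igraph::V(g)$name)
  if (anyDuplicated(igraph::V(g)$name)) stop("node ids must be unique")
  if (!"weight" %in% igraph::edge_attr_names(g)) {
    igraph::E(g)$weight <- 1
  }
  if (any(igraph::E(g)$weight < 0)) stop("negative edge weight")
  n_loops <- sum(igraph::which_loop(g))
  if (n_loops > 0) {
    warning(sprintf("dropped %d self-loop(s)", n_loops))
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = list(weight = "sum", "ignore"))
  igraph::permute(g, order(order(igraph::V(g)$name)))
}

#' Write a graph as an edge-list TSV
#'
#' Columns `from`, `to`, `weight`, tab-separated, no header; readable back
#' with [read_graph_file()].
#'
#' @param graph an igraph object.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_graph_tsv <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  w <- igraph::E(graph)$weight %||% rep(1, nrow(el))
  writeLines(sprintf("%s\t%s\t%s", el[, 1], el[, 2], format(w, trim = TRUE)),
             path)
  invisible(path)
}

#' The Zachary karate club graph
#'
#' The canonical 34-member, 78-friendship social network observed before a
#' university karate club split into two factions, embedded as a static
#' edge list. A standard non-trivial benchmark: most members sort cleanly
#' into one faction, but one individual with exactly one friendship on each
#' side of the split cannot be unambiguously assigned — the textbook
#' high-versatility node.
#'
#' @return An undirected, unweighted igraph with 34 named vertices and 78
#'   edges.
#' @export
karate_fixture <- function() {
  path <- system.file("extdata", "karate_club.tsv", package = "versatility",
                      mustWork = TRUE)
  read_graph_file(path, format = "edgelist", directed = FALSE)
}

#' Read / write a partition ensemble as CSV
#'
#' Layout: first column `node`, one column per run named `run_0001`, ...;
#' cells hold community labels (opaque strings, compared only within a
#' column).
#'
#' @param path file path.
#' @return [read_partition_ensemble_csv()] returns a
#'   [partition_ensemble()]; the writer returns `path` invisibly.
#' @export
read_partition_ensemble_csv <- function(path) {
  d <- read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(d) < 2L || names(d)[1L] != "node") {
    stop(sprintf("%s: expected a 'node' column followed by run columns",
                 path))
  }
  labels <- as.matrix(d[, -1L, drop = FALSE])
  rownames(labels) <- d$node
  partition_ensemble(labels, provenance = sprintf("read from %s", path))
}

#' @rdname read_partition_ensemble_csv
#' @param ensemble a [partition_ensemble()].
#' @export
write_partition_ensemble_csv <- function(ensemble, path) {
  d <- data.frame(node = ensemble$node_ids, ensemble$labels,
                  check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an association matrix as CSV
#'
#' Square CSV with node ids on both the header row and the first column.
#'
#' @param path file path.
#' @param run_count run count to attach on reading (`NA` when unknown or
#'   idealised).
#' @return [read_association_csv()] returns an [association_matrix()]; the
#'   writer returns `path` invisibly.
#' @export
read_association_csv <- function(path, run_count = NA_integer_) {
  p <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  association_matrix(p, run_count = run_count)
}

#' @rdname read_association_csv
#' @param assoc an [association_matrix()].
#' @export
write_association_csv <- function(assoc, path) {
  write.csv(assoc$p, path, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Write per-node values as TSV with a JSON sidecar
#'
#' The TSV has columns `node` and `versatility` (or `participation`); the
#' sidecar `<path>.json` records estimator code, run count and provenance
#' so the table can be traced back to its ensemble.
#'
#' @param result a `versatility_result` or `participation_result`.
#' @param path output TSV path.
#' @param provenance optional free-text provenance for the sidecar.
#' @return Invisibly, `path`.
#' @export
write_result_tsv <- function(result, path, provenance = "") {
  d <- as.data.frame(result)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(kind = class(result)[1L],
               estimator = result$estimator %||% NA,
               run_count = result$run_count %||% NA,
               provenance = provenance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Write a sweep result as TSV and JSON
#'
#' @param sweep a [sweep_resolution()] result.
#' @param path output path; the TSV goes to `path` and the JSON to
#'   `paste0(path, ".json")`.
#' @return Invisibly, `path`.
#' @export
write_sweep_tsv <- function(sweep, path) {
  utils::write.table(as.data.frame(sweep)[, c("gamma", "mean_versatility",
                                              "sem", "mean_n_communities",
                                              "trivial")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(gammas = sweep$gamma, mean_versatility = sweep$mean_versatility,
         sem = sweep$sem, mean_n_communities = sweep$mean_n_communities,
         trivial = sweep$trivial,
         runs_per_gamma = attr(sweep, "runs_per_gamma"),
         base_seed = attr(sweep, "base_seed"),
         estimator = attr(sweep, "estimator")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
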