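test_that("seed derivation is deterministic, bounded and collision-free", {
  s <- derive_seed(123, 4, 17)
  expect_identical(s, derive_seed(123, 4, 17))
  grid <- expand.grid(g = 0:19, k = 1:500)
  seeds <- mapply(derive_seed, 7, grid$g, grid$k)
  expect_false(anyDuplicated(seeds) > 0)
  expect_true(all(seeds >= 0 & seeds < 2^31))
})

test_that("seeded Louvain behaves as expected at resolution extremes", {
  g2 <- two_cliques_graph(5)
  # gamma = 0: one community per connected component
  p0 <- louvain_gamma(g2, 0, seed = 1)
  expect_equal(length(unique(p0)), 2)
  expect_equal(length(unique(p0[1:5])), 1)
  # gamma = 1 recovers the two cliques exactly
  p1 <- louvain_gamma(g2, 1, seed = 2)
  expect_equal(length(unique(p1)), 2)
  expect_equal(length(unique(p1[1:5])), 1)
  expect_false(p1[1] == p1[6])
  # huge gamma shatters the karate graph into singletons
  k <- karate_fixture()
  expect_equal(length(unique(louvain_gamma(k, 1000, seed = 3))), 34)
  # reproducibility contract
  expect_identical(louvain_gamma(k, 0.7, seed = 11),
                   louvain_gamma(k, 0.7, seed = 11))
  # negative weights are rejected
  gw <- two_cliques_graph(3)
  igraph::E(gw)$weight <- c(rep(1, 5), -1)
  expect_error(louvain_gamma(gw, 1, seed = 1), "negative")
})

test_that("directed graphs are symmetrised with notice before Louvain", {
  gd <- igraph::make_graph(~ a -+ b, b -+ c, c -+ a)
  igraph::E(gd)$weight <- c(2, 2, 2)
  expect_message(p <- louvain_gamma(gd, 0.5, seed = 1), "symmetrised")
  expect_equal(length(p), 3)
})

test_that("run_ensemble is reproducible and reports failing runs", {
  g <- karate_fixture()
  one <- run_ensemble(g, detector_louvain(1), 1, base_seed = 9)
  expect_equal(one$run_count, 1L)
  a <- run_ensemble(g, detector_louvain(1), 25, base_seed = 42)
  b <- run_ensemble(g, detector_louvain(1), 25, base_seed = 42)
  expect_identical(a$labels, b$labels)
  expect_match(a$provenance, "louvain")
  expect_match(a$provenance, "base_seed=42")

  flaky <- detector_adapter("flaky", function(graph, seed) {
    if (seed %% 7 == 0) stop("boom")
    louvain_gamma(graph, 1, seed)
  })
  expect_error(run_ensemble(g, flaky, 50, base_seed = 1), "run \\d+")
})

test_that("sweeps are bit-reproducible and exactly zero for stable optima", {
  g2 <- two_cliques_graph(5)
  sw <- sweep_resolution(g2, gammas = c(0.5, 1), runs_per_gamma = 30,
                         base_seed = 3, n_boot = 20)
  # Louvain always recovers the cliques: all co-assignments are 0/1
  expect_true(all(sw$mean_versatility == 0))
  expect_true(all(sw$sem == 0))
  expect_false(any(sw$trivial))
  sw2 <- sweep_resolution(g2, gammas = c(0.5, 1), runs_per_gamma = 30,
                          base_seed = 3, n_boot = 20)
  expect_identical(as.data.frame(sw), as.data.frame(sw2))
})

test_that("degenerate partitions are flagged trivial at grid extremes", {
  k <- karate_fixture()
  sw <- sweep_resolution(k, gammas = c(0, 40), runs_per_gamma = 10,
                         base_seed = 1, n_boot = 5)
  expect_true(all(sw$trivial))
  expect_equal(sw$mean_versatility[1], 0)  # single community: all p = 1
  expect_warning(opt <- find_optima(sw), "trivial")
  expect_equal(nrow(opt), 0)
})

test_that("community counts increase with resolution on modular graphs", {
  g <- build_ncluster_graph(ncluster_spec(3, 5, p = 0.5), inter_weight = 0.4)
  sw <- sweep_resolution(g, gammas = c(0.2, 1, 3, 8), runs_per_gamma = 40,
                         base_seed = 6, n_boot = 5)
  expect_true(all(diff(sw$mean_n_communities) >= -0.2))
})

test_that("find_optima locates minima and plateaus on synthetic curves", {
  mk <- function(v, sem = rep(0, length(v)), trivial = rep(FALSE, length(v))) {
    out <- data.frame(gamma = seq(0.1, by = 0.1, length.out = length(v)),
                      mean_versatility = v, sem = sem,
                      mean_n_communities = rep(2, length(v)),
                      trivial = trivial)
    class(out) <- c("sweep_result", "data.frame")
    out
  }
  # V-shaped: unique minimum in the middle
  opt <- find_optima(mk(c(3, 2, 1, 2, 3)))
  expect_equal(opt$gamma[opt$kind == "minimum"], 0.3)
  # monotone decreasing: minimum at the last grid point
  opt2 <- find_optima(mk(c(5, 4, 3, 2, 1)))
  expect_equal(opt2$gamma[opt2$kind == "minimum"], 0.5)
  # ties break toward lower gamma
  opt3 <- find_optima(mk(c(3, 1, 1, 3)))
  expect_equal(opt3$gamma[opt3$kind == "minimum"], 0.2)
  # trivial points are excluded from candidacy
  opt4 <- find_optima(mk(c(0, 2, 1, 2, 0), trivial = c(TRUE, FALSE, FALSE,
                                                       FALSE, TRUE)))
  expect_equal(opt4$gamma[opt4$kind == "minimum"], 0.3)
  # a flat low stretch within one SEM of its minimum is a plateau
  opt5 <- find_optima(mk(c(2, 0.52, 0.5, 0.51, 2), sem = rep(0.05, 5)),
                      plateau_len = 3)
  pl <- opt5[opt5$kind == "plateau", ]
  expect_equal(nrow(pl), 1)
  expect_equal(pl$gamma_lo, 0.2)
  expect_equal(pl$gamma_hi, 0.4)
  expect_equal(pl$gamma, 0.3)
})

test_that("convergence ladder caps at max_runs and is exact when stable", {
  g2 <- two_cliques_graph(4)
  constant <- detector_adapter("constant", function(graph, seed) {
    setNames(rep(c(1, 2), each = 4), igraph::V(graph)$name)
  })
  d <- convergence_diagnostic(g2, constant, max_runs = 50, n_replicates = 3,
                              base_seed = 1)
  expect_equal(d$runs, c(10, 30, 50))
  expect_true(all(d$sd_mean_versatility == 0))
})

test_that("mean-versatility noise shrinks roughly as one over sqrt(runs)", {
  k <- karate_fixture()
  d <- convergence_diagnostic(k, detector_louvain(0.5), max_runs = 160,
                              n_replicates = 6, base_seed = 8,
                              ladder = c(10, 40, 160))
  expect_true(all(diff(d$sd_mean_versatility) < 0.05))
  # factor-4 more runs should halve the sd, within a factor of ~3 of that
  expect_lt(d$sd_mean_versatility[3], d$sd_mean_versatility[1])
})
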