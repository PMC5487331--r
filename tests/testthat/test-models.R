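test_that("closed-form oracles reproduce hand-derived values", {
  expect_equal(analytic_versatility_nsplit(nsplit_spec(1, 5)), 0)
  expect_equal(analytic_versatility_nsplit(nsplit_spec(2, 3)), 1.5)
  # two-way split tends to the landmark value 2 as clusters grow
  approach <- vapply(c(10, 100, 1000, 10000), function(cc) {
    analytic_versatility_nsplit(nsplit_spec(2, cc))
  }, numeric(1))
  expect_true(all(diff(approach) > 0))
  expect_lt(abs(approach[4] - 2), 1e-3)

  expect_equal(analytic_versatility_ncluster(ncluster_spec(3, 4, p = 0)), 0)
  expect_equal(analytic_versatility_ncluster(ncluster_spec(3, 4, p = 1)), 0)
  expect_equal(analytic_versatility_ncluster(ncluster_spec(3, 5, p = 0.5)), 1)
  expect_equal(analytic_versatility_ncluster(ncluster_spec(3, 50, p = 0.5)), 1)
  expect_equal(analytic_versatility_ncluster(ncluster_spec(2, 4, p = 0.25)),
               sin(pi / 4) / 1.25, tolerance = 1e-12)
})

test_that("extra nodes change network-size-normalised estimators only", {
  for (x in c(0, 10, 50)) {
    expect_equal(analytic_versatility_nsplit(nsplit_spec(3, 4, x)),
                 analytic_versatility_nsplit(nsplit_spec(3, 4, 0)))
    expect_equal(analytic_versatility_ncluster(ncluster_spec(3, 4, x, 0.5)),
                 analytic_versatility_ncluster(ncluster_spec(3, 4, 0, 0.5)))
  }
  expect_lt(analytic_versatility_nsplit(nsplit_spec(3, 4, 50), "SU"),
            analytic_versatility_nsplit(nsplit_spec(3, 4, 0), "SU"))
})

test_that("idealised association matrices agree with the closed forms", {
  for (code in estimator_codes()) {
    sp <- nsplit_spec(3, 4, x = 2)
    expect_equal(
      unname(versatility(idealised_association(sp), code)$values["ind"]),
      analytic_versatility_nsplit(sp, code), tolerance = 1e-12, info = code)
    sp2 <- ncluster_spec(3, 4, x = 2, p = 0.4)
    expect_equal(
      unname(versatility(idealised_association(sp2), code)$values["c1_1"]),
      analytic_versatility_ncluster(sp2, code), tolerance = 1e-12,
      info = code)
  }
})

test_that("idealised samplers hit their affiliation probabilities", {
  # n-split: indicator joins each cluster with probability 1/n
  ens <- sample_model_ensemble(nsplit_spec(4, 2), 4000, base_seed = 2)
  p <- accumulate(ens)$p
  se3 <- 3 * sqrt(0.25 * 0.75 / 4000)
  expect_lt(abs(p["ind", "c1_1"] - 0.25), se3)
  expect_lt(abs(p["ind", "c3_2"] - 0.25), se3)
  expect_equal(p["c1_1", "c2_1"], 0)   # clusters never co-assigned
  expect_equal(p["c1_1", "c1_2"], 1)   # clusters stay whole

  # degenerate n = 1: all runs identical, versatility exactly 0
  det <- sample_model_ensemble(nsplit_spec(1, 5), 300, base_seed = 3)
  expect_true(all(versatility(accumulate(det))$values == 0))

  # n-clusters: pairwise probability with the indicator cluster is p
  ens2 <- sample_model_ensemble(ncluster_spec(3, 2, p = 0.5), 4000,
                                base_seed = 4)
  p2 <- accumulate(ens2)$p
  expect_lt(abs(p2["c1_1", "c2_1"] - 0.5), 3 * sqrt(0.25 / 4000))
  expect_equal(p2["c1_1", "c1_2"], 1)
  # p = 0 and p = 1 are deterministic
  for (pp in c(0, 1)) {
    d <- sample_model_ensemble(ncluster_spec(3, 4, p = pp), 200,
                               base_seed = 5)
    expect_true(all(versatility(accumulate(d))$values == 0))
  }
})

test_that("model graphs have the documented structure", {
  g <- build_nsplit_graph(nsplit_spec(2, 3))
  expect_equal(igraph::vcount(g), 7)          # n*c + x + 1
  expect_equal(igraph::ecount(g), 8)          # 2 * C(3,2) + 2
  expect_setequal(igraph::V(g)$name[igraph::neighbors(g, "ind")],
                  c("c1_1", "c2_1"))          # deterministic attachment

  g1 <- build_nsplit_graph(nsplit_spec(1, 1))
  expect_equal(igraph::vcount(g1), 2)
  expect_equal(igraph::ecount(g1), 1)

  gx <- build_nsplit_graph(nsplit_spec(2, 2, x = 3))
  expect_equal(igraph::vcount(gx), 8)
  comp <- igraph::components(gx)
  expect_equal(comp$no, 2)                    # extras form an isolated clique

  gc <- build_ncluster_graph(ncluster_spec(3, 4, p = 0.5), inter_weight = 0.2)
  expect_equal(igraph::vcount(gc), 12)
  expect_equal(igraph::ecount(gc), 3 * 6 + 3) # intra cliques + 3 inter edges
  expect_equal(sort(unique(igraph::E(gc)$weight)), c(0.2, 1))

  g0 <- build_ncluster_graph(ncluster_spec(3, 4, p = 0.5), inter_weight = 0)
  expect_equal(igraph::components(g0)$no, 3)  # disconnected cliques
})

test_that("maximum versatility grows with network size toward pi", {
  expect_equal(max_versatility(2), 0)
  expect_equal(max_versatility(10), 9 * sin(pi / 3) / 4, tolerance = 1e-12)
  sizes <- c(2, 3, 5, 10, 30, 100, 300, 1000, 10000, 100000)
  vals <- vapply(sizes, max_versatility, numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals < pi))
})
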