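test_that("composition enumeration has the stars-and-bars count", {
  expect_equal(nrow(enumerate_compositions(3, 8)), choose(10, 8))   # 45
  expect_equal(nrow(enumerate_compositions(1, 8)), 1L)
  expect_equal(nrow(enumerate_compositions(8, 8)), choose(15, 8))   # 6435
  comps <- enumerate_compositions(3, 8)
  expect_true(all(rowSums(comps) == 8L))
  expect_equal(anyDuplicated(comps), 0L)
})

test_that("expected cost at a vertex equals the deterministic composition cost", {
  p <- table1_params()
  # all-Lazy world: a Lazy focal pays the bare baseline
  expect_equal(cf_expected_cost(c(1, 0, 0), p)[["csr"]], p$c0)
  # all-Trusty world: 8 Tr co-members + La focal, theta = 1
  expect_equal(cf_expected_cost(c(0, 1, 0), p)[["csr"]], (1 - p$b) * p$c0)
  expect_equal(cf_expected_cost(c(0, 1, 0), p)[["Csr"]],
               (1 - p$b) * (p$c0 + p$c))
})

test_that("enumeration agrees with a Monte-Carlo group-sampling oracle", {
  p <- table1_params()
  set.seed(123)
  n <- 2e4
  for (trial in 1:2) {
    x <- runif_simplex(3)
    enum <- cf_expected_cost(x, p, strategies = feasible3)
    draws <- t(stats::rmultinom(n, p$N - 1L, x))
    uniq <- unique(draws)
    key <- apply(draws, 1L, paste, collapse = ",")
    ukey <- apply(uniq, 1L, paste, collapse = ",")
    for (f in feasible3) {
      ucost <- apply(uniq, 1L, function(row) {
        focal_cost_oracle(f, stats::setNames(row, feasible3), p)
      })
      per_draw <- ucost[match(key, ukey)]
      se <- stats::sd(per_draw) / sqrt(n)
      expect_lt(abs(enum[[f]] - mean(per_draw)), 3 * se + 1e-12)
    }
  }
})

test_that("the CF flow conserves the simplex and fixes the vertices", {
  p <- table1_params()
  for (v in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    expect_equal(unname(cf_flow(v, p)), c(0, 0, 0), tolerance = 1e-14)
  }
  set.seed(5)
  for (i in 1:20) {
    x <- runif_simplex(3)
    expect_lt(abs(sum(cf_flow(x, p))), 1e-14)
  }
})

test_that("CF trajectories stay on the simplex and run downhill in cost", {
  p <- table1_params(b = 0.3)
  traj <- cf_trajectory(rep(1 / 3, 3), p, T = 800, dt = 0.4)
  sums <- rowSums(traj[, c("x_La", "x_Tr", "x_Sm")])
  expect_true(all(abs(sums - 1) < 1e-9))
  # b = 0.3 regime: cooperation collapses toward Lazy
  expect_gt(traj$x_La[nrow(traj)], 0.99)
})

test_that("raising b with cheap signal response hands the polymorphism to Smart", {
  # one light regime probe (the full four-case inventory runs in the
  # acceptance suite): at b = 0.5 the stable set is La plus a Smart/Lazy
  # edge polymorphism and Trusty is absent from every attractor
  p <- table1_params(b = 0.5, r = 0.01)
  fp <- cf_fixed_points(p, seed_resolution = 0.1)
  stable <- fp[fp$class == "stable", ]
  expect_equal(nrow(stable), 2L)
  expect_true(any(stable$x_La > 0.999))
  edge <- stable[stable$x_La < 0.999, ]
  expect_equal(edge$x_Tr, 0)
  expect_gt(edge$x_Sm, 0.05)
})

test_that("the 8-strategy mutation mixing term balances at the uniform rates", {
  p <- table1_params(rho = 1e-4)
  all8 <- qs_genotypes()$allele
  # flow still sums to ~0: mutation only redistributes
  set.seed(9)
  x <- runif_simplex(8)
  v <- cf_flow(x, p, strategies = all8)
  expect_lt(abs(sum(v)), 1e-12)
  # at the uniform distribution the uniform-rate mixing term cancels
  # (every genotype has three one-locus neighbors at the same rate)
  p0 <- table1_params()
  u <- rep(1 / 8, 8)
  expect_equal(cf_flow(u, p, strategies = all8),
               cf_flow(u, p0, strategies = all8), tolerance = 1e-12)
})
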