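test_that("signal doses count cooperators plus extra signalers", {
  p <- table1_params()
  expect_equal(signal_doses(qs_group(c(Tr = 3, La = 6)), p), 3L)
  expect_equal(signal_doses(qs_group(c(Bo = 1, La = 8)), p), 2L)  # Bo = 2 doses
  expect_equal(signal_doses(qs_group(c(Li = 2, Sm = 1, Vo = 6)), p), 3L)
})

test_that("doses are additive over merged multisets and permutation-invariant", {
  p <- table1_params()
  g <- qs_genotypes()$allele
  set.seed(41)
  for (i in 1:20) {
    a <- sample(g, 4, replace = TRUE)
    b <- sample(g, 5, replace = TRUE)
    merged <- signal_doses(qs_group(c(a, b)), p)
    gt <- qs_genotypes()
    dose1 <- stats::setNames(gt$has_C + gt$has_S, gt$allele)
    per_member <- sum(dose1[c(a, b)])
    expect_equal(merged, per_member)
    expect_equal(signal_doses(qs_group(sample(c(a, b))), p), merged)
  }
})

test_that("activation resolves conditional cooperators against the shared pool", {
  p <- table1_params(kappa = 3)  # Q = kappa = 3
  a <- resolve_activation(qs_group(c(Tr = 2, Sm = 1, La = 6)), p)
  expect_equal(a$doses, 3L)
  expect_equal(a$gamma[["CsR"]], 1L)   # Smart switched on
  expect_equal(a$n_active, 3L)
  expect_equal(a$theta, 1L)

  b <- resolve_activation(qs_group(c(La = 9)), p)
  expect_equal(b$doses, 0L)
  expect_equal(b$n_active, 0L)
  expect_equal(b$theta, 0L)

  d <- resolve_activation(qs_group(c(Tr = 1, Sm = 1, La = 7)), p)
  expect_equal(d$doses, 2L)
  expect_equal(d$gamma[["CsR"]], 0L)   # below quorum: Smart stays silent
  expect_equal(d$n_active, 1L)
  expect_equal(d$theta, 0L)
})

test_that("the cue is constitutive: doses ignore whether activation succeeds", {
  p <- table1_params(kappa = 5)
  grp <- qs_group(c(Sm = 2, La = 7))
  expect_equal(signal_doses(grp, p), 2L)       # silent Smarts still cue
  act <- resolve_activation(grp, p)
  expect_equal(act$n_active, 0L)               # 2 < Q: nobody activates
  expect_equal(signal_doses(grp, p), 2L)
})

test_that("realized cost follows the discounted-bracket form", {
  p <- table1_params()
  expect_equal(realized_cost("La", 0, 0, p), 1.0)
  expect_equal(realized_cost("Sm", 1, 1, p), 0.5 * 1.31)
  expect_equal(realized_cost("Li", 0, 1, p), 0.5 * 1.01)
  # benefit multiplies s and r too
  expect_equal(realized_cost("Vo", 0, 1, p), (1 - p$b) * (p$c0 + p$r))
  expect_error(realized_cost("La", 1, 0, p), "without the C locus")
})

test_that("benefit monotonicity: theta = 1 scales every cost by (1 - b)", {
  p <- table1_params(b = 0.37)
  for (g in qs_genotypes()$allele) {
    for (gam in if (substr(g, 1, 1) == "C") c(0, 1) else 0) {
      c0 <- realized_cost(g, gam, 0, p)
      c1 <- realized_cost(g, gam, 1, p)
      expect_equal(c1, (1 - p$b) * c0)
      expect_lt(c1, c0)
    }
  }
})

test_that("imitation probability is 0.5 at equal costs and antisymmetric", {
  p <- table1_params()
  expect_identical(imitation_probability(1, 1, p), 0.5)
  dmax <- delta_C_max(p)
  expect_equal(imitation_probability(0, dmax, p), 1.0)
  # hand-derived value: La (no benefit) vs an activated, unrewarded Smart
  expect_equal(imitation_probability(1.0, 1.31, p), 0.5 * (1 + 0.31 / 0.82))
  set.seed(42)
  for (i in 1:200) {
    ci <- runif(1, 0, dmax)
    cj <- runif(1, max(0, ci - dmax), min(ci + dmax, 2 * dmax))
    expect_equal(imitation_probability(ci, cj, p) +
                   imitation_probability(cj, ci, p), 1.0)
  }
  expect_error(imitation_probability(0, 2 * dmax, p), "delta_C_max")
})

test_that("weak selection shrinks imitation bias toward 1/2", {
  p1 <- table1_params(sigma = 1)
  p2 <- table1_params(sigma = 0.1)
  expect_gt(imitation_probability(0.5, 0.9, p1),
            imitation_probability(0.5, 0.9, p2))
  expect_gt(imitation_probability(0.5, 0.9, p2), 0.5)
})

test_that("mutation flips loci at direction-specific rates", {
  p0 <- table1_params()  # all rates 0
  expect_equal(mutate_genotype(rep("Sm", 10), p0), rep("CsR", 10))
  pC <- table1_params(mu = c(C_loss = 1, C_gain = 0, S_loss = 0,
                             S_gain = 0, R_loss = 0, R_gain = 0))
  expect_equal(mutate_genotype("Tr", pC), "csr")   # forced C loss
  expect_equal(mutate_genotype("La", pC), "csr")   # gain rate is 0

  # per-offspring mutation fraction matches the closed binomial form
  rate <- 1e-4
  pmu <- table1_params(rho = rate)
  set.seed(7)
  n <- 1e5
  off <- mutate_genotype(rep("csr", n), pmu)
  frac <- mean(off != "csr")
  expected <- 1 - (1 - rate)^3
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(frac - expected), 3 * se)
})
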