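test_that("the population size is conserved and frequencies sum to 1", {
  p <- table1_params(P = 600)
  set.seed(1)
  traj <- abm_run(even3, p, generations = 20, record_every = 5)
  xc <- grep("^x_", names(traj), value = TRUE)
  expect_true(all(abs(rowSums(traj[, xc]) - 1) < 1e-12))
  expect_length(attr(traj, "final_state"), p$P)
})

test_that("runs are bitwise reproducible from the seed", {
  p <- table1_params(P = 500)
  set.seed(99)
  t1 <- abm_run(even3, p, generations = 15)
  set.seed(99)
  t2 <- abm_run(even3, p, generations = 15)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(attr(t1, "final_state"), attr(t2, "final_state"))
  set.seed(100)
  t3 <- abm_run(even3, p, generations = 15)
  expect_false(identical(as.data.frame(t1), as.data.frame(t3)))
})

test_that("without mutation the initial strategy support is closed", {
  p <- table1_params(P = 800)
  set.seed(3)
  traj <- abm_run(even3, p, generations = 50, record_every = 1)
  outside <- c("x_Bo", "x_Ne", "x_Li", "x_Cl", "x_Vo")
  expect_true(all(as.matrix(traj[, outside]) == 0))
})

test_that("a monomorphic unconditional-cooperator population is static", {
  p <- table1_params(P = 400, kappa = 3)
  set.seed(8)
  traj <- abm_run(rep("Csr", 400), p, generations = 10)
  expect_true(all(traj$x_Tr == 1))
})

test_that("exact-count initialisation hits the requested frequencies", {
  p <- table1_params(P = 1000)
  set.seed(2)
  pop <- abm_init(c(La = 0.507, Tr = 0.331, Sm = 0.162), p)
  counts <- table(factor(pop, levels = qs_genotypes()$allele))
  expect_equal(sum(counts), 1000)
  expect_equal(unname(counts[["csr"]]), 507)
  expect_equal(unname(counts[["Csr"]]), 331)
  expect_equal(unname(counts[["CsR"]]), 162)
})

test_that("under a low benefit the finite population collapses to Lazy", {
  # the b = 0.3 regime has the Lazy vertex as unique attractor
  p <- table1_params(b = 0.3, P = 2000)
  set.seed(21)
  traj <- abm_run(even3, p, generations = 600, record_every = 100)
  expect_gte(final_frequencies(traj)[["x_La"]], 0.99)
})

test_that("short-run empirical drift points with the CF flow at interior states", {
  p <- table1_params(P = 4000)
  set.seed(31)
  pts <- list(c(0.4, 0.4, 0.2), c(0.6, 0.2, 0.2))
  for (x0 in pts) {
    drift <- rep(0, 3)
    reps <- 12
    for (i in seq_len(reps)) {
      pop <- abm_init(stats::setNames(x0, feasible3), p)
      start <- as.numeric(table(factor(pop, levels = feasible3))) / p$P
      traj <- abm_run(pop, p, generations = 3, record_every = 3)
      fin <- final_frequencies(traj)[c("x_La", "x_Tr", "x_Sm")]
      drift <- drift + (as.numeric(fin) - start) / 3
    }
    drift <- drift / reps
    v <- cf_flow(x0, p)
    expect_gt(sum(drift * v) / sqrt(sum(drift^2) * sum(v^2)), 0)
  }
})
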