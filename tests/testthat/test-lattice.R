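test_that("the Moore group wraps the torus and always has 9 members", {
  g <- matrix("Csr", 5, 5)
  grp <- moore_group(g, 3, 3)
  expect_equal(sum(grp), 9)
  expect_equal(unname(grp[["Csr"]]), 9)
  # corner group draws from the wrapped rows/cols
  g2 <- matrix("csr", 5, 5)
  g2[5, 5] <- "Csr"; g2[1, 2] <- "CsR"; g2[2, 5] <- "cSr"
  grp2 <- moore_group(g2, 1, 1)
  expect_equal(sum(grp2), 9)
  expect_equal(unname(grp2[["Csr"]]), 1)  # (5,5) wraps into (1,1)'s block
  expect_equal(unname(grp2[["CsR"]]), 1)
  expect_equal(unname(grp2[["cSr"]]), 1)
})

test_that("site costs resolve activation against each agent's own neighborhood", {
  p <- table1_params(kappa = 3)
  gTr <- matrix("Csr", 6, 6)
  expect_equal(site_cost(gTr, 2, 4, p), (1 - p$b) * (p$c0 + p$c))
  gLa <- matrix("csr", 6, 6)
  expect_equal(site_cost(gLa, 1, 1, p), p$c0)
  # a lone Smart among Lazy sees only its own cue: silent, pays c0 + r
  gSm <- matrix("csr", 7, 7); gSm[4, 4] <- "CsR"
  expect_equal(site_cost(gSm, 4, 4, p), p$c0 + p$r)
  # give it a quorum of neighbors and it activates
  gSm[4, 3] <- "Csr"; gSm[4, 5] <- "Csr"
  expect_equal(site_cost(gSm, 4, 4, p), (1 - p$b) * (p$c0 + p$c + p$r))
})

test_that("site cost depends only on the 5x5 block around the site", {
  p <- table1_params(kappa = 4)
  set.seed(17)
  alleles <- qs_genotypes()$allele
  g <- matrix(sample(alleles, 81, TRUE), 9, 9)
  base <- site_cost(g, 5, 5, p)
  wrap <- function(i) (i - 1) %% 9 + 1
  inside <- as.matrix(expand.grid(wrap(3:7), wrap(3:7)))
  for (trial in 1:10) {
    g2 <- matrix(sample(alleles, 81, TRUE), 9, 9)
    g2[inside] <- g[inside]
    expect_equal(site_cost(g2, 5, 5, p), base)
  }
})

test_that("the compiled engine and the R reference agree on all site costs", {
  set.seed(23)
  alleles <- qs_genotypes()$allele
  for (kq in list(c(3, 3), c(5, 5), c(2, 4))) {
    p <- table1_params(kappa = kq[1], Q = kq[2])
    g <- matrix(sample(alleles, 100, TRUE), 10, 10)
    eng <- cueqs:::.lattice_site_costs(cueqs:::as_lattice_codes(g),
                                       cueqs:::engine_par(p))
    ref <- matrix(NA_real_, 10, 10)
    for (i in 1:10) for (j in 1:10) ref[i, j] <- site_cost(g, i, j, p)
    expect_equal(eng, ref)
  }
})

test_that("diffusion permutes the grid without changing genotype counts", {
  p <- table1_params(D = 2.5, M = 12)
  set.seed(4)
  g <- lattice_init(even8, p)
  out <- diffusion_steps(g, p, n_steps = 200)
  expect_equal(table(as.character(unclass(out))),
               table(as.character(unclass(g))))
  expect_false(identical(unclass(out)[, ], unclass(g)[, ]))
  # D = 0 leaves the grid untouched
  p0 <- table1_params(D = 0, M = 12)
  out0 <- diffusion_steps(g, p0, n_steps = 50)
  expect_identical(unclass(out0)[, ], unclass(g)[, ])
})

test_that("the Poisson swap count has mean D", {
  p <- table1_params(D = 0.5, M = 10)
  set.seed(6)
  g <- lattice_init(even8, p)
  n_steps <- 1e5
  out <- diffusion_steps(g, p, n_steps = n_steps)
  mean_swaps <- attr(out, "total_swaps") / n_steps
  se <- sqrt(p$D / n_steps)
  expect_lt(abs(mean_swaps - p$D), 3 * se)
  # deterministic alternative: floor(D) + Bernoulli remainder
  pd <- table1_params(D = 1.25, M = 10,
                      diffusion_mode = "deterministic")
  set.seed(7)
  out2 <- diffusion_steps(g, pd, n_steps = 2e4)
  mean2 <- attr(out2, "total_swaps") / 2e4
  expect_lt(abs(mean2 - 1.25), 3 * sqrt(0.25 * 0.75 / 2e4))
})

test_that("lattice runs are seed-deterministic, conservative and closed", {
  p <- table1_params(M = 16)
  set.seed(12)
  t1 <- lattice_run(even3, p, generations = 20, record_every = 5)
  set.seed(12)
  t2 <- lattice_run(even3, p, generations = 20, record_every = 5)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_identical(unclass(attr(t1, "final_state"))[, ],
                   unclass(attr(t2, "final_state"))[, ])
  xc <- grep("^x_", names(t1), value = TRUE)
  expect_true(all(abs(rowSums(t1[, xc]) - 1) < 1e-12))
  expect_equal(dim(attr(t1, "final_state")), c(16, 16))
  # closure without mutation
  expect_true(all(as.matrix(t1[, c("x_Bo", "x_Ne", "x_Li", "x_Cl", "x_Vo")])
                  == 0))
})

test_that("identical neighbors and zero mutation leave a step inert", {
  # an all-Trusty lattice never changes: every pair has equal costs and
  # copying preserves the state
  p <- table1_params(M = 8)
  g <- matrix("Csr", 8, 8)
  set.seed(2)
  tr <- lattice_run(g, p, generations = 5)
  expect_true(all(tr$x_Tr == 1))
})

test_that("snapshots and plain-text round trips preserve the grid", {
  p <- table1_params(M = 10)
  set.seed(14)
  tr <- lattice_run(even8, p, generations = 4, record_every = 2,
                    snapshot_every = 2)
  snaps <- attr(tr, "snapshots")
  expect_length(snaps, 2L)
  expect_identical(unclass(snaps[[2]])[, ],
                   unclass(attr(tr, "final_state"))[, ])
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_lattice(snaps[[1]], tmp)
  back <- read_lattice(tmp)
  expect_identical(unclass(back)[, ], unclass(snaps[[1]])[, ])
})

test_that("von Neumann pairing restricts competition to orthogonal neighbors", {
  # a smoke check through the toggle: dynamics still conserve and close
  p <- table1_params(M = 12, pair_adjacency = "vonneumann")
  set.seed(19)
  tr <- lattice_run(even3, p, generations = 10)
  xc <- grep("^x_", names(tr), value = TRUE)
  expect_true(all(abs(rowSums(tr[, xc]) - 1) < 1e-12))
})
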