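test_that("mean-field costs follow the threshold-indicator regimes", {
  p <- table1_params()
  # no cooperators anywhere: nobody benefits, Smart stays silent
  c1 <- mf_costs(c(1, 0, 0), p, K = 1 / 3)
  expect_equal(as.numeric(c1), c(p$c0, p$c0 + p$c, p$c0 + p$r))
  # above both thresholds: everyone benefits, Smart active
  c2 <- mf_costs(c(0.5, 0.4, 0.1), p, K = 1 / 3)
  expect_equal(as.numeric(c2), c(0.5, 0.65, 0.655))
  # signal carriers below quorum: Smart silent, no benefit
  c3 <- mf_costs(c(0.8, 0.1, 0.1), p, K = 1 / 3)
  expect_equal(as.numeric(c3), c(p$c0, p$c0 + p$c, p$c0 + p$r))
})

test_that("the mean-field flow conserves the simplex and fixes its vertices", {
  p <- table1_params()
  for (v in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    expect_equal(unname(mf_flow(v, p)), c(0, 0, 0))
  }
  set.seed(11)
  for (i in 1:50) {
    x <- runif_simplex(3)
    expect_lt(abs(sum(mf_flow(x, p))), 1e-14)
  }
})

test_that("equal costs give zero selection", {
  p <- table1_params()
  # on the Tr-Sm-free edge interior there is still selection; force equality
  # by a state where all three strategies are absent except one
  expect_equal(unname(mf_flow(c(0, 1, 0), p)), c(0, 0, 0))
  # theta = 1 regime on the La-Tr edge: Lazy undercuts Trusty
  v <- mf_flow(c(0.5, 0.5, 0), p, K = 1 / 3)
  expect_gt(v[["La"]], 0)
  expect_lt(v[["Tr"]], 0)
})

test_that("trajectories stay on the simplex and Lazy absorbs sub-threshold mutants", {
  p <- table1_params()
  traj <- mf_trajectory(c(0.8, 0.1, 0.1), p, T = 800, dt = 0.2)
  sums <- traj$x_La + traj$x_Tr + traj$x_Sm
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(traj$x_La >= -1e-12))
  fin <- unlist(traj[nrow(traj), c("x_La", "x_Tr", "x_Sm")])
  expect_gt(fin[["x_La"]], 0.999)
})

test_that("the La/Tr boundary equilibrium appears exactly above b = c/(c0+c)", {
  p_lo <- table1_params(b = 0.20)   # below 0.3/1.3
  p_hi <- table1_params(b = 0.26)   # above 0.3/1.3
  has_latr <- function(p) {
    fp <- mf_fixed_points(p)
    any(fp$type == "edge" & fp$edge == "La-Tr")
  }
  expect_false(has_latr(p_lo))
  expect_true(has_latr(p_hi))
  # and the pinned point sits at the threshold fraction x_Tr = K
  fp <- mf_fixed_points(p_hi)
  pt <- fp[fp$type == "edge" & fp$edge == "La-Tr" &
             fp$class != "unstable", ]
  expect_equal(pt$x_Tr[1], p_hi$kappa / p_hi$N, tolerance = 1e-3)
  expect_true(all(pt$pinned))
})

test_that("the mean-field vector field exports the standard CSV schema", {
  p <- table1_params()
  f <- mf_vector_field(p, resolution = 0.25)
  expect_named(f, c("x_La", "x_Tr", "x_Sm", "v_La", "v_Tr", "v_Sm"))
  expect_true(all(abs(f$v_La + f$v_Tr + f$v_Sm) < 1e-14))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_qs_csv(f, tmp)
  back <- readr::read_csv(tmp, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(tibble::as_tibble(f)),
               tolerance = 1e-12, ignore_attr = TRUE)
})
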