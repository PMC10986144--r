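# Configuration-field (CF) model: the population is infinite but interaction
# groups are finite random samples of size N. Expected strategy costs are
# exact multinomial averages over all compositions of the N-1 co-members;
# the dynamics is replicator flow on negative expected costs. Because every
# composition carries a fixed cost, the expected cost is a polynomial in the
# strategy frequencies and the flow is smooth, unlike the mean-field tier.

#' Enumerate neighbor compositions
#'
#' All multisets of `slots` co-members over `n_strategies` strategies;
#' `choose(slots + n_strategies - 1, slots)` compositions in total.
#'
#' @param n_strategies number of strategies.
#' @param slots number of co-member slots (`N - 1` in the CF model).
#' @return Integer matrix, one row per composition, rows summing to `slots`.
#' @examples
#' nrow(enumerate_compositions(3, 8))  # 45
#' @export
enumerate_compositions <- function(n_strategies, slots) {
  stopifnot(n_strategies >= 1L, slots >= 0L)
  compositions_matrix(n_strategies, slots)
}

compositions_matrix <- function(k, m) {
  if (k == 1L) return(matrix(as.integer(m), 1L, 1L))
  out <- vector("list", m + 1L)
  for (first in 0:m) {
    rest <- compositions_matrix(k - 1L, m - first)
    out[[first + 1L]] <- cbind(as.integer(first), rest)
  }
  do.call(rbind, out)
}

# Precompute, for a strategy set and params, the per-composition realized
# cost of each focal strategy plus the log multinomial coefficients.
# Costs depend only on the composition, not on x, so fixed-point searches
# reuse this table.
cf_setup <- function(params, strategies) {
  strategies <- as_genotype(strategies)
  k <- length(strategies)
  comps <- compositions_matrix(k, params$N - 1L)
  hasC <- genotype_has_C(strategies)
  hasS <- genotype_has_S(strategies)
  hasR <- genotype_has_R(strategies)
  dose_w <- hasC + hasS
  lcoef <- lgamma(params$N) - rowSums(lgamma(comps + 1))  # (N-1)! / prod n_i!
  costs <- matrix(NA_real_, nrow(comps), k,
                  dimnames = list(NULL, strategies))
  for (f in seq_len(k)) {
    grp <- comps
    grp[, f] <- grp[, f] + 1L           # focal joins its own group
    doses <- as.vector(grp %*% dose_w)
    active <- doses >= params$Q
    # gamma per member strategy: unconditional C always, conditional C iff
    # the shared group dose pool reaches Q
    gmat <- outer(active, hasC & hasR) | matrix(hasC & !hasR, nrow(grp), k,
                                                byrow = TRUE)
    n_active <- rowSums(grp * gmat)
    theta <- as.integer(n_active >= params$kappa)
    gamma_f <- as.integer(gmat[, f])
    costs[, f] <- (1 - theta * params$b) *
      (params$c0 + gamma_f * params$c * hasC[f] +
         params$s * hasS[f] + params$r * hasR[f])
  }
  list(strategies = strategies, comps = comps, lcoef = lcoef, costs = costs)
}

# multinomial weights, evaluated as a polynomial in x (integer powers), so
# the flow extends smoothly to a neighborhood of the simplex boundary --
# needed for central-difference Jacobians at vertices and edges
cf_weights <- function(x, setup) {
  w <- exp(setup$lcoef)
  for (j in seq_along(x)) {
    w <- w * x[j]^setup$comps[, j]
  }
  w
}

#' Expected configuration-field cost of each strategy
#'
#' The expected realized cost of a focal individual of each strategy when its
#' `N - 1` co-members are an i.i.d. multinomial draw from the population
#' frequencies `x`: a weighted average of the focal's realized cost over all
#' compositions, with the whole group (focal included) sharing one signal
#' pool for quorum evaluation.
#'
#' @param x frequency vector over `strategies` (non-negative, sums to 1).
#' @param params a [qs_params()] object.
#' @param strategies character vector of strategy labels; default the three
#'   feasible strategies La, Tr, Sm.
#' @param setup optional precomputed composition/cost table (internal reuse).
#' @return Named numeric vector of expected costs.
#' @examples
#' cf_expected_cost(c(0.6, 0.3, 0.1), qs_params())
#' @export
cf_expected_cost <- function(x, params = qs_params(),
                             strategies = c("csr", "Csr", "CsR"),
                             setup = NULL) {
  if (is.null(setup)) setup <- cf_setup(params, strategies)
  x <- check_freq(x, length(setup$strategies))
  w <- cf_weights(x, setup)
  stats::setNames(as.vector(crossprod(setup$costs, w)), setup$strategies)
}

check_freq <- function(x, k) {
  x <- as.numeric(x)
  if (length(x) != k) stop("frequency vector has wrong length", call. = FALSE)
  if (any(x < -1e-12) || abs(sum(x) - 1) > 1e-8) {
    stop("frequencies must be non-negative and sum to 1", call. = FALSE)
  }
  pmax(x, 0)
}

# single-locus mutation mixing matrix over a strategy set (rate per locus per
# replication); multi-locus flips are O(rho^2) and omitted from the flow
cf_mutation_matrix <- function(params, strategies) {
  strategies <- as_genotype(strategies)
  k <- length(strategies)
  codes <- genotype_code(strategies)
  mu <- params$mu
  bits <- c(1L, 2L, 4L)
  loss <- c(mu[["C_loss"]], mu[["S_loss"]], mu[["R_loss"]])
  gain <- c(mu[["C_gain"]], mu[["S_gain"]], mu[["R_gain"]])
  Mmat <- matrix(0, k, k, dimnames = list(strategies, strategies))
  for (i in seq_len(k)) {
    for (l in 1:3) {
      target <- bitwXor(codes[i], bits[l])
      j <- match(target, codes)
      if (!is.na(j)) {
        rate <- if (bitwAnd(codes[i], bits[l]) > 0L) loss[l] else gain[l]
        Mmat[i, j] <- Mmat[i, j] + rate
      }
    }
  }
  Mmat
}

#' Configuration-field replicator flow
#'
#' Replicator dynamics on negative expected CF costs, with the same
#' `sigma / delta_C_max` scaling as the mean-field tier. If any mutation rate
#' in `params$mu` is positive, a linear one-locus mutation mixing term is
#' added.
#'
#' @inheritParams cf_expected_cost
#' @return Named numeric velocity vector (sums to zero when mutation is off).
#' @export
cf_flow <- function(x, params = qs_params(),
                    strategies = c("csr", "Csr", "CsR"), setup = NULL) {
  if (is.null(setup)) setup <- cf_setup(params, strategies)
  x <- check_freq(x, length(setup$strategies))
  cf_flow_raw(x, params, setup)
}

# polynomial extension of the flow; no simplex validation (used by Newton
# polish and Jacobians, which probe slightly outside the boundary)
cf_flow_raw <- function(x, params, setup) {
  w <- cf_weights(x, setup)
  costs <- as.vector(crossprod(setup$costs, w))
  cbar <- sum(x * costs)
  v <- x * (cbar - costs) * params$sigma / delta_C_max(params)
  if (any(params$mu > 0)) {
    Mmat <- cf_mutation_matrix(params, setup$strategies)
    v <- v + as.vector(crossprod(Mmat, x)) - x * rowSums(Mmat)
  }
  stats::setNames(as.numeric(v), setup$strategies)
}

#' Integrate a configuration-field trajectory
#'
#' Fixed-step RK4 on the smooth CF flow.
#'
#' @inheritParams cf_expected_cost
#' @param x0 initial frequency vector.
#' @param T total integration time.
#' @param dt time step.
#' @return A tibble of class `qs_trajectory`.
#' @export
cf_trajectory <- function(x0, params = qs_params(),
                          strategies = c("csr", "Csr", "CsR"),
                          T = 200, dt = 0.2) {
  setup <- cf_setup(params, strategies)
  k <- length(setup$strategies)
  x <- check_freq(x0, k)
  renorm <- function(z) { z <- pmax(z, 0); z / sum(z) }
  flow <- function(z) cf_flow(z, params, setup = setup)
  n_steps <- ceiling(T / dt)
  xs <- matrix(NA_real_, n_steps + 1L, k)
  xs[1L, ] <- x
  for (i in seq_len(n_steps)) {
    k1 <- flow(x)
    k2 <- flow(renorm(x + dt / 2 * k1))
    k3 <- flow(renorm(x + dt / 2 * k2))
    k4 <- flow(renorm(x + dt * k3))
    x <- renorm(x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
    xs[i + 1L, ] <- x
  }
  out <- tibble::as_tibble(stats::setNames(
    as.data.frame(xs), strategy_cols(setup$strategies)))
  out <- tibble::add_column(out, time = seq(0, by = dt, length.out = n_steps + 1L),
                            .before = 1L)
  new_qs_trajectory(out, model = "configfield",
                    strategies = setup$strategies, params = params)
}

#' Sample the configuration-field vector field on the simplex
#'
#' @inheritParams cf_expected_cost
#' @param resolution barycentric grid spacing.
#' @return A tibble of class `qs_field` with `x_*` and `v_*` columns.
#' @export
cf_vector_field <- function(params = qs_params(),
                            strategies = c("csr", "Csr", "CsR"),
                            resolution = 0.05) {
  setup <- cf_setup(params, strategies)
  k <- length(setup$strategies)
  grid <- simplex_grid(k, resolution)
  v <- t(apply(grid, 1L, function(x) cf_flow(x, params, setup = setup)))
  lab <- strategy_label(setup$strategies)
  out <- tibble::as_tibble(cbind(
    stats::setNames(as.data.frame(grid), paste0("x_", lab)),
    stats::setNames(as.data.frame(v), paste0("v_", lab))
  ))
  new_qs_field(out, model = "configfield", strategies = setup$strategies,
               params = params)
}

#' Configuration-field fixed points
#'
#' Dense barycentric grid seeding followed by damped Newton polish on the
#' reduced (`k - 1`)-coordinate flow, duplicate merging, and stability
#' classification from the eigenvalues of the numerical Jacobian restricted
#' to the simplex tangent space (transversal directions at boundary points
#' included).
#'
#' @inheritParams cf_expected_cost
#' @param seed_resolution spacing of the seeding grid (default 0.02).
#' @param tol Newton convergence tolerance on the flow norm.
#' @param merge_tol Euclidean distance below which two converged points are
#'   considered the same fixed point.
#' @return A tibble of class `qs_fixed_points` with one frequency column per
#'   strategy, `class` (`"stable"`, `"unstable"`, `"saddle"`,
#'   `"unclassified"`), `max_re` and `min_re` (extreme real parts of the
#'   tangent-space eigenvalues) and `n_seeds` (how many seeds converged
#'   there).
#' @examples
#' \donttest{
#' cf_fixed_points(qs_params(b = 0.5, r = 0.01), seed_resolution = 0.1)
#' }
#' @export
cf_fixed_points <- function(params = qs_params(),
                            strategies = c("csr", "Csr", "CsR"),
                            seed_resolution = 0.02,
                            tol = 1e-10, merge_tol = 1e-6) {
  setup <- cf_setup(params, strategies)
  k <- length(setup$strategies)
  # reduced coordinates u = x[1..k-1], x_k = 1 - sum(u); the polynomial
  # extension of the flow is valid slightly outside the simplex
  Fu <- function(u) {
    x <- c(u, 1 - sum(u))
    if (any(x < -1e-4)) return(rep(NA_real_, k - 1L))
    cf_flow_raw(x, params, setup)[seq_len(k - 1L)]
  }
  seeds <- simplex_grid(k, seed_resolution)
  found <- list()
  for (srow in seq_len(nrow(seeds))) {
    u <- seeds[srow, seq_len(k - 1L)]
    ok <- FALSE
    for (iter in 1:60) {
      f <- Fu(u)
      if (anyNA(f)) break
      if (max(abs(f)) < tol) { ok <- TRUE; break }
      J <- num_jacobian(Fu, u)
      step <- tryCatch(solve(J, f), error = function(e) NULL)
      if (is.null(step) || anyNA(step) || any(!is.finite(step))) break
      # dampen steps that would leave the simplex
      lambda <- 1
      repeat {
        u_new <- u - lambda * step
        x_new <- c(u_new, 1 - sum(u_new))
        if (all(x_new > -1e-5) || lambda < 1e-4) break
        lambda <- lambda / 2
      }
      if (max(abs(u_new - u)) < 1e-15) { ok <- max(abs(f)) < 1e-8; break }
      u <- u_new
    }
    if (!ok) next
    x <- c(u, 1 - sum(u))
    if (any(x < -1e-7)) next
    x[abs(x) < 1e-7] <- 0
    x <- x / sum(x)
    # merge with previously found points
    merged <- FALSE
    for (q in seq_along(found)) {
      if (sqrt(sum((found[[q]]$x - x)^2)) < merge_tol) {
        found[[q]]$n <- found[[q]]$n + 1L
        merged <- TRUE
        break
      }
    }
    if (!merged) found[[length(found) + 1L]] <- list(x = x, n = 1L)
  }

  if (length(found) == 0L) {
    out <- tibble::as_tibble(stats::setNames(
      as.data.frame(matrix(numeric(0), 0L, k)),
      strategy_cols(setup$strategies)))
    out$class <- character(0); out$max_re <- numeric(0)
    out$min_re <- numeric(0); out$n_seeds <- integer(0)
  } else {
    cls <- character(length(found))
    max_re <- min_re <- numeric(length(found))
    for (q in seq_along(found)) {
      u <- found[[q]]$x[seq_len(k - 1L)]
      J <- num_jacobian(Fu, u)
      if (anyNA(J)) {
        cls[q] <- "unclassified"; max_re[q] <- NA; min_re[q] <- NA
        next
      }
      ev <- Re(eigen(J, only.values = TRUE)$values)
      max_re[q] <- max(ev); min_re[q] <- min(ev)
      cls[q] <- if (max(ev) < -1e-8) "stable"
      else if (min(ev) > 1e-8) "unstable"
      else if (max(ev) > 1e-8 && min(ev) < -1e-8) "saddle"
      else "unclassified"
    }
    xmat <- do.call(rbind, lapply(found, `[[`, "x"))
    out <- tibble::as_tibble(stats::setNames(
      as.data.frame(xmat), strategy_cols(setup$strategies)))
    out$class <- cls
    out$max_re <- max_re
    out$min_re <- min_re
    out$n_seeds <- vapply(found, `[[`, integer(1), "n")
    out <- dplyr::arrange(out, dplyr::desc(.data$n_seeds))
  }
  class(out) <- c("qs_fixed_points", class(out))
  attr(out, "model") <- "configfield"
  attr(out, "strategies") <- setup$strategies
  attr(out, "params") <- params
  out
}

num_jacobian <- function(f, u, h = 1e-7) {
  m <- length(u)
  f0 <- f(u)
  J <- matrix(NA_real_, length(f0), m)
  for (j in seq_len(m)) {
    up <- u; up[j] <- up[j] + h
    um <- u; um[j] <- um[j] - h
    fp <- f(up); fm <- f(um)
    if (anyNA(fp) || anyNA(fm)) {
      # one-sided at the simplex boundary
      if (anyNA(fp)) { fp <- f0; up <- u }
      if (anyNA(fm)) { fm <- f0; um <- u }
      denom <- up[j] - um[j]
      if (denom == 0) return(matrix(NA_real_, length(f0), m))
      J[, j] <- (fp - fm) / denom
    } else {
      J[, j] <- (fp - fm) / (2 * h)
    }
  }
  J
}
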