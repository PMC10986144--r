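# Mean-field (infinite population, infinitely large groups) dynamics of the
# three feasible strategies La (csr), Tr (Csr), Sm (CsR). The flow is
# replicator dynamics on negative costs -- the exact mean dynamics of the
# pairwise-imitation process -- and is piecewise smooth, with discontinuity
# surfaces where the quorum indicator gamma_Sm or the benefit indicator theta
# switches.

mf_strategies <- c("csr", "Csr", "CsR")

as_simplex3 <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 3L) stop("state must have 3 components", call. = FALSE)
  if (any(x < -1e-12) || abs(sum(x) - 1) > 1e-9) {
    stop("state must lie on the 3-simplex", call. = FALSE)
  }
  pmax(x, 0)
}

#' Mean-field strategy costs
#'
#' Expected metabolic costs of Lazy, Trusty and Smart at a point on the
#' 3-strategy simplex, in the limit of infinitely large interaction groups
#' where the cooperator fraction in every group equals the population
#' frequency. Smart activates when the signal-carrier fraction `x_C =
#' x_Tr + x_Sm` reaches the threshold fraction `K = kappa / N`; the benefit
#' arrives when the active-cooperator fraction reaches `K`.
#'
#' `offset` is the finite-group-size correction: an agent is a member of its
#' own group, so a cooperator's own dose/activity shifts its effective
#' threshold down by `1/N`. The continuum flow uses `offset = 0`; the
#' fixed-point analysis uses `offset = 1/N` by default, which is what makes
#' the Lazy/Trusty boundary equilibrium of the theory visible.
#'
#' @param x numeric length-3 frequency vector `(x_La, x_Tr, x_Sm)`.
#' @param params a [qs_params()] object (costs, `b`, `kappa`, `N`).
#' @param K threshold fraction; defaults to `kappa / N`.
#' @param offset finite-size threshold offset for self-inclusion (default 0).
#' @return Named numeric vector of the three strategy costs, with attributes
#'   `gamma_Sm` and `theta` (named 0/1 per strategy).
#' @export
mf_costs <- function(x, params = qs_params(), K = params$kappa / params$N,
                     offset = 0) {
  x <- as_simplex3(x)
  x_C <- x[2] + x[3]
  gamma_Sm <- as.integer(x_C >= K - offset)      # Smart's own cue counts
  a <- x[2] + gamma_Sm * x[3]                    # active-cooperator fraction
  theta <- c(La = as.integer(a >= K),
             Tr = as.integer(a >= K - offset),
             Sm = as.integer(a >= K - offset * gamma_Sm))
  costs <- c(
    La = (1 - theta[["La"]] * params$b) * params$c0,
    Tr = (1 - theta[["Tr"]] * params$b) * (params$c0 + params$c),
    Sm = (1 - theta[["Sm"]] * params$b) *
      (params$c0 + gamma_Sm * params$c + params$r)
  )
  attr(costs, "gamma_Sm") <- gamma_Sm
  attr(costs, "theta") <- theta
  costs
}

#' Mean-field replicator flow
#'
#' `dx_i/dt = x_i * sum_j x_j * sigma * (cost_j - cost_i) / delta_C_max`:
#' replicator dynamics on negative costs, the continuous-time mean dynamics of
#' the pairwise imitation rule. Velocities sum to zero.
#'
#' @inheritParams mf_costs
#' @return Named numeric length-3 velocity vector.
#' @export
mf_flow <- function(x, params = qs_params(), K = params$kappa / params$N,
                    offset = 0) {
  x <- as_simplex3(x)
  costs <- mf_costs(x, params, K, offset)
  cbar <- sum(x * costs)
  v <- x * (cbar - costs) * params$sigma / delta_C_max(params)
  stats::setNames(as.numeric(v), c("La", "Tr", "Sm"))
}

# detect which smooth piece a state is in (indicator signature)
mf_region <- function(x, params, K, offset) {
  costs <- mf_costs(x, params, K, offset)
  c(attr(costs, "gamma_Sm"), attr(costs, "theta"))
}

#' Integrate a mean-field trajectory
#'
#' Fixed-step RK4 with event handling at the discontinuity surfaces (where
#' `gamma_Sm` or any `theta` indicator flips): a step that crosses a surface
#' is shortened by bisection so that the integrator lands just past the
#' boundary instead of straddling it.
#'
#' @inheritParams mf_costs
#' @param x0 initial frequencies `(x_La, x_Tr, x_Sm)`.
#' @param T total integration time.
#' @param dt time step.
#' @return A tibble of class `qs_trajectory` with columns `time`, `x_La`,
#'   `x_Tr`, `x_Sm`.
#' @examples
#' mf_trajectory(c(0.4, 0.4, 0.2), qs_params(b = 0.5), T = 50)
#' @export
mf_trajectory <- function(x0, params = qs_params(),
                          T = 100, dt = 0.05,
                          K = params$kappa / params$N, offset = 0) {
  flow <- function(x) mf_flow(x, params, K, offset)
  region <- function(x) mf_region(x, params, K, offset)
  traj <- integrate_piecewise(x0, flow, region, T, dt)
  out <- tibble::tibble(time = traj$time,
                        x_La = traj$x[, 1], x_Tr = traj$x[, 2],
                        x_Sm = traj$x[, 3])
  new_qs_trajectory(out, model = "meanfield",
                    strategies = mf_strategies, params = params)
}

# shared fixed-step RK4 with indicator-aware step shortening
integrate_piecewise <- function(x0, flow, region, T, dt) {
  renorm <- function(x) { x <- pmax(x, 0); x / sum(x) }
  x <- renorm(as.numeric(x0))
  n_steps <- ceiling(T / dt)
  xs <- matrix(NA_real_, n_steps + 1L, length(x))
  ts <- numeric(n_steps + 1L)
  xs[1L, ] <- x
  rk4 <- function(x, h) {
    k1 <- flow(x)
    k2 <- flow(renorm(x + h / 2 * k1))
    k3 <- flow(renorm(x + h / 2 * k2))
    k4 <- flow(renorm(x + h * k3))
    renorm(x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
  }
  t <- 0
  for (i in seq_len(n_steps)) {
    reg0 <- region(x)
    x1 <- rk4(x, dt)
    if (!identical(region(x1), reg0)) {
      # bisect the step length down to the crossing, then take the remainder
      lo <- 0; hi <- dt
      for (k in 1:30) {
        mid <- (lo + hi) / 2
        if (identical(region(rk4(x, mid)), reg0)) lo <- mid else hi <- mid
      }
      x_boundary <- rk4(x, lo)
      rest <- dt - lo
      x1 <- if (rest > 1e-12) rk4(x_boundary, rest) else x_boundary
    }
    x <- x1
    t <- t + dt
    xs[i + 1L, ] <- x
    ts[i + 1L] <- t
  }
  list(time = ts, x = xs)
}

#' Sample the mean-field vector field on the simplex
#'
#' @inheritParams mf_costs
#' @param resolution barycentric grid spacing.
#' @return A tibble of class `qs_field` with columns `x_La`, `x_Tr`, `x_Sm`,
#'   `v_La`, `v_Tr`, `v_Sm`.
#' @export
mf_vector_field <- function(params = qs_params(), resolution = 0.05,
                            K = params$kappa / params$N, offset = 0) {
  grid <- simplex_grid(3L, resolution)
  v <- t(apply(grid, 1L, function(x) mf_flow(x, params, K, offset)))
  out <- tibble::tibble(
    x_La = grid[, 1], x_Tr = grid[, 2], x_Sm = grid[, 3],
    v_La = v[, 1], v_Tr = v[, 2], v_Sm = v[, 3]
  )
  new_qs_field(out, model = "meanfield", strategies = mf_strategies,
               params = params)
}

# barycentric grid over the (k-1)-simplex with spacing `resolution`
simplex_grid <- function(k, resolution) {
  m <- round(1 / resolution)
  comps <- compositions_matrix(k, m)
  comps / m
}

#' Mean-field fixed points
#'
#' Locates and classifies the fixed points of the piecewise mean-field flow:
#' the three vertices (always fixed), interior zeros of the edge flows, and
#' threshold-pinned boundary points where the edge flow jumps sign across a
#' discontinuity surface without vanishing (Filippov sliding points). With
#' the default finite-size `offset = 1/N` the Lazy/Trusty pinned coexistence
#' point exists exactly when `b / c > 1 / (c0 + c)`; with `offset = 0` the
#' activation band collapses and the pinned point disappears, which is why
#' the default here differs from the continuum flow functions.
#'
#' @inheritParams mf_costs
#' @param offset finite-size threshold offset; default `1/N`.
#' @param edge_grid number of scan points per edge.
#' @return A tibble of class `qs_fixed_points`: columns `x_La`, `x_Tr`,
#'   `x_Sm`, `type` (`"vertex"`/`"edge"`), `edge`, `pinned` (logical),
#'   `class` (`"stable"`, `"unstable"`, `"saddle"`).
#' @export
mf_fixed_points <- function(params = qs_params(),
                            K = params$kappa / params$N,
                            offset = 1 / params$N,
                            edge_grid = 2000L) {
  flow <- function(x) mf_flow(x, params, K, offset)
  labels <- c("La", "Tr", "Sm")
  rows <- list()

  # vertices: always fixed; stability by small mixed perturbations
  eps <- min(1e-3, (K - offset) / 4, na.rm = TRUE)
  eps <- max(eps, 1e-6)
  for (i in 1:3) {
    stable <- TRUE
    for (j in setdiff(1:3, i)) {
      x <- numeric(3); x[i] <- 1 - eps; x[j] <- eps
      v <- flow(x)
      if (v[j] > 1e-14) { stable <- FALSE; break }
    }
    # a combined perturbation as well
    if (stable) {
      x <- numeric(3); x[i] <- 1 - 2 * eps
      x[setdiff(1:3, i)] <- eps
      v <- flow(x)
      if (any(v[setdiff(1:3, i)] > 1e-14)) stable <- FALSE
    }
    xv <- numeric(3); xv[i] <- 1
    rows[[length(rows) + 1L]] <- list(
      x = xv, type = "vertex", edge = NA_character_, pinned = FALSE,
      class = if (stable) "stable" else "unstable"
    )
  }

  # edges: scan tangential velocity of the second strategy along the edge
  for (pair in list(c(1L, 2L), c(1L, 3L), c(2L, 3L))) {
    i <- pair[1]; j <- pair[2]
    ts <- seq(1e-6, 1 - 1e-6, length.out = edge_grid)
    g <- vapply(ts, function(t) {
      x <- numeric(3); x[i] <- 1 - t; x[j] <- t
      flow(x)[j]
    }, numeric(1))
    sgn <- sign(g)
    changes <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    for (idx in changes) {
      lo <- ts[idx]; hi <- ts[idx + 1]
      f <- function(t) {
        x <- numeric(3); x[i] <- 1 - t; x[j] <- t
        flow(x)[j]
      }
      for (k in 1:60) {
        mid <- (lo + hi) / 2
        if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
      }
      t_star <- (lo + hi) / 2
      # pinned (jump) vs smooth zero: |g| stays bounded away from 0 at a jump
  	  pinned <- min(abs(f(lo)), abs(f(hi))) > 1e-10
      tang_stable <- f(lo) > 0 && f(hi) < 0
      # transversal stability: growth of the third strategy
      kth <- setdiff(1:3, c(i, j))
      epsv <- 1e-7
      x <- numeric(3); x[i] <- (1 - t_star) * (1 - epsv)
      x[j] <- t_star * (1 - epsv); x[kth] <- epsv
      trans_stable <- flow(x)[kth] < 0
      cls <- if (tang_stable && trans_stable) "stable"
      else if (!tang_stable && !trans_stable) "unstable"
      else "saddle"
      xe <- numeric(3); xe[i] <- 1 - t_star; xe[j] <- t_star
      rows[[length(rows) + 1L]] <- list(
        x = xe, type = "edge",
        edge = paste(labels[i], labels[j], sep = "-"),
        pinned = pinned, class = cls
      )
    }
  }

  out <- tibble::tibble(
    x_La = vapply(rows, function(r) r$x[1], numeric(1)),
    x_Tr = vapply(rows, function(r) r$x[2], numeric(1)),
    x_Sm = vapply(rows, function(r) r$x[3], numeric(1)),
    type = vapply(rows, function(r) r$type, character(1)),
    edge = vapply(rows, function(r) r$edge, character(1)),
    pinned = vapply(rows, function(r) r$pinned, logical(1)),
    class = vapply(rows, function(r) r$class, character(1))
  )
  class(out) <- c("qs_fixed_points", class(out))
  attr(out, "model") <- "meanfield"
  attr(out, "params") <- params
  out
}
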