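#' Model parameters
#'
#' Collects every cost, benefit, threshold and dynamics parameter shared by
#' the four model tiers. Defaults follow the study's standard setting
#' (configuration-field column of the parameter table), with the lattice /
#' population sizes at the desk-scale values used throughout the package's
#' examples and tests.
#'
#' @param c0 baseline metabolic cost paid by every agent (dimensionless).
#' @param c cost of expressed cooperation.
#' @param s cost of the extra signal dose (charged whenever the `S` locus is
#'   active; the constitutive cue of `C`-carriers is free).
#' @param r cost of operating the signal-response machinery (`R` locus).
#' @param b cooperation benefit, in (0, 1); multiplies the whole metabolic
#'   cost by `1 - b` when the group reaches the cooperation threshold.
#' @param sigma selection strength in the imitation rule, in (0, 1].
#' @param kappa cooperation threshold: minimum number of actively cooperating
#'   group members needed to deliver the benefit (integer, `2..N`).
#' @param Q quorum signal threshold: minimum signal doses that switch a
#'   conditional cooperator on. Defaults to `kappa` (the evolutionary optimum
#'   assumed throughout).
#' @param N interaction-group size (9: a lattice Moore neighborhood).
#' @param P population size of the non-spatial agent-based model.
#' @param M lattice side length (population `M^2`).
#' @param G number of generations to simulate.
#' @param D mean number of diffusion site-swaps per elementary game step.
#' @param rho per-locus, per-direction functional mutation rate; shorthand
#'   that fills all six entries of `mu`.
#' @param mu named numeric vector of the six mutation rates
#'   (`C_loss`, `C_gain`, `S_loss`, `S_gain`, `R_loss`, `R_gain`); overrides
#'   `rho` when supplied.
#' @param diffusion_mode `"poisson"` draws the per-step swap count from
#'   Poisson(`D`); `"deterministic"` performs `floor(D)` swaps plus one more
#'   with probability `D - floor(D)`.
#' @param pair_adjacency adjacency used for competing pairs and diffusion
#'   partners on the lattice: `"moore"` (8 neighbors) or `"vonneumann"` (4).
#'
#' @return A list of class `qs_params`.
#' @examples
#' p <- qs_params(b = 0.5, r = 0.01)
#' delta_C_max(p)
#' @export
qs_params <- function(c0 = 1, c = 0.3, s = 0.01, r = 0.01, b = 0.5,
                      sigma = 1, kappa = 3L, Q = kappa, N = 9L,
                      P = 10000L, M = 100L, G = 2000L, D = 0,
                      rho = 0, mu = NULL,
                      diffusion_mode = c("poisson", "deterministic"),
                      pair_adjacency = c("moore", "vonneumann")) {
  diffusion_mode <- match.arg(diffusion_mode)
  pair_adjacency <- match.arg(pair_adjacency)
  if (is.null(mu)) {
    mu <- stats::setNames(rep(rho, 6L),
                          c("C_loss", "C_gain", "S_loss", "S_gain",
                            "R_loss", "R_gain"))
  } else {
    need <- c("C_loss", "C_gain", "S_loss", "S_gain", "R_loss", "R_gain")
    if (is.null(names(mu)) && length(mu) == 6L) names(mu) <- need
    if (!all(need %in% names(mu))) {
      stop("mu must name all six rates: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    mu <- mu[need]
  }
  p <- list(c0 = c0, c = c, s = s, r = r, b = b, sigma = sigma,
            kappa = as.integer(kappa), Q = as.integer(Q), N = as.integer(N),
            P = as.integer(P), M = as.integer(M), G = as.integer(G),
            D = D, mu = mu,
            diffusion_mode = diffusion_mode,
            pair_adjacency = pair_adjacency)
  class(p) <- "qs_params"
  validate_qs_params(p)
  p
}

validate_qs_params <- function(p) {
  stopifnot(p$c0 > 0, p$c >= 0, p$s >= 0, p$r >= 0)
  if (!(p$b > 0 && p$b < 1)) stop("b must be in (0, 1)", call. = FALSE)
  if (!(p$sigma > 0 && p$sigma <= 1)) {
    stop("sigma must be in (0, 1]", call. = FALSE)
  }
  if (p$kappa < 2L || p$kappa > p$N) {
    stop("kappa must satisfy 2 <= kappa <= N", call. = FALSE)
  }
  if (p$Q < 1L) stop("Q must be a positive integer", call. = FALSE)
  if (p$D < 0) stop("D must be non-negative", call. = FALSE)
  if (any(p$mu < 0) || any(p$mu > 1)) {
    stop("mutation rates must lie in [0, 1]", call. = FALSE)
  }
  if (delta_C_max(p) <= 0) stop("delta_C_max must be positive", call. = FALSE)
  invisible(p)
}

#' @rdname qs_params
#' @param p a `qs_params` object.
#' @details `delta_C_max(p)` is the largest possible realized-cost difference,
#'   `c + s + r + b * c0`: an agent expressing every functional locus without
#'   the benefit versus one expressing none with the full benefit. It
#'   normalises the fitness difference in the imitation rule.
#' @export
delta_C_max <- function(p) p$c + p$s + p$r + p$b * p$c0

#' @export
print.qs_params <- function(x, ...) {
  cat("<qs_params>\n")
  cat(sprintf("  costs: c0=%g c=%g s=%g r=%g   benefit b=%g   sigma=%g\n",
              x$c0, x$c, x$s, x$r, x$b, x$sigma))
  cat(sprintf("  thresholds: kappa=%d Q=%d   group N=%d\n",
              x$kappa, x$Q, x$N))
  cat(sprintf("  sizes: P=%d M=%d G=%d   D=%g (%s, %s pairs)\n",
              x$P, x$M, x$G, x$D, x$diffusion_mode, x$pair_adjacency))
  cat(sprintf("  mutation: %s\n",
              paste(sprintf("%s=%g", names(x$mu), x$mu), collapse = " ")))
  invisible(x)
}

# shallow update helper used by sweeps/CLI
update_params <- function(p, ...) {
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm == "rho") {
      p$mu[] <- dots[[nm]]
    } else if (!nm %in% names(p)) {
      stop("unknown parameter: ", nm, call. = FALSE)
    } else {
      p[[nm]] <- if (nm %in% c("kappa", "Q", "N", "P", "M", "G")) {
        as.integer(dots[[nm]])
      } else {
        dots[[nm]]
      }
    }
  }
  # keep Q tied to kappa unless the caller set Q explicitly
  if ("kappa" %in% names(dots) && !"Q" %in% names(dots)) p$Q <- p$kappa
  validate_qs_params(p)
  p
}
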