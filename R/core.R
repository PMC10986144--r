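# Shared game kernel: signal-dose accounting, conditional activation,
# realized metabolic cost, pairwise imitation and mutation.

#' Count signal doses in an interaction group
#'
#' Every `C`-carrier emits one constitutive dose (the cue), every `S`-carrier
#' one extra dose, so each agent contributes 0, 1 or 2 doses. The cue is
#' constitutive: a conditional cooperator contributes its dose whether or not
#' its cooperation is switched on.
#'
#' @param group group composition: a vector of `N` genotype labels or a named
#'   count vector (see [qs_group()]).
#' @param params a [qs_params()] object (used to validate the group size).
#' @return Integer number of signal doses.
#' @examples
#' p <- qs_params()
#' signal_doses(qs_group(c(Tr = 3, La = 6)), p)  # 3
#' signal_doses(qs_group(c(Bo = 1, La = 8)), p)  # 2: Bouncer counts twice
#' @export
signal_doses <- function(group, params = qs_params()) {
  counts <- check_group(group, params)
  g <- names(counts)
  sum(counts * (genotype_has_C(g) + genotype_has_S(g)))
}

#' Resolve conditional activation and the benefit indicator for a group
#'
#' Computes the group's signal doses, each genotype's cooperation expression
#' indicator `gamma` (1 for unconditional cooperators; `doses >= Q` for
#' conditional cooperators; 0 for non-`C` genotypes), the number of actively
#' cooperating members, and the benefit indicator
#' `theta = [n_active >= kappa]`. All group members evaluate the same shared
#' dose pool; this is the convention of the configuration-field and
#' non-spatial models (the lattice model instead evaluates each agent's
#' activation against its own neighborhood, see [site_cost()]).
#'
#' @inheritParams signal_doses
#' @return A list with `doses`, `gamma` (named 0/1 vector over the 8
#'   genotypes), `n_active` and `theta`.
#' @examples
#' p <- qs_params(kappa = 3)
#' resolve_activation(qs_group(c(Tr = 2, Sm = 1, La = 6)), p)
#' @export
resolve_activation <- function(group, params = qs_params()) {
  counts <- check_group(group, params)
  g <- names(counts)
  doses <- sum(counts * (genotype_has_C(g) + genotype_has_S(g)))
  gamma <- ifelse(is_unconditional_cooperator(g), 1L,
                  ifelse(is_conditional_cooperator(g),
                         as.integer(doses >= params$Q), 0L))
  gamma <- stats::setNames(as.integer(gamma), g)
  n_active <- sum(counts * gamma)
  list(doses = doses,
       gamma = gamma,
       n_active = n_active,
       theta = as.integer(n_active >= params$kappa))
}

#' Realized metabolic cost of a genotype
#'
#' `cost = (1 - theta * b) * (c0 + gamma * c * [C] + s * [S] + r * [R])`:
#' the benefit discounts the whole bracket, signal and response costs
#' included. `gamma` is the agent's own cooperation-expression indicator and
#' must be 0 for genotypes without the `C` locus.
#'
#' @param g genotype label(s), any accepted form; vectorized.
#' @param gamma 0/1 cooperation expression indicator (recycled).
#' @param theta 0/1 group benefit indicator (recycled).
#' @param params a [qs_params()] object.
#' @return Numeric vector of non-negative costs.
#' @examples
#' p <- qs_params(b = 0.5, c = 0.3, r = 0.01)
#' realized_cost("La", 0, 0, p)            # 1.0
#' realized_cost("Sm", 1, 1, p)            # 0.5 * 1.31 = 0.655
#' @export
realized_cost <- function(g, gamma, theta, params = qs_params()) {
  g <- as_genotype(g)
  n <- max(length(g), length(gamma), length(theta))
  g <- rep_len(g, n); gamma <- rep_len(gamma, n); theta <- rep_len(theta, n)
  if (any(gamma == 1 & !genotype_has_C(g))) {
    stop("gamma = 1 for a genotype without the C locus", call. = FALSE)
  }
  if (!all(gamma %in% c(0, 1)) || !all(theta %in% c(0, 1))) {
    stop("gamma and theta must be 0/1 indicators", call. = FALSE)
  }
  (1 - theta * params$b) *
    (params$c0 +
       gamma * params$c * genotype_has_C(g) +
       params$s * genotype_has_S(g) +
       params$r * genotype_has_R(g))
}

#' Pairwise imitation probability
#'
#' Probability that the offspring of player `i` replaces player `j`:
#' `p_ij = 0.5 * (1 + sigma * (C_j - C_i) / delta_C_max)`, clamped to
#' `[0, 1]`. The antisymmetry `p_ji = 1 - p_ij` holds exactly. A normalized
#' cost difference outside `[-1, 1]` indicates inconsistent parameters and is
#' an error.
#'
#' @param cost_i,cost_j realized metabolic costs of the two players
#'   (vectorized).
#' @param params a [qs_params()] object.
#' @return Numeric vector of probabilities.
#' @examples
#' p <- qs_params()
#' imitation_probability(1, 1, p)  # 0.5
#' @export
imitation_probability <- function(cost_i, cost_j, params = qs_params()) {
  dmax <- delta_C_max(params)
  dw <- (cost_j - cost_i) / dmax
  if (any(abs(dw) > 1 + 1e-12)) {
    stop("|cost difference| exceeds delta_C_max; inconsistent parameters",
         call. = FALSE)
  }
  pmin(1, pmax(0, 0.5 * (1 + params$sigma * dw)))
}

#' Mutate genotypes at replication
#'
#' Each of the three loci flips independently, with a direction-specific rate
#' (loss of function and gain of function are distinct rates, the six `mu`
#' entries of [qs_params()]). Applied to the offspring copy only.
#'
#' @param g genotype label(s); vectorized.
#' @param params a [qs_params()] object carrying the `mu` rates.
#' @return Character vector of (possibly mutated) canonical allele strings.
#' @examples
#' p <- qs_params(mu = c(C_loss = 1, C_gain = 0, S_loss = 0, S_gain = 0,
#'                       R_loss = 0, R_gain = 0))
#' mutate_genotype("Tr", p)  # forced C loss: "csr"
#' @export
mutate_genotype <- function(g, params = qs_params()) {
  code <- genotype_code(g)
  n <- length(code)
  mu <- params$mu
  bits <- c(C = 1L, S = 2L, R = 4L)
  loss <- c(mu[["C_loss"]], mu[["S_loss"]], mu[["R_loss"]])
  gain <- c(mu[["C_gain"]], mu[["S_gain"]], mu[["R_gain"]])
  for (k in 1:3) {
    active <- bitwAnd(code, bits[k]) > 0L
    rate <- ifelse(active, loss[k], gain[k])
    flip <- stats::runif(n) < rate
    code[flip] <- bitwXor(code[flip], bits[k])
  }
  genotype_from_code(code)
}
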