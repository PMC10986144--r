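# shared fixtures: the study's standard parameter set and common starts

table1_params <- function(...) {
  defaults <- list(c0 = 1, c = 0.3, s = 0.01, r = 0.01, b = 0.5, sigma = 1,
                   kappa = 3L, N = 9L)
  do.call(qs_params, utils::modifyList(defaults, list(...)))
}

even3 <- c(La = 1, Tr = 1, Sm = 1)
even8 <- stats::setNames(rep(1, 8), qs_genotypes()$allele)

feasible3 <- c("csr", "Csr", "CsR")

# random point on the k-simplex
runif_simplex <- function(k) {
  e <- stats::rexp(k)
  e / sum(e)
}

# independent focal-cost oracle: resolve a sampled group with the shared-pool
# rules via the core operations (used against the CF enumeration)
focal_cost_oracle <- function(focal, co_counts, params) {
  grp <- co_counts
  grp[focal] <- grp[focal] + 1L
  act <- resolve_activation(qs_group(grp), params)
  realized_cost(focal, act$gamma[[as_genotype(focal)]], act$theta, params)
}
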