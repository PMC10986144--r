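# Non-spatial agent-based model: the stochastic finite-population
# realization of the configuration-field dynamics. Each elementary step draws
# two independent random groups of N agents, one random focal per group, and
# plays the pairwise imitation game between the focals; the loser's slot is
# overwritten by a (possibly mutated) copy of the winner. One generation is
# floor(P / 2) steps.

#' Initialise a well-mixed population at given strategy frequencies
#'
#' Frequencies are realized as exact counts by largest-remainder rounding, so
#' the genotype counts always total `P`, then shuffled.
#'
#' @param freq named numeric vector of initial frequencies (names are
#'   genotype labels in any accepted form); needs not sum exactly to 1, it is
#'   normalised.
#' @param params a [qs_params()] object (`P` is taken from it).
#' @return Character vector of `P` canonical allele strings.
#' @examples
#' pop <- abm_init(c(La = 1, Tr = 1, Sm = 1), qs_params(P = 90))
#' table(pop)
#' @export
abm_init <- function(freq, params = qs_params()) {
  counts <- largest_remainder_counts(freq, params$P)
  pop <- rep(as_genotype(names(counts)), counts)
  sample(pop)
}

# exact-count rounding: floor everything, hand out remainders by size
largest_remainder_counts <- function(freq, total) {
  x <- freq / sum(freq)
  raw <- x * total
  base <- floor(raw)
  short <- total - sum(base)
  if (short > 0) {
    order_rem <- order(raw - base, decreasing = TRUE)
    base[order_rem[seq_len(short)]] <- base[order_rem[seq_len(short)]] + 1
  }
  stats::setNames(as.integer(base), names(freq))
}

#' Run the non-spatial agent-based simulation
#'
#' @param init initial population: either a character vector of `P` genotype
#'   labels (as from [abm_init()]) or a named frequency vector, which is
#'   expanded with [abm_init()].
#' @param params a [qs_params()] object.
#' @param generations number of generations (`floor(P/2)` imitation steps
#'   each); defaults to `params$G`.
#' @param record_every record genotype frequencies every this many
#'   generations.
#' @return A tibble of class `qs_trajectory`: column `generation` plus one
#'   frequency column per genotype (`x_La`, `x_Tr`, ..., canonical order),
#'   with the final population in attribute `final_state`.
#' @examples
#' set.seed(1)
#' p <- qs_params(P = 500, b = 0.5)
#' abm_run(c(La = 1, Tr = 1, Sm = 1), p, generations = 10)
#' @export
abm_run <- function(init, params = qs_params(),
                    generations = params$G, record_every = 1L) {
  if (!is.null(names(init)) && length(init) < params$P) {
    init <- abm_init(init, params)
  }
  if (length(init) != params$P) {
    stop("initial population length must equal P", call. = FALSE)
  }
  if (params$P < 2L * params$N) {
    stop("P must be at least 2 * N", call. = FALSE)
  }
  pop0 <- genotype_code(init)
  res <- .abm_engine(pop0, engine_par(params), params$N,
                     as.integer(generations), as.integer(record_every))
  out <- freq_records_tibble(res$freq, res$generation)
  out <- new_qs_trajectory(out, model = "abm",
                           strategies = .qs_allele, params = params)
  attr(out, "final_state") <- genotype_from_code(res$pop)
  out
}

# flat parameter list handed to the C++ engines
engine_par <- function(params) {
  list(c0 = params$c0, c = params$c, s = params$s, r = params$r,
       b = params$b, sigma = params$sigma, D = params$D,
       Q = params$Q, kappa = params$kappa,
       mu = unname(params$mu),
       diffusion_poisson = as.integer(params$diffusion_mode == "poisson"),
       pair_moore = as.integer(params$pair_adjacency == "moore"))
}

freq_records_tibble <- function(freq, generation) {
  colnames(freq) <- paste0("x_", .qs_short)
  out <- tibble::as_tibble(as.data.frame(freq))
  tibble::add_column(out, generation = as.integer(generation), .before = 1L)
}

#' Final (or windowed mean) genotype frequencies of a trajectory
#'
#' @param traj a `qs_trajectory` tibble.
#' @param window fraction of the trailing records to average over; `0` takes
#'   the last record only.
#' @return Named numeric vector of genotype frequencies.
#' @export
final_frequencies <- function(traj, window = 0) {
  xc <- grep("^x_", names(traj), value = TRUE)
  n <- nrow(traj)
  rows <- if (window > 0) seq.int(max(1L, ceiling(n * (1 - window))), n) else n
  colMeans(traj[rows, xc, drop = FALSE])
}
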