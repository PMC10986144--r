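# Spatially explicit lattice model: an M x M toroidal grid, one agent per
# site. An agent's interaction group is its 3 x 3 Moore neighborhood (itself
# included). Unlike the group-shared pool of the CF/ABM tiers, every
# conditional cooperator evaluates the quorum against the signal doses in its
# OWN neighborhood, so a site's realized cost depends on the surrounding
# 5 x 5 block.

#' Initialise a lattice at given strategy frequencies
#'
#' Exact-count (largest remainder) rounding to `M^2` agents, randomly
#' arranged.
#'
#' @param freq named numeric vector of initial frequencies.
#' @param params a [qs_params()] object (`M` is taken from it).
#' @return `M x M` character matrix of canonical allele strings, class
#'   `qs_lattice`.
#' @examples
#' set.seed(1)
#' g <- lattice_init(c(La = 1, Tr = 1, Sm = 1), qs_params(M = 10))
#' @export
lattice_init <- function(freq, params = qs_params()) {
  counts <- largest_remainder_counts(freq, params$M^2)
  cells <- sample(rep(as_genotype(names(counts)), counts))
  grid <- matrix(cells, params$M, params$M)
  class(grid) <- c("qs_lattice", class(grid))
  grid
}

as_lattice_codes <- function(grid) {
  m <- matrix(genotype_code(as.character(grid)), nrow(grid), ncol(grid))
  storage.mode(m) <- "integer"
  m
}

codes_to_lattice <- function(codes) {
  grid <- matrix(genotype_from_code(as.vector(codes)),
                 nrow(codes), ncol(codes))
  class(grid) <- c("qs_lattice", class(grid))
  grid
}

#' Moore-neighborhood interaction group of a site
#'
#' The 9 genotypes of the 3 x 3 block centered on `(row, col)`, with toroidal
#' wrap-around; the focal site is included.
#'
#' @param grid a genotype matrix (as from [lattice_init()]).
#' @param row,col site coordinates (1-based).
#' @return Named integer count vector over the 8 genotypes (a group in the
#'   sense of [qs_group()]).
#' @export
moore_group <- function(grid, row, col) {
  M <- nrow(grid)
  rows <- ((row - 2):row) %% M + 1L
  cols <- ((col - 2):col) %% M + 1L
  qs_group(as.character(grid[rows, cols]))
}

#' Realized cost of a lattice site
#'
#' Two-stage local resolution: every conditional cooperator in the focal's
#' Moore group sets its activation `gamma` from the signal doses in its own
#' Moore neighborhood; the focal's benefit indicator `theta` then compares
#' the number of active cooperators within the focal's group against `kappa`.
#' Depends only on the 5 x 5 block around the site. This is the R reference
#' implementation; the simulation engine computes the same quantity in
#' compiled code.
#'
#' @inheritParams moore_group
#' @param params a [qs_params()] object.
#' @return The focal agent's realized metabolic cost.
#' @examples
#' p <- qs_params(kappa = 3)
#' g <- matrix("csr", 7, 7)
#' g[4, 4] <- "CsR"                   # a lone Smart among Lazy
#' site_cost(g, 4, 4, p)              # own doses 1 < Q: silent, pays c0 + r
#' @export
site_cost <- function(grid, row, col, params = qs_params()) {
  M <- nrow(grid)
  wrap <- function(i) (i - 1L) %% M + 1L
  own_doses <- function(i, j) {
    blk <- grid[wrap((i - 1):(i + 1)), wrap((j - 1):(j + 1))]
    sum(genotype_has_C(as.character(blk)) + genotype_has_S(as.character(blk)))
  }
  gamma_of <- function(i, j) {
    g <- grid[wrap(i), wrap(j)]
    if (!genotype_has_C(g)) return(0L)
    if (!genotype_has_R(g)) return(1L)
    as.integer(own_doses(i, j) >= params$Q)
  }
  n_active <- 0L
  for (i in (row - 1):(row + 1)) {
    for (j in (col - 1):(col + 1)) {
      n_active <- n_active + gamma_of(i, j)
    }
  }
  theta <- as.integer(n_active >= params$kappa)
  realized_cost(grid[row, col], gamma_of(row, col), theta, params)
}

#' Run the spatially explicit lattice simulation
#'
#' One generation is `floor(M^2 / 2)` elementary steps. Each step picks a
#' uniform random site and a random adjacent site (Moore adjacency by
#' default), plays the imitation game on their realized costs, overwrites the
#' loser's site with a (possibly mutated) copy of the winner, and then
#' performs a Poisson(`D`)-distributed number of swaps between random
#' adjacent site pairs.
#'
#' @param init initial lattice: a genotype matrix (as from [lattice_init()])
#'   or a named frequency vector, expanded with [lattice_init()].
#' @param params a [qs_params()] object.
#' @param generations number of generations; defaults to `params$G`.
#' @param record_every record genotype frequencies every this many
#'   generations.
#' @param snapshot_every if positive, keep a full-grid snapshot every this
#'   many generations (attribute `snapshots`).
#' @return A tibble of class `qs_trajectory` (column `generation` plus one
#'   frequency column per genotype), with the final grid in attribute
#'   `final_state` and optional snapshots in attribute `snapshots`.
#' @examples
#' set.seed(1)
#' p <- qs_params(M = 20, b = 0.5)
#' lattice_run(c(La = 1, Tr = 1, Sm = 1), p, generations = 5)
#' @export
lattice_run <- function(init, params = qs_params(),
                        generations = params$G, record_every = 1L,
                        snapshot_every = 0L) {
  if (!is.matrix(init)) init <- lattice_init(init, params)
  if (nrow(init) != ncol(init)) stop("lattice must be square", call. = FALSE)
  codes <- as_lattice_codes(init)
  res <- .lattice_engine(codes, engine_par(params),
                         as.integer(generations), as.integer(record_every),
                         as.integer(snapshot_every))
  out <- freq_records_tibble(res$freq, res$generation)
  out <- new_qs_trajectory(out, model = "lattice",
                           strategies = .qs_allele, params = params)
  attr(out, "final_state") <- codes_to_lattice(res$grid)
  if (snapshot_every > 0L) {
    attr(out, "snapshots") <- lapply(res$snapshots, codes_to_lattice)
  }
  out
}

#' Apply diffusion swaps to a lattice
#'
#' Performs the diffusion phase alone: for each of `n_steps` game-step
#' equivalents, draws a swap count (Poisson(`D`) or the deterministic
#' integer-plus-Bernoulli alternative, per `params$diffusion_mode`) and swaps
#' that many random adjacent site pairs. Genotype counts are invariant.
#'
#' @inheritParams lattice_run
#' @param grid a genotype matrix.
#' @param n_steps number of game-step equivalents.
#' @return The permuted grid, with the total number of swaps performed in
#'   attribute `total_swaps`.
#' @export
diffusion_steps <- function(grid, params = qs_params(), n_steps = 1L) {
  codes <- as_lattice_codes(grid)
  res <- .diffusion_engine(codes, engine_par(params), as.integer(n_steps))
  out <- codes_to_lattice(res$grid)
  attr(out, "total_swaps") <- res$total_swaps
  out
}

#' Read and write lattice snapshots as plain text
#'
#' One lattice row per line, whitespace-separated canonical allele strings.
#'
#' @param grid a genotype matrix.
#' @param path file path.
#' @return `write_lattice` returns `grid` invisibly; `read_lattice` returns
#'   the genotype matrix.
#' @export
write_lattice <- function(grid, path) {
  writeLines(apply(unclass(grid), 1L, paste, collapse = " "), path)
  invisible(grid)
}

#' @rdname write_lattice
#' @export
read_lattice <- function(path) {
  rows <- strsplit(readLines(path), "\\s+")
  M <- length(rows)
  grid <- matrix(as_genotype(unlist(rows)), M, M, byrow = TRUE)
  class(grid) <- c("qs_lattice", class(grid))
  grid
}
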