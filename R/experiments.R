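# Reproduction harnesses: simulated drift fields on the 3-strategy simplex
# and steady-state genotype-distribution sweeps over (kappa, s, r, D).

#' Simulated drift field on the strategy simplex
#'
#' For every barycentric grid point, initialises populations at those
#' frequencies (exact-count rounding, random arrangement), runs a short
#' horizon, and reports the mean per-generation frequency displacement with
#' a dispersion estimate — the stochastic analogue of [cf_vector_field()].
#'
#' @param params a [qs_params()] object.
#' @param model `"lattice"` or `"abm"`.
#' @param resolution barycentric grid spacing.
#' @param horizon run length in generations over which drift is measured.
#' @param replicates independent runs per grid point.
#' @param strategies strategy labels spanning the simplex (default the three
#'   feasible strategies La, Tr, Sm).
#' @return A tibble of class `qs_field`: `x_*` grid frequencies, `v_*` mean
#'   drift per generation, `sd_*` between-replicate standard deviation of the
#'   drift.
#' @examples
#' set.seed(1)
#' f <- simulated_vector_field(qs_params(P = 500), model = "abm",
#'                             resolution = 0.5, horizon = 2, replicates = 2)
#' @export
simulated_vector_field <- function(params = qs_params(),
                                   model = c("lattice", "abm"),
                                   resolution = 0.2, horizon = 5L,
                                   replicates = 10L,
                                   strategies = c("csr", "Csr", "CsR")) {
  model <- match.arg(model)
  strategies <- as_genotype(strategies)
  lab <- strategy_label(strategies)
  grid <- simplex_grid(length(strategies), resolution)
  xcols <- paste0("x_", lab)
  rows <- vector("list", nrow(grid))
  for (gidx in seq_len(nrow(grid))) {
    x0 <- stats::setNames(grid[gidx, ], strategies)
    drifts <- matrix(NA_real_, replicates, length(strategies))
    for (rep_i in seq_len(replicates)) {
      if (model == "abm") {
        pop <- abm_init(x0, params)
        start <- table(factor(pop, levels = strategies)) / params$P
        traj <- abm_run(pop, params, generations = horizon,
                        record_every = horizon)
      } else {
        gridm <- lattice_init(x0, params)
        start <- table(factor(as.character(gridm), levels = strategies)) /
          params$M^2
        traj <- lattice_run(gridm, params, generations = horizon,
                            record_every = horizon)
      }
      fin <- final_frequencies(traj)[xcols]
      drifts[rep_i, ] <- (as.numeric(fin) - as.numeric(start)) / horizon
    }
    rows[[gidx]] <- c(grid[gidx, ], colMeans(drifts),
                      apply(drifts, 2L, stats::sd))
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- c(xcols, paste0("v_", lab), paste0("sd_", lab))
  out <- tibble::as_tibble(as.data.frame(mat))
  new_qs_field(out, model = model, strategies = strategies, params = params)
}

#' Specify a steady-state parameter sweep
#'
#' Defines the cell grid of a genotype-distribution sweep: a base parameter
#' set plus named axis value lists over any of `kappa`, `s`, `r`, `D` (or any
#' other scalar parameter). `paper_scale = TRUE` restores the full published
#' problem size (`M = 300`, `G = 10000`, `P = 90000`); the default keeps the
#' desk-scale sizes of the base parameters.
#'
#' @param params base [qs_params()] object. Sweeps default to the 8-strategy
#'   even start with functional mutation `rho = 1e-4`; pass `rho` explicitly
#'   in `params` (via `qs_params(rho = ...)`) to override.
#' @param ... named axes, e.g. `kappa = 2:6, s = c(0.01, 0.05, 0.1)`.
#' @param replicates independent runs per cell.
#' @param model `"lattice"` or `"cf"`.
#' @param burn_in fraction of generations discarded before averaging.
#' @param record_every recording cadence in generations (default `G / 100`).
#' @param paper_scale logical; restore full published problem sizes.
#' @return A list of class `qs_sweep_spec`.
#' @export
sweep_spec <- function(params = qs_params(rho = 1e-4), ...,
                       replicates = 3L, model = c("lattice", "cf"),
                       burn_in = 0.5, record_every = NULL,
                       paper_scale = FALSE) {
  model <- match.arg(model)
  axes <- list(...)
  if (length(axes) && is.null(names(axes))) {
    stop("sweep axes must be named", call. = FALSE)
  }
  if (paper_scale) params <- update_params(params, M = 300L, G = 10000L,
                                           P = 90000L)
  structure(list(params = params, axes = axes, replicates = replicates,
                 model = model, burn_in = burn_in,
                 record_every = record_every),
            class = "qs_sweep_spec")
}

#' Run a steady-state genotype-distribution sweep
#'
#' For every cell of the axis grid, runs the lattice model (or integrates the
#' 8-strategy CF flow) from the even 8-strategy start, discards the burn-in
#' window, and averages the remaining records over time and replicates. Cell
#' failures are caught, marked and skipped, and completed cells cached in
#' `out_dir` are not recomputed on restart.
#'
#' @param spec a [sweep_spec()].
#' @param out_dir optional directory for per-cell CSV caching (enables
#'   resumability).
#' @param seed integer; per-cell seeds are derived from it, so the sweep is
#'   reproducible and cells are independent of execution order.
#' @return A tibble with one row per cell x genotype: the axis columns,
#'   `replicate`-averaged `mean_freq` and between-replicate `sd_freq`,
#'   and a `failed` flag.
#' @examples
#' \donttest{
#' spec <- sweep_spec(qs_params(M = 30, G = 50, rho = 1e-4), D = c(0, 0.5),
#'                    replicates = 1)
#' set.seed(1)
#' steady_state_sweep(spec)
#' }
#' @export
steady_state_sweep <- function(spec, out_dir = NULL, seed = NULL) {
  stopifnot(inherits(spec, "qs_sweep_spec"))
  cells <- if (length(spec$axes)) {
    do.call(tidyr::crossing, lapply(spec$axes, unlist))
  } else {
    tibble::tibble(.dummy = 1L)
  }
  axis_names <- setdiff(names(cells), ".dummy")
  even8 <- stats::setNames(rep(1 / 8, 8L), .qs_allele)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max %/% 2L, 1L)

  res <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, axis_names, drop = FALSE]
    tag <- paste(sprintf("%s%g", axis_names, as.numeric(cell[1, ])),
                 collapse = "_")
    if (tag == "") tag <- "base"
    cache <- if (!is.null(out_dir)) {
      file.path(out_dir, paste0("cell_", tag, ".csv"))
    }
    if (!is.null(cache) && file.exists(cache)) {
      cached <- readr::read_csv(cache, show_col_types = FALSE)
      cached$mean_freq <- as.numeric(cached$mean_freq)
      cached$sd_freq <- as.numeric(cached$sd_freq)   # all-NA columns
      res[[ci]] <- cached
      next
    }
    p <- do.call(update_params, c(list(spec$params),
                                  stats::setNames(as.list(cell[1, ]),
                                                  axis_names)))
    record_every <- spec$record_every %||% max(1L, p$G %/% 100L)
    cell_res <- tryCatch({
      reps <- matrix(NA_real_, spec$replicates, 8L)
      for (rp in seq_len(spec$replicates)) {
        set.seed((seed + 7919L * ci + rp) %% .Machine$integer.max)
        if (spec$model == "lattice") {
          traj <- lattice_run(even8, p, generations = p$G,
                              record_every = record_every)
          reps[rp, ] <- final_frequencies(traj, window = 1 - spec$burn_in)
        } else {
          traj <- cf_trajectory(rep(1 / 8, 8L), p, strategies = .qs_allele,
                                T = p$G, dt = 0.5)
          reps[rp, ] <- final_frequencies(traj, window = 1 - spec$burn_in)
        }
      }
      out <- tibble::tibble(
        genotype = .qs_allele,
        strategy = .qs_short,
        mean_freq = colMeans(reps),
        sd_freq = apply(reps, 2L, stats::sd),
        failed = FALSE
      )
      dplyr::bind_cols(cell[rep(1L, 8L), , drop = FALSE], out)
    }, error = function(e) {
      warning("sweep cell ", tag, " failed: ", conditionMessage(e),
              call. = FALSE)
      out <- tibble::tibble(
        genotype = .qs_allele, strategy = .qs_short,
        mean_freq = NA_real_, sd_freq = NA_real_, failed = TRUE
      )
      dplyr::bind_cols(cell[rep(1L, 8L), , drop = FALSE], out)
    })
    if (!is.null(cache) && !any(cell_res$failed)) {
      readr::write_csv(cell_res, cache)
    }
    res[[ci]] <- cell_res
  }
  dplyr::bind_rows(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
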