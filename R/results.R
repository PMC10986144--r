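# Lightweight result classes: trajectories, vector fields, fixed points.
# All are tibbles with attributes; tidy()/glance()/autoplot() methods live in
# plots.R and tidiers.R.

new_qs_trajectory <- function(x, model, strategies, params) {
  class(x) <- c("qs_trajectory", class(x))
  attr(x, "model") <- model
  attr(x, "strategies") <- strategies
  attr(x, "params") <- params
  x
}

new_qs_field <- function(x, model, strategies, params) {
  class(x) <- c("qs_field", class(x))
  attr(x, "model") <- model
  attr(x, "strategies") <- strategies
  attr(x, "params") <- params
  x
}

strategy_cols <- function(strategies, prefix = "x_") {
  paste0(prefix, strategy_label(strategies))
}

# short display labels ("La", "Tr", ...) for canonical allele strings
strategy_label <- function(strategies) {
  .qs_short[match(as_genotype(strategies), .qs_allele)]
}

#' Write a trajectory or vector field to CSV
#'
#' Trajectories use columns `generation` (or `time`) plus one frequency column
#' per strategy; vector fields use `x_*` position and `v_*` velocity columns.
#'
#' @param x a `qs_trajectory` or `qs_field` tibble.
#' @param path output file path.
#' @return `x`, invisibly.
#' @export
write_qs_csv <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(x)
}
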