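# broom-style tidiers for the result classes.

#' Turn a model result into a tidy tibble
#'
#' @param x a result object (`qs_trajectory`, `qs_fixed_points`).
#' @param ... passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row summary of a model result
#'
#' @param x a result object (`qs_trajectory`, `qs_fixed_points`).
#' @param ... passed to methods.
#' @return A one-row tibble.
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @describeIn tidy long format: one row per record and strategy, with
#'   columns `generation` (or `time`), `strategy`, `frequency`.
#' @export
tidy.qs_trajectory <- function(x, ...) {
  idcol <- intersect(c("generation", "time"), names(x))[1]
  out <- tidyr::pivot_longer(tibble::as_tibble(x),
                             dplyr::starts_with("x_"),
                             names_to = "strategy", names_prefix = "x_",
                             values_to = "frequency")
  dplyr::select(out, dplyr::all_of(idcol), "strategy", "frequency")
}

#' @describeIn glance the model tier, run length, and final frequencies.
#' @export
glance.qs_trajectory <- function(x, ...) {
  fin <- final_frequencies(x)
  idcol <- intersect(c("generation", "time"), names(x))[1]
  dplyr::bind_cols(
    tibble::tibble(model = attr(x, "model"),
                   n_records = nrow(x),
                   span = max(x[[idcol]]) - min(x[[idcol]])),
    tibble::as_tibble(as.list(fin))
  )
}

#' @describeIn tidy the fixed-point table itself (already one row per point).
#' @export
tidy.qs_fixed_points <- function(x, ...) tibble::as_tibble(x)

#' @describeIn glance counts of fixed points by stability class.
#' @export
glance.qs_fixed_points <- function(x, ...) {
  tibble::tibble(
    model = attr(x, "model"),
    n_fixed_points = nrow(x),
    n_stable = sum(x$class == "stable"),
    n_unstable = sum(x$class == "unstable"),
    n_saddle = sum(x$class == "saddle")
  )
}
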