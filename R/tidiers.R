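#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fitted parameters of a staged fit
#'
#' @param x A [staged_fit()] result.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `term`, `start`,
#'   `estimate`, `rel_change`.
#' @export
tidy.synapse_fit <- function(x, ...) {
  start <- get_params(x$start_params, x$free)
  est <- get_params(x$params, x$free)
  tibble::tibble(term = x$free, start = unname(start),
                 estimate = unname(est),
                 rel_change = unname((est - start) / start))
}

#' One-row summary of a staged fit
#'
#' @param x A [staged_fit()] result.
#' @param ... Unused.
#' @return A tibble with `loss`, `n_free`, `n_traces`, `n_stages_run`.
#' @export
glance.synapse_fit <- function(x, ...) {
  tibble::tibble(loss = x$loss, n_free = length(x$free),
                 n_traces = length(x$recordings),
                 n_stages_run = sum(!x$stages$skipped))
}
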