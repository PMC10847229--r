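#' Turn suvrnet result objects into tidy tibbles
#'
#' Broom-style methods: `tidy()` returns one row per element (edge, region,
#' parameter), `glance()` a one-row model summary.
#'
#' @param x A suvrnet result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
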