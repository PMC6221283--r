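#' Broom-style methods for nicheshift objects
#'
#' `tidy()` returns the per-component detail of an object (model
#' coefficients, ROC curve points, null replicates, PCA loadings, dropped
#' variables) and `glance()` a one-row summary, following the broom
#' convention.
#'
#' @param x A nicheshift result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy-methods
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
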