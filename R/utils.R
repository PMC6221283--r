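#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble is_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider
#' @importFrom purrr map map_dbl map_chr imap walk
#' @importFrom stats plogis prcomp quantile sd cor rank dnorm runif rnorm
#'   setNames median IQR ks.test approx complete.cases predict
#' @importFrom utils read.csv write.csv head tail combn packageVersion
#' @importFrom graphics hist
NULL

# Deterministic seed fan-out: fold a master seed and a stage label into a
# child seed in [1, 2^31 - 2]. Pure integer arithmetic in doubles (always
# below 2^53), so it is stable across platforms and R versions.
#' Derive a stage-specific seed from a master seed
#'
#' Every stochastic stage of the pipeline receives its own seed derived from
#' the run's master seed and a label, so stages can be re-run in isolation
#' and the whole run is reproducible from one integer.
#'
#' @param master Integer master seed.
#' @param ... Character or numeric labels identifying the stage (taxon, era,
#'   pair, stage name); coerced to character and folded into the hash.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' fan_seed(1, "fit", "taxon_a")
fan_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  label <- paste(vapply(list(...), paste, character(1), collapse = "/"),
                 collapse = "/")
  m <- 2147483647
  h <- abs(master) %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

`%||%` <- rlang::`%||%`

# shared argument checks ------------------------------------------------

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)))
  }
  invisible(x)
}
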