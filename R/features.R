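#' Feature specification for the maximum-entropy model
#'
#' Restricts the model to the smooth feature classes: `linear` (the scaled
#' variable itself), `quadratic` (its square) and `product` (pairwise
#' products of scaled variables). Hinge and threshold features are not
#' representable by construction, which keeps response curves smooth and
#' interpretable. Each raw variable is min-max scaled to [0, 1] using the
#' stored bounds, and optionally clamped there when projecting onto novel
#' climates.
#'
#' @param variables Character vector of variable names.
#' @param classes Subset of `c("linear", "quadratic", "product")`.
#' @param lower,upper Named numeric vectors of per-variable scaling bounds.
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(variables,
                         classes = c("linear", "quadratic", "product"),
                         lower, upper) {
  classes <- match.arg(classes, c("linear", "quadratic", "product"),
                       several.ok = TRUE)
  if (any(upper[variables] <= lower[variables])) {
    degenerate <- variables[upper[variables] <= lower[variables]]
    warn(paste0("constant variable(s), features will be degenerate: ",
                paste(degenerate, collapse = ", ")))
  }
  structure(list(variables = variables, classes = classes,
                 lower = lower[variables], upper = upper[variables]),
            class = "feature_spec")
}

# Bounds from an environment table (min/max per variable).
feature_spec_from_env <- function(env, variables, classes) {
  lower <- vapply(variables, function(v) min(env[[v]], na.rm = TRUE), 0)
  upper <- vapply(variables, function(v) max(env[[v]], na.rm = TRUE), 0)
  feature_spec(variables, classes, lower, upper)
}

#' Expand an environment table into the model's feature matrix
#'
#' Scales each variable to [0, 1] with the spec's bounds (clamping outside
#' values when `clamp = TRUE`), then builds the requested feature columns:
#' `d` linear, `d` quadratic and `d(d-1)/2` product columns for `d`
#' variables, all of which stay within [0, 1].
#'
#' @param env Data frame of raw variable values.
#' @param spec A [feature_spec()].
#' @param clamp Clamp values outside the training bounds (default `TRUE`).
#' @return Numeric matrix, one row per input row, named feature columns.
#' @export
make_features <- function(env, spec, clamp = TRUE) {
  stopifnot(inherits(spec, "feature_spec"))
  missing <- setdiff(spec$variables, names(env))
  if (length(missing) > 0) {
    abort(paste0("missing variable(s): ", paste(missing, collapse = ", ")))
  }
  d <- length(spec$variables)
  X <- matrix(0, nrow(env), d, dimnames = list(NULL, spec$variables))
  for (v in spec$variables) {
    span <- spec$upper[[v]] - spec$lower[[v]]
    z <- if (span > 0) (env[[v]] - spec$lower[[v]]) / span else env[[v]] * 0
    if (clamp) z <- pmin(pmax(z, 0), 1)
    X[, v] <- z
  }
  blocks <- list()
  if ("linear" %in% spec$classes) blocks$linear <- X
  if ("quadratic" %in% spec$classes) {
    Q <- X^2
    colnames(Q) <- paste0(spec$variables, "^2")
    blocks$quadratic <- Q
  }
  if ("product" %in% spec$classes && d >= 2) {
    pairs <- utils::combn(d, 2)
    P <- matrix(0, nrow(env), ncol(pairs))
    cn <- character(ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      P[, j] <- X[, i1] * X[, i2]
      cn[j] <- paste0(spec$variables[i1], "*", spec$variables[i2])
    }
    colnames(P) <- cn
    blocks$product <- P
  }
  out <- do.call(cbind, blocks)
  attr(out, "classes") <- rep(names(blocks), vapply(blocks, ncol, 0L))
  out
}
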