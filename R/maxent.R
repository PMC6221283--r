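#' Collinearity filter for candidate variables
#'
#' Computes pairwise Pearson correlations over all off-nodata cells and
#' iteratively drops variables until no pair has `|r| >= r_threshold`
#' (default 0.95): at each step the offending pair's member with the larger
#' mean absolute correlation to all remaining variables is removed. Also
#' checks the over-parameterization guard that the number of occurrences be
#' at least ten times the number of retained variables.
#'
#' @param stack A [raster_stack()] of candidate layers (>= 2).
#' @param r_threshold Absolute correlation at or above which a pair is
#'   considered collinear.
#' @param n_occurrences Occurrence count used for the 10x guard.
#' @return An object of class `variable_selection` with fields `kept`
#'   (character), `dropped` (tibble: `variable`, `partner`, `r`), `guard_ok`
#'   (logical) and `r_threshold`.
#' @export
select_variables <- function(stack, r_threshold = 0.95, n_occurrences) {
  stopifnot(is_raster_stack(stack))
  vars <- names(stack$layers)
  if (length(vars) < 2) abort("need at least 2 variables.")
  env <- as_tibble(stack, drop_na = TRUE)
  M <- as.matrix(env[vars])
  if (any(apply(M, 2, sd) == 0) && all(apply(M, 2, sd) == 0)) {
    abort("all variables are degenerate (zero variance).")
  }
  R <- suppressWarnings(cor(M))
  R[is.na(R)] <- 1  # zero-variance pairs treated as perfectly collinear
  kept <- vars
  dropped <- list()
  repeat {
    sub <- R[kept, kept, drop = FALSE]
    off <- abs(sub); diag(off) <- 0
    if (length(kept) < 2 || max(off) < r_threshold) break
    worst <- which(off == max(off), arr.ind = TRUE)[1, ]
    cand <- kept[c(worst[1], worst[2])]
    mean_abs <- rowMeans(off[cand, , drop = FALSE])
    victim <- cand[which.max(mean_abs)]
    partner <- setdiff(cand, victim)
    dropped[[victim]] <- tibble(variable = victim, partner = partner,
                                r = sub[victim, partner])
    kept <- setdiff(kept, victim)
  }
  structure(list(kept = kept,
                 dropped = if (length(dropped)) dplyr::bind_rows(dropped)
                           else tibble(variable = character(),
                                       partner = character(), r = double()),
                 guard_ok = n_occurrences >= 10 * length(kept),
                 r_threshold = r_threshold,
                 n_occurrences = n_occurrences),
            class = "variable_selection")
}

#' @export
print.variable_selection <- function(x, ...) {
  cat(sprintf("<variable_selection> kept %d: %s\n", length(x$kept),
              paste(x$kept, collapse = ", ")))
  if (nrow(x$dropped) > 0) {
    cat(sprintf("  dropped %d at |r| >= %g\n", nrow(x$dropped), x$r_threshold))
  }
  cat(sprintf("  10x occurrence guard: %s (n = %d, need >= %d)\n",
              if (x$guard_ok) "ok" else "VIOLATED",
              x$n_occurrences, 10 * length(x$kept)))
  invisible(x)
}

#' @rdname tidy-methods
#' @export
tidy.variable_selection <- function(x, ...) x$dropped

#' Uniform background sample of a landscape
#'
#' Draws up to `n` distinct off-nodata cell centers (on the mask, if one is
#' given) uniformly at random and returns their coordinates with all layer
#' values — the "availability" sample the maximum-entropy model and the
#' PCA environmental space are calibrated against. If the landscape has
#' fewer eligible cells than `n`, all of them are returned.
#'
#' @param stack A [raster_stack()].
#' @param n Target sample size (default 10000).
#' @param seed Integer seed.
#' @param mask Optional binary single-layer [raster_stack()].
#' @return Tibble: `row`, `col`, `lon`, `lat`, one column per layer.
#' @export
sample_background <- function(stack, n = 10000, seed = 1L, mask = NULL) {
  stopifnot(is_raster_stack(stack))
  env <- as_tibble(stack, drop_na = TRUE)
  if (!is.null(mask)) {
    stop_if_geometry_differs(stack, mask)
    m <- stack_layer(mask)
    env <- env[m[cbind(env$row, env$col)] > 0, , drop = FALSE]
  }
  if (nrow(env) == 0) abort("no eligible background cells.")
  if (nrow(env) <= n) {
    inform(sprintf("background: only %d eligible cells (<= n = %d); using all.",
                   nrow(env), n))
    return(env)
  }
  set.seed(seed)
  env[sort(sample.int(nrow(env), n)), , drop = FALSE]
}

# Published default L1 base constants per feature class, interpolated in the
# presence count m (piecewise-linear, clamped at the table ends).
maxent_default_beta <- function(class, m) {
  tables <- list(
    linear    = list(x = c(0, 10, 30, 100),     y = c(1, 1, 0.2, 0.05)),
    quadratic = list(x = c(0, 10, 17, 30, 100), y = c(1.3, 0.8, 0.5, 0.25, 0.05)),
    product   = list(x = c(0, 10, 17, 30, 100), y = c(2.6, 1.6, 1.0, 0.5, 0.1))
  )
  tb <- tables[[class]]
  approx(tb$x, tb$y, xout = min(max(m, min(tb$x)), max(tb$x)), rule = 2)$y
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Fit a maximum-entropy presence-background model
#'
#' Estimates the Gibbs distribution over the background that maximizes the
#' L1-penalized log-likelihood of the presences:
#' \deqn{L(\lambda) = \overline{\lambda' f(x_{pres})}
#'   - \log \sum_{bg} e^{\lambda' f(x)} - \sum_j \beta_j |\lambda_j|}
#' with per-feature penalties \eqn{\beta_j = reg \cdot \beta_{class}(m)
#' \cdot s_j / \sqrt{m}}, where \eqn{s_j} is the feature's standard
#' deviation over the presences, \eqn{m} the presence count and
#' \eqn{\beta_{class}} the published class-default constant. The optimizer
#' is proximal gradient ascent with backtracking line search and an exact
#' soft-threshold L1 step, which makes the penalized objective
#' non-decreasing at every iteration. Features that are constant over the
#' background carry no information and their coefficients are pinned to 0.
#'
#' @param presence_env Data frame of raw variable values at the (>= 2)
#'   presence records.
#' @param background_env Data frame of raw variable values at the background
#'   sample.
#' @param variables Variables to use; defaults to all shared numeric columns
#'   except coordinate bookkeeping (`row`, `col`, `lon`, `lat`).
#' @param classes Feature classes, see [feature_spec()].
#' @param reg_multiplier Single multiplier on all penalties (default 1).
#' @param max_iter,tol Optimizer budget and convergence tolerance on the
#'   objective change.
#' @return An object of class `maxent_model`: coefficients, feature spec,
#'   log-partition over the training background, entropy of the fitted raw
#'   distribution, regularization vector and the objective trace.
#' @export
fit_maxent <- function(presence_env, background_env, variables = NULL,
                       classes = c("linear", "quadratic", "product"),
                       reg_multiplier = 1, max_iter = 10000, tol = 1e-6) {
  reserved <- c("row", "col", "lon", "lat", "inside", "on_nodata", "taxon")
  if (is.null(variables)) {
    shared <- intersect(names(presence_env), names(background_env))
    variables <- setdiff(shared[vapply(background_env[shared], is.numeric, TRUE)],
                         reserved)
  }
  if (length(variables) == 0) abort("no model variables found.")
  m <- nrow(presence_env)
  if (m < 2) abort("need at least 2 presence records.")
  spec <- feature_spec_from_env(
    dplyr::bind_rows(presence_env[variables], background_env[variables]),
    variables, classes)
  Fp <- make_features(presence_env, spec)
  Fb <- make_features(background_env, spec)
  feature_class <- attr(Fp, "classes")
  J <- ncol(Fp)

  s_pres <- apply(Fp, 2, sd)
  base <- vapply(feature_class, maxent_default_beta, 0, m = m)
  beta <- reg_multiplier * base * s_pres / sqrt(m)
  # background-constant features are unidentifiable under the Gibbs model
  identifiable <- apply(Fb, 2, sd) > 0

  f_bar <- colMeans(Fp)
  lambda <- numeric(J)

  smooth_obj <- function(lam) {
    # concave part: mean presence score - log partition over background
    eta <- as.vector(Fb %*% lam)
    M <- max(eta)
    sum(f_bar * lam) - (M + log(sum(exp(eta - M))))
  }
  penalty <- function(lam) sum(beta * abs(lam))
  grad <- function(lam) {
    eta <- as.vector(Fb %*% lam)
    w <- exp(eta - max(eta)); w <- w / sum(w)
    f_bar - as.vector(crossprod(Fb, w))
  }

  obj_trace <- numeric(0)
  f_cur <- smooth_obj(lambda)
  obj_trace[1] <- f_cur - penalty(lambda)
  step <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- grad(lambda)
    g[!identifiable] <- 0
    step <- step * 1.5  # optimistic growth, backtracking shrinks as needed
    repeat {
      cand <- soft_threshold(lambda + step * g, step * beta)
      cand[!identifiable] <- 0
      d <- cand - lambda
      f_cand <- smooth_obj(cand)
      # majorization check for the concave smooth part; non-finite values
      # (overflow under near-separated data) count as a rejected step
      if (is.finite(f_cand) &&
          f_cand >= f_cur + sum(g * d) - sum(d^2) / (2 * step) - 1e-12) break
      step <- step / 2
      if (step < 1e-12) { cand <- lambda; f_cand <- f_cur; break }
    }
    lambda <- cand
    f_cur <- f_cand
    obj_trace[it + 1] <- f_cur - penalty(lambda)
    if (abs(obj_trace[it + 1] - obj_trace[it]) < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    abort(sprintf(paste0("maxent optimizer did not converge in %d iterations ",
                         "(last objective change %.3g); increase max_iter or ",
                         "loosen tol."),
                  max_iter, abs(diff(utils::tail(obj_trace, 2)))))
  }
  eta_b <- as.vector(Fb %*% lambda)
  Mx <- max(eta_b)
  log_z <- Mx + log(sum(exp(eta_b - Mx)))
  raw <- exp(eta_b - log_z)
  entropy <- -sum(ifelse(raw > 0, raw * log(raw), 0))
  structure(
    list(spec = spec, coefficients = setNames(as.vector(lambda), colnames(Fp)),
         feature_class = feature_class, log_z = log_z, entropy = entropy,
         reg_multiplier = reg_multiplier, reg = beta,
         n_presence = m, n_background = nrow(background_env),
         objective_trace = obj_trace, converged = converged,
         identifiable = identifiable),
    class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf(paste0("<maxent_model> %d/%d nonzero features (classes: %s), ",
                     "%d presences vs %d background\n"),
              nz, length(x$coefficients),
              paste(x$spec$classes, collapse = "/"), x$n_presence,
              x$n_background))
  cat(sprintf("  penalized log-likelihood: %.6g after %d iterations\n",
              utils::tail(x$objective_trace, 1),
              length(x$objective_trace) - 1))
  invisible(x)
}

#' @rdname tidy-methods
#' @export
tidy.maxent_model <- function(x, ...) {
  tibble(feature = names(x$coefficients), class = x$feature_class,
         estimate = unname(x$coefficients), penalty = unname(x$reg))
}

#' @rdname tidy-methods
#' @export
glance.maxent_model <- function(x, ...) {
  tibble(n_presence = x$n_presence, n_background = x$n_background,
         n_features = length(x$coefficients),
         n_nonzero = sum(x$coefficients != 0),
         reg_multiplier = x$reg_multiplier,
         log_partition = x$log_z, entropy = x$entropy,
         objective = utils::tail(x$objective_trace, 1),
         iterations = length(x$objective_trace) - 1,
         converged = x$converged)
}

#' Predict habitat suitability
#'
#' Evaluates the fitted Gibbs density. The `raw` output is
#' `exp(lambda . f(x)) / Z` with `Z` the partition function over the
#' training background (so raw values over that background sum to 1). The
#' default `cloglog` transform maps raw onto [0, 1] as
#' `1 - exp(-exp(H) * raw)` with `H` the entropy of the fitted raw
#' distribution; `logistic` uses `r = exp(H) * raw; r / (1 + r)`. Both are
#' strictly monotone in raw, so rankings (and hence AUC) are identical
#' across transforms.
#'
#' @param object A `maxent_model`.
#' @param newdata A data frame of variable values, or a [raster_stack()]
#'   (projection; returns a suitability map).
#' @param transform One of `"cloglog"` (default), `"logistic"`, `"raw"`.
#' @param clamp Clamp variables to the training bounds (default `TRUE`).
#'   When projecting onto a stack, per-layer clamp counts are reported via a
#'   message whenever any cell falls outside the training range.
#' @param ... Unused.
#' @return Numeric vector (data-frame input) or a single-layer
#'   [raster_stack()] named `"suitability"` (stack input).
#' @export
predict.maxent_model <- function(object, newdata,
                                 transform = c("cloglog", "logistic", "raw"),
                                 clamp = TRUE, ...) {
  transform <- match.arg(transform)
  if (is_raster_stack(newdata)) {
    env <- as_tibble(newdata, drop_na = FALSE)
    keep <- stats::complete.cases(env[object$spec$variables])
    vals <- rep(NA_real_, nrow(env))
    if (any(keep)) {
      sub <- env[keep, , drop = FALSE]
      n_clamped <- vapply(object$spec$variables, function(v) {
        sum(sub[[v]] < object$spec$lower[[v]] |
              sub[[v]] > object$spec$upper[[v]])
      }, 0L)
      if (clamp && any(n_clamped > 0)) {
        inform(paste0("projection clamped cells outside training bounds: ",
                      paste(sprintf("%s=%d", names(n_clamped)[n_clamped > 0],
                                    n_clamped[n_clamped > 0]),
                            collapse = ", ")))
      }
      vals[keep] <- predict(object, sub, transform = transform, clamp = clamp)
    }
    m <- matrix(vals, newdata$nrows, newdata$ncols)
    return(raster_stack(list(suitability = m), xmin = newdata$xmin,
                        ymin = newdata$ymin, cellsize = newdata$cellsize,
                        nodata = newdata$nodata))
  }
  missing <- setdiff(object$spec$variables, names(newdata))
  if (length(missing) > 0) {
    abort(paste0("missing variable(s): ", paste(missing, collapse = ", ")))
  }
  Fx <- make_features(newdata, object$spec, clamp = clamp)
  raw <- exp(as.vector(Fx %*% object$coefficients) - object$log_z)
  switch(transform,
    raw = raw,
    cloglog = 1 - exp(-exp(object$entropy) * raw),
    logistic = {
      r <- exp(object$entropy) * raw
      r / (1 + r)
    })
}

#' Zero out suitability off the soil mask
#'
#' Gypsum-restricted taxa have true suitability 0 wherever the substrate is
#' absent; given a binary soil layer this sets the climatic suitability to 0
#' off-mask. Given a point table instead, it extracts suitability only at
#' those indicator points.
#'
#' @param map Single-layer suitability [raster_stack()].
#' @param soil Binary single-layer [raster_stack()], or a tibble of points
#'   with `lon`/`lat` columns.
#' @return A masked [raster_stack()], or (point input) the extraction tibble
#'   from [extract_at_points()].
#' @export
apply_soil_mask <- function(map, soil) {
  stopifnot(is_raster_stack(map))
  if (is_raster_stack(soil)) {
    stop_if_geometry_differs(map, soil)
    out <- map
    nm <- names(map$layers)[1]
    out$layers[[nm]] <- map$layers[[nm]] * (stack_layer(soil) > 0)
    return(out)
  }
  extract_at_points(map, soil)
}
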