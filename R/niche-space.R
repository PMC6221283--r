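#' Two-axis PCA environmental space
#'
#' Standardizes the background environment table (correlation-matrix PCA)
#' and keeps the first two principal axes. The axis ranges of the
#' calibration background define the environmental envelope of the study
#' area, which later bounds the density grids. Loadings follow a
#' deterministic sign convention (the largest-magnitude loading on each
#' axis is positive) so serialized spaces are reproducible.
#'
#' @param background_env Data frame of environmental values across the whole
#'   study area (>= 3 rows; >= 2 variables with nonzero variance).
#' @param variables Variables to ordinate; defaults to all numeric columns
#'   except coordinate bookkeeping.
#' @return An object of class `env_space`: `loadings` (variables x 2),
#'   `explained_variance` (proportions), `center`, `scale`, `axis_range`.
#' @export
fit_pca_env <- function(background_env, variables = NULL) {
  reserved <- c("row", "col", "lon", "lat", "inside", "on_nodata", "taxon")
  if (is.null(variables)) {
    variables <- setdiff(
      names(background_env)[vapply(background_env, is.numeric, TRUE)],
      reserved)
  }
  X <- as.matrix(background_env[variables])
  if (nrow(X) < 3) abort("need >= 3 background rows for the ordination.")
  sds <- apply(X, 2, sd)
  live <- sds > 0
  if (sum(live) < 2) abort("need >= 2 variables with nonzero variance.")
  variables <- variables[live]
  X <- X[, live, drop = FALSE]
  p <- prcomp(X, center = TRUE, scale. = TRUE)
  loadings <- p$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
    }
  }
  scores <- scale(X, center = p$center, scale = p$scale) %*% loadings
  structure(
    list(variables = variables, loadings = loadings,
         explained_variance = (p$sdev^2 / sum(p$sdev^2))[1:2],
         center = p$center, scale = p$scale,
         axis_range = apply(scores, 2, range)),
    class = "env_space")
}

#' @export
print.env_space <- function(x, ...) {
  cat(sprintf("<env_space> %d variables -> 2 axes (%.1f%% + %.1f%% variance)\n",
              length(x$variables), 100 * x$explained_variance[1],
              100 * x$explained_variance[2]))
  invisible(x)
}

#' @rdname tidy-methods
#' @export
tidy.env_space <- function(x, ...) {
  tibble(variable = rep(x$variables, 2),
         axis = rep(c("axis1", "axis2"), each = length(x$variables)),
         loading = c(x$loadings[, 1], x$loadings[, 2]))
}

#' @rdname tidy-methods
#' @export
glance.env_space <- function(x, ...) {
  tibble(n_variables = length(x$variables),
         var_axis1 = x$explained_variance[1],
         var_axis2 = x$explained_variance[2])
}

#' Project environment rows into the PCA space
#'
#' @param space An [fit_pca_env()] result.
#' @param env Data frame containing the space's variables.
#' @return Tibble with columns `axis1`, `axis2`.
#' @export
project_scores <- function(space, env) {
  stopifnot(inherits(space, "env_space"))
  missing <- setdiff(space$variables, names(env))
  if (length(missing) > 0) {
    abort(paste0("missing variable(s): ", paste(missing, collapse = ", ")))
  }
  X <- as.matrix(env[space$variables])
  S <- scale(X, center = space$center, scale = space$scale) %*% space$loadings
  dimnames(S) <- NULL
  tibble(axis1 = S[, 1], axis2 = S[, 2])
}

silverman_bw <- function(x) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  0.9 * min(sd(x), IQR(x) / 1.34) * n^(-1/5)
}

# Silverman per axis, floored at one grid-cell width so kernels never
# vanish between cell centers; fallback span/20 for degenerate point sets.
default_grid_bw <- function(scores, span, R) {
  bw <- c(silverman_bw(scores$axis1), silverman_bw(scores$axis2))
  bad <- !is.finite(bw) | bw <= 0
  bw[bad] <- (span / 20)[bad]
  pmax(bw, span / R)
}

# Occupancy divided by availability. Availability below a numerical-noise
# threshold (1e-6 of its peak; Gaussian tails that far out are smaller than
# kernel-truncation error) counts as zero availability: the ratio there is
# 0 by definition, which keeps far-tail cells from dominating after the
# division.
corrected_density <- function(occ_raw, env_raw) {
  live <- env_raw > 1e-6 * max(env_raw)
  out <- matrix(0, nrow(occ_raw), ncol(occ_raw))
  out[live] <- occ_raw[live] / env_raw[live]
  out
}

# Gaussian product-kernel density on an R x R grid via MASS::kde2d (whose
# `h` argument is 4x the kernel sd). Returns the density matrix indexed
# [axis1, axis2] plus the cell-center coordinates.
kde_on_grid <- function(scores, bw, R, extent) {
  k <- MASS::kde2d(scores$axis1, scores$axis2, h = 4 * bw, n = R,
                   lims = c(extent[, 1], extent[, 2]))
  list(x = k$x, y = k$y, z = k$z)
}

#' Kernel-smoothed occurrence and availability densities in niche space
#'
#' Grids the two-axis environmental space into `R x R` cells spanning the
#' background envelope (or a supplied extent) and evaluates Gaussian
#' product-kernel densities of the occurrence scores (`occ_density`,
#' max-normalized) and the background scores (`env_density`, availability).
#' `occ_corrected` is occupancy divided by availability — the density of
#' occurrences relative to how common those conditions are — max-normalized,
#' and defined as 0 where availability is (numerically) zero. Bandwidths
#' default to Silverman's rule per axis on each point set, floored at one
#' grid-cell width so kernels never vanish between cell centers.
#'
#' @param occ_scores Tibble of occurrence scores (`axis1`, `axis2`), >= 1
#'   row.
#' @param background_scores Tibble of background scores, >= 2 rows.
#' @param R Grid resolution per axis (default 100).
#' @param extent Optional 2x2 matrix (rows: min, max; cols: axis1, axis2);
#'   defaults to the background envelope.
#' @param occ_bw,env_bw Optional length-2 bandwidth overrides.
#' @return An object of class `niche_density` with the grids, extent,
#'   cell-center coordinates and bandwidths.
#' @export
density_grid <- function(occ_scores, background_scores, R = 100,
                         extent = NULL, occ_bw = NULL, env_bw = NULL) {
  if (nrow(occ_scores) < 1) abort("need >= 1 occurrence score.")
  if (nrow(background_scores) < 2) abort("need >= 2 background scores.")
  if (is.null(extent)) {
    extent <- cbind(axis1 = range(background_scores$axis1),
                    axis2 = range(background_scores$axis2))
  }
  span <- extent[2, ] - extent[1, ]
  if (any(span <= 0)) abort("degenerate extent: zero span on an axis.")
  occ_bw <- occ_bw %||% default_grid_bw(occ_scores, span, R)
  env_bw <- env_bw %||% default_grid_bw(background_scores, span, R)
  occ_k <- kde_on_grid(occ_scores, occ_bw, R, extent)
  env_k <- kde_on_grid(background_scores, env_bw, R, extent)
  occ_raw <- occ_k$z
  env_raw <- env_k$z
  corrected <- corrected_density(occ_raw, env_raw)
  norm <- function(m) if (max(m) > 0) m / max(m) else m
  structure(
    list(R = R, extent = extent, axis1 = occ_k$x, axis2 = occ_k$y,
         occ_density = norm(occ_raw), env_density = env_raw,
         occ_corrected = norm(corrected), occ_raw = occ_raw,
         occ_bw = occ_bw, env_bw = env_bw,
         n_occ = nrow(occ_scores), n_background = nrow(background_scores)),
    class = "niche_density")
}

#' @export
print.niche_density <- function(x, ...) {
  cat(sprintf("<niche_density> %d x %d grid, %d occurrences vs %d background\n",
              x$R, x$R, x$n_occ, x$n_background))
  cat(sprintf("  extent: axis1 [%.3g, %.3g], axis2 [%.3g, %.3g]\n",
              x$extent[1, 1], x$extent[2, 1], x$extent[1, 2], x$extent[2, 2]))
  invisible(x)
}

#' Schoener's D niche overlap
#'
#' Normalizes each taxon's chosen density grid to sum 1 and returns
#' `D = 1 - 0.5 * sum(|p1 - p2|)`, which ranges from 0 (no overlap) to 1
#' (complete overlap). Both grids must share resolution and extent.
#'
#' @param g1,g2 [density_grid()] results on the same grid.
#' @param corrected Use the availability-corrected occupancy (default
#'   `TRUE`) or the uncorrected occurrence density.
#' @return A scalar in [0, 1].
#' @export
schoener_d <- function(g1, g2, corrected = TRUE) {
  stopifnot(inherits(g1, "niche_density"), inherits(g2, "niche_density"))
  if (g1$R != g2$R || max(abs(g1$extent - g2$extent)) > 1e-9) {
    abort("density grids differ in resolution or extent.")
  }
  field <- if (corrected) "occ_corrected" else "occ_density"
  schoener_d_grids(g1[[field]], g2[[field]])
}

# Core overlap on plain matrices (also used by the permutation machinery).
schoener_d_grids <- function(z1, z2) {
  s1 <- sum(z1); s2 <- sum(z2)
  if (s1 <= 0 || s2 <= 0) abort("density grid with zero total mass.")
  1 - 0.5 * sum(abs(z1 / s1 - z2 / s2))
}
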