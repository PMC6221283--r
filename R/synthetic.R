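#' Default bioclimatic layer set
#'
#' The seven derived climate summaries the package uses by default:
#' annual mean temperature (bio1), temperature seasonality (bio4), minimum
#' temperature of the coldest month (bio6), temperature annual range (bio7),
#' annual precipitation (bio12), precipitation seasonality (bio15) and
#' precipitation of the driest quarter (bio17).
#'
#' @return Character vector of layer names.
#' @export
default_layer_names <- function() {
  c("bio1", "bio4", "bio6", "bio7", "bio12", "bio15", "bio17")
}

# Realistic Mediterranean-ish marginals for the default layers: means and
# spatial standard deviations in each variable's native units (degC, mm,
# index units). Only the spatial *structure* matters downstream (everything
# is standardized before modelling); units just keep configs readable.
default_layer_means <- function() {
  c(bio1 = 13, bio4 = 550, bio6 = 0.5, bio7 = 28, bio12 = 520, bio15 = 42,
    bio17 = 70)
}
default_layer_sds <- function() {
  c(bio1 = 3, bio4 = 80, bio6 = 3, bio7 = 4, bio12 = 150, bio15 = 10,
    bio17 = 35)
}

# Block cross-correlation: temperature layers moderately correlated with one
# another, precipitation layers likewise, weak coupling across the blocks.
# Constant-block matrices of this form are positive semi-definite.
default_cross_correlation <- function(layer_names = default_layer_names()) {
  k <- length(layer_names)
  temp <- grepl("^bio[1467]$", layer_names)
  C <- matrix(0.15, k, k)
  C[temp, temp] <- 0.5
  C[!temp, !temp] <- 0.5
  diag(C) <- 1
  dimnames(C) <- list(layer_names, layer_names)
  C
}

# Glacial cooling/drying of roughly 1-1.5 present-day spatial sd per layer,
# and a mid-era shift of about a third of that. The magnitudes are free
# scenario parameters; these defaults are set once (see the methods
# vignette) and shared by all examples and tests.
default_era_shifts <- function() {
  list(
    lgm = c(bio1 = -5, bio4 = 90, bio6 = -6, bio7 = 4, bio12 = -150,
            bio15 = 8, bio17 = -35),
    mid_holocene = c(bio1 = -1.5, bio4 = 30, bio6 = -2, bio7 = 1.5,
                     bio12 = -50, bio15 = 3, bio17 = -12),
    present = c(bio1 = 0, bio4 = 0, bio6 = 0, bio7 = 0, bio12 = 0,
                bio15 = 0, bio17 = 0)
  )
}

#' Ground-truth niche for a synthetic taxon
#'
#' Defines a known suitability surface as a logistic function of the
#' standardized layer values: `plogis(beta0 + sum(beta_linear * z) +
#' sum(beta_quadratic * z^2))`. Quadratic terms let the niche peak at an
#' interior optimum; the coefficients are the ground truth that recovery
#' tests compare fitted models against.
#'
#' @param taxon_id Label for the taxon.
#' @param beta0 Intercept (controls peak suitability).
#' @param beta_linear,beta_quadratic Numeric vectors, one coefficient per
#'   layer.
#' @return An object of class `true_niche`.
#' @export
true_niche <- function(taxon_id, beta0, beta_linear, beta_quadratic) {
  if (length(beta_linear) != length(beta_quadratic)) {
    abort("beta_linear and beta_quadratic must have equal length.")
  }
  structure(list(taxon_id = taxon_id, beta0 = beta0,
                 beta_linear = beta_linear,
                 beta_quadratic = beta_quadratic),
            class = "true_niche")
}

#' Build a niche peaked at an interior climatic optimum
#'
#' Convenience constructor for a [true_niche()] whose suitability peaks
#' where the named layers sit at `center` standard deviations from the
#' landscape mean, with quadratic falloff of `strength` per squared standard
#' deviation and peak suitability `plogis(peak_logit)`. The default strength
#' concentrates essentially all suitability within about half a standard
#' deviation of the optimum, so two taxa with opposite centers occupy
#' disjoint regions of environmental space.
#'
#' @param taxon_id Taxon label.
#' @param layer_names All layer names of the scenario.
#' @param on Layers defining the optimum.
#' @param center Optimum position in standardized layer units.
#' @param strength Quadratic falloff per layer.
#' @param peak_logit Logit of the peak suitability.
#' @return A [true_niche()].
#' @export
peaked_niche <- function(taxon_id, layer_names, on = c("bio1", "bio12"),
                         center = 1, strength = 4, peak_logit = 3) {
  k <- length(layer_names)
  bl <- setNames(numeric(k), layer_names)
  bq <- setNames(numeric(k), layer_names)
  bl[on] <- 2 * strength * center
  bq[on] <- -strength
  b0 <- peak_logit - strength * center^2 * length(on)
  true_niche(taxon_id, b0, bl, bq)
}

#' Synthetic landscape and occurrence scenario
#'
#' Bundles every knob of the synthetic generator: grid geometry, number of
#' autocorrelated climate layers and their cross-correlation, era shifts,
#' soil-patch fraction, and per-taxon ground-truth niches with occurrence
#' counts. The defaults describe the study conditions all tests run under:
#' a 100 x 100 grid of seven correlated bioclimatic layers, a clustered
#' soil mask covering 6.1% of the landscape (the documented gypsum-outcrop
#' share of the study region), three eras, and two taxa with well-separated
#' climatic optima (one preferring warm/wet cells, the other cold/dry), 50
#' occurrences each.
#'
#' @param grid_rows,grid_cols Grid dimensions (>= 10).
#' @param cell_size Cell size in degrees.
#' @param origin Length-2 numeric, (lon, lat) of the lower-left corner.
#' @param layer_names Names of the climate layers.
#' @param layer_means,layer_sds Marginal mean and spatial sd per layer.
#' @param autocorr_length Gaussian kernel scale of the random fields, cells.
#' @param cross_correlation Target layer cross-correlation matrix (symmetric
#'   positive semi-definite).
#' @param era_shifts Named list: era -> per-layer additive offsets.
#' @param niches Named list of [true_niche()] objects, one per taxon.
#' @param n_occurrences Occurrences per taxon (single count or named vector).
#' @param soil_fraction Fraction of the landscape covered by soil patches,
#'   in (0, 1].
#' @param soil_patch_scale Autocorrelation scale of the soil field, cells.
#' @param seed Integer master seed for the scenario.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(grid_rows = 100, grid_cols = 100,
                            cell_size = 0.05, origin = c(-5, 36),
                            layer_names = default_layer_names(),
                            layer_means = default_layer_means(),
                            layer_sds = default_layer_sds(),
                            autocorr_length = 8,
                            cross_correlation = default_cross_correlation(layer_names),
                            era_shifts = default_era_shifts(),
                            niches = list(
                              taxon_a = peaked_niche("taxon_a", layer_names,
                                                     center = 1),
                              taxon_b = peaked_niche("taxon_b", layer_names,
                                                     center = -1)
                            ),
                            n_occurrences = 50,
                            soil_fraction = 0.061,
                            soil_patch_scale = 5,
                            seed = 1L) {
  if (grid_rows < 10 || grid_cols < 10) {
    abort("grid_rows and grid_cols must be >= 10.")
  }
  k <- length(layer_names)
  if (length(layer_means) != k || length(layer_sds) != k) {
    abort("layer_means and layer_sds must have one value per layer.")
  }
  if (!is.matrix(cross_correlation) ||
      any(dim(cross_correlation) != k)) {
    abort("cross_correlation must be a k x k matrix (k = number of layers).")
  }
  if (max(abs(cross_correlation - t(cross_correlation))) > 1e-8) {
    abort("cross_correlation must be symmetric.")
  }
  ev <- eigen(cross_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort(sprintf(paste0("cross_correlation is not positive semi-definite ",
                         "(smallest eigenvalue %.3g)."), min(ev)))
  }
  if (soil_fraction <= 0 || soil_fraction > 1) {
    abort("soil_fraction must be in (0, 1].")
  }
  for (nm in names(era_shifts)) {
    if (length(era_shifts[[nm]]) != k) {
      abort(sprintf("era_shifts[['%s']] must have one offset per layer.", nm))
    }
  }
  for (nm in names(niches)) {
    ni <- niches[[nm]]
    if (length(ni$beta_linear) != k) {
      abort(sprintf("niche '%s' has %d coefficients but %d layers.",
                    nm, length(ni$beta_linear), k))
    }
  }
  if (is.null(names(n_occurrences))) {
    n_occurrences <- setNames(rep(n_occurrences[1], length(niches)),
                              names(niches))
  }
  if (any(n_occurrences < 1)) abort("n_occurrences must be >= 1.")
  structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         cell_size = cell_size, origin = origin, layer_names = layer_names,
         layer_means = layer_means, layer_sds = layer_sds,
         autocorr_length = autocorr_length,
         cross_correlation = cross_correlation, era_shifts = era_shifts,
         niches = niches, n_occurrences = n_occurrences,
         soil_fraction = soil_fraction, soil_patch_scale = soil_patch_scale,
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

# 1-D Gaussian smoothing matrix (rows normalized to sum 1); smoothing a
# white-noise field from both sides yields a Gaussian random field with
# correlation length ~ell cells.
gaussian_smoother <- function(n, ell) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  W <- exp(-0.5 * (d / ell)^2)
  W / rowSums(W)
}

smooth_field <- function(z, ell) {
  Kr <- gaussian_smoother(nrow(z), ell)
  Kc <- gaussian_smoother(ncol(z), ell)
  Kr %*% z %*% t(Kc)
}

standardize <- function(v) {
  s <- sd(v)
  if (s == 0) return(v * 0)
  (v - mean(v)) / s
}

# Symmetric PSD square root via eigendecomposition; unlike Cholesky it
# tolerates singular targets (e.g. correlation exactly 1 between layers).
psd_sqrt <- function(C) {
  e <- eigen(C, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(C)) %*% t(e$vectors)
}

#' Generate spatially autocorrelated, cross-correlated climate layers
#'
#' Each layer is a Gaussian random field built by smoothing white noise with
#' a Gaussian kernel of scale `autocorr_length`, standardizing, then mixing
#' the independent fields with the PSD square root of the target
#' cross-correlation matrix; finally each layer is rescaled to its
#' configured marginal mean and sd. Deterministic for a fixed seed.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed; defaults to the scenario seed.
#' @return A [raster_stack()] with `length(config$layer_names)` layers.
#' @export
generate_layers <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  k <- length(config$layer_names)
  set.seed(seed)
  fields <- matrix(0, nr * nc, k)
  for (j in seq_len(k)) {
    z <- matrix(rnorm(nr * nc), nr, nc)
    fields[, j] <- standardize(as.vector(smooth_field(z, config$autocorr_length)))
  }
  mixed <- fields %*% psd_sqrt(config$cross_correlation)
  layers <- list()
  for (j in seq_len(k)) {
    v <- config$layer_means[[j]] + config$layer_sds[[j]] * mixed[, j]
    layers[[config$layer_names[j]]] <- matrix(v, nr, nc)
  }
  raster_stack(layers, xmin = config$origin[1], ymin = config$origin[2],
               cellsize = config$cell_size)
}

#' Generate a clustered binary soil mask
#'
#' Thresholds an independent autocorrelated field at the quantile that
#' leaves `soil_fraction` of cells above it, producing contiguous "outcrop"
#' patches rather than salt-and-pepper noise.
#'
#' @param config A [scenario_config()] (supplies geometry, fraction, patch
#'   scale).
#' @param seed Integer seed; defaults to a fan-out of the scenario seed.
#' @return A single-layer [raster_stack()] named `"soil"` with values 0/1.
#' @export
generate_soil_mask <- function(config, seed = fan_seed(config$seed, "soil")) {
  stopifnot(inherits(config, "scenario_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  if (config$soil_fraction >= 1) {
    m <- matrix(1, nr, nc)
  } else {
    set.seed(seed)
    f <- smooth_field(matrix(rnorm(nr * nc), nr, nc), config$soil_patch_scale)
    cut <- quantile(f, 1 - config$soil_fraction, type = 7)
    m <- (f > cut) * 1
  }
  raster_stack(list(soil = m), xmin = config$origin[1],
               ymin = config$origin[2], cellsize = config$cell_size)
}

#' Evaluate a ground-truth suitability surface
#'
#' Computes `plogis(beta0 + sum(beta_lin * z) + sum(beta_quad * z^2))`
#' per cell, where `z` are the layer values standardized over the stack's
#' off-nodata cells. Values lie strictly in (0, 1).
#'
#' @param stack A [raster_stack()] of climate layers.
#' @param niche A [true_niche()] with one coefficient pair per layer.
#' @return A single-layer [raster_stack()] named `"suitability"`.
#' @export
true_suitability <- function(stack, niche) {
  stopifnot(is_raster_stack(stack), inherits(niche, "true_niche"))
  k <- length(stack$layers)
  if (length(niche$beta_linear) != k) {
    abort(sprintf("niche has %d coefficients but the stack has %d layers.",
                  length(niche$beta_linear), k))
  }
  eta <- matrix(niche$beta0, stack$nrows, stack$ncols)
  for (j in seq_len(k)) {
    z <- stack$layers[[j]]
    zs <- (z - mean(z, na.rm = TRUE)) / sd(as.vector(z), na.rm = TRUE)
    eta <- eta + niche$beta_linear[[j]] * zs + niche$beta_quadratic[[j]] * zs^2
  }
  raster_stack(list(suitability = plogis(eta)), xmin = stack$xmin,
               ymin = stack$ymin, cellsize = stack$cellsize)
}

#' Sample occurrences from a suitability surface
#'
#' Draws `n` distinct cell centers without replacement with probability
#' proportional to `suitability * mask`, emulating presence records of a
#' taxon confined to suitable soil. Sampling at cell centers matches the
#' per-pixel thinning applied to real records downstream.
#'
#' @param suitability Single-layer [raster_stack()] of suitabilities.
#' @param n Number of occurrences (>= 1).
#' @param mask Optional binary single-layer [raster_stack()] (e.g. from
#'   [generate_soil_mask()]); cells with 0 are never sampled.
#' @param taxon_id Label written into the `taxon` column.
#' @param seed Integer seed.
#' @return A tibble with columns `taxon`, `lon`, `lat`.
#' @export
sample_occurrences <- function(suitability, n, mask = NULL,
                               taxon_id = "taxon", seed = 1L) {
  stopifnot(is_raster_stack(suitability))
  if (n < 1) abort("n must be >= 1.")
  s <- stack_layer(suitability)
  w <- as.vector(s)
  if (!is.null(mask)) {
    stop_if_geometry_differs(suitability, mask)
    w <- w * as.vector(stack_layer(mask))
  }
  w[is.na(w)] <- 0
  eligible <- which(w > 0)
  if (length(eligible) == 0) {
    abort("no eligible cells: suitability * mask is zero everywhere.")
  }
  if (n > length(eligible)) {
    abort(sprintf("requested %d occurrences but only %d eligible cells.",
                  n, length(eligible)))
  }
  set.seed(seed)
  picked <- if (length(eligible) == 1) eligible else {
    sample(eligible, n, replace = FALSE, prob = w[eligible])
  }
  rows <- ((picked - 1) %% suitability$nrows) + 1
  cols <- ((picked - 1) %/% suitability$nrows) + 1
  tibble(taxon = taxon_id,
         lon = cell_center_lon(suitability, cols),
         lat = cell_center_lat(suitability, rows))
}

#' Materialize a whole scenario
#'
#' Runs the generator end to end: climate layers, per-era shifted stacks,
#' soil mask, per-taxon true suitability surfaces and occurrence samples.
#' All randomness is fanned out from the scenario seed, so the result is a
#' pure function of the configuration.
#'
#' @param config A [scenario_config()].
#' @return A list with elements `config`, `stacks` (named list of
#'   [raster_stack()] per era), `soil` (mask stack), `truth` (named list of
#'   suitability stacks per taxon, present era), and `occurrences` (tibble
#'   of all taxa pooled).
#' @export
build_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  base <- generate_layers(config, seed = fan_seed(config$seed, "layers"))
  stacks <- lapply(config$era_shifts, function(off) {
    apply_era_shift(base, off[config$layer_names])
  })
  if (!"present" %in% names(stacks)) stacks$present <- base
  soil <- generate_soil_mask(config)
  truth <- list()
  occs <- list()
  for (nm in names(config$niches)) {
    truth[[nm]] <- true_suitability(stacks$present, config$niches[[nm]])
    occs[[nm]] <- sample_occurrences(
      truth[[nm]], config$n_occurrences[[nm]], mask = soil, taxon_id = nm,
      seed = fan_seed(config$seed, "occ", nm))
  }
  list(config = config, stacks = stacks, soil = soil, truth = truth,
       occurrences = dplyr::bind_rows(occs))
}
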