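#' Write a fitted model as a flat text file
#'
#' Header metadata (`key value` lines) followed by one line per feature:
#' `feature<TAB>class<TAB>coefficient`, then one line per variable:
#' `bound<TAB>variable<TAB>lower<TAB>upper`. Full double precision, so a
#' write/read round trip reproduces predictions exactly.
#'
#' @param model A `maxent_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maxent_model <- function(model, path) {
  stopifnot(inherits(model, "maxent_model"))
  con <- file(path, "wb")
  on.exit(close(con))
  meta <- c(
    sprintf("log_z %.17g", model$log_z),
    sprintf("entropy %.17g", model$entropy),
    sprintf("reg_multiplier %.17g", model$reg_multiplier),
    sprintf("n_presence %d", model$n_presence),
    sprintf("n_background %d", model$n_background),
    sprintf("classes %s", paste(model$spec$classes, collapse = ",")))
  feats <- sprintf("feature\t%s\t%s\t%.17g", names(model$coefficients),
                   model$feature_class, model$coefficients)
  bounds <- sprintf("bound\t%s\t%.17g\t%.17g", model$spec$variables,
                    model$spec$lower, model$spec$upper)
  writeLines(c(meta, feats, bounds), con)
  invisible(path)
}

#' Read a model written by [write_maxent_model()]
#'
#' @param path File path.
#' @return A `maxent_model` (without the optimizer trace).
#' @export
read_maxent_model <- function(path) {
  lines <- readLines(path)
  kv <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)[1]
    sub(paste0("^", key, " "), "", ln)
  }
  feat_lines <- strsplit(grep("^feature\t", lines, value = TRUE), "\t")
  bound_lines <- strsplit(grep("^bound\t", lines, value = TRUE), "\t")
  variables <- vapply(bound_lines, `[`, "", 2)
  lower <- setNames(as.numeric(vapply(bound_lines, `[`, "", 3)), variables)
  upper <- setNames(as.numeric(vapply(bound_lines, `[`, "", 4)), variables)
  spec <- feature_spec(variables, strsplit(kv("classes"), ",")[[1]],
                       lower, upper)
  coefs <- setNames(as.numeric(vapply(feat_lines, `[`, "", 4)),
                    vapply(feat_lines, `[`, "", 2))
  structure(
    list(spec = spec, coefficients = coefs,
         feature_class = vapply(feat_lines, `[`, "", 3),
         log_z = as.numeric(kv("log_z")), entropy = as.numeric(kv("entropy")),
         reg_multiplier = as.numeric(kv("reg_multiplier")),
         reg = rep(NA_real_, length(coefs)),
         n_presence = as.integer(kv("n_presence")),
         n_background = as.integer(kv("n_background")),
         objective_trace = NA_real_, converged = TRUE,
         identifiable = rep(TRUE, length(coefs))),
    class = "maxent_model")
}

#' Serialize a niche density grid
#'
#' Writes the three grids (`occ_density`, `env_density`, `occ_corrected`) as
#' ASCII grids in grid-index coordinates (origin 0, cell size 1 — the two
#' PCA axes generally have unequal cell sizes, which the `.asc` format
#' cannot carry) plus a JSON sidecar with the true extent, resolution and
#' bandwidths needed to reconstruct axis coordinates.
#'
#' @param g A [density_grid()] result.
#' @param prefix Output path prefix; files `<prefix>_<grid>.asc` and
#'   `<prefix>_meta.json` are written.
#' @return `prefix`, invisibly.
#' @export
write_density_grid <- function(g, prefix) {
  stopifnot(inherits(g, "niche_density"))
  for (nm in c("occ_density", "env_density", "occ_corrected")) {
    # transpose: matrix rows are axis1 bins; .asc rows run north -> south
    m <- t(g[[nm]])[rev(seq_len(g$R)), , drop = FALSE]
    st <- raster_stack(setNames(list(m), nm), xmin = 0, ymin = 0,
                       cellsize = 1)
    write_ascii_grid(st, paste0(prefix, "_", nm, ".asc"))
  }
  meta <- list(R = g$R,
               extent = list(axis1 = g$extent[, 1], axis2 = g$extent[, 2]),
               occ_bw = g$occ_bw, env_bw = g$env_bw, n_occ = g$n_occ,
               n_background = g$n_background)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(prefix)
}

#' Serialize a permutation test result
#'
#' Writes `<prefix>_replicates.csv` (one row per replicate),
#' `<prefix>_summary.json` (observed D, p-value, verdict, seed) and
#' `<prefix>_histogram.csv` (null-distribution bin edges and counts with the
#' observed D marker, ready for plotting).
#'
#' @param x An `overlap_test`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_overlap_test <- function(x, prefix) {
  stopifnot(inherits(x, "overlap_test"))
  reps <- tidy(x)
  if (!is.null(x$shift_log)) reps$truncated_mass <- x$shift_log$truncated_mass
  write_csv_plain(reps, paste0(prefix, "_replicates.csv"))
  jsonlite::write_json(
    c(as.list(glance(x)), list(alpha = x$alpha)),
    paste0(prefix, "_summary.json"), digits = NA, auto_unbox = TRUE)
  h <- graphics::hist(x$null_d, breaks = seq(0, 1, length.out = 21),
                      plot = FALSE)
  write_csv_plain(tibble(bin_low = h$breaks[-length(h$breaks)],
                         bin_high = h$breaks[-1], count = h$counts,
                         d_obs = x$d_obs),
                  paste0(prefix, "_histogram.csv"))
  invisible(prefix)
}

#' Write a scenario configuration as YAML
#'
#' @param config A [scenario_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  lst <- unclass(config)
  lst$cross_correlation <- as.vector(lst$cross_correlation)
  lst$niches <- lapply(lst$niches, unclass)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a scenario configuration from YAML
#'
#' @param path YAML file written by [write_scenario_config()] (or by hand
#'   with the same keys).
#' @return A validated [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  lst <- yaml::read_yaml(path)
  k <- length(lst$layer_names)
  niches <- lapply(lst$niches, function(ni) {
    true_niche(ni$taxon_id, ni$beta0,
               setNames(unlist(ni$beta_linear), lst$layer_names),
               setNames(unlist(ni$beta_quadratic), lst$layer_names))
  })
  scenario_config(
    grid_rows = lst$grid_rows, grid_cols = lst$grid_cols,
    cell_size = lst$cell_size, origin = unlist(lst$origin),
    layer_names = unlist(lst$layer_names),
    layer_means = setNames(unlist(lst$layer_means), lst$layer_names),
    layer_sds = setNames(unlist(lst$layer_sds), lst$layer_names),
    autocorr_length = lst$autocorr_length,
    cross_correlation = matrix(unlist(lst$cross_correlation), k, k,
                               dimnames = list(lst$layer_names,
                                               lst$layer_names)),
    era_shifts = lapply(lst$era_shifts, function(v)
      setNames(unlist(v), lst$layer_names)),
    niches = niches,
    n_occurrences = setNames(unlist(lst$n_occurrences), names(lst$niches)),
    soil_fraction = lst$soil_fraction,
    soil_patch_scale = lst$soil_patch_scale, seed = lst$seed)
}
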