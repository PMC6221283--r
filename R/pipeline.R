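#' Five-number boxplot summary with Tukey outliers
#'
#' The standard R boxplot statistics: linear-interpolation (type-7)
#' quartiles, whiskers at the most extreme values within 1.5 IQR of the
#' quartiles, and everything beyond flagged as outliers.
#'
#' @param values Numeric vector (>= 1 value; `NA`s dropped).
#' @return A one-row tibble: `n`, `min`, `q1`, `median`, `q3`, `max`,
#'   `whisker_low`, `whisker_high`, `n_outliers`, and `outliers`
#'   (list-column).
#' @export
summarize_boxplot <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("empty input.")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  out <- values[values < lo | values > hi]
  tibble(n = length(values), min = min(values), q1 = q[1], median = q[2],
         q3 = q[3], max = max(values),
         whisker_low = min(values[values >= lo]),
         whisker_high = max(values[values <= hi]),
         n_outliers = length(out), outliers = list(sort(out)))
}

#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs. Exactly one input mode is
#' used: a synthetic `scenario` ([scenario_config()]), or file paths
#' (`stack_dirs`, a named list era -> directory of `.asc` layers;
#' `occurrences`, a CSV path; optional `soil`, an `.asc` path). The master
#' `seed` is fanned out deterministically to every stochastic stage (see
#' [fan_seed()]) and recorded in every output.
#'
#' @param scenario Optional [scenario_config()] (synthetic mode).
#' @param stack_dirs Named list, era -> directory of layer grids (file
#'   mode).
#' @param occurrences Occurrence CSV path (file mode).
#' @param soil Optional soil-mask `.asc` path (file mode).
#' @param present_era Era used for fitting and ordination (default
#'   `"present"`).
#' @param variables Optional fixed variable list; default: run the
#'   collinearity filter.
#' @param r_threshold Collinearity threshold (default 0.95).
#' @param train_fraction Train share of each taxon's occurrences (default
#'   0.7).
#' @param reg_multiplier MaxEnt regularization multiplier (default 1).
#' @param background_n Background sample size (default 10000).
#' @param R Niche-space grid resolution (default 100).
#' @param n_reps Permutation replicates per test (default 100).
#' @param corrected Compare availability-corrected densities (default
#'   `TRUE`).
#' @param seed Master seed.
#' @param out_dir Output directory for the run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(scenario = NULL, stack_dirs = NULL, occurrences = NULL,
                       soil = NULL, present_era = "present",
                       variables = NULL, r_threshold = 0.95,
                       train_fraction = 0.7, reg_multiplier = 1,
                       background_n = 10000, R = 100, n_reps = 100,
                       corrected = TRUE, seed = 1L, out_dir = tempfile("run")) {
  synthetic <- !is.null(scenario)
  if (synthetic && (!is.null(stack_dirs) || !is.null(occurrences))) {
    abort("exactly one input mode: give either `scenario` or file paths.")
  }
  if (!synthetic && (is.null(stack_dirs) || is.null(occurrences))) {
    abort("file mode needs both `stack_dirs` and `occurrences`.")
  }
  if (!synthetic && anyDuplicated(names(stack_dirs))) {
    abort("era names must be unique.")
  }
  structure(
    list(scenario = scenario, stack_dirs = stack_dirs,
         occurrences = occurrences, soil = soil, present_era = present_era,
         variables = variables, r_threshold = r_threshold,
         train_fraction = train_fraction, reg_multiplier = reg_multiplier,
         background_n = background_n, R = R, n_reps = n_reps,
         corrected = corrected, seed = as.integer(seed), out_dir = out_dir),
    class = "run_config")
}

write_csv_plain <- function(x, path) {
  x <- as.data.frame(x)
  for (nm in names(x)) {
    if (is.list(x[[nm]])) {
      x[[nm]] <- vapply(x[[nm]], function(v) paste(format(v, digits = 15),
                                                   collapse = ";"), "")
    }
  }
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full niche-shift pipeline
#'
#' Orchestrates the whole analysis: materialize or load the inputs, thin
#' occurrences per pixel, filter collinear variables, sample the background,
#' then per taxon fit and evaluate a maximum-entropy model, project it onto
#' every era's climate (with a soil-masked variant when a mask is present),
#' and extract per-era suitability at the taxon's own points; finally, for
#' every taxon pair, build the two-axis PCA environmental space and run the
#' equivalency test plus both directional similarity tests. All tabular
#' outputs are CSV, rasters are `.asc`, and the whole run is a pure function
#' of the configuration: re-running with the same master seed reproduces
#' every numeric output byte for byte.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `out_dir`, the fitted `models`, `evals`,
#'   `selection`, `suitability` (per-era point extractions with boxplot
#'   summaries), `overlap` (per-pair test objects) and the Table-style
#'   `comparison` tibble.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf("%s  %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    writeLines(log_lines, log_path)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      say("FAILED at stage '%s': %s", name, conditionMessage(e))
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  say("run start; master seed %d; package nicheshift %s", config$seed,
      as.character(utils::packageVersion("nicheshift")))

  # ---- inputs ----------------------------------------------------------
  inp <- stage("inputs", {
    if (!is.null(config$scenario)) {
      sc <- build_scenario(config$scenario)
      list(stacks = sc$stacks, soil = sc$soil, occ = sc$occurrences)
    } else {
      stacks <- lapply(config$stack_dirs, read_stack)
      soil <- if (!is.null(config$soil)) read_ascii_grid(config$soil, "soil")
      list(stacks = stacks, soil = soil, occ = read_occurrences(config$occurrences))
    }
  })
  if (!config$present_era %in% names(inp$stacks)) {
    abort(sprintf("no era named '%s' among stacks.", config$present_era))
  }
  present <- inp$stacks[[config$present_era]]
  taxa <- unique(inp$occ$taxon)
  say("inputs ready: %d eras, %d taxa, %d occurrence rows",
      length(inp$stacks), length(taxa), nrow(inp$occ))

  # ---- occurrence thinning --------------------------------------------
  occ <- stage("dedupe", dedupe_per_pixel(inp$occ, present))
  say("per-pixel thinning: %d -> %d records", nrow(inp$occ), nrow(occ))

  # ---- variable selection ---------------------------------------------
  sel <- stage("select_variables", {
    n_min <- min(table(occ$taxon))
    if (is.null(config$variables)) {
      select_variables(present, r_threshold = config$r_threshold,
                       n_occurrences = n_min)
    } else {
      structure(list(kept = config$variables,
                     dropped = tibble(variable = character(),
                                      partner = character(), r = double()),
                     guard_ok = n_min >= 10 * length(config$variables),
                     r_threshold = config$r_threshold,
                     n_occurrences = n_min),
                class = "variable_selection")
    }
  })
  say("variables kept (%d): %s; guard_ok = %s", length(sel$kept),
      paste(sel$kept, collapse = ", "), sel$guard_ok)
  stacks <- lapply(inp$stacks, select_layers, keep = sel$kept)
  present <- stacks[[config$present_era]]
  write_csv_plain(
    tibble(variable = sel$kept, kept = TRUE, seed = config$seed),
    file.path(config$out_dir, "variables.csv"))

  # ---- background ------------------------------------------------------
  background <- stage("background", sample_background(
    present, n = config$background_n,
    seed = fan_seed(config$seed, "background")))

  # ---- per-taxon modelling --------------------------------------------
  models <- list(); evals <- list(); suit_rows <- list(); extract_rows <- list()
  for (tx in taxa) {
    occ_t <- occ[occ$taxon == tx, , drop = FALSE]
    env_t <- extract_at_points(present, occ_t)
    env_t <- env_t[env_t$inside & !env_t$on_nodata, , drop = FALSE]
    split <- stage(paste0("split/", tx), split_occurrences(
      env_t, config$train_fraction, seed = fan_seed(config$seed, "split", tx)))
    model <- stage(paste0("fit/", tx), fit_maxent(
      split$train, background, variables = sel$kept,
      reg_multiplier = config$reg_multiplier))
    models[[tx]] <- model
    write_maxent_model(model,
                       file.path(config$out_dir, paste0("model_", tx, ".txt")))
    ev <- stage(paste0("evaluate/", tx), evaluate_model(
      model, split$test, background, n_train = nrow(split$train)))
    evals[[tx]] <- ev
    say("taxon %s: %d train / %d test; AUC %.4f, TSS %.4f", tx,
        nrow(split$train), nrow(split$test), ev$auc, ev$tss)
    for (era in names(stacks)) {
      map <- stage(paste0("project/", tx, "/", era),
                   predict(model, stacks[[era]]))
      write_ascii_grid(map, file.path(config$out_dir,
                                      sprintf("suitability_%s_%s.asc", tx, era)))
      if (!is.null(inp$soil)) {
        masked <- apply_soil_mask(map, inp$soil)
        write_ascii_grid(masked, file.path(
          config$out_dir, sprintf("suitability_%s_%s_soilmasked.asc", tx, era)))
      }
      ext <- extract_at_points(map, occ_t)
      extract_rows[[paste(tx, era)]] <- tibble(
        taxon = tx, era = era, point_id = seq_len(nrow(ext)),
        lon = ext$lon, lat = ext$lat, inside = ext$inside,
        suitability = ext$suitability)
      ok <- ext$inside & !ext$on_nodata
      suit_rows[[paste(tx, era)]] <- dplyr::bind_cols(
        tibble(taxon = tx, era = era), summarize_boxplot(ext$suitability[ok]))
    }
  }
  eval_tbl <- dplyr::bind_rows(lapply(evals, glance), .id = "taxon")
  write_csv_plain(eval_tbl, file.path(config$out_dir, "evaluation.csv"))
  extraction <- dplyr::bind_rows(extract_rows)
  write_csv_plain(extraction, file.path(config$out_dir, "point_suitability.csv"))
  suitability <- dplyr::bind_rows(suit_rows)
  write_csv_plain(suitability %>% dplyr::select(-"outliers"),
                  file.path(config$out_dir, "suitability_boxplots.csv"))

  # ---- niche comparison ------------------------------------------------
  space <- stage("pca", fit_pca_env(background, variables = sel$kept))
  write_csv_plain(tidy(space), file.path(config$out_dir, "pca_loadings.csv"))
  bg_scores <- project_scores(space, background)
  overlap <- list(); comp_rows <- list()
  if (length(taxa) >= 2) {
    pairs <- utils::combn(taxa, 2, simplify = FALSE)
    for (pr in pairs) {
      a <- pr[1]; b <- pr[2]
      env_a <- extract_at_points(present, occ[occ$taxon == a, ])
      env_b <- extract_at_points(present, occ[occ$taxon == b, ])
      env_a <- env_a[env_a$inside & !env_a$on_nodata, ]
      env_b <- env_b[env_b$inside & !env_b$on_nodata, ]
      sc_a <- project_scores(space, env_a)
      sc_b <- project_scores(space, env_b)
      key <- paste(a, b, sep = "|")
      eq <- stage(paste0("equivalency/", key), equivalency_test(
        sc_a, sc_b, bg_scores, R = config$R, n_reps = config$n_reps,
        corrected = config$corrected,
        seed = fan_seed(config$seed, "equivalency", a, b)))
      sim_ab <- stage(paste0("similarity_ab/", key), similarity_test(
        sc_a, sc_b, bg_scores, R = config$R, n_reps = config$n_reps,
        corrected = config$corrected, direction = paste0(a, "->", b),
        seed = fan_seed(config$seed, "similarity", a, b)))
      sim_ba <- stage(paste0("similarity_ba/", key), similarity_test(
        sc_b, sc_a, bg_scores, R = config$R, n_reps = config$n_reps,
        corrected = config$corrected, direction = paste0(b, "->", a),
        seed = fan_seed(config$seed, "similarity", b, a)))
      overlap[[key]] <- list(equivalency = eq, similarity_ab = sim_ab,
                             similarity_ba = sim_ba)
      # D under both density choices, reported side by side
      st <- overlap_setup(bg_scores, bg_scores, config$R, TRUE)
      ga <- st$grid_for(sc_a, bg_scores); gb <- st$grid_for(sc_b, bg_scores)
      d_corr <- schoener_d(ga, gb, corrected = TRUE)
      d_uncorr <- schoener_d(ga, gb, corrected = FALSE)
      write_density_grid(ga, file.path(config$out_dir, paste0("density_", a)))
      write_density_grid(gb, file.path(config$out_dir, paste0("density_", b)))
      for (res in list(eq, sim_ab, sim_ba)) {
        comp_rows[[length(comp_rows) + 1]] <- dplyr::bind_cols(
          tibble(taxon_a = a, taxon_b = b), glance(res),
          tibble(d_corrected = d_corr, d_uncorrected = d_uncorr))
        write_overlap_test(res, file.path(
          config$out_dir,
          sprintf("overlap_%s_%s_%s", res$kind,
                  gsub("->", "_to_", res$direction %||% "pooled"), key)))
      }
      say("pair %s vs %s: D = %.4f, equivalency p = %.4f (%s)", a, b,
          eq$d_obs, eq$p_value, eq$verdict)
    }
    write_csv_plain(dplyr::bind_rows(comp_rows),
                    file.path(config$out_dir, "niche_comparison.csv"))
  }
  say("run complete")
  invisible(list(out_dir = config$out_dir, selection = sel, models = models,
                 evals = evals, suitability = suitability,
                 extraction = extraction, space = space, overlap = overlap,
                 comparison = if (length(comp_rows))
                   dplyr::bind_rows(comp_rows) else NULL))
}
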