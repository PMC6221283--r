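two_layer_config <- function(cross, seed = 5, n = 100) {
  scenario_config(
    grid_rows = n, grid_cols = n, layer_names = c("a", "b"),
    layer_means = c(a = 0, b = 0), layer_sds = c(a = 1, b = 1),
    cross_correlation = cross, autocorr_length = 4,
    era_shifts = list(present = c(a = 0, b = 0)),
    niches = list(t = true_niche("t", 0, c(0, 0), c(0, 0))),
    seed = seed)
}

test_that("generated fields honour the requested cross-correlation", {
  id <- generate_layers(two_layer_config(diag(2)))
  r_id <- cor(as.vector(stack_layer(id, "a")), as.vector(stack_layer(id, "b")))
  expect_lt(abs(r_id), 0.15)

  dup <- generate_layers(two_layer_config(matrix(1, 2, 2)))
  r_dup <- cor(as.vector(stack_layer(dup, "a")),
               as.vector(stack_layer(dup, "b")))
  expect_gte(r_dup, 0.99)

  expect_error(two_layer_config(matrix(c(1, 1.5, 1.5, 1), 2, 2)),
               "positive semi-definite")
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- scen60_config()
  expect_identical(generate_layers(cfg, seed = 5)$layers,
                   generate_layers(cfg, seed = 5)$layers)
  expect_false(identical(generate_layers(cfg, seed = 5)$layers,
                         generate_layers(cfg, seed = 6)$layers))
  expect_identical(stack_layer(generate_soil_mask(cfg, seed = 5)),
                   stack_layer(generate_soil_mask(cfg, seed = 5)))
  tr <- true_suitability(generate_layers(cfg), cfg$niches$taxon_a)
  expect_identical(sample_occurrences(tr, 30, seed = 9),
                   sample_occurrences(tr, 30, seed = 9))
})

test_that("soil mask hits the requested cover fraction in clustered patches", {
  cfg <- scenario_config(grid_rows = 200, grid_cols = 200,
                         soil_fraction = 0.061, seed = 11)
  mask <- stack_layer(generate_soil_mask(cfg))
  expect_true(all(mask %in% c(0, 1)))
  frac <- mean(mask)
  expect_gte(frac, 0.011)
  expect_lte(frac, 0.111)
  # clustering: a 1-cell's neighbours are far more often 1 than the base rate
  ones <- which(mask == 1, arr.ind = TRUE)
  inner <- ones[ones[, 1] > 1 & ones[, 1] < 200 & ones[, 2] > 1 &
                  ones[, 2] < 200, , drop = FALSE]
  neigh <- mean(mask[cbind(inner[, 1] + 1, inner[, 2])])
  expect_gt(neigh, 5 * frac)

  all_soil <- generate_soil_mask(scenario_config(soil_fraction = 1, seed = 1))
  expect_true(all(stack_layer(all_soil) == 1))
})

test_that("true suitability matches the closed-form logistic", {
  # all betas zero -> exactly 0.5 everywhere
  st <- scen60()$stacks$present
  flat <- true_suitability(st, true_niche("t", 0, numeric(7), numeric(7)))
  expect_true(all(stack_layer(flat) == 0.5))

  # deeply negative intercept -> suitability approaches 0
  low <- true_suitability(st, true_niche("t", -50, numeric(7), numeric(7)))
  expect_lt(max(stack_layer(low)), 1e-20)

  # hand-computed single cell: standardized value 2 with beta = (1, 0, ...)
  m <- matrix(c(-2, -1, 0, 1, 2, rep(0, 4)), 3, 3)  # sd-scaled by construction
  z <- (m - mean(m)) / sd(as.vector(m))
  st1 <- stack_from(x = m)
  ni <- true_niche("t", 0, 1, 0)
  got <- stack_layer(true_suitability(st1, ni))
  expect_equal(got, plogis(z), tolerance = 1e-12)
  expect_equal(plogis(2), 0.8807971, tolerance = 1e-7)

  expect_error(true_suitability(st1, true_niche("t", 0, c(1, 1), c(0, 0))),
               "layers")
})

test_that("occurrence sampling respects mask, weights and exhaustion", {
  suit <- stack_from(suitability = matrix(1, 10, 10), cellsize = 1)
  # uniform suitability, all-mask, n = grid size -> every cell exactly once
  all_cells <- sample_occurrences(suit, 100, seed = 4)
  expect_equal(nrow(dplyr::distinct(all_cells, lon, lat)), 100)

  # hard mask constraint: zero on the left half
  mask <- matrix(1, 10, 10); mask[, 1:5] <- 0
  msk <- stack_from(soil = mask, cellsize = 1)
  occ <- sample_occurrences(suit, 30, mask = msk, seed = 4)
  expect_true(all(occ$lon > 5))

  expect_error(sample_occurrences(suit, 101, seed = 1), "eligible")
  zero <- stack_from(suitability = matrix(0, 10, 10), cellsize = 1)
  expect_error(sample_occurrences(zero, 1, seed = 1), "eligible")

  # strongly peaked suitability (Gaussian bump over a near-zero baseline)
  # concentrates samples in the top-decile region
  bump <- outer(dnorm(1:60, 30, 3), dnorm(1:60, 30, 3)) + 1e-10
  peak <- stack_from(suitability = bump / max(bump), cellsize = 1)
  o <- sample_occurrences(peak, 200, taxon_id = "t", seed = 5)
  thr <- quantile(stack_layer(peak), 0.9)
  v <- extract_at_points(peak, o)$suitability
  expect_gte(mean(v >= thr), 0.8)
})

test_that("scenario occurrences always sit on soil with finite climate", {
  sc <- scen60()
  soil_at <- extract_at_points(sc$soil, sc$occurrences)
  expect_true(all(soil_at$soil == 1))
  env <- extract_at_points(sc$stacks$present, sc$occurrences)
  expect_true(all(is.finite(as.matrix(env[default_layer_names()]))))
})

test_that("scenario configs survive a YAML round trip", {
  cfg <- scen60_config()
  path <- withr::local_tempfile(fileext = ".yml")
  write_scenario_config(cfg, path)
  back <- read_scenario_config(path)
  expect_equal(back$cross_correlation, cfg$cross_correlation)
  expect_equal(back$niches$taxon_a$beta_linear, cfg$niches$taxon_a$beta_linear)
  expect_identical(generate_layers(back)$layers, generate_layers(cfg)$layers)
})
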