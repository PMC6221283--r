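test_that("feature expansion has the right columns, scaling and clamping", {
  vars <- default_layer_names()
  env <- scen60_bg()
  spec <- feature_spec(vars, lower = sapply(env[vars], min),
                       upper = sapply(env[vars], max))
  X <- make_features(env, spec)
  expect_equal(ncol(X), 7 + 7 + 21)
  expect_true(all(X >= 0 & X <= 1))

  # value at the spec max scales to exactly 1; above it clamps to 1
  at_max <- env[1, ]
  at_max$bio1 <- spec$upper[["bio1"]]
  expect_equal(make_features(at_max, spec)[1, "bio1"], c(bio1 = 1))
  above <- env[1, ]; above$bio1 <- spec$upper[["bio1"]] + 100
  expect_equal(make_features(above, spec)[1, "bio1"], c(bio1 = 1))
  expect_gt(make_features(above, spec, clamp = FALSE)[1, "bio1"], 1)

  expect_error(make_features(env[, 1:3], spec), "missing variable")
})

test_that("collinearity filter drops duplicated layers and verifies the kept set", {
  sc <- scen60()
  st <- sc$stacks$present
  st$layers$bio1_copy <- st$layers$bio1
  sel <- select_variables(st, n_occurrences = 80)
  expect_equal(nrow(sel$dropped), 1)
  expect_equal(sel$dropped$r[1], 1.0, tolerance = 1e-12)
  expect_true(sel$dropped$variable %in% c("bio1", "bio1_copy"))
  expect_true(sel$dropped$partner %in% c("bio1", "bio1_copy"))
  # brute-force recheck: no kept pair at or above the threshold
  env <- tibble::as_tibble(select_layers(st, sel$kept))
  R <- cor(as.matrix(env[sel$kept]))
  diag(R) <- 0
  expect_lt(max(abs(R)), 0.95)
})

test_that("the ten-occurrences-per-variable guard trips at the boundary", {
  st <- scen60()$stacks$present
  expect_true(select_variables(st, n_occurrences = 70)$guard_ok)
  expect_false(select_variables(st, n_occurrences = 69)$guard_ok)
})

test_that("uniform presences yield near-uniform predictions (null model)", {
  stk <- generate_layers(scenario_config(grid_rows = 80, grid_cols = 80,
                                         seed = 5))
  bg <- sample_background(stk, 3000, seed = 2)
  set.seed(33)
  pres <- bg[sample.int(nrow(bg), 1000), ]
  m0 <- fit_maxent(pres, bg)
  expect_monotone_objective(m0)
  raw <- predict(m0, bg, transform = "raw")
  expect_lt(max(raw) / min(raw), 2)
})

test_that("a one-variable preference is recovered with the right sign", {
  set.seed(2)
  bgx <- tibble::tibble(x = runif(1000))
  px <- tibble::tibble(x = sample(bgx$x, 60, prob = bgx$x^3))
  mt <- fit_maxent(px, bgx, classes = "linear")
  expect_gt(mt$coefficients[["x"]], 0)
  expect_monotone_objective(mt)
})

test_that("raw predictions normalize over the training background", {
  fx <- recovery_fit()
  raw <- predict(fx$model, fx$bg, transform = "raw")
  expect_equal(sum(raw), 1, tolerance = 1e-9)
  # degenerate all-zero model: uniform raw = 1/N
  bg <- scen60_bg()
  m0 <- fit_maxent(bg[1:50, ], bg, reg_multiplier = 1e6)
  expect_true(all(m0$coefficients == 0))
  expect_equal(unname(predict(m0, bg, transform = "raw")),
               rep(1 / nrow(bg), nrow(bg)), tolerance = 1e-12)
})

test_that("cloglog and logistic outputs are monotone in raw and in [0,1]", {
  fx <- recovery_fit()
  idx <- seq(1, nrow(fx$bg), by = 37)
  sub <- fx$bg[idx, ]
  raw <- predict(fx$model, sub, transform = "raw")
  for (tr in c("cloglog", "logistic")) {
    v <- predict(fx$model, sub, transform = tr)
    expect_true(all(v >= 0 & v <= 1))
    expect_identical(order(v), order(raw))
  }
})

test_that("projection onto the training stack reproduces tabular predictions", {
  fx <- recovery_fit()
  map <- predict(fx$model, fx$stack)
  at_bg <- extract_at_points(map, fx$bg)$suitability
  direct <- predict(fx$model, fx$bg)
  expect_equal(at_bg, unname(direct), tolerance = 1e-12)
  # era projection with zero shift is exactly the present-day prediction
  zero <- apply_era_shift(fx$stack, setNames(numeric(7), names(fx$stack$layers)))
  expect_identical(stack_layer(predict(fx$model, zero)), stack_layer(map))
})

test_that("fitted suitability ranks recover the known truth", {
  fx <- recovery_fit()
  expect_monotone_objective(fx$model)
  pred <- predict(fx$model, fx$bg, transform = "raw")
  truth <- extract_at_points(fx$truth, fx$bg)$suitability
  expect_gte(cor(pred, truth, method = "spearman"), 0.8)
})

test_that("model text serialization round-trips predictions exactly", {
  fx <- recovery_fit()
  path <- withr::local_tempfile(fileext = ".txt")
  write_maxent_model(fx$model, path)
  back <- read_maxent_model(path)
  sub <- fx$bg[seq(1, nrow(fx$bg), by = 53), ]
  expect_identical(unname(predict(back, sub)), unname(predict(fx$model, sub)))
})

test_that("soil masking zeroes off-mask suitability and never raises it", {
  suit <- stack_from(suitability = matrix(runif(100), 10, 10), cellsize = 1)
  all1 <- stack_from(soil = matrix(1, 10, 10), cellsize = 1)
  all0 <- stack_from(soil = matrix(0, 10, 10), cellsize = 1)
  expect_identical(stack_layer(apply_soil_mask(suit, all1)),
                   stack_layer(suit))
  expect_true(all(stack_layer(apply_soil_mask(suit, all0)) == 0))
  set.seed(8)
  patchy <- stack_from(soil = matrix(rbinom(100, 1, 0.3), 10, 10),
                       cellsize = 1)
  masked <- stack_layer(apply_soil_mask(suit, patchy))
  expect_true(all(masked <= stack_layer(suit)))
  # point form extracts at indicator points
  pts <- tibble::tibble(lon = c(0.5, 5.5), lat = c(0.5, 5.5))
  expect_equal(apply_soil_mask(suit, pts)$suitability,
               extract_at_points(suit, pts)$suitability)
})

test_that("background sampling respects mask, saturation and the seed", {
  sc <- scen60()
  st <- sc$stacks$present
  b1 <- sample_background(st, 500, seed = 3)
  b2 <- sample_background(st, 500, seed = 3)
  expect_identical(b1, b2)
  expect_equal(nrow(b1), 500)
  expect_equal(nrow(dplyr::distinct(b1, row, col)), 500)
  expect_message(all_cells <- sample_background(st, 1e6, seed = 1), "using all")
  expect_equal(nrow(all_cells), 3600)
  on_soil <- sample_background(st, 200, seed = 4, mask = sc$soil)
  soil_at <- extract_at_points(sc$soil, on_soil)
  expect_true(all(soil_at$soil == 1))
})
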