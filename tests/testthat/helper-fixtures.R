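# Shared fixtures, memoized so expensive scenario builds run once per suite.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small deterministic stack from explicit matrices
stack_from <- function(..., xmin = 0, ymin = 0, cellsize = 1) {
  raster_stack(list(...), xmin = xmin, ymin = ymin, cellsize = cellsize)
}

# the default study conditions at a reduced grid, used by most module tests
scen60_config <- function(seed = 7) {
  scenario_config(grid_rows = 60, grid_cols = 60, seed = seed)
}

scen60 <- function() fixture("scen60", function() build_scenario(scen60_config()))

scen60_bg <- function() fixture("scen60_bg", function() {
  sample_background(scen60()$stacks$present, 2000, seed = 2)
})

# full-size recovery scenario: a known logistic niche on a 100 x 100
# seven-layer landscape, 500 occurrences, all-cell background
recovery_fit <- function() fixture("recovery_fit", function() {
  cfg <- scenario_config(seed = 42)
  stack <- generate_layers(cfg, seed = fan_seed(42, "layers"))
  niche <- true_niche("t", -1,
                      beta_linear = c(1, 0, 0.5, 0, 1, 0, 0),
                      beta_quadratic = c(-0.8, -0.3, 0, 0, -0.8, 0, -0.3))
  truth <- true_suitability(stack, niche)
  occ <- sample_occurrences(truth, 500, taxon_id = "t",
                            seed = fan_seed(42, "occ"))
  bg <- suppressMessages(sample_background(stack, 10000,
                                           seed = fan_seed(42, "bg")))
  env <- extract_at_points(stack, occ)
  model <- fit_maxent(env, bg)
  list(stack = stack, truth = truth, occ = occ, bg = bg, env = env,
       model = model)
})

expect_monotone_objective <- function(model) {
  expect_true(all(diff(model$objective_trace) >= -1e-9))
}
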