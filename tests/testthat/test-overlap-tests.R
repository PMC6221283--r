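test_that("add-one rank p-values match hand counts and never reach 0", {
  null100 <- seq(0.3, 0.8, length.out = 100)
  # observed below all 100 nulls, lower tail -> 1/101
  expect_equal(rank_p_value(0.1, null100, "lower"), 1 / 101)
  expect_equal(round(rank_p_value(0.1, null100, "lower"), 4), 0.0099)
  # observed above all nulls, lower tail -> 1
  expect_equal(rank_p_value(0.9, null100, "lower"), 1)
  # 25 nulls at or below the observed -> 26/101
  expect_equal(rank_p_value(null100[25], null100, "lower"), 26 / 101)
  # upper tail with exactly 4 nulls >= observed -> 5/101 = 0.0495
  expect_equal(round(rank_p_value(null100[97], null100, "upper"), 4), 0.0495)
  # ties are counted in the rejection tail
  expect_equal(rank_p_value(0.5, c(0.5, 0.5, 0.7), "lower"), 3 / 4)
  expect_error(rank_p_value(0.5, numeric(0)), "empty")
})

shared_bg <- function() fixture("overlap_bg", function() {
  set.seed(40)
  tibble::tibble(axis1 = rnorm(1200), axis2 = rnorm(1200))
})

cloud <- function(n, cx, cy, sd = 0.3, seed = 1) {
  set.seed(seed)
  tibble::tibble(axis1 = rnorm(n, cx, sd), axis2 = rnorm(n, cy, sd))
}

test_that("equivalency test separates disjoint niches and accepts identical ones", {
  bg <- shared_bg()
  a <- cloud(40, -1.2, -1.2, 0.2, seed = 2)
  b <- cloud(40, 1.2, 1.2, 0.2, seed = 3)
  eq <- equivalency_test(a, b, bg, R = 80, n_reps = 100, seed = 5)
  expect_lt(eq$d_obs, min(eq$null_d))
  expect_equal(eq$p_value, 1 / 101)
  expect_equal(eq$verdict, "Not Equivalent")

  same <- equivalency_test(a, a, bg, R = 80, n_reps = 50, seed = 6)
  expect_equal(same$d_obs, 1)
  expect_gt(same$p_value, 0.9)
  expect_equal(same$verdict, "ns")
})

test_that("permutation tests are reproducible from (inputs, seed)", {
  bg <- shared_bg()
  a <- cloud(30, -0.5, 0, seed = 7)
  b <- cloud(30, 0.5, 0, seed = 8)
  e1 <- equivalency_test(a, b, bg, R = 60, n_reps = 30, seed = 11)
  e2 <- equivalency_test(a, b, bg, R = 60, n_reps = 30, seed = 11)
  expect_identical(e1$null_d, e2$null_d)
  e3 <- equivalency_test(a, b, bg, R = 60, n_reps = 30, seed = 12)
  expect_false(identical(e1$null_d, e3$null_d))
  s1 <- similarity_test(a, b, bg, R = 60, n_reps = 30, seed = 11)
  s2 <- similarity_test(a, b, bg, R = 60, n_reps = 30, seed = 11)
  expect_identical(s1$null_d, s2$null_d)
  # p always within its attainable bounds
  for (x in list(e1, e3, s1)) {
    expect_gte(x$p_value, 1 / (x$n_reps + 1))
    expect_lte(x$p_value, 1)
  }
})

test_that("similarity is directional and degrades to p ~ 1 for envelope-wide niches", {
  bg <- shared_bg()
  a <- cloud(50, -0.8, 0, 0.25, seed = 6)
  b <- cloud(50, 0.9, 0.4, 0.8, seed = 9)
  p_ab <- similarity_test(a, b, bg, R = 60, n_reps = 100, seed = 9)$p_value
  p_ba <- similarity_test(b, a, bg, R = 60, n_reps = 100, seed = 9)$p_value
  expect_false(isTRUE(all.equal(p_ab, p_ba)))

  # taxon b uniform over the envelope: centroid shifts barely change D
  set.seed(10)
  concentrated <- cloud(60, 0, 0, 0.2, seed = 10)
  uniform_b <- tibble::tibble(
    axis1 = runif(200, min(bg$axis1), max(bg$axis1)),
    axis2 = runif(200, min(bg$axis2), max(bg$axis2)))
  s <- similarity_test(concentrated, uniform_b, bg, R = 60, n_reps = 100,
                       seed = 3)
  expect_gt(s$p_value, 0.5)
})

test_that("matched niches are declared similar against random centroids", {
  bg <- shared_bg()
  a <- cloud(50, 0.4, 0.4, 0.25, seed = 21)
  b <- cloud(50, 0.5, 0.3, 0.25, seed = 22)
  s <- similarity_test(a, b, bg, R = 60, n_reps = 100, seed = 4)
  expect_lt(s$p_value, 0.05)
  expect_equal(s$verdict, "Similar")
  # truncated mass is logged per replicate
  expect_equal(nrow(s$shift_log), 100)
  expect_true(all(s$shift_log$truncated_mass >= -1e-12 &
                    s$shift_log$truncated_mass <= 1))
})

test_that("test results serialize with replicates, summary and histogram", {
  bg <- shared_bg()
  a <- cloud(20, -0.5, 0, seed = 31)
  b <- cloud(20, 0.5, 0, seed = 32)
  eq <- equivalency_test(a, b, bg, R = 50, n_reps = 20, seed = 2)
  prefix <- file.path(withr::local_tempdir(), "eq")
  write_overlap_test(eq, prefix)
  reps <- read.csv(paste0(prefix, "_replicates.csv"))
  expect_equal(reps$null_d, eq$null_d, tolerance = 1e-12)
  summ <- jsonlite::read_json(paste0(prefix, "_summary.json"))
  expect_equal(summ$p_value, eq$p_value, tolerance = 1e-12)
  hist_tbl <- read.csv(paste0(prefix, "_histogram.csv"))
  expect_equal(sum(hist_tbl$count), 20)
  expect_equal(unique(hist_tbl$d_obs), eq$d_obs, tolerance = 1e-12)
})
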