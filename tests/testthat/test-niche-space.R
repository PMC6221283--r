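test_that("correlation-matrix PCA matches a dense eigendecomposition", {
  set.seed(10)
  X <- as.data.frame(matrix(rnorm(50 * 7), 50, 7))
  names(X) <- paste0("v", 1:7)
  X$v2 <- X$v1 * 2 + rnorm(50, 0, 0.3)  # induce structure
  space <- fit_pca_env(X)
  eig <- eigen(cor(as.matrix(X)), symmetric = TRUE)
  expect_equal(unname(space$explained_variance),
               (eig$values / sum(eig$values))[1:2], tolerance = 1e-10)
  expect_equal(abs(unname(space$loadings[, 1])), abs(eig$vectors[, 1]),
               tolerance = 1e-8)
  # loadings orthonormal
  expect_equal(crossprod(space$loadings), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  # deterministic sign convention: dominant loading positive
  expect_gt(space$loadings[which.max(abs(space$loadings[, 1])), 1], 0)
  expect_gt(space$loadings[which.max(abs(space$loadings[, 2])), 2], 0)
})

test_that("two perfectly correlated variables load on one axis", {
  set.seed(3)
  X <- tibble::tibble(a = rnorm(40))
  X$b <- 2 * X$a + 5
  space <- fit_pca_env(X)
  expect_equal(unname(space$explained_variance[1]), 1, tolerance = 1e-10)
  expect_error(fit_pca_env(tibble::tibble(a = rep(1, 10), b = rep(2, 10))),
               "nonzero variance")
})

test_that("score projection is centered, scale-invariant and contained", {
  bg <- scen60_bg()
  space <- fit_pca_env(bg)
  # the background mean point projects to the origin
  mean_pt <- as.data.frame(as.list(colMeans(bg[space$variables])))
  expect_equal(unlist(project_scores(space, mean_pt)), c(axis1 = 0, axis2 = 0),
               tolerance = 1e-10)
  # rescaling a raw variable leaves scores unchanged (standardization absorbs it)
  bg2 <- bg
  bg2$bio12 <- bg2$bio12 * 2
  space2 <- fit_pca_env(bg2)
  s1 <- project_scores(space, bg)
  s2 <- project_scores(space2, bg2)
  expect_equal(abs(s2$axis1), abs(s1$axis1), tolerance = 1e-8)
  # calibration rows fall inside the stored axis ranges
  expect_true(all(s1$axis1 >= space$axis_range[1, 1] - 1e-12 &
                    s1$axis1 <= space$axis_range[2, 1] + 1e-12))
  # projection is an exact linear map: repeating it changes nothing
  expect_identical(project_scores(space, bg), s1)
  expect_error(project_scores(space, bg[, 1:4]), "missing variable")
})

test_that("density grids peak at the data and integrate to ~1", {
  set.seed(4)
  bg <- tibble::tibble(axis1 = rnorm(2000), axis2 = rnorm(2000))
  # single occurrence at the extent center: unimodal with central argmax
  center <- tibble::tibble(axis1 = mean(range(bg$axis1)),
                           axis2 = mean(range(bg$axis2)))
  g1 <- density_grid(center, bg, R = 51)
  am <- which(g1$occ_density == max(g1$occ_density), arr.ind = TRUE)
  expect_equal(unname(am[1, ]), c(26, 26), tolerance = 1)
  expect_equal(max(g1$occ_density), 1)

  # kernel mass integrates to ~1 for well-interior occurrences
  occ <- tibble::tibble(axis1 = rnorm(80, 0.3, 0.4), axis2 = rnorm(80, 0, 0.4))
  g2 <- density_grid(occ, bg, R = 100)
  cell_area <- prod((g2$extent[2, ] - g2$extent[1, ]) / 100)
  expect_equal(sum(g2$occ_raw) * cell_area, 1, tolerance = 0.05)

  # occurrences identical to the background: corrected density exactly flat
  g3 <- density_grid(bg, bg, R = 60)
  live <- g3$env_density > 0.1 * max(g3$env_density)
  expect_lt(max(g3$occ_corrected[live]) / min(g3$occ_corrected[live]),
            1 + 1e-9)

  expect_error(density_grid(occ, tibble::tibble(axis1 = c(1, 1),
                                                axis2 = c(0, 1)), R = 10),
               "degenerate extent")
})

test_that("Schoener's D hits its endpoints and the naive-loop oracle", {
  set.seed(5)
  bg <- tibble::tibble(axis1 = rnorm(1000), axis2 = rnorm(1000))
  occ <- tibble::tibble(axis1 = rnorm(50, 0.5), axis2 = rnorm(50, -0.2))
  g <- density_grid(occ, bg, R = 80)
  expect_equal(schoener_d(g, g), 1)
  expect_equal(schoener_d(g, g, corrected = FALSE), 1)

  # disjoint supports -> 0
  extent <- cbind(axis1 = c(0, 1), axis2 = c(0, 1))
  lo <- density_grid(tibble::tibble(axis1 = rep(0.05, 5), axis2 = rep(0.05, 5)),
                     bg, R = 100, extent = extent, occ_bw = c(0.005, 0.005))
  hi <- density_grid(tibble::tibble(axis1 = rep(0.95, 5), axis2 = rep(0.95, 5)),
                     bg, R = 100, extent = extent, occ_bw = c(0.005, 0.005))
  expect_equal(schoener_d(lo, hi, corrected = FALSE), 0, tolerance = 1e-12)

  # naive cell-loop oracle on random grids
  set.seed(6)
  ga <- density_grid(tibble::tibble(axis1 = rnorm(30), axis2 = rnorm(30)),
                     bg, R = 40)
  gb <- density_grid(tibble::tibble(axis1 = rnorm(30, 1), axis2 = rnorm(30)),
                     bg, R = 40)
  p1 <- ga$occ_corrected / sum(ga$occ_corrected)
  p2 <- gb$occ_corrected / sum(gb$occ_corrected)
  acc <- 0
  for (i in 1:40) for (j in 1:40) acc <- acc + abs(p1[i, j] - p2[i, j])
  expect_equal(schoener_d(ga, gb), 1 - 0.5 * acc, tolerance = 1e-12)

  # symmetry and positive-scaling invariance
  expect_identical(schoener_d(ga, gb), schoener_d(gb, ga))
  gb_scaled <- gb
  gb_scaled$occ_corrected <- gb_scaled$occ_corrected * 7.3
  expect_equal(schoener_d(ga, gb_scaled), schoener_d(ga, gb),
               tolerance = 1e-12)

  expect_error(schoener_d(ga, density_grid(occ, bg, R = 41)), "resolution")
})

test_that("D is stable under grid refinement on smooth densities", {
  set.seed(11)
  bg <- tibble::tibble(axis1 = rnorm(2000), axis2 = rnorm(2000))
  o1 <- tibble::tibble(axis1 = rnorm(100, -0.5, 0.6), axis2 = rnorm(100, 0, 0.6))
  o2 <- tibble::tibble(axis1 = rnorm(100, 0.5, 0.6), axis2 = rnorm(100, 0.2, 0.6))
  ds <- vapply(c(50, 100, 200), function(R) {
    schoener_d(density_grid(o1, bg, R = R), density_grid(o2, bg, R = R))
  }, 0)
  expect_lt(max(ds) - min(ds), 0.02)
})
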