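#' Add-one permutation rank p-value
#'
#' `p = (#{null in tail, ties included} + 1) / (n + 1)`: the standard
#' permutation p-value that counts the observed statistic as one more
#' replicate. It can never be 0; with 100 replicates its floor is
#' 1/101 = 0.0099.
#'
#' @param d_obs Observed statistic.
#' @param null_d Non-empty numeric vector of null replicates.
#' @param tail `"lower"` (rejection for small observed values) or
#'   `"upper"`.
#' @return A scalar in (0, 1].
#' @export
rank_p_value <- function(d_obs, null_d, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  if (length(null_d) == 0) abort("empty null distribution.")
  hits <- if (tail == "lower") sum(null_d <= d_obs) else sum(null_d >= d_obs)
  (hits + 1) / (length(null_d) + 1)
}

new_overlap_test <- function(kind, direction, d_obs, null_d, p_value, n_reps,
                             seed, verdict, corrected, alpha, shift_log = NULL) {
  structure(
    list(kind = kind, direction = direction, d_obs = d_obs, null_d = null_d,
         p_value = p_value, n_reps = n_reps, seed = seed, verdict = verdict,
         corrected = corrected, alpha = alpha, shift_log = shift_log),
    class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  dir <- if (is.null(x$direction)) "" else sprintf(" (%s)", x$direction)
  cat(sprintf("<overlap_test> %s%s: D = %.4f, p = %.4f over %d replicates -> %s\n",
              x$kind, dir, x$d_obs, x$p_value, x$n_reps, x$verdict))
  invisible(x)
}

#' @rdname tidy-methods
#' @export
tidy.overlap_test <- function(x, ...) {
  tibble(replicate = seq_along(x$null_d), null_d = x$null_d)
}

#' @rdname tidy-methods
#' @export
glance.overlap_test <- function(x, ...) {
  tibble(kind = x$kind,
         direction = x$direction %||% NA_character_,
         d_obs = x$d_obs, p_value = x$p_value, n_reps = x$n_reps,
         verdict = x$verdict, corrected = x$corrected, seed = x$seed)
}

# Shared setup: pooled extent across both taxa's backgrounds, availability
# grids computed once per taxon (they never change across permutation
# replicates), and a fast path producing the chosen occurrence-density
# matrix for arbitrary occurrence scores. `field_for` and the full
# density_grid() constructor share the same bandwidth rule, so the observed
# D and replicate Ds are computed identically.
overlap_setup <- function(bg_scores_1, bg_scores_2, R, corrected) {
  extent <- cbind(
    axis1 = range(c(bg_scores_1$axis1, bg_scores_2$axis1)),
    axis2 = range(c(bg_scores_1$axis2, bg_scores_2$axis2)))
  span <- extent[2, ] - extent[1, ]
  if (any(span <= 0)) abort("degenerate background envelope.")
  env_cache <- list(
    kde_on_grid(bg_scores_1, default_grid_bw(bg_scores_1, span, R), R, extent),
    if (identical(bg_scores_1, bg_scores_2)) NULL else
      kde_on_grid(bg_scores_2, default_grid_bw(bg_scores_2, span, R), R, extent))
  env_z <- function(side) {
    if (side == 2 && !is.null(env_cache[[2]])) env_cache[[2]]$z
    else env_cache[[1]]$z
  }
  field_for <- function(occ_scores, side) {
    bw <- default_grid_bw(occ_scores, span, R)
    occ <- kde_on_grid(occ_scores, bw, R, extent)$z
    if (corrected) corrected_density(occ, env_z(side)) else occ
  }
  grid_for <- function(occ_scores, bg_scores) {
    density_grid(occ_scores, bg_scores, R = R, extent = extent)
  }
  list(extent = extent, grid_for = grid_for, field_for = field_for,
       axis1 = env_cache[[1]]$x, axis2 = env_cache[[1]]$y,
       field = if (corrected) "occ_corrected" else "occ_density")
}

#' Niche equivalency permutation test
#'
#' Are the two taxa's niches interchangeable? All occurrences are pooled and
#' randomly relocated into two datasets of the original sizes; both density
#' grids are rebuilt (each against its own background) and Schoener's D
#' recomputed, `n_reps` times. The observed D is compared against this null
#' with a one-sided lower-tail add-one p-value: niches are declared "Not
#' Equivalent" (at `alpha`) when the observed overlap is smaller than
#' essentially all overlaps among randomly relabelled taxa.
#'
#' @param occ_scores_1,occ_scores_2 Occurrence scores (`axis1`, `axis2`) of
#'   the two taxa, >= 2 rows each.
#' @param bg_scores_1,bg_scores_2 Background scores per taxon (may be the
#'   same table when both taxa share a study area).
#' @param R Density-grid resolution (default 100).
#' @param n_reps Number of permutation replicates (default 100).
#' @param seed Integer seed.
#' @param corrected Compare availability-corrected densities (default
#'   `TRUE`).
#' @param alpha Significance level for the verdict label (default 0.05).
#' @return An `overlap_test` with the observed D, the null distribution,
#'   the p-value and a verdict (`"Not Equivalent"` or `"ns"`).
#' @export
equivalency_test <- function(occ_scores_1, occ_scores_2, bg_scores_1,
                             bg_scores_2 = bg_scores_1, R = 100,
                             n_reps = 100, seed = 1L, corrected = TRUE,
                             alpha = 0.05) {
  if (nrow(occ_scores_1) < 2 || nrow(occ_scores_2) < 2) {
    abort("need >= 2 occurrences per taxon.")
  }
  if (n_reps < 1) abort("n_reps must be >= 1.")
  st <- overlap_setup(bg_scores_1, bg_scores_2, R, corrected)
  d_obs <- schoener_d_grids(st$field_for(occ_scores_1, 1),
                            st$field_for(occ_scores_2, 2))
  pooled <- dplyr::bind_rows(occ_scores_1[c("axis1", "axis2")],
                             occ_scores_2[c("axis1", "axis2")])
  n1 <- nrow(occ_scores_1); n <- nrow(pooled)
  set.seed(seed)
  null_d <- vapply(seq_len(n_reps), function(i) {
    idx <- sample.int(n)
    z1 <- st$field_for(pooled[idx[seq_len(n1)], ], 1)
    z2 <- st$field_for(pooled[idx[seq(n1 + 1, n)], ], 2)
    # a replicate with all its mass on zero-availability cells overlaps nothing
    if (sum(z1) <= 0 || sum(z2) <= 0) return(0)
    schoener_d_grids(z1, z2)
  }, 0)
  p <- rank_p_value(d_obs, null_d, tail = "lower")
  verdict <- if (p < alpha) "Not Equivalent" else "ns"
  new_overlap_test("equivalency", NULL, d_obs, null_d, p, n_reps, seed,
                   verdict, corrected, alpha)
}

# Translate a density matrix by whole grid cells, zero-filling; mass pushed
# past the extent is truncated (the caller renormalizes via Schoener's D).
shift_grid <- function(z, dr, dc) {
  R1 <- nrow(z); R2 <- ncol(z)
  out <- matrix(0, R1, R2)
  src_r <- seq_len(R1) - dr
  src_c <- seq_len(R2) - dc
  ok_r <- src_r >= 1 & src_r <= R1
  ok_c <- src_c >= 1 & src_c <= R2
  if (any(ok_r) && any(ok_c)) {
    out[which(ok_r), which(ok_c)] <- z[src_r[ok_r], src_c[ok_c], drop = FALSE]
  }
  out
}

grid_centroid <- function(z, axis1, axis2) {
  s <- sum(z)
  c(sum(rowSums(z) * axis1) / s, sum(colSums(z) * axis2) / s)
}

#' Directional niche similarity permutation test
#'
#' Does taxon a's niche predict taxon b's better than random niches drawn
#' from b's background? Each replicate draws a uniform random centroid
#' within taxon b's background envelope, translates b's smoothed occurrence
#' density so its centroid lands there (mass shifted outside the extent is
#' truncated and the density renormalized), and recomputes D against taxon
#' a's observed grid. The one-sided upper-tail add-one p-value declares the
#' niches "Similar" (at `alpha`) when the observed overlap beats essentially
#' all random-centroid overlaps. The test is directional: a -> b and b -> a
#' generally differ.
#'
#' @inheritParams equivalency_test
#' @param occ_scores_a,occ_scores_b Occurrence scores of the reference (a)
#'   and shifted (b) taxon.
#' @param bg_scores_a,bg_scores_b Background scores per taxon; b's envelope
#'   is where random centroids are drawn.
#' @param direction Label recorded in the result (default `"a->b"`).
#' @return An `overlap_test` with verdict `"Similar"` or `"ns"` and a
#'   per-replicate log of the truncated mass fraction.
#' @export
similarity_test <- function(occ_scores_a, occ_scores_b, bg_scores_a,
                            bg_scores_b = bg_scores_a, R = 100,
                            n_reps = 100, seed = 1L, corrected = TRUE,
                            alpha = 0.05, direction = "a->b") {
  if (nrow(occ_scores_a) < 2 || nrow(occ_scores_b) < 2) {
    abort("need >= 2 occurrences per taxon.")
  }
  if (n_reps < 1) abort("n_reps must be >= 1.")
  st <- overlap_setup(bg_scores_a, bg_scores_b, R, corrected)
  za <- st$field_for(occ_scores_a, 1)
  zb <- st$field_for(occ_scores_b, 2)
  d_obs <- schoener_d_grids(za, zb)
  env_b <- cbind(axis1 = range(bg_scores_b$axis1),
                 axis2 = range(bg_scores_b$axis2))
  if (any(env_b[2, ] - env_b[1, ] <= 0)) abort("empty background envelope.")
  centroid <- grid_centroid(zb, st$axis1, st$axis2)
  cell <- c(st$axis1[2] - st$axis1[1], st$axis2[2] - st$axis2[1])
  set.seed(seed)
  truncated <- numeric(n_reps)
  null_d <- vapply(seq_len(n_reps), function(i) {
    target <- c(runif(1, env_b[1, 1], env_b[2, 1]),
                runif(1, env_b[1, 2], env_b[2, 2]))
    dd <- round((target - centroid) / cell)
    zs <- shift_grid(zb, dd[1], dd[2])
    truncated[i] <<- 1 - sum(zs) / sum(zb)
    if (sum(zs) <= 0) return(0)
    schoener_d_grids(za, zs)
  }, 0)
  # a replicate whose whole mass was truncated contributes zero overlap
  p <- rank_p_value(d_obs, null_d, tail = "upper")
  verdict <- if (p < alpha) "Similar" else "ns"
  new_overlap_test("similarity", direction, d_obs, null_d, p, n_reps, seed,
                   verdict, corrected, alpha,
                   shift_log = tibble(replicate = seq_len(n_reps),
                                      truncated_mass = truncated))
}
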