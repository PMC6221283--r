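#' Split occurrences into training and test sets
#'
#' Seeded shuffle followed by a `round(train_fraction * n)` /
#' `n - round(train_fraction * n)` partition (the conventional 70/30 by
#' default).
#'
#' @param occ Tibble of occurrence rows (>= 2).
#' @param train_fraction Fraction assigned to training (default 0.7).
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test`; disjoint, union = input.
#' @export
split_occurrences <- function(occ, train_fraction = 0.7, seed = 1L) {
  n <- nrow(occ)
  if (n < 2) abort("need at least 2 records to split.")
  check_scalar_number(train_fraction, "train_fraction", 0, 1)
  set.seed(seed)
  idx <- sample.int(n)
  n_train <- round(train_fraction * n)
  list(train = occ[sort(idx[seq_len(n_train)]), , drop = FALSE],
       test = occ[sort(idx[seq(n_train + 1, length.out = n - n_train)]), ,
                  drop = FALSE])
}

# Midrank (Mann-Whitney) AUC: probability a random presence outscores a
# random background point, ties counting one half. Equals the trapezoidal
# area under the ROC curve.
auc_mann_whitney <- function(pres_scores, bg_scores) {
  np <- length(pres_scores); nb <- length(bg_scores)
  r <- rank(c(pres_scores, bg_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Evaluate a fitted model with ROC-AUC and the True Skill Statistic
#'
#' Presence-background evaluation: test presences are scored against a
#' background sample standing in for absences. AUC is the Mann-Whitney
#' probability that a random presence outscores a random background point
#' (ties count one half). TSS = sensitivity + specificity - 1 is reported at
#' the threshold maximizing sensitivity + specificity (a point is predicted
#' present when its score >= threshold). If all scores are identical the
#' model is uninformative: AUC 0.5, TSS 0, and the report is flagged
#' `degenerate`.
#'
#' @param model A `maxent_model`.
#' @param test_presence_env Data frame of variable values at >= 1 test
#'   presences.
#' @param background_env Data frame of variable values at >= 2 background
#'   points.
#' @param transform Output transform used for scoring (AUC is invariant to
#'   it; the reported threshold is on this scale). Default `"cloglog"`.
#' @param n_train Optional training-presence count carried into the report.
#' @return An object of class `maxent_eval`; see [glance.maxent_eval()].
#' @export
evaluate_model <- function(model, test_presence_env, background_env,
                           transform = "cloglog", n_train = NA_integer_) {
  if (nrow(test_presence_env) < 1) abort("need >= 1 test presence.")
  if (nrow(background_env) < 2) abort("need >= 2 background points.")
  ps <- as.vector(predict(model, test_presence_env, transform = transform))
  bs <- as.vector(predict(model, background_env, transform = transform))
  degenerate <- (max(c(ps, bs)) - min(c(ps, bs))) == 0
  if (degenerate) {
    auc <- 0.5
    best <- list(threshold = ps[1], sens = 1, spec = 0)
    tss <- 0
    warn("constant scores: model is uninformative (AUC = 0.5, TSS = 0).")
  } else {
    auc <- auc_mann_whitney(ps, bs)
    thresholds <- sort(unique(c(ps, bs)))
    sens <- vapply(thresholds, function(t) mean(ps >= t), 0)
    spec <- vapply(thresholds, function(t) mean(bs < t), 0)
    k <- which.max(sens + spec)
    best <- list(threshold = thresholds[k], sens = sens[k], spec = spec[k])
    tss <- best$sens + best$spec - 1
  }
  roc <- {
    ts <- sort(unique(c(-Inf, ps, bs)))
    tibble(threshold = ts,
           tpr = vapply(ts, function(t) mean(ps >= t), 0),
           fpr = vapply(ts, function(t) mean(bs >= t), 0))
  }
  structure(
    list(auc = auc, tss = tss, threshold = best$threshold,
         sensitivity = best$sens, specificity = best$spec,
         n_train = n_train, n_test = length(ps), n_background = length(bs),
         transform = transform, degenerate = degenerate, roc = roc),
    class = "maxent_eval")
}

#' @export
print.maxent_eval <- function(x, ...) {
  cat(sprintf("<maxent_eval> AUC %.4f, TSS %.4f @ threshold %.4f (%s)\n",
              x$auc, x$tss, x$threshold, x$transform))
  cat(sprintf("  sensitivity %.4f, specificity %.4f; %d test presences vs %d background%s\n",
              x$sensitivity, x$specificity, x$n_test, x$n_background,
              if (x$degenerate) " [degenerate scores]" else ""))
  invisible(x)
}

#' @rdname tidy-methods
#' @export
tidy.maxent_eval <- function(x, ...) x$roc

#' @rdname tidy-methods
#' @export
glance.maxent_eval <- function(x, ...) {
  tibble(auc = x$auc, tss = x$tss, threshold = x$threshold,
         sensitivity = x$sensitivity, specificity = x$specificity,
         n_train = x$n_train, n_test = x$n_test,
         n_background = x$n_background, degenerate = x$degenerate)
}
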