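#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`, with the total sum of squares taken about the mean
#' of the reference values.  Requires a non-constant reference vector.
#'
#' @param pred,truth Equal-length numeric vectors (length >= 2).
#' @return R-squared (dimensionless, at most 1).
#' @export
#' @examples
#' r_squared(c(0.1, 0.2, 0.4), c(0.1, 0.2, 0.3))  # 0.5
r_squared <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(truth) >= 2)
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) abort("r_squared is undefined for a constant reference vector")
  1 - sum((pred - truth)^2) / ss_tot
}

#' Root mean squared error
#'
#' @param pred,truth Equal-length numeric vectors.
#' @return RMSE in the units of the inputs (strain).
#' @export
rmse <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(truth) >= 1)
  sqrt(mean((pred - truth)^2))
}

#' Flag impacts inside the targeted peak-velocity band
#'
#' The augmented training data deliberately concentrate on peak resultant
#' velocities strictly inside `(v_min, v_max)`; testing metrics are reported
#' both for the full dataset and for this within-range subset.  Bounds are
#' strict: a peak of exactly `v_min` or `v_max` is outside.
#'
#' @param profiles Profile tibble, or a tibble already carrying a
#'   `peak_magnitude` column (e.g. from [peak_resultant()]).
#' @param v_min,v_max Band bounds in rad/s.
#' @return One row per impact with `impact_id`, `peak_magnitude` and a
#'   logical `within_range` column; filter on it for either partition.
#' @export
split_within_range <- function(profiles, v_min = 21.9, v_max = 40) {
  peaks <- if ("peak_magnitude" %in% names(profiles)) {
    profiles
  } else {
    peak_resultant(profiles)
  }
  peaks$within_range <- peaks$peak_magnitude > v_min & peaks$peak_magnitude < v_max
  peaks
}

#' Testing metrics for one prediction set
#'
#' Computes R-squared and RMSE, for the full sample and -- when peak
#' velocities are supplied -- for the within-range subset.
#'
#' @param pred,truth Equal-length numeric vectors.
#' @param peaks Optional numeric vector of peak resultant velocities, used to
#'   add the within-range partition.
#' @param v_min,v_max Band bounds in rad/s.
#' @return Tibble with one row per partition: `partition`, `r2`, `rmse`, `n`.
#' @export
evaluate_predictions <- function(pred, truth, peaks = NULL,
                                 v_min = 21.9, v_max = 40) {
  out <- tibble::tibble(partition = "all",
                        r2 = r_squared(pred, truth),
                        rmse = rmse(pred, truth),
                        n = length(truth))
  if (!is.null(peaks)) {
    stopifnot(length(peaks) == length(truth))
    w <- peaks > v_min & peaks < v_max
    if (sum(w) >= 2 && stats::sd(truth[w]) > 0) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        partition = "within_range",
        r2 = r_squared(pred[w], truth[w]),
        rmse = rmse(pred[w], truth[w]),
        n = sum(w)))
    }
  }
  out
}

#' Cross-validation plan
#'
#' k-fold cross-validation repeated over independently seeded trials.  Each
#' trial reshuffles the fold assignment and reinitializes the network.
#'
#' @param k Number of folds.
#' @param n_trials Number of repeated trials.
#' @param seed Seed used to draw one sub-seed per trial (or pass `seeds`
#'   explicitly).
#' @param seeds Optional integer vector of per-trial seeds, length `n_trials`.
#' @return An object of class `cv_plan`.
#' @export
cv_plan <- function(k = 10, n_trials = 30, seed = NULL, seeds = NULL) {
  stopifnot(k >= 2, n_trials >= 1)
  if (is.null(seeds)) {
    if (!is.null(seed)) withr::local_seed(seed)
    seeds <- sample.int(.Machine$integer.max, n_trials)
  }
  stopifnot(length(seeds) == n_trials)
  structure(list(k = as.integer(k), n_trials = as.integer(n_trials),
                 seeds = as.integer(seeds)),
            class = "cv_plan")
}

#' Repeated k-fold cross-validation of the strain network
#'
#' For each trial: shuffle the samples with the trial seed, split into `k`
#' folds, train on `k - 1` folds and predict the held-out fold, then pool the
#' held-out predictions across all folds and score them once.  Pooled scoring
#' gives one R-squared/RMSE per trial, matching how a single test set would
#' be scored.  Trials differ only in their seeds.
#'
#' @param data A `strain_input`, N x 3 x 201 array, or D x N matrix.
#' @param labels Numeric labels, or `NULL` to pull `measure` from
#'   `data$labels`.
#' @param plan A [cv_plan()].
#' @param spec A [cnn_spec()].
#' @param config A [training_config()]; its `seed` is ignored (per-trial
#'   seeds come from the plan).
#' @param measure Strain measure name (used to pull labels and recorded in
#'   the results).
#'
#' @return A tibble of class `strain_cv` with one row per trial: `trial`,
#'   `seed`, `r2`, `rmse`, `n`, `n_within`, `measure`, and a nested
#'   `predictions` list-column (tibbles with `impact_id`, `fold`, `truth`,
#'   `pred`, `peak`).
#' @export
kfold_cv <- function(data, labels = NULL, plan = cv_plan(),
                     spec = cnn_spec(), config = training_config(),
                     measure = NULL) {
  stopifnot(inherits(plan, "cv_plan"))
  X <- as_input_matrix(data)
  if (is.null(labels)) {
    if (is.null(measure) || !inherits(data, "strain_input") || is.null(data$labels)) {
      abort("labels are required (or pass a labelled strain_input plus measure)")
    }
    labels <- data$labels[[measure]]
  }
  N <- ncol(X)
  stopifnot(length(labels) == N, N >= plan$k)
  ids <- if (inherits(data, "strain_input")) data$impact_id else
    sprintf("sample%05d", seq_len(N))
  peaks <- vapply(seq_len(N), function(i) {
    sqrt(max(colSums(matrix(X[, i], 3, 201)^2)))
  }, 0)
  config$seed <- NULL  # per-trial seeds govern all randomness

  trials <- purrr::map(seq_len(plan$n_trials), function(tr) {
    trial_seed <- plan$seeds[tr]
    withr::with_seed(trial_seed, {
      fold <- sample(rep(seq_len(plan$k), length.out = N))
      pred <- numeric(N)
      for (f in seq_len(plan$k)) {
        test <- which(fold == f)
        train <- which(fold != f)
        model <- build_cnn(spec, input_height = 3, input_width = 201)
        fit <- train_cnn(model, X[, train, drop = FALSE], labels[train], config)
        pred[test] <- predict(fit, X[, test, drop = FALSE])
      }
      w <- peaks > 21.9 & peaks < 40
      tibble::tibble(
        trial = tr, seed = trial_seed,
        r2 = r_squared(pred, labels),
        rmse = rmse(pred, labels),
        n = N, n_within = sum(w),
        measure = measure %||% NA_character_,
        predictions = list(tibble::tibble(
          impact_id = ids, fold = fold, truth = labels, pred = pred,
          peak = peaks))
      )
    })
  })
  out <- dplyr::bind_rows(trials)
  attr(out, "k") <- plan$k
  class(out) <- c("strain_cv", class(out))
  out
}

#' @export
glance.strain_cv <- function(x, ...) {
  tibble::tibble(
    n_trials = nrow(x), k = attr(x, "k") %||% NA_integer_,
    mean_r2 = mean(x$r2), sd_r2 = stats::sd(x$r2),
    mean_rmse = mean(x$rmse), sd_rmse = stats::sd(x$rmse)
  )
}

#' Predicted-versus-reference scatter for a cross-validation run
#'
#' @param object A `strain_cv` result.
#' @param trial Which trial to plot (default 1).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.strain_cv <- function(object, trial = 1, ...) {
  p <- object$predictions[[trial]]
  ggplot2::ggplot(p, ggplot2::aes(x = .data$truth, y = .data$pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "reference strain", y = "estimated strain") +
    ggplot2::theme_minimal()
}

#' Corrected resampled t-test for repeated cross-validation scores
#'
#' Paired one-tailed comparison of per-trial cross-validation scores.  Scores
#' from repeated CV runs are positively correlated because their training
#' sets overlap, so the naive paired t-test is anti-conservative.  The
#' corrected statistic inflates the variance by the test/train size ratio
#' `rho = 1/(k - 1)` of k-fold CV:
#' `t = mean(d) / sqrt(var(d) * (1/n + rho))`, `df = n - 1`,
#' where `d = a - b`.  The one-sided p-value tests whether `a` scores higher
#' than `b`.
#'
#' @param a,b Equal-length paired score vectors (one entry per trial).
#' @param k Number of CV folds behind each score.
#' @return One-row tibble: `estimate` (mean difference), `statistic`,
#'   `p.value`, `parameter` (df), `method`, `alternative`.
#' @export
corrected_cv_ttest <- function(a, b, k = 10) {
  stopifnot(length(a) == length(b), length(a) >= 2, k >= 2)
  d <- a - b
  n <- length(d)
  rho <- 1 / (k - 1)
  v <- stats::var(d)
  if (v == 0) {
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
  } else {
    t_stat <- mean(d) / sqrt(v * (1 / n + rho))
  }
  p <- stats::pt(t_stat, df = n - 1, lower.tail = FALSE)
  tibble::tibble(
    estimate = mean(d), statistic = t_stat, p.value = p,
    parameter = n - 1,
    method = "corrected resampled t-test",
    alternative = "greater"
  )
}

#' One-tailed Welch t-test
#'
#' Unequal-variance comparison of two independent score samples
#' (Welch--Satterthwaite degrees of freedom), one-sided for
#' `mean(a) > mean(b)`.  Delegates to [stats::t.test()]; degenerate
#' zero-variance inputs follow the same conventions as
#' [corrected_cv_ttest()].
#'
#' @param a,b Numeric vectors (length >= 2 each).
#' @return One-row tibble: `estimate`, `statistic`, `p.value`, `parameter`,
#'   `method`, `alternative`.
#' @export
welch_ttest <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    dm <- mean(a) - mean(b)
    t_stat <- if (dm == 0) 0 else sign(dm) * Inf
    p <- if (dm == 0) 0.5 else if (dm > 0) 0 else 1
    return(tibble::tibble(estimate = dm, statistic = t_stat, p.value = p,
                          parameter = NA_real_,
                          method = "Welch two-sample t-test",
                          alternative = "greater"))
  }
  ht <- stats::t.test(a, b, alternative = "greater", var.equal = FALSE)
  tibble::tibble(
    estimate = unname(ht$estimate[1] - ht$estimate[2]),
    statistic = unname(ht$statistic),
    p.value = ht$p.value,
    parameter = unname(ht$parameter),
    method = "Welch two-sample t-test",
    alternative = "greater"
  )
}
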