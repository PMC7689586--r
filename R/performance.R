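# DeLong structural components: V10 (per case) and V01 (per control) of the
# Mann-Whitney kernel, ties counted 1/2; midrank formulation, O(n log n).
delong_components <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  m <- length(cases)
  n <- length(controls)
  if (m == 0 || n == 0) abort("Both classes must be present to compute an AUC")
  r_all <- rank(c(cases, controls), ties.method = "average")
  r_case <- rank(cases, ties.method = "average")
  r_ctrl <- rank(controls, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_case) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_ctrl) / m
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' AUROC with a DeLong confidence interval
#'
#' The AUC is the Mann-Whitney concordance probability between case and
#' control scores (ties count one half). Its variance is estimated by the
#' DeLong structural-components method and the 95% CI is the normal interval,
#' clipped to `[0, 1]`.
#'
#' @param scores Numeric vector of risk scores or fitted probabilities.
#' @param labels Binary outcome vector (0/1 or logical), same length.
#' @param model Optional model identifier carried into the output.
#' @return One-row tibble: `model`, `auc`, `auc_var`, `conf.low`, `conf.high`,
#'   `n`, `n_cases`.
#' @export
#' @examples
#' auc_with_ci(c(0.9, 0.4, 0.5, 0.3), c(1, 1, 0, 0))
auc_with_ci <- function(scores, labels, model = NA_character_) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  dc <- delong_components(scores, labels)
  v <- var(dc$v10) / dc$m + var(dc$v01) / dc$n
  half <- 1.96 * sqrt(v)
  tibble(
    model = model, auc = dc$auc, auc_var = v,
    conf.low = max(0, dc$auc - half), conf.high = min(1, dc$auc + half),
    n = dc$m + dc$n, n_cases = dc$m
  )
}

#' Paired DeLong test comparing two correlated ROC curves
#'
#' Both score vectors must be computed on the same subjects with the same
#' labels; the covariance of the two AUCs is estimated from the paired
#' structural components and the two-sided p-value from a normal reference.
#' When the two score vectors induce identical structural components (e.g. a
#' model compared with itself) the variance of the difference is zero; the
#' difference is then reported with `p = NA` and `degenerate = TRUE`.
#'
#' @param scores_a,scores_b Score vectors from the two models.
#' @param labels Shared binary outcome vector.
#' @return One-row tibble: `auc_a`, `auc_b`, `delta` (`auc_b - auc_a`),
#'   `var_delta`, `statistic`, `p.value`, `degenerate`.
#' @export
compare_auc_delong <- function(scores_a, scores_b, labels) {
  labels <- as.numeric(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    abort("scores_a, scores_b and labels must have the same length")
  }
  da <- delong_components(scores_a, labels)
  db <- delong_components(scores_b, labels)
  s10 <- stats::cov(cbind(da$v10, db$v10))
  s01 <- stats::cov(cbind(da$v01, db$v01))
  S <- s10 / da$m + s01 / da$n
  delta <- db$auc - da$auc
  var_delta <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  degenerate <- var_delta <= .Machine$double.eps
  z <- if (degenerate) NA_real_ else delta / sqrt(var_delta)
  tibble(
    auc_a = da$auc, auc_b = db$auc, delta = delta,
    var_delta = max(var_delta, 0),
    statistic = z,
    p.value = if (degenerate) NA_real_ else 2 * pnorm(-abs(z)),
    degenerate = degenerate
  )
}

#' Scaled Brier score
#'
#' `1 - mean((score - y)^2) / (pbar * (1 - pbar))` where `pbar` is the
#' observed event fraction: 1 for perfect predictions, 0 for a constant
#' prediction at the prevalence, negative for models worse than that
#' reference.
#'
#' @param scores Predicted probabilities in `[0, 1]`.
#' @param labels Binary outcomes.
#' @return Scalar scaled Brier score.
#' @export
#' @examples
#' scaled_brier(c(0.8, 0.2, 0.6, 0.1), c(1, 0, 1, 0))
scaled_brier <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  if (any(scores < 0 | scores > 1)) abort("scores must lie in [0, 1]")
  pbar <- mean(labels)
  if (pbar == 0 || pbar == 1) {
    abort("Both classes must be present (reference Brier score is 0)")
  }
  1 - mean((scores - labels)^2) / (pbar * (1 - pbar))
}

#' Fit metrics for a continuous outcome model
#'
#' @param fit An `fhprs_fit` from the OLS estimator.
#' @return One-row tibble with `adj.r.squared` (`1 - (1 - R^2)(n-1)/(n-p-1)`)
#'   and `mse` (residual sum of squares over n).
#' @export
continuous_fit_metrics <- function(fit) {
  stopifnot(inherits(fit, "fhprs_fit"))
  if (fit$spec$estimator != "ols") abort("continuous metrics need an OLS fit")
  p <- length(fit$engine$coefficients) - 1
  if (fit$n_used <= p + 1) abort("n must exceed the number of parameters + 1")
  tibble(adj.r.squared = fit$engine$adj_r_squared, mse = fit$engine$mse)
}

#' Discrimination and calibration table across the three nested models
#'
#' Fits models 1-3 for a binary outcome and evaluates apparent (in-sample)
#' AUROC with DeLong CIs, paired DeLong comparisons against model 3, and
#' scaled Brier scores.
#'
#' @param data Derived cohort tibble.
#' @param outcome Binary outcome column.
#' @param ... Passed to [model_spec()].
#' @return A list with `performance` (one row per model) and `comparisons`
#'   (model 3 vs models 1 and 2), both tibbles, of class `fhprs_performance`.
#' @export
performance_table <- function(data, outcome = "copd_status", ...) {
  fits <- fit_models_123(data, outcome, ...)
  labels <- fits$model1$response
  if (!identical(length(labels), length(fits$model2$response)) ||
      !identical(length(labels), length(fits$model3$response)) ||
      !identical(labels, fits$model2$response) ||
      !identical(labels, fits$model3$response)) {
    abort(paste0(
      "Models 1-3 were fitted on different analysis samples (differential ",
      "missingness across predictors); restrict to complete cases first"
    ))
  }
  perf <- purrr::imap_dfr(fits, function(f, nm) {
    out <- auc_with_ci(f$fitted, labels, model = nm)
    out$scaled_brier <- scaled_brier(f$fitted, labels)
    out
  })
  comparisons <- bind_rows(
    mutate(compare_auc_delong(fits$model1$fitted, fits$model3$fitted, labels),
           comparison = "model3_vs_model1"),
    mutate(compare_auc_delong(fits$model2$fitted, fits$model3$fitted, labels),
           comparison = "model3_vs_model2")
  )
  structure(list(performance = perf, comparisons = comparisons,
                 outcome = outcome, fits = fits),
            class = "fhprs_performance")
}

#' @export
print.fhprs_performance <- function(x, ...) {
  cat("<fhprs_performance> outcome:", x$outcome, "\n")
  print(x$performance)
  print(x$comparisons)
  invisible(x)
}

#' @rdname performance_table
#' @param object An `fhprs_performance` object.
#' @method autoplot fhprs_performance
#' @export
autoplot.fhprs_performance <- function(object, ...) {
  ggplot2::ggplot(object$performance,
                  ggplot2::aes(x = .data$model, y = .data$auc)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$conf.low,
                                          ymax = .data$conf.high)) +
    ggplot2::labs(y = "AUROC (DeLong 95% CI)", x = NULL,
                  title = paste("Discrimination for", object$outcome)) +
    ggplot2::theme_minimal()
}
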