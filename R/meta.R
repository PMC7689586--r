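#' Build per-study estimates from odds ratios with 95% confidence intervals
#'
#' Converts printed odds ratios and interval bounds to log-scale effects with
#' standard errors recovered as `(log(upper) - log(lower)) / (2 * 1.96)`.
#'
#' @param study Study labels.
#' @param or Odds ratios.
#' @param conf.low,conf.high 95% interval bounds on the OR scale.
#' @param n Optional per-study sample sizes.
#' @return Tibble of study estimates on the log-OR scale (`study`, `effect`,
#'   `se`, `n`).
#' @export
#' @examples
#' study_estimates_from_or(
#'   c("cohortA", "cohortB"), or = c(1.67, 1.74),
#'   conf.low = c(1.45, 1.36), conf.high = c(1.92, 2.21)
#' )
study_estimates_from_or <- function(study, or, conf.low, conf.high,
                                    n = NA_real_) {
  stopifnot(length(or) == length(study),
            length(conf.low) == length(or), length(conf.high) == length(or))
  if (any(or <= 0 | conf.low <= 0 | conf.high <= 0)) {
    abort("Odds ratios and CI bounds must be positive")
  }
  if (any(conf.high < conf.low)) abort("CI bounds must be ordered")
  tibble(
    study = study, effect = log(or),
    se = (log(conf.high) - log(conf.low)) / (2 * qnorm(0.975)),
    n = n
  )
}

#' Inverse-variance fixed-effect meta-analysis
#'
#' Pools log-scale study effects with weights `1/SE^2`; reports the Cochran Q
#' heterogeneity statistic and `I^2 = max(0, (Q - df)/Q) * 100`. All pooling
#' happens on the log scale, so meta-analysing odds ratios and exponentiating
#' the pooled effect is the same operation.
#'
#' @param estimates Tibble with columns `study`, `effect` (log scale), `se`,
#'   e.g. from [study_estimates_from_or()]; at least two studies.
#' @param conf.level Interval coverage.
#' @return An object of class `fhprs_meta`; `tidy()` gives per-study rows
#'   plus the pooled row, `glance()` the pooled effect, Q, df and I^2.
#' @export
fixed_effect_meta <- function(estimates, conf.level = 0.95) {
  stopifnot(all(c("study", "effect", "se") %in% names(estimates)))
  if (nrow(estimates) < 2) abort("Meta-analysis needs at least 2 studies")
  if (any(!is.finite(estimates$se) | estimates$se <= 0)) {
    abort("All study SEs must be positive and finite")
  }
  if (!"n" %in% names(estimates)) estimates$n <- NA_real_
  w <- 1 / estimates$se^2
  pooled <- sum(w * estimates$effect) / sum(w)
  se_pooled <- 1 / sqrt(sum(w))
  q <- sum(w * (estimates$effect - pooled)^2)
  df <- nrow(estimates) - 1
  i2 <- max(0, (q - df) / q) * 100
  if (q == 0) i2 <- 0
  zq <- qnorm(1 - (1 - conf.level) / 2)
  per_study <- mutate(estimates,
                      weight = w / sum(w),
                      conf.low = .data$effect - zq * .data$se,
                      conf.high = .data$effect + zq * .data$se,
                      pooled = FALSE)
  pooled_row <- tibble(
    study = "pooled (fixed)", effect = pooled, se = se_pooled,
    n = sum(estimates$n, na.rm = TRUE), weight = 1,
    conf.low = pooled - zq * se_pooled, conf.high = pooled + zq * se_pooled,
    pooled = TRUE
  )
  structure(
    list(tidy = bind_rows(per_study, pooled_row),
         pooled = pooled, se = se_pooled, q = q, df = df, i2 = i2,
         p_heterogeneity = pchisq(q, df, lower.tail = FALSE),
         conf.level = conf.level),
    class = "fhprs_meta"
  )
}

#' @export
print.fhprs_meta <- function(x, ...) {
  cat("<fhprs_meta> fixed-effect pooling of", x$df + 1, "studies\n")
  cat(sprintf("pooled log-effect %.4f (SE %.4f); Q = %.3f on %d df; I2 = %.1f%%\n",
              x$pooled, x$se, x$q, x$df, x$i2))
  print(x$tidy)
  invisible(x)
}

#' @method tidy fhprs_meta
#' @export
tidy.fhprs_meta <- function(x, ...) x$tidy

#' @method glance fhprs_meta
#' @export
glance.fhprs_meta <- function(x, ...) {
  tibble(effect = x$pooled, se = x$se,
         conf.low = x$pooled - qnorm(1 - (1 - x$conf.level) / 2) * x$se,
         conf.high = x$pooled + qnorm(1 - (1 - x$conf.level) / 2) * x$se,
         or = exp(x$pooled), q = x$q, df = x$df, i2 = x$i2,
         p_heterogeneity = x$p_heterogeneity)
}

#' Forest-style plot of a fixed-effect meta-analysis
#'
#' @param object An `fhprs_meta` object.
#' @param exponentiate Plot on the OR scale.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fhprs_meta
#' @export
autoplot.fhprs_meta <- function(object, exponentiate = TRUE, ...) {
  d <- object$tidy
  if (exponentiate) {
    d <- mutate(d, effect = exp(.data$effect),
                conf.low = exp(.data$conf.low),
                conf.high = exp(.data$conf.high))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$effect,
                                  y = stats::reorder(.data$study,
                                                     !.data$pooled),
                                  shape = .data$pooled)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::geom_vline(xintercept = if (exponentiate) 1 else 0,
                        linetype = 2) +
    ggplot2::labs(x = if (exponentiate) "Odds ratio (95% CI)"
                  else "log effect (95% CI)",
                  y = NULL, shape = "pooled") +
    ggplot2::theme_minimal()
}
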