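rhs_of <- function(...) paste(c(...), collapse = " + ")

# Complete-case analysis frame for COPD interaction analyses: binary outcome
# copd (0/1), logical family_history, PRS columns, covariates.
prepare_interaction_frame <- function(data, covariates, prs_col) {
  need <- c("copd_status", "family_history", prs_col, covariates)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("Interaction analysis needs column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  d <- data[, need]
  d <- d[!is.na(d$copd_status) & d$copd_status != "excluded", , drop = FALSE]
  d$copd <- as.numeric(d$copd_status == "case")
  d$copd_status <- NULL
  if ("sex" %in% names(d)) d$sex <- factor(d$sex, levels = c("female", "male"))
  d <- d[complete.cases(d), , drop = FALSE]
  d
}

#' Attributable fractions from an adjusted odds ratio
#'
#' Case-based (Miettinen) attributable fractions for a binary exposure in a
#' case-control design, valid when the odds ratio approximates the risk
#' ratio: the fraction of exposed cases attributable to exposure is
#' `(OR - 1)/OR`, and the population attributable fraction multiplies this by
#' the exposure prevalence among cases.
#'
#' @param or_adjusted Adjusted odds ratio (> 0).
#' @param p_c Exposure prevalence among cases, in `[0, 1]` (`NA` allowed if
#'   only the exposed fraction is needed).
#' @param exposure Optional label.
#' @return One-row tibble: `exposure`, `or`, `p_cases_exposed`, `af_exposed`,
#'   `af_population`, `method`.
#' @export
#' @examples
#' attributable_fractions(1.71, p_c = 0.193)
attributable_fractions <- function(or_adjusted, p_c = NA_real_,
                                   exposure = NA_character_) {
  if (!is.finite(or_adjusted) || or_adjusted <= 0) {
    abort("or_adjusted must be a positive finite number")
  }
  if (!is.na(p_c) && (p_c < 0 || p_c > 1)) abort("p_c must lie in [0, 1]")
  af_exp <- (or_adjusted - 1) / or_adjusted
  tibble(
    exposure = exposure, or = or_adjusted, p_cases_exposed = p_c,
    af_exposed = af_exp,
    af_population = p_c * af_exp,
    method = "miettinen_case_based"
  )
}

#' Joint effects of family history and the dichotomised PRS
#'
#' Fits a single covariate-adjusted logistic model with a four-level factor
#' crossing family history with the top PRS tertile; odds ratios are relative
#' to the doubly-unexposed reference.
#'
#' @param data Derived cohort tibble.
#' @param covariates Adjustment set (default age, sex, pack-years, matching
#'   the interaction-model adjustment).
#' @return An object of class `fhprs_joint` with elements `tidy` (four rows:
#'   joint cell, OR, CI; reference OR fixed at 1), `fit` (the glm), and the
#'   coefficient names/covariance needed for RERI.
#' @export
joint_effects <- function(data, covariates = c("age", "sex", "pack_years")) {
  d <- prepare_interaction_frame(data, covariates, "prs_top_tertile")
  d$joint <- factor(
    paste0("FH", as.numeric(d$family_history),
           "_PRS", as.numeric(d$prs_top_tertile)),
    levels = c("FH0_PRS0", "FH1_PRS0", "FH0_PRS1", "FH1_PRS1")
  )
  counts <- table(d$joint)
  if (any(counts == 0)) {
    abort(paste0("Empty joint-exposure cell(s): ",
                 paste(names(counts)[counts == 0], collapse = ", ")))
  }
  form <- as.formula(paste("copd ~", rhs_of("joint", covariates)))
  fit <- glm(form, data = d, family = binomial(),
             control = list(epsilon = 1e-12, maxit = 100))
  cn <- paste0("joint", c("FH1_PRS0", "FH0_PRS1", "FH1_PRS1"))
  co <- coef(fit)[cn]
  se <- sqrt(diag(vcov(fit))[cn])
  tid <- tibble(
    cell = c("FH0_PRS0", "FH1_PRS0", "FH0_PRS1", "FH1_PRS1"),
    n = as.numeric(counts),
    estimate = c(0, unname(co)), std.error = c(NA, unname(se)),
    odds.ratio = c(1, exp(unname(co))),
    or.conf.low = c(NA, exp(unname(co - 1.96 * se))),
    or.conf.high = c(NA, exp(unname(co + 1.96 * se))),
    p.value = c(NA, 2 * pnorm(-abs(unname(co / se))))
  )
  structure(list(tidy = tid, fit = fit, coef_names = cn,
                 parameterization = "joint"),
            class = "fhprs_joint")
}

#' @export
print.fhprs_joint <- function(x, ...) {
  cat("<fhprs_joint> joint effects of family history x top-tertile PRS\n")
  print(x$tidy)
  invisible(x)
}

#' @method tidy fhprs_joint
#' @export
tidy.fhprs_joint <- function(x, ...) x$tidy

#' Multiplicative interaction between family history and the PRS
#'
#' Fits `COPD ~ family_history * PRS + covariates` (continuous PRS by
#' default) and tests the product term by Wald and likelihood-ratio tests.
#'
#' @param data Derived cohort tibble.
#' @param covariates Adjustment set.
#' @param prs_form `"continuous_z"` or `"top_tertile"`.
#' @return One-row tibble: `gamma` (product-term log-OR), `std.error`,
#'   `p.wald`, `p.lrt`, `n`.
#' @export
multiplicative_interaction_test <- function(data,
                                            covariates = c("age", "sex",
                                                           "pack_years"),
                                            prs_form = c("continuous_z",
                                                         "top_tertile")) {
  prs_form <- match.arg(prs_form)
  prs_col <- if (prs_form == "continuous_z") "prs_z" else "prs_top_tertile"
  d <- prepare_interaction_frame(data, covariates, prs_col)
  base <- paste("copd ~", rhs_of("family_history", prs_col, covariates))
  full <- paste0(base, " + family_history:", prs_col)
  fit0 <- glm(as.formula(base), data = d, family = binomial(),
              control = list(epsilon = 1e-12, maxit = 100))
  fit1 <- glm(as.formula(full), data = d, family = binomial(),
              control = list(epsilon = 1e-12, maxit = 100))
  term <- grep(":", names(coef(fit1)), value = TRUE)
  g <- coef(fit1)[term]
  se <- sqrt(vcov(fit1)[term, term])
  lrt <- as.numeric(2 * (logLik(fit1) - logLik(fit0)))
  tibble(
    term = term, gamma = unname(g), std.error = unname(se),
    p.wald = unname(2 * pnorm(-abs(g / se))),
    p.lrt = pchisq(lrt, df = 1, lower.tail = FALSE),
    n = nrow(d)
  )
}

#' Relative excess risk due to interaction (RERI)
#'
#' Additive-scale interaction between family history and the PRS:
#' `RERI = OR11 - OR10 - OR01 + 1`, computed from a fitted joint-effects
#' model ([joint_effects()]) or from a product-term logistic model fitted
#' here when a cohort table is supplied. The confidence interval and p-value
#' use the multivariate delta method on the coefficient covariance
#' (Hosmer-Lemeshow); sidedness of the p-value is configurable because a
#' directional (one-sided) test of RERI > 0 is sometimes reported alongside a
#' two-sided interval.
#'
#' @param x An `fhprs_joint` object, or a derived cohort tibble (in which
#'   case a product-term model with the dichotomised PRS is fitted).
#' @param covariates Adjustment set used when `x` is a data frame.
#' @param prs_form PRS coding when `x` is a data frame; with
#'   `"continuous_z"` the RERI contrasts PRS at +1 SD vs the mean.
#' @param sided 2 (default) or 1.
#' @param conf.level Interval coverage.
#' @return One-row tibble: `reri`, `std.error`, `conf.low`, `conf.high`,
#'   `p.value`, `or11`, `or10`, `or01`, `parameterization`.
#' @export
reri <- function(x, covariates = c("age", "sex", "pack_years"),
                 prs_form = c("top_tertile", "continuous_z"),
                 sided = 2, conf.level = 0.95) {
  prs_form <- match.arg(prs_form)
  if (inherits(x, "fhprs_joint")) {
    cn <- x$coef_names
    b <- coef(x$fit)[cn]
    V <- vcov(x$fit)[cn, cn]
    or10 <- exp(b[[1]]); or01 <- exp(b[[2]]); or11 <- exp(b[[3]])
    grad <- c(-or10, -or01, or11)
    param <- "joint"
  } else {
    prs_col <- if (prs_form == "continuous_z") "prs_z" else "prs_top_tertile"
    d <- prepare_interaction_frame(x, covariates, prs_col)
    form <- as.formula(paste("copd ~", rhs_of(
      paste("family_history *", prs_col), covariates)))
    fit <- glm(form, data = d, family = binomial(),
               control = list(epsilon = 1e-12, maxit = 100))
    all_cn <- names(coef(fit))
    fh_cn <- grep("^family_history", all_cn[!grepl(":", all_cn)], value = TRUE)
    prs_cn <- grep(paste0("^", prs_col), all_cn[!grepl(":", all_cn)],
                   value = TRUE)
    int_cn <- grep(":", all_cn, value = TRUE)
    cn <- c(fh_cn, prs_cn, int_cn)
    b <- coef(fit)[cn]
    V <- vcov(fit)[cn, cn]
    or10 <- exp(b[[1]]); or01 <- exp(b[[2]]); or11 <- exp(sum(b))
    # d RERI / d(b1, b2, b3)
    grad <- c(or11 - or10, or11 - or01, or11)
    param <- "product_term"
  }
  est <- or11 - or10 - or01 + 1
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  zq <- qnorm(1 - (1 - conf.level) / 2)
  z <- est / se
  p <- if (sided == 2) 2 * pnorm(-abs(z)) else pnorm(-z)
  tibble(
    reri = est, std.error = se,
    conf.low = est - zq * se, conf.high = est + zq * se,
    p.value = p, or11 = or11, or10 = or10, or01 = or01,
    parameterization = param
  )
}

#' PRS effect within family-history strata
#'
#' Model-2-style logistic fits of COPD on the PRS, run separately in the
#' family-history-positive and -negative strata.
#'
#' @param data Derived cohort tibble.
#' @param covariates Adjustment set.
#' @param prs_form PRS coding.
#' @return Tibble with one row per stratum: PRS log-OR, SE, OR with CI, n.
#' @export
stratified_estimates <- function(data,
                                 covariates = c("age", "sex", "pack_years"),
                                 prs_form = c("continuous_z", "top_tertile")) {
  prs_form <- match.arg(prs_form)
  prs_col <- if (prs_form == "continuous_z") "prs_z" else "prs_top_tertile"
  d <- prepare_interaction_frame(data, covariates, prs_col)
  purrr::map_dfr(c(FALSE, TRUE), function(stratum) {
    ds <- d[d$family_history == stratum, , drop = FALSE]
    if (nrow(ds) == 0 || length(unique(ds$copd)) < 2) {
      abort(paste0("Stratum family_history=", stratum,
                   " is empty or single-class"))
    }
    form <- as.formula(paste("copd ~", rhs_of(prs_col, covariates)))
    fit <- glm(form, data = ds, family = binomial(),
               control = list(epsilon = 1e-12, maxit = 100))
    cn <- grep(paste0("^", prs_col), names(coef(fit)), value = TRUE)[1]
    b <- coef(fit)[cn]
    se <- sqrt(vcov(fit)[cn, cn])
    tibble(
      stratum = paste0("family_history=", stratum),
      term = cn, estimate = unname(b), std.error = unname(se),
      odds.ratio = exp(unname(b)),
      or.conf.low = exp(unname(b - 1.96 * se)),
      or.conf.high = exp(unname(b + 1.96 * se)),
      p.value = 2 * pnorm(-abs(unname(b / se))), n = nrow(ds)
    )
  })
}
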