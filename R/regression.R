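# Outcome-specific extra covariates: exacerbation outcomes add baseline lung
# function and current smoking; walk distance adds height/weight; death adds
# BODE; CT traits add the scanner.
.extra_covariates <- function(outcome) {
  switch(outcome,
    frequent_exacerbations = ,
    severe_exacerbation = c("fev1_pp", "current_smoker"),
    sixmwd = c("height", "weight"),
    dead = "bode",
    pct_laa950 = , perc15 = , pi10 = , wa_pct = "ct_scanner",
    character(0)
  )
}

.binary_outcomes <- c("copd_status", "frequent_exacerbations",
                      "severe_exacerbation", "dead")

#' Declare one of the three nested model specifications
#'
#' The three predictor sets are: model 1 — family history only; model 2 — PRS
#' only; model 3 — family history and PRS together. All models adjust for age,
#' sex (female reference) and pack-years; outcomes carry their own extra
#' covariates (exacerbations: baseline FEV1 % predicted and current smoking;
#' six-minute walk distance: height and weight; death: BODE; CT traits:
#' scanner). Genetic-ancestry principal components enter only the models that
#' contain the PRS.
#'
#' @param outcome Outcome column. `"copd_status"` is modelled as
#'   case (1) vs control (0) with excluded subjects dropped.
#' @param predictors `"fh_only"`, `"prs_only"` or `"fh_plus_prs"` (models 1-3).
#' @param family `"auto"` (binary for known binary outcomes, else gaussian),
#'   `"binomial"` or `"gaussian"`.
#' @param prs_form PRS coding: `"continuous_z"` (per SD) or `"top_tertile"`.
#' @param estimator `"mle"` (IRLS logistic), `"firth"` (Jeffreys-penalised
#'   logistic for sparse or imbalanced data) or `"ols"`; `"auto"` picks mle or
#'   ols from the family.
#' @param n_pcs Number of principal components (`pc1..pcK`) for models 2-3.
#' @param covariates Override the adjustment set (base + extra) entirely.
#' @param constrain_zero Terms to drop from the design (used for nested-model
#'   checks).
#' @return A list of class `fhprs_model_spec`.
#' @export
#' @examples
#' model_spec("copd_status", "fh_plus_prs")
model_spec <- function(outcome,
                       predictors = c("fh_plus_prs", "fh_only", "prs_only"),
                       family = c("auto", "binomial", "gaussian"),
                       prs_form = c("continuous_z", "top_tertile"),
                       estimator = c("auto", "mle", "firth", "ols"),
                       n_pcs = 5, covariates = NULL,
                       constrain_zero = character(0)) {
  predictors <- match.arg(predictors)
  family <- match.arg(family)
  prs_form <- match.arg(prs_form)
  estimator <- match.arg(estimator)
  if (family == "auto") {
    family <- if (outcome %in% .binary_outcomes) "binomial" else "gaussian"
  }
  if (estimator == "auto") estimator <- if (family == "binomial") "mle" else "ols"
  if (estimator == "ols" && family == "binomial") {
    abort("ols estimator requires a gaussian family")
  }
  if (estimator %in% c("mle", "firth") && family != "binomial") {
    abort("logistic estimators require a binary outcome")
  }
  if (is.null(covariates)) {
    covariates <- c("age", "sex", "pack_years", .extra_covariates(outcome))
  }
  structure(
    list(outcome = outcome, predictors = predictors, family = family,
         prs_form = prs_form, estimator = estimator, n_pcs = n_pcs,
         covariates = covariates, constrain_zero = constrain_zero),
    class = "fhprs_model_spec"
  )
}

# Right-hand-side terms implied by a spec.
spec_terms <- function(spec) {
  prs_term <- if (spec$prs_form == "continuous_z") "prs_z" else "prs_top_tertile"
  preds <- switch(spec$predictors,
    fh_only = "family_history",
    prs_only = prs_term,
    fh_plus_prs = c("family_history", prs_term)
  )
  pcs <- if (spec$predictors != "fh_only" && spec$n_pcs > 0) {
    paste0("pc", seq_len(spec$n_pcs))
  } else character(0)
  setdiff(c(preds, spec$covariates, pcs), spec$constrain_zero)
}

# Assemble response + design for a spec: complete cases, sex releveled to
# female reference, copd_status mapped to 0/1 with excluded dropped.
build_design <- function(data, spec) {
  terms <- spec_terms(spec)
  missing_cols <- setdiff(c(spec$outcome, terms), names(data))
  if (length(missing_cols)) {
    abort(paste0("Model needs column(s) absent from the data: ",
                 paste(missing_cols, collapse = ", ")))
  }
  d <- data[, c(spec$outcome, terms)]
  if (spec$outcome == "copd_status") {
    d <- d[!is.na(d$copd_status) & d$copd_status != "excluded", , drop = FALSE]
    d$copd_status <- as.numeric(d$copd_status == "case")
  }
  if ("sex" %in% names(d)) {
    d$sex <- factor(d$sex, levels = c("female", "male"))
  }
  d <- d[complete.cases(d), , drop = FALSE]
  y <- d[[spec$outcome]]
  if (is.logical(y)) y <- as.numeric(y)
  if (spec$family == "binomial") {
    if (length(unique(y)) < 2) {
      abort(paste0("Outcome '", spec$outcome,
                   "' has a single class after complete-case filtering"))
    }
    if (!all(y %in% c(0, 1))) abort("Binary outcome must be 0/1")
  }
  form <- as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- model.matrix(form, data = d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("Rank-deficient design; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  list(X = X, y = y, data = d, formula = form)
}

# Firth-penalised logistic regression: maximises the Jeffreys-prior penalised
# log-likelihood l(beta) + 0.5*log det I(beta) by modified IRLS with
# hat-value-adjusted scores and step-halving.
fit_firth_engine <- function(X, y, maxit = 50, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  pen_loglik <- function(beta) {
    eta <- drop(X %*% beta)
    p <- expit(eta)
    w <- pmax(p * (1 - p), 1e-12)
    I <- crossprod(X * sqrt(w))
    sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(I)$modulus
  }
  ll <- pen_loglik(beta)
  converged <- FALSE
  grad_norm <- Inf
  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- expit(eta)
    w <- pmax(p * (1 - p), 1e-12)
    XW <- X * sqrt(w)
    I <- crossprod(XW)
    Iinv <- chol2inv(chol(I))
    h <- rowSums((XW %*% Iinv) * XW)
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    grad_norm <- max(abs(U))
    if (grad_norm < tol) { converged <- TRUE; break }
    delta <- drop(Iinv %*% U)
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- pen_loglik(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-10) break
    }
    beta <- beta + step * delta
    ll <- pen_loglik(beta)
  }
  if (!converged && grad_norm >= sqrt(tol)) {
    abort(paste0("Firth fit did not converge after ", maxit,
                 " iterations (score norm ", signif(grad_norm, 3), ")"))
  }
  eta <- drop(X %*% beta)
  p <- expit(eta)
  w <- pmax(p * (1 - p), 1e-12)
  I <- crossprod(X * sqrt(w))
  list(coefficients = setNames(beta, colnames(X)),
       vcov = chol2inv(chol(I)),
       fitted = p, penalized_loglik = as.numeric(ll),
       loglik = sum(y * eta - log1p(exp(eta))),
       iter = iter, converged = TRUE)
}

#' Fit a nested risk model on a cohort table
#'
#' Fits the model described by a [model_spec()] on complete cases: logistic
#' regression by IRLS maximum likelihood, Firth-penalised logistic regression
#' (finite estimates under separation or severe case:control imbalance), or
#' ordinary least squares for continuous outcomes. Wald 95% intervals
#' throughout; odds ratios are `exp(beta)` for binary outcomes.
#'
#' @param data A derived cohort tibble (see [derive_cohort()]).
#' @param spec A [model_spec()].
#' @return An object of class `fhprs_fit`; see [tidy.fhprs_fit()] and
#'   [glance.fhprs_fit()].
#' @export
#' @examples
#' cohort <- derive_cohort(generate_synthetic_cohort(sim_config(n = 2000)))
#' fit <- fit_model(cohort, model_spec("copd_status", "fh_plus_prs"))
#' tidy(fit)
fit_model <- function(data, spec) {
  stopifnot(inherits(spec, "fhprs_model_spec"))
  des <- build_design(data, spec)
  X <- des$X
  y <- des$y

  if (spec$estimator == "ols") {
    df <- des$data
    fit <- lm(as.formula(paste(spec$outcome, "~",
                               paste(spec_terms(spec), collapse = " + "))),
              data = df)
    co <- summary(fit)$coefficients
    rss <- sum(fit$residuals^2)
    res <- list(
      coefficients = coef(fit), vcov = vcov(fit),
      se = co[, 2], fitted = fit$fitted.values,
      loglik = as.numeric(logLik(fit)),
      r_squared = summary(fit)$r.squared,
      adj_r_squared = summary(fit)$adj.r.squared,
      mse = rss / nrow(df), converged = TRUE, lm_fit = fit
    )
  } else if (spec$estimator == "mle") {
    fit <- glm.fit(X, y, family = binomial(),
                   control = list(epsilon = 1e-10, maxit = 100))
    beta <- fit$coefficients
    if (any(abs(beta) > 15)) {
      abort(paste0(
        "Apparent separation (|beta| > 15 for ",
        paste(names(beta)[abs(beta) > 15], collapse = ", "),
        "); refit with estimator = 'firth'"
      ))
    }
    p <- fit$fitted.values
    w <- p * (1 - p)
    V <- chol2inv(chol(crossprod(X * sqrt(w))))
    dimnames(V) <- list(colnames(X), colnames(X))
    res <- list(
      coefficients = beta, vcov = V, se = sqrt(diag(V)), fitted = p,
      loglik = sum(y * log(p) + (1 - y) * log(1 - p)),
      converged = fit$converged, glm_fit = fit
    )
  } else {
    res <- fit_firth_engine(X, y)
    res$se <- sqrt(diag(res$vcov))
  }

  est <- res$coefficients
  se <- if (!is.null(res$se)) res$se else sqrt(diag(res$vcov))
  z <- est / se
  tid <- tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(z),
    p.value = if (spec$estimator == "ols") {
      unname(2 * stats::pt(-abs(z), df = length(y) - length(est)))
    } else unname(2 * pnorm(-abs(z))),
    conf.low = unname(est - 1.96 * se),
    conf.high = unname(est + 1.96 * se)
  )
  if (spec$family == "binomial") {
    tid <- mutate(tid, odds.ratio = exp(.data$estimate),
                  or.conf.low = exp(.data$conf.low),
                  or.conf.high = exp(.data$conf.high))
  }
  structure(
    list(spec = spec, engine = res, tidy = tid, n_used = length(y),
         n_events = if (spec$family == "binomial") sum(y) else NA_real_,
         fitted = res$fitted, response = y, design = X,
         model_frame = des$data),
    class = "fhprs_fit"
  )
}

#' Fit all three nested models for one outcome
#'
#' @param data Derived cohort tibble.
#' @param outcome Outcome column name.
#' @param ... Passed to [model_spec()].
#' @return Named list of `fhprs_fit` objects (`model1`, `model2`, `model3`).
#' @export
fit_models_123 <- function(data, outcome = "copd_status", ...) {
  list(
    model1 = fit_model(data, model_spec(outcome, "fh_only", ...)),
    model2 = fit_model(data, model_spec(outcome, "prs_only", ...)),
    model3 = fit_model(data, model_spec(outcome, "fh_plus_prs", ...))
  )
}

#' @export
print.fhprs_fit <- function(x, ...) {
  cat("<fhprs_fit> outcome:", x$spec$outcome,
      "| predictors:", x$spec$predictors,
      "| estimator:", x$spec$estimator,
      "| n =", x$n_used, "\n")
  print(x$tidy, n = Inf)
  invisible(x)
}

#' Tidy a fitted risk model
#'
#' @param x An `fhprs_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`, Wald `conf.low`/`conf.high`, and for
#'   binary outcomes `odds.ratio` with its interval.
#' @method tidy fhprs_fit
#' @export
tidy.fhprs_fit <- function(x, ...) x$tidy

#' One-row model summary
#'
#' @param x An `fhprs_fit`.
#' @param ... Unused.
#' @return A tibble with `outcome`, `predictors`, `estimator`, `n_used`,
#'   `n_events`, `logLik`, and for linear fits `adj.r.squared` and `mse`.
#' @method glance fhprs_fit
#' @export
glance.fhprs_fit <- function(x, ...) {
  tibble(
    outcome = x$spec$outcome, predictors = x$spec$predictors,
    estimator = x$spec$estimator, n_used = x$n_used,
    n_events = x$n_events,
    logLik = x$engine$loglik,
    adj.r.squared = if (!is.null(x$engine$adj_r_squared))
      x$engine$adj_r_squared else NA_real_,
    mse = if (!is.null(x$engine$mse)) x$engine$mse else NA_real_,
    converged = isTRUE(x$engine$converged)
  )
}
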