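#' Biserial correlation between a binary exposure and a continuous mediator
#'
#' Estimates the correlation between the continuous variable and the latent
#' normal trait assumed to underlie the binary variable. Two estimators:
#'
#' * `"closed_form"`: converts the Pearson point-biserial correlation,
#'   `r_b = r_pb * sqrt(p(1-p)) / phi(qnorm(p))` with `p` the positive-class
#'   fraction.
#' * `"binned_ml"`: cuts the continuous variable into `bins` equal-count bins
#'   and maximises the bivariate-normal (polychoric-style) likelihood of the
#'   resulting 2 x bins table over the latent correlation, with thresholds
#'   fixed at the marginal quantiles (two-step estimator).
#'
#' The p-value in both cases is the point-biserial t-test on `n - 2` degrees
#' of freedom.
#'
#' @param fh Binary vector (logical or 0/1); both classes must be present.
#' @param prs Continuous vector, same length, at least 3 distinct values.
#' @param method Estimator, see above.
#' @param bins Number of bins for `"binned_ml"`.
#' @return One-row tibble: `method`, `r_biserial`, `r_point_biserial`,
#'   `p_positive`, `statistic`, `p.value`, `n`.
#' @export
#' @examples
#' set.seed(1)
#' fh <- rbinom(500, 1, 0.3)
#' prs <- rnorm(500, 0.3 * fh)
#' biserial_correlation(fh, prs)
biserial_correlation <- function(fh, prs,
                                 method = c("closed_form", "binned_ml"),
                                 bins = 10) {
  method <- match.arg(method)
  ok <- !is.na(fh) & !is.na(prs)
  fh <- as.numeric(fh[ok])
  prs <- prs[ok]
  if (length(unique(fh)) < 2) abort("fh must contain both classes")
  if (length(unique(prs)) < 3) abort("prs needs at least 3 distinct values")
  n <- length(fh)
  p <- mean(fh)
  r_pb <- stats::cor(fh, prs)
  tstat <- r_pb * sqrt((n - 2) / (1 - r_pb^2))
  pval <- 2 * stats::pt(-abs(tstat), df = n - 2)

  if (method == "closed_form") {
    rb <- r_pb * sqrt(p * (1 - p)) / dnorm(qnorm(p))
  } else {
    cuts <- quantile(prs, probs = seq_len(bins - 1) / bins,
                     type = 7, names = FALSE)
    bin <- findInterval(prs, vec = cuts, left.open = TRUE) + 1
    counts <- table(factor(fh, levels = 0:1), factor(bin, levels = seq_len(bins)))
    tau <- qnorm(1 - p)                       # latent threshold for fh = 1
    colp <- cumsum(colSums(counts)) / n
    ccut <- qnorm(colp[-bins])                # latent bin boundaries
    negll <- function(rho) {
      sig <- matrix(c(1, rho, rho, 1), 2)
      cdf <- vapply(ccut, function(cc) {
        mvtnorm::pmvnorm(upper = c(tau, cc), sigma = sig)[1]
      }, 0)
      low <- c(0, cdf)                        # Phi2(tau, c_k) running values
      high <- c(cdf, pnorm(tau))
      p0 <- pmax(high - low, 1e-12)           # fh=0 cells
      margin <- diff(c(0, colp))
      p1 <- pmax(margin - p0, 1e-12)          # fh=1 cells
      -sum(counts[1, ] * log(p0) + counts[2, ] * log(p1))
    }
    rb <- optimize(negll, interval = c(-0.995, 0.995))$minimum
  }
  rb <- max(min(rb, 1), -1)
  tibble(method = method, r_biserial = rb, r_point_biserial = r_pb,
         p_positive = p, statistic = tstat, p.value = pval, n = n)
}

# Point estimator for the imputation-based natural-effects decomposition.
# Returns c(nde, nie) on the log-odds scale.
ne_point_estimate <- function(d, covariates, interaction) {
  rhs <- paste(c("x", "m", if (interaction) "x:m", covariates),
               collapse = " + ")
  fit1 <- glm(as.formula(paste("y ~", rhs)), data = d, family = binomial(),
              control = list(epsilon = 1e-10, maxit = 100))
  expand <- bind_rows(mutate(d, x1 = 0), mutate(d, x1 = 1))
  expand$x0 <- expand$x
  newd <- expand
  newd$x <- newd$x1                         # hypothetical direct exposure
  expand$yhat <- predict(fit1, newdata = newd, type = "response")
  form2 <- as.formula(paste("yhat ~",
                            paste(c("x1", "x0", covariates),
                                  collapse = " + ")))
  fit2 <- glm(form2, data = expand, family = quasibinomial(),
              control = list(epsilon = 1e-10, maxit = 100))
  c(nde = unname(coef(fit2)["x1"]), nie = unname(coef(fit2)["x0"]))
}

#' Natural direct and indirect effects of family history through the PRS
#'
#' Imputation-based natural-effects decomposition of the exposure's effect on
#' a binary outcome into the pathway through the mediator (natural indirect
#' effect, NIE) and all other pathways (natural direct effect, NDE), on the
#' log-odds scale:
#'
#' 1. fit the outcome model `logit P(Y=1) ~ exposure + mediator + covariates`
#'    (an exposure-mediator product term is optional and off by default);
#' 2. duplicate each record with a hypothetical exposure level `x1` in
#'    \{0, 1\} while keeping the observed mediator (which encodes the
#'    mediator's response to the observed exposure `x0`), imputing the
#'    counterfactual outcome expectation from step 1;
#' 3. fit the natural-effects model
#'    `logit E(Y(x1, M(x0))) ~ x1 + x0 + covariates` on the expanded data.
#'
#' The `x1` coefficient is the NDE, the `x0` coefficient the NIE; the total
#' effect is their sum and the proportion mediated `NIE / (NDE + NIE)`.
#' Inference is by nonparametric bootstrap over subjects (percentile
#' intervals; p-values from the normal approximation with the bootstrap SE).
#' The proportion-mediated interval is flagged unstable unless the total
#' effect's bootstrap distribution keeps one sign in at least 97.5% of
#' replicates. Identification assumes no unmeasured exposure-outcome,
#' mediator-outcome or exposure-mediator confounding beyond the covariates.
#'
#' @param data Derived cohort tibble.
#' @param exposure Binary exposure column (default `family_history`).
#' @param mediator Continuous mediator column (default `prs_z`).
#' @param outcome Binary outcome column (default `copd_status`,
#'   case vs control).
#' @param covariates Confounder adjustment set.
#' @param interaction Include an exposure-mediator product term in the
#'   outcome model.
#' @param B Bootstrap replicates (0 skips interval estimation).
#' @param seed Seed for the bootstrap resampling.
#' @param conf.level Interval coverage.
#' @return An object of class `fhprs_mediation`; `tidy()` returns rows
#'   `nde`, `nie`, `total`, `proportion_mediated` with estimates, percentile
#'   CIs and p-values.
#' @export
natural_effects_mediation <- function(data, exposure = "family_history",
                                      mediator = "prs_z",
                                      outcome = "copd_status",
                                      covariates = c("age", "sex",
                                                     "pack_years"),
                                      interaction = FALSE,
                                      B = 1000, seed = 1,
                                      conf.level = 0.95) {
  need <- c(exposure, mediator, outcome, covariates)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("Mediation analysis needs column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  d <- data[, need]
  if (outcome == "copd_status") {
    d <- d[!is.na(d$copd_status) & d$copd_status != "excluded", , drop = FALSE]
    d$y <- as.numeric(d$copd_status == "case")
  } else {
    d$y <- as.numeric(d[[outcome]])
  }
  d$x <- as.numeric(d[[exposure]])
  d$m <- d[[mediator]]
  if ("sex" %in% names(d)) d$sex <- factor(d$sex, levels = c("female", "male"))
  d <- d[, c("y", "x", "m", covariates)]
  d <- d[complete.cases(d), , drop = FALSE]
  if (!all(d$x %in% c(0, 1))) abort("exposure must be binary")
  if (min(table(d$x)) < 10) {
    abort("Non-overlap: an exposure level has fewer than 10 subjects")
  }

  est <- ne_point_estimate(d, covariates, interaction)
  nde <- est[["nde"]]; nie <- est[["nie"]]
  total <- nde + nie
  pm <- if (abs(total) > 0) nie / total else NA_real_

  boot <- NULL
  if (B > 0) {
    set.seed(seed)
    boot <- t(vapply(seq_len(B), function(b) {
      idx <- sample.int(nrow(d), replace = TRUE)
      ne_point_estimate(d[idx, , drop = FALSE], covariates, interaction)
    }, c(nde = 0, nie = 0)))
    boot <- cbind(boot, total = boot[, 1] + boot[, 2],
                  pm = (boot[, 1] + boot[, 2] != 0) *
                    boot[, 2] / (boot[, 1] + boot[, 2]))
  }
  alpha <- 1 - conf.level
  ci <- function(col) {
    if (is.null(boot)) return(c(NA_real_, NA_real_))
    quantile(boot[, col], c(alpha / 2, 1 - alpha / 2), names = FALSE)
  }
  pv <- function(est, col) {
    if (is.null(boot)) return(NA_real_)
    2 * pnorm(-abs(est / sd(boot[, col])))
  }
  pm_stable <- if (is.null(boot)) NA else {
    mean(sign(boot[, "total"]) == sign(total)) >= 0.975
  }
  tid <- tibble(
    effect = c("nde", "nie", "total", "proportion_mediated"),
    estimate = c(nde, nie, total, pm),
    conf.low = c(ci("nde")[1], ci("nie")[1], ci("total")[1],
                 if (isTRUE(pm_stable)) ci("pm")[1] else NA_real_),
    conf.high = c(ci("nde")[2], ci("nie")[2], ci("total")[2],
                  if (isTRUE(pm_stable)) ci("pm")[2] else NA_real_),
    p.value = c(pv(nde, "nde"), pv(nie, "nie"), pv(total, "total"), NA_real_)
  )
  structure(
    list(tidy = tid, nde = nde, nie = nie, total = total,
         proportion_mediated = pm, pm_stable = pm_stable,
         B = B, seed = seed, n_used = nrow(d), boot = boot,
         interaction = interaction),
    class = "fhprs_mediation"
  )
}

#' @export
print.fhprs_mediation <- function(x, ...) {
  cat("<fhprs_mediation> natural-effects decomposition (log-odds scale), n =",
      x$n_used, ", B =", x$B, "\n")
  print(x$tidy)
  if (isFALSE(x$pm_stable)) {
    cat("note: total effect not bounded away from 0 in >=97.5% of bootstrap",
        "replicates; proportion-mediated interval suppressed\n")
  }
  invisible(x)
}

#' @method tidy fhprs_mediation
#' @export
tidy.fhprs_mediation <- function(x, ...) x$tidy

#' @method glance fhprs_mediation
#' @export
glance.fhprs_mediation <- function(x, ...) {
  tibble(nde = x$nde, nie = x$nie, total = x$total,
         proportion_mediated = x$proportion_mediated,
         pm_stable = isTRUE(x$pm_stable), B = x$B, n_used = x$n_used)
}
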