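test_that("saturated 2x2 logistic reproduces the cross-product odds ratio", {
  cohort <- twobytwo_cohort(30, 70, 10, 90)
  fit <- fit_model(cohort, model_spec("copd_status", "fh_only",
                                      covariates = character(0)))
  or_oracle <- (30 * 90) / (70 * 10)
  expect_equal(exp(tidy(fit)$estimate[2]), or_oracle, tolerance = 1e-6)
  expect_equal(fit$n_used, 200)
  # CI of OR is exp of CI of beta
  td <- tidy(fit)
  expect_equal(td$or.conf.low, exp(td$conf.low))
  expect_true(all(td$conf.low < td$conf.high))
})

test_that("Firth on a zero-cell 2x2 equals the Haldane half-cell correction", {
  cohort <- twobytwo_cohort(10, 0, 5, 5)
  fit <- fit_model(cohort, model_spec("copd_status", "fh_only",
                                      covariates = character(0),
                                      estimator = "firth"))
  or_haldane <- (10.5 * 5.5) / (0.5 * 5.5)
  beta_hat <- tidy(fit)$estimate[2]
  expect_equal(exp(beta_hat), or_haldane, tolerance = 1e-4)

  # brute-force maximisation of the penalised likelihood as oracle
  y <- as.numeric(cohort$copd_status == "case")
  X <- cbind(1, as.numeric(cohort$family_history))
  pen <- function(b) {
    eta <- drop(X %*% b)
    p <- plogis(eta)
    I <- crossprod(X * sqrt(p * (1 - p)))
    sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(I)$modulus
  }
  opt <- optim(c(0, 0), function(b) -pen(b), method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(beta_hat, opt$par[2], tolerance = 1e-4)
})

test_that("Firth returns finite estimates under complete separation; MLE refuses", {
  set.seed(4)
  n <- 60
  x <- sort(rnorm(n))
  cohort <- tibble::tibble(
    copd_status = factor(rep(c("control", "case"), each = n / 2),
                         levels = c("control", "case"))[rank(x)],
    prs_z = x
  )
  spec_mle <- model_spec("copd_status", "prs_only",
                         covariates = character(0), n_pcs = 0)
  expect_error(suppressWarnings(fit_model(cohort, spec_mle)), "firth")
  spec_f <- model_spec("copd_status", "prs_only",
                       covariates = character(0), n_pcs = 0,
                       estimator = "firth")
  fit <- fit_model(cohort, spec_f)
  expect_true(all(is.finite(tidy(fit)$estimate)))
  expect_true(all(is.finite(tidy(fit)$std.error)))
})

test_that("Firth and MLE agree on balanced large samples", {
  cohort <- sim_derived(n = 10000, seed = 6)
  spec <- function(est) model_spec("copd_status", "fh_plus_prs",
                                   estimator = est, n_pcs = 0)
  b_mle <- tidy(fit_model(cohort, spec("mle")))$estimate
  b_fir <- tidy(fit_model(cohort, spec("firth")))$estimate
  expect_equal(b_fir, b_mle, tolerance = 0.01)
})

test_that("the MLE matches a derivative-free optimiser on small instances", {
  set.seed(12)
  n <- 150
  cohort <- tibble::tibble(
    copd_status = factor(sample(c("case", "control"), n, replace = TRUE),
                         levels = c("control", "case")),
    family_history = runif(n) < 0.3,
    prs_z = rnorm(n),
    age = rnorm(n, 60, 8)
  )
  fit <- fit_model(cohort, model_spec("copd_status", "fh_plus_prs",
                                      covariates = "age", n_pcs = 0))
  y <- as.numeric(cohort$copd_status == "case")
  X <- cbind(1, as.numeric(cohort$family_history), cohort$prs_z, cohort$age)
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta)))
  }
  opt <- optim(rep(0, 4), nll, method = "Nelder-Mead",
               control = list(reltol = 1e-15, maxit = 20000))
  expect_equal(unname(tidy(fit)$estimate), opt$par, tolerance = 1e-4)
})

test_that("estimates are invariant to row permutation and affinely equivariant", {
  cohort <- sim_derived(n = 3000, seed = 9)
  spec <- model_spec("copd_status", "fh_plus_prs", n_pcs = 2)
  base <- tidy(fit_model(cohort, spec))
  perm <- tidy(fit_model(cohort[sample(nrow(cohort)), ], spec))
  expect_equal(base$estimate, perm$estimate, tolerance = 1e-9)

  scaled <- dplyr::mutate(cohort, prs_z = 2 * prs_z)
  sc <- fit_model(scaled, spec)
  expect_equal(tidy(sc)$estimate[tidy(sc)$term == "prs_z"],
               base$estimate[base$term == "prs_z"] / 2, tolerance = 1e-8)
  expect_equal(glance(sc)$logLik,
               glance(fit_model(cohort, spec))$logLik, tolerance = 1e-8)
})

test_that("model 3 with PRS terms constrained to zero reproduces model 1", {
  cohort <- sim_derived(n = 3000, seed = 10)
  m1 <- tidy(fit_model(cohort, model_spec("copd_status", "fh_only")))
  m3c <- tidy(fit_model(cohort, model_spec(
    "copd_status", "fh_plus_prs",
    constrain_zero = c("prs_z", paste0("pc", 1:5))
  )))
  expect_equal(m3c$term, m1$term)
  expect_equal(m3c$estimate, m1$estimate, tolerance = 1e-10)
})

test_that("rank-deficient designs fail naming the collinear column", {
  cohort <- sim_derived(n = 500, seed = 2)
  cohort$pc1 <- cohort$prs_z  # exact collinearity
  expect_error(
    fit_model(cohort, model_spec("copd_status", "prs_only", n_pcs = 1)),
    "pc1"
  )
})

test_that("linear fits solve the normal equations and flag exact fits", {
  # noiseless line
  d <- tibble::tibble(sgrq_total = 2 * (1:20), prs_z = as.numeric(1:20))
  fit <- suppressWarnings(fit_model(d, model_spec(
    "sgrq_total", "prs_only", covariates = character(0), n_pcs = 0)))
  expect_equal(tidy(fit)$estimate[2], 2, tolerance = 1e-10)
  expect_equal(fit$engine$r_squared, 1, tolerance = 1e-10)

  # 4-point dataset vs hand-solved normal equations
  x <- c(0, 1, 2, 3); yv <- c(1, 3, 4, 8)
  d2 <- tibble::tibble(sgrq_total = yv, prs_z = x)
  fit2 <- fit_model(d2, model_spec("sgrq_total", "prs_only",
                                   covariates = character(0), n_pcs = 0))
  X <- cbind(1, x)
  beta_oracle <- unname(drop(solve(t(X) %*% X, t(X) %*% yv)))
  expect_equal(unname(tidy(fit2)$estimate), beta_oracle, tolerance = 1e-12)

  # pure noise: adjusted R^2 near zero
  set.seed(77)
  d3 <- tibble::tibble(sgrq_total = rnorm(10000), prs_z = rnorm(10000))
  fit3 <- fit_model(d3, model_spec("sgrq_total", "prs_only",
                                   covariates = character(0), n_pcs = 0))
  expect_lt(abs(fit3$engine$adj_r_squared), 0.01)
})

test_that("outcome-specific covariate sets follow the analysis plan", {
  expect_true(all(c("fev1_pp", "current_smoker") %in%
                    model_spec("frequent_exacerbations")$covariates))
  expect_true(all(c("height", "weight") %in% model_spec("sixmwd")$covariates))
  expect_true("bode" %in% model_spec("dead")$covariates)
  expect_true("ct_scanner" %in% model_spec("pi10")$covariates)
  # model 1 never contains PCs
  expect_false(any(grepl("^pc", spec_terms <- fhprs:::spec_terms(
    model_spec("copd_status", "fh_only")))))
})
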