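test_that("AUC equals pairwise concordance enumeration on toy sets", {
  # full separation
  expect_equal(auc_with_ci(c(0.9, 0.8, 0.7, 0.6, 0.4),
                           c(1, 1, 1, 0, 0))$auc, 1)
  # enumerate 4 case-control pairs: 3 concordant
  expect_equal(auc_with_ci(c(0.9, 0.4, 0.5, 0.3), c(1, 1, 0, 0))$auc, 3 / 4)
  # all tied scores
  expect_equal(auc_with_ci(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)

  # midrank implementation vs naive O(mn) enumeration with ties
  set.seed(3)
  for (i in 1:10) {
    s <- sample(seq(0, 1, by = 0.1), 40, replace = TRUE)
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    fast <- fhprs:::delong_components(s, y)
    slow <- pairwise_delong(s, y)
    expect_equal(fast$auc, slow$auc)
    expect_equal(fast$v10, unname(slow$v10))
    expect_equal(fast$v01, unname(slow$v01))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(8)
  s <- rnorm(200)
  y <- rbinom(200, 1, plogis(s))
  a0 <- auc_with_ci(s, y)
  for (f in list(function(x) exp(x), function(x) 3 * x - 7, plogis)) {
    expect_equal(auc_with_ci(f(s), y)$auc, a0$auc)
    expect_equal(auc_with_ci(f(s), y)$auc_var, a0$auc_var)
  }
})

test_that("AUC and DeLong CI match the reference ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  s <- rnorm(300)
  y <- rbinom(300, 1, plogis(1.2 * s))
  mine <- auc_with_ci(s, y)
  ref <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  ci <- pROC::ci.auc(ref, method = "delong")
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_equal(mine$auc_var, as.numeric(pROC::var(ref)), tolerance = 1e-10)

  s2 <- s + rnorm(300, sd = 0.8)
  cmp <- compare_auc_delong(s2, s, y)
  ref2 <- pROC::roc.test(
    pROC::roc(y, s2, quiet = TRUE, direction = "<"), ref,
    method = "delong", paired = TRUE
  )
  expect_equal(cmp$p.value, as.numeric(ref2$p.value), tolerance = 1e-10)
})

test_that("self-comparison is degenerate with zero variance", {
  set.seed(2)
  s <- rnorm(50)
  y <- rbinom(50, 1, 0.5)
  cmp <- compare_auc_delong(s, s, y)
  expect_equal(cmp$delta, 0)
  expect_equal(cmp$var_delta, 0)
  expect_true(cmp$degenerate)
  expect_true(is.na(cmp$p.value))
  expect_error(compare_auc_delong(s[-1], s, y), "length")
})

test_that("DeLong p agrees with a stratified-bootstrap oracle on a small set", {
  set.seed(14)
  n <- 20
  y <- rep(c(0, 1), each = n / 2)
  u <- rnorm(n)
  sa <- u + rnorm(n, sd = 0.7) + 0.8 * y
  sb <- u + rnorm(n, sd = 0.7) + 1.2 * y
  cmp <- compare_auc_delong(sa, sb, y)

  B <- 10000
  idx_case <- which(y == 1); idx_ctrl <- which(y == 0)
  deltas <- vapply(seq_len(B), function(b) {
    idx <- c(sample(idx_case, replace = TRUE), sample(idx_ctrl, replace = TRUE))
    da <- fhprs:::delong_components(sa[idx], y[idx])
    db <- fhprs:::delong_components(sb[idx], y[idx])
    db$auc - da$auc
  }, 0)
  p_boot <- 2 * pnorm(-abs(cmp$delta / sd(deltas)))
  expect_equal(cmp$p.value, p_boot, tolerance = 0.02)
})

test_that("an added informative predictor is detected with high power", {
  hits <- vapply(1:60, function(seed) {
    set.seed(seed)
    n <- 5000
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x1 + 0.5 * x2))
    cmp <- compare_auc_delong(x1, 0.8 * x1 + 0.5 * x2, y)
    cmp$delta > 0 && cmp$p.value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("the paired DeLong test holds its nominal size under the null", {
  rejections <- vapply(1:1000, function(seed) {
    set.seed(seed)
    n <- 150
    y <- rep(c(0, 1), length.out = n)
    u <- rnorm(n)
    sa <- u + rnorm(n)
    sb <- u + rnorm(n)
    compare_auc_delong(sa, sb, y)$p.value < 0.05
  }, TRUE)
  expect_lt(abs(mean(rejections) - 0.05), 0.02)
})

test_that("scaled Brier follows its definition and edge cases", {
  expect_equal(scaled_brier(c(0.8, 0.2, 0.6, 0.1), c(1, 0, 1, 0)),
               1 - 0.0625 / 0.25)
  y <- c(1, 0, 1, 1, 0)
  expect_equal(scaled_brier(y, y), 1)                 # perfect
  expect_equal(scaled_brier(rep(mean(y), 5), y), 0)   # prevalence reference
  expect_error(scaled_brier(c(0.5, 0.5), c(1, 1)), "class")
  expect_error(scaled_brier(c(1.2, 0.5), c(1, 0)), "0, 1")
})

test_that("continuous fit metrics match their closed forms", {
  d <- tibble::tibble(sgrq_total = 3 * (1:6), prs_z = as.numeric(1:6))
  fit <- suppressWarnings(fit_model(d, model_spec(
    "sgrq_total", "prs_only", covariates = character(0), n_pcs = 0)))
  m <- continuous_fit_metrics(fit)
  expect_equal(m$adj.r.squared, 1)
  expect_equal(m$mse, 0)

  # 5-point hand example
  x <- c(1, 2, 3, 4, 5); yv <- c(2, 2, 4, 5, 9)
  d2 <- tibble::tibble(sgrq_total = yv, prs_z = x)
  fit2 <- fit_model(d2, model_spec("sgrq_total", "prs_only",
                                   covariates = character(0), n_pcs = 0))
  lm_o <- lm(yv ~ x)
  rss <- sum(residuals(lm_o)^2)
  r2 <- 1 - rss / sum((yv - mean(yv))^2)
  m2 <- continuous_fit_metrics(fit2)
  expect_equal(m2$adj.r.squared, 1 - (1 - r2) * 4 / 3, tolerance = 1e-12)
  expect_equal(m2$mse, rss / 5, tolerance = 1e-12)
})

test_that("the three-model performance table orders discrimination sensibly", {
  cohort <- sim_derived(n = 6000, seed = 19)
  pt <- performance_table(cohort)
  perf <- pt$performance
  expect_equal(perf$model, c("model1", "model2", "model3"))
  # model 3 nests both: apparent AUC cannot be lower
  expect_gte(perf$auc[3] + 1e-12, perf$auc[1])
  expect_gte(perf$auc[3] + 1e-12, perf$auc[2])
  expect_true(all(perf$conf.low < perf$auc & perf$auc < perf$conf.high))
  expect_true(all(pt$comparisons$delta >= 0))
  expect_s3_class(autoplot(pt), "ggplot")
})
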