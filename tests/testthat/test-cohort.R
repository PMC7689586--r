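test_that("spirometry maps to a partition of case/control/excluded", {
  df <- tibble::tibble(
    fev1_pp = c(48.8, 94.9, 85, 70, 79.9, 80, NA),
    fev1_fvc = c(0.48, 0.77, 0.65, 0.75, 0.699, 0.7, 0.5)
  )
  st <- derive_copd_status(df)$copd_status
  expect_equal(as.character(st),
               c("case", "control", "excluded", "excluded", "case",
                 "control", NA))
  # partition: every complete record is in exactly one class
  grid <- tidyr::expand_grid(fev1_pp = seq(20, 140, by = 5),
                             fev1_fvc = seq(0.2, 0.95, by = 0.05))
  st2 <- derive_copd_status(grid)$copd_status
  expect_false(any(is.na(st2)))
  # monotonicity: lowering fev1 below 80 with ratio < 0.7 keeps cases cases
  cases <- grid[st2 == "case", ]
  lowered <- dplyr::mutate(cases, fev1_pp = fev1_pp - 10)
  expect_true(all(derive_copd_status(lowered)$copd_status == "case"))
})

test_that("COPD derivation requires spirometry columns", {
  expect_error(derive_copd_status(tibble::tibble(fev1_fvc = 0.5)), "fev1_pp")
})

test_that("family-history harmonisation follows the three coding modes", {
  df <- tibble::tibble(
    fh_copd = c("unknown", "yes", "unknown", "no", NA),
    fh_chronic_bronchitis = c("no", "no", "unknown", "no", NA),
    fh_emphysema = c("yes", "no", "unknown", "unknown", NA)
  )
  full <- harmonize_family_history(df, "copdgene_full")$family_history
  expect_equal(full, c(TRUE, TRUE, FALSE, FALSE, NA))
  harm <- harmonize_family_history(df, "eclipse_harmonized")$family_history
  # a COPD-question 'yes' alone does not count under the harmonised coding
  expect_equal(harm[2], FALSE)
  expect_equal(harm[1], TRUE)
  excl <- harmonize_family_history(df, "exclude_unknown")$family_history
  expect_equal(excl, c(TRUE, TRUE, NA, FALSE, NA))
  # idempotence: re-running on the output changes nothing
  expect_identical(
    harmonize_family_history(harmonize_family_history(df, "copdgene_full"),
                             "copdgene_full"),
    harmonize_family_history(df, "copdgene_full")
  )
})

test_that("PRS standardisation is exact per group and tertile cut is ties-below", {
  df <- tibble::tibble(cohort = "a", prs_raw = as.numeric(1:9))
  out <- standardize_prs(df)
  expect_equal(mean(out$prs_z), 0, tolerance = 1e-9)
  expect_equal(sd(out$prs_z), 1, tolerance = 1e-9)
  expect_equal(out$prs_raw[out$prs_top_tertile], c(7, 8, 9))

  # groups standardised independently
  df2 <- tibble::tibble(
    cohort = rep(c("a", "b"), each = 50),
    prs_raw = c(rnorm(50, 10, 2), rnorm(50, -5, 0.5))
  )
  out2 <- standardize_prs(df2)
  for (g in c("a", "b")) {
    z <- out2$prs_z[out2$cohort == g]
    expect_equal(mean(z), 0, tolerance = 1e-9)
    expect_equal(sd(z), 1, tolerance = 1e-9)
  }
  # tertile count is floor or ceiling of n/3
  n_top <- sum(out2$prs_top_tertile[out2$cohort == "a"])
  expect_true(n_top %in% c(floor(50 / 3), ceiling(50 / 3)))

  expect_error(standardize_prs(tibble::tibble(prs_raw = rep(1, 10)), by = NULL),
               "degenerate")
})

test_that("summary percentages reproduce count/total arithmetic", {
  df <- tibble::tibble(
    copd_status = factor(rep(c("control", "case"), c(2506, 2668)),
                         levels = c("control", "case")),
    family_history = c(rep(c(TRUE, FALSE), c(710, 2506 - 710)),
                       rep(c(TRUE, FALSE), c(991, 2668 - 991)))
  )
  s <- summarize_cohort(df, continuous = character(0),
                        categorical = "family_history")
  ctrl <- s[s$group == "control", ]
  case <- s[s$group == "case", ]
  expect_equal(ctrl$count, 710)
  expect_equal(round(ctrl$percent, 1), 28.3)
  expect_equal(round(case$percent, 1), 37.1)
  expect_equal(ctrl$n, 2506)

  # zero numerator
  df$family_history[df$copd_status == "control"] <- FALSE
  s0 <- summarize_cohort(df, continuous = character(0),
                         categorical = "family_history")
  expect_equal(s0$percent[s0$group == "control"], 0)
})

test_that("summaries pick mean/SD or median/IQR by normality and attach tests", {
  set.seed(42)
  df <- tibble::tibble(
    copd_status = factor(rep(c("control", "case"), each = 300),
                         levels = c("control", "case")),
    age = rnorm(600, 60, 8),
    pack_years = rexp(600, 1 / 40) + 10
  )
  s <- summarize_cohort(df, continuous = c("age", "pack_years"),
                        categorical = character(0))
  expect_equal(unique(s$summary_type[s$variable == "age"]), "mean_sd")
  expect_equal(unique(s$summary_type[s$variable == "pack_years"]), "median_iqr")
  expect_equal(unique(s$test[s$variable == "age"]), "t")
  expect_equal(unique(s$test[s$variable == "pack_years"]), "wilcoxon")
})

test_that("cohort tables round-trip through delimited text", {
  cohort <- generate_synthetic_cohort(sim_config(n = 60, seed = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- load_cohort(path)
  for (col in names(cohort)) {
    if (is.numeric(cohort[[col]])) {
      expect_equal(back[[col]], cohort[[col]], tolerance = 1e-12)
    } else {
      expect_equal(as.character(back[[col]]), as.character(cohort[[col]]))
    }
  }
  expect_equal(attr(back, "n_input"), 60)
})

test_that("the reader enforces schema and cell-level parsing", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,age,sex,pack_years,fh_copd",
               "s1,60,female,30,unknown",
               "s2,55,male,20,yes"), path)
  d <- load_cohort(path)
  # 'unknown' survives as a level, not missing
  expect_equal(d$fh_copd, c("unknown", "yes"))
  expect_error(derive_copd_status(d), "fev1_pp")

  writeLines(c("subject_id,age,sex,pack_years",
               "s1,sixty,female,30"), path)
  expect_error(load_cohort(path), "age")

  writeLines(c("subject_id,age,sex", "s1,60,female"), path)
  expect_error(load_cohort(path), "pack_years")

  writeLines(c("subject_id,age,sex,pack_years,fev1_fvc",
               "s1,60,female,30,1.4"), path)
  expect_error(load_cohort(path), "fev1_fvc")
})
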