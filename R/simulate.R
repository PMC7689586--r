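# Truncated-normal draws by inverse-CDF; bounds may be infinite.
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  qnorm(runif(n, pl, pu), mean, sd)
}

expit <- function(x) 1 / (1 + exp(-x))

#' Simulation configuration for a synthetic smoker case-control cohort
#'
#' Defaults emulate a COPDGene-like non-Hispanic-white smoker cohort:
#' family-history prevalence 0.33; a standard-normal PRS whose mean is shifted
#' by `a` SD in subjects with a family history (the default `a = 0.1527`
#' reproduces a biserial family-history/PRS correlation of 0.093 at that
#' prevalence); and a logistic disease model with odds ratios 1.67 per
#' positive family history and 2.11 per SD of PRS, adjusted for age, sex and
#' pack-years, with an intercept giving a roughly balanced case:control split.
#' Secondary outcomes (exacerbations, severe exacerbations, death, BODE, SGRQ,
#' six-minute walk distance, quantitative CT traits) are generated from simple
#' generalised-linear models on disease status, family history and PRS.
#'
#' @param n Number of subjects.
#' @param seed Integer master seed; per-block child seeds are drawn from it so
#'   the output is bit-reproducible.
#' @param cohort Cohort label written into the table.
#' @param fh_prevalence Family-history probability.
#' @param a Mean shift of the raw PRS (in SD units) for subjects with a
#'   positive family history — the mediated path.
#' @param beta0,beta_fh,beta_prs,gamma Logistic coefficients: intercept, family
#'   history, PRS per SD, and the family-history-by-PRS product term.
#' @param beta_age,beta_sex,beta_packyears Covariate coefficients (age and
#'   pack-years are centred at their generating means; sex coefficient applies
#'   to males).
#' @param age_mean,age_sd,packyears_mean,packyears_sd,female_fraction,
#'   current_smoker_fraction Covariate distribution parameters. Ages are
#'   truncated to 45-80 years and pack-years to at least 10, matching a
#'   heavy-smoker enrolment criterion.
#' @param n_pcs Number of standard-normal ancestry principal-component columns.
#' @param risk_scale `"logit"` (default) or `"additive"`. The additive scale
#'   generates `P(case) = p0 + d_fh*FH + d_prs*PRS_top + d_int*FH*PRS_top`
#'   using the dichotomised PRS (top tertile of the raw score), a construction
#'   whose excess risks are exactly additive when `d_int = 0` — the additive
#'   null used to calibrate RERI.
#' @param p0,d_fh,d_prs,d_int Additive-scale baseline risk and risk
#'   differences (used only when `risk_scale = "additive"`).
#' @param case_control_sampling Optional `list(n_cases =, n_controls =)` to
#'   subsample an imbalanced design (e.g. 1713 cases : 147 controls).
#' @param unknown_fh_rate Probability that a negative family-history response
#'   is recorded as `"unknown"` rather than `"no"`.
#'
#' @return A list of class `fhprs_sim_config`.
#' @export
sim_config <- function(n = 5000, seed = 1, cohort = "SIM",
                       fh_prevalence = 0.33, a = 0.1527,
                       beta0 = -0.35, beta_fh = log(1.67),
                       beta_prs = log(2.11), gamma = 0,
                       beta_age = 0.05, beta_sex = 0.15,
                       beta_packyears = 0.02,
                       age_mean = 62, age_sd = 9,
                       packyears_mean = 47, packyears_sd = 25,
                       female_fraction = 0.5,
                       current_smoker_fraction = 0.45,
                       n_pcs = 5,
                       risk_scale = c("logit", "additive"),
                       p0 = 0.02, d_fh = 0.01, d_prs = 0.015, d_int = 0,
                       case_control_sampling = NULL,
                       unknown_fh_rate = 0.05) {
  risk_scale <- match.arg(risk_scale)
  stopifnot(
    n >= 10, fh_prevalence > 0, fh_prevalence < 1,
    age_sd > 0, packyears_sd > 0, n_pcs >= 0,
    p0 >= 0, p0 + abs(d_fh) + abs(d_prs) + abs(d_int) <= 1
  )
  structure(as.list(environment()), class = "fhprs_sim_config")
}

#' Generate a synthetic cohort table
#'
#' Draws a cohort from the structural model in [sim_config()]: family history
#' first, then the PRS given family history, covariates, disease status from
#' the logistic (or additive-risk) model, spirometry back-filled on the
#' correct side of the case/control thresholds, and all secondary outcomes.
#' Spirometry is sampled from truncated normals so that re-deriving COPD
#' status from the written table reproduces the generated status exactly.
#'
#' @param config A [sim_config()] object.
#' @return A raw cohort tibble (as if read by [load_cohort()]) with attributes
#'   `sim_config` (the generating configuration) and `truth` (a tibble of the
#'   latent case indicator and linear predictor).
#' @export
#' @examples
#' cohort <- generate_synthetic_cohort(sim_config(n = 500, seed = 42))
#' table(derive_copd_status(cohort)$copd_status)
generate_synthetic_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "fhprs_sim_config"))
  cf <- config
  set.seed(cf$seed)
  # independent child streams per generation block
  block_seeds <- sample.int(.Machine$integer.max - 1, 8)
  n <- cf$n

  set.seed(block_seeds[1])
  fh <- rbinom(n, 1, cf$fh_prevalence)
  prs_raw <- rnorm(n, cf$a * fh, 1)

  set.seed(block_seeds[2])
  age <- rtnorm(n, cf$age_mean, cf$age_sd, 45, 80)
  sex <- ifelse(runif(n) < cf$female_fraction, "female", "male")
  pack_years <- rtnorm(n, cf$packyears_mean, cf$packyears_sd, 10, Inf)
  current_smoker <- runif(n) < cf$current_smoker_fraction
  height <- rnorm(n, ifelse(sex == "male", 176, 163), 7)
  weight <- rnorm(n, ifelse(sex == "male", 88, 75), 15)
  pcs <- if (cf$n_pcs > 0) {
    matrix(rnorm(n * cf$n_pcs), n, cf$n_pcs,
           dimnames = list(NULL, paste0("pc", seq_len(cf$n_pcs))))
  } else NULL

  set.seed(block_seeds[3])
  if (cf$risk_scale == "logit") {
    male <- as.numeric(sex == "male")
    lp <- cf$beta0 + cf$beta_fh * fh + cf$beta_prs * prs_raw +
      cf$gamma * fh * prs_raw +
      cf$beta_age * (age - cf$age_mean) + cf$beta_sex * male +
      cf$beta_packyears * (pack_years - cf$packyears_mean)
    p_case <- expit(lp)
  } else {
    cut <- quantile(prs_raw, 2 / 3, type = 7, names = FALSE)
    prs_top <- as.numeric(prs_raw > cut)
    p_case <- cf$p0 + cf$d_fh * fh + cf$d_prs * prs_top +
      cf$d_int * fh * prs_top
    p_case <- pmin(pmax(p_case, 0), 1)
    lp <- qlogis(pmin(pmax(p_case, 1e-12), 1 - 1e-12))
  }
  case <- rbinom(n, 1, p_case)

  # spirometry consistent with assigned status (case-control marginals
  # resemble a severe-COPD enriched smoker cohort)
  set.seed(block_seeds[4])
  fev1_pp <- ifelse(case == 1,
                    rtnorm(n, 48.8, 17.8, 15, 79.99),
                    rtnorm(n, 94.9, 13.1, 80, 150))
  fev1_fvc <- ifelse(case == 1,
                     rtnorm(n, 0.48, 0.13, 0.10, 0.6999),
                     rtnorm(n, 0.77, 0.06, 0.70, 0.95))

  set.seed(block_seeds[5])
  ex_rate <- exp(-2.2 + 0.9 * case + 0.35 * fh + 0.10 * prs_raw +
                   0.04 * (90 - fev1_pp) / 10 +
                   0.20 * current_smoker)
  exacerbations_12mo <- rpois(n, ex_rate)
  severe_exacerbation <- runif(n) < expit(-3 + 1.4 * case + 0.2 * fh)
  bode <- pmin(pmax(round(0.4 + 3 * case + rnorm(n, 0, 1.3)), 0), 10)
  dead <- runif(n) < expit(-3.5 + 0.35 * bode)

  set.seed(block_seeds[6])
  sgrq_total <- pmin(pmax(17 + 24 * case + 1.5 * fh + 2 * prs_raw +
                            rnorm(n, 0, 17), 0), 100)
  sixmwd <- pmax(1550 + 6 * (height - 170) - 3 * (weight - 80) -
                   350 * case - 20 * fh - 25 * prs_raw +
                   rnorm(n, 0, 300), 0)

  set.seed(block_seeds[7])
  pct_laa950 <- pmin(pmax(1.5 + 9 * case + 0.5 * fh + 1.2 * prs_raw +
                            rnorm(n, 0, 5), 0), 60)
  perc15 <- -880 - 40 * case - 2 * fh - 5 * prs_raw + rnorm(n, 0, 25)
  pi10 <- 3.6 + 0.12 * case + 0.01 * fh + 0.015 * prs_raw + rnorm(n, 0, 0.15)
  wa_pct <- 60 + 3 * case + 0.2 * fh + 0.4 * prs_raw + rnorm(n, 0, 3)
  ct_scanner <- sample(c("scannerA", "scannerB"), n, replace = TRUE)
  visual_ct_subtype <- ifelse(
    case == 1,
    sample(c("centrilobular", "panlobular", "airway_predominant"), n,
           replace = TRUE, prob = c(0.5, 0.2, 0.3)),
    "none"
  )

  # decompose the binary family history into the three questionnaire items
  set.seed(block_seeds[8])
  decompose_fh <- function(fh) {
    yes_copd <- fh == 1 & runif(n) < 0.7
    yes_cb <- fh == 1 & runif(n) < 0.45
    yes_em <- fh == 1 & runif(n) < 0.45
    none <- fh == 1 & !(yes_copd | yes_cb | yes_em)
    yes_copd[none] <- TRUE  # at least one positive item for positives
    code <- function(yes) {
      out <- ifelse(yes, "yes", "no")
      unk <- !yes & runif(n) < cf$unknown_fh_rate
      out[unk] <- "unknown"
      out
    }
    list(fh_copd = code(yes_copd), fh_chronic_bronchitis = code(yes_cb),
         fh_emphysema = code(yes_em))
  }
  fhq <- decompose_fh(fh)

  out <- tibble(
    subject_id = sprintf("S%06d", seq_len(n)),
    cohort = cf$cohort,
    age = age, sex = sex, pack_years = pack_years,
    current_smoker = current_smoker, height = height, weight = weight,
    fev1_pp = fev1_pp, fev1_fvc = fev1_fvc,
    fh_copd = fhq$fh_copd,
    fh_chronic_bronchitis = fhq$fh_chronic_bronchitis,
    fh_emphysema = fhq$fh_emphysema,
    prs_raw = prs_raw,
    exacerbations_12mo = exacerbations_12mo,
    severe_exacerbation = severe_exacerbation,
    dead = dead, bode = bode, sgrq_total = sgrq_total, sixmwd = sixmwd,
    pct_laa950 = pct_laa950, perc15 = perc15, pi10 = pi10, wa_pct = wa_pct,
    visual_ct_subtype = visual_ct_subtype, ct_scanner = ct_scanner
  )
  if (!is.null(pcs)) out <- dplyr::bind_cols(out, as_tibble(pcs))
  truth <- tibble(subject_id = out$subject_id, case = case,
                  fh = fh, linear_predictor = lp, p_case = p_case)

  if (!is.null(cf$case_control_sampling)) {
    tgt <- cf$case_control_sampling
    idx_case <- which(case == 1)
    idx_ctrl <- which(case == 0)
    if (tgt$n_cases > length(idx_case) || tgt$n_controls > length(idx_ctrl)) {
      abort(paste0(
        "Unreachable case-control targets (generated ", length(idx_case),
        " cases, ", length(idx_ctrl), " controls); increase n."
      ))
    }
    keep <- sort(c(sample(idx_case, tgt$n_cases),
                   sample(idx_ctrl, tgt$n_controls)))
    out <- out[keep, ]
    truth <- truth[keep, ]
  }

  validate_cohort(out)
  attr(out, "sim_config") <- cf
  attr(out, "truth") <- truth
  out
}
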