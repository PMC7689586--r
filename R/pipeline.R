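#' Configuration for the full analysis pipeline
#'
#' @param cohorts Named list describing each cohort: either a [sim_config()]
#'   object (the cohort is simulated) or a `list(path =, schema =)` entry
#'   read with [load_cohort()].
#' @param outcomes Outcome columns to model; binary outcomes get the three
#'   logistic models plus discrimination metrics, continuous outcomes the
#'   three linear models plus fit metrics.
#' @param fh_mode Family-history coding, see [harmonize_family_history()].
#' @param n_pcs Principal components in PRS-containing models.
#' @param estimator Estimator for binary outcomes (`"mle"` or `"firth"`).
#' @param run_interaction,run_mediation,run_meta Stage toggles; interaction
#'   and mediation run on the first cohort's primary outcome, meta pools the
#'   model-3 family-history log-OR for `copd_status` across cohorts.
#' @param mediation_B Bootstrap replicates for the mediation stage.
#' @param seed Pipeline seed (drives mediation bootstrap and any simulation
#'   whose config has no seed).
#' @return A list of class `fhprs_pipeline_config`.
#' @export
pipeline_config <- function(cohorts, outcomes = "copd_status",
                            fh_mode = "copdgene_full", n_pcs = 5,
                            estimator = "mle",
                            run_interaction = TRUE, run_mediation = TRUE,
                            run_meta = TRUE, mediation_B = 200, seed = 1) {
  stopifnot(is.list(cohorts), length(cohorts) >= 1)
  if (is.null(names(cohorts)) || any(names(cohorts) == "")) {
    abort("cohorts must be a named list")
  }
  structure(as.list(environment()), class = "fhprs_pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage '", name, "' failed: ",
                 conditionMessage(e)))
  })
}

#' Run the full family-history vs PRS analysis
#'
#' Executes cohort acquisition (simulation or file), derivation of analysis
#' columns, the three nested models per outcome per cohort, discrimination
#' and calibration metrics, attributable fractions, interaction
#' (multiplicative and RERI), natural-effects mediation, and fixed-effect
#' meta-analysis of the model-3 family-history effect across cohorts.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every result table is
#'   written as CSV together with a JSON run manifest.
#' @return A list of tibbles (`models`, `performance`, `auc_comparisons`,
#'   `attributable`, `interaction`, `reri`, `joint_effects`, `stratified`,
#'   `mediation`, `meta`, `table1`) plus `cohorts` (derived tables) and
#'   `manifest`.
#' @export
run_full_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "fhprs_pipeline_config"))
  cohorts <- stage("acquire", {
    purrr::imap(config$cohorts, function(cc, nm) {
      raw <- if (inherits(cc, "fhprs_sim_config")) {
        generate_synthetic_cohort(cc)
      } else {
        load_cohort(cc$path,
                    schema = if (!is.null(cc$schema)) cc$schema
                             else cohort_schema())
      }
      raw$cohort <- nm
      raw
    })
  })
  derived <- stage("derive", {
    purrr::map(cohorts, derive_cohort, fh_mode = config$fh_mode)
  })

  models <- stage("fit", {
    purrr::imap_dfr(derived, function(d, nm) {
      purrr::map_dfr(config$outcomes, function(oc) {
        if (!oc %in% names(d)) {
          abort(paste0("outcome column '", oc, "' absent from cohort '",
                       nm, "'"))
        }
        est <- if (oc %in% .binary_outcomes) config$estimator else "ols"
        fits <- fit_models_123(d, oc, estimator = est, n_pcs = config$n_pcs)
        purrr::imap_dfr(fits, function(f, mn) {
          mutate(tidy(f), cohort = nm, outcome = oc, model = mn,
                 n_used = f$n_used)
        })
      })
    })
  })

  perf_objs <- stage("performance", {
    purrr::imap(derived, function(d, nm) {
      purrr::map(intersect(config$outcomes, .binary_outcomes),
                 function(oc) performance_table(d, oc,
                                                estimator = config$estimator,
                                                n_pcs = config$n_pcs)) %>%
        setNames(intersect(config$outcomes, .binary_outcomes))
    })
  })
  performance <- purrr::imap_dfr(perf_objs, function(po, nm) {
    purrr::imap_dfr(po, function(p, oc) {
      mutate(p$performance, cohort = nm, outcome = oc)
    })
  })
  auc_comparisons <- purrr::imap_dfr(perf_objs, function(po, nm) {
    purrr::imap_dfr(po, function(p, oc) {
      mutate(p$comparisons, cohort = nm, outcome = oc)
    })
  })

  attributable <- stage("attributable_fractions", {
    purrr::imap_dfr(derived, function(d, nm) {
      if (!"copd_status" %in% config$outcomes) return(tibble())
      cases <- filter(d, .data$copd_status == "case")
      purrr::map_dfr(
        c(fh = "family_history", prs_top = "prs_top_tertile"),
        function(col) {
          spec <- model_spec("copd_status",
                             if (col == "family_history") "fh_only"
                             else "prs_only",
                             prs_form = "top_tertile",
                             estimator = config$estimator,
                             n_pcs = config$n_pcs)
          fit <- fit_model(d, spec)
          term <- grep(if (col == "family_history") "^family_history"
                       else "^prs_top_tertile",
                       fit$tidy$term, value = TRUE)[1]
          or <- fit$tidy$odds.ratio[fit$tidy$term == term]
          attributable_fractions(or, p_c = mean(cases[[col]], na.rm = TRUE),
                                 exposure = col)
        }
      ) %>% mutate(cohort = nm)
    })
  })

  first <- derived[[1]]
  interaction_tbl <- reri_tbl <- joint_tbl <- strat_tbl <- tibble()
  if (config$run_interaction && "copd_status" %in% config$outcomes) {
    interaction_tbl <- stage("interaction", {
      mutate(multiplicative_interaction_test(first),
             cohort = names(derived)[1])
    })
    joint <- stage("joint_effects", joint_effects(first))
    joint_tbl <- mutate(joint$tidy, cohort = names(derived)[1])
    reri_tbl <- stage("reri", mutate(reri(joint), cohort = names(derived)[1]))
    strat_tbl <- stage("stratified",
                       mutate(stratified_estimates(first),
                              cohort = names(derived)[1]))
  }

  mediation_tbl <- tibble()
  if (config$run_mediation && "copd_status" %in% config$outcomes) {
    mediation_tbl <- stage("mediation", {
      med <- natural_effects_mediation(first, B = config$mediation_B,
                                       seed = config$seed)
      mutate(tidy(med), cohort = names(derived)[1], B = med$B,
             n_used = med$n_used)
    })
  }

  meta_tbl <- tibble()
  if (config$run_meta && length(derived) >= 2 &&
      "copd_status" %in% config$outcomes) {
    meta_tbl <- stage("meta", {
      ests <- models %>%
        filter(.data$outcome == "copd_status", .data$model == "model3",
               grepl("^family_history", .data$term)) %>%
        mutate(study = .data$cohort) %>%
        select("study", effect = "estimate", se = "std.error", n = "n_used")
      tidy(fixed_effect_meta(ests)) %>%
        mutate(i2 = fixed_effect_meta(ests)$i2)
    })
  }

  table1 <- stage("table1", {
    purrr::imap_dfr(derived, function(d, nm) {
      mutate(summarize_cohort(d), cohort = nm)
    })
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("fhprs")),
    r_version = R.version.string,
    seed = config$seed,
    cohorts = names(derived),
    outcomes = config$outcomes,
    timestamp = format(Sys.time(), tz = "UTC")
  )

  bundle <- list(
    models = models, performance = performance,
    auc_comparisons = auc_comparisons, attributable = attributable,
    interaction = interaction_tbl, joint_effects = joint_tbl,
    reri = reri_tbl, stratified = strat_tbl, mediation = mediation_tbl,
    meta = meta_tbl, table1 = table1, cohorts = derived, manifest = manifest
  )

  if (!is.null(out_dir)) {
    stage("write", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      tables <- bundle[vapply(bundle, is.data.frame, TRUE)]
      purrr::iwalk(tables, function(tb, nm) {
        readr::write_csv(tb, file.path(out_dir, paste0(nm, ".csv")))
      })
      purrr::iwalk(derived, function(d, nm) {
        write_cohort(d, file.path(out_dir, paste0("cohort_", nm, ".csv")))
      })
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    })
  }
  bundle
}
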