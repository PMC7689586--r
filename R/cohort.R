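#' Canonical cohort column schema
#'
#' Returns the default mapping from canonical analysis column names to the
#' column names expected in an input file. Supplying a modified copy to
#' [load_cohort()] adapts the reader to files with different headers.
#'
#' @param ... Named overrides, e.g. `fev1_pp = "FEV1_percent_pred"`.
#'
#' @return Named character vector mapping canonical names to file columns.
#' @export
#' @examples
#' cohort_schema(prs_raw = "PRS", fev1_pp = "fev1pp_utah")
cohort_schema <- function(...) {
  schema <- c(
    subject_id = "subject_id", cohort = "cohort", age = "age", sex = "sex",
    pack_years = "pack_years", current_smoker = "current_smoker",
    height = "height", weight = "weight", bmi = "bmi",
    fev1_pp = "fev1_pp", fev1_fvc = "fev1_fvc",
    fh_copd = "fh_copd", fh_chronic_bronchitis = "fh_chronic_bronchitis",
    fh_emphysema = "fh_emphysema",
    prs_raw = "prs_raw",
    exacerbations_12mo = "exacerbations_12mo",
    severe_exacerbation = "severe_exacerbation", dead = "dead",
    bode = "bode", sgrq_total = "sgrq_total", sixmwd = "sixmwd",
    pct_laa950 = "pct_laa950", perc15 = "perc15", pi10 = "pi10",
    wa_pct = "wa_pct", visual_ct_subtype = "visual_ct_subtype",
    ct_scanner = "ct_scanner"
  )
  overrides <- c(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(schema))
    if (length(bad)) {
      abort(paste0("Unknown canonical column(s): ", paste(bad, collapse = ", ")))
    }
    schema[names(overrides)] <- overrides
  }
  schema
}

# Columns that must be numeric / logical / fh-coded after renaming.
.numeric_cols <- c(
  "age", "pack_years", "height", "weight", "bmi", "fev1_pp", "fev1_fvc",
  "prs_raw", "exacerbations_12mo", "bode", "sgrq_total", "sixmwd",
  "pct_laa950", "perc15", "pi10", "wa_pct"
)
.logical_cols <- c("current_smoker", "severe_exacerbation", "dead")
.fh_cols <- c("fh_copd", "fh_chronic_bronchitis", "fh_emphysema")

#' Read a cohort table from delimited text
#'
#' Reads a CSV/TSV of per-subject records, renames columns to canonical names
#' via a schema, coerces semantic types (numerics, yes/no/unknown family
#' history, logical flags), enforces basic range invariants, and attaches
#' row-count and per-column missingness as attributes.
#'
#' Family-history responses are kept as the three-level coding
#' `"yes"/"no"/"unknown"`: an explicit `"unknown"` response is data, not a
#' missing value, because the primary analysis recodes it as `"no"` while a
#' sensitivity analysis drops it (see [harmonize_family_history()]).
#'
#' @param path Path to a delimited text file.
#' @param schema Mapping from canonical to file column names, from
#'   [cohort_schema()]. Only mapped columns found in the file are read; columns
#'   listed in `required` must be present.
#' @param required Canonical column names that must exist in the file.
#' @param delim Field delimiter; `NULL` guesses from the file extension
#'   (`.tsv`/`.txt` tab, otherwise comma).
#' @param na Strings to read as missing.
#'
#' @return A tibble with canonical column names and attributes
#'   `n_input` (rows read) and `missingness` (named fraction missing per
#'   column).
#' @export
load_cohort <- function(path, schema = cohort_schema(),
                        required = c("subject_id", "age", "sex", "pack_years"),
                        delim = NULL, na = c("", "NA")) {
  if (!file.exists(path)) abort(paste0("Cohort file not found: ", path))
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, na = na, col_types = readr::cols(
    .default = readr::col_character()
  ), show_col_types = FALSE)

  missing_req <- required[!schema[required] %in% names(raw)]
  if (length(missing_req)) {
    abort(paste0(
      "Schema error: required column(s) absent from ", path, ": ",
      paste0(missing_req, " (file column '", schema[missing_req], "')",
             collapse = ", ")
    ))
  }

  present <- schema[schema %in% names(raw)]
  # ancestry principal components are read by convention (pc1, pc2, ...)
  pc_cols <- grep("^pc[0-9]+$", names(raw), value = TRUE)
  present <- c(present, setNames(pc_cols, pc_cols))
  data <- raw[, unname(present), drop = FALSE]
  names(data) <- names(present)

  coerce_num <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      abort(paste0(
        "Unparseable numeric value in column '", col, "' at data row(s) ",
        paste(head(bad, 5), collapse = ", "), " (value '", x[bad[1]], "')"
      ))
    }
    out
  }
  coerce_lgl <- function(x, col) {
    x2 <- tolower(trimws(x))
    out <- dplyr::case_when(
      x2 %in% c("1", "true", "t", "yes", "y") ~ TRUE,
      x2 %in% c("0", "false", "f", "no", "n") ~ FALSE,
      TRUE ~ NA
    )
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad)) {
      abort(paste0("Unparseable logical value in column '", col,
                   "' at data row(s) ", paste(head(bad, 5), collapse = ", ")))
    }
    out
  }
  coerce_fh <- function(x, col) {
    x2 <- tolower(trimws(x))
    bad <- which(!is.na(x2) & !x2 %in% c("yes", "no", "unknown"))
    if (length(bad)) {
      abort(paste0("Family-history column '", col,
                   "' must be yes/no/unknown; bad value at data row(s) ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    x2
  }

  for (col in intersect(c(.numeric_cols, pc_cols), names(data))) {
    data[[col]] <- coerce_num(data[[col]], col)
  }
  for (col in intersect(.logical_cols, names(data))) {
    data[[col]] <- coerce_lgl(data[[col]], col)
  }
  for (col in intersect(.fh_cols, names(data))) {
    data[[col]] <- coerce_fh(data[[col]], col)
  }
  if ("sex" %in% names(data)) {
    s <- tolower(trimws(data$sex))
    bad <- which(!is.na(s) & !s %in% c("female", "male", "f", "m"))
    if (length(bad)) {
      abort(paste0("Column 'sex' must be female/male; bad value at data row(s) ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    data$sex <- ifelse(s %in% c("female", "f"), "female",
                       ifelse(s %in% c("male", "m"), "male", NA))
  }

  validate_cohort(data)
  data <- as_tibble(data)
  attr(data, "n_input") <- nrow(data)
  attr(data, "missingness") <- vapply(data, function(x) mean(is.na(x)), 0)
  data
}

#' Write a cohort table to delimited text
#'
#' Numeric columns are written at full precision so a write-then-load
#' round-trip reproduces values exactly at the stated precision.
#'
#' @param data Cohort tibble.
#' @param path Output path; extension picks the delimiter as in [load_cohort()].
#' @return `data`, invisibly.
#' @export
write_cohort <- function(data, path) {
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(data, path, delim = delim, na = "")
  invisible(data)
}

# Range invariants on raw fields; called on load and after simulation.
validate_cohort <- function(data) {
  check <- function(col, ok, what) {
    if (!col %in% names(data)) return(invisible())
    x <- data[[col]]
    bad <- which(!is.na(x) & !ok(x))
    if (length(bad)) {
      abort(paste0("Invalid ", what, " in column '", col, "' at data row(s) ",
                   paste(head(bad, 5), collapse = ", ")))
    }
  }
  check("fev1_fvc", function(x) x >= 0 & x <= 1, "FEV1/FVC ratio (must be in [0,1])")
  check("pack_years", function(x) x >= 0, "pack-years (must be >= 0)")
  check("exacerbations_12mo", function(x) x >= 0 & x == round(x),
        "exacerbation count (must be a non-negative integer)")
  invisible(data)
}

#' Derive COPD case/control status from spirometry
#'
#' Moderate-to-severe COPD cases have post-bronchodilator FEV1 < 80% predicted
#' and FEV1/FVC < 0.7; controls have FEV1 >= 80% predicted and FEV1/FVC >= 0.7.
#' Subjects in neither group are `"excluded"`: mild obstruction (GOLD 1,
#' ratio < 0.7 with preserved FEV1) and preserved-ratio impaired spirometry
#' (PRISm, ratio >= 0.7 with FEV1 < 80%). Records with missing spirometry get
#' `NA` status and are dropped from COPD models only.
#'
#' @param data Cohort tibble with `fev1_pp` and `fev1_fvc` columns.
#' @return `data` with a `copd_status` factor column
#'   (levels control, case, excluded).
#' @export
#' @examples
#' df <- tibble::tibble(fev1_pp = c(48.8, 95, 85, 70), fev1_fvc = c(0.48, 0.77, 0.65, 0.75))
#' derive_copd_status(df)$copd_status
derive_copd_status <- function(data) {
  for (col in c("fev1_pp", "fev1_fvc")) {
    if (!col %in% names(data)) {
      abort(paste0("Schema error: COPD status derivation needs column '", col, "'"))
    }
  }
  data %>%
    mutate(copd_status = factor(
      case_when(
        is.na(.data$fev1_pp) | is.na(.data$fev1_fvc) ~ NA_character_,
        .data$fev1_pp < 80 & .data$fev1_fvc < 0.7 ~ "case",
        .data$fev1_pp >= 80 & .data$fev1_fvc >= 0.7 ~ "control",
        TRUE ~ "excluded"
      ),
      levels = c("control", "case", "excluded")
    ))
}

#' Harmonise family-history questionnaire responses to a binary exposure
#'
#' A positive family history is a parental report of COPD, chronic bronchitis
#' or emphysema. Three coding modes are supported:
#'
#' * `"copdgene_full"` (primary): positive iff any of the three questions is
#'   `"yes"`; `"unknown"` counts as `"no"`.
#' * `"eclipse_harmonized"`: same rule over chronic bronchitis and emphysema
#'   only (the COPD question is unavailable in ECLIPSE-style questionnaires).
#' * `"exclude_unknown"` (sensitivity): as the primary coding, but subjects
#'   whose every contributing response is `"unknown"` become missing.
#'
#' Subjects with all contributing fields absent are missing in every mode.
#' The operation is idempotent: it recomputes `family_history` from the raw
#' three-level fields each time.
#'
#' @param data Cohort tibble with `fh_copd`, `fh_chronic_bronchitis`,
#'   `fh_emphysema` columns coded `"yes"/"no"/"unknown"` (any may be absent,
#'   but at least one contributing field must exist).
#' @param mode Coding mode, see above.
#' @return `data` with a logical `family_history` column.
#' @export
harmonize_family_history <- function(data,
                                     mode = c("copdgene_full",
                                              "eclipse_harmonized",
                                              "exclude_unknown")) {
  mode <- match.arg(mode)
  fields <- switch(mode,
    copdgene_full = .fh_cols,
    exclude_unknown = .fh_cols,
    eclipse_harmonized = c("fh_chronic_bronchitis", "fh_emphysema")
  )
  fields <- intersect(fields, names(data))
  if (!length(fields)) {
    abort("No family-history columns present; cannot harmonise.")
  }
  m <- as.matrix(data[, fields, drop = FALSE])
  any_yes <- rowSums(m == "yes", na.rm = TRUE) > 0
  n_nonmiss <- rowSums(!is.na(m))
  n_unknown <- rowSums(m == "unknown", na.rm = TRUE)
  fh <- ifelse(n_nonmiss == 0, NA, any_yes)
  if (mode == "exclude_unknown") {
    fh[n_nonmiss > 0 & n_unknown == n_nonmiss] <- NA
  }
  data$family_history <- as.logical(fh)
  data
}

#' Standardise the PRS and flag its top tertile, per cohort
#'
#' Within each grouping level (by default the `cohort` column), `prs_z` is the
#' raw PRS centred and scaled to unit SD over that group's full analysis
#' sample, so odds ratios per SD are defined against the cohort's own PRS
#' distribution. `prs_top_tertile` is `TRUE` iff the raw PRS lies strictly
#' above the group's empirical 2/3 quantile (quantile type 7); values tied
#' with the cut point fall in the bottom group, a deterministic tie-break.
#'
#' @param data Cohort tibble with a numeric `prs_raw` column.
#' @param by Grouping column name, or `NULL` to treat the table as one group.
#' @return `data` with `prs_z` and `prs_top_tertile` columns.
#' @export
standardize_prs <- function(data, by = "cohort") {
  if (!"prs_raw" %in% names(data)) {
    abort("Schema error: PRS standardisation needs column 'prs_raw'")
  }
  if (!is.null(by) && !by %in% names(data)) by <- NULL
  std_one <- function(d) {
    x <- d$prs_raw
    ok <- !is.na(x)
    if (length(unique(x[ok])) < 3) {
      abort("degenerate PRS: fewer than 3 distinct values in a group")
    }
    s <- sd(x[ok])
    if (s == 0) abort("degenerate PRS: zero variance in a group")
    cut <- quantile(x[ok], 2 / 3, type = 7, names = FALSE)
    d$prs_z <- (x - mean(x[ok])) / s
    d$prs_top_tertile <- x > cut
    d
  }
  if (is.null(by)) {
    std_one(data)
  } else {
    data %>%
      group_by(across(all_of(by))) %>%
      dplyr::group_modify(~ std_one(.x)) %>%
      ungroup() %>%
      select(all_of(names(data)), "prs_z", "prs_top_tertile")
  }
}

#' Derive all analysis columns on a cohort table
#'
#' Convenience wrapper applying [derive_copd_status()],
#' [harmonize_family_history()], [standardize_prs()], the frequent-exacerbation
#' flag (more than one exacerbation in the prior 12 months) and, when absent,
#' BMI from height and weight.
#'
#' @param data Cohort tibble of raw fields.
#' @param fh_mode Family-history coding mode, see [harmonize_family_history()].
#' @param prs_by Grouping column for PRS standardisation.
#' @return Tibble with derived columns added.
#' @export
derive_cohort <- function(data, fh_mode = "copdgene_full", prs_by = "cohort") {
  out <- data
  if (all(c("fev1_pp", "fev1_fvc") %in% names(out))) {
    out <- derive_copd_status(out)
  }
  if (any(.fh_cols %in% names(out))) {
    out <- harmonize_family_history(out, mode = fh_mode)
  }
  if ("prs_raw" %in% names(out)) out <- standardize_prs(out, by = prs_by)
  if ("exacerbations_12mo" %in% names(out)) {
    out <- mutate(out, frequent_exacerbations = .data$exacerbations_12mo > 1)
  }
  if (!"bmi" %in% names(out) && all(c("height", "weight") %in% names(out))) {
    out <- mutate(out, bmi = .data$weight / (.data$height / 100)^2)
  }
  out
}

#' Case/control characteristics table
#'
#' Summarises a derived cohort by COPD status in the style of a baseline
#' characteristics table: continuous variables as mean (SD) or median (IQR) —
#' chosen by a Shapiro-Wilk normality check at alpha = 0.05 on at most 5000
#' subsampled values per group — with t-test or Wilcoxon p-values; categorical
#' variables as count (percent of the group's non-missing n) with chi-square
#' p-values. P-values are descriptive, for reporting only.
#'
#' @param data Derived cohort tibble with a `copd_status` column.
#' @param continuous,categorical Character vectors of columns to summarise;
#'   defaults cover the standard fields and are intersected with what is
#'   present.
#' @param shapiro_alpha Normality-test significance level.
#' @param shapiro_cap Maximum group size used for the normality test.
#' @return Long tibble: one row per variable x group with `n`, `mean`, `sd`,
#'   `median`, `q1`, `q3`, `count`, `percent`, the chosen `summary_type`, and a
#'   shared `p_value`/`test` per variable.
#' @export
summarize_cohort <- function(data,
                             continuous = c("age", "bmi", "pack_years",
                                            "sgrq_total", "sixmwd", "bode",
                                            "fev1_pp", "fev1_fvc", "prs_raw",
                                            "prs_z"),
                             categorical = c("sex", "current_smoker",
                                             "family_history",
                                             "frequent_exacerbations",
                                             "severe_exacerbation", "dead",
                                             "prs_top_tertile"),
                             shapiro_alpha = 0.05, shapiro_cap = 5000) {
  if (!"copd_status" %in% names(data)) {
    abort("summarize_cohort needs a derived 'copd_status' column")
  }
  d <- filter(data, .data$copd_status %in% c("control", "case"))
  d$copd_status <- droplevels(factor(d$copd_status, levels = c("control", "case")))
  groups <- levels(d$copd_status)
  continuous <- intersect(continuous, names(d))
  categorical <- intersect(categorical, names(d))

  normal_in_group <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 4 || sd(x) == 0) return(FALSE)
    if (length(x) > shapiro_cap) x <- x[seq_len(shapiro_cap)]
    shapiro.test(x)$p.value > shapiro_alpha
  }

  cont_rows <- purrr::map_dfr(continuous, function(v) {
    xs <- split(d[[v]], d$copd_status)
    use_mean <- all(vapply(xs, normal_in_group, TRUE))
    pv <- tryCatch({
      if (all(vapply(xs, function(x) sum(!is.na(x)) >= 2, TRUE))) {
        if (use_mean) t.test(d[[v]] ~ d$copd_status)$p.value
        else suppressWarnings(wilcox.test(d[[v]] ~ d$copd_status)$p.value)
      } else NA_real_
    }, error = function(e) NA_real_)
    purrr::map_dfr(groups, function(g) {
      x <- xs[[g]][!is.na(xs[[g]])]
      tibble(
        variable = v, group = g, type = "continuous",
        summary_type = if (use_mean) "mean_sd" else "median_iqr",
        n = length(x),
        mean = if (length(x)) mean(x) else NA_real_,
        sd = if (length(x) > 1) sd(x) else NA_real_,
        median = if (length(x)) stats::median(x) else NA_real_,
        q1 = if (length(x)) quantile(x, 0.25, names = FALSE) else NA_real_,
        q3 = if (length(x)) quantile(x, 0.75, names = FALSE) else NA_real_,
        count = NA_real_, percent = NA_real_,
        p_value = pv, test = if (use_mean) "t" else "wilcoxon"
      )
    })
  })

  cat_rows <- purrr::map_dfr(categorical, function(v) {
    x <- d[[v]]
    pos <- if (is.logical(x)) x else tolower(as.character(x)) %in%
      c("male", "yes", "true", "1")
    pos[is.na(x)] <- NA
    tab <- table(d$copd_status[!is.na(pos)], pos[!is.na(pos)])
    pv <- tryCatch(
      if (all(dim(tab) == c(2, 2))) suppressWarnings(chisq.test(tab)$p.value)
      else NA_real_,
      error = function(e) NA_real_
    )
    purrr::map_dfr(groups, function(g) {
      sel <- d$copd_status == g & !is.na(pos)
      n_g <- sum(sel)
      cnt <- sum(pos[sel])
      tibble(
        variable = v, group = g, type = "categorical",
        summary_type = "count_pct",
        n = n_g, mean = NA_real_, sd = NA_real_, median = NA_real_,
        q1 = NA_real_, q3 = NA_real_,
        count = cnt,
        percent = if (n_g > 0) 100 * cnt / n_g else NA_real_,
        p_value = pv, test = "chisq"
      )
    })
  })

  bind_rows(cont_rows, cat_rows)
}
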