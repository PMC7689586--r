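# Small in-code fixtures shared across test files.

# Minimal derived cohort built from explicit cell counts: copd_status
# (case/control), family_history and top-tertile PRS flags. Covariate-free,
# for closed-form logistic oracles.
cells_cohort <- function(counts) {
  # counts: tibble with columns case (0/1), fh (0/1), prs_top (0/1), n
  rows <- counts[rep(seq_len(nrow(counts)), counts$n), ]
  tibble::tibble(
    copd_status = factor(ifelse(rows$case == 1, "case", "control"),
                         levels = c("control", "case")),
    family_history = rows$fh == 1,
    prs_top_tertile = rows$prs_top == 1
  )
}

# 2x2 exposure-outcome table as a derived cohort (no PRS).
twobytwo_cohort <- function(case_exposed, case_unexposed,
                            control_exposed, control_unexposed) {
  tibble::tibble(
    copd_status = factor(
      rep(c("case", "case", "control", "control"),
          c(case_exposed, case_unexposed, control_exposed, control_unexposed)),
      levels = c("control", "case")
    ),
    family_history = rep(c(TRUE, FALSE, TRUE, FALSE),
                         c(case_exposed, case_unexposed,
                           control_exposed, control_unexposed))
  )
}

# Standard small simulated derived cohort.
sim_derived <- function(n = 4000, seed = 1, ...) {
  derive_cohort(generate_synthetic_cohort(sim_config(n = n, seed = seed, ...)))
}

# Naive O(m*n) pairwise AUC + DeLong components, used as the enumeration
# oracle for the midrank implementation.
pairwise_delong <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  psi <- outer(cases, controls, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi),
       m = length(cases), n = length(controls))
}
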