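# Category vocabularies for the cohort tables. These are the controlled
# level sets used everywhere: readers validate against them, the generator
# samples from them, and model code reference-codes against their first level.

#' Controlled vocabularies for participant and dyad categorical fields
#'
#' Named list of character vectors giving the admissible levels of every
#' categorical column in the participant and dyad tables. The first level of
#' each vector is the modelling reference level.
#'
#' @format Named list of character vectors.
#' @export
netmmm_vocab <- list(
  gender      = c("male", "female", "hijra"),
  marital     = c("single_widowed_divorced", "married_partnered"),
  education   = c("none", "primary", "secondary_plus"),
  alcohol     = c("none", "low_moderate", "harmful", "dependence"),
  depression  = c("none_mild", "moderate_severe"),
  relationship    = c("friend", "family", "spouse_sexual", "other"),
  alter_hiv_known = c("pos", "neg", "unknown"),
  alter_hcv_known = c("pos", "neg", "unknown")
)

# Column layout of the three tables. Order is canonical: write_cohort() emits
# columns in this order so that read/write round-trips are byte-stable.
.participant_cols <- c(
  "pid", "age", "gender", "marital", "education",
  "hiv_pos", "hiv_aware_pos", "hcv_pos", "ever_hcv_test",
  "outcome_hiv_test_6m", "outcome_moud_6m", "outcome_ssp_6m",
  "homeless", "inject_daily", "nonsterile_6m", "venue40_6m",
  "prison_6m", "overdose_1y", "alcohol", "depression"
)

.participant_binary_cols <- c(
  "hiv_pos", "hiv_aware_pos", "hcv_pos", "ever_hcv_test",
  "outcome_hiv_test_6m", "outcome_moud_6m", "outcome_ssp_6m",
  "homeless", "inject_daily", "nonsterile_6m", "venue40_6m",
  "prison_6m", "overdose_1y"
)

.dyad_cols <- c(
  "ego_pid", "alter_pid", "relationship", "years_known", "trust_score",
  "support_material", "support_financial", "discuss_health",
  "inject_times_30d", "shared_equipment_30d",
  "alter_hiv_known", "alter_hcv_known"
)

.dyad_binary_cols <- c(
  "support_material", "support_financial", "discuss_health",
  "shared_equipment_30d"
)

.referral_cols <- c("coupon_id", "issuer_pid", "redeemer_pid", "returned")

.service_outcomes <- c("outcome_hiv_test_6m", "outcome_moud_6m", "outcome_ssp_6m")

.check_levels <- function(x, column, levels, table) {
  bad <- which(!is.na(x) & !(x %in% levels))
  if (length(bad)) {
    stop(sprintf(
      "%s: unknown level '%s' in column '%s' (row %d); admissible levels: %s",
      table, x[bad[1]], column, bad[1], paste(levels, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(x)
}

.check_binary <- function(x, column, table) {
  bad <- which(!is.na(x) & !(x %in% c(0L, 1L)))
  if (length(bad)) {
    stop(sprintf("%s: column '%s' must be 0/1 (row %d has '%s')",
                 table, column, bad[1], x[bad[1]]), call. = FALSE)
  }
  invisible(as.integer(x))
}
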