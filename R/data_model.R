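# Typed cohort tables and their CSV readers/writers.
#
# The pipeline exchanges three plain data.frames:
#   participants  -- one row per enrolled person (ego attributes + outcomes)
#   dyads         -- ego-reported injecting partnership characteristics
#   referrals     -- coupon issuance/redemption records (candidate edges)
# Missing data are plain NA, serialized as empty CSV cells; there are no
# numeric sentinels.

#' Validate a participant table
#'
#' Checks identifier uniqueness, the age floor (participants are adults,
#' age >= 18), binary coding, category vocabularies, and the serostatus
#' consistency rule that awareness of HIV-positive status implies a positive
#' baseline HIV test.
#'
#' @param participants Data frame with the participant columns.
#' @return The validated table, invisibly, with canonical column order and
#'   integer-coded binary columns.
#' @export
validate_participants <- function(participants) {
  missing_cols <- setdiff(.participant_cols, names(participants))
  if (length(missing_cols)) {
    stop("participants: missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  participants <- participants[, .participant_cols]
  participants$pid <- as.character(participants$pid)
  if (anyNA(participants$pid) || any(participants$pid == "")) {
    stop("participants: pid must be non-missing", call. = FALSE)
  }
  dup <- unique(participants$pid[duplicated(participants$pid)])
  if (length(dup)) {
    stop("participants: duplicate pid: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  participants$age <- as.integer(participants$age)
  if (any(!is.na(participants$age) & participants$age < 18L)) {
    stop("participants: age below 18 found (adult cohort)", call. = FALSE)
  }
  for (col in .participant_binary_cols) {
    participants[[col]] <- .check_binary(participants[[col]], col, "participants")
  }
  for (col in c("gender", "marital", "education", "alcohol", "depression")) {
    participants[[col]] <- as.character(participants[[col]])
    participants[[col]][!is.na(participants[[col]]) & participants[[col]] == ""] <- NA_character_
    .check_levels(participants[[col]], col, netmmm_vocab[[col]], "participants")
  }
  aware_neg <- !is.na(participants$hiv_aware_pos) & participants$hiv_aware_pos == 1L &
    (is.na(participants$hiv_pos) | participants$hiv_pos != 1L)
  if (any(aware_neg)) {
    stop("participants: hiv_aware_pos = 1 requires hiv_pos = 1 (pid ",
         paste(participants$pid[aware_neg], collapse = ", "), ")", call. = FALSE)
  }
  invisible(participants)
}

#' Validate a dyad-report table
#'
#' Each row is one ego-reported partnership. Pairs must be unique, an ego
#' cannot report itself as a partner, the trust scale is restricted to its
#' observed 2-10 range, and counts must be non-negative.
#'
#' @param dyads Data frame with the dyad-report columns.
#' @return The validated table, invisibly.
#' @export
validate_dyads <- function(dyads) {
  missing_cols <- setdiff(.dyad_cols, names(dyads))
  if (length(missing_cols)) {
    stop("dyads: missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dyads <- dyads[, .dyad_cols]
  dyads$ego_pid <- as.character(dyads$ego_pid)
  dyads$alter_pid <- as.character(dyads$alter_pid)
  if (any(dyads$ego_pid == dyads$alter_pid)) {
    stop("dyads: ego_pid equal to alter_pid (self-partnership)", call. = FALSE)
  }
  key <- paste(dyads$ego_pid, dyads$alter_pid, sep = "\r")
  if (anyDuplicated(key)) {
    d <- dyads[duplicated(key), , drop = FALSE]
    stop("dyads: duplicated (ego_pid, alter_pid) pair: ",
         d$ego_pid[1], " -> ", d$alter_pid[1], call. = FALSE)
  }
  dyads$trust_score <- as.integer(dyads$trust_score)
  bad_trust <- !is.na(dyads$trust_score) &
    (dyads$trust_score < 2L | dyads$trust_score > 10L)
  if (any(bad_trust)) {
    stop("dyads: trust_score outside observed range 2-10 (row ",
         which(bad_trust)[1], ")", call. = FALSE)
  }
  dyads$years_known <- as.numeric(dyads$years_known)
  if (any(!is.na(dyads$years_known) & dyads$years_known < 0)) {
    stop("dyads: negative years_known", call. = FALSE)
  }
  dyads$inject_times_30d <- as.integer(dyads$inject_times_30d)
  if (any(!is.na(dyads$inject_times_30d) & dyads$inject_times_30d < 0L)) {
    stop("dyads: negative inject_times_30d", call. = FALSE)
  }
  for (col in .dyad_binary_cols) {
    dyads[[col]] <- .check_binary(dyads[[col]], col, "dyads")
  }
  for (col in c("relationship", "alter_hiv_known", "alter_hcv_known")) {
    dyads[[col]] <- as.character(dyads[[col]])
    dyads[[col]][!is.na(dyads[[col]]) & dyads[[col]] == ""] <- NA_character_
    .check_levels(dyads[[col]], col, netmmm_vocab[[col]], "dyads")
  }
  invisible(dyads)
}

#' Validate a referral (coupon) table
#'
#' Coupon identifiers must be unique; a returned coupon must name a redeemer
#' different from its issuer; an unreturned coupon has no redeemer.
#'
#' @param referrals Data frame with the referral columns.
#' @return The validated table, invisibly.
#' @export
validate_referrals <- function(referrals) {
  missing_cols <- setdiff(.referral_cols, names(referrals))
  if (length(missing_cols)) {
    stop("referrals: missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  referrals <- referrals[, .referral_cols]
  referrals$coupon_id <- as.character(referrals$coupon_id)
  dup <- unique(referrals$coupon_id[duplicated(referrals$coupon_id)])
  if (length(dup)) {
    stop("referrals: duplicate coupon_id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  referrals$issuer_pid <- as.character(referrals$issuer_pid)
  referrals$redeemer_pid <- as.character(referrals$redeemer_pid)
  referrals$redeemer_pid[!is.na(referrals$redeemer_pid) &
                           referrals$redeemer_pid == ""] <- NA_character_
  referrals$returned <- .check_binary(referrals$returned, "returned", "referrals")
  self <- referrals$returned == 1L &
    !is.na(referrals$redeemer_pid) &
    referrals$issuer_pid == referrals$redeemer_pid
  if (any(self)) {
    stop("referrals: self-referral coupon: ",
         paste(referrals$coupon_id[self], collapse = ", "), call. = FALSE)
  }
  no_redeemer <- referrals$returned == 1L & is.na(referrals$redeemer_pid)
  if (any(no_redeemer)) {
    stop("referrals: returned coupon without redeemer_pid: ",
         paste(referrals$coupon_id[no_redeemer], collapse = ", "), call. = FALSE)
  }
  invisible(referrals)
}

#' Read a cohort from three CSV files
#'
#' Reads and validates the participant, dyad-report and referral tables.
#' Empty cells become NA; category levels are checked against
#' [netmmm_vocab]; structural invariants (unique pids, no self-partnerships,
#' serostatus-awareness consistency, trust range) raise errors naming the
#' offending row or identifier.
#'
#' @param participants_path,dyads_path,referrals_path Paths to the CSV files.
#' @param quiet Suppress the row-count message.
#' @return List with elements `participants`, `dyads`, `referrals`.
#' @export
read_cohort <- function(participants_path, dyads_path, referrals_path,
                        quiet = FALSE) {
  read1 <- function(path) {
    utils::read.csv(path, colClasses = "character", na.strings = "",
                    check.names = TRUE, fileEncoding = "UTF-8")
  }
  participants <- validate_participants(read1(participants_path))
  dyads <- validate_dyads(read1(dyads_path))
  referrals <- validate_referrals(read1(referrals_path))
  if (!quiet) {
    message(sprintf("read cohort: %d participants, %d dyad reports, %d coupons",
                    nrow(participants), nrow(dyads), nrow(referrals)))
  }
  list(participants = participants, dyads = dyads, referrals = referrals)
}

#' Write a cohort to three CSV files
#'
#' Inverse of [read_cohort()]: emits RFC-4180 CSVs with a header row, columns
#' in canonical order and NA as the empty cell, so that
#' `write_cohort(read_cohort(...))` is byte-identical to canonicalized input.
#'
#' @param cohort List with `participants`, `dyads`, `referrals` tables.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("participants.csv", "dyads.csv", "referrals.csv"))
  utils::write.csv(validate_participants(cohort$participants), paths[1],
                   row.names = FALSE, na = "", quote = FALSE, eol = "\n")
  utils::write.csv(validate_dyads(cohort$dyads), paths[2],
                   row.names = FALSE, na = "", quote = FALSE, eol = "\n")
  utils::write.csv(validate_referrals(cohort$referrals), paths[3],
                   row.names = FALSE, na = "", quote = FALSE, eol = "\n")
  invisible(paths)
}

#' Service-engagement prevalences with the serostatus-awareness exclusion
#'
#' Computes the prior-6-month prevalence (in percent) of HIV testing, MOUD
#' use and syringe-service use, plus baseline HIV seroprevalence. The HIV
#' testing denominator excludes participants already aware of their
#' HIV-positive status, since a known-positive has no indication for an HIV
#' test; the other denominators are the full cohort.
#'
#' @param participants Participant table.
#' @return Named numeric vector of percentages: `hiv_test_pct`, `moud_pct`,
#'   `ssp_pct`, `hiv_pos_pct`, plus denominators `n_total` and `n_hiv_test_denom`.
#' @export
cohort_prevalences <- function(participants) {
  participants <- validate_participants(participants)
  n <- nrow(participants)
  aware <- !is.na(participants$hiv_aware_pos) & participants$hiv_aware_pos == 1L
  eligible <- participants[!aware, , drop = FALSE]
  pct <- function(x, denom) 100 * sum(x == 1L, na.rm = TRUE) / denom
  c(
    hiv_test_pct = pct(eligible$outcome_hiv_test_6m, nrow(eligible)),
    moud_pct     = pct(participants$outcome_moud_6m, n),
    ssp_pct      = pct(participants$outcome_ssp_6m, n),
    hiv_pos_pct  = pct(participants$hiv_pos, n),
    n_total = n,
    n_hiv_test_denom = nrow(eligible)
  )
}

#' Share of network dyads with an ego-reported characterization
#'
#' Partnership characteristics are reported only by the ego who first
#' recruited the alter, so cross-network linkages discovered through
#' duplicate recruitment have no dyad report. This summarizes how much of
#' the edge set carries partnership covariates.
#'
#' @param dyads Dyad-report table.
#' @param network Sociometric network built by [build_network()].
#' @return Named vector: `n_dyads` (unique network edges), `n_reported`,
#'   `reported_pct`.
#' @export
dyad_report_coverage <- function(dyads, network) {
  n_edges <- igraph::ecount(network)
  c(n_dyads = n_edges,
    n_reported = nrow(dyads),
    reported_pct = 100 * nrow(dyads) / n_edges)
}
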