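# Cross-classified dyad-level logistic models.
#
# One row per unique ego-alter dyad with ego-reported partnership
# characteristics. The outcome is the alter's engagement in a service, the
# focal predictor is the ego's use of any HIV prevention service in the
# prior 6 months, and a binary partnership flag (duration > 1 year,
# injected together > 15 times in 30 days, or moderate/high trust) enters
# as an effect modifier:
#
#   logit P(y_ea = 1) = x_a' beta + b_f f_e + b_int f_e m_ea + v_e + r_a,
#   v_e ~ Normal(0, sigma_e^2),  r_a ~ Normal(0, sigma_a^2),
#
# with crossed (non-nested) ego and alter random intercepts, since a
# participant can serve as both ego and alter.

# Alter-level adjustment sets per outcome (a-priori + retained factors).
.dyad_covariates <- list(
  outcome_hiv_test_6m = c("age", "gender_male", "marital", "education",
                          "homeless", "ever_hcv_test", "inject_daily",
                          "venue40_6m", "prison_6m"),
  outcome_moud_6m = c("age", "gender_male", "marital", "hiv_pos", "education",
                      "ever_hcv_test", "inject_daily", "venue40_6m",
                      "alcohol"),
  outcome_ssp_6m = c("age", "gender_male", "marital", "hiv_pos", "education",
                     "homeless", "ever_hcv_test", "alcohol", "venue40_6m",
                     "depression")
)

.moderator_flags <- c("years_known_gt1", "inject_gt15", "trust_high")

#' Build a cross-classified dyad design
#'
#' Restricts to dyads carrying an ego report of the requested moderator,
#' derives the focal predictor (ego used any of the three services), the
#' moderator flag and their interaction, attaches the alter-level
#' adjustment covariates for the outcome, and indexes the crossed ego and
#' alter random intercepts. For the HIV-testing outcome, dyads whose alter
#' was already aware of a positive serostatus are excluded. Rows incomplete
#' in any retained column are dropped and counted.
#'
#' @param dyads Dyad-report table.
#' @param participants Participant table.
#' @param moderator One of `"years_known_gt1"`, `"inject_gt15"`,
#'   `"trust_high"`.
#' @param outcome Service outcome column (alter-level).
#' @return Object of class `netmmm_dyad_design`: list with `X` (includes
#'   `focal` and `focal_x_mod` columns), `y`, `ego_idx`, `alter_idx`,
#'   `ego_levels`, `alter_levels`, `moderator`, `n_dropped`.
#' @export
build_dyad_design <- function(dyads, participants, moderator,
                              outcome = "outcome_hiv_test_6m") {
  if (!moderator %in% .moderator_flags) {
    stop("build_dyad_design: moderator must be one of ",
         paste(.moderator_flags, collapse = ", "), " (got '", moderator, "')",
         call. = FALSE)
  }
  stopifnot(outcome %in% .service_outcomes)
  participants <- validate_participants(participants)
  dd <- dyad_moderators(dyads)
  n_input <- nrow(dd)
  p <- participants
  any_service <- as.integer(
    (!is.na(p$outcome_hiv_test_6m) & p$outcome_hiv_test_6m == 1L) |
      (!is.na(p$outcome_moud_6m) & p$outcome_moud_6m == 1L) |
      (!is.na(p$outcome_ssp_6m) & p$outcome_ssp_6m == 1L)
  )
  ego_row <- match(dd$ego_pid, p$pid)
  alter_row <- match(dd$alter_pid, p$pid)
  if (anyNA(ego_row) || anyNA(alter_row)) {
    stop("build_dyad_design: dyad references pid absent from participant table",
         call. = FALSE)
  }
  df <- data.frame(
    focal = any_service[ego_row],
    moderator = dd[[moderator]],
    y = p[[outcome]][alter_row],
    ego_pid = dd$ego_pid, alter_pid = dd$alter_pid,
    stringsAsFactors = FALSE
  )
  covs <- .dyad_covariates[[outcome]]
  alter_attrs <- p[alter_row, , drop = FALSE]
  df <- cbind(df, .design_columns(alter_attrs, covs))
  if (outcome == "outcome_hiv_test_6m") {
    aware <- !is.na(p$hiv_aware_pos[alter_row]) & p$hiv_aware_pos[alter_row] == 1L
    df <- df[!aware, , drop = FALSE]
  }
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  if (!nrow(df)) stop("build_dyad_design: no complete dyads", call. = FALSE)
  strata <- unique(df$moderator)
  if (length(strata) < 2L) {
    stop("build_dyad_design: all dyads fall in moderator stratum ",
         strata, "; no interaction is estimable", call. = FALSE)
  }
  cov_cols <- setdiff(names(df), c("focal", "moderator", "y",
                                   "ego_pid", "alter_pid"))
  X <- cbind(
    `(Intercept)` = 1,
    focal = df$focal,
    moderator = df$moderator,
    focal_x_mod = df$focal * df$moderator,
    as.matrix(df[, cov_cols, drop = FALSE])
  )
  pr <- prune_design(X)
  if (any(c("focal", "moderator", "focal_x_mod") %in% pr$dropped)) {
    stop("build_dyad_design: focal/moderator structure is degenerate (",
         paste(pr$dropped, collapse = ", "), ")", call. = FALSE)
  }
  if (length(pr$dropped)) {
    message("build_dyad_design: dropped inestimable column(s): ",
            paste(pr$dropped, collapse = ", "))
  }
  X <- pr$X
  ego_levels <- sort(unique(df$ego_pid))
  alter_levels <- sort(unique(df$alter_pid))
  structure(list(
    X = X, y = as.numeric(df$y),
    ego_idx = match(df$ego_pid, ego_levels),
    alter_idx = match(df$alter_pid, alter_levels),
    ego_levels = ego_levels, alter_levels = alter_levels,
    moderator = moderator, outcome = outcome,
    n_dropped = n_input - nrow(df)
  ), class = "netmmm_dyad_design")
}

#' Assemble a dyad design from bare vectors
#'
#' Low-level constructor used for simulation studies: takes the outcome,
#' focal predictor, moderator, optional extra covariate matrix and the
#' ego/alter indices directly.
#'
#' @param y Binary outcome.
#' @param focal,moderator Binary vectors.
#' @param ego_idx,alter_idx Integer level indices (1-based).
#' @param Z Optional extra covariate matrix.
#' @return A `netmmm_dyad_design`.
#' @export
dyad_design <- function(y, focal, moderator, ego_idx, alter_idx, Z = NULL) {
  stopifnot(length(y) == length(focal), length(y) == length(moderator),
            length(y) == length(ego_idx), length(y) == length(alter_idx))
  if (length(unique(moderator)) < 2L) {
    stop("dyad_design: all dyads fall in one moderator stratum", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, focal = focal, moderator = moderator,
             focal_x_mod = focal * moderator)
  if (!is.null(Z)) X <- cbind(X, Z)
  structure(list(
    X = X, y = as.numeric(y),
    ego_idx = as.integer(ego_idx), alter_idx = as.integer(alter_idx),
    ego_levels = seq_len(max(ego_idx)), alter_levels = seq_len(max(alter_idx)),
    moderator = "moderator", outcome = "y", n_dropped = 0L
  ), class = "netmmm_dyad_design")
}

#' Fit a cross-classified dyad model by MCMC
#'
#' Same sampling machinery as [fit_mmmm()] with two independent random
#' intercept vectors (ego and alter). Reports stratum-specific odds ratios
#' of the focal predictor — exp(b_focal) in the moderator = 0 stratum and
#' exp(b_focal + b_int) in the moderator = 1 stratum, both with percentile
#' intervals from the joint draws — and two-sided posterior tail evidence
#' for the interaction, 2 min(P(b_int > 0), P(b_int < 0)), in the p-value
#' slot (a Bayesian analogue of, not identical to, a frequentist
#' interaction p-value).
#'
#' @param design A `netmmm_dyad_design`.
#' @param config An [mcmc_config()].
#' @return A [fit_result()]; attribute `extra` holds the stratum summaries.
#' @export
fit_crossclassified <- function(design, config = mcmc_config()) {
  stopifnot(inherits(design, "netmmm_dyad_design"))
  n <- length(design$y)
  terms <- list(
    .re_term(as.list(design$ego_idx), as.list(rep(1, n)),
             length(design$ego_levels), config$sigma_fixed),
    .re_term(as.list(design$alter_idx), as.list(rep(1, n)),
             length(design$alter_levels), config$sigma_fixed)
  )
  run <- .run_sampler(design$y, design$X, terms, config)
  s <- run$summary
  bd <- run$beta_draws
  b_focal <- bd[, "focal"]
  b_int <- bd[, "focal_x_mod"]
  or0 <- exp(b_focal)
  or1 <- exp(b_focal + b_int)
  p_tail <- 2 * min(mean(b_int > 0), mean(b_int < 0))
  p_tail <- max(p_tail, 2 / nrow(bd))  # resolution floor of the draw count
  extra <- list(
    or_mod0 = stats::median(or0),
    or_mod0_low = stats::quantile(or0, 0.025, names = FALSE),
    or_mod0_high = stats::quantile(or0, 0.975, names = FALSE),
    or_mod1 = stats::median(or1),
    or_mod1_low = stats::quantile(or1, 0.025, names = FALSE),
    or_mod1_high = stats::quantile(or1, 0.975, names = FALSE)
  )
  res <- fit_result(
    term = rownames(s), estimate = s[, "median"],
    or_low = exp(s[, "low"]), or_high = exp(s[, "high"]),
    method = "mcmc-crossclassified", n_used = n,
    n_dropped = design$n_dropped,
    rhat = s[, "rhat"], ess = s[, "ess"],
    sigma = c(sigma_ego = unname(run$sigma_summary[1, "median"]),
              sigma_alter = unname(run$sigma_summary[2, "median"])),
    p_interaction = p_tail,
    converged = run$converged,
    extra = extra
  )
  attr(res, "draws") <- list(beta = run$beta_draws, sigma = run$sigma_draws)
  res
}
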