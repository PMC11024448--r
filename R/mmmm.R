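# Multilevel multiple-membership logistic model.
#
# Each ego's linear predictor adds a weighted sum of its direct injecting
# partners' random effects to the fixed-effects part:
#
#   logit P(y_i = 1) = x_i' beta + sum_{j in alters(i)} w_ij u_j,
#   w_ij = 1 / degree(i),   u_j ~ Normal(0, sigma_u^2).
#
# Every participant indexes a random effect u_j, because every participant
# may appear as an alter in other egos' membership sets: each undirected
# partnership induces membership in both directions, realizing the doubled
# ego/alter representation of the dyads without duplicating any outcome row.

#' Build the design for a multiple-membership model
#'
#' Applies the model's row exclusions (for the HIV-testing outcome, the
#' participants already aware of a positive serostatus), screens candidate
#' covariates, assembles fixed effects (exposure indicators + a-priori set +
#' retained candidates), drops incomplete rows, and attaches each remaining
#' ego's membership set (direct alters with weights 1/degree). The
#' random-effect index space is the full participant list: excluded or
#' incomplete participants still index a u_j because they remain alters in
#' other egos' networks. An eligible ego with no injecting partners has no
#' membership set and raises an error; filter such isolates out first.
#'
#' @param network Sociometric network.
#' @param exposures Exposure table from [build_exposures()].
#' @param participants Participant table.
#' @param spec A [model_spec()].
#' @param screened Optional precomputed screened-covariate list (skips
#'   re-screening).
#' @return Object of class `netmmm_mmmm_design`: list with `X`, `y`,
#'   `membership_idx`, `membership_w`, `re_pids`, `row_pids`, `n_dropped`,
#'   `screened`.
#' @export
build_mmmm_design <- function(network, exposures, participants, spec,
                              screened = NULL) {
  stopifnot(inherits(spec, "netmmm_model_spec"))
  participants <- validate_participants(participants)
  df <- merge(participants, exposures, by = "pid", sort = FALSE)
  n_input <- nrow(df)
  df <- .apply_exclusions(df, spec$exclusions)
  if (is.null(screened)) screened <- screen_covariates(participants, spec)
  exp_cols <- vapply(spec$exposures, `[[`, "", "name")
  covariates <- c(exp_cols, spec$a_priori, screened)
  bad <- intersect(covariates, c("venue40_cluster", "cluster"))
  if (length(bad)) {
    stop("cluster-level variables (", paste(bad, collapse = ", "),
         ") cannot be adjusted for in the multiple-membership model: they ",
         "are collinear with the individual-level covariates", call. = FALSE)
  }
  d <- build_design(df, covariates, spec$outcome)
  pr <- prune_design(d$X)
  if (length(pr$dropped)) {
    message("build_mmmm_design: dropped inestimable column(s): ",
            paste(pr$dropped, collapse = ", "))
  }
  d$X <- pr$X
  rows <- df$pid[d$keep]
  deg <- net_degree(network, rows)
  if (any(deg == 0L)) {
    stop("build_mmmm_design: eligible ego(s) with degree 0 cannot be ",
         "assigned membership sets: ",
         paste(utils::head(rows[deg == 0L], 5), collapse = ", "), call. = FALSE)
  }
  re_pids <- participants$pid
  membership <- lapply(rows, function(pp) membership_weights(network, pp))
  membership_idx <- lapply(membership, function(w) match(names(w), re_pids))
  membership_w <- lapply(membership, as.numeric)
  structure(list(
    X = d$X, y = d$y,
    membership_idx = membership_idx, membership_w = membership_w,
    re_pids = re_pids, row_pids = rows,
    n_dropped = (n_input - nrow(df)) + d$n_dropped,
    screened = screened, spec = spec
  ), class = "netmmm_mmmm_design")
}

#' Log posterior density of the multiple-membership model
#'
#' Reference implementation of the sampler's target: Bernoulli-logit
#' likelihood, Normal(0, sigma_u^2) density of the random effects,
#' Normal(0, prior_beta_sd^2) prior on the fixed effects and half-Normal
#' prior on sigma_u. Used for small-case verification of the MCMC kernel.
#'
#' @param design A `netmmm_mmmm_design`.
#' @param beta Fixed-effect vector (length `ncol(design$X)`).
#' @param u Random-effect vector (length `length(design$re_pids)`).
#' @param sigma_u Random-effect SD, > 0.
#' @param prior_beta_sd,prior_sigma_scale Prior hyperparameters.
#' @return Scalar log posterior (unnormalized).
#' @export
mmmm_log_posterior <- function(design, beta, u, sigma_u,
                               prior_beta_sd = 5, prior_sigma_scale = 2) {
  stopifnot(length(beta) == ncol(design$X),
            length(u) == length(design$re_pids), sigma_u > 0)
  if (!all(is.finite(beta)) || !all(is.finite(u)) || !is.finite(sigma_u)) {
    stop("mmmm_log_posterior: non-finite input", call. = FALSE)
  }
  eta <- as.vector(design$X %*% beta)
  for (i in seq_along(eta)) {
    eta[i] <- eta[i] + sum(design$membership_w[[i]] *
                             u[design$membership_idx[[i]]])
  }
  log1pexp <- function(x) ifelse(x > 35, x, log1p(exp(pmin(x, 35))))
  ll <- sum(design$y * eta - log1pexp(eta))
  lp_u <- sum(stats::dnorm(u, 0, sigma_u, log = TRUE))
  lp_beta <- sum(stats::dnorm(beta, 0, prior_beta_sd, log = TRUE))
  lp_sigma <- stats::dnorm(sigma_u, 0, prior_sigma_scale, log = TRUE)
  ll + lp_u + lp_beta + lp_sigma
}

#' Fit a multiple-membership model by MCMC
#'
#' Adaptive Metropolis-within-Gibbs sampling of (beta, u, sigma_u).
#' Adjusted odds ratios are posterior medians of exp(beta) with 2.5/97.5
#' percentile intervals; per-term split-chain R-hat and effective sample
#' size are reported and the fit is flagged non-converged when any R-hat
#' exceeds the configured threshold (the result is still returned).
#'
#' @param design A `netmmm_mmmm_design` from [build_mmmm_design()].
#' @param config An [mcmc_config()].
#' @return A [fit_result()]; attributes `draws` (named list of beta / sigma
#'   / u draw matrices), `sigma` (posterior median of sigma_u), `screened`.
#' @export
fit_mmmm <- function(design, config = mcmc_config()) {
  stopifnot(inherits(design, "netmmm_mmmm_design"))
  if (nrow(design$X) == 0) stop("fit_mmmm: empty design", call. = FALSE)
  term <- .re_term(design$membership_idx, design$membership_w,
                   length(design$re_pids), config$sigma_fixed)
  run <- .run_sampler(design$y, design$X, list(term), config)
  s <- run$summary
  res <- fit_result(
    term = rownames(s), estimate = s[, "median"],
    or_low = exp(s[, "low"]), or_high = exp(s[, "high"]),
    method = "mcmc-mmmm", n_used = nrow(design$X),
    n_dropped = design$n_dropped,
    rhat = s[, "rhat"], ess = s[, "ess"],
    sigma = c(sigma_u = unname(run$sigma_summary[1, "median"])),
    converged = run$converged
  )
  attr(res, "draws") <- list(beta = run$beta_draws, sigma = run$sigma_draws,
                             u = run$u_draws)
  attr(res, "screened") <- design$screened
  attr(res, "beta_accept") <- run$beta_accept
  res
}
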