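# Logistic regression engine and covariate screening.
#
# The egocentric models are ordinary logistic regressions fit by iteratively
# reweighted least squares (IRLS), with Wald 95% intervals. Covariate
# screening follows the analysis plan: the a-priori adjustment set (age,
# gender, marital status, education, log network size) is always retained;
# each remaining candidate is screened univariably and kept when its Wald
# p-value is below 0.10.

#' Declare a model specification
#'
#' @param outcome Binary participant outcome column.
#' @param exposures List of [exposure_spec()] objects entering the model.
#' @param a_priori Covariates always retained. `"age"`, `"gender_male"`
#'   (male versus non-male), `"marital"`, `"education"` plus the log network
#'   size appropriate to the exposure scope (`"log_degree"` for direct
#'   exposures, `"log_proximal_size_1_3"` / `"log_proximal_size_2_3"` for
#'   proximal scopes).
#' @param candidates Covariates screened at `screen_alpha`.
#' @param screen_alpha Screening threshold (default 0.10).
#' @param exclusions Named list; rows where `field == value` are dropped
#'   before fitting. For the HIV-testing outcome the default drops the
#'   participants already aware of their HIV-positive serostatus.
#' @return Object of class `netmmm_model_spec`.
#' @export
model_spec <- function(outcome,
                       exposures = list(),
                       a_priori = c("age", "gender_male", "marital",
                                    "education", "log_degree"),
                       candidates = c("homeless", "inject_daily",
                                      "nonsterile_6m", "venue40_6m",
                                      "prison_6m", "overdose_1y", "alcohol",
                                      "depression", "ever_hcv_test",
                                      "hcv_pos", "hiv_pos"),
                       screen_alpha = 0.10,
                       exclusions = NULL) {
  stopifnot(screen_alpha > 0, screen_alpha < 1)
  if (inherits(exposures, "netmmm_exposure_spec")) exposures <- list(exposures)
  candidates <- setdiff(candidates, c(a_priori, outcome))
  if (outcome %in% a_priori) {
    stop("model_spec: outcome cannot be a covariate", call. = FALSE)
  }
  if (is.null(exclusions) && outcome == "outcome_hiv_test_6m") {
    exclusions <- list(hiv_aware_pos = 1L)
  }
  structure(list(outcome = outcome, exposures = exposures,
                 a_priori = a_priori, candidates = candidates,
                 screen_alpha = screen_alpha, exclusions = exclusions),
            class = "netmmm_model_spec")
}

.apply_exclusions <- function(df, exclusions) {
  if (is.null(exclusions)) return(df)
  keep <- rep(TRUE, nrow(df))
  for (field in names(exclusions)) {
    keep <- keep & !(!is.na(df[[field]]) & df[[field]] == exclusions[[field]])
  }
  df[keep, , drop = FALSE]
}

# Expand covariate names into design columns. Categorical columns are
# reference-coded against the first vocabulary level; "gender_male" is the
# binary male-vs-non-male modelling covariate; anything else must already be
# a numeric/binary column of `df`.
.design_columns <- function(df, covariates) {
  cols <- list()
  for (cv in covariates) {
    if (cv == "gender_male") {
      cols[["gender_male"]] <- as.numeric(df$gender == "male")
    } else if (cv %in% names(netmmm_vocab) &&
               cv %in% c("marital", "education", "alcohol", "depression",
                         "gender", "relationship")) {
      lv <- netmmm_vocab[[cv]]
      x <- df[[cv]]
      for (l in lv[-1]) {
        cols[[paste(cv, l, sep = "_")]] <-
          ifelse(is.na(x), NA_real_, as.numeric(x == l))
      }
    } else if (cv %in% names(df)) {
      cols[[cv]] <- as.numeric(df[[cv]])
    } else {
      stop("unknown covariate '", cv, "'", call. = FALSE)
    }
  }
  cols
}

#' Assemble a complete-case design matrix
#'
#' @param df Data frame holding covariate columns (participants merged with
#'   the exposure table as needed).
#' @param covariates Covariate names (see [.design_columns] conventions).
#' @param outcome Outcome column name.
#' @return List: `X` (with intercept), `y`, `keep` (logical complete-case
#'   mask over rows of `df`), `n_dropped`.
#' @export
build_design <- function(df, covariates, outcome) {
  cols <- .design_columns(df, covariates)
  X <- cbind(`(Intercept)` = rep(1, nrow(df)), do.call(cbind, cols))
  y <- as.numeric(df[[outcome]])
  keep <- stats::complete.cases(X) & !is.na(y)
  list(X = X[keep, , drop = FALSE], y = y[keep], keep = keep,
       n_dropped = sum(!keep))
}

# Remove non-intercept columns that cannot be estimated: constants (a
# category level or binary state unobserved in this subset) and aliased
# columns (QR rank deficiency). Returns the pruned matrix and the names
# dropped. Routine for small cohorts where rare levels vanish.
prune_design <- function(X) {
  dropped <- character(0)
  repeat {
    keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2,
                          function(v) length(unique(v)) > 1))
    if (!all(keep)) {
      dropped <- c(dropped, colnames(X)[!keep])
      X <- X[, keep, drop = FALSE]
    }
    q <- qr(X)
    if (q$rank == ncol(X)) break
    alias <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    dropped <- c(dropped, alias)
    X <- X[, setdiff(colnames(X), alias), drop = FALSE]
  }
  list(X = X, dropped = dropped)
}

# Fit, recovering from (quasi-)separation by dropping implicated columns
# when they belong to the droppable set; anything else rethrows.
.fit_logistic_robust <- function(X, y, droppable) {
  dropped <- character(0)
  repeat {
    fit <- tryCatch(fit_logistic(X, y), error = function(e) e)
    if (!inherits(fit, "error")) {
      attr(fit, "cols_dropped") <- dropped
      return(fit)
    }
    cand <- intersect(fit$offenders %||% character(0), droppable)
    if (inherits(fit, "netmmm_separation") && length(cand) &&
        ncol(X) > length(cand)) {
      dropped <- c(dropped, cand)
      X <- X[, setdiff(colnames(X), cand), drop = FALSE]
      next
    }
    stop(fit)
  }
}

#' Fit a logistic regression by IRLS
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares, converging when the deviance changes by less than `tol`
#' (default 1e-8) or after `max_iter` iterations. Supports grouped binomial
#' data through `weights` (number of trials per row, with `y` the success
#' proportion). A separation guard aborts, naming the offending column,
#' when any coefficient exceeds 15 on the logit scale; rank-deficient
#' designs are refused.
#'
#' @param X Design matrix including the intercept column.
#' @param y Binary response (or success proportion when `weights` given).
#' @param weights Optional trials per row (grouped data).
#' @param tol Deviance convergence tolerance.
#' @param max_iter Iteration cap.
#' @return A [fit_result()] with Wald 95% intervals, plus attribute
#'   `vcov` and component columns `se` and `p_value`.
#' @export
fit_logistic <- function(X, y, weights = NULL, tol = 1e-8, max_iter = 100L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (is.null(weights)) weights <- rep(1, n)
  if (n == 0 || sum(weights) <= p) {
    stop("fit_logistic: not enough observations (n = ", sum(weights),
         ", p = ", p, ")", call. = FALSE)
  }
  qrX <- qr(X)
  if (qrX$rank < p) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("fit_logistic: rank-deficient design; aliased column(s): ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  beta <- rep(0, p)
  dev_old <- Inf
  for (iter in seq_len(max_iter)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    w <- weights * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    fit <- stats::lm.wfit(X, z, w)
    beta <- fit$coefficients
    # guard against separation once past the initial transient: coefficients
    # of a separated fit grow without bound while a stable fit settles
    if (iter >= 4L && any(abs(beta) > 15)) {
      off <- which(abs(beta) > 15)
      non_int <- off[colnames(X)[off] != "(Intercept)"]
      worst <- if (length(non_int)) {
        colnames(X)[non_int[which.max(abs(beta)[non_int])]]
      } else {
        colnames(X)[which.max(abs(beta))]
      }
      # every strongly diverging column is implicated; a quasi-separated
      # indicator typically drags the intercept with it
      offenders <- colnames(X)[abs(beta) > 10]
      stop(errorCondition(
        paste0("fit_logistic: apparent separation; coefficient for '", worst,
               "' diverged beyond 15 on the logit scale"),
        class = "netmmm_separation", offenders = offenders))
    }
    eta <- as.vector(X %*% beta)
    mu <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
    dev <- -2 * sum(weights * (y * log(mu) + (1 - y) * log(1 - mu)))
    if (abs(dev_old - dev) < tol) break
    dev_old <- dev
  }
  mu <- pmin(pmax(stats::plogis(as.vector(X %*% beta)), 1e-12), 1 - 1e-12)
  W <- weights * mu * (1 - mu)
  info <- crossprod(X * sqrt(W))
  vc <- solve(info)
  se <- sqrt(diag(vc))
  zval <- beta / se
  pval <- 2 * stats::pnorm(-abs(zval))
  res <- fit_result(
    term = colnames(X), estimate = beta,
    or_low = exp(beta - 1.959963984540054 * se),
    or_high = exp(beta + 1.959963984540054 * se),
    method = "irls", n_used = n
  )
  res$se <- se
  res$p_value <- pval
  attr(res, "vcov") <- vc
  attr(res, "deviance") <- dev
  attr(res, "iterations") <- iter
  res
}

#' Screen candidate covariates against an outcome
#'
#' For each candidate, fits a univariable logistic regression of the
#' outcome on that candidate alone (after the model's row exclusions) and
#' retains it when the Wald p-value is below `screen_alpha`; for
#' categorical candidates, when any level's indicator is below the
#' threshold. Candidates that are constant in the data are skipped with a
#' warning; a candidate that separates the outcome perfectly is retained
#' (the association is as strong as it gets). Output order follows the
#' candidate list, so selection is deterministic.
#'
#' @param participants Participant table.
#' @param spec A [model_spec()].
#' @return Character vector of retained candidate names.
#' @export
screen_covariates <- function(participants, spec) {
  stopifnot(inherits(spec, "netmmm_model_spec"))
  df <- .apply_exclusions(validate_participants(participants), spec$exclusions)
  keep <- character(0)
  for (cand in spec$candidates) {
    cols <- tryCatch(.design_columns(df, cand), error = function(e) NULL)
    if (is.null(cols)) {
      warning("screen_covariates: unknown candidate '", cand, "' skipped")
      next
    }
    d <- build_design(df, cand, spec$outcome)
    if (nrow(d$X) == 0 || any(apply(d$X[, -1, drop = FALSE], 2,
                                    function(v) length(unique(v)) < 2))) {
      warning("screen_covariates: candidate '", cand,
              "' is constant in the data; skipped")
      next
    }
    fit <- tryCatch(fit_logistic(d$X, d$y), error = function(e) e)
    if (inherits(fit, "error")) {
      if (grepl("separation", conditionMessage(fit))) {
        keep <- c(keep, cand)  # perfect association: retain
        next
      }
      warning("screen_covariates: candidate '", cand, "' failed: ",
              conditionMessage(fit))
      next
    }
    pv <- fit$p_value[fit$term != "(Intercept)"]
    if (any(pv < spec$screen_alpha)) keep <- c(keep, cand)
  }
  keep
}

#' Fit an egocentric network-exposure logistic model
#'
#' Implements the egocentric analysis path: applies the model's row
#' exclusions, screens candidate covariates, assembles the design from the
#' a-priori set, retained candidates and the exposure columns, drops
#' incomplete rows, and fits by IRLS.
#'
#' @param participants Participant table.
#' @param exposures Exposure table from [build_exposures()] (must contain
#'   every exposure column and the log-size column named in the spec).
#' @param spec A [model_spec()].
#' @return A [fit_result()]; attribute `screened` lists retained candidates.
#' @export
fit_ego <- function(participants, exposures, spec) {
  stopifnot(inherits(spec, "netmmm_model_spec"))
  participants <- validate_participants(participants)
  df <- merge(participants, exposures, by = "pid", sort = FALSE)
  n_input <- nrow(df)
  df <- .apply_exclusions(df, spec$exclusions)
  n_excluded <- n_input - nrow(df)
  screened <- screen_covariates(participants, spec)
  exp_cols <- vapply(spec$exposures, `[[`, "", "name")
  missing_exp <- setdiff(exp_cols, names(df))
  if (length(missing_exp)) {
    stop("fit_ego: exposure column(s) absent from exposure table: ",
         paste(missing_exp, collapse = ", "), call. = FALSE)
  }
  covariates <- c(exp_cols, spec$a_priori, screened)
  d <- build_design(df, covariates, spec$outcome)
  pr <- prune_design(d$X)
  if (length(pr$dropped)) {
    message("fit_ego: dropped inestimable column(s): ",
            paste(pr$dropped, collapse = ", "))
  }
  # a quasi-separated adjustment covariate (screened or a-priori) is
  # inestimable in this subset and is dropped with a message; the exposure
  # of interest is never dropped — its separation is a hard error
  droppable <- names(.design_columns(df, c(spec$a_priori, screened)))
  fit <- .fit_logistic_robust(pr$X, d$y, droppable)
  if (length(attr(fit, "cols_dropped"))) {
    message("fit_ego: dropped separating adjustment column(s): ",
            paste(attr(fit, "cols_dropped"), collapse = ", "))
  }
  attr(fit, "n_dropped") <- n_excluded + d$n_dropped
  attr(fit, "screened") <- screened
  attr(fit, "method") <- "irls-ego"
  fit
}
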