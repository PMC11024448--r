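# MCMC configuration and convergence diagnostics shared by the
# multiple-membership and cross-classified models.

#' MCMC configuration
#'
#' @param n_chains Number of independent chains.
#' @param n_warmup Adaptation iterations discarded per chain.
#' @param n_draws Retained draws per chain.
#' @param seed RNG seed; each chain derives its own stream.
#' @param prior_beta_sd SD of the Normal(0, sd^2) prior on fixed effects.
#' @param prior_sigma_scale Scale of the half-Normal prior on random-effect
#'   SDs.
#' @param rhat_threshold Fit is flagged non-converged when any split-chain
#'   R-hat exceeds this.
#' @param sigma_fixed Optional fixed value for the random-effect SD(s)
#'   instead of sampling them; `0` collapses the model to plain logistic
#'   regression (the random effects drop out).
#' @param save_u Retain the per-level random-effect draws (memory-heavy for
#'   large cohorts).
#' @return Object of class `netmmm_mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4L, n_warmup = 1000L, n_draws = 1000L,
                        seed = 1L, prior_beta_sd = 5, prior_sigma_scale = 2,
                        rhat_threshold = 1.05, sigma_fixed = NULL,
                        save_u = FALSE) {
  stopifnot(n_chains >= 1L, n_warmup >= 1L, n_draws >= 1L,
            prior_beta_sd > 0, prior_sigma_scale > 0, rhat_threshold > 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_warmup = as.integer(n_warmup),
                 n_draws = as.integer(n_draws), seed = as.integer(seed),
                 prior_beta_sd = prior_beta_sd,
                 prior_sigma_scale = prior_sigma_scale,
                 rhat_threshold = rhat_threshold,
                 sigma_fixed = sigma_fixed, save_u = isTRUE(save_u)),
            class = "netmmm_mcmc_config")
}

#' Split-chain potential scale reduction factor
#'
#' Each chain is split in half and the classical between/within variance
#' ratio is computed over the resulting sequences.
#'
#' @param draws Matrix of draws, one column per chain.
#' @return R-hat (scalar).
#' @export
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  seqs <- cbind(draws[seq_len(half), , drop = FALSE],
                draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(seqs); nn <- nrow(seqs)
  mu <- colMeans(seqs)
  s2 <- apply(seqs, 2, stats::var)
  W <- mean(s2)
  B <- nn * stats::var(mu)
  if (W < 1e-300) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Effective sample size across chains
#'
#' Combined autocorrelation-based ESS with Geyer's initial positive
#' sequence truncation, using within-chain autocovariances and the
#' split-chain variance estimate.
#'
#' @param draws Matrix of draws, one column per chain.
#' @return Effective sample size (scalar).
#' @export
ess_mean <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws); m <- ncol(draws)
  if (n < 4) return(NA_real_)
  s2 <- apply(draws, 2, stats::var)
  W <- mean(s2)
  mu <- colMeans(draws)
  var_plus <- (n - 1) / n * W + (if (m > 1) stats::var(mu) else 0)
  if (var_plus < 1e-300) return(n * m)
  max_lag <- min(n - 2, 1000L)
  acov <- sapply(seq_len(m), function(c) {
    a <- stats::acf(draws[, c], lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  })
  rho <- 1 - (W - rowMeans(as.matrix(acov))[-1]) / var_plus
  # Geyer: sum consecutive pairs while their sum stays positive
  tau <- 1
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2
  }
  max(n * m / tau, 1)
}

# Convert a per-row membership structure (list of integer level vectors and
# matching weight vectors) to the CSR layout the C++ sampler expects.
.re_term <- function(idx_list, w_list, n_levels, sigma_fixed = NULL) {
  lens <- lengths(idx_list)
  list(
    row_ptr = as.integer(c(0L, cumsum(lens))),
    idx = as.integer(unlist(idx_list, use.names = FALSE) - 1L),
    w = as.numeric(unlist(w_list, use.names = FALSE)),
    n_levels = as.integer(n_levels),
    sigma_fixed = if (is.null(sigma_fixed)) NA_real_ else as.numeric(sigma_fixed)
  )
}

# Run the sampler and assemble per-parameter summaries.
# Returns list(beta_draws [draws x p x chains collapsed row-wise],
#              summaries data frame, sigma summaries, converged flag).
.run_sampler <- function(y, X, re_terms, config) {
  X <- as.matrix(X)
  p <- ncol(X)
  # initialize at the fixed-effects-only MLE with its Wald covariance as the
  # proposal shape; fall back to a conservative diagonal when IRLS fails
  # (separation, rank issues)
  init <- tryCatch({
    f <- fit_logistic(X, as.numeric(y))
    list(beta = f$estimate, cov = attr(f, "vcov"))
  }, error = function(e) {
    list(beta = rep(0, p),
         cov = solve(crossprod(X) / 4 + diag(1e-6, p)))
  })
  chains <- .mm_logit_mcmc(
    as.numeric(y), X, re_terms,
    config$n_chains, config$n_warmup, config$n_draws,
    config$prior_beta_sd, config$prior_sigma_scale,
    config$seed, config$save_u,
    as.numeric(init$beta), as.matrix(init$cov)
  )
  p <- ncol(X); K <- length(re_terms)
  beta_cube <- lapply(chains, `[[`, "beta")
  sigma_cube <- lapply(chains, `[[`, "sigma")
  per_param <- function(cube, j) sapply(cube, function(mm) mm[, j])
  beta_all <- do.call(rbind, beta_cube)
  colnames(beta_all) <- colnames(X)
  summ <- lapply(seq_len(p), function(j) {
    d <- per_param(beta_cube, j)
    c(median = stats::median(d), low = stats::quantile(d, 0.025, names = FALSE),
      high = stats::quantile(d, 0.975, names = FALSE),
      rhat = split_rhat(d), ess = ess_mean(d))
  })
  summ <- do.call(rbind, summ)
  rownames(summ) <- colnames(X)
  sig_summ <- NULL
  free_sigma <- vapply(re_terms, function(t) is.na(t$sigma_fixed), TRUE)
  if (K > 0) {
    sig_summ <- lapply(seq_len(K), function(k) {
      d <- per_param(sigma_cube, k)
      c(median = stats::median(d), rhat = if (free_sigma[k]) split_rhat(d) else 1,
        ess = if (free_sigma[k]) ess_mean(d) else NA_real_)
    })
    sig_summ <- do.call(rbind, sig_summ)
  }
  rhats <- c(summ[, "rhat"], if (!is.null(sig_summ)) sig_summ[free_sigma, "rhat"])
  list(
    beta_draws = beta_all,
    sigma_draws = do.call(rbind, sigma_cube),
    u_draws = if (config$save_u) do.call(rbind, lapply(chains, `[[`, "u")),
    summary = summ,
    sigma_summary = sig_summ,
    beta_accept = mean(vapply(chains, `[[`, 0, "beta_accept")),
    converged = all(rhats < config$rhat_threshold, na.rm = TRUE)
  )
}
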