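test_that("membership design rows, weights and exclusions are correct", {
  p <- make_participants(6, pid = c("E1", "E2", "A", "B", "C", "Z"),
                         hiv_pos = c(0L, 1L, 0L, 0L, 0L, 0L),
                         hiv_aware_pos = c(0L, 1L, 0L, 0L, 0L, 0L))
  rf <- make_referrals(c("E1", "E1", "E2", "A", "B"),
                       c("A", "B", "C", "Z", "C"))
  g <- build_network(rf, p)
  ex <- build_exposures(g, p, exposure_spec("nonsterile_6m", "direct"))
  sp <- model_spec("outcome_hiv_test_6m",
                   exposures = list(exposure_spec("nonsterile_6m", "direct")),
                   candidates = character(0))
  des <- build_mmmm_design(g, ex, p, sp)
  # E2 is aware-positive: excluded from rows but still indexes a random effect
  expect_false("E2" %in% des$row_pids)
  expect_true("E2" %in% des$re_pids)
  expect_equal(nrow(des$X), 5)
  # E1 has 2 alters with weights 1/2 each
  i <- which(des$row_pids == "E1")
  expect_setequal(des$re_pids[des$membership_idx[[i]]], c("A", "B"))
  expect_equal(des$membership_w[[i]], c(0.5, 0.5))
  # union of memberships = participants that appear as alters
  members <- unique(des$re_pids[unlist(des$membership_idx)])
  deg <- net_degree(g, p$pid)
  expect_setequal(members,
                  intersect(p$pid[deg >= 1],
                            unique(unlist(lapply(des$row_pids, function(e)
                              names(membership_weights(g, e)))))))
})

test_that("an eligible ego with no partners is refused", {
  p <- make_participants(4, pid = c("A", "B", "C", "iso"),
                         age = c(20L, 25L, 30L, 35L),
                         outcome_moud_6m = c(1L, 0L, 1L, 0L))
  g <- build_network(make_referrals(c("A", "B"), c("B", "C")), p)
  ex <- build_exposures(g, p, exposure_spec("nonsterile_6m", "direct"))
  # no exposure covariate, so the isolate survives complete-case filtering
  # and must be refused for lack of a membership set
  sp <- model_spec("outcome_moud_6m", exposures = list(),
                   a_priori = "age", candidates = character(0))
  expect_error(build_mmmm_design(g, ex, p, sp), "degree 0")
})

test_that("log posterior matches a hand-expanded computation", {
  p <- make_participants(4, pid = c("E", "A", "B", "C"),
                         nonsterile_6m = c(0L, 0L, 1L, 0L))
  p$outcome_moud_6m <- c(1L, 0L, 1L, 0L)
  rf <- make_referrals(c("E", "A", "B"), c("A", "B", "C"))  # path E-A-B-C
  g <- build_network(rf, p)
  ex <- build_exposures(g, p, exposure_spec("nonsterile_6m", "direct"))
  sp <- model_spec("outcome_moud_6m",
                   exposures = list(exposure_spec("nonsterile_6m", "direct")),
                   a_priori = "log_degree", candidates = character(0))
  des <- build_mmmm_design(g, ex, p, sp)
  expect_equal(ncol(des$X), 3)  # intercept + exposure + log_degree survive
  beta <- c(0.3, -0.2, 0.1)
  u <- c(0.5, -0.4, 0.2, -0.1)
  sigma_u <- 0.8
  # hand expansion row by row
  eta <- as.vector(des$X %*% beta)
  for (i in seq_along(eta)) {
    eta[i] <- eta[i] + sum(des$membership_w[[i]] * u[des$membership_idx[[i]]])
  }
  by_hand <- sum(des$y * eta - log(1 + exp(eta))) +
    sum(dnorm(u, 0, sigma_u, log = TRUE)) +
    sum(dnorm(beta, 0, 5, log = TRUE)) +
    dnorm(sigma_u, 0, 2, log = TRUE)
  expect_equal(mmmm_log_posterior(des, beta, u, sigma_u), by_hand,
               tolerance = 1e-10)
  # invariant under permutation of each membership list
  des2 <- des
  des2$membership_idx <- lapply(des$membership_idx, rev)
  des2$membership_w <- lapply(des$membership_w, rev)
  expect_equal(mmmm_log_posterior(des2, beta, u, sigma_u),
               mmmm_log_posterior(des, beta, u, sigma_u), tolerance = 1e-12)
  # weight renormalization invariance: scaling then renormalizing is identity
  des3 <- des
  des3$membership_w <- lapply(des$membership_w, function(w) 7 * w / sum(7 * w))
  expect_equal(mmmm_log_posterior(des3, beta, u, sigma_u),
               mmmm_log_posterior(des, beta, u, sigma_u), tolerance = 1e-12)
  expect_error(mmmm_log_posterior(des, beta, u, -1), "sigma_u > 0")
  expect_error(mmmm_log_posterior(des, c(Inf, 0, 0), u, 1), "non-finite")
})

test_that("MCMC posterior matches dense-grid quadrature on a 2-level design", {
  set.seed(9)
  n <- 30
  x <- rbinom(n, 1, .5)
  idx <- lapply(seq_len(n), function(i) {
    if (i %% 3 == 0) c(1L, 2L) else if (i %% 3 == 1) 1L else 2L
  })
  w <- lapply(idx, function(ii) rep(1 / length(ii), length(ii)))
  eta_true <- -0.3 + 0.9 * x +
    vapply(seq_len(n), function(i) sum(w[[i]] * c(0.8, -0.5)[idx[[i]]]), 0)
  y <- rbinom(n, 1, plogis(eta_true))
  X <- cbind(`(Intercept)` = 1, x = x)
  sig <- 1.0
  # dense-grid posterior over (b0, b1, u1, u2), sigma fixed; rows grouped by
  # (x, membership pattern) so the grid evaluation is exact and fast
  pat <- vapply(idx, paste, "", collapse = "+")
  gl <- split(seq_len(n), interaction(x, pat, drop = TRUE))
  gr <- seq(-4, 4, length.out = 41)
  G <- as.matrix(expand.grid(b0 = gr, b1 = gr, u1 = gr, u2 = gr))
  lp <- dnorm(G[, 1], 0, 5, log = TRUE) + dnorm(G[, 2], 0, 5, log = TRUE) +
    dnorm(G[, 3], 0, sig, log = TRUE) + dnorm(G[, 4], 0, sig, log = TRUE)
  for (rows in gl) {
    i1 <- rows[1]
    m <- if (length(idx[[i1]]) == 2) 0.5 * (G[, 3] + G[, 4])
         else if (idx[[i1]] == 1L) G[, 3] else G[, 4]
    e <- G[, 1] + G[, 2] * x[i1] + m
    lp <- lp + sum(y[rows]) * e - length(rows) * ifelse(e > 30, e, log1p(exp(e)))
  }
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  oracle <- c(b0 = sum(pr * G[, 1]), b1 = sum(pr * G[, 2]),
              u1 = sum(pr * G[, 3]))
  term <- netmmm:::.re_term(idx, w, 2L, sig)
  run <- netmmm:::.run_sampler(y, X, list(term),
    mcmc_config(n_chains = 4, n_warmup = 2000, n_draws = 4000, seed = 8,
                sigma_fixed = sig, save_u = TRUE))
  mcse <- function(v) sd(v) / sqrt(ess_mean(matrix(v, ncol = 4)))
  b <- run$beta_draws
  expect_lt(abs(mean(b[, 1]) - oracle["b0"]), 3 * mcse(b[, 1]) + 0.02)
  expect_lt(abs(mean(b[, 2]) - oracle["b1"]), 3 * mcse(b[, 2]) + 0.02)
  expect_lt(abs(mean(run$u_draws[, 1]) - oracle["u1"]),
            3 * mcse(run$u_draws[, 1]) + 0.02)
})

test_that("sigma fixed at 0 reduces the MMMM to plain logistic regression", {
  # dense covariates only, so prior shrinkage on sparse levels cannot blur
  # the comparison
  fx <- make_mechanistic_fixture(n = 800, seed = 51, sigma_u = 0,
                                 a_priori = c("age", "log_degree"))
  des <- build_mmmm_design(fx$sim$network, fx$exps,
                           fx$sim$cohort$participants, fx$spec)
  fit_b <- fit_mmmm(des, mcmc_config(n_warmup = 1500, n_draws = 1500,
                                     seed = 2, sigma_fixed = 0))
  fit_g <- fit_logistic(des$X, des$y)
  expect_equal(fit_b$estimate, fit_g$estimate, tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("one-alter-per-ego topology agrees with a two-level random-intercept fit", {
  skip_if_not_installed("lme4")
  set.seed(4)
  n <- 1500; m <- 200
  grp <- sample.int(m, n, replace = TRUE)
  u <- rnorm(m, 0, 0.8)
  x <- rbinom(n, 1, .5)
  y <- rbinom(n, 1, plogis(-0.8 + 0.7 * x + u[grp]))
  X <- cbind(`(Intercept)` = 1, x = x)
  term <- netmmm:::.re_term(as.list(grp), as.list(rep(1, n)), m)
  run <- netmmm:::.run_sampler(y, X, list(term),
    mcmc_config(n_chains = 4, n_warmup = 2000, n_draws = 2000, seed = 6))
  ref <- lme4::glmer(y ~ x + (1 | grp), family = binomial, nAGQ = 10)
  expect_equal(unname(run$summary[, "median"]),
               unname(lme4::fixef(ref)), tolerance = 0.08)
  expect_equal(unname(run$sigma_summary[1, "median"]),
               unname(sqrt(unlist(lme4::VarCorr(ref)))), tolerance = 0.15)
})

test_that("null data give a credible interval covering OR = 1", {
  fx <- make_mechanistic_fixture(
    n = 1000, seed = 71, sigma_u = 0,
    beta = c(`(Intercept)` = -1, any_nonsterile_6m = 0))
  des <- build_mmmm_design(fx$sim$network, fx$exps,
                           fx$sim$cohort$participants, fx$spec)
  fit <- fit_mmmm(des, mcmc_config(n_warmup = 1500, n_draws = 1000, seed = 3))
  i <- fit$term == "any_nonsterile_6m_direct"
  expect_true(fit$or_low[i] < 1 && fit$or_high[i] > 1)
})

test_that("cluster-level adjustment is refused with an explanation", {
  fx <- make_mechanistic_fixture(n = 300, seed = 81)
  sp <- fx$spec
  sp$a_priori <- c(sp$a_priori, "cluster")
  expect_error(
    build_mmmm_design(fx$sim$network, fx$exps, fx$sim$cohort$participants, sp),
    "cluster-level"
  )
})
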