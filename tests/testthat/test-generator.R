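test_that("degenerate configurations give the expected topologies", {
  # no coupons at all: isolated seeds only
  cfg <- generator_config(n_target = 10, n_seeds = 10,
                          coupon_probs = c(1, rep(0, 6)),
                          p_duplicate_recruit = 0, seed = 1)
  sim <- simulate_recruitment(cfg)
  g <- build_network(sim$referrals, sim$participants)
  expect_equal(igraph::vcount(g), 10)
  expect_equal(igraph::ecount(g), 0)
  # one seed, exactly one always-returned coupon each: a path graph
  cfg <- generator_config(n_target = 5, n_seeds = 1,
                          coupon_probs = c(0, 1, rep(0, 5)),
                          p_coupon_return = 1, p_duplicate_recruit = 0,
                          reseed = FALSE, seed = 1)
  sim <- simulate_recruitment(cfg)
  g <- build_network(sim$referrals, sim$participants)
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 4)
  expect_equal(sort(unname(igraph::degree(g))), c(1, 1, 2, 2, 2))
})

test_that("recruitment extinction without reseeding raises the suggested fix", {
  cfg <- generator_config(n_target = 500, n_seeds = 2,
                          coupon_probs = c(0.9, 0.1, rep(0, 5)),
                          reseed = FALSE, seed = 4)
  expect_error(simulate_recruitment(cfg), "coupon")
})

test_that("generated cohorts reproduce the configured recruitment statistics", {
  cfg <- generator_config(seed = 20)  # defaults: n = 2512, 10 seeds
  sim <- simulate_recruitment(cfg)
  expect_equal(nrow(sim$participants), 2512)
  # coupon return fraction within 3 points of the configured 75%
  expect_lt(abs(mean(sim$referrals$returned) - 0.75), 0.03)
  g <- build_network(sim$referrals, sim$participants)
  ds <- degree_summary(g)
  expect_true(ds["median"] %in% c(1, 2, 3))
  expect_lte(ds["q75"], 5)
  # every non-seed is linked to at least one recruiter
  expect_lte(ds["n_isolates"], cfg$n_seeds)
  # dyad reports: one per first-recruitment edge, unique, from the recruiter
  expect_equal(anyDuplicated(sim$dyads[, c("ego_pid", "alter_pid")]), 0L)
  expect_lte(nrow(sim$dyads), igraph::ecount(g))
})

test_that("identical config and seed give identical outputs", {
  cfg <- generator_config(n_target = 300, seed = 31,
                          outcome_mode = "mechanistic",
                          true_beta = c(`(Intercept)` = -0.5,
                                        any_nonsterile_6m = 0.5),
                          true_sigma_u = 0.5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth, b$truth)
})

test_that("marginal outcomes track configured prevalences", {
  cfg <- generator_config(n_target = 2000, seed = 17)
  sim <- simulate_cohort(cfg)
  p <- sim$cohort$participants
  aware <- p$hiv_aware_pos == 1L
  expect_lt(abs(mean(p$outcome_hiv_test_6m[!aware]) - 0.142), 0.03)
  expect_lt(abs(mean(p$outcome_moud_6m) - 0.329), 0.03)
  expect_lt(abs(mean(p$hiv_pos) - 0.373), 0.04)
  expect_true(all(p$outcome_hiv_test_6m[aware] == 0L))
})

test_that("mechanistic outcomes marginalize correctly", {
  # beta = 0, sigma = 0: prevalence ~ 0.5
  cfg <- generator_config(n_target = 2000, seed = 23,
                          outcome_mode = "mechanistic",
                          true_beta = c(`(Intercept)` = 0), true_sigma_u = 0,
                          attribute_prevalences = list(hiv_aware_given_pos = 0))
  sim <- simulate_cohort(cfg)
  prev <- mean(sim$cohort$participants$outcome_hiv_test_6m)
  expect_lt(abs(prev - 0.5), 2.5 * sqrt(0.25 / 2000) + 0.01)
  # intercept at logit of the observed testing rate reproduces it
  cfg2 <- generator_config(n_target = 2000, seed = 24,
                           outcome_mode = "mechanistic",
                           true_beta = c(`(Intercept)` = stats::qlogis(0.142)),
                           true_sigma_u = 0,
                           attribute_prevalences = list(hiv_aware_given_pos = 0))
  sim2 <- simulate_cohort(cfg2)
  expect_lt(abs(mean(sim2$cohort$participants$outcome_hiv_test_6m) - 0.142),
            0.025)
})

test_that("single binary exposure with beta = log 2 yields empirical OR near 2", {
  cfg <- generator_config(n_target = 4000, seed = 29,
                          outcome_mode = "mechanistic",
                          true_beta = c(`(Intercept)` = -1,
                                        nonsterile_6m = log(2)),
                          true_sigma_u = 0,
                          missing_rates = list(nonsterile_6m = 0),
                          attribute_prevalences = list(hiv_aware_given_pos = 0))
  sim <- simulate_cohort(cfg)
  p <- sim$cohort$participants
  tab <- table(p$nonsterile_6m, p$outcome_hiv_test_6m)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  expect_lt(abs(log(or) - log(2)), 0.25)
})

test_that("alter random effects overdisperse outcomes across ego-networks", {
  # egos of degree 1 sharing the same recruiter share that alter's u_j, so
  # their outcomes are exchangeable Bernoulli within group; the excess of
  # between-group variance over the binomial expectation detects sigma_u
  excess_between_var <- function(sigma_u, seed) {
    cfg <- generator_config(n_target = 2000, seed = seed,
                            outcome_mode = "mechanistic",
                            true_beta = c(`(Intercept)` = 0),
                            true_sigma_u = sigma_u,
                            attribute_prevalences =
                              list(hiv_aware_given_pos = 0))
    sim <- simulate_cohort(cfg)
    p <- sim$cohort$participants
    deg <- net_degree(sim$network, p$pid)
    rec <- sim$cohort$referrals
    rec <- rec[rec$returned == 1L, ]
    first <- rec[!duplicated(rec$redeemer_pid), ]
    grp <- first$issuer_pid[match(p$pid, first$redeemer_pid)]
    keep <- !is.na(grp) & deg == 1
    y <- p$outcome_hiv_test_6m[keep]
    means <- tapply(y, grp[keep], mean)
    sizes <- tapply(y, grp[keep], length)
    ok <- sizes >= 3
    pbar <- stats::weighted.mean(means[ok], sizes[ok])
    mean((means[ok] - pbar)^2 - pbar * (1 - pbar) / sizes[ok])
  }
  v0 <- excess_between_var(0, 101)
  v3 <- excess_between_var(3, 101)
  expect_gt(v3, v0 + 0.05)
})

test_that("dyad-level simulator reproduces its own generative parameters", {
  sim <- simulate_dyad_data(n_dyads = 5000, sigma_e = 0, sigma_a = 0,
                            seed = 7)
  d <- sim$design
  f <- glm(y ~ focal * moderator, family = binomial, data = d)
  expect_lt(abs(coef(f)["focal"] - sim$truth$beta_focal), 0.25)
  expect_lt(abs(coef(f)["focal:moderator"] - sim$truth$beta_int), 0.35)
})
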