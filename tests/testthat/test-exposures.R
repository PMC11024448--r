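test_that("any/proportion aggregation over direct alters is correct", {
  p <- make_participants(5, pid = c("E", "A1", "A2", "A3", "X"),
                         outcome_hiv_test_6m = c(0L, 1L, 0L, 0L, 1L))
  rf <- make_referrals(rep("E", 3), c("A1", "A2", "A3"))
  g <- build_network(rf, p)
  ex <- build_exposures(g, p, list(
    exposure_spec("outcome_hiv_test_6m", "direct", "any"),
    exposure_spec("outcome_hiv_test_6m", "direct", "proportion")
  ))
  e <- ex[ex$pid == "E", ]
  expect_equal(e$any_outcome_hiv_test_6m_direct, 1)
  expect_equal(e$prop_outcome_hiv_test_6m_direct, 1 / 3)
  expect_equal(e$degree, 3L)
  expect_equal(e$log_degree, log(3))
  # ego with zero positive alters
  a1 <- ex[ex$pid == "A2", ]  # single alter E with outcome 0
  expect_equal(a1$any_outcome_hiv_test_6m_direct, 0)
  expect_equal(a1$prop_outcome_hiv_test_6m_direct, 0)
})

test_that("missing alter attributes drop from numerator and denominator", {
  p <- make_participants(4, pid = c("E", "A1", "A2", "A3"),
                         nonsterile_6m = c(0L, NA, 1L, NA))
  rf <- make_referrals(rep("E", 3), c("A1", "A2", "A3"))
  g <- build_network(rf, p)
  ex <- build_exposures(g, p,
                        exposure_spec("nonsterile_6m", "direct", "proportion"))
  expect_equal(ex$prop_nonsterile_6m_direct[ex$pid == "E"], 1)  # 1 of 1 observed
  # all alters missing: exposure missing
  p2 <- make_participants(3, pid = c("E", "A1", "A2"),
                          nonsterile_6m = c(0L, NA, NA))
  g2 <- build_network(make_referrals(rep("E", 2), c("A1", "A2")), p2)
  ex2 <- build_exposures(g2, p2, exposure_spec("nonsterile_6m", "direct"))
  expect_true(is.na(ex2$any_nonsterile_6m_direct[ex2$pid == "E"]))
})

test_that("proximal scopes nest consistently (set-difference identity)", {
  sim <- simulate_cohort(generator_config(n_target = 200, seed = 12))
  p <- sim$cohort$participants
  ex <- build_exposures(sim$network, p, list(
    exposure_spec("hiv_pos", "proximal_1_3", "proportion"),
    exposure_spec("hiv_pos", "proximal_2_3", "proportion"),
    exposure_spec("hiv_pos", "direct", "proportion")
  ))
  hiv <- p$hiv_pos[match(ex$pid, p$pid)]
  for (i in sample(nrow(ex), 30)) {
    m13 <- proximal_set(sim$network, ex$pid[i], 1, 3)$members
    m23 <- proximal_set(sim$network, ex$pid[i], 2, 3)$members
    direct <- proximal_set(sim$network, ex$pid[i], 1, 1)$members
    expect_setequal(m13, union(m23, direct))
    n13 <- sum(p$hiv_pos[match(m13, p$pid)], na.rm = TRUE)
    n23 <- sum(p$hiv_pos[match(m23, p$pid)], na.rm = TRUE)
    nd <- sum(p$hiv_pos[match(direct, p$pid)], na.rm = TRUE)
    expect_equal(n13, n23 + nd)  # scopes 2-3 and direct partition 1-3
  }
})

test_that("any equals the indicator of positive proportion, and adding a
           positive alter never switches any from 1 to 0", {
  sim <- simulate_cohort(generator_config(n_target = 300, seed = 14))
  p <- sim$cohort$participants
  ex <- build_exposures(sim$network, p, list(
    exposure_spec("inject_daily", "proximal_1_3", "any"),
    exposure_spec("inject_daily", "proximal_1_3", "proportion")
  ))
  ok <- !is.na(ex$any_inject_daily_proximal_1_3)
  expect_equal(ex$any_inject_daily_proximal_1_3[ok],
               as.numeric(ex$prop_inject_daily_proximal_1_3[ok] > 0))
  expect_true(all(ex$prop_inject_daily_proximal_1_3[ok] >= 0 &
                    ex$prop_inject_daily_proximal_1_3[ok] <= 1))
  # monotonicity: flipping one in-scope alter to positive cannot lower any
  flip <- p
  idx <- which(flip$inject_daily == 0L)[1:20]
  flip$inject_daily[idx] <- 1L
  ex2 <- build_exposures(sim$network, flip,
                         exposure_spec("inject_daily", "proximal_1_3", "any"))
  both <- ok & !is.na(ex2$any_inject_daily_proximal_1_3)
  expect_true(all(ex2$any_inject_daily_proximal_1_3[both] >=
                    ex$any_inject_daily_proximal_1_3[both]))
})

test_that("any_service flag is the OR of the three service outcomes", {
  p <- make_participants(4, pid = c("E", "A1", "A2", "A3"),
                         outcome_hiv_test_6m = c(0L, 0L, 0L, 0L),
                         outcome_moud_6m = c(0L, 1L, 0L, 0L),
                         outcome_ssp_6m = c(0L, 0L, 0L, 1L))
  g <- build_network(make_referrals(rep("E", 3), c("A1", "A2", "A3")), p)
  ex <- build_exposures(g, p, exposure_spec("any_service", "direct",
                                            "proportion"))
  expect_equal(ex$prop_any_service_direct[ex$pid == "E"], 2 / 3)
})

test_that("dyad moderator dichotomizations sit at the documented boundaries", {
  dy <- make_dyads(rep("E", 6), paste0("A", 1:6),
                   trust_score = c(6L, 7L, 2L, 10L, 6L, 8L),
                   inject_times_30d = c(15L, 16L, 0L, 40L, 15L, 16L),
                   years_known = c(0.5, 1, 1.5, 10, 1, 2))
  m <- dyad_moderators(dy)
  expect_equal(m$trust_high, c(0L, 1L, 0L, 1L, 0L, 1L))
  expect_equal(m$inject_gt15, c(0L, 1L, 0L, 1L, 0L, 1L))
  expect_equal(m$years_known_gt1, c(0L, 0L, 1L, 1L, 0L, 1L))
  # missing propagates
  dy$trust_score[1] <- NA
  expect_true(is.na(dyad_moderators(dy)$trust_high[1]))
})
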