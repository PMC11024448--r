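test_that("returned coupons collapse to undirected deduplicated edges", {
  p <- make_participants(3, pid = c("A", "B", "C"))
  # reciprocal pair + duplicate recruit + an unreturned coupon
  rf <- make_referrals(c("A", "B", "C", "A"), c("B", "A", "B", NA),
                       returned = c(1L, 1L, 1L, 0L))
  g <- build_network(rf, p)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)  # {A,B} collapsed, {C,B} cross-link
  expect_setequal(net_degree(g, c("A", "B", "C")), c(1L, 2L, 1L))
})

test_that("self-referrals and unknown redeemers are rejected", {
  p <- make_participants(2, pid = c("A", "B"))
  expect_error(build_network(make_referrals("A", "A"), p), "self-referral")
  expect_error(build_network(make_referrals("A", "Z"), p), "absent")
})

test_that("degree handles isolates, stars and matches a brute recount", {
  p <- make_participants(7, pid = c("hub", paste0("L", 1:5), "iso"))
  rf <- make_referrals(rep("hub", 5), paste0("L", 1:5))
  g <- build_network(rf, p)
  expect_equal(net_degree(g, "iso"), 0L)
  expect_equal(net_degree(g, "hub"), 5L)
  expect_error(net_degree(g, "nope"), "unknown pid")
  # brute-force recount from the edge list on a generated graph
  sim <- simulate_cohort(generator_config(n_target = 120, seed = 9))
  el <- igraph::as_edgelist(sim$network)
  pid <- sim$cohort$participants$pid
  brute <- table(factor(c(el[, 1], el[, 2]), levels = pid))
  expect_equal(net_degree(sim$network, pid), as.integer(brute))
})

test_that("proximal sets follow the <=3-link window on a path graph", {
  p <- make_participants(5, pid = LETTERS[1:5])
  rf <- make_referrals(LETTERS[1:4], LETTERS[2:5])  # path A-B-C-D-E
  g <- build_network(rf, p)
  expect_setequal(proximal_set(g, "A", 1, 3)$members, c("B", "C", "D"))
  expect_setequal(proximal_set(g, "A", 2, 3)$members, c("C", "D"))
  expect_setequal(proximal_set(g, "A", 1, 1)$members, "B")
  expect_equal(proximal_set(g, "A", 1, 3)$size, 3)
  expect_error(proximal_set(g, "Z"), "unknown ego")
})

test_that("BFS proximity equals exhaustive path enumeration on random graphs", {
  set.seed(77)
  for (rep in 1:200) {
    n <- sample(4:15, 1)
    pid <- sprintf("N%02d", seq_len(n))
    p_edge <- stats::runif(1, 0.1, 0.4)
    adj <- which(upper.tri(matrix(0, n, n)) &
                   matrix(stats::runif(n * n) < p_edge, n, n), arr.ind = TRUE)
    p <- make_participants(n, pid = pid)
    if (nrow(adj) == 0) next
    rf <- make_referrals(pid[adj[, 1]], pid[adj[, 2]])
    g <- build_network(rf, p)
    edges <- cbind(pid[adj[, 1]], pid[adj[, 2]])
    ego <- sample(pid, 1)
    for (md in list(c(1, 3), c(2, 3), c(1, 2))) {
      expect_identical(
        sort(proximal_set(g, ego, md[1], md[2])$members),
        brute_proximal(edges, pid, ego, md[1], md[2])
      )
    }
  }
})

test_that("proximity windows are monotone and consistent with adjacency", {
  sim <- simulate_cohort(generator_config(n_target = 150, seed = 5))
  g <- sim$network
  pids <- sample(sim$cohort$participants$pid, 25)
  for (ego in pids) {
    direct <- proximal_set(g, ego, 1, 1)$members
    expect_setequal(direct,
                    igraph::V(g)$name[igraph::neighbors(g, ego)])
    m13 <- proximal_set(g, ego, 1, 3)$members
    m23 <- proximal_set(g, ego, 2, 3)$members
    m12 <- proximal_set(g, ego, 1, 2)$members
    expect_true(all(m23 %in% m13))
    expect_true(all(m12 %in% m13))
    expect_true(all(direct %in% m13))
    expect_false(ego %in% m13)
  }
})

test_that("membership weights are uniform 1/degree and sum to one exactly", {
  p <- make_participants(6, pid = c("E", paste0("A", 1:4), "iso"))
  rf <- make_referrals(rep("E", 4), paste0("A", 1:4))
  g <- build_network(rf, p)
  w <- membership_weights(g, "E")
  expect_equal(unname(w), rep(0.25, 4))
  expect_equal(unname(membership_weights(g, "A1")), 1.0)
  expect_error(membership_weights(g, "iso"), "degree 0")
  # normalization sweep over a generated graph
  sim <- simulate_cohort(generator_config(n_target = 200, seed = 8))
  deg <- net_degree(sim$network, sim$cohort$participants$pid)
  for (pp in sim$cohort$participants$pid[deg > 0]) {
    ww <- membership_weights(sim$network, pp)
    expect_equal(sum(ww), 1, tolerance = 1e-12)
    expect_true(all(abs(ww - 1 / length(ww)) < 1e-9))
  }
})

test_that("graph symmetry: j in alters(i) iff i in alters(j)", {
  sim <- simulate_cohort(generator_config(n_target = 100, seed = 13))
  g <- sim$network
  for (ego in sample(igraph::V(g)$name, 15)) {
    for (alt in proximal_set(g, ego, 1, 1)$members) {
      expect_true(ego %in% proximal_set(g, alt, 1, 1)$members)
    }
  }
})

test_that("directed dyad records double the unique dyads", {
  p <- make_participants(4, pid = LETTERS[1:4])
  rf <- make_referrals(c("A", "B", "C"), c("B", "C", "D"))
  g <- build_network(rf, p)
  dd <- directed_dyad_records(g)
  expect_equal(nrow(dd), 6)
  key <- paste(dd$ego_pid, dd$alter_pid)
  expect_equal(anyDuplicated(key), 0L)
  expect_setequal(paste(dd$alter_pid, dd$ego_pid), key)
})
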