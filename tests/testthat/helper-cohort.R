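# Fixture builders used across the suite. Everything is constructed in code;
# no files ship with the package.

# Minimal valid participant table; override columns via ...
make_participants <- function(n, pid = sprintf("P%03d", seq_len(n)), ...) {
  df <- data.frame(
    pid = pid,
    age = rep(25L, n),
    gender = rep("male", n),
    marital = rep("single_widowed_divorced", n),
    education = rep("none", n),
    hiv_pos = rep(0L, n),
    hiv_aware_pos = rep(0L, n),
    hcv_pos = rep(0L, n),
    ever_hcv_test = rep(0L, n),
    outcome_hiv_test_6m = rep(0L, n),
    outcome_moud_6m = rep(0L, n),
    outcome_ssp_6m = rep(0L, n),
    homeless = rep(0L, n),
    inject_daily = rep(0L, n),
    nonsterile_6m = rep(0L, n),
    venue40_6m = rep(0L, n),
    prison_6m = rep(0L, n),
    overdose_1y = rep(0L, n),
    alcohol = rep("none", n),
    depression = rep("none_mild", n),
    stringsAsFactors = FALSE
  )
  dots <- list(...)
  for (nm in names(dots)) df[[nm]] <- dots[[nm]]
  df
}

# Referral table from an edge list: each row one returned coupon
make_referrals <- function(issuer, redeemer, returned = NULL) {
  k <- length(issuer)
  if (is.null(returned)) returned <- rep(1L, k)
  data.frame(
    coupon_id = sprintf("C%04d", seq_len(k)),
    issuer_pid = issuer, redeemer_pid = redeemer, returned = returned,
    stringsAsFactors = FALSE
  )
}

make_dyads <- function(ego, alter, ...) {
  n <- length(ego)
  df <- data.frame(
    ego_pid = ego, alter_pid = alter,
    relationship = rep("friend", n),
    years_known = rep(2, n),
    trust_score = rep(7L, n),
    support_material = rep(0L, n),
    support_financial = rep(0L, n),
    discuss_health = rep(0L, n),
    inject_times_30d = rep(10L, n),
    shared_equipment_30d = rep(0L, n),
    alter_hiv_known = rep("unknown", n),
    alter_hcv_known = rep("unknown", n),
    stringsAsFactors = FALSE
  )
  dots <- list(...)
  for (nm in names(dots)) df[[nm]] <- dots[[nm]]
  df
}

# Small mechanistic cohort + network + exposure table for model tests
make_mechanistic_fixture <- function(n = 600, seed = 42, sigma_u = 0,
                                     beta = c(`(Intercept)` = -1,
                                              any_nonsterile_6m = log(2)),
                                     a_priori = c("age", "gender_male",
                                                  "marital", "education",
                                                  "log_degree")) {
  cfg <- generator_config(n_target = n, seed = seed,
                          outcome_mode = "mechanistic",
                          true_beta = beta, true_sigma_u = sigma_u)
  sim <- simulate_cohort(cfg)
  exps <- build_exposures(sim$network, sim$cohort$participants,
                          exposure_spec("nonsterile_6m", "direct"))
  list(sim = sim, exps = exps,
       spec = model_spec("outcome_hiv_test_6m",
                         exposures = list(exposure_spec("nonsterile_6m",
                                                        "direct")),
                         a_priori = a_priori,
                         candidates = character(0)))
}

# Exhaustive proximity oracle: nodes reachable from ego by a path of at most
# max_dist edges equal nodes at BFS distance <= max_dist (a shortest path is
# itself simple); enumerate by repeated neighbourhood expansion on the raw
# edge list, independently of igraph.
brute_proximal <- function(edges, nodes, ego, min_dist, max_dist) {
  nbr <- function(v) {
    unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
  }
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[ego] <- 0
  frontier <- ego
  d <- 0
  while (length(frontier) && d < max_dist) {
    d <- d + 1
    nxt <- unique(unlist(lapply(frontier, nbr)))
    nxt <- nxt[dist[nxt] == Inf]
    dist[nxt] <- d
    frontier <- nxt
  }
  sort(names(dist)[dist >= min_dist & dist <= max_dist])
}
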