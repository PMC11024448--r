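# Synthetic-cohort generator.
#
# Emulates the study's coupon-referral recruitment: 10 seed participants,
# 0-6 coupons each (median 1), 75% coupon return, iterative recruitment to
# the target sample size, and duplicate recruitment creating cross-network
# linkages without re-enrolment. Participant attributes are drawn at the
# cohort's observed marginal prevalences; dyad characteristics at the
# observed partnership marginals. Outcomes are drawn either at their
# marginal prevalences or from a mechanistic logistic process with known
# coefficients and alter random effects, for parameter-recovery studies.

#' Generator configuration
#'
#' Defaults reproduce the cohort's recruitment statistics (2512
#' participants from 10 seeds; coupon count per participant with median 1
#' and range 0-6; 75% coupon return) and attribute prevalences (e.g. 37.3%
#' HIV positive, 67% daily injection, 46.9% non-sterile equipment use).
#' `p_duplicate_recruit` is the probability a returned coupon was redeemed
#' by an already-enrolled participant, creating a cross-network linkage.
#'
#' @param n_target Number of participants to enrol.
#' @param n_seeds Number of seed participants.
#' @param coupon_probs Probabilities of issuing 0..6 coupons.
#' @param p_coupon_return Probability a coupon is returned.
#' @param p_duplicate_recruit Probability a returned coupon points to an
#'   already-enrolled participant.
#' @param attribute_prevalences Named list overriding binary attribute
#'   prevalences and categorical level probabilities.
#' @param missing_rates Named list overriding per-field missingness rates.
#' @param dyad_distributions Named list overriding dyad field distributions.
#' @param latent_risk_sd Standard deviation of an optional shared latent
#'   risk factor inducing positive correlation across the risk attributes
#'   (0 = attributes independent).
#' @param reseed When coupon chains die out before `n_target`, issue a
#'   fresh coupon batch to a randomly chosen enrolled participant and
#'   continue (emulating the field practice of handing out additional
#'   coupons, with no upper limit, until the desired sample size is
#'   reached). With `reseed = FALSE` extinction is an error instead.
#' @param outcome_mode `"marginal"` or `"mechanistic"`.
#' @param true_beta Named log-odds coefficients for mechanistic outcomes
#'   (see [simulate_outcomes()]).
#' @param true_sigma_u Alter random-effect standard deviation (mechanistic).
#' @param seed RNG seed.
#' @return Object of class `netmmm_gen_config` (a named list).
#' @export
generator_config <- function(n_target = 2512L,
                             n_seeds = 10L,
                             coupon_probs = c(0.34, 0.31, 0.16, 0.09, 0.05, 0.03, 0.02),
                             p_coupon_return = 0.75,
                             p_duplicate_recruit = 0.05,
                             attribute_prevalences = list(),
                             missing_rates = list(),
                             dyad_distributions = list(),
                             latent_risk_sd = 0,
                             reseed = TRUE,
                             outcome_mode = c("marginal", "mechanistic"),
                             true_beta = c(`(Intercept)` = 0),
                             true_sigma_u = 0,
                             seed = 1L) {
  outcome_mode <- match.arg(outcome_mode)
  stopifnot(length(coupon_probs) == 7L, all(coupon_probs >= 0),
            abs(sum(coupon_probs) - 1) < 1e-8,
            p_coupon_return >= 0, p_coupon_return <= 1,
            p_duplicate_recruit >= 0, p_duplicate_recruit <= 1,
            n_seeds >= 1L, n_seeds <= n_target,
            true_sigma_u >= 0, latent_risk_sd >= 0)
  prev <- utils::modifyList(list(
    hiv_pos = 0.373,
    hiv_aware_given_pos = 10 / 938,   # 10 aware of 938 positive
    hcv_pos = 0.650,
    ever_hcv_test = 0.042,
    outcome_hiv_test_6m = 0.142,      # among those not known positive
    outcome_moud_6m = 0.329,
    outcome_ssp_6m = 0.135,
    homeless = 0.301,
    inject_daily = 0.673,
    nonsterile_6m = 0.472,
    venue40_6m = 0.485,
    prison_6m = 0.030,
    overdose_1y = 0.193,              # among non-missing reports
    gender = c(male = 0.991, female = 0.008, hijra = 0.001),
    marital = c(single_widowed_divorced = 0.718, married_partnered = 0.282),
    education = c(none = 0.301, primary = 0.247, secondary_plus = 0.452),
    alcohol = c(none = 0.607, low_moderate = 0.092, harmful = 0.179,
                dependence = 0.121),
    depression = c(none_mild = 0.739, moderate_severe = 0.261)
  ), attribute_prevalences)
  miss <- utils::modifyList(list(
    marital = 0.002, education = 0.004, ever_hcv_test = 0.011,
    inject_daily = 0.005, nonsterile_6m = 0.006, alcohol = 0.0004,
    overdose_1y = 0.314
  ), missing_rates)
  dyad <- utils::modifyList(list(
    relationship = c(friend = 0.711, family = 0.008, spouse_sexual = 0.001,
                     other = 0.280),
    years_known_meanlog = log(4), years_known_sdlog = 1.19,
    trust_probs = stats::setNames(
      c(0.05, 0.06, 0.08, 0.12, 0.14, 0.20, 0.20, 0.10, 0.05), 2:10),
    support_material = 0.538, support_financial = 0.603,
    discuss_health = 0.194,
    inject_times_mu = 22, inject_times_size = 1.3,
    shared_equipment_30d = 0.292,
    alter_hiv_known = c(pos = 0.10, neg = 0.30, unknown = 0.60),
    alter_hcv_known = c(pos = 0.15, neg = 0.25, unknown = 0.60)
  ), dyad_distributions)
  structure(list(
    n_target = as.integer(n_target), n_seeds = as.integer(n_seeds),
    coupon_probs = coupon_probs, p_coupon_return = p_coupon_return,
    p_duplicate_recruit = p_duplicate_recruit,
    attribute_prevalences = prev, missing_rates = miss,
    dyad_distributions = dyad, latent_risk_sd = latent_risk_sd,
    reseed = isTRUE(reseed),
    outcome_mode = outcome_mode, true_beta = true_beta,
    true_sigma_u = true_sigma_u, seed = as.integer(seed)
  ), class = "netmmm_gen_config")
}

.rbern <- function(n, p) stats::rbinom(n, 1L, p)

.rcat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

.inject_missing <- function(x, rate) {
  if (rate > 0) x[stats::runif(length(x)) < rate] <- NA
  x
}

# Attributes influenced by the optional shared latent risk factor: a single
# standard-normal per-person score shifts these logits by latent_risk_sd * z,
# inducing positive correlation without per-pair copulas.
.risk_attrs <- c("nonsterile_6m", "inject_daily", "overdose_1y",
                 "venue40_6m", "hcv_pos", "hiv_pos")

.draw_attributes <- function(pids, cfg) {
  n <- length(pids)
  prev <- cfg$attribute_prevalences
  miss <- cfg$missing_rates
  z <- if (cfg$latent_risk_sd > 0) stats::rnorm(n) else numeric(n)
  draw_bin <- function(field) {
    p <- prev[[field]]
    if (cfg$latent_risk_sd > 0 && field %in% .risk_attrs) {
      p <- stats::plogis(stats::qlogis(p) + cfg$latent_risk_sd * z)
    }
    .rbern(n, p)
  }
  age <- pmax(18L, as.integer(round(17 + stats::rlnorm(n, log(9), 0.9))))
  hiv_pos <- draw_bin("hiv_pos")
  hiv_aware <- integer(n)
  hiv_aware[hiv_pos == 1L] <- .rbern(sum(hiv_pos), prev$hiv_aware_given_pos)
  df <- data.frame(
    pid = pids,
    age = age,
    gender = .rcat(n, prev$gender),
    marital = .inject_missing(.rcat(n, prev$marital), miss$marital %||% 0),
    education = .inject_missing(.rcat(n, prev$education), miss$education %||% 0),
    hiv_pos = hiv_pos,
    hiv_aware_pos = hiv_aware,
    hcv_pos = draw_bin("hcv_pos"),
    ever_hcv_test = .inject_missing(.rbern(n, prev$ever_hcv_test),
                                    miss$ever_hcv_test %||% 0),
    outcome_hiv_test_6m = NA_integer_,
    outcome_moud_6m = NA_integer_,
    outcome_ssp_6m = NA_integer_,
    homeless = .rbern(n, prev$homeless),
    inject_daily = .inject_missing(draw_bin("inject_daily"),
                                   miss$inject_daily %||% 0),
    nonsterile_6m = .inject_missing(draw_bin("nonsterile_6m"),
                                    miss$nonsterile_6m %||% 0),
    venue40_6m = draw_bin("venue40_6m"),
    prison_6m = .rbern(n, prev$prison_6m),
    overdose_1y = .inject_missing(draw_bin("overdose_1y"),
                                  miss$overdose_1y %||% 0),
    alcohol = .inject_missing(.rcat(n, prev$alcohol), miss$alcohol %||% 0),
    depression = .rcat(n, prev$depression),
    stringsAsFactors = FALSE
  )
  df
}

.draw_dyads <- function(ego, alter, cfg) {
  n <- length(ego)
  d <- cfg$dyad_distributions
  data.frame(
    ego_pid = ego, alter_pid = alter,
    relationship = .rcat(n, d$relationship),
    years_known = round(stats::rlnorm(n, d$years_known_meanlog,
                                      d$years_known_sdlog), 1),
    trust_score = as.integer(.rcat(n, d$trust_probs)),
    support_material = .rbern(n, d$support_material),
    support_financial = .rbern(n, d$support_financial),
    discuss_health = .rbern(n, d$discuss_health),
    inject_times_30d = stats::rnbinom(n, mu = d$inject_times_mu,
                                      size = d$inject_times_size),
    shared_equipment_30d = .rbern(n, d$shared_equipment_30d),
    alter_hiv_known = .rcat(n, d$alter_hiv_known),
    alter_hcv_known = .rcat(n, d$alter_hcv_known),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate coupon-referral recruitment of a synthetic cohort
#'
#' Seeds are enrolled first; each enrolled participant is issued 0-6
#' coupons reflecting the number of injecting partners named; each coupon
#' is returned with probability `p_coupon_return`. A returned coupon either
#' enrols a new participant (creating a referral-tree edge and an
#' ego-reported dyad record from the recruiting ego) or, with probability
#' `p_duplicate_recruit`, is redeemed by an already-enrolled participant:
#' the duplicate is not enrolled again and provides no additional dyad
#' report, but the coupon establishes a cross-network linkage. Recruitment
#' proceeds breadth-first until `n_target` is reached; coupons still
#' pending then resolve as returns-to-duplicate or non-returns only.
#'
#' @param config A [generator_config()].
#' @return List with `participants`, `dyads`, `referrals` tables (outcomes
#'   NA; fill with [simulate_outcomes()]).
#' @export
simulate_recruitment <- function(config = generator_config()) {
  cfg <- config
  set.seed(cfg$seed)
  n_target <- cfg$n_target
  pids <- sprintf("P%05d", seq_len(n_target))
  n_enrolled <- cfg$n_seeds
  # queue of participants whose coupons are not yet issued
  queue <- seq_len(cfg$n_seeds)
  qhead <- 1L
  coupons <- list()
  dyad_ego <- character(0); dyad_alter <- character(0)
  linked <- new.env(hash = TRUE)  # "i:j" keys of existing links, i < j
  link_key <- function(a, b) paste0(min(a, b), ":", max(a, b))
  cid <- 0L
  n_reseeds <- 0L
  repeat {
    # recruitment halts once the desired sample size is reached
    if (n_enrolled >= n_target) break
    if (qhead > length(queue)) {
      # coupon chains exhausted before reaching the target
      if (!cfg$reseed || n_reseeds >= 100000L) break
      # top up: a random enrolled participant gets a fresh coupon batch
      n_reseeds <- n_reseeds + 1L
      queue <- c(queue, sample.int(n_enrolled, 1L))
    }
    issuer <- queue[qhead]; qhead <- qhead + 1L
    k <- sample(0:6, 1L, prob = cfg$coupon_probs)
    if (k == 0L) next
    for (cc in seq_len(k)) {
      cid <- cid + 1L
      returned <- stats::runif(1) < cfg$p_coupon_return
      if (!returned) {
        coupons[[cid]] <- list(id = cid, issuer = issuer, redeemer = NA_integer_,
                               returned = 0L)
        next
      }
      dup <- n_enrolled >= n_target ||
        (n_enrolled > 1L && stats::runif(1) < cfg$p_duplicate_recruit)
      if (dup) {
        # redeemed by an already-enrolled participant: cross-network linkage
        cand <- setdiff(seq_len(n_enrolled), issuer)
        redeemer <- if (length(cand) == 1L) cand else sample(cand, 1L)
        coupons[[cid]] <- list(id = cid, issuer = issuer, redeemer = redeemer,
                               returned = 1L)
        assign(link_key(issuer, redeemer), TRUE, envir = linked)
      } else {
        n_enrolled <- n_enrolled + 1L
        redeemer <- n_enrolled
        queue <- c(queue, redeemer)
        coupons[[cid]] <- list(id = cid, issuer = issuer, redeemer = redeemer,
                               returned = 1L)
        assign(link_key(issuer, redeemer), TRUE, envir = linked)
        # alter information is provided only by the recruiting ego
        dyad_ego <- c(dyad_ego, pids[issuer])
        dyad_alter <- c(dyad_alter, pids[redeemer])
      }
    }
  }
  if (n_enrolled < n_target) {
    stop(sprintf(paste0(
      "recruitment extinguished at %d of %d participants: all coupon chains ",
      "died out; increase coupon counts (coupon_probs) or p_coupon_return"),
      n_enrolled, n_target), call. = FALSE)
  }
  referrals <- data.frame(
    coupon_id = sprintf("C%06d", vapply(coupons, `[[`, 0L, "id")),
    issuer_pid = pids[vapply(coupons, `[[`, 0L, "issuer")],
    redeemer_pid = pids[vapply(coupons, function(x) {
      if (is.na(x$redeemer)) NA_integer_ else x$redeemer
    }, 0L)],
    returned = vapply(coupons, `[[`, 0L, "returned"),
    stringsAsFactors = FALSE
  )
  participants <- .draw_attributes(pids[seq_len(n_enrolled)], cfg)
  dyads <- .draw_dyads(dyad_ego, dyad_alter, cfg)
  list(participants = validate_participants(participants),
       dyads = validate_dyads(dyads),
       referrals = validate_referrals(referrals))
}

#' Fill outcome columns of a simulated cohort
#'
#' In `marginal` mode the three service outcomes are independent Bernoulli
#' draws at their configured prevalences (HIV testing only among
#' participants not already aware of a positive serostatus; known
#' positives get outcome 0). In `mechanistic` mode each outcome named in
#' `outcomes` is drawn from the logistic model
#' \deqn{y_i ~ Bernoulli(logit^{-1}(x_i'\beta + \sum_j w_{ij} u_j))}
#' with membership weights w_ij = 1/degree(i) over direct alters and
#' u_j ~ Normal(0, sigma_u^2). Coefficient names in `true_beta` must be the
#' intercept `"(Intercept)"`, a binary participant column, `"age_std"`
#' (age standardized), `"log_degree"`, or a network-exposure term
#' `"any_<attr>"`/`"prop_<attr>"` over direct alters, where `<attr>` is a
#' non-outcome binary participant column (outcome-based exposures would be
#' circular at generation time).
#'
#' @param cohort List with `participants`, `dyads`, `referrals`.
#' @param network Sociometric network; built from the cohort if NULL.
#' @param config A [generator_config()]; its `outcome_mode`, `true_beta`,
#'   `true_sigma_u` and prevalences drive the draw.
#' @param seed RNG seed for the outcome draw (defaults to `config$seed + 1`).
#' @return List: the cohort with outcomes filled, plus `truth` (named list
#'   with `beta`, `sigma_u`, `u` in mechanistic mode).
#' @export
simulate_outcomes <- function(cohort, network = NULL,
                              config = generator_config(), seed = NULL) {
  cfg <- config
  set.seed(if (is.null(seed)) cfg$seed + 1L else seed)
  participants <- cohort$participants
  n <- nrow(participants)
  prev <- cfg$attribute_prevalences
  if (cfg$outcome_mode == "marginal") {
    aware <- !is.na(participants$hiv_aware_pos) & participants$hiv_aware_pos == 1L
    ht <- .rbern(n, prev$outcome_hiv_test_6m)
    ht[aware] <- 0L
    participants$outcome_hiv_test_6m <- ht
    participants$outcome_moud_6m <- .rbern(n, prev$outcome_moud_6m)
    participants$outcome_ssp_6m <- .rbern(n, prev$outcome_ssp_6m)
    cohort$participants <- participants
    return(list(cohort = cohort, truth = NULL))
  }
  if (is.null(network)) network <- build_network(cohort$referrals, participants)
  X <- .mechanistic_design(participants, network, names(cfg$true_beta))
  eta_fixed <- as.vector(X %*% cfg$true_beta)
  u <- stats::rnorm(n, 0, cfg$true_sigma_u)
  names(u) <- participants$pid
  eta_re <- numeric(n)
  deg <- net_degree(network, participants$pid)
  for (i in which(deg > 0L)) {
    w <- membership_weights(network, participants$pid[i])
    eta_re[i] <- sum(w * u[names(w)])
  }
  y <- .rbern(n, stats::plogis(eta_fixed + eta_re))
  participants$outcome_hiv_test_6m <- y
  participants$outcome_moud_6m <- .rbern(n, prev$outcome_moud_6m)
  participants$outcome_ssp_6m <- .rbern(n, prev$outcome_ssp_6m)
  aware <- !is.na(participants$hiv_aware_pos) & participants$hiv_aware_pos == 1L
  participants$outcome_hiv_test_6m[aware] <- 0L
  cohort$participants <- participants
  list(cohort = cohort,
       truth = list(beta = cfg$true_beta, sigma_u = cfg$true_sigma_u, u = u))
}

# Design matrix for the mechanistic outcome process. Separate from
# build_exposures() so that generation-time truth does not depend on the
# analysis path being tested.
.mechanistic_design <- function(participants, network, terms) {
  n <- nrow(participants)
  adj <- igraph::adjacent_vertices(network, match(participants$pid,
                                                  igraph::V(network)$name))
  vnames <- igraph::V(network)$name
  cols <- lapply(terms, function(tm) {
    if (tm == "(Intercept)") return(rep(1, n))
    if (tm == "age_std") return(as.vector(scale(participants$age)))
    if (tm == "log_degree") {
      d <- lengths(adj)
      return(ifelse(d > 0, log(d), 0))
    }
    m <- regmatches(tm, regexec("^(any|prop)_(.+)$", tm))[[1]]
    if (length(m) == 3L && m[3] %in% names(participants)) {
      attr_name <- m[3]
      if (attr_name %in% .service_outcomes) {
        stop("mechanistic true_beta term '", tm,
             "' references an outcome column (circular)", call. = FALSE)
      }
      vals <- participants[[attr_name]][match(vnames, participants$pid)]
      out <- vapply(seq_len(n), function(i) {
        a <- as.integer(adj[[i]])
        av <- vals[a]; av <- av[!is.na(av)]
        if (!length(av)) return(0)
        if (m[2] == "any") as.numeric(any(av == 1L)) else mean(av == 1L)
      }, 0)
      return(out)
    }
    if (tm %in% names(participants)) {
      v <- participants[[tm]]
      if (anyNA(v)) v[is.na(v)] <- 0L
      return(as.numeric(v))
    }
    stop("mechanistic true_beta term '", tm,
         "' has no constructible design column", call. = FALSE)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- terms
  X
}

#' Simulate a full cohort (recruitment + outcomes) in one call
#'
#' @param config A [generator_config()].
#' @return List with `cohort` (three tables), `network`, `truth`.
#' @export
simulate_cohort <- function(config = generator_config()) {
  cohort <- simulate_recruitment(config)
  network <- build_network(cohort$referrals, cohort$participants)
  out <- simulate_outcomes(cohort, network, config)
  list(cohort = out$cohort, network = network, truth = out$truth)
}

#' Simulate a dyad-level dataset with crossed ego/alter random effects
#'
#' Generates dyad rows with a binary focal predictor (ego used any
#' prevention service), a binary moderator (partnership characteristic),
#' and a binary alter outcome drawn from
#' logit(p) = b0 + b_focal x + b_int x m + v_ego + r_alter,
#' with v_ego ~ N(0, sigma_e^2) and r_alter ~ N(0, sigma_a^2). Egos and
#' alters are drawn from overlapping pools so a participant can appear in
#' both roles. Used for parameter-recovery checks of the cross-classified
#' model.
#'
#' @param n_dyads Number of dyad rows.
#' @param n_participants Size of the shared ego/alter pool.
#' @param beta0 Intercept.
#' @param beta_focal Log-OR of the focal predictor in the moderator = 0
#'   stratum.
#' @param beta_int Interaction log-OR (stratum-1 effect is
#'   `beta_focal + beta_int`).
#' @param sigma_e,sigma_a Ego and alter random-intercept SDs.
#' @param p_focal,p_moderator Bernoulli rates of predictor and moderator.
#' @param seed RNG seed.
#' @return List: `design` data frame (`ego`, `alter`, `focal`, `moderator`,
#'   `y`) and `truth`.
#' @export
simulate_dyad_data <- function(n_dyads = 3000L, n_participants = 1200L,
                               beta0 = -1.5, beta_focal = 1.32,
                               beta_int = -0.84, sigma_e = 0.5,
                               sigma_a = 0.5, p_focal = 0.5,
                               p_moderator = 0.4, seed = 1L) {
  set.seed(seed)
  ego <- sample.int(n_participants, n_dyads, replace = TRUE)
  alter <- sample.int(n_participants, n_dyads, replace = TRUE)
  clash <- ego == alter
  alter[clash] <- (alter[clash] %% n_participants) + 1L
  v <- stats::rnorm(n_participants, 0, sigma_e)
  r <- stats::rnorm(n_participants, 0, sigma_a)
  focal <- .rbern(n_dyads, p_focal)
  moderator <- .rbern(n_dyads, p_moderator)
  eta <- beta0 + beta_focal * focal + beta_int * focal * moderator +
    v[ego] + r[alter]
  y <- .rbern(n_dyads, stats::plogis(eta))
  list(
    design = data.frame(ego = ego, alter = alter, focal = focal,
                        moderator = moderator, y = y),
    truth = list(beta0 = beta0, beta_focal = beta_focal, beta_int = beta_int,
                 sigma_e = sigma_e, sigma_a = sigma_a)
  )
}

#' Realized degree summary of a generated network
#'
#' @param network Sociometric network.
#' @return Named vector: median, q25, q75, max degree and isolate count.
#' @export
degree_summary <- function(network) {
  d <- igraph::degree(network)
  q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE, type = 1)
  c(q25 = q[1], median = q[2], q75 = q[3], max = max(d),
    n_isolates = sum(d == 0))
}
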