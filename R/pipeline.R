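# End-to-end orchestration: simulate (or load) -> build network -> build
# exposures -> fit the three model families for the three service outcomes
# plus sensitivity variants -> write a manifest, per-model JSON results and
# a long-format summary table.

# One global seed fans out to stage-specific seeds deterministically, so
# stages are independently rerunnable: stage k gets
# (seed * 1000003 + k) mod (2^31 - 19).
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 1000003 + stage) %% 2147483629)
}

# FNV-1a 32-bit hash of a string; used for the config fingerprint in the
# manifest (no cryptographic intent).
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^31 * (h >= 2^31)), b)
    h <- (as.double(h %% 2^32) * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Run configuration
#'
#' @param generator A [generator_config()], or NULL to read an existing
#'   cohort from `input_dir`.
#' @param input_dir Directory with participants.csv / dyads.csv /
#'   referrals.csv (used when `generator` is NULL).
#' @param outcomes Service outcomes to model.
#' @param mmmm_exposure_attrs Alter attributes aggregated over direct
#'   partners for the multiple-membership models.
#' @param ego_exposure_attrs Attributes aggregated over socially proximal
#'   peers for the egocentric models.
#' @param moderators Partnership flags for the cross-classified models.
#' @param mcmc An [mcmc_config()] (its seed is overridden by the fan-out).
#' @param sensitivity Run the sensitivity variants (proportion exposure,
#'   HIV-positive exclusion, direct-tie-excluded proximal scope, aggregated
#'   direct-tie egocentric fit).
#' @param seed Global seed.
#' @param out_dir Output directory.
#' @return Object of class `netmmm_run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       input_dir = NULL,
                       outcomes = .service_outcomes,
                       mmmm_exposure_attrs = "outcome_hiv_test_6m",
                       ego_exposure_attrs = "outcome_hiv_test_6m",
                       moderators = "inject_gt15",
                       mcmc = mcmc_config(),
                       sensitivity = FALSE,
                       seed = 1L,
                       out_dir = tempfile("netmmm_run_")) {
  stopifnot(all(outcomes %in% .service_outcomes))
  structure(list(generator = generator, input_dir = input_dir,
                 outcomes = outcomes,
                 mmmm_exposure_attrs = mmmm_exposure_attrs,
                 ego_exposure_attrs = ego_exposure_attrs,
                 moderators = moderators, mcmc = mcmc,
                 sensitivity = isTRUE(sensitivity),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "netmmm_run_config")
}

#' Summarize fits as a long forest table
#'
#' @param fits Named list of [fit_result()] objects; names encode
#'   `outcome.family` (free-form labels are kept as-is).
#' @return Data frame: label, term, or, low, high, converged; sorted by
#'   label then term.
#' @export
summarize_fits <- function(fits) {
  stopifnot(length(fits) >= 1)
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(label = nm, term = f$term, or = f$or,
               low = f$or_low, high = f$or_high,
               converged = attr(f, "converged"),
               n_used = attr(f, "n_used"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$label, out$term, method = "radix"), , drop = FALSE]
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, network assembly, exposure construction and the
#' three model families for each configured outcome, plus sensitivity
#' variants when requested; writes `manifest.json`, one JSON per fit, and
#' `summary.csv` to the output directory. Any stage error aborts with the
#' stage name; results written so far stay on disk next to a `FAILED`
#' marker file.
#'
#' @param config A [run_config()].
#' @return Invisibly, list with `fits`, `summary`, `network`, `cohort`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "netmmm_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fail <- function(stage, e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  log_line <- function(...) message(sprintf(...))

  # -- stage 1: cohort ------------------------------------------------------
  cohort <- tryCatch({
    if (is.null(config$generator)) {
      read_cohort(file.path(config$input_dir, "participants.csv"),
                  file.path(config$input_dir, "dyads.csv"),
                  file.path(config$input_dir, "referrals.csv"), quiet = TRUE)
    } else {
      gen <- config$generator
      gen$seed <- stage_seed(config$seed, 1L)
      sim <- simulate_recruitment(gen)
      simulate_outcomes(sim, config = gen,
                        seed = stage_seed(config$seed, 2L))$cohort
    }
  }, error = function(e) fail("cohort", e))
  log_line("stage cohort: n = %d participants, seed = %d",
           nrow(cohort$participants), config$seed)

  # -- stage 2: network -----------------------------------------------------
  network <- tryCatch(build_network(cohort$referrals, cohort$participants),
                      error = function(e) fail("network", e))
  deg <- igraph::degree(network)
  isolates <- igraph::V(network)$name[deg == 0]
  modeled <- cohort$participants[!cohort$participants$pid %in% isolates, ,
                                 drop = FALSE]
  log_line("stage network: %d edges, %d isolates excluded from modelling",
           igraph::ecount(network), length(isolates))

  # -- stage 3: exposures ---------------------------------------------------
  specs <- c(
    lapply(config$mmmm_exposure_attrs, exposure_spec, scope = "direct"),
    lapply(config$ego_exposure_attrs, exposure_spec, scope = "proximal_1_3")
  )
  if (config$sensitivity) {
    specs <- c(specs,
      lapply(config$mmmm_exposure_attrs, exposure_spec, scope = "direct",
             parameterization = "proportion"),
      lapply(config$ego_exposure_attrs, exposure_spec, scope = "proximal_2_3"))
  }
  exposures <- tryCatch(build_exposures(network, cohort$participants, specs),
                        error = function(e) fail("exposures", e))

  # -- stage 4: fits --------------------------------------------------------
  fits <- list()
  k <- 10L
  mc <- config$mcmc
  for (outc in config$outcomes) {
    k <- k + 1L
    mc$seed <- stage_seed(config$seed, k)
    # multiple-membership, direct partners
    sp_mm <- model_spec(outc, exposures = lapply(
      config$mmmm_exposure_attrs, exposure_spec, scope = "direct"))
    fits[[paste0(outc, ".mmmm")]] <- tryCatch({
      des <- build_mmmm_design(network, exposures, modeled, sp_mm)
      fit_mmmm(des, mc)
    }, error = function(e) fail(paste0("mmmm:", outc), e))
    # egocentric, socially proximal peers
    sp_ego <- model_spec(outc,
      exposures = lapply(config$ego_exposure_attrs, exposure_spec,
                         scope = "proximal_1_3"),
      a_priori = c("age", "gender_male", "marital", "education",
                   "log_proximal_size_1_3"))
    fits[[paste0(outc, ".ego")]] <- tryCatch(
      fit_ego(modeled, exposures, sp_ego),
      error = function(e) fail(paste0("ego:", outc), e))
    # cross-classified dyad models
    for (mod in config$moderators) {
      k <- k + 1L
      mc$seed <- stage_seed(config$seed, k)
      fits[[paste0(outc, ".dyad.", mod)]] <- tryCatch({
        des <- build_dyad_design(cohort$dyads, cohort$participants, mod, outc)
        fit_crossclassified(des, mc)
      }, error = function(e) fail(paste0("dyad:", outc, ":", mod), e))
    }
    if (config$sensitivity) {
      # proportion-parameterized direct exposure
      k <- k + 1L
      mc$seed <- stage_seed(config$seed, k)
      sp_prop <- model_spec(outc, exposures = lapply(
        config$mmmm_exposure_attrs, exposure_spec, scope = "direct",
        parameterization = "proportion"))
      fits[[paste0(outc, ".mmmm_prop")]] <- tryCatch({
        des <- build_mmmm_design(network, exposures, modeled, sp_prop)
        fit_mmmm(des, mc)
      }, error = function(e) fail(paste0("mmmm_prop:", outc), e))
      # excluding all baseline HIV-positive participants
      k <- k + 1L
      mc$seed <- stage_seed(config$seed, k)
      sp_hiv <- model_spec(outc,
        exposures = lapply(config$mmmm_exposure_attrs, exposure_spec,
                           scope = "direct"),
        exclusions = list(hiv_pos = 1L))
      fits[[paste0(outc, ".mmmm_hivneg")]] <- tryCatch({
        des <- build_mmmm_design(network, exposures, modeled, sp_hiv)
        fit_mmmm(des, mc)
      }, error = function(e) fail(paste0("mmmm_hivneg:", outc), e))
      # direct-tie-excluded proximal scope
      sp_2_3 <- model_spec(outc,
        exposures = lapply(config$ego_exposure_attrs, exposure_spec,
                           scope = "proximal_2_3"),
        a_priori = c("age", "gender_male", "marital", "education",
                     "log_proximal_size_2_3"))
      fits[[paste0(outc, ".ego_2_3")]] <- tryCatch(
        fit_ego(modeled, exposures, sp_2_3),
        error = function(e) fail(paste0("ego_2_3:", outc), e))
      # aggregated direct ego-network egocentric fit
      sp_dir <- model_spec(outc, exposures = lapply(
        config$mmmm_exposure_attrs, exposure_spec, scope = "direct"))
      fits[[paste0(outc, ".ego_direct")]] <- tryCatch(
        fit_ego(modeled, exposures, sp_dir),
        error = function(e) fail(paste0("ego_direct:", outc), e))
    }
  }

  # -- stage 5: report ------------------------------------------------------
  for (nm in names(fits)) {
    write_results(fits[[nm]], file.path(config$out_dir, paste0(nm, ".json")))
  }
  summary_df <- summarize_fits(fits)
  utils::write.csv(summary_df, file.path(config$out_dir, "summary.csv"),
                   row.names = FALSE)
  cfg_plain <- config
  cfg_plain$out_dir <- NULL    # paths are not part of the run identity
  cfg_plain$input_dir <- NULL
  cfg_plain$mcmc <- unclass(cfg_plain$mcmc)
  cfg_plain$generator <- if (!is.null(cfg_plain$generator))
    unclass(cfg_plain$generator)
  cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA,
                               null = "null", force = TRUE)
  manifest <- list(
    schema = "netmmm-manifest/1",
    seed = config$seed,
    config_hash = .fnv1a(as.character(cfg_json)),
    n_participants = nrow(cohort$participants),
    n_edges = igraph::ecount(network),
    n_isolates = length(isolates),
    fits = names(fits),
    package_version = as.character(utils::packageVersion("netmmm"))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(fits = fits, summary = summary_df, network = network,
                 cohort = cohort, out_dir = config$out_dir))
}
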