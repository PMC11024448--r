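# Ego-level network-exposure covariates.
#
# An exposure is an aggregation of a binary alter attribute over a network
# scope: the ego's direct injecting partners, the socially proximal peers at
# path length 1-3, or the direct-tie-excluded window 2-3. Parameterizations
# are `any` (>= 1 versus 0 alters with the attribute) and `proportion`
# (positives over alters with a non-missing value). Alters missing the
# attribute are dropped from numerator and denominator; an ego all of whose
# in-scope alters are missing gets NA and falls to complete-case handling
# downstream.

#' Declare a network exposure
#'
#' @param attribute Binary participant column to aggregate (e.g.
#'   `outcome_hiv_test_6m`, `hiv_pos`, `nonsterile_6m`), or `"any_service"`,
#'   a derived flag equal to the OR of the three service outcomes.
#' @param scope One of `"direct"`, `"proximal_1_3"`, `"proximal_2_3"`.
#' @param parameterization `"any"` (>= 1 vs 0) or `"proportion"`.
#' @return Object of class `netmmm_exposure_spec`.
#' @export
exposure_spec <- function(attribute,
                          scope = c("direct", "proximal_1_3", "proximal_2_3"),
                          parameterization = c("any", "proportion")) {
  scope <- match.arg(scope)
  parameterization <- match.arg(parameterization)
  structure(list(attribute = attribute, scope = scope,
                 parameterization = parameterization,
                 name = paste(substr(parameterization, 1, 4), attribute, scope,
                              sep = "_")),
            class = "netmmm_exposure_spec")
}

.exposure_attribute_values <- function(participants, attribute) {
  if (attribute == "any_service") {
    s <- cbind(participants$outcome_hiv_test_6m, participants$outcome_moud_6m,
               participants$outcome_ssp_6m)
    v <- as.integer(rowSums(s == 1L, na.rm = TRUE) > 0)
    v[rowSums(!is.na(s)) == 0L] <- NA_integer_
    return(v)
  }
  if (!attribute %in% names(participants)) {
    stop("exposure attribute '", attribute, "' is not a participant column",
         call. = FALSE)
  }
  v <- participants[[attribute]]
  if (!all(is.na(v) | v %in% c(0L, 1L))) {
    stop("exposure attribute '", attribute, "' is not binary", call. = FALSE)
  }
  as.integer(v)
}

.scope_members <- function(network, scope) {
  vnames <- igraph::V(network)$name
  if (scope == "direct") {
    adj <- igraph::adjacent_vertices(network, seq_along(vnames))
    return(lapply(adj, as.integer))
  }
  window <- if (scope == "proximal_1_3") c(1, 3) else c(2, 3)
  D <- igraph::distances(network)
  lapply(seq_along(vnames), function(i) {
    which(D[i, ] >= window[1] & D[i, ] <= window[2])
  })
}

#' Build the ego-level exposure table
#'
#' One row per participant. For each exposure spec, emits the aggregated
#' exposure column (named `<param>_<attribute>_<scope>`). Also emits the
#' network-size columns used for a-priori adjustment: `degree` and
#' `log_degree` (log number of injecting partners), `proximal_size_1_3` /
#' `proximal_size_2_3` and their logs (log ego-network size), computed for
#' every scope any spec requests. Log sizes are NA for empty sets.
#'
#' @param network Sociometric network.
#' @param participants Participant table.
#' @param specs List of [exposure_spec()] objects.
#' @return Data frame keyed by `pid`.
#' @export
build_exposures <- function(network, participants, specs) {
  participants <- validate_participants(participants)
  if (inherits(specs, "netmmm_exposure_spec")) specs <- list(specs)
  vnames <- igraph::V(network)$name
  ord <- match(participants$pid, vnames)
  if (anyNA(ord)) {
    stop("build_exposures: participants absent from network: ",
         paste(utils::head(participants$pid[is.na(ord)], 5), collapse = ", "),
         call. = FALSE)
  }
  scopes <- unique(c("direct", vapply(specs, `[[`, "", "scope")))
  members_by_scope <- lapply(stats::setNames(scopes, scopes), function(s) {
    .scope_members(network, s)
  })
  out <- data.frame(pid = participants$pid, stringsAsFactors = FALSE)
  deg <- lengths(members_by_scope[["direct"]])[ord]
  out$degree <- as.integer(deg)
  out$log_degree <- ifelse(deg > 0, log(deg), NA_real_)
  for (s in setdiff(scopes, "direct")) {
    sz <- lengths(members_by_scope[[s]])[ord]
    nm <- sub("proximal", "proximal_size", s)
    out[[nm]] <- as.integer(sz)
    out[[paste0("log_", nm)]] <- ifelse(sz > 0, log(sz), NA_real_)
  }
  for (spec in specs) {
    vals <- .exposure_attribute_values(participants, spec$attribute)
    vals_by_vertex <- vals[match(vnames, participants$pid)]
    members <- members_by_scope[[spec$scope]]
    col <- vapply(ord, function(i) {
      av <- vals_by_vertex[members[[i]]]
      av <- av[!is.na(av)]
      if (!length(av)) return(NA_real_)
      if (spec$parameterization == "any") as.numeric(any(av == 1L))
      else mean(av == 1L)
    }, 0)
    out[[spec$name]] <- col
  }
  out
}

#' Derive dyad-level partnership moderator flags
#'
#' Dichotomizations of the ego-reported partnership characteristics used as
#' effect modifiers: partnership duration over one year, injecting together
#' more than 15 times in the prior 30 days, and moderate-to-high trust
#' (trust score of 7 or more on the 1-10 scale; scores of 6 or less are
#' none/low trust). Missing inputs propagate to missing flags.
#'
#' @param dyads Dyad-report table.
#' @return The table with integer columns `years_known_gt1`, `inject_gt15`,
#'   `trust_high` appended.
#' @export
dyad_moderators <- function(dyads) {
  dyads <- validate_dyads(dyads)
  dyads$years_known_gt1 <- as.integer(dyads$years_known > 1)
  dyads$inject_gt15 <- as.integer(dyads$inject_times_30d > 15L)
  dyads$trust_high <- as.integer(dyads$trust_score >= 7L)
  dyads
}
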