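# Sociometric network assembly from coupon-referral records.
#
# Every returned coupon defines an (issuer, redeemer) injecting partnership.
# Linkages are assumed reciprocal, so the graph is undirected; multiple
# coupons between the same pair collapse to a single edge; unreturned
# coupons contribute nothing. Duplicate recruitment (a redeemer already
# enrolled) therefore yields cross-network linkages without new nodes.

#' Build the deduplicated sociometric network
#'
#' One node per enrolled participant (including isolates never linked by a
#' returned coupon), one undirected edge per returned coupon's
#' (issuer, redeemer) pair, collapsed across duplicate and reciprocal
#' coupons.
#'
#' @param referrals Referral table (see [validate_referrals()]).
#' @param participants Participant table; defines the node set.
#' @return An undirected simple [igraph::graph] with vertex name = pid.
#' @export
build_network <- function(referrals, participants) {
  participants <- validate_participants(participants)
  referrals <- validate_referrals(referrals)
  returned <- referrals[referrals$returned == 1L, , drop = FALSE]
  unknown <- setdiff(c(returned$issuer_pid, returned$redeemer_pid),
                     participants$pid)
  if (length(unknown)) {
    stop("build_network: coupon references pid absent from participant table: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(participants), name = participants$pid)
  if (nrow(returned)) {
    g <- igraph::add_edges(
      g, rbind(match(returned$issuer_pid, participants$pid),
               match(returned$redeemer_pid, participants$pid))
    )
  }
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Number of distinct direct injecting partners of a participant
#'
#' @param network Sociometric network.
#' @param pid Participant identifier(s).
#' @return Integer vector of degrees.
#' @export
net_degree <- function(network, pid) {
  idx <- match(pid, igraph::V(network)$name)
  if (anyNA(idx)) {
    stop("net_degree: unknown pid: ", paste(pid[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  as.integer(igraph::degree(network, idx))
}

#' Socially proximal peer set of an ego
#'
#' Members whose shortest-path distance d from the ego satisfies
#' `min_dist <= d <= max_dist`, computed by breadth-first search on the
#' undirected deduplicated graph. Path length counts edges, so a direct
#' injecting partner is at distance 1 and the default (1, 3) window gives
#' the socially proximal peers at three or fewer links. `min_dist = 2`
#' gives the direct-tie-excluded variant used in sensitivity analyses.
#' Proximity never crosses connected components.
#'
#' @param network Sociometric network.
#' @param ego_pid Ego identifier.
#' @param min_dist,max_dist Distance window, `1 <= min_dist <= max_dist`.
#' @return List with `ego_pid`, `members` (character vector of pids),
#'   `min_dist`, `max_dist`, `size`.
#' @export
proximal_set <- function(network, ego_pid, min_dist = 1L, max_dist = 3L) {
  stopifnot(min_dist >= 1L, min_dist <= max_dist)
  idx <- match(ego_pid, igraph::V(network)$name)
  if (is.na(idx)) stop("proximal_set: unknown ego: ", ego_pid, call. = FALSE)
  d <- as.vector(igraph::distances(network, v = idx, mode = "all"))
  keep <- which(d >= min_dist & d <= max_dist)
  members <- igraph::V(network)$name[keep]
  list(ego_pid = ego_pid, members = members,
       min_dist = as.integer(min_dist), max_dist = as.integer(max_dist),
       size = length(members))
}

#' Multiple-membership weights of an ego
#'
#' Each ego belongs fractionally to its direct injecting partners' higher
#' level units, with weights inversely proportional to the ego's total
#' number of injecting partners in the sociometric network and summing to
#' one: w_ij = 1/degree(i) for every direct alter j.
#'
#' @param network Sociometric network.
#' @param ego_pid Ego identifier.
#' @return Named numeric vector: names are alter pids, values the weights.
#' @export
membership_weights <- function(network, ego_pid) {
  idx <- match(ego_pid, igraph::V(network)$name)
  if (is.na(idx)) stop("membership_weights: unknown ego: ", ego_pid, call. = FALSE)
  alters <- igraph::V(network)$name[igraph::neighbors(network, idx)]
  k <- length(alters)
  if (k == 0L) {
    stop("membership_weights: ego '", ego_pid,
         "' has no injecting partners (degree 0); no membership set exists",
         call. = FALSE)
  }
  w <- rep(1 / k, k)
  w[k] <- 1 - sum(w[-k])  # force exact unit sum despite rounding
  stats::setNames(w, alters)
}

#' Expand unique dyads to directed ego/alter records
#'
#' Every undirected partnership is represented twice, once for each
#' participant's role as ego and as alter. This is the doubled dyad
#' representation underpinning the multiple-membership random-effect
#' structure.
#'
#' @param network Sociometric network.
#' @return Data frame with columns `ego_pid`, `alter_pid`; one row per
#'   ordered pair, i.e. twice the number of unique dyads.
#' @export
directed_dyad_records <- function(network) {
  el <- igraph::as_edgelist(network, names = TRUE)
  data.frame(
    ego_pid = c(el[, 1], el[, 2]),
    alter_pid = c(el[, 2], el[, 1]),
    stringsAsFactors = FALSE
  )
}

#' Write the network edge list as CSV (and optionally GraphML)
#'
#' @param network Sociometric network.
#' @param path Output CSV path (`ego_pid`, `alter_pid`, one row per
#'   undirected edge).
#' @param graphml Optional GraphML path for visualization tools.
#' @return Invisibly, `path`.
#' @export
write_edgelist <- function(network, path, graphml = NULL) {
  el <- igraph::as_edgelist(network, names = TRUE)
  utils::write.csv(
    data.frame(ego_pid = el[, 1], alter_pid = el[, 2]),
    path, row.names = FALSE, quote = FALSE
  )
  if (!is.null(graphml)) {
    igraph::write_graph(network, graphml, format = "graphml")
  }
  invisible(path)
}
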