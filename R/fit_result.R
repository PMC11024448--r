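# Common container for model fits: per-term log-odds estimates, odds ratios
# with 95% intervals, and estimation metadata. All three model families
# (egocentric IRLS, multiple-membership MCMC, cross-classified MCMC) return
# this shape so downstream reporting is uniform.

#' Construct a fit result
#'
#' @param term Character vector of coefficient names.
#' @param estimate Log-odds point estimates (posterior medians for Bayesian
#'   fits, maximum-likelihood estimates otherwise).
#' @param or_low,or_high 95% interval bounds on the odds-ratio scale.
#' @param method Estimation method label, e.g. "irls" or "mcmc-mmmm".
#' @param n_used Rows entering the fit after exclusions and complete-case
#'   filtering.
#' @param n_dropped Rows dropped (exclusion rules plus missing data).
#' @param rhat,ess Optional per-term convergence diagnostic and effective
#'   sample size (Bayesian fits).
#' @param sigma Optional named vector of random-effect standard deviation
#'   estimates.
#' @param p_interaction Optional interaction evidence: two-sided posterior
#'   tail probability (Bayesian) or Wald p-value (frequentist).
#' @param converged Logical convergence flag.
#' @param extra Optional named list of additional scalar summaries (e.g.
#'   stratum-specific odds ratios).
#' @return Object of class `netmmm_fit`: a data frame of terms with metadata
#'   attributes.
#' @export
fit_result <- function(term, estimate, or_low, or_high, method, n_used,
                       n_dropped = 0L, rhat = NULL, ess = NULL, sigma = NULL,
                       p_interaction = NULL, converged = TRUE, extra = NULL) {
  stopifnot(length(term) == length(estimate),
            length(or_low) == length(estimate),
            length(or_high) == length(estimate))
  res <- data.frame(
    term = as.character(term),
    estimate = as.numeric(estimate),
    or = exp(as.numeric(estimate)),
    or_low = as.numeric(or_low),
    or_high = as.numeric(or_high),
    stringsAsFactors = FALSE
  )
  if (!is.null(rhat)) res$rhat <- as.numeric(rhat)
  if (!is.null(ess)) res$ess <- as.numeric(ess)
  bad <- res$or_low > res$or + 1e-8 | res$or_high < res$or - 1e-8
  if (any(bad)) {
    stop("fit_result: interval does not bracket point estimate for term ",
         res$term[which(bad)[1]], call. = FALSE)
  }
  structure(res,
            class = c("netmmm_fit", "data.frame"),
            method = method,
            n_used = as.integer(n_used),
            n_dropped = as.integer(n_dropped),
            sigma = sigma,
            p_interaction = p_interaction,
            converged = isTRUE(converged),
            extra = extra)
}

#' @export
print.netmmm_fit <- function(x, ...) {
  cat(sprintf("<netmmm fit: %s, n = %d (%d dropped)%s>\n",
              attr(x, "method"), attr(x, "n_used"), attr(x, "n_dropped"),
              if (attr(x, "converged")) "" else ", NOT CONVERGED"))
  df <- as.data.frame(x)
  df$or <- sprintf("%.3f", df$or)
  df$ci <- sprintf("(%.3f, %.3f)", x$or_low, x$or_high)
  print(df[, c("term", "or", "ci")], row.names = FALSE)
  sig <- attr(x, "sigma")
  if (!is.null(sig)) {
    cat("random-effect sd:",
        paste(sprintf("%s = %.3f", names(sig), sig), collapse = ", "), "\n")
  }
  pint <- attr(x, "p_interaction")
  if (!is.null(pint)) cat(sprintf("interaction evidence: p = %.4g\n", pint))
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' Writes a schema-versioned JSON document. Terms are emitted in sorted term
#' order so that serialization is byte-stable regardless of how the fit
#' ordered its coefficients. Non-finite estimates are refused.
#'
#' @param fit A `netmmm_fit`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_results <- function(fit, path) {
  stopifnot(inherits(fit, "netmmm_fit"))
  if (!all(is.finite(fit$estimate)) || !all(is.finite(fit$or_low)) ||
      !all(is.finite(fit$or_high))) {
    stop("write_results: non-finite estimate or interval bound", call. = FALSE)
  }
  ord <- order(fit$term, method = "radix")
  terms <- as.data.frame(fit)[ord, , drop = FALSE]
  doc <- list(
    schema = "netmmm-fit/1",
    method = attr(fit, "method"),
    n_used = attr(fit, "n_used"),
    n_dropped = attr(fit, "n_dropped"),
    converged = attr(fit, "converged"),
    terms = terms
  )
  sig <- attr(fit, "sigma")
  if (!is.null(sig)) doc$sigma <- as.list(sig)
  pint <- attr(fit, "p_interaction")
  if (!is.null(pint)) doc$p_interaction <- pint
  extra <- attr(fit, "extra")
  if (!is.null(extra)) doc$extra <- extra
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a fit result written by [write_results()]
#'
#' @param path JSON file path.
#' @return A `netmmm_fit`.
#' @export
read_results <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "netmmm-fit/1")) {
    stop("read_results: unrecognized schema: ", doc$schema, call. = FALSE)
  }
  terms <- doc$terms
  fit_result(
    term = terms$term, estimate = terms$estimate,
    or_low = terms$or_low, or_high = terms$or_high,
    method = doc$method, n_used = doc$n_used, n_dropped = doc$n_dropped,
    rhat = terms$rhat, ess = terms$ess,
    sigma = if (!is.null(doc$sigma)) unlist(doc$sigma),
    p_interaction = doc$p_interaction,
    converged = doc$converged,
    extra = doc$extra
  )
}
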