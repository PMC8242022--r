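#' Logistic psychometric function
#'
#' Probability of a right-first response, `p(t) = 1 / (1 + exp(-theta * t))`,
#' with `t` the signed SOA in model time units (seconds by convention;
#' negative = left hand first) and `theta` the slope. Numerically stable
#' over the full double range; satisfies `p(-t) = 1 - p(t)`.
#'
#' @param theta Slope (per time unit). Recycled against `t`.
#' @param t Signed SOA in model time units.
#' @return Probabilities in `[0, 1]`.
#' @examples
#' psychometric_p(10, 0)          # 0.5
#' psychometric_p(log(3), 1)      # 0.75
#' @export
psychometric_p <- function(theta, t) {
  stopifnot(all(is.finite(theta)), all(is.finite(t)))
  plogis(theta * t)
}

#' Psychometric slopes from reference-frame weights
#'
#' In the uncrossed posture the internal (anatomical) and external
#' (spatial) reference frames agree, so the slope is the sum of the
#' weights; crossing the hands puts the external frame in conflict, so
#' the crossed slope is the difference and may be negative (below-chance
#' responding when the external weight dominates).
#'
#' @param omega_internal,omega_external Positive weights.
#' @return A list with `theta_uncrossed` (`omega_internal +
#'   omega_external`) and `theta_crossed` (`omega_internal -
#'   omega_external`).
#' @export
slopes_from_weights <- function(omega_internal, omega_external) {
  if (any(omega_internal <= 0) || any(omega_external <= 0)) {
    stop("weights must be strictly positive", call. = FALSE)
  }
  list(theta_uncrossed = omega_internal + omega_external,
       theta_crossed = omega_internal - omega_external)
}

#' Apply the body-posture context multipliers
#'
#' Lying-down weights are the upright weights scaled by the population
#' context parameters, identically for every participant: a delta below
#' 1 shrinks the weight when lying down, above 1 grows it.
#'
#' @param omega_internal,omega_external Positive upright weights.
#' @param delta_internal,delta_external Positive context multipliers.
#' @return A list with the lying-posture `omega_internal` and
#'   `omega_external`.
#' @export
apply_context <- function(omega_internal, omega_external,
                          delta_internal, delta_external) {
  if (any(c(omega_internal, omega_external,
            delta_internal, delta_external) <= 0)) {
    stop("weights and context parameters must be strictly positive",
         call. = FALSE)
  }
  list(omega_internal = delta_internal * omega_internal,
       omega_external = delta_external * omega_external)
}

#' Uniform hyperprior bounds for the population parameters
#'
#' All population parameters carry strictly positive, flat hyperpriors;
#' these upper bounds make them proper. Defaults are generous enough to
#' be effectively flat over the posterior mass.
#'
#' @param max_mean,max_sd,max_delta Upper bounds for the population
#'   weight means, SDs, and context multipliers.
#' @return An object of class `toj_hyperprior`.
#' @export
hyperprior_spec <- function(max_mean = 100, max_sd = 100, max_delta = 10) {
  stopifnot(max_mean > 0, max_sd > 0, max_delta > 0)
  structure(list(max_mean = max_mean, max_sd = max_sd,
                 max_delta = max_delta), class = "toj_hyperprior")
}

#' Construct a model hypothesis
#'
#' One hypothesis bundles the 6 population parameters with an upright
#' internal/external weight pair per participant — `6 + 2N` parameters
#' in all (46 for the canonical 20 participants). Internally a named
#' numeric vector in the fixed order `mu_internal`, `mu_external`,
#' `sigma_internal`, `sigma_external`, `delta_internal`,
#' `delta_external`, then `omega_internal[<id>]`, then
#' `omega_external[<id>]`.
#'
#' @param mu_internal,mu_external,sigma_internal,sigma_external
#'   Population truncated-Gaussian parameters of the upright weights.
#' @param delta_internal,delta_external Context multipliers.
#' @param omega_internal,omega_external Per-participant upright weights
#'   (equal-length vectors).
#' @param participant_ids Optional participant labels.
#' @return A named numeric vector of class `toj_hypothesis` with
#'   attribute `n_participants`.
#' @export
hypothesis <- function(mu_internal, mu_external,
                       sigma_internal, sigma_external,
                       delta_internal, delta_external,
                       omega_internal, omega_external,
                       participant_ids = NULL) {
  n <- length(omega_internal)
  if (length(omega_external) != n) {
    stop("omega_internal and omega_external must have equal length",
         call. = FALSE)
  }
  if (is.null(participant_ids)) participant_ids <- sprintf("P%02d", seq_len(n))
  h <- c(mu_internal = mu_internal, mu_external = mu_external,
         sigma_internal = sigma_internal, sigma_external = sigma_external,
         delta_internal = delta_internal, delta_external = delta_external,
         setNames(omega_internal, paste0("omega_internal[", participant_ids, "]")),
         setNames(omega_external, paste0("omega_external[", participant_ids, "]")))
  structure(h, n_participants = n, class = "toj_hypothesis")
}

#' Prepare a cell-count table for repeated likelihood evaluation
#'
#' Flattens counts into parallel vectors (participant index, SOA in
#' model time units, crossed sign, lying flag, response tallies) so the
#' sampler can evaluate the joint likelihood without data-frame
#' overhead.
#'
#' @noRd
.prepare_counts <- function(counts, time_unit = 1e-3) {
  pids <- sort(unique(counts$participant_id))
  list(
    participant_ids = pids,
    n = length(pids),
    pid = match(counts$participant_id, pids),
    t = counts$soa_ms * time_unit,
    sgn = ifelse(counts$hand_posture == "crossed", -1, 1),
    lying = counts$body_posture == "side",
    r = counts$n_right_first,
    l = counts$n_left_first)
}

#' Joint binomial log-likelihood over all cells, fast path
#'
#' `par` is the hypothesis vector in canonical order. Omits the
#' binomial coefficient (constant in the parameters).
#' @noRd
.loglik_cells <- function(par, prep) {
  n <- prep$n
  wi <- par[6 + prep$pid]
  we <- par[6 + n + prep$pid]
  wi[prep$lying] <- wi[prep$lying] * par[5]
  we[prep$lying] <- we[prep$lying] * par[6]
  x <- (wi + prep$sgn * we) * prep$t
  sum(prep$r * plogis(x, log.p = TRUE) +
      prep$l * plogis(-x, log.p = TRUE))
}

#' Per-participant binomial log-likelihood
#'
#' The log-probability of one participant's right-/left-first tallies
#' under the four psychometric curves the hypothesis implies (two hand
#' postures in each body posture): the sum over cells of
#' `r * log p(t) + l * log(1 - p(t))`, with lying-down cells using the
#' context-multiplied weights. The binomial coefficient is omitted
#' (constant in the parameters). Saturated cells with discordant counts
#' yield `-Inf`, never an error.
#'
#' @param counts Cell-count rows for a single participant.
#' @param omega_internal,omega_external The participant's upright
#'   weights.
#' @param delta_internal,delta_external Context multipliers.
#' @param time_unit Factor converting `soa_ms` to model time units
#'   (default `1e-3`: seconds).
#' @return The log-likelihood (scalar; may be `-Inf`).
#' @export
participant_loglik <- function(counts, omega_internal, omega_external,
                               delta_internal = 1, delta_external = 1,
                               time_unit = 1e-3) {
  if (length(unique(counts$participant_id)) > 1) {
    stop("counts must belong to a single participant", call. = FALSE)
  }
  prep <- .prepare_counts(counts, time_unit)
  par <- c(0, 0, 0, 0, delta_internal, delta_external,
           omega_internal, omega_external)
  .loglik_cells(par, prep)
}

#' Log-prior of a hypothesis
#'
#' Each participant's upright weights are a priori truncated-Gaussian
#' (limits 0, Inf) given the population means and SDs — the log-density
#' includes the truncation normalizer, which matters because the SDs
#' are themselves sampled — plus a flat (constant) hyperprior on the
#' population parameters inside the positive bounds of `hyper`. Any
#' parameter at or below zero, or beyond its bound, gives `-Inf`.
#'
#' @param h A [hypothesis()].
#' @param hyper A [hyperprior_spec()].
#' @return Scalar log-prior (may be `-Inf`).
#' @export
log_prior <- function(h, hyper = hyperprior_spec()) {
  n <- attr(h, "n_participants")
  .log_prior_par(unclass(h), n, hyper)
}

#' @noRd
.log_prior_par <- function(par, n, hyper) {
  if (any(par <= 0)) return(-Inf)
  if (par[1] > hyper$max_mean || par[2] > hyper$max_mean ||
      par[3] > hyper$max_sd || par[4] > hyper$max_sd ||
      par[5] > hyper$max_delta || par[6] > hyper$max_delta) {
    return(-Inf)
  }
  wi <- par[6 + seq_len(n)]
  we <- par[6 + n + seq_len(n)]
  sum(.dtruncnorm0_log(wi, par[1], par[3])) +
    sum(.dtruncnorm0_log(we, par[2], par[4]))
}

#' Unnormalized log-posterior of a hypothesis
#'
#' The sum over participants of the binomial log-likelihood (lying
#' cells use the context-multiplied weights) plus the
#' hierarchical log-prior. Out-of-support hypotheses give `-Inf`.
#'
#' @param h A [hypothesis()] whose participant count matches the data.
#' @param counts Cell-count table for every participant (one vision
#'   group; see [aggregate_counts()]).
#' @param hyper A [hyperprior_spec()].
#' @param time_unit Factor converting `soa_ms` to model time units.
#' @return Scalar unnormalized log-posterior (may be `-Inf`).
#' @export
log_posterior <- function(h, counts, hyper = hyperprior_spec(),
                          time_unit = 1e-3) {
  prep <- .prepare_counts(counts, time_unit)
  if (prep$n != attr(h, "n_participants")) {
    stop("hypothesis has ", attr(h, "n_participants"),
         " participants but the data have ", prep$n, call. = FALSE)
  }
  .log_post_par(unclass(h), prep, hyper)
}

#' @noRd
.log_post_par <- function(par, prep, hyper) {
  lp <- .log_prior_par(par, prep$n, hyper)
  if (!is.finite(lp)) return(-Inf)
  lp + .loglik_cells(par, prep)
}
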