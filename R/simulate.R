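#' Generating-parameter configuration for a synthetic experiment
#'
#' Population-level ground truth for the generative model: participant
#' weights for the internal and external reference frame are drawn from
#' Gaussians truncated to (0, Inf) with means `mu_*` and standard
#' deviations `sigma_*` (per-second slope units), and lying-down weights
#' are the upright weights multiplied by the context parameters
#' `delta_*`, identically for all participants. Nuisance timeout and
#' premature-response trials can be injected to exercise the
#' preprocessing filters.
#'
#' No generating values are defaulted silently; use [truth_preset()] for
#' a documented ready-made configuration.
#'
#' @param n_participants Number of participants.
#' @param mu_internal,mu_external Population means of the upright
#'   weights (per-second units); must be positive.
#' @param sigma_internal,sigma_external Population SDs of the upright
#'   weights; must be positive.
#' @param delta_internal,delta_external Context multipliers applied to
#'   the upright weights in the lying posture; must be positive.
#' @param timeout_rate,premature_rate Probabilities in `[0, 1)` of a
#'   trial timing out / being answered prematurely (< 100 ms).
#' @return An object of class `toj_truth_config`.
#' @export
truth_config <- function(n_participants,
                         mu_internal, mu_external,
                         sigma_internal, sigma_external,
                         delta_internal, delta_external,
                         timeout_rate = 0, premature_rate = 0) {
  pos <- c(mu_internal = mu_internal, mu_external = mu_external,
           sigma_internal = sigma_internal, sigma_external = sigma_external,
           delta_internal = delta_internal, delta_external = delta_external)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("all weight, scale and context parameters must be positive; got ",
         paste(names(pos)[pos <= 0 | !is.finite(pos)], collapse = ", "),
         call. = FALSE)
  }
  rates <- c(timeout_rate, premature_rate)
  if (any(rates < 0 | rates >= 1)) {
    stop("timeout_rate and premature_rate must lie in [0, 1)", call. = FALSE)
  }
  if (n_participants < 1) stop("n_participants must be >= 1", call. = FALSE)
  structure(list(
    n_participants = as.integer(n_participants),
    mu_internal = mu_internal, mu_external = mu_external,
    sigma_internal = sigma_internal, sigma_external = sigma_external,
    delta_internal = delta_internal, delta_external = delta_external,
    timeout_rate = timeout_rate, premature_rate = premature_rate
  ), class = "toj_truth_config")
}

#' Ready-made generating configurations
#'
#' Two documented presets emulating a full-vision and a blindfolded
#' crossed-hands TOJ experiment. Both use the same population weight
#' distribution — mean internal weight 8, mean external weight 5,
#' both SDs 2 (per-second slope units) — chosen so that uncrossed
#' accuracy is near ceiling at +/-400 ms, crossed accuracy is clearly
#' degraded, and the upright crossed-hands deficit is of the size seen
#' in published experiments. The presets differ in the context
#' multipliers: lying on the side raises the internal weight slightly
#' and cuts the external weight sharply, more so when blindfolded
#' (full vision: `delta_internal` 1.25, `delta_external` 0.31;
#' blindfold: 1.16 and 0.16 — representative posterior point estimates
#' for these conditions).
#'
#' @param preset `"full_vision"` or `"blindfold"`.
#' @param n_participants Number of participants (default 20).
#' @param timeout_rate,premature_rate Nuisance-trial rates, passed to
#'   [truth_config()].
#' @return A `toj_truth_config`.
#' @examples
#' truth_preset("blindfold")$delta_external  # 0.16
#' @export
truth_preset <- function(preset = c("full_vision", "blindfold"),
                         n_participants = 20,
                         timeout_rate = 0, premature_rate = 0) {
  preset <- match.arg(preset)
  deltas <- switch(preset,
    full_vision = c(internal = 1.25, external = 0.31),
    blindfold = c(internal = 1.16, external = 0.16))
  truth_config(
    n_participants = n_participants,
    mu_internal = 8, mu_external = 5,
    sigma_internal = 2, sigma_external = 2,
    delta_internal = deltas[["internal"]],
    delta_external = deltas[["external"]],
    timeout_rate = timeout_rate, premature_rate = premature_rate)
}

#' Truncated-normal draws on (0, Inf) by inverse CDF
#'
#' Exact, seed-stable sampling without a rejection loop.
#' @noRd
.rtruncnorm0 <- function(n, mean, sd) {
  p0 <- pnorm(0, mean, sd)
  qnorm(p0 + runif(n) * (1 - p0), mean, sd)
}

#' Truncated-normal log-density on (0, Inf)
#' @noRd
.dtruncnorm0_log <- function(x, mean, sd) {
  ifelse(x > 0,
         dnorm(x, mean, sd, log = TRUE) -
           pnorm(0, mean, sd, lower.tail = FALSE, log.p = TRUE),
         -Inf)
}

#' Draw a synthetic participant population
#'
#' Draws each participant's upright internal and external weights
#' independently from the truncated-Gaussian population distributions of
#' the configuration, by inverse-CDF sampling on the truncated domain.
#'
#' @param config A [truth_config()].
#' @param seed Optional integer seed.
#' @return A data frame with columns `participant_id`,
#'   `omega_internal`, `omega_external`; all weights strictly positive.
#' @export
draw_population <- function(config, seed = NULL) {
  stopifnot(inherits(config, "toj_truth_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_participants
  data.frame(
    participant_id = sprintf("P%02d", seq_len(n)),
    omega_internal = .rtruncnorm0(n, config$mu_internal,
                                  config$sigma_internal),
    omega_external = .rtruncnorm0(n, config$mu_external,
                                  config$sigma_external),
    stringsAsFactors = FALSE)
}

#' Simulate one participant's session
#'
#' Generates the full trial table for one participant from the
#' generative model: per trial, the probability of a right-first
#' response is the logistic `1 / (1 + exp(-theta * t))` with `t` the
#' signed SOA in seconds and `theta` the posture-specific slope —
#' `omega_internal + omega_external` uncrossed,
#' `omega_internal - omega_external` crossed, with lying-down weights
#' `delta_internal * omega_internal` and
#' `delta_external * omega_external`. Nuisance trials are injected at
#' the configured rates: timeouts carry no latency, premature trials
#' get a latency below 100 ms and a response drawn at chance. Responded
#' non-premature trials get a latency drawn uniformly in 300-1500 ms.
#'
#' @param truth One-row slice of [draw_population()] output (or any list
#'   with `participant_id`, `omega_internal`, `omega_external`).
#' @param config The [truth_config()] used to draw the population.
#' @param design A [design_spec()].
#' @param vision `"intact"` or `"blindfold"` metadata for the session.
#' @param posture_order,hand_order Counterbalancing, see
#'   [schedule_trials()].
#' @param seed Optional integer seed.
#' @return A validated trial data frame; attribute `injected` is a
#'   logical vector marking the injected nuisance rows.
#' @export
simulate_session <- function(truth, config, design = design_spec(),
                             vision = c("intact", "blindfold"),
                             posture_order = "upright_first",
                             hand_order = "uncrossed_first",
                             seed = NULL) {
  stopifnot(inherits(config, "toj_truth_config"))
  vision <- match.arg(vision)
  if (!is.null(seed)) set.seed(seed)

  sch <- schedule_trials(design, posture_order = posture_order,
                         hand_order = hand_order)
  lying <- sch$body_posture == "side"
  wi <- truth$omega_internal * ifelse(lying, config$delta_internal, 1)
  we <- truth$omega_external * ifelse(lying, config$delta_external, 1)
  theta <- ifelse(sch$hand_posture == "crossed", wi - we, wi + we)
  p_right <- plogis(theta * sch$soa_ms / 1000)

  n <- nrow(sch)
  response <- ifelse(rbinom(n, 1, p_right) == 1, "right_first", "left_first")
  latency <- round(runif(n, 300, 1500))

  u <- runif(n)
  is_timeout <- u < config$timeout_rate
  is_premature <- !is_timeout &
    u < config$timeout_rate + config$premature_rate
  response[is_timeout] <- "timeout"
  latency[is_timeout] <- NA_real_
  response[is_premature] <- ifelse(runif(sum(is_premature)) < 0.5,
                                   "left_first", "right_first")
  latency[is_premature] <- round(runif(sum(is_premature), 0, 99))

  trials <- data.frame(
    participant_id = truth$participant_id,
    vision = vision,
    body_posture = sch$body_posture,
    hand_posture = sch$hand_posture,
    soa_ms = sch$soa_ms,
    response = response,
    latency_ms = latency,
    block_index = sch$block_index,
    trial_index = sch$trial_index,
    stringsAsFactors = FALSE)
  validate_trials(trials, soa_set_ms = design$soa_set_ms)
  attr(trials, "injected") <- is_timeout | is_premature
  trials
}

#' Simulate a complete synthetic experiment
#'
#' Draws a participant population and simulates every participant's
#' session, counterbalancing starting body and hand posture across
#' participants in a Latin-square rotation.
#'
#' @param config A [truth_config()] or [truth_preset()].
#' @param design A [design_spec()].
#' @param vision Session metadata, `"intact"` or `"blindfold"`.
#' @param seed Integer seed; the whole experiment is reproducible
#'   given `config` and `seed`.
#' @return A list with elements `trials` (all participants' trial rows,
#'   with attribute `injected` marking nuisance rows), `truth` (the
#'   drawn population weights) and `config`.
#' @examples
#' sim <- simulate_experiment(truth_preset("full_vision",
#'                                         n_participants = 2), seed = 8)
#' table(sim$trials$hand_posture)
#' @export
simulate_experiment <- function(config, design = design_spec(),
                                vision = c("intact", "blindfold"),
                                seed = NULL) {
  stopifnot(inherits(config, "toj_truth_config"))
  vision <- match.arg(vision)
  if (!is.null(seed)) set.seed(seed)

  truth <- draw_population(config)
  orders <- expand.grid(
    posture_order = c("upright_first", "side_first"),
    hand_order = c("uncrossed_first", "crossed_first"),
    stringsAsFactors = FALSE)

  sessions <- lapply(seq_len(config$n_participants), function(i) {
    o <- orders[(i - 1) %% nrow(orders) + 1, ]
    simulate_session(truth[i, ], config, design, vision = vision,
                     posture_order = o$posture_order,
                     hand_order = o$hand_order)
  })
  trials <- do.call(rbind, sessions)
  rownames(trials) <- NULL
  attr(trials, "injected") <- unlist(lapply(sessions, attr, "injected"),
                                     use.names = FALSE)
  list(trials = trials, truth = truth, config = config)
}
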