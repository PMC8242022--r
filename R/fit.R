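#' Fit the hierarchical reference-frame model
#'
#' The front-end of the Bayesian layer: runs several independent
#' Metropolis-Hastings chains ([run_chain()]) over the
#' `6 + 2N`-parameter hypothesis, pools the post-burn-in samples, and
#' summarises the posterior — means and equal-tail 95% credible
#' intervals for the six population parameters with split-chain R-hat
#' per parameter, plus per-participant weight posterior means.
#'
#' Each experiment (vision condition) is modelled separately: the data
#' passed here must contain a single vision level. Trial-level input is
#' aggregated with [aggregate_counts()] and must already be filtered
#' ([filter_trials()]).
#'
#' @param data A cell-count table ([aggregate_counts()]) or a filtered
#'   trial table.
#' @param config A [sampler_config()]; use [reduced_budget_config()]
#'   for desk-scale runs.
#' @param hyper A [hyperprior_spec()].
#' @param time_unit Factor converting `soa_ms` to model time units
#'   (default `1e-3`: seconds).
#' @param inits Optional list of initial [hypothesis()] objects, one
#'   per chain; by default each chain draws its own dispersed random
#'   initial values.
#' @return An object of class `rf_fit` with components `chains` (list
#'   of `toj_chain`), `summary` (population-parameter table:
#'   `mean`, `lo`, `hi`, `rhat`), `participant_weights` (posterior-mean
#'   upright weights per participant), `acceptance_rates`, `config`,
#'   `hyper`, `time_unit`, `participants`, and `call`. Methods:
#'   [print.rf_fit()], [summary.rf_fit()], [coef.rf_fit()],
#'   [plot.rf_fit()].
#' @examples
#' \donttest{
#' sim <- simulate_experiment(truth_preset("full_vision", 4), seed = 2)
#' counts <- aggregate_counts(filter_trials(sim$trials)$trials)
#' fit <- fit_reference_frames(counts,
#'   config = reduced_budget_config(n_samples = 2000, burn_in = 500))
#' coef(fit)
#' }
#' @export
fit_reference_frames <- function(data, config = sampler_config(),
                                 hyper = hyperprior_spec(),
                                 time_unit = 1e-3, inits = NULL) {
  cl <- match.call()
  if ("response" %in% names(data)) data <- aggregate_counts(data)
  if (length(unique(data$vision)) > 1) {
    stop("fit one vision condition at a time; got: ",
         paste(unique(data$vision), collapse = ", "), call. = FALSE)
  }
  prep <- .prepare_counts(data, time_unit)
  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max, config$n_chains)
  if (!is.null(inits) && length(inits) != config$n_chains) {
    stop("need one init per chain", call. = FALSE)
  }

  chains <- lapply(seq_len(config$n_chains), function(k) {
    run_chain(data, config = config,
              init = if (is.null(inits)) NULL else inits[[k]],
              chain_seed = chain_seeds[k], hyper = hyper,
              time_unit = time_unit)
  })

  pooled <- do.call(rbind, lapply(chains, `[[`, "samples"))
  pop_names <- c("mu_internal", "mu_external", "sigma_internal",
                 "sigma_external", "delta_internal", "delta_external")
  rhat <- if (config$n_chains >= 2) {
    vapply(pop_names, function(p) {
      gelman_rubin(lapply(chains, function(ch) ch$samples[, p]))
    }, numeric(1))
  } else {
    setNames(rep(NA_real_, length(pop_names)), pop_names)
  }
  smry <- data.frame(
    parameter = pop_names,
    mean = colMeans(pooled[, pop_names, drop = FALSE]),
    lo = vapply(pop_names, function(p) credible_interval(pooled[, p])[["lo"]],
                numeric(1)),
    hi = vapply(pop_names, function(p) credible_interval(pooled[, p])[["hi"]],
                numeric(1)),
    rhat = rhat, row.names = NULL, stringsAsFactors = FALSE)

  w_means <- data.frame(
    participant_id = prep$participant_ids,
    omega_internal = colMeans(pooled)[paste0("omega_internal[",
                                             prep$participant_ids, "]")],
    omega_external = colMeans(pooled)[paste0("omega_external[",
                                             prep$participant_ids, "]")],
    row.names = NULL, stringsAsFactors = FALSE)

  structure(list(
    chains = chains,
    summary = smry,
    participant_weights = w_means,
    acceptance_rates = vapply(chains, `[[`, numeric(1), "acceptance_rate"),
    config = config, hyper = hyper, time_unit = time_unit,
    participants = prep$participant_ids,
    call = cl
  ), class = "rf_fit")
}

#' Pooled post-burn-in samples of a fitted model
#'
#' @param fit An `rf_fit`.
#' @param parameters Optional character vector of parameter names.
#' @return A matrix, pooled across chains.
#' @export
posterior_samples <- function(fit, parameters = NULL) {
  stopifnot(inherits(fit, "rf_fit"))
  pooled <- do.call(rbind, lapply(fit$chains, `[[`, "samples"))
  if (is.null(parameters)) pooled else pooled[, parameters, drop = FALSE]
}

#' @rdname fit_reference_frames
#' @param x,object An `rf_fit`.
#' @param ... Unused.
#' @export
print.rf_fit <- function(x, ...) {
  cat("Hierarchical reference-frame model fit\n")
  cat("  participants:", length(x$participants),
      " chains:", length(x$chains),
      " samples/chain:", x$config$n_samples,
      "(burn-in", paste0(x$config$burn_in, ")"), "\n")
  cat("  acceptance rates:",
      paste(sprintf("%.1f%%", 100 * x$acceptance_rates), collapse = ", "),
      "\n")
  if (!anyNA(x$summary$rhat)) {
    cat("  max split-chain R-hat (population):",
        sprintf("%.3f", max(x$summary$rhat)), "\n")
  }
  cat("\nPopulation posterior means [95% equal-tail CI]:\n")
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %-15s %6.3f  [%.3f, %.3f]\n",
                s$parameter, s$mean, s$lo, s$hi))
  }
  invisible(x)
}

#' @rdname fit_reference_frames
#' @export
summary.rf_fit <- function(object, ...) {
  structure(list(population = object$summary,
                 participant_weights = object$participant_weights,
                 acceptance_rates = object$acceptance_rates),
            class = "summary.rf_fit")
}

#' @export
print.summary.rf_fit <- function(x, ...) {
  cat("Population parameters:\n")
  print(x$population, digits = 4)
  cat("\nParticipant upright weight posterior means:\n")
  print(x$participant_weights, digits = 4)
  invisible(x)
}

#' @rdname fit_reference_frames
#' @param participants If `TRUE`, return the per-participant weight
#'   posterior means instead of the population parameters.
#' @export
coef.rf_fit <- function(object, participants = FALSE, ...) {
  if (participants) return(object$participant_weights)
  setNames(object$summary$mean, object$summary$parameter)
}

#' @rdname fit_reference_frames
#' @param parameters Which population parameters to trace.
#' @export
plot.rf_fit <- function(x, parameters = c("delta_internal",
                                          "delta_external"), ...) {
  old <- par(mfrow = c(length(parameters), 1), mar = c(3, 4, 2, 1))
  on.exit(par(old))
  for (p in parameters) {
    traces <- vapply(x$chains, function(ch) ch$samples[, p],
                     numeric(nrow(x$chains[[1]]$samples)))
    matplot(traces, type = "l", lty = 1, main = p,
            xlab = "retained iteration", ylab = p, ...)
  }
  invisible(x)
}
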