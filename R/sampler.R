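#' Sampler configuration
#'
#' Settings for the random-walk Metropolis-Hastings sampler. Defaults
#' are the full production budget (5 chains of 250,000 samples, the
#' first 50,000 discarded as burn-in) with proposal standard deviations
#' of 0.26 for the weights, 0.23 for the population standard deviations
#' and 0.02 for the context parameters — step sizes tuned for
#' acceptance rates in the low tens of percent on the canonical design.
#' The population means move on the weight scale and default to the
#' weights' proposal SD. Use [reduced_budget_config()] for desk-scale
#' runs.
#'
#' @param n_chains Number of chains.
#' @param n_samples Iterations per chain (including burn-in).
#' @param burn_in Iterations discarded from the front of each chain.
#' @param proposal_sd_weights Proposal SD for the per-participant
#'   weights.
#' @param proposal_sd_means Proposal SD for the population means
#'   (defaults to the weights' SD).
#' @param proposal_sd_sigmas Proposal SD for the population SDs.
#' @param proposal_sd_deltas Proposal SD for the context parameters.
#' @param init_weights,init_sigmas,init_deltas Ranges of the uniform
#'   random initial values for weights/means, SDs, and deltas.
#' @param thin Keep every `thin`-th post-burn-in sample (default 1).
#'   Thinning only bounds the memory footprint of long runs; the target
#'   distribution is unchanged.
#' @param seed Integer seed; chain seeds and initial values derive
#'   from it.
#' @return An object of class `toj_sampler_config`.
#' @export
sampler_config <- function(n_chains = 5, n_samples = 250000,
                           burn_in = 50000,
                           proposal_sd_weights = 0.26,
                           proposal_sd_means = proposal_sd_weights,
                           proposal_sd_sigmas = 0.23,
                           proposal_sd_deltas = 0.02,
                           init_weights = c(0.5, 20),
                           init_sigmas = c(0.1, 5),
                           init_deltas = c(0.5, 1.5),
                           thin = 1,
                           seed = 1) {
  if (burn_in >= n_samples) {
    stop("burn_in must be smaller than n_samples", call. = FALSE)
  }
  sds <- c(proposal_sd_weights, proposal_sd_means,
           proposal_sd_sigmas, proposal_sd_deltas)
  if (any(sds <= 0)) stop("proposal SDs must be positive", call. = FALSE)
  if (n_chains < 1) stop("need at least one chain", call. = FALSE)
  if (thin < 1 || (n_samples - burn_in) < thin) {
    stop("thin must be >= 1 and leave at least one retained sample",
         call. = FALSE)
  }
  structure(list(
    n_chains = as.integer(n_chains),
    n_samples = as.integer(n_samples),
    burn_in = as.integer(burn_in),
    thin = as.integer(thin),
    proposal_sd_weights = proposal_sd_weights,
    proposal_sd_means = proposal_sd_means,
    proposal_sd_sigmas = proposal_sd_sigmas,
    proposal_sd_deltas = proposal_sd_deltas,
    init_weights = init_weights,
    init_sigmas = init_sigmas,
    init_deltas = init_deltas,
    seed = as.integer(seed)
  ), class = "toj_sampler_config")
}

#' Reduced desk-scale sampler budget
#'
#' The production proposal SDs with a smaller chain budget (default 2
#' chains of 40,000 samples, burn-in 8,000) for tests and quick
#' recovery studies.
#'
#' @param n_chains,n_samples,burn_in Chain budget.
#' @param ... Passed to [sampler_config()].
#' @return A `toj_sampler_config`.
#' @export
reduced_budget_config <- function(n_chains = 2, n_samples = 40000,
                                  burn_in = 8000, ...) {
  sampler_config(n_chains = n_chains, n_samples = n_samples,
                 burn_in = burn_in, ...)
}

#' @noRd
.proposal_sds <- function(config, n) {
  c(rep(config$proposal_sd_means, 2),
    rep(config$proposal_sd_sigmas, 2),
    rep(config$proposal_sd_deltas, 2),
    rep(config$proposal_sd_weights, 2 * n))
}

#' Gaussian random-walk proposal
#'
#' Perturbs every parameter of the hypothesis by an independent
#' Gaussian step with its category's proposal SD. The proposal is
#' symmetric; out-of-support proposals are returned as-is and die in
#' the acceptance step through their `-Inf` posterior.
#'
#' @param current A [hypothesis()].
#' @param config A [sampler_config()].
#' @return The proposed `toj_hypothesis`.
#' @export
propose <- function(current, config = sampler_config()) {
  n <- attr(current, "n_participants")
  sds <- .proposal_sds(config, n)
  out <- current + rnorm(length(current), 0, sds)
  attributes(out) <- attributes(current)
  out
}

#' @noRd
.random_init <- function(config, n) {
  hypothesis(
    mu_internal = runif(1, config$init_weights[1], config$init_weights[2]),
    mu_external = runif(1, config$init_weights[1], config$init_weights[2]),
    sigma_internal = runif(1, config$init_sigmas[1], config$init_sigmas[2]),
    sigma_external = runif(1, config$init_sigmas[1], config$init_sigmas[2]),
    delta_internal = runif(1, config$init_deltas[1], config$init_deltas[2]),
    delta_external = runif(1, config$init_deltas[1], config$init_deltas[2]),
    omega_internal = runif(n, config$init_weights[1], config$init_weights[2]),
    omega_external = runif(n, config$init_weights[1], config$init_weights[2]))
}

#' Run one Metropolis-Hastings chain
#'
#' Standard random-walk MH over the `6 + 2N`-parameter hypothesis: at
#' each iteration every parameter is jointly perturbed ([propose()]),
#' and the move is accepted with probability
#' `exp(log_posterior(proposal) - log_posterior(current))`. The first
#' `burn_in` iterations are discarded from the returned samples; the
#' acceptance rate is reported over all iterations. Deterministic given
#' `chain_seed`.
#'
#' @param counts Cell-count table (one vision group).
#' @param config A [sampler_config()].
#' @param init Optional initial [hypothesis()] inside the posterior
#'   support; by default drawn uniformly within the configured ranges.
#' @param chain_seed Integer seed for this chain.
#' @param hyper A [hyperprior_spec()].
#' @param time_unit Factor converting `soa_ms` to model time units.
#' @param fixed Optional logical or character vector naming parameters
#'   to hold fixed at their initial values (no proposal step), e.g. to
#'   freeze the population level in toy posteriors.
#' @param engine `"cpp"` (default) runs the compiled kernel; `"R"` runs
#'   the pure-R reference loop. Both consume the RNG identically and
#'   return identical chains for the same seed.
#' @return A list of class `toj_chain`: `samples` (retained iterations
#'   by parameters, named columns), `acceptance_rate`, `n_accepted`,
#'   `n_samples`, `burn_in`, `seed`, `init`.
#' @export
run_chain <- function(counts, config = sampler_config(), init = NULL,
                      chain_seed = config$seed,
                      hyper = hyperprior_spec(), time_unit = 1e-3,
                      fixed = NULL, engine = c("cpp", "R")) {
  stopifnot(inherits(config, "toj_sampler_config"))
  engine <- match.arg(engine)
  prep <- .prepare_counts(counts, time_unit)
  n <- prep$n
  set.seed(chain_seed)
  if (is.null(init)) init <- .random_init(config, n)
  if (attr(init, "n_participants") != n) {
    stop("init hypothesis does not match the data's participant count",
         call. = FALSE)
  }
  par <- unclass(init)
  lp <- .log_post_par(par, prep, hyper)
  if (!is.finite(lp)) {
    stop("initial hypothesis lies outside the posterior support",
         call. = FALSE)
  }

  npar <- length(par)
  sds <- .proposal_sds(config, n)
  free <- rep(TRUE, npar)
  if (!is.null(fixed)) {
    if (is.character(fixed)) fixed <- names(par) %in% fixed
    free <- !fixed
  }
  sds[!free] <- 0

  n_iter <- config$n_samples
  thin <- config$thin
  n_keep <- (n_iter - config$burn_in) %/% thin

  if (engine == "cpp") {
    res <- .mh_chain_cpp(unname(par), sds, n_iter, config$burn_in, thin,
                         n, prep$pid, prep$t, prep$sgn,
                         as.integer(prep$lying), as.numeric(prep$r),
                         as.numeric(prep$l), hyper$max_mean, hyper$max_sd,
                         hyper$max_delta)
    samples <- res$samples
    colnames(samples) <- names(par)
    n_accepted <- res$n_accepted
  } else {
    samples <- matrix(NA_real_, n_keep, npar,
                      dimnames = list(NULL, names(par)))
    n_accepted <- 0L
    row <- 0L
    for (i in seq_len(n_iter)) {
      prop <- par + rnorm(npar, 0, sds)
      lp_prop <- .log_post_par(prop, prep, hyper)
      if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp) {
        par <- prop
        lp <- lp_prop
        n_accepted <- n_accepted + 1L
      }
      if (i > config$burn_in && (i - config$burn_in) %% thin == 0 &&
          row < n_keep) {
        row <- row + 1L
        samples[row, ] <- par
      }
    }
  }

  structure(list(
    samples = samples,
    acceptance_rate = n_accepted / n_iter,
    n_accepted = n_accepted,
    n_samples = n_iter,
    burn_in = config$burn_in,
    seed = chain_seed,
    init = init
  ), class = "toj_chain")
}

#' Split-chain Gelman-Rubin diagnostic
#'
#' The potential scale reduction factor computed after splitting each
#' chain in half, so within-chain drift also registers as
#' non-convergence: with `m` half-chains of length `n`, `W` the mean
#' within-chain variance and `B/n` the variance of the half-chain
#' means, `R-hat = sqrt(((n - 1)/n * W + B/n) / W)`. Values near 1
#' indicate convergence.
#'
#' @param chains A list of numeric vectors (one parameter's post-burn-in
#'   samples per chain, equal lengths) or a list of `toj_chain` objects
#'   (then a named vector of R-hats, one per parameter, is returned).
#' @return Scalar R-hat, or a named vector for chain objects. Degenerate
#'   (zero within-chain variance) input yields `NaN` with a warning.
#' @export
gelman_rubin <- function(chains) {
  if (inherits(chains[[1]], "toj_chain")) {
    pars <- colnames(chains[[1]]$samples)
    return(vapply(pars, function(p) {
      gelman_rubin(lapply(chains, function(ch) ch$samples[, p]))
    }, numeric(1)))
  }
  if (length(chains) < 2) {
    stop("need at least two chains for the split-chain diagnostic",
         call. = FALSE)
  }
  len <- unique(vapply(chains, length, integer(1)))
  if (length(len) != 1) stop("chains must have equal length", call. = FALSE)

  halves <- unlist(lapply(chains, function(x) {
    h <- length(x) %/% 2
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B_over_n <- var(means)
  if (W == 0 || !is.finite(W)) {
    warning("degenerate chains: zero within-chain variance")
    return(NaN)
  }
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Equal-tail credible interval
#'
#' Empirical `(1 - mass)/2` and `1 - (1 - mass)/2` quantiles of the
#' pooled posterior samples, by linear interpolation between order
#' statistics (R's default quantile rule).
#'
#' @param samples Non-empty numeric vector.
#' @param mass Interval mass in (0, 1); default 0.95.
#' @return Named numeric vector `c(lo, hi)`.
#' @export
credible_interval <- function(samples, mass = 0.95) {
  if (!length(samples)) stop("samples must be non-empty", call. = FALSE)
  if (mass <= 0 || mass >= 1) stop("mass must lie in (0, 1)", call. = FALSE)
  a <- (1 - mass) / 2
  setNames(quantile(samples, c(a, 1 - a), names = FALSE, type = 7),
           c("lo", "hi"))
}
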