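test_that("logistic psychometric function: anchors, symmetry, stability", {
  expect_equal(psychometric_p(12, 0), 0.5)
  expect_equal(psychometric_p(0, 0.4), 0.5)
  expect_equal(psychometric_p(log(3), 1), 0.75)
  expect_equal(psychometric_p(log(3) / 0.2, 0.2), 0.75)

  set.seed(14)
  theta <- runif(50, -30, 30)
  t <- runif(50, -0.4, 0.4)
  expect_equal(psychometric_p(theta, -t), 1 - psychometric_p(theta, t))

  # extreme arguments stay in [0, 1] without overflow
  expect_equal(psychometric_p(2000, 0.4), 1)
  expect_equal(psychometric_p(-2000, 0.4), 0)
})

test_that("weights map to slopes: sum uncrossed, difference crossed", {
  s <- slopes_from_weights(3, 1)
  expect_equal(s$theta_uncrossed, 4)
  expect_equal(s$theta_crossed, 2)
  expect_equal(slopes_from_weights(1, 3)$theta_crossed, -2)
  expect_equal(slopes_from_weights(2.5, 2.5)$theta_crossed, 0)
  expect_error(slopes_from_weights(-1, 2), "positive")
})

test_that("context multipliers scale the lying-down weights", {
  expect_equal(apply_context(3, 4, 1, 1),
               list(omega_internal = 3, omega_external = 4))
  expect_equal(apply_context(3, 4, 1, 0.5)$omega_external, 2)
  expect_equal(apply_context(3, 4, 2, 2),
               list(omega_internal = 6, omega_external = 8))
  expect_error(apply_context(3, 4, -1, 1), "positive")
})

test_that("participant log-likelihood: chance cells and saturated cells", {
  # equal weights make every crossed cell exactly chance
  soas <- toj_soa_set()
  counts <- data.frame(
    participant_id = "P01", vision = "intact", body_posture = "upright",
    hand_posture = "crossed", soa_ms = soas,
    n_right_first = 12L, n_left_first = 12L, stringsAsFactors = FALSE)
  ll <- participant_loglik(counts, omega_internal = 4, omega_external = 4)
  expect_equal(ll, 8 * 24 * log(0.5))

  # saturated cell with a huge concordant slope contributes ~0
  sat <- counts[1, ]
  sat$soa_ms <- 400L
  sat$n_right_first <- 24L
  sat$n_left_first <- 0L
  sat$hand_posture <- "uncrossed"
  expect_gt(participant_loglik(sat, 300, 100), -1e-6)
  expect_lte(participant_loglik(sat, 300, 100), 0)
})

test_that("participant log-likelihood matches the binomial pmf oracle", {
  set.seed(21)
  for (rep in 1:5) {
    soas <- toj_soa_set()
    counts <- expand.grid(soa_ms = soas,
                          hand_posture = c("uncrossed", "crossed"),
                          body_posture = c("upright", "side"),
                          stringsAsFactors = FALSE)
    counts$participant_id <- "P01"
    counts$vision <- "intact"
    counts$n_right_first <- rbinom(nrow(counts), 24, 0.5)
    counts$n_left_first <- 24L - counts$n_right_first

    wi <- runif(1, 2, 10); we <- runif(1, 1, 8)
    di <- runif(1, 0.8, 1.4); de <- runif(1, 0.1, 1)

    # brute-force: dbinom per cell minus the (constant) coefficient
    oracle <- 0
    for (i in seq_len(nrow(counts))) {
      w <- if (counts$body_posture[i] == "side") {
        apply_context(wi, we, di, de)
      } else list(omega_internal = wi, omega_external = we)
      th <- if (counts$hand_posture[i] == "crossed") {
        w$omega_internal - w$omega_external
      } else w$omega_internal + w$omega_external
      p <- psychometric_p(th, counts$soa_ms[i] / 1000)
      r <- counts$n_right_first[i]; n <- 24
      oracle <- oracle + dbinom(r, n, p, log = TRUE) - lchoose(n, r)
    }
    expect_equal(participant_loglik(counts, wi, we, di, de), oracle)
  }
})

test_that("single-cell likelihood peaks where p(t) equals the observed rate", {
  counts <- data.frame(
    participant_id = "P01", vision = "intact", body_posture = "upright",
    hand_posture = "uncrossed", soa_ms = 100L,
    n_right_first = 18L, n_left_first = 6L, stringsAsFactors = FALSE)
  # theta grid via equal split of the slope into two weights
  thetas <- seq(0.5, 40, by = 0.05)
  lls <- vapply(thetas, function(th) {
    participant_loglik(counts, th / 2, th / 2)
  }, numeric(1))
  best <- thetas[which.max(lls)]
  # p(t) = 0.75 at theta = log(3)/0.1
  expect_equal(best, log(3) / 0.1, tolerance = 0.05)
})

test_that("log-prior: truncated-normal closed form, support, sigma scaling", {
  n <- 4
  h <- hypothesis(5, 3, 2, 1.5, 1.2, 0.4,
                  omega_internal = rep(5, n), omega_external = rep(3, n))
  # closed-form truncated-normal log-density oracle
  dtn <- function(x, mu, sd) {
    dnorm(x, mu, sd, log = TRUE) - log(1 - pnorm(0, mu, sd))
  }
  expect_equal(log_prior(h), n * (dtn(5, 5, 2) + dtn(3, 3, 1.5)))

  # doubling sigma at the mean: each term drops by log 2 plus the change
  # in truncation normalizer
  h2 <- hypothesis(5, 3, 4, 1.5, 1.2, 0.4,
                   omega_internal = rep(5, n), omega_external = rep(3, n))
  delta_norm <- log(1 - pnorm(0, 5, 4)) - log(1 - pnorm(0, 5, 2))
  expect_equal(log_prior(h2) - log_prior(h), n * (-log(2) - delta_norm))

  h_bad <- hypothesis(5, 3, 2, 1.5, 1.2, -0.1,
                      omega_internal = rep(5, n), omega_external = rep(3, n))
  expect_identical(log_prior(h_bad), -Inf)

  h_oob <- hypothesis(5, 3, 2, 1.5, 1.2, 50,
                      omega_internal = rep(5, n), omega_external = rep(3, n))
  expect_identical(log_prior(h_oob), -Inf)  # beyond the delta hyperbound
})

test_that("log-posterior decomposes into likelihood plus prior", {
  sim <- small_sim(n = 1, seed = 71)
  counts <- aggregate_counts(sim$trials)
  h <- hypothesis(8, 5, 2, 2, 1.25, 0.31,
                  omega_internal = 7.5, omega_external = 4.5,
                  participant_ids = "P01")
  lp <- log_posterior(h, counts)
  ll <- participant_loglik(counts, 7.5, 4.5, 1.25, 0.31)
  expect_equal(lp, ll + log_prior(h))

  h_out <- hypothesis(8, 5, -2, 2, 1.25, 0.31,
                      omega_internal = 7.5, omega_external = 4.5)
  expect_identical(log_posterior(h_out, counts), -Inf)

  h_wrong_n <- hypothesis(8, 5, 2, 2, 1.25, 0.31,
                          omega_internal = c(7, 8), omega_external = c(4, 5))
  expect_error(log_posterior(h_wrong_n, counts), "participants")

  # finite exactly when strictly inside support and bounds
  h_edge <- hypothesis(8, 5, 2, 2, 1.25, 0.31,
                       omega_internal = 1e-300, omega_external = 4.5)
  expect_true(is.finite(log_posterior(h_edge, counts)))
})
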