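# Shared fixture builders: everything is generated in code at test time.

# A minimal hand-written trial table, one row per SOA sign, mixed responses.
tiny_trials <- function() {
  data.frame(
    participant_id = "P01",
    vision = "intact",
    body_posture = c("upright", "upright", "side", "side"),
    hand_posture = c("uncrossed", "crossed", "uncrossed", "crossed"),
    soa_ms = c(-400L, -50L, 50L, 400L),
    response = c("left_first", "right_first", "right_first", "left_first"),
    latency_ms = c(512, 431, 389, 1204),
    block_index = c(0L, 3L, 6L, 9L),
    trial_index = 0:3,
    stringsAsFactors = FALSE)
}

# Counts for one participant/posture stratum with given per-cell accuracy
# (same accuracy at every SOA within a hand posture), 24 trials per cell.
counts_with_accuracy <- function(acc_uncrossed, acc_crossed,
                                 participant_id = "P01",
                                 body_posture = "upright",
                                 n_per_cell = 24) {
  soas <- toj_soa_set()
  build <- function(hand, acc) {
    n_correct <- round(acc * n_per_cell)
    data.frame(
      participant_id = participant_id, vision = "intact",
      body_posture = body_posture, hand_posture = hand, soa_ms = soas,
      n_right_first = ifelse(soas > 0, n_correct, n_per_cell - n_correct),
      n_left_first = ifelse(soas > 0, n_per_cell - n_correct, n_correct),
      stringsAsFactors = FALSE)
  }
  rbind(build("uncrossed", acc_uncrossed), build("crossed", acc_crossed))
}

# Small simulated experiment shared by several tests.
small_sim <- function(n = 3, seed = 101, ...) {
  simulate_experiment(truth_preset("full_vision", n_participants = n, ...),
                      seed = seed)
}

pop_names <- c("mu_internal", "mu_external", "sigma_internal",
               "sigma_external", "delta_internal", "delta_external")

# Independent split-plot sums-of-squares oracle for the 2x2 mixed ANOVA
# (never calls aov): between-subject stratum carries the vision effect,
# the posture-by-subject stratum carries posture and the interaction.
anova_oracle <- function(d) {
  b <- 2  # body-posture levels
  grand <- mean(d$pcd)
  subj <- aggregate(pcd ~ participant_id + vision, d, mean)
  grp <- aggregate(pcd ~ vision, d, mean)
  body <- aggregate(pcd ~ body_posture, d, mean)
  cellm <- aggregate(pcd ~ vision + body_posture, d, mean)
  n_subj <- nrow(subj)
  n_per_grp <- table(subj$vision)

  ss_total <- sum((d$pcd - grand)^2)
  ss_bs <- b * sum((subj$pcd - grand)^2)
  ss_vision <- b * sum(n_per_grp * (grp$pcd - grand)^2)
  ss_subj_err <- ss_bs - ss_vision
  ss_within <- ss_total - ss_bs
  ss_body <- n_subj * sum((body$pcd - grand)^2)
  cellm$exp <- grp$pcd[match(cellm$vision, grp$vision)] +
    body$pcd[match(cellm$body_posture, body$body_posture)] - grand
  ss_int <- sum(n_per_grp[cellm$vision] * (cellm$pcd - cellm$exp)^2)
  ss_body_err <- ss_within - ss_body - ss_int

  df_err <- n_subj - 2
  list(
    F_vision = ss_vision / (ss_subj_err / df_err),
    F_body = ss_body / (ss_body_err / df_err),
    F_int = ss_int / (ss_body_err / df_err),
    eta_vision = ss_vision / (ss_vision + ss_subj_err + ss_body_err),
    eta_body = ss_body / (ss_body + ss_subj_err + ss_body_err),
    eta_int = ss_int / (ss_int + ss_subj_err + ss_body_err))
}

# Independent truncated-normal moments on (0, Inf), closed form.
truncnorm_moments <- function(mu, sigma) {
  a <- -mu / sigma
  lambda <- dnorm(a) / (1 - pnorm(a))
  m <- mu + sigma * lambda
  v <- sigma^2 * (1 + a * lambda - lambda^2)
  list(mean = m, sd = sqrt(v))
}
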