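#' Per-SOA accuracy for one participant and body posture
#'
#' Accuracy respects the sign convention: negative SOAs mean the left
#' hand was stimulated first, so the correct response there is
#' `left_first` and accuracy is `l / (r + l)`; at positive SOAs it is
#' `r / (r + l)`.
#'
#' @param counts Cell-count rows (see [aggregate_counts()]) for a single
#'   participant, vision condition and body posture.
#' @return A data frame with columns `hand_posture`, `soa_ms`,
#'   `accuracy`, sorted by hand posture then SOA.
#' @export
accuracy_by_soa <- function(counts) {
  .check_single_stratum(counts)
  n <- counts$n_right_first + counts$n_left_first
  if (any(n < 1)) {
    bad <- which(n < 1)[1]
    stop("empty cell: participant ", counts$participant_id[bad],
         ", ", counts$hand_posture[bad], ", SOA ", counts$soa_ms[bad],
         " ms has no trials", call. = FALSE)
  }
  acc <- ifelse(counts$soa_ms < 0,
                counts$n_left_first, counts$n_right_first) / n
  out <- data.frame(hand_posture = counts$hand_posture,
                    soa_ms = counts$soa_ms, accuracy = acc,
                    stringsAsFactors = FALSE)
  out[order(out$hand_posture, out$soa_ms), ]
}

#' @noRd
.check_single_stratum <- function(counts) {
  for (col in c("participant_id", "vision", "body_posture")) {
    if (length(unique(counts[[col]])) != 1) {
      stop("counts must come from a single ", col,
           "; got ", length(unique(counts[[col]])), call. = FALSE)
    }
  }
}

#' Proportion-correct-difference (PCD) crossed-hands-deficit score
#'
#' The PCD score of one participant in one body posture: the uncrossed
#' minus crossed accuracy difference summed over the signed SOAs. With
#' `S` SOAs the score is bounded by `[-S, S]`; a chance responder has
#' expected PCD 0, and a positive PCD indicates a crossed-hands deficit.
#'
#' @param counts Cell-count rows for a single participant, vision
#'   condition and body posture, covering every SOA in both hand
#'   postures.
#' @param soa_set_ms The SOA set over which the sum runs.
#' @return A one-row data frame `participant_id`, `vision`,
#'   `body_posture`, `pcd`.
#' @examples
#' # uncrossed perfect, crossed at chance over 8 SOAs: PCD = 8 * 0.5 = 4
#' @export
pcd <- function(counts, soa_set_ms = toj_soa_set()) {
  .check_single_stratum(counts)
  acc <- accuracy_by_soa(counts)
  for (hp in c("uncrossed", "crossed")) {
    have <- acc$soa_ms[acc$hand_posture == hp]
    miss <- setdiff(soa_set_ms, have)
    if (length(miss)) {
      stop("missing cell(s) for participant ", counts$participant_id[1],
           ", ", hp, " posture, SOA ", paste(miss, collapse = ", "), " ms",
           call. = FALSE)
    }
  }
  unc <- acc[acc$hand_posture == "uncrossed", ]
  cro <- acc[acc$hand_posture == "crossed", ]
  value <- sum(unc$accuracy[match(soa_set_ms, unc$soa_ms)] -
               cro$accuracy[match(soa_set_ms, cro$soa_ms)])
  data.frame(participant_id = counts$participant_id[1],
             vision = counts$vision[1],
             body_posture = counts$body_posture[1],
             pcd = value, stringsAsFactors = FALSE)
}

#' PCD scores for every participant and body posture
#'
#' @param counts Full cell-count table (see [aggregate_counts()]).
#' @param soa_set_ms The SOA set over which each score sums.
#' @return A data frame with one PCD row per
#'   (participant, vision, body posture).
#' @export
pcd_scores <- function(counts, soa_set_ms = toj_soa_set()) {
  strata <- unique(counts[c("participant_id", "vision", "body_posture")])
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    s <- strata[i, ]
    sub <- counts[counts$participant_id == s$participant_id &
                  counts$vision == s$vision &
                  counts$body_posture == s$body_posture, ]
    pcd(sub, soa_set_ms = soa_set_ms)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' 2 x 2 mixed ANOVA on PCD scores
#'
#' Body posture (upright vs. side) as the within-subject factor and
#' vision (intact vs. blindfold) as the between-subject factor, on a
#' balanced design with one PCD score per participant and posture.
#' F ratios come from the standard split-plot decomposition
#' (between-subject error stratum for the vision effect; the
#' posture-by-subject stratum for posture and the interaction). Effect
#' sizes are generalized eta-squared: each effect's sum of squares over
#' itself plus all subject-related error sums of squares.
#'
#' @param pcd_table Output of [pcd_scores()] (columns `participant_id`,
#'   `vision`, `body_posture`, `pcd`), each participant contributing
#'   both body postures and one vision group.
#' @return A data frame with one row per effect (`vision`,
#'   `body_posture`, `vision:body_posture`) and columns `effect`, `F`,
#'   `df_num`, `df_den`, `p`, `eta_sq_g`.
#' @export
mixed_anova_2x2 <- function(pcd_table) {
  d <- pcd_table
  tab <- table(d$participant_id, d$body_posture)
  if (any(tab != 1) || ncol(tab) != 2) {
    stop("each participant needs exactly one PCD score per body posture",
         call. = FALSE)
  }
  vis_by_pid <- unique(d[c("participant_id", "vision")])
  if (anyDuplicated(vis_by_pid$participant_id)) {
    stop("a participant appears in more than one vision group", call. = FALSE)
  }
  if (length(unique(d$vision)) != 2 || any(table(vis_by_pid$vision) < 2)) {
    stop("need two vision groups with at least two participants each",
         call. = FALSE)
  }
  d$participant_id <- factor(d$participant_id)
  d$vision <- factor(d$vision)
  d$body_posture <- factor(d$body_posture)

  fit <- aov(pcd ~ vision * body_posture +
               Error(participant_id / body_posture), data = d)
  s <- summary(fit)
  between <- as.data.frame(s[["Error: participant_id"]][[1]])
  within <- as.data.frame(s[["Error: participant_id:body_posture"]][[1]])
  rn_b <- trimws(rownames(between))
  rn_w <- trimws(rownames(within))

  ss_err_b <- between$`Sum Sq`[rn_b == "Residuals"]
  ss_err_w <- within$`Sum Sq`[rn_w == "Residuals"]
  ss_subject_error <- ss_err_b + ss_err_w

  .row <- function(effect, stratum, rn) {
    i <- which(rn == effect)
    data.frame(effect = effect,
               F = stratum$`F value`[i],
               df_num = stratum$Df[i],
               df_den = stratum$Df[rn == "Residuals"],
               p = stratum$`Pr(>F)`[i],
               eta_sq_g = stratum$`Sum Sq`[i] /
                 (stratum$`Sum Sq`[i] + ss_subject_error),
               stringsAsFactors = FALSE)
  }
  out <- rbind(.row("vision", between, rn_b),
               .row("body_posture", within, rn_w),
               .row("vision:body_posture", within, rn_w))
  rownames(out) <- NULL
  out
}

#' One-sample t-test with Cohen's d
#'
#' Two-sided test of the mean against `mu0`, with
#' `d = (mean - mu0) / SD`. Used to test PCD scores against zero.
#'
#' @param values Numeric vector, length >= 2, non-degenerate.
#' @param mu0 Null value (default 0).
#' @return A list `t`, `df`, `p`, `cohens_d`, `mean`, `sd`, `n`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  if (length(values) < 2) stop("need at least two values", call. = FALSE)
  if (sd(values) == 0) stop("values have zero variance", call. = FALSE)
  tt <- t.test(values, mu = mu0)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohens_d = (mean(values) - mu0) / sd(values),
       mean = mean(values), sd = sd(values), n = length(values))
}

#' Within-subject-corrected standard errors of the mean
#'
#' Error bars for repeated-measures condition means: each subject's
#' scores are centred on the subject mean and shifted back to the grand
#' mean, removing between-subject offsets; the per-condition SEM of the
#' normalized scores is then inflated by the bias-correction factor
#' `sqrt(C / (C - 1))` for `C` conditions.
#'
#' @param m Numeric matrix, participants in rows, conditions in columns,
#'   complete (no missing cells), at least two columns.
#' @return A list with `sem` (named per-condition corrected SEM),
#'   `normalized` (the normalized matrix) and `mean` (condition means).
#' @export
within_subject_sem <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least two conditions", call. = FALSE)
  if (anyNA(m)) stop("matrix must be complete", call. = FALSE)
  C <- ncol(m)
  z <- m - rowMeans(m) + mean(m)
  sem <- apply(z, 2, sd) / sqrt(nrow(m)) * sqrt(C / (C - 1))
  list(sem = sem, normalized = z, mean = colMeans(m))
}
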