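#' Canonical set of signed stimulus onset asynchronies
#'
#' The eight signed SOAs (ms) of the canonical crossed-hands TOJ design.
#' Negative SOAs mean the left hand was stimulated first.
#'
#' @return Integer vector of signed SOAs in milliseconds.
#' @export
toj_soa_set <- function() {
  c(-400L, -200L, -100L, -50L, 50L, 100L, 200L, 400L)
}

.vision_levels <- c("intact", "blindfold")
.body_levels <- c("upright", "side")
.hand_levels <- c("uncrossed", "crossed")
.response_levels <- c("left_first", "right_first", "timeout")

#' Experimental design specification
#'
#' Describes the block structure of a two-posture crossed-hands TOJ
#' session: practice blocks, experimental blocks, trials per block and
#' the SOA set. The canonical design has 12 experimental blocks of 64
#' trials; the first six blocks are run in one body posture and the last
#' six in the other, and within each body posture three consecutive
#' blocks share a hand posture, giving 24 trials per
#' (body posture x hand posture x SOA) cell.
#'
#' @param n_practice_blocks Number of practice blocks (not scheduled by
#'   [schedule_trials()]; recorded for completeness).
#' @param practice_trials_per_block Trials per practice block.
#' @param n_experimental_blocks Number of experimental blocks; must be a
#'   multiple of 4 so body and hand posture can each split the session
#'   into equal runs of consecutive blocks.
#' @param trials_per_block Trials per experimental block; must be a
#'   multiple of the SOA-set size so SOAs balance within block.
#' @param soa_set_ms Integer vector of signed SOAs (ms).
#' @return An object of class `toj_design` (a list of the above fields
#'   plus `trials_per_cell`).
#' @examples
#' d <- design_spec()
#' d$trials_per_cell  # 24
#' @export
design_spec <- function(n_practice_blocks = 2,
                        practice_trials_per_block = 16,
                        n_experimental_blocks = 12,
                        trials_per_block = 64,
                        soa_set_ms = toj_soa_set()) {
  if (length(soa_set_ms) < 2 || anyDuplicated(soa_set_ms)) {
    stop("soa_set_ms must contain at least two distinct SOAs", call. = FALSE)
  }
  if (trials_per_block %% length(soa_set_ms) != 0) {
    stop("trials_per_block (", trials_per_block,
         ") must be divisible by the number of SOAs (",
         length(soa_set_ms), ")", call. = FALSE)
  }
  if (n_experimental_blocks %% 4 != 0) {
    stop("n_experimental_blocks must be a multiple of 4 so both body and ",
         "hand posture split the session evenly", call. = FALSE)
  }
  blocks_per_cell <- n_experimental_blocks / 4  # body x hand combinations
  structure(list(
    n_practice_blocks = n_practice_blocks,
    practice_trials_per_block = practice_trials_per_block,
    n_experimental_blocks = n_experimental_blocks,
    trials_per_block = trials_per_block,
    soa_set_ms = as.integer(soa_set_ms),
    trials_per_cell = blocks_per_cell * trials_per_block / length(soa_set_ms)
  ), class = "toj_design")
}

#' Schedule the experimental trials of one session
#'
#' Expands a [design_spec()] into a trial-by-trial schedule: the first
#' half of the experimental blocks is run in one body posture and the
#' second half in the other; within each body posture the blocks split
#' into two runs of consecutive blocks, one per hand posture. SOAs are
#' balanced within every block and their order within a block is
#' randomised.
#'
#' @param design A `toj_design` object.
#' @param posture_order `"upright_first"` or `"side_first"`.
#' @param hand_order `"uncrossed_first"` or `"crossed_first"`.
#' @param seed Optional integer seed for the within-block SOA shuffle.
#' @return A data frame with columns `block_index`, `trial_index`
#'   (0-based, `trial_index` within block), `body_posture`,
#'   `hand_posture`, `soa_ms`.
#' @examples
#' sch <- schedule_trials(design_spec(), seed = 1)
#' nrow(sch)  # 768
#' @export
schedule_trials <- function(design = design_spec(),
                            posture_order = c("upright_first", "side_first"),
                            hand_order = c("uncrossed_first", "crossed_first"),
                            seed = NULL) {
  stopifnot(inherits(design, "toj_design"))
  posture_order <- match.arg(posture_order)
  hand_order <- match.arg(hand_order)
  if (!is.null(seed)) set.seed(seed)

  nb <- design$n_experimental_blocks
  tpb <- design$trials_per_block
  soas <- design$soa_set_ms
  bodies <- if (posture_order == "upright_first") c("upright", "side")
            else c("side", "upright")
  hands <- if (hand_order == "uncrossed_first") c("uncrossed", "crossed")
           else c("crossed", "uncrossed")

  per_body <- nb / 2
  per_hand <- per_body / 2
  body_by_block <- rep(bodies, each = per_body)
  hand_by_block <- rep(rep(hands, each = per_hand), times = 2)

  blocks <- lapply(seq_len(nb), function(b) {
    soa_seq <- sample(rep(soas, times = tpb / length(soas)))
    data.frame(
      block_index = b - 1L,
      trial_index = seq_len(tpb) - 1L,
      body_posture = body_by_block[b],
      hand_posture = hand_by_block[b],
      soa_ms = soa_seq,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, blocks)
}
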