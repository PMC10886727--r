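#' Summarise trial-level reaction times into block RTs
#'
#' Collapses a trial-level RT table to one RT per block using the median
#' (default) or mean of the block's trials. Tables that are already
#' block-level (one row per block) pass through [sequence_specific_skill()]
#' unchanged, so this helper is only needed for raw trial data.
#'
#' @param trials data.frame with columns subject, session, sequence, hand,
#'   block_index, block_type, rt.
#' @param stat `"median"` or `"mean"`.
#' @return a block-level data.frame with the same columns.
#' @export
block_rt <- function(trials, stat = c("median", "mean")) {
  stat <- match.arg(stat)
  f <- if (stat == "median") stats::median else mean
  agg <- stats::aggregate(
    rt ~ subject + session + sequence + hand + block_index + block_type,
    data = trials, FUN = f)
  agg[order(agg$subject, agg$session, agg$sequence, agg$hand, agg$block_index), ]
}

select_blocks <- function(table, sequence, session, which) {
  stopifnot(all(c("session", "sequence", "block_index", "block_type", "rt")
                %in% names(table)))
  sub <- table[table$sequence == sequence & table$session == session, ]
  rand <- sub[sub$block_type == "random", ]
  seqb <- sub[sub$block_type == "sequence", ]
  seqb <- seqb[order(seqb$block_index), ]
  if (nrow(rand) == 0L)
    stop("missing random blocks for ", sequence, "/", session)
  if (nrow(seqb) < 4L)
    stop("need at least 4 sequence blocks for ", sequence, "/", session,
         " (found ", nrow(seqb), ")")
  ref <- switch(which,
                pre = utils::tail(seqb, 4L),
                post_late = utils::tail(seqb, 4L),
                post_early = utils::head(seqb, 4L),
                stop("`which` must be pre, post_early or post_late"))
  list(random = rand, reference = ref)
}

#' Sequence-specific skill
#'
#' Skill on one sequence in one session: the mean RT of that session's random
#' blocks minus the mean RT of the four reference sequence blocks (the last
#' four for `pre` and `post_late`, the first four after waking for
#' `post_early`). Subtracting the random blocks removes general sensorimotor
#' speed-up, leaving the sequence-specific component; larger values mean more
#' skill.
#'
#' @param table block-level behavioural table (see [generate_behavioural()]);
#'   restrict to one subject (and optionally one hand) before calling.
#' @param sequence `"Re"` (reactivated) or `"NRe"`.
#' @param which `"pre"`, `"post_early"` or `"post_late"` (the session is
#'   implied: `pre` uses pre-sleep blocks, the others post-sleep).
#' @param hand optional hand restriction (`"L"` or `"R"`).
#'
#' @return skill in milliseconds.
#' @export
sequence_specific_skill <- function(table, sequence = c("Re", "NRe"),
                                    which = c("pre", "post_early", "post_late"),
                                    hand = NULL) {
  sequence <- match.arg(sequence)
  which <- match.arg(which)
  if (!is.null(hand)) table <- table[table$hand == hand, ]
  session <- if (which == "pre") "pre" else "post"
  b <- select_blocks(table, sequence, session, which)
  mean(b$random$rt) - mean(b$reference$rt)
}

#' Sequence-specific skill and improvement metrics for one subject
#'
#' Computes the full metric set for both sequences: `sss_pre`,
#' `sss_post_early`, `sss_post_late`, and the overnight improvements
#' `ssi_early = sss_post_early - sss_pre` and
#' `ssi_late = sss_post_late - sss_pre` (exact identities; higher values
#' indicate more improvement).
#'
#' @param table block-level behavioural table for one subject.
#' @param hand optional hand restriction applied before block selection.
#'
#' @return a one-row data.frame with columns `<seq>_sss_pre`,
#'   `<seq>_sss_post_early`, `<seq>_sss_post_late`, `<seq>_ssi_early`,
#'   `<seq>_ssi_late` for `<seq>` in `Re`, `NRe` (all in ms).
#' @export
skill_metrics <- function(table, hand = NULL) {
  out <- list()
  for (sq in c("Re", "NRe")) {
    sss_pre <- sequence_specific_skill(table, sq, "pre", hand = hand)
    sss_pe <- sequence_specific_skill(table, sq, "post_early", hand = hand)
    sss_pl <- sequence_specific_skill(table, sq, "post_late", hand = hand)
    out[[paste0(sq, "_sss_pre")]] <- sss_pre
    out[[paste0(sq, "_sss_post_early")]] <- sss_pe
    out[[paste0(sq, "_sss_post_late")]] <- sss_pl
    out[[paste0(sq, "_ssi_early")]] <- sss_pe - sss_pre
    out[[paste0(sq, "_ssi_late")]] <- sss_pl - sss_pre
  }
  as.data.frame(out)
}

#' Sequence-specific improvement from precomputed skill values
#'
#' The overnight differences `ssi_early = sss_post_early - sss_pre` and
#' `ssi_late = sss_post_late - sss_pre`.
#'
#' @param sss_pre,sss_post_early,sss_post_late skill values in ms.
#' @return a list with `ssi_early` and `ssi_late`.
#' @export
sequence_specific_improvement <- function(sss_pre, sss_post_early, sss_post_late) {
  list(ssi_early = sss_post_early - sss_pre,
       ssi_late = sss_post_late - sss_pre)
}

#' Skill metrics for every subject in a behavioural table
#'
#' @param table block-level behavioural table with a `subject` column.
#' @param hand optional hand restriction.
#' @return a data.frame with one row per subject.
#' @export
study_skill_metrics <- function(table, hand = NULL) {
  subjects <- sort(unique(table$subject))
  rows <- lapply(subjects, function(s) {
    cbind(data.frame(subject = s, stringsAsFactors = FALSE),
          skill_metrics(table[table$subject == s, ], hand = hand))
  })
  do.call(rbind, rows)
}
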