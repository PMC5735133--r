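#' Build the clarity-rating trial schedule (Experiment 1)
#'
#' A fully crossed 2 (cue congruency: match/mismatch) x 3 (vocoder channels:
#' 4/8/16) factorial design: 108 trials per condition over six blocks, each
#' block holding 18 trials of every condition in one of two fixed random
#' orders. Each trial pairs a written cue with a spoken word: match trials
#' repeat the cued word, mismatch trials present an unrelated word. Spoken
#' words are reused at most twice per listener, at most once per congruency
#' level (once with a congruent and once with an incongruent cue). Cue-to-
#' speech and speech-to-probe intervals are jittered uniformly within
#' 1050 +/- 50 ms.
#'
#' @param word_pool Character vector of distinct word ids; at least 324 are
#'   needed (one spoken word per match trial, reusable once for mismatch).
#' @param order_label `"A"` or `"B"`, selecting one of two fixed trial-order
#'   permutations derived from `seed`.
#' @param seed Integer seed; the schedule is deterministic given
#'   `(word_pool, order_label, seed)`.
#' @return A data frame of class `"exp1_schedule"` with one row per trial:
#'   `block`, `trial`, `congruency`, `channels`, `written_word`,
#'   `spoken_word`, `cue_onset_to_speech_ms`, `speech_onset_to_probe_ms`,
#'   `order_label`. The attribute `"summary"` reports the realised counts of
#'   words used twice and once.
#' @examples
#' sched <- exp1_schedule(sprintf("w%03d", 1:432), seed = 1)
#' table(sched$congruency, sched$channels)  # 108 everywhere
#' @export
exp1_schedule <- function(word_pool, order_label = c("A", "B"), seed) {
  order_label <- match.arg(order_label)
  word_pool <- as.character(word_pool)
  if (anyDuplicated(word_pool)) stop("`word_pool` contains duplicate ids")
  n_per_congruency <- 324L
  if (length(word_pool) < n_per_congruency)
    stop("word pool too small: need at least ", n_per_congruency,
         " distinct words (one spoken word per match trial, each reusable ",
         "once under the opposite congruency)")

  out <- with_seed(seed, {
    pool <- sample(word_pool)
    p <- length(pool)
    match_words <- pool[seq_len(n_per_congruency)]
    n_fresh <- min(p - n_per_congruency, n_per_congruency)
    mism_words <- c(if (n_fresh > 0) pool[n_per_congruency + seq_len(n_fresh)],
                    if (n_fresh < n_per_congruency)
                      match_words[seq_len(n_per_congruency - n_fresh)])
    mism_words <- sample(mism_words)
    # written cue of a mismatch trial is another mismatch trial's spoken word
    mism_written <- mism_words[c(seq_len(n_per_congruency)[-1], 1L)]

    cells <- expand.grid(congruency = c("match", "mismatch"),
                         channels = c(4L, 8L, 16L),
                         stringsAsFactors = FALSE)
    block_rows <- cells[rep(seq_len(6L), each = 18L), ]
    trials <- do.call(rbind, lapply(1:6, function(b)
      cbind(block = b, block_rows)))

    is_match <- trials$congruency == "match"
    trials$spoken_word <- NA_character_
    trials$spoken_word[is_match] <- match_words
    trials$spoken_word[!is_match] <- mism_words
    trials$written_word <- NA_character_
    trials$written_word[is_match] <- match_words
    trials$written_word[!is_match] <- mism_written
    trials$cue_onset_to_speech_ms <- stats::runif(nrow(trials), 1000, 1100)
    trials$speech_onset_to_probe_ms <- stats::runif(nrow(trials), 1000, 1100)
    trials
  })

  # one of two fixed within-block orders, both derived from the seed
  perm_seed <- child_seed(seed, if (order_label == "A") 101L else 202L)
  out <- with_seed(perm_seed, {
    idx <- unlist(lapply(1:6, function(b) {
      rows <- which(out$block == b)
      rows[sample.int(length(rows))]
    }))
    out[idx, ]
  })
  out$trial <- stats::ave(out$block, out$block, FUN = seq_along)
  out$order_label <- order_label
  rownames(out) <- NULL
  out <- out[, c("block", "trial", "congruency", "channels", "written_word",
                 "spoken_word", "cue_onset_to_speech_ms",
                 "speech_onset_to_probe_ms", "order_label")]

  tally <- table(table(out$spoken_word))
  attr(out, "summary") <- list(
    n_trials = nrow(out),
    words_spoken_twice = if ("2" %in% names(tally)) unname(tally[["2"]]) else 0L,
    words_spoken_once = if ("1" %in% names(tally)) unname(tally[["1"]]) else 0L,
    order_label = order_label)
  class(out) <- c("exp1_schedule", "data.frame")
  out
}

#' Generate labelled 4AFC response sets
#'
#' Convenience generator of synthetic response sets for the word-
#' identification task: each set holds four distinct word ids labelled
#' target, offset neighbour, onset neighbour and unrelated (the roles in
#' the set "Daze / Gaze / Game / Then").
#'
#' @param n Number of sets (the design requires 30).
#' @return Data frame with columns `set_id`, `target`, `offset_neighbour`,
#'   `onset_neighbour`, `unrelated`.
#' @export
make_response_sets <- function(n = 30L) {
  data.frame(
    set_id = sprintf("set%02d", seq_len(n)),
    target = sprintf("s%02d_target", seq_len(n)),
    offset_neighbour = sprintf("s%02d_offn", seq_len(n)),
    onset_neighbour = sprintf("s%02d_onn", seq_len(n)),
    unrelated = sprintf("s%02d_unrel", seq_len(n)),
    stringsAsFactors = FALSE)
}

## fixed per-channel difficulty-slot order: 10x case1, 5x case2, 5x case3,
## 10x case4 in a fixed interleaving (word identity, not slot order, is
## randomised across listeners)
exp2_case_slots <- function() rep(c(1L, 2L, 4L, 1L, 3L, 4L), 5L)

#' Build the 4AFC word-identification schedule (Experiment 2)
#'
#' 90 trials in one block: 3 levels of sensory detail (4/8/16 vocoder
#' channels) fully crossed with a 4-level manipulation of distractor
#' difficulty. Each of the 30 response sets is presented three times, once
#' per channel level, with a different member spoken each time: case 1
#' speaks the target (two neighbours in the response array), cases 2 and 3
#' speak the offset/onset neighbour (one neighbour in the array), case 4
#' speaks the unrelated word (no neighbours). Per channel level the case
#' tallies are 10/5/5/10. The channel and difficulty slot order is fixed;
#' which word fills each slot is randomised by `seed`.
#'
#' @param response_sets Data frame from [make_response_sets()]; exactly 30
#'   sets are required.
#' @param seed Integer seed.
#' @return Data frame of class `"exp2_schedule"`: `trial`, `channels`,
#'   `set_id`, `case_label` (1-4), `spoken_word`, `n_neighbours_in_array`
#'   (2/1/1/0 for cases 1/2/3/4), plus the four response-option columns.
#' @export
exp2_schedule <- function(response_sets, seed) {
  rs <- as.data.frame(response_sets)
  need <- c("set_id", "target", "offset_neighbour", "onset_neighbour", "unrelated")
  if (!all(need %in% names(rs))) stop("`response_sets` lacks required columns")
  if (nrow(rs) != 30L) stop("exactly 30 response sets are required, got ", nrow(rs))
  members <- unlist(rs[, need[-1]])
  if (any(vapply(seq_len(nrow(rs)), function(i)
    anyDuplicated(unlist(rs[i, need[-1]])) > 0, logical(1))))
    stop("each response set must contain four distinct words")

  channels <- c(4L, 8L, 16L)
  plan <- with_seed(seed, {
    # 15 sets use case 2, 15 use case 3 for their middle presentation;
    # a balanced latin-square rotation spreads cases over channel levels
    mid_case <- sample(rep(c(2L, 3L), each = 15L))
    rows <- vector("list", 30L)
    for (half in c(2L, 3L)) {
      sets_h <- which(mid_case == half)
      rot <- sample(rep(0:2, each = 5L))
      for (j in seq_along(sets_h)) {
        i <- sets_h[j]
        # cases (1, mid, 4) assigned to channels by cyclic rotation rot[j]
        ch_idx <- ((0:2 + rot[j]) %% 3L) + 1L
        rows[[i]] <- data.frame(set_id = rs$set_id[i],
                                channels = channels[ch_idx],
                                case_label = c(1L, half, 4L),
                                stringsAsFactors = FALSE)
      }
    }
    long <- do.call(rbind, rows)
    # fixed slot order per channel; randomise which same-case trial fills which slot
    out <- vector("list", 3L)
    for (k in seq_along(channels)) {
      slots <- exp2_case_slots()
      sub <- long[long$channels == channels[k], ]
      ord <- integer(length(slots))
      for (cs in 1:4) {
        cand <- sample(which(sub$case_label == cs))
        ord[slots == cs] <- cand
      }
      out[[k]] <- sub[ord, ]
    }
    do.call(rbind, out)
  })

  i <- match(plan$set_id, rs$set_id)
  spoken_col <- c("target", "offset_neighbour", "onset_neighbour", "unrelated")
  plan$spoken_word <- vapply(seq_len(nrow(plan)), function(r)
    rs[i[r], spoken_col[plan$case_label[r]]], character(1))
  plan$n_neighbours_in_array <- c(2L, 1L, 1L, 0L)[plan$case_label]
  plan <- cbind(trial = seq_len(nrow(plan)), plan, rs[i, need[-1]])
  rownames(plan) <- NULL
  class(plan) <- c("exp2_schedule", "data.frame")
  plan
}

#' Build the neutral-cue replication schedule
#'
#' The out-of-scanner replication adds a neutral (uninformative) cue level
#' to the congruency factor: 3 congruency x 3 channel conditions, 18 trials
#' each, in a single block. Neutral trials carry an uninformative written
#' token rather than a word.
#'
#' @param word_pool Character vector of distinct word ids; at least 81 are
#'   needed (54 spoken words per congruency level, each word reusable once).
#' @param seed Integer seed.
#' @return Data frame of class `"neutral_schedule"` with the Experiment 1
#'   trial columns plus `cue_informative` (FALSE on neutral trials, whose
#'   `written_word` is the token `"<neutral>"`).
#' @export
neutral_replication_schedule <- function(word_pool, seed) {
  word_pool <- as.character(word_pool)
  if (anyDuplicated(word_pool)) stop("`word_pool` contains duplicate ids")
  n_per_cell <- 18L
  n_per_congruency <- 3L * n_per_cell           # 54
  need_min <- ceiling(3 * n_per_congruency / 2) # each word usable twice
  if (length(word_pool) < need_min)
    stop("word pool too small: need at least ", need_min,
         " distinct words for 54 spoken words per congruency level with ",
         "at most two uses per word")

  out <- with_seed(seed, {
    pool <- sample(word_pool)
    p <- length(pool)
    idx <- ((seq_len(3L * n_per_congruency) - 1L) %% p) + 1L
    spoken <- split(pool[idx], rep(c("match", "mismatch", "neutral"),
                                   each = n_per_congruency))
    cells <- expand.grid(congruency = c("match", "mismatch", "neutral"),
                         channels = c(4L, 8L, 16L),
                         stringsAsFactors = FALSE)
    trials <- cells[rep(seq_len(9L), each = n_per_cell), ]
    trials <- trials[sample.int(nrow(trials)), ]
    for (g in names(spoken)) {
      rows <- trials$congruency == g
      trials$spoken_word[rows] <- spoken[[g]]
    }
    trials$written_word <- trials$spoken_word
    mm <- trials$congruency == "mismatch"
    sw <- trials$spoken_word[mm]
    trials$written_word[mm] <- sw[c(seq_along(sw)[-1], 1L)]
    trials$written_word[trials$congruency == "neutral"] <- "<neutral>"
    trials$cue_informative <- trials$congruency != "neutral"
    trials$cue_onset_to_speech_ms <- stats::runif(nrow(trials), 1000, 1100)
    trials$speech_onset_to_probe_ms <- stats::runif(nrow(trials), 1000, 1100)
    trials
  })
  out$block <- 1L
  out$trial <- seq_len(nrow(out))
  rownames(out) <- NULL
  out <- out[, c("block", "trial", "congruency", "channels", "written_word",
                 "spoken_word", "cue_informative", "cue_onset_to_speech_ms",
                 "speech_onset_to_probe_ms")]
  class(out) <- c("neutral_schedule", "data.frame")
  out
}

#' Summarise a trial schedule
#'
#' Condition tallies plus, for Experiment 1 schedules, the realised counts
#' of spoken words used once and twice.
#'
#' @param schedule An `exp1_schedule`, `exp2_schedule` or `neutral_schedule`.
#' @return A list of tallies suitable for JSON serialisation.
#' @export
schedule_summary <- function(schedule) {
  if (inherits(schedule, "exp2_schedule")) {
    list(n_trials = nrow(schedule),
         per_channel_case = as.list(as.data.frame.matrix(
           table(schedule$channels, schedule$case_label))),
         sets_presentations = as.list(table(table(schedule$set_id))))
  } else {
    s <- attr(schedule, "summary")
    c(list(n_trials = nrow(schedule),
           per_condition = as.list(as.data.frame.matrix(
             table(schedule$congruency, schedule$channels)))),
      if (!is.null(s)) s[c("words_spoken_twice", "words_spoken_once")])
  }
}

#' Write a schedule to CSV
#'
#' @param schedule A schedule data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}
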