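pool <- sprintf("w%03d", 1:432)

test_that("clarity-rating schedule satisfies the factorial counts and block structure", {
  sched <- exp1_schedule(pool, seed = 1)
  expect_equal(nrow(sched), 648)
  tab <- table(sched$congruency, sched$channels)
  expect_true(all(tab == 108))
  # each block holds 18 trials of every congruency x channels cell
  for (b in 1:6) {
    bt <- table(sched$congruency[sched$block == b], sched$channels[sched$block == b])
    expect_true(all(bt == 18))
  }
  expect_true(all(sched$cue_onset_to_speech_ms >= 1000 &
                    sched$cue_onset_to_speech_ms <= 1100))
  expect_true(all(sched$speech_onset_to_probe_ms >= 1000 &
                    sched$speech_onset_to_probe_ms <= 1100))
})

test_that("spoken-word reuse is capped at twice, once per congruency level", {
  sched <- exp1_schedule(pool, seed = 3)
  expect_true(max(table(sched$spoken_word)) <= 2)
  expect_true(max(table(sched$spoken_word, sched$congruency)) <= 1)
  # match trials repeat the cue; mismatch trials never do
  m <- sched$congruency == "match"
  expect_true(all(sched$written_word[m] == sched$spoken_word[m]))
  expect_true(all(sched$written_word[!m] != sched$spoken_word[!m]))
  s <- attr(sched, "summary")
  expect_equal(s$words_spoken_twice * 2 + s$words_spoken_once, 648)
})

test_that("schedules are deterministic in the seed and vary across seeds and orders", {
  a1 <- exp1_schedule(pool, "A", seed = 5)
  a2 <- exp1_schedule(pool, "A", seed = 5)
  expect_identical(a1, a2)
  b <- exp1_schedule(pool, "B", seed = 5)
  expect_false(identical(a1$spoken_word, b$spoken_word))
  other <- exp1_schedule(pool, "A", seed = 6)
  expect_false(identical(a1$spoken_word, other$spoken_word))
  # marginal counts unchanged across seeds
  expect_equal(table(other$congruency, other$channels),
               table(a1$congruency, a1$channels))
})

test_that("too-small word pools are rejected with the binding constraint named", {
  expect_error(exp1_schedule(sprintf("w%03d", 1:300), seed = 1), "pool too small")
  expect_error(neutral_replication_schedule(sprintf("w%02d", 1:60), seed = 1),
               "pool too small")
})

test_that("identification schedule has 90 trials, triple set use, 10/5/5/10 case tallies", {
  rs <- make_response_sets()
  sched <- exp2_schedule(rs, seed = 2)
  expect_equal(nrow(sched), 90)
  expect_true(all(table(sched$set_id) == 3))
  tab <- table(sched$channels, sched$case_label)
  expect_true(all(tab[, "1"] == 10 & tab[, "2"] == 5 &
                    tab[, "3"] == 5 & tab[, "4"] == 10))
  # each set is presented once per channel level, speaking distinct members
  per_set <- split(sched, sched$set_id)
  for (s in per_set) {
    expect_setequal(s$channels, c(4, 8, 16))
    expect_equal(length(unique(s$spoken_word)), 3)
  }
  # neighbour counts follow the case definition
  expect_equal(sched$n_neighbours_in_array,
               c(2L, 1L, 1L, 0L)[sched$case_label])
  expect_error(exp2_schedule(rs[1:29, ], seed = 1), "30 response sets")
  expect_identical(exp2_schedule(rs, seed = 9), exp2_schedule(rs, seed = 9))
})

test_that("neutral replication has nine 18-trial cells in one block with uninformative cues", {
  sched <- neutral_replication_schedule(pool, seed = 4)
  tab <- table(sched$congruency, sched$channels)
  expect_true(all(tab == 18))
  expect_equal(nrow(sched), 9 * 18)
  expect_true(all(sched$block == 1))
  neutral <- sched$congruency == "neutral"
  expect_true(all(!sched$cue_informative[neutral]))
  expect_true(all(sched$written_word[neutral] == "<neutral>"))
  expect_true(max(table(sched$spoken_word)) <= 2)
  expect_true(max(table(sched$spoken_word, sched$congruency)) <= 1)
})

test_that("schedules serialise to CSV and summarise to JSON-ready tallies", {
  sched <- exp1_schedule(pool, seed = 1)
  p <- tempfile(fileext = ".csv")
  on.exit(unlink(p))
  write_schedule(sched, p)
  back <- read.csv(p)
  expect_equal(nrow(back), 648)
  expect_equal(sort(unique(back$channels)), c(4, 8, 16))
  s <- schedule_summary(sched)
  expect_equal(s$n_trials, 648)
  expect_equal(s$words_spoken_twice, 216)
  s2 <- schedule_summary(exp2_schedule(make_response_sets(), seed = 1))
  expect_equal(s2$n_trials, 90)
})
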