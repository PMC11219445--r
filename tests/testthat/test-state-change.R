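test_that("eligibility enforces the 90-s visible lead/follow and status", {
  b <- toy_bundle()
  yw <- b$yawns
  yw$status <- c("spontaneous", "spontaneous", "response")
  yw$start_s <- c(95, 60, 250)
  el <- eligible_yawns(yw, b$sessions, b$visibility)
  expect_equal(el$retained$yawn_id, "Y1")  # 95 >= 90 and 600 - 95 >= 90
  expect_equal(el$rejections$reason[el$rejections$yawn_id == "Y2"],
               "insufficient_lead")
  expect_equal(el$rejections$reason[el$rejections$yawn_id == "Y3"],
               "not_spontaneous")
  # visibility gap breaks eligibility
  vis <- data.frame(subject_id = "A", session_id = "S1",
                    start_s = c(0, 100), end_s = c(90, 600))
  el2 <- eligible_yawns(yw[1, ], b$sessions, vis)
  expect_equal(el2$rejections$reason, "not_visible")
})

test_that("slots partition [t0-90, t0+90) exactly", {
  sl <- build_slots(200)
  expect_equal(sl$start_s, c(110, 170, 230))
  expect_equal(sl$end_s, c(170, 230, 290))
  # property over arbitrary onsets
  for (t0 in c(90, 123.4, 500)) {
    sl <- build_slots(t0)
    expect_equal(sl$end_s[-3], sl$start_s[-1])      # contiguous
    expect_equal(sl$start_s[1], t0 - 90)
    expect_equal(sl$end_s[3], t0 + 90)
    expect_true(all(sl$end_s - sl$start_s == 60))   # pairwise disjoint 60-s
  }
})

test_that("shift detection respects the half-open window", {
  st <- data.frame(subject_id = "A", session_id = "S1",
                   state = c("sitting", "standing"),
                   start_s = c(0, 210), end_s = c(210, 600))
  # sitting throughout
  expect_false(detect_shift(st, "A", "S1", 0, 200))
  # transition at 210 inside the window
  expect_true(detect_shift(st, "A", "S1", 180, 240))
  # transition exactly at window end -> outside (half-open)
  expect_false(detect_shift(st, "A", "S1", 150, 210))
  # transition exactly at window start -> inside
  expect_true(detect_shift(st, "A", "S1", 210, 270))
  # coverage gap is an error, never a silent FALSE
  expect_error(detect_shift(st, "A", "S1", 550, 650), "state_gap")
  # a same-state boundary is not a change
  st2 <- data.frame(subject_id = "A", session_id = "S1",
                    state = c("sitting", "sitting"),
                    start_s = c(0, 210), end_s = c(210, 600))
  expect_false(detect_shift(st2, "A", "S1", 180, 240))
})

test_that("Y halves split a transition at t0 into the post half", {
  st <- data.frame(subject_id = "A", session_id = "S1",
                   state = c("sitting", "standing"),
                   start_s = c(0, 200), end_s = c(200, 600))
  t0 <- 190  # change at t0+10, inside Y
  expect_false(detect_shift(st, "A", "S1", t0 - 30, t0))     # pre
  expect_true(detect_shift(st, "A", "S1", t0, t0 + 30))      # post
  expect_true(detect_shift(st, "A", "S1", t0 - 30, t0 + 30)) # whole Y
})

test_that("baseline selection is matched, yawn-free and seed-deterministic", {
  # 1200-s session: A stands in [200,400) (yawn there at 250) and again in
  # [700,1100), far from any yawn -> candidates exist only in the second run
  b <- ethogram_bundle(
    subjects = toy_subjects(),
    sessions = data.frame(session_id = "S1", date = "2020-09-01",
                          start_clock = "09:00:00", duration_s = 1200),
    states = data.frame(subject_id = "A", session_id = "S1",
                        state = c("sitting", "standing", "sitting",
                                  "standing", "lying"),
                        start_s = c(0, 200, 400, 700, 1100),
                        end_s = c(200, 400, 700, 1100, 1200)),
    yawns = data.frame(yawn_id = "Y1", subject_id = "A", session_id = "S1",
                       start_s = 250, end_s = 253, morph = "UCT",
                       au_string = NA_character_),
    aggressions = data.frame(event_id = character(), session_id = character(),
                             winner_id = character(), loser_id = character(),
                             start_s = numeric(), end_s = numeric(),
                             intensity = character(), decided = logical(),
                             witnesses = character()),
    visibility = data.frame(subject_id = "A", session_id = "S1",
                            start_s = 0, end_s = 1200))
  b <- annotate_yawns(b)
  y1 <- b$yawns[1, ]  # standing at t0
  bl <- select_baseline(y1, b, seed = 5)
  expect_false(is.null(bl))
  expect_equal(bl$end_s - bl$start_s, 60)
  # starts in the same state as at t0, inside the second standing run
  expect_equal(state_at(b$states, "A", bl$session_id, bl$start_s), "standing")
  # no overlap with the yawn's slot set
  expect_true(bl$end_s <= 250 - 90 || bl$start_s >= 250 + 90)
  expect_identical(select_baseline(y1, b, seed = 5), bl)
  starts6 <- vapply(1:8, function(s) select_baseline(y1, b, seed = s)$start_s,
                    numeric(1))
  expect_gt(length(unique(starts6)), 1L)  # the draw really is random
  # subject never enters the requested state -> no baseline
  y_forced <- y1
  y_forced$posture <- "walking"
  expect_null(select_baseline(y_forced, b, seed = 1))
})

test_that("the long dataset has 4 rows per yawn with BL, else 3", {
  sd_ <- build_shift_dataset(annotate_yawns(cached_bundle()), seed = 3)
  per_yawn <- table(sd_$slots$yawn_id)
  has_bl <- tapply(sd_$slots$has_bl, sd_$slots$yawn_id, unique)
  expect_true(all(per_yawn[has_bl[names(per_yawn)]] == 4L))
  expect_true(all(per_yawn[!has_bl[names(per_yawn)]] == 3L))
  expect_equal(nrow(sd_$yhalf), 2L * length(per_yawn))
  expect_true(all(levels(sd_$slots$condition) == c("C1", "Y", "C2", "BL")))
})

test_that("shift shares reproduce the printed worked example", {
  sh <- summarize_shift_shares(c(C1 = 42, Y = 146, C2 = 72, BL = 45))
  expect_equal(sh$share_rounded[sh$condition == "Y"], 48)
  expect_equal(sh$share_truncated[sh$condition == "BL"], 14)
  # rounding audit: integer shares sum to 100 +/- 1
  expect_lte(abs(sum(sh$share_rounded) - 100), 1)
  eq <- summarize_shift_shares(c(C1 = 5, Y = 5, C2 = 5, BL = 5))
  expect_true(all(eq$share_rounded == 25))
  zero <- summarize_shift_shares(c(C1 = 0, Y = 0, C2 = 0, BL = 0))
  expect_true(all(is.na(zero$share_pct)))
  expect_error(summarize_shift_shares(c(C1 = -1, Y = 0, C2 = 0, BL = 0)),
               "non-negative")
})

test_that("a post-yawn hazard boost shows up as a Y-condition shift excess", {
  # scaled-down sweep: 8 seeds on reduced-effort bundles
  wins <- 0L
  for (s in 1:8) {
    b <- generate_bundle(small_config(n_days = 6L), seed = 200L + s)
    sd_ <- build_shift_dataset(annotate_yawns(b), seed = s)
    p <- tapply(sd_$slots$shift, sd_$slots$condition, mean)
    if (p[["Y"]] > p[["C1"]] && p[["Y"]] > p[["BL"]]) wins <- wins + 1L
  }
  expect_gte(wins, 7L)
})
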