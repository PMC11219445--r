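# In-code fixtures shared across test files.

toy_subjects <- function() {
  data.frame(subject_id = c("A", "B", "C"),
             sex = c("male", "female", "male"),
             age_years = c(15, 14, 4),
             age_class = c("adult", "adult", "juvenile"))
}

# One 600-s session with hand-placed events:
#  A: sitting [0,200), standing [200,400), sitting [400,600); yawns at 250, 420
#  B: lying throughout; yawn at 250
#  C: walking then sitting; no yawns
#  aggression A beats C at [40, 60), witnessed by B
toy_bundle <- function() {
  ethogram_bundle(
    subjects = toy_subjects(),
    sessions = data.frame(session_id = "S1", date = "2020-09-01",
                          start_clock = "09:00:00", duration_s = 600),
    states = data.frame(
      subject_id = c("A", "A", "A", "B", "C", "C"),
      session_id = "S1",
      state = c("sitting", "standing", "sitting", "lying", "walking", "sitting"),
      start_s = c(0, 200, 400, 0, 0, 300),
      end_s = c(200, 400, 600, 600, 300, 600)),
    yawns = data.frame(
      yawn_id = c("Y1", "Y2", "Y3"),
      subject_id = c("A", "A", "B"),
      session_id = "S1",
      start_s = c(250, 420, 250),
      end_s = c(253, 423, 252.5),
      morph = c("UCT", "CT", "CT"),
      au_string = c("AU25+AU27+AU12+EAD3", "AU25+AU26", "AU25+AU26+AU43")),
    aggressions = data.frame(
      event_id = "G1", session_id = "S1", winner_id = "A", loser_id = "C",
      start_s = 40, end_s = 60, intensity = "contact", decided = TRUE,
      witnesses = "B"),
    exposures = data.frame(
      trigger_yawn_id = c("Y1", "Y1"), receiver_id = c("B", "C"),
      seen = c("yes", "no"), observable_for_s = c(180, 180)),
    visibility = data.frame(
      subject_id = c("A", "B", "C"), session_id = "S1",
      start_s = 0, end_s = 600))
}

# Reduced-effort generator configuration used where a full bundle is needed
# but the default 30-day schedule would be wasteful. Only observation effort
# is reduced; all effect parameters stay at their defaults.
small_config <- function(...) {
  generator_config(n_days = 10L, sessions_per_day = 4L,
                   session_duration_s = 600, ...)
}

# One cached default-scale bundle + datasets for the expensive end-to-end
# tests (generated once per test run).
cached_bundle <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- generate_bundle(small_config(), seed = 101L)
    val
  }
})
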