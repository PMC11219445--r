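ctg_yawns <- function(...) {
  d <- data.frame(...)
  d$session_id <- "S1"
  d$end_s <- d$start_s + 3
  d$morph <- "UCT"
  d
}

test_that("responses are attributed within the half-open 3-min window", {
  yw <- ctg_yawns(yawn_id = c("T1", "R1"), subject_id = c("A", "B"),
                  start_s = c(0, 100))
  ex <- data.frame(trigger_yawn_id = "T1", receiver_id = "B", seen = "yes",
                   observable_for_s = 180)
  res <- attribute_responses(yw, ex)
  expect_true(res$records$response)
  expect_equal(res$records$latency_s, 100)
  expect_equal(unname(res$status), c("spontaneous", "response"))
  # boundary: 181 s is outside, 180 s is inside
  yw2 <- ctg_yawns(yawn_id = c("T1", "R1"), subject_id = c("A", "B"),
                   start_s = c(0, 181))
  res2 <- attribute_responses(yw2, ex)
  expect_false(res2$records$response)
  expect_equal(unname(res2$status[2]), "spontaneous")
  yw3 <- ctg_yawns(yawn_id = c("T1", "R1"), subject_id = c("A", "B"),
                   start_s = c(0, 180))
  expect_true(attribute_responses(yw3, ex)$records$response)
  # a not-seen window never converts the receiver's yawn to a response
  ex_no <- transform(ex, seen = "no")
  res4 <- attribute_responses(yw, ex_no)
  expect_true(res4$records$response)  # the exposure saw a yawn in-window
  expect_equal(unname(res4$status[2]), "spontaneous")
})

test_that("censored exposures are dropped with a reason", {
  yw <- ctg_yawns(yawn_id = "T1", subject_id = "A", start_s = 500)
  ex <- data.frame(trigger_yawn_id = "T1", receiver_id = "B", seen = "yes",
                   observable_for_s = 60)
  res <- attribute_responses(yw, ex)
  expect_equal(nrow(res$records), 0L)
  expect_equal(res$dropped$reason, "censored")
})

test_that("multi-trigger overlap attributes to the earliest seen trigger", {
  yw <- ctg_yawns(yawn_id = c("T1", "T2", "R1"),
                  subject_id = c("A", "C", "B"),
                  start_s = c(0, 50, 120))
  ex <- data.frame(trigger_yawn_id = c("T1", "T2"), receiver_id = "B",
                   seen = "yes", observable_for_s = 180)
  res <- attribute_responses(yw, ex)
  expect_equal(unname(res$status["R1"]), "response")
  r <- res$records
  expect_equal(r$latency_s[r$trigger_yawn_id == "T1"], 120)
  # both exposures saw the yawn in their window; status is attributed once
  expect_equal(sum(res$status == "response"), 1L)
})

test_that("status labels partition the yawns and attribution is stable", {
  b <- annotate_yawns(cached_bundle())
  res <- attribute_responses(b$yawns, b$exposures, b$subjects)
  expect_equal(length(res$status), nrow(b$yawns))
  expect_true(all(res$status %in% c("spontaneous", "response", "unassigned")))
  # idempotence / order invariance
  perm <- sample(nrow(b$yawns))
  res2 <- attribute_responses(b$yawns[perm, ], b$exposures, b$subjects)
  expect_equal(res2$status[b$yawns$yawn_id], res$status[b$yawns$yawn_id])
  ex_perm <- b$exposures[sample(nrow(b$exposures)), ]
  res3 <- attribute_responses(b$yawns, ex_perm, b$subjects)
  expect_equal(sort(res3$records$trigger_yawn_id),
               sort(res$records$trigger_yawn_id))
})

test_that("an unknown seen status marks in-window yawns unassigned", {
  yw <- ctg_yawns(yawn_id = c("T1", "R1"), subject_id = c("A", "B"),
                  start_s = c(0, 100))
  ex <- data.frame(trigger_yawn_id = "T1", receiver_id = "B",
                   seen = NA_character_, observable_for_s = 180)
  res <- attribute_responses(yw, ex)
  expect_equal(unname(res$status[2]), "unassigned")
})

test_that("sex combinations are ordered trigger-first", {
  expect_equal(sex_combination("male", "female"), "MF")
  expect_equal(sex_combination("female", "male"), "FM")
  expect_equal(sex_combination(c("male", "female"), c("male", "female")),
               c("MM", "FF"))
  expect_true(is.na(sex_combination("male", NA)))
})

test_that("response rates reproduce the printed not-seen example", {
  rec <- data.frame(seen = rep(c("yes", "no"), c(63, 58)),
                    response = c(rep(c(TRUE, FALSE), c(16, 47)),
                                 rep(c(TRUE, FALSE), c(3, 55))),
                    latency_s = NA_real_)
  rec$latency_s[rec$response] <- 17
  rr <- response_rates(rec)
  expect_equal(rr$pct[rr$seen == "no"], 5.17)
  expect_equal(rr$pct[rr$seen == "yes"], 25.4)  # exact quotient 16/63
  expect_equal(attr(rr, "latency_mean"), 17)
  # all-absent responses
  rec0 <- transform(rec, response = FALSE, latency_s = NA_real_)
  expect_true(all(response_rates(rec0)$pct == 0))
})

test_that("a zero contagion boost leaves seen and not-seen rates equal", {
  b <- generate_bundle(small_config(contagion_p1 = 0.05), seed = 42L)
  res <- attribute_responses(b$yawns, b$exposures, b$subjects)
  rr <- response_rates(res$records)
  p <- sum(rr$n_response) / sum(rr$n)
  se <- sqrt(p * (1 - p) * sum(1 / rr$n))
  expect_lt(abs(rr$proportion[1] - rr$proportion[2]), 3 * se + 1e-9)
})
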