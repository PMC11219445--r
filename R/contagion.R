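# Yawn-contagion attribution: response labeling within the 3-min perception
# window, exposure classification (seen / not-seen), and the response-model
# dataset.

#' Ordered trigger/receiver sex combination
#'
#' @param trigger_sex,receiver_sex `"male"`/`"female"` vectors.
#' @return character vector in `MM`, `MF`, `FM`, `FF` (trigger first);
#'   `NA` when a sex is missing.
#' @export
sex_combination <- function(trigger_sex, receiver_sex) {
  code <- function(s) ifelse(s %in% "male", "M", ifelse(s %in% "female", "F",
                                                        NA_character_))
  out <- paste0(code(trigger_sex), code(receiver_sex))
  out[is.na(code(trigger_sex)) | is.na(code(receiver_sex))] <- NA_character_
  out
}

#' Attribute yawn responses to triggers within the perception window
#'
#' For every exposure annotation (trigger yawn, receiver, seen/not-seen),
#' a response occurs when the receiver yawns within `(t_trigger,
#' t_trigger + window_s]` in the same session. Every receiver yawn that
#' falls in the window after a *seen* trigger is labeled `response` and
#' leaves the spontaneous pool; when windows of several seen triggers
#' overlap, the yawn is attributed to the earliest one. Receivers not
#' followable for the full window who showed no response are dropped as
#' `censored`, mirroring the study design that kept only fully followable
#' cases. Yawns inside the window of a trigger whose seen status is missing
#' are labeled `unassigned`.
#'
#' By default attribution is chained: a yawn labeled `response` can itself
#' act as a trigger for its own annotated receivers.
#'
#' @param yawns yawn table (time-ordered or not; ordered internally).
#' @param exposures exposure table (`trigger_yawn_id`, `receiver_id`,
#'   `seen`, `observable_for_s`).
#' @param subjects subject table (for sexes).
#' @param adi_tab optional per-subject ADI table; enables `delta_adi`.
#' @param window_s perception window, seconds (default 180; half-open on the
#'   left, closed at `window_s`).
#' @param chain allow response yawns to trigger further responses
#'   (default `TRUE`).
#' @return list of class `contagion_result`: `records` (one row per retained
#'   exposure: `trigger_yawn_id`, `receiver_id`, `seen`, `response`,
#'   `latency_s`, `sex_combination`, `delta_adi`, `trigger_morph`,
#'   `trigger_context`, `chain_depth`), `status` (named vector labeling every
#'   yawn `spontaneous`/`response`/`unassigned`), `dropped` (censored
#'   exposures with reasons).
#' @export
attribute_responses <- function(yawns, exposures, subjects = NULL,
                                adi_tab = NULL, window_s = 180, chain = TRUE) {
  yw <- yawns[order(yawns$session_id, yawns$start_s), , drop = FALSE]
  status <- stats::setNames(rep("spontaneous", nrow(yw)), yw$yawn_id)
  depth <- stats::setNames(rep(0L, nrow(yw)), yw$yawn_id)
  attributed_to <- stats::setNames(rep(NA_character_, nrow(yw)), yw$yawn_id)
  # pass 1: label responses, earliest seen trigger wins (time order)
  for (i in seq_len(nrow(yw))) {
    tid <- yw$yawn_id[i]
    if (!chain && status[tid] == "response") next
    ex <- exposures[exposures$trigger_yawn_id == tid, , drop = FALSE]
    for (j in seq_len(nrow(ex))) {
      rec <- ex$receiver_id[j]
      hits <- yw$session_id == yw$session_id[i] & yw$subject_id == rec &
        yw$start_s > yw$start_s[i] & yw$start_s <= yw$start_s[i] + window_s
      if (!any(hits)) next
      for (h in which(hits)) {
        hid <- yw$yawn_id[h]
        if (!is.na(attributed_to[hid])) next  # earlier trigger already claimed it
        if (is.na(ex$seen[j])) {
          status[hid] <- "unassigned"
          attributed_to[hid] <- tid
        } else if (ex$seen[j] == "yes") {
          status[hid] <- "response"
          attributed_to[hid] <- tid
          depth[hid] <- depth[tid] + 1L
        }
      }
    }
  }
  # pass 2: response records per exposure
  recs <- list()
  dropped <- list()
  for (j in seq_len(nrow(exposures))) {
    tid <- exposures$trigger_yawn_id[j]
    i <- match(tid, yw$yawn_id)
    if (is.na(i)) next
    if (!chain && status[tid] == "response") next
    rec <- exposures$receiver_id[j]
    hits <- which(yw$session_id == yw$session_id[i] & yw$subject_id == rec &
                    yw$start_s > yw$start_s[i] &
                    yw$start_s <= yw$start_s[i] + window_s)
    responded <- length(hits) > 0L
    obs <- exposures$observable_for_s[j]
    if (!responded && !is.na(obs) && obs < window_s) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(trigger_yawn_id = tid, receiver_id = rec,
                   reason = "censored")
      next
    }
    latency <- if (responded) yw$start_s[hits[1L]] - yw$start_s[i] else NA_real_
    sc <- if (!is.null(subjects))
      sex_combination(subjects$sex[match(yw$subject_id[i], subjects$subject_id)],
                      subjects$sex[match(rec, subjects$subject_id)])
      else NA_character_
    dadi <- if (!is.null(adi_tab))
      abs(adi_tab$adi[match(yw$subject_id[i], adi_tab$subject_id)] -
            adi_tab$adi[match(rec, adi_tab$subject_id)])
      else NA_real_
    recs[[length(recs) + 1L]] <-
      data.frame(trigger_yawn_id = tid, trigger_subject_id = yw$subject_id[i],
                 receiver_id = rec,
                 seen = exposures$seen[j], response = responded,
                 latency_s = latency, sex_combination = sc, delta_adi = dadi,
                 trigger_morph = yw$morph[i],
                 trigger_context = if (!is.null(yw$context)) yw$context[i]
                   else NA_character_,
                 chain_depth = depth[tid])
  }
  empty_rec <- data.frame(trigger_yawn_id = character(),
                          trigger_subject_id = character(),
                          receiver_id = character(),
                          seen = character(), response = logical(),
                          latency_s = numeric(), sex_combination = character(),
                          delta_adi = numeric(), trigger_morph = character(),
                          trigger_context = character(), chain_depth = integer())
  structure(list(records = if (length(recs)) do.call(rbind, recs) else empty_rec,
                 status = status[yawns$yawn_id],
                 dropped = if (length(dropped)) do.call(rbind, dropped)
                   else data.frame(trigger_yawn_id = character(),
                                   receiver_id = character(),
                                   reason = character())),
            class = "contagion_result")
}

#' Response rates per exposure class
#'
#' @param records response-record table from [attribute_responses()].
#' @return data frame per `seen` class: `n`, `n_response`, `proportion`,
#'   `pct` (two decimals); attributes `latency_mean` and `latency_se` carry
#'   the mean response latency and its standard error among responders.
#' @export
response_rates <- function(records) {
  cls <- c(yes = "yes", no = "no")
  rows <- lapply(names(cls), function(k) {
    d <- records[records$seen == cls[[k]] & !is.na(records$seen), , drop = FALSE]
    n <- nrow(d)
    nr <- sum(d$response)
    data.frame(seen = cls[[k]], n = n, n_response = nr,
               proportion = if (n) nr / n else NA_real_,
               pct = if (n) round(100 * nr / n, 2) else NA_real_)
  })
  lat <- records$latency_s[records$response & !is.na(records$latency_s)]
  structure(do.call(rbind, rows),
            latency_mean = if (length(lat)) mean(lat) else NA_real_,
            latency_se = if (length(lat) > 1L)
              stats::sd(lat) / sqrt(length(lat)) else NA_real_)
}

#' Assemble the response-model dataset
#'
#' Joins trigger and receiver identities and covariates into the dataset of
#' the response model: one row per retained exposure, response 0/1, with
#' `seen`, `sex_combination`, `delta_adi`, trigger `morph` and `context`,
#' and the trigger x receiver pair id used as random-intercept grouping.
#' Rows with missing ADI (e.g. infants) or missing sex are excluded.
#'
#' @param contagion a `contagion_result`.
#' @return data frame ready for [fit_mixed()].
#' @export
build_response_dataset <- function(contagion) {
  d <- contagion$records
  d <- d[!is.na(d$seen) & !is.na(d$sex_combination) & !is.na(d$delta_adi), ,
         drop = FALSE]
  d$response <- as.integer(d$response)
  d$pair_id <- paste(d$trigger_subject_id, d$receiver_id, sep = ":")
  d
}
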