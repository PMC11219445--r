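# Behavioral state-change analysis: per-yawn slot quartets (C1, Y, C2, BL),
# shift detection, and the long-format datasets for the shift models.
#
# For a yawn at t0 the yawn slot Y = [t0-30, t0+30) is flanked by
# C1 = [t0-90, t0-30) and C2 = [t0+30, t0+90); the baseline BL is a 60-s
# block on the same subject and date starting in the same posture state and
# free of yawning. t0 is the yawn's onset (lips first parted).

#' Filter yawns eligible for the slot analysis
#'
#' A yawn is retained when it is spontaneous and the subject remained
#' completely visible for at least 90 s before and after t0 (one visibility
#' interval covering `[t0-90, t0+90)`), so that C1 and C2 can be matched to
#' the Y slot.
#'
#' @param yawns yawn table with `status` filled by the contagion stage (rows
#'   with status `response` are rejected).
#' @param sessions session table (for session bounds).
#' @param visibility visible-interval table.
#' @param lead_s,follow_s required visible lead/follow around t0 (default 90).
#' @return list with `retained` (subset of `yawns`) and `rejections`
#'   (`yawn_id`, `reason`).
#' @export
eligible_yawns <- function(yawns, sessions, visibility,
                           lead_s = 90, follow_s = 90) {
  reasons <- character(nrow(yawns))
  dur <- sessions$duration_s[match(yawns$session_id, sessions$session_id)]
  for (i in seq_len(nrow(yawns))) {
    t0 <- yawns$start_s[i]
    if (identical(yawns$status[i], "response")) {
      reasons[i] <- "not_spontaneous"
    } else if (t0 - lead_s < 0) {
      reasons[i] <- "insufficient_lead"
    } else if (t0 + follow_s > dur[i]) {
      reasons[i] <- "insufficient_follow"
    } else {
      vis <- visibility$subject_id == yawns$subject_id[i] &
        visibility$session_id == yawns$session_id[i] &
        visibility$start_s <= t0 - lead_s & visibility$end_s >= t0 + follow_s
      if (!any(vis)) reasons[i] <- "not_visible"
    }
  }
  keep <- reasons == ""
  list(retained = yawns[keep, , drop = FALSE],
       rejections = data.frame(yawn_id = yawns$yawn_id[!keep],
                               reason = reasons[!keep]))
}

#' Construct the C1/Y/C2 intervals around a yawn onset
#'
#' @param t0 yawn onset, seconds from session start.
#' @param half_s half-width of the yawn slot (default 30).
#' @return data frame with `condition` (`C1`, `Y`, `C2`), `start_s`, `end_s`;
#'   the three 60-s slots partition `[t0-90, t0+90)` exactly.
#' @export
build_slots <- function(t0, half_s = 30) {
  w <- 2 * half_s
  data.frame(condition = c("C1", "Y", "C2"),
             start_s = c(t0 - half_s - w, t0 - half_s, t0 + half_s),
             end_s = c(t0 - half_s, t0 + half_s, t0 + half_s + w))
}

#' Detect a behavioral state change within a half-open interval
#'
#' True iff the subject's posture state changes at least once at a time `t`
#' with `start_s <= t < end_s`. A transition exactly at the interval's end
#' boundary does not count (half-open convention); one exactly at its start
#' does, so a change at t0 is credited to the post-yawn half of the Y slot.
#'
#' @param states posture interval table.
#' @param subject_id,session_id identifiers.
#' @param start_s,end_s query interval.
#' @return logical scalar.
#' @export
detect_shift <- function(states, subject_id, session_id, start_s, end_s) {
  d <- states[states$subject_id == subject_id &
                states$session_id == session_id, , drop = FALSE]
  d <- d[order(d$start_s), , drop = FALSE]
  cover <- d[d$end_s > start_s & d$start_s < end_s, , drop = FALSE]
  if (!nrow(cover) || cover$start_s[1L] > start_s ||
      cover$end_s[nrow(cover)] < end_s ||
      (nrow(cover) > 1L && any(cover$start_s[-1L] != cover$end_s[-nrow(cover)])))
    stop("state_gap: posture intervals do not cover the query window")
  if (nrow(d) < 2L) return(FALSE)
  # transitions are taken from the full stream so that a change exactly at
  # the window start (previous interval outside the window) still counts
  change_t <- d$start_s[-1L]
  changed <- d$state[-1L] != d$state[-nrow(d)] &
    d$end_s[-nrow(d)] == d$start_s[-1L]  # only true boundaries, no gaps
  any(changed & change_t >= start_s & change_t < end_s)
}

#' Select a matched baseline block for one yawn
#'
#' Searches the same subject's posture stream on the same calendar date for
#' a 60-s block whose starting state equals the state at t0, that contains
#' no yawn by the subject, and that does not overlap the C1/Y/C2 slots of
#' any of the subject's yawns that day. Candidate block starts are laid on a
#' 1-s grid; when several candidates exist one is drawn uniformly at random
#' under the given seed (the selection is reproducible).
#'
#' @param yawn single-row yawn data frame (annotated with `posture`).
#' @param bundle an `ethogram_bundle`.
#' @param seed integer seed for the uniform draw.
#' @param block_s block length, seconds (default 60).
#' @return data frame (`session_id`, `start_s`, `end_s`) or `NULL` when no
#'   candidate exists.
#' @export
select_baseline <- function(yawn, bundle, seed = 1L, block_s = 60) {
  date <- bundle$sessions$date[match(yawn$session_id,
                                     bundle$sessions$session_id)]
  day_sessions <- bundle$sessions$session_id[bundle$sessions$date == date]
  target_state <- if (!is.na(yawn$posture) && nzchar(yawn$posture)) yawn$posture
    else state_at(bundle$states, yawn$subject_id, yawn$session_id, yawn$start_s)
  if (is.na(target_state)) return(NULL)
  day_yawns <- bundle$yawns[bundle$yawns$subject_id == yawn$subject_id &
                              bundle$yawns$session_id %in% day_sessions, ,
                            drop = FALSE]
  cands <- list()
  for (ses in day_sessions) {
    ses_dur <- bundle$sessions$duration_s[match(ses, bundle$sessions$session_id)]
    st <- bundle$states[bundle$states$subject_id == yawn$subject_id &
                          bundle$states$session_id == ses &
                          bundle$states$state == target_state, , drop = FALSE]
    yw <- day_yawns[day_yawns$session_id == ses, , drop = FALSE]
    forbidden <- if (nrow(yw))
      cbind(yw$start_s - 90, yw$start_s + 90) else matrix(numeric(0), 0, 2)
    for (j in seq_len(nrow(st))) {
      # block must *start* in the matching state; it may run on into later
      # states (a baseline shift), but must fit inside the session
      hi <- min(st$end_s[j] - 1, ses_dur - block_s)
      if (hi < st$start_s[j]) next
      starts <- seq(st$start_s[j], hi, by = 1)
      ok <- rep(TRUE, length(starts))
      for (r in seq_len(nrow(forbidden)))
        ok <- ok & (starts + block_s <= forbidden[r, 1L] |
                      starts >= forbidden[r, 2L])
      if (nrow(yw))  # no yawn inside the block
        for (r in seq_len(nrow(yw)))
          ok <- ok & (starts + block_s <= yw$start_s[r] | starts > yw$start_s[r])
      if (any(ok))
        cands[[length(cands) + 1L]] <- data.frame(session_id = ses,
                                                  start_s = starts[ok])
    }
  }
  if (!length(cands)) return(NULL)
  cands <- do.call(rbind, cands)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  pick <- cands[sample.int(nrow(cands), 1L), , drop = FALSE]
  data.frame(session_id = pick$session_id, start_s = pick$start_s,
             end_s = pick$start_s + block_s)
}

#' Build the long-format shift datasets
#'
#' Runs eligibility, slot construction, baseline matching and shift
#' detection for every spontaneous yawn and assembles (i) the four-condition
#' long dataset (one row per slot: C1, Y, C2 and, when found, BL) and
#' (ii) the Y-half dataset (two rows per yawn: the 30-s pre and post
#' halves). Covariates `sex`, `adi` and `morph` are joined per yawner.
#'
#' @param bundle an annotated `ethogram_bundle` (see [annotate_yawns()]).
#' @param adi_tab per-subject ADI table from [adi_table()]; computed from
#'   the bundle when `NULL`. Subjects with undefined ADI are dropped from
#'   the model datasets.
#' @param seed seed for baseline selection.
#' @return list of class `shift_data`: `slots` (long dataset with columns
#'   `yawn_id`, `condition`, `shift`, `sex`, `adi`, `morph`, `has_bl`),
#'   `yhalf` (`yawn_id`, `half` in `pre`/`post`, `shift`, covariates),
#'   `rejections`, `overlap_flags` (yawns whose slot sets overlap a
#'   neighboring yawn's slots; retained but flagged).
#' @export
build_shift_dataset <- function(bundle, adi_tab = NULL, seed = 1L) {
  if (is.null(adi_tab)) adi_tab <- adi_table(bundle)
  el <- eligible_yawns(bundle$yawns, bundle$sessions, bundle$visibility)
  yw <- el$retained
  slot_rows <- list()
  half_rows <- list()
  overlap <- character(0)
  for (i in seq_len(nrow(yw))) {
    t0 <- yw$start_s[i]
    sl <- build_slots(t0)
    others <- yw[yw$session_id == yw$session_id[i] &
                   yw$subject_id == yw$subject_id[i] &
                   yw$yawn_id != yw$yawn_id[i], , drop = FALSE]
    if (nrow(others) && any(abs(others$start_s - t0) < 180))
      overlap <- c(overlap, yw$yawn_id[i])
    shifts <- vapply(seq_len(3L), function(j)
      detect_shift(bundle$states, yw$subject_id[i], yw$session_id[i],
                   sl$start_s[j], sl$end_s[j]), logical(1))
    bl <- select_baseline(yw[i, , drop = FALSE], bundle,
                          seed = seed + i, block_s = 60)
    base <- data.frame(yawn_id = yw$yawn_id[i],
                       subject_id = yw$subject_id[i],
                       sex = bundle$subjects$sex[
                         match(yw$subject_id[i], bundle$subjects$subject_id)],
                       adi = adi_tab$adi[
                         match(yw$subject_id[i], adi_tab$subject_id)],
                       morph = yw$morph[i], has_bl = !is.null(bl))
    rows <- cbind(base[rep(1L, 3L), ], condition = sl$condition,
                  shift = as.integer(shifts))
    if (!is.null(bl)) {
      bl_shift <- detect_shift(bundle$states, yw$subject_id[i], bl$session_id,
                               bl$start_s, bl$end_s)
      rows <- rbind(rows, cbind(base, condition = "BL",
                                shift = as.integer(bl_shift)))
    }
    slot_rows[[i]] <- rows
    half_rows[[i]] <- cbind(base[rep(1L, 2L), ], half = c("pre", "post"),
                            shift = c(
                              as.integer(detect_shift(bundle$states,
                                yw$subject_id[i], yw$session_id[i], t0 - 30, t0)),
                              as.integer(detect_shift(bundle$states,
                                yw$subject_id[i], yw$session_id[i], t0, t0 + 30))))
  }
  empty_cov <- data.frame(yawn_id = character(), subject_id = character(),
                          sex = character(), adi = numeric(),
                          morph = character(), has_bl = logical())
  slots <- if (length(slot_rows)) do.call(rbind, slot_rows)
    else cbind(empty_cov, condition = character(), shift = integer())
  yhalf <- if (length(half_rows)) do.call(rbind, half_rows)
    else cbind(empty_cov, half = character(), shift = integer())
  rownames(slots) <- rownames(yhalf) <- NULL
  slots$condition <- factor(slots$condition, levels = c("C1", "Y", "C2", "BL"))
  yhalf$half <- factor(yhalf$half, levels = c("pre", "post"))
  structure(list(slots = slots, yhalf = yhalf, rejections = el$rejections,
                 overlap_flags = overlap),
            class = "shift_data")
}

#' Per-condition shares of all observed shifts
#'
#' Each condition's share is its shift count over the total shift count
#' across the four conditions, as a percentage. Shares are reported both
#' rounded to the nearest integer and truncated, because printed shares in
#' the field use either convention; the exact percentage is kept alongside.
#'
#' @param counts named numeric vector of shift counts (names `C1`, `Y`,
#'   `C2`, `BL`, in any order).
#' @return data frame: `condition`, `n_shift`, `share_pct` (exact),
#'   `share_rounded`, `share_truncated`. All-zero counts give `NA` shares.
#' @export
summarize_shift_shares <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  share <- if (total > 0) 100 * counts / total else rep(NA_real_, length(counts))
  data.frame(condition = names(counts), n_shift = as.numeric(counts),
             share_pct = as.numeric(share),
             share_rounded = as.numeric(round(share)),
             share_truncated = as.numeric(trunc(share)), row.names = NULL)
}
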