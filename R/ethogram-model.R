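# Domain model for behavioral event tables: time conventions, validation,
# context and daytime annotation, and delimited-text bundle I/O.
#
# All within-session times are seconds from session start; intervals are
# half-open [start_s, end_s). Absolute clock time of an event is the session's
# start_clock plus the within-session offset.

DAYTIME_BINS <- c("08-10", "10-12", "12-14", "14-16", "16-18")
POSTURE_STATES <- c("lying", "sitting", "standing", "walking")
MORPH_LEVELS <- c("CT", "UCT", "unknown")
CONTEXT_LEVELS <- c("resting_sleeping", "tension", "unclassified")
STATUS_LEVELS <- c("spontaneous", "response", "unassigned")

#' Convert a clock string to seconds since midnight
#'
#' @param x character vector, `"HH:MM"` or `"HH:MM:SS"`.
#' @return numeric vector of seconds since midnight.
#' @export
clock_to_s <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    if (length(p) == 2L) p <- c(p, 0)
    if (length(p) != 3L || anyNA(p)) stop("malformed clock time", call. = FALSE)
    p[1L] * 3600 + p[2L] * 60 + p[3L]
  }, numeric(1))
}

#' Format seconds since midnight as a clock string
#' @param s numeric seconds since midnight.
#' @return character `"HH:MM:SS"`.
#' @export
s_to_clock <- function(s) {
  sprintf("%02d:%02d:%02d", floor(s / 3600), floor((s %% 3600) / 60),
          round(s %% 60))
}

#' Assign the 2-h daytime bin of an event
#'
#' The observation day spans 08:00-18:30 and is divided into five 2-h bins
#' (08-10, 10-12, 12-14, 14-16, 16-18), each half-open `[lower, upper)`.
#' Events whose absolute clock time falls in the trailing 18:00-18:30 stretch
#' belong to no bin and return `NA` with reason `"after_bins"`; events outside
#' 08:00-18:30 return `NA` with reason `"outside_observation_window"`.
#'
#' @param start_clock session start as clock string or seconds since midnight.
#' @param event_start_s event offset from session start, seconds.
#' @return character vector of bin labels (`NA` where unassignable), with a
#'   `"reason"` attribute carrying the rejection reason per element.
#' @examples
#' assign_daytime_bin("09:50", 700)  # 10:01:40 -> "10-12"
#' @export
assign_daytime_bin <- function(start_clock, event_start_s) {
  s0 <- if (is.numeric(start_clock)) start_clock else clock_to_s(start_clock)
  abs_s <- s0 + event_start_s
  h <- abs_s / 3600
  idx <- findInterval(h, c(8, 10, 12, 14, 16, 18))
  bin <- ifelse(idx >= 1 & idx <= 5, DAYTIME_BINS[pmax(idx, 1L)], NA_character_)
  reason <- rep(NA_character_, length(abs_s))
  reason[h < 8 | h > 18.5] <- "outside_observation_window"
  bin[h < 8 | h > 18.5] <- NA_character_
  reason[h >= 18 & h <= 18.5] <- "after_bins"
  structure(bin, reason = reason)
}

#' Assign the social context of yawn events
#'
#' A yawn is in the `tension` context when its start lies inside an
#' aggressive interaction involving (or witnessed by) the yawner, or within
#' the 3-min tail following that interaction's end (half-open,
#' `[agg_start, agg_end + tail_s)`). It is `resting_sleeping` when the yawner
#' is inside a lying posture interval and no tension window applies.
#' Everything else is `unclassified`. When tension and resting windows
#' overlap, tension wins: an aggressive interaction is directly observable
#' while the rest/sleep alternation is inferred.
#'
#' @param yawns yawn table (`yawn_id`, `subject_id`, `session_id`, `start_s`).
#' @param aggressions aggression table (`session_id`, `winner_id`, `loser_id`,
#'   `start_s`, `end_s`, optional `witnesses` as `";"`-joined subject ids).
#' @param states posture interval table (`subject_id`, `session_id`, `state`,
#'   `start_s`, `end_s`).
#' @param tail_s tension tail after aggression end, seconds (default 180).
#' @return factor of contexts, one per yawn row.
#' @export
assign_context <- function(yawns, aggressions, states, tail_s = 180) {
  n <- nrow(yawns)
  out <- rep("unclassified", n)
  wit <- if (!is.null(aggressions$witnesses) && nrow(aggressions)) {
    strsplit(ifelse(is.na(aggressions$witnesses), "", aggressions$witnesses),
             ";", fixed = TRUE)
  } else rep(list(character(0)), nrow(aggressions))
  for (i in seq_len(n)) {
    sid <- yawns$subject_id[i]
    ses <- yawns$session_id[i]
    t0 <- yawns$start_s[i]
    if (nrow(aggressions)) {
      ag <- aggressions$session_id == ses &
        t0 >= aggressions$start_s & t0 < aggressions$end_s + tail_s
      involved <- aggressions$winner_id == sid | aggressions$loser_id == sid |
        vapply(wit, function(w) sid %in% w, logical(1))
      if (any(ag & involved)) {
        out[i] <- "tension"
        next
      }
    }
    lying <- states$subject_id == sid & states$session_id == ses &
      states$state == "lying" & states$start_s <= t0 & t0 < states$end_s
    if (any(lying)) out[i] <- "resting_sleeping"
  }
  factor(out, levels = CONTEXT_LEVELS)
}

#' Look up the posture state at a time point
#' @param states posture interval table.
#' @param subject_id,session_id identifiers.
#' @param t_s time point, seconds from session start.
#' @return state label or `NA` if uncovered.
#' @export
state_at <- function(states, subject_id, session_id, t_s) {
  hit <- states$subject_id == subject_id & states$session_id == session_id &
    states$start_s <= t_s & t_s < states$end_s
  if (!any(hit)) return(NA_character_)
  states$state[which(hit)[1L]]
}

# ---- bundle container -------------------------------------------------------

BUNDLE_TABLES <- c("subjects", "sessions", "states", "yawns", "aggressions",
                   "exposures", "visibility")

#' Construct an ethogram bundle
#'
#' Bundles the seven event tables of one study into a validated container.
#'
#' @param subjects `subject_id`, `sex`, `age_years`, `age_class`.
#' @param sessions `session_id`, `date`, `start_clock`, `duration_s`.
#' @param states posture intervals: `subject_id`, `session_id`, `state`,
#'   `start_s`, `end_s`.
#' @param yawns `yawn_id`, `subject_id`, `session_id`, `start_s`, `end_s`,
#'   `morph`, `au_string`, plus annotation columns (`context`, `daytime_bin`,
#'   `posture`, `status`) that default to their unassigned values.
#' @param aggressions `event_id`, `session_id`, `winner_id`, `loser_id`,
#'   `start_s`, `end_s`, `intensity`, `decided`, `witnesses`.
#' @param exposures seen annotations: `trigger_yawn_id`, `receiver_id`,
#'   `seen`, `observable_for_s`.
#' @param visibility visible intervals: `subject_id`, `session_id`,
#'   `start_s`, `end_s`.
#' @param validate validate on construction (default `TRUE`); invalid bundles
#'   raise an error carrying the validation report.
#' @return an object of class `ethogram_bundle` (a named list of data frames).
#' @export
ethogram_bundle <- function(subjects, sessions, states, yawns, aggressions,
                            exposures = NULL, visibility = NULL,
                            validate = TRUE) {
  if (is.null(exposures))
    exposures <- data.frame(trigger_yawn_id = character(), receiver_id = character(),
                            seen = character(), observable_for_s = numeric())
  if (is.null(visibility))
    visibility <- data.frame(subject_id = character(), session_id = character(),
                             start_s = numeric(), end_s = numeric())
  for (col in c("morph")) if (is.null(yawns[[col]])) yawns[[col]] <- "unknown"
  if (is.null(yawns$au_string)) yawns$au_string <- NA_character_
  if (is.null(yawns$context)) yawns$context <- "unclassified"
  if (is.null(yawns$daytime_bin)) yawns$daytime_bin <- NA_character_
  if (is.null(yawns$posture)) yawns$posture <- NA_character_
  if (is.null(yawns$status)) yawns$status <- "unassigned"
  if (is.null(aggressions$witnesses)) aggressions$witnesses <- ""
  b <- structure(list(subjects = subjects, sessions = sessions, states = states,
                      yawns = yawns, aggressions = aggressions,
                      exposures = exposures, visibility = visibility),
                 class = "ethogram_bundle")
  if (validate) {
    rep <- validate_bundle(b)
    if (nrow(rep)) {
      stop(structure(class = c("yawnscope_validation_error", "error", "condition"),
                     list(message = paste0("bundle validation failed (",
                                           nrow(rep), " problems); first: ",
                                           rep$code[1L], " - ", rep$message[1L]),
                          call = sys.call(-1), report = rep)))
    }
  }
  b
}

#' @export
print.ethogram_bundle <- function(x, ...) {
  cat("<ethogram_bundle>\n")
  for (nm in BUNDLE_TABLES)
    cat(sprintf("  %-12s %5d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' Validate an ethogram bundle
#'
#' Checks referential integrity and the interval/time invariants of every
#' table; violations are collected (never raised) into a structured report.
#'
#' @param bundle an `ethogram_bundle` or plain list of the seven tables.
#' @return data frame with columns `code`, `table`, `row`, `message`;
#'   zero rows when the bundle is valid.
#' @export
validate_bundle <- function(bundle) {
  errs <- list()
  add <- function(code, table, row, message)
    errs[[length(errs) + 1L]] <<- data.frame(code = code, table = table,
                                             row = row, message = message)
  sub <- bundle$subjects
  if (anyDuplicated(sub$subject_id))
    add("duplicate_subject", "subjects", anyDuplicated(sub$subject_id),
        "subject_id not unique")
  if (any(bad <- !sub$sex %in% c("male", "female")))
    add("bad_sex", "subjects", which(bad)[1L], "sex must be male/female")
  if (any(bad <- !sub$age_class %in% c("infant", "juvenile", "adult")))
    add("bad_age_class", "subjects", which(bad)[1L], "unknown age_class")
  if (any(bad <- sub$age_years < 0))
    add("bad_age", "subjects", which(bad)[1L], "negative age")
  ses <- bundle$sessions
  if (anyDuplicated(ses$session_id))
    add("duplicate_session", "sessions", anyDuplicated(ses$session_id),
        "session_id not unique")
  if (any(bad <- !(ses$duration_s > 0)))
    add("bad_duration", "sessions", which(bad)[1L], "duration_s must be > 0")
  known_sub <- function(ids) ids %in% sub$subject_id
  known_ses <- function(ids) ids %in% ses$session_id
  iv_check <- function(tab, name) {
    if (!nrow(tab)) return(invisible())
    if (any(bad <- !(tab$end_s > tab$start_s)))
      add("bad_interval", name, which(bad)[1L], "end_s must exceed start_s")
    if (any(bad <- !known_sub(tab$subject_id)))
      add("unknown_subject", name, which(bad)[1L],
          paste("unknown subject", tab$subject_id[which(bad)[1L]]))
    if (any(bad <- !known_ses(tab$session_id)))
      add("unknown_session", name, which(bad)[1L],
          paste("unknown session", tab$session_id[which(bad)[1L]]))
    key <- interaction(tab$subject_id, tab$session_id, drop = TRUE)
    for (k in levels(key)) {
      d <- tab[key == k, , drop = FALSE]
      d <- d[order(d$start_s), , drop = FALSE]
      if (nrow(d) > 1L && any(d$start_s[-1L] < d$end_s[-nrow(d)]))
        add("overlapping_intervals", name, NA_integer_,
            paste("overlapping intervals for", k))
    }
  }
  iv_check(bundle$states, "states")
  iv_check(bundle$visibility, "visibility")
  if (nrow(bundle$states) &&
      any(bad <- !bundle$states$state %in% POSTURE_STATES))
    add("bad_state", "states", which(bad)[1L], "unknown posture state")
  yw <- bundle$yawns
  if (nrow(yw)) {
    if (anyDuplicated(yw$yawn_id))
      add("duplicate_yawn", "yawns", anyDuplicated(yw$yawn_id),
          "yawn_id not unique")
    if (any(bad <- !(yw$end_s > yw$start_s)))
      add("bad_interval", "yawns", which(bad)[1L], "end_s must exceed start_s")
    if (any(bad <- !known_sub(yw$subject_id)))
      add("unknown_subject", "yawns", which(bad)[1L],
          paste("unknown subject", yw$subject_id[which(bad)[1L]]))
    if (any(bad <- !known_ses(yw$session_id)))
      add("unknown_session", "yawns", which(bad)[1L], "unknown session")
    if (any(bad <- !yw$morph %in% MORPH_LEVELS))
      add("bad_morph", "yawns", which(bad)[1L], "unknown morph label")
    ok_au <- is.na(yw$au_string) | yw$au_string == "" |
      vapply(yw$au_string, function(s) {
        !inherits(try(parse_au_string(s), silent = TRUE), "try-error")
      }, logical(1))
    if (any(!ok_au))
      add("bad_au_string", "yawns", which(!ok_au)[1L], "unparsable AU string")
  }
  ag <- bundle$aggressions
  if (nrow(ag)) {
    if (any(bad <- ag$winner_id == ag$loser_id))
      add("self_aggression", "aggressions", which(bad)[1L],
          "winner_id equals loser_id")
    if (any(bad <- !(ag$end_s > ag$start_s)))
      add("bad_interval", "aggressions", which(bad)[1L],
          "end_s must exceed start_s")
    if (any(bad <- !(known_sub(ag$winner_id) & known_sub(ag$loser_id))))
      add("unknown_subject", "aggressions", which(bad)[1L], "unknown combatant")
  }
  ex <- bundle$exposures
  if (nrow(ex)) {
    if (any(bad <- !ex$trigger_yawn_id %in% yw$yawn_id))
      add("unknown_yawn", "exposures", which(bad)[1L], "unknown trigger yawn")
    if (any(bad <- !known_sub(ex$receiver_id)))
      add("unknown_subject", "exposures", which(bad)[1L], "unknown receiver")
    if (any(bad <- !(ex$seen %in% c("yes", "no") | is.na(ex$seen))))
      add("bad_seen", "exposures", which(bad)[1L], "seen must be yes/no/NA")
  }
  if (length(errs)) do.call(rbind, errs)
  else data.frame(code = character(), table = character(), row = integer(),
                  message = character())
}

#' Annotate yawns with context, daytime bin and posture
#'
#' @param bundle an `ethogram_bundle`.
#' @param tail_s tension tail length, seconds.
#' @return the bundle with `context`, `daytime_bin` and `posture` columns of
#'   the yawn table filled in.
#' @export
annotate_yawns <- function(bundle, tail_s = 180) {
  yw <- bundle$yawns
  if (!nrow(yw)) return(bundle)
  yw$context <- as.character(assign_context(yw, bundle$aggressions,
                                            bundle$states, tail_s = tail_s))
  start_clock <- bundle$sessions$start_clock[
    match(yw$session_id, bundle$sessions$session_id)]
  yw$daytime_bin <- as.character(assign_daytime_bin(clock_to_s(start_clock),
                                                    yw$start_s))
  yw$posture <- vapply(seq_len(nrow(yw)), function(i)
    state_at(bundle$states, yw$subject_id[i], yw$session_id[i], yw$start_s[i]),
    character(1))
  bundle$yawns <- yw
  bundle
}

# ---- delimited-text I/O -----------------------------------------------------

BUNDLE_SCHEMA_VERSION <- "1"

#' Write an ethogram bundle to a directory of CSV files
#'
#' One UTF-8 comma-delimited file per table plus a small `schema.yaml`
#' recording the schema version and time conventions.
#'
#' @param bundle an `ethogram_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in BUNDLE_TABLES)
    utils::write.csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  yaml::write_yaml(list(schema_version = BUNDLE_SCHEMA_VERSION,
                        time_convention = "seconds_from_session_start",
                        interval_convention = "half_open"),
                   file.path(dir, "schema.yaml"))
  invisible(dir)
}

#' Read an ethogram bundle from a directory of CSV files
#'
#' @param dir directory written by [write_bundle()] (or hand-assembled with
#'   the same file set).
#' @param validate validate after reading (default `TRUE`).
#' @return an `ethogram_bundle`.
#' @export
read_bundle <- function(dir, validate = TRUE) {
  sfile <- file.path(dir, "schema.yaml")
  if (file.exists(sfile)) {
    sch <- yaml::read_yaml(sfile)
    if (!identical(as.character(sch$schema_version), BUNDLE_SCHEMA_VERSION))
      stop("schema_mismatch: expected version ", BUNDLE_SCHEMA_VERSION,
           ", found ", sch$schema_version)
  }
  tabs <- lapply(BUNDLE_TABLES, function(nm) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f)) stop("missing table file: ", f)
    utils::read.csv(f, stringsAsFactors = FALSE)
  })
  names(tabs) <- BUNDLE_TABLES
  for (col in c("witnesses")) {
    if (!is.null(tabs$aggressions[[col]]))
      tabs$aggressions[[col]][is.na(tabs$aggressions[[col]])] <- ""
  }
  id_cols <- list(subjects = "subject_id", sessions = c("session_id", "start_clock", "date"),
                  states = c("subject_id", "session_id", "state"),
                  yawns = c("yawn_id", "subject_id", "session_id", "morph",
                            "au_string", "context", "daytime_bin", "posture",
                            "status"),
                  aggressions = c("event_id", "session_id", "winner_id",
                                  "loser_id", "intensity", "witnesses"),
                  exposures = c("trigger_yawn_id", "receiver_id", "seen"),
                  visibility = c("subject_id", "session_id"))
  for (nm in names(id_cols)) for (cl in id_cols[[nm]])
    if (!is.null(tabs[[nm]][[cl]])) tabs[[nm]][[cl]] <- as.character(tabs[[nm]][[cl]])
  b <- ethogram_bundle(tabs$subjects, tabs$sessions, tabs$states, tabs$yawns,
                       tabs$aggressions, tabs$exposures, tabs$visibility,
                       validate = FALSE)
  if (validate) {
    rep <- validate_bundle(b)
    if (nrow(rep))
      stop(structure(class = c("yawnscope_validation_error", "error", "condition"),
                     list(message = paste0("bundle validation failed (",
                                           nrow(rep), " problems)"),
                          call = sys.call(-1), report = rep)))
  }
  b
}
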