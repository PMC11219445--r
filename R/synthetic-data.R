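# Synthetic ethogram generator: complete bundles with the statistical
# structure the pipeline assumes (two AU-defined yawn morphs, sex-dependent
# morph odds and log-normal durations, a post-yawn boost of the behavioral
# state-change hazard, and a seen-conditional yawn-response process), plus
# exported ground truth for parameter-recovery tests.

# Table of per-morph AU presence probabilities used as generator defaults:
# deterministic separators (0 or 1) and free AUs at their observed marginal
# rates in the 25 covered-teeth / 39 uncovered-teeth reference sample.
AU_PROB_CT <- c("AU1/2" = 2 / 25, "AU6" = 2 / 25, "AU8" = 7 / 25,
                "AU9+10" = 0, "AU12" = 0, "AU16" = 0, "AU25+26" = 1,
                "AU25+27" = 0, "AU43" = 4 / 25, "AU45" = 0, "AD101" = 0,
                "EAD3" = 0)
AU_PROB_UCT <- c("AU1/2" = 0, "AU6" = 35 / 39, "AU8" = 0, "AU9+10" = 1,
                 "AU12" = 1, "AU16" = 1, "AU25+26" = 0, "AU25+27" = 1,
                 "AU43" = 5 / 39, "AU45" = 24 / 39, "AD101" = 31 / 39,
                 "EAD3" = 1)

#' Default generator configuration
#'
#' The defaults state the world the pipeline targets: a 13-member zoo group
#' (2 adult males, 2 adult females, 7 juveniles, 2 infants) observed in
#' short sessions across the 08:00-18:00 day; adult males yawning an order
#' of magnitude more than other classes; uncovered-teeth yawns favored in
#' males and lasting longer on the log scale; per-morph AU probabilities at
#' the reference marginal rates; a six-fold state-change hazard in the 30 s
#' after a yawn; and a seen-conditional response probability of 0.25 against
#' a 0.05 baseline with ~17 s mean latency inside the 180-s window.
#'
#' @param ... overrides of any default element.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(...) {
  cfg <- list(
    n_days = 30L, sessions_per_day = 5L, session_duration_s = 720,
    day_start_clock = "08:30", session_gap_s = 6600,
    dwell_mean_s = c(lying = 300, sitting = 180, standing = 120, walking = 90),
    min_dwell_s = 5,
    aggression_rate_per_h = 2, p_decided = 0.9, p_contact = 0.3,
    p_win_higher_rank = 0.85, witness_prob = 0.3,
    yawn_rate_per_h = c(adult_male = 2.5, adult_female = 0.3,
                        juvenile = 0.25, infant = 0.05),
    yawn_in_lying_prob = 0.6,
    morph_logodds_uct = 1.1, morph_logodds_female = -1.7,
    duration_mu_log = 1.0, duration_beta_female = -0.32,
    duration_beta_uct = 0.24, duration_sd_log = 0.35,
    au_prob_ct = AU_PROB_CT, au_prob_uct = AU_PROB_UCT,
    shift_hazard_multiplier = 6,
    contagion_p0 = 0.05, contagion_p1 = 0.25, latency_mean_s = 17,
    response_window_s = 180, seen_prob = 0.52, max_chain_depth = 2L,
    n_receivers_per_yawn = 2L,
    visibility_full_prob = 0.85, coder_flip_eps = 0.05)
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config field: ", nm)
    cfg[[nm]] <- over[[nm]]
  }
  probs <- c(cfg$p_decided, cfg$p_contact, cfg$p_win_higher_rank,
             cfg$witness_prob, cfg$contagion_p0, cfg$contagion_p1,
             cfg$seen_prob, cfg$visibility_full_prob, cfg$coder_flip_eps,
             cfg$au_prob_ct, cfg$au_prob_uct)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(c(cfg$aggression_rate_per_h, cfg$yawn_rate_per_h) < 0))
    stop("rates must be non-negative")
  if (cfg$session_duration_s < 2 * cfg$response_window_s)
    stop("infeasible config: sessions shorter than twice the response window")
  if (max(cfg$yawn_rate_per_h) / 3600 * cfg$session_duration_s > 50)
    stop("infeasible config: yawn rate incompatible with session length")
  structure(cfg, class = "generator_config")
}

.default_subjects <- function() {
  data.frame(
    subject_id = c("AM1", "AM2", "AF1", "AF2", "JM1", "JM2", "JM3", "JM4",
                   "JF1", "JF2", "JF3", "IM1", "IF1"),
    sex = c("male", "male", "female", "female", "male", "male", "male",
            "male", "female", "female", "female", "male", "female"),
    age_years = c(18, 15, 14, 15, 4, 4, 2, 4, 3, 3, 3, 1, 0.5),
    age_class = c(rep("adult", 4L), rep("juvenile", 7L), rep("infant", 2L)))
}

.rate_class <- function(sub) {
  ifelse(sub$age_class == "adult",
         ifelse(sub$sex == "male", "adult_male", "adult_female"),
         sub$age_class)
}

# one subject-session posture stream (semi-Markov, exponential dwells)
.gen_states <- function(cfg, dur) {
  states <- names(cfg$dwell_mean_s)
  s <- sample(states, 1L, prob = cfg$dwell_mean_s)
  t <- 0
  out <- list()
  while (t < dur) {
    d <- cfg$min_dwell_s + stats::rexp(1L, 1 / cfg$dwell_mean_s[[s]])
    out[[length(out) + 1L]] <- data.frame(state = s, start_s = t,
                                          end_s = min(t + d, dur))
    t <- t + d
    s <- sample(setdiff(states, s), 1L)
  }
  do.call(rbind, out)
}

.draw_au_config <- function(p) {
  pres <- names(p)[stats::runif(length(p)) < p]
  format_au_string(pres)
}

#' Generate a complete synthetic ethogram bundle
#'
#' Identical `(config, seed)` pairs give byte-identical bundles. The result
#' carries a `truth` attribute with every latent parameter, the subjects'
#' latent dominance ranks, and each yawn's true origin (spontaneous vs
#' induced response with its trigger).
#'
#' @param config a [generator_config()].
#' @param seed integer master seed.
#' @return a validated `ethogram_bundle` with attribute `"truth"`.
#' @export
generate_bundle <- function(config = generator_config(), seed = 1L) {
  if (!inherits(config, "generator_config")) config <- do.call(generator_config, config)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sub <- .default_subjects()
  rank <- stats::setNames(rev(seq_len(nrow(sub))) / nrow(sub), sub$subject_id)
  rate <- config$yawn_rate_per_h[.rate_class(sub)]
  sessions <- list(); states <- list(); visibility <- list()
  yawns <- list(); aggr <- list(); expo <- list(); truth_yawns <- list()
  yawn_n <- 0L; aggr_n <- 0L
  day0 <- as.Date("2020-08-14")
  for (day in seq_len(config$n_days)) {
    for (si in seq_len(config$sessions_per_day)) {
      ses_id <- sprintf("D%02dS%d", day, si)
      start_clock_s <- clock_to_s(config$day_start_clock) +
        (si - 1L) * config$session_gap_s
      dur <- config$session_duration_s
      sessions[[ses_id]] <- data.frame(
        session_id = ses_id, date = as.character(day0 + day - 1L),
        start_clock = s_to_clock(start_clock_s), duration_s = dur)
      ses_states <- list()
      for (k in seq_len(nrow(sub))) {
        st <- .gen_states(config, dur)
        st <- cbind(subject_id = sub$subject_id[k], session_id = ses_id, st)
        ses_states[[sub$subject_id[k]]] <- st
        if (stats::runif(1L) < config$visibility_full_prob) {
          visibility[[length(visibility) + 1L]] <- data.frame(
            subject_id = sub$subject_id[k], session_id = ses_id,
            start_s = 0, end_s = dur)
        } else {
          gap_at <- stats::runif(1L, 0.2, 0.8) * dur
          visibility[[length(visibility) + 1L]] <- data.frame(
            subject_id = rep(sub$subject_id[k], 2L), session_id = ses_id,
            start_s = c(0, gap_at + 30), end_s = c(gap_at, dur))
        }
      }
      # aggressions
      n_ag <- stats::rpois(1L, config$aggression_rate_per_h * dur / 3600)
      for (a in seq_len(n_ag)) {
        pair <- sample(sub$subject_id[sub$age_class != "infant"], 2L)
        hi <- pair[which.max(rank[pair])]
        lo <- setdiff(pair, hi)
        win_hi <- stats::runif(1L) < config$p_win_higher_rank
        t_a <- stats::runif(1L, 0, dur - 30)
        aggr_n <- aggr_n + 1L
        others <- setdiff(sub$subject_id, pair)
        wit <- others[stats::runif(length(others)) < config$witness_prob]
        aggr[[aggr_n]] <- data.frame(
          event_id = sprintf("A%04d", aggr_n), session_id = ses_id,
          winner_id = if (win_hi) hi else lo,
          loser_id = if (win_hi) lo else hi,
          start_s = t_a, end_s = t_a + stats::runif(1L, 5, 30),
          intensity = if (stats::runif(1L) < config$p_contact) "contact"
            else "no_contact",
          decided = stats::runif(1L) < config$p_decided,
          witnesses = paste(wit, collapse = ";"))
      }
      # spontaneous yawns, then a time-ordered contagion sweep
      pend <- list()
      for (k in seq_len(nrow(sub))) {
        n_y <- stats::rpois(1L, rate[k] * dur / 3600)
        if (!n_y) next
        # drowsiness structure: most spontaneous yawns fall inside lying
        # bouts (classifiable resting context), the rest anywhere
        st_k <- ses_states[[sub$subject_id[k]]]
        ly <- st_k[st_k$state == "lying" & st_k$end_s - st_k$start_s > 2, ,
                   drop = FALSE]
        t_ys <- vapply(seq_len(n_y), function(..ignored) {
          if (nrow(ly) && stats::runif(1L) < config$yawn_in_lying_prob) {
            iv <- sample.int(nrow(ly), 1L, prob = ly$end_s - ly$start_s)
            stats::runif(1L, ly$start_s[iv] + 1, ly$end_s[iv] - 1)
          } else stats::runif(1L, 1, dur - 1)
        }, numeric(1))
        for (t_y in sort(round(t_ys, 2)))
          pend[[length(pend) + 1L]] <- list(sid = sub$subject_id[k],
                                            t = t_y, origin = "spontaneous",
                                            trigger = NA_character_,
                                            depth = 0L)
      }
      done <- list()
      while (length(pend)) {
        ts <- vapply(pend, `[[`, numeric(1), "t")
        i <- which.min(ts)
        ev <- pend[[i]]
        pend[[i]] <- NULL
        yawn_n <- yawn_n + 1L
        yid <- sprintf("Y%05d", yawn_n)
        sx <- sub$sex[sub$subject_id == ev$sid]
        p_uct <- stats::plogis(config$morph_logodds_uct +
                                 (sx == "female") * config$morph_logodds_female)
        morph <- if (stats::runif(1L) < p_uct) "UCT" else "CT"
        mu <- config$duration_mu_log +
          (sx == "female") * config$duration_beta_female +
          (morph == "UCT") * config$duration_beta_uct
        dlog <- stats::rnorm(1L, mu, config$duration_sd_log)
        dur_y <- max(0.5, round(exp(dlog), 2))
        au <- .draw_au_config(if (morph == "CT") config$au_prob_ct
                              else config$au_prob_uct)
        yawns[[yawn_n]] <- data.frame(
          yawn_id = yid, subject_id = ev$sid, session_id = ses_id,
          start_s = ev$t, end_s = min(ev$t + dur_y, dur), morph = morph,
          au_string = au)
        truth_yawns[[yawn_n]] <- data.frame(
          yawn_id = yid, origin = ev$origin, trigger_yawn_id = ev$trigger,
          chain_depth = ev$depth)
        # exposures of the followable receivers (the focal subgroup around
        # the trigger; annotation exists only for them)
        receivers <- setdiff(sub$subject_id[sub$age_class != "infant"], ev$sid)
        receivers <- sample(receivers, min(config$n_receivers_per_yawn,
                                           length(receivers)))
        for (rec in receivers) {
          seen <- stats::runif(1L) < config$seen_prob
          expo[[length(expo) + 1L]] <- data.frame(
            trigger_yawn_id = yid, receiver_id = rec,
            seen = if (seen) "yes" else "no",
            observable_for_s = min(config$response_window_s, dur - ev$t))
          if (ev$depth >= config$max_chain_depth) next
          p_resp <- if (seen) config$contagion_p1 else config$contagion_p0
          if (stats::runif(1L) < p_resp) {
            lat <- stats::qexp(stats::runif(1L) *
                                 stats::pexp(config$response_window_s,
                                             1 / config$latency_mean_s),
                               1 / config$latency_mean_s)
            t_r <- ev$t + max(lat, 0.5)
            if (t_r < dur - 1)
              pend[[length(pend) + 1L]] <- list(sid = rec, t = round(t_r, 2),
                                                origin = "induced",
                                                trigger = yid,
                                                depth = ev$depth + 1L)
          }
        }
      }
      # post-yawn state-change hazard boost
      ses_yawns <- do.call(rbind, yawns[vapply(yawns, function(y)
        y$session_id == ses_id, logical(1))])
      if (!is.null(ses_yawns) && config$shift_hazard_multiplier > 1) {
        for (r in seq_len(nrow(ses_yawns))) {
          sid <- ses_yawns$subject_id[r]
          t0 <- ses_yawns$start_s[r]
          st <- ses_states[[sid]]
          cur <- which(st$start_s <= t0 & t0 < st$end_s)
          if (!length(cur)) next
          lam <- 1 / config$dwell_mean_s[[st$state[cur]]]
          p_extra <- 1 - exp(-(config$shift_hazard_multiplier - 1) * lam * 30)
          if (stats::runif(1L) < p_extra) {
            u <- round(stats::runif(1L, t0 + 0.5, t0 + 30), 2)
            cur <- which(st$start_s <= u & u < st$end_s)
            if (!length(cur)) next
            new_state <- sample(setdiff(names(config$dwell_mean_s),
                                        st$state[cur]), 1L)
            tail_row <- st[cur, ]
            st$end_s[cur] <- u
            tail_row$start_s <- u
            tail_row$state <- new_state
            st <- rbind(st[seq_len(cur), ], tail_row,
                        if (cur < nrow(st)) st[(cur + 1L):nrow(st), ])
            ses_states[[sid]] <- st
          }
        }
      }
      states[[length(states) + 1L]] <- do.call(rbind, ses_states)
    }
  }
  bundle <- ethogram_bundle(
    subjects = sub,
    sessions = do.call(rbind, sessions),
    states = do.call(rbind, states),
    yawns = do.call(rbind, yawns),
    aggressions = if (aggr_n) do.call(rbind, aggr) else
      data.frame(event_id = character(), session_id = character(),
                 winner_id = character(), loser_id = character(),
                 start_s = numeric(), end_s = numeric(),
                 intensity = character(), decided = logical(),
                 witnesses = character()),
    exposures = do.call(rbind, expo),
    visibility = do.call(rbind, visibility))
  rownames(bundle$states) <- rownames(bundle$yawns) <- NULL
  attr(bundle, "truth") <- list(
    config = unclass(config), seed = seed, latent_rank = rank,
    yawns = do.call(rbind, truth_yawns))
  bundle
}

#' Reconstruct the 64-event reference AU fixture
#'
#' Builds 25 covered-teeth (CT) and 39 uncovered-teeth (UCT) AU
#' configurations whose per-AU column sums exactly match the reference
#' per-morph marginal counts: the deterministic separators (AU25+26 in all
#' CT; AU9+10, AU12, AU16, AU25+27, EAD3 in all UCT) are fixed, and the free
#' AUs (AU1/2: 2 CT; AU6: 2 CT, 35 UCT; AU8: 7 CT; AU43: 4 CT, 5 UCT;
#' AU45: 24 UCT; AD101: 31 UCT) are assigned to rows by a seeded draw.
#' Mutual exclusivity of AU25+26 / AU25+27 holds by construction.
#'
#' @param seed integer seed for the free-AU assignment.
#' @return data frame: `yawn_id`, `apriori_label` (`CT`/`UCT`), `au_string`.
#' @export
fixture_table3 <- function(seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  counts_ct <- c("AU1/2" = 2, "AU6" = 2, "AU8" = 7, "AU9+10" = 0, "AU12" = 0,
                 "AU16" = 0, "AU25+26" = 25, "AU25+27" = 0, "AU43" = 4,
                 "AU45" = 0, "AD101" = 0, "EAD3" = 0)
  counts_uct <- c("AU1/2" = 0, "AU6" = 35, "AU8" = 0, "AU9+10" = 39,
                  "AU12" = 39, "AU16" = 39, "AU25+26" = 0, "AU25+27" = 39,
                  "AU43" = 5, "AU45" = 24, "AD101" = 31, "EAD3" = 39)
  build <- function(counts, n, label, offset) {
    sets <- replicate(n, character(0), simplify = FALSE)
    for (cd in names(counts)) {
      if (counts[[cd]] == 0) next
      rows <- if (counts[[cd]] == n) seq_len(n)
        else sample.int(n, counts[[cd]])
      for (r in rows) sets[[r]] <- c(sets[[r]], cd)
    }
    data.frame(yawn_id = sprintf("F%03d", offset + seq_len(n)),
               apriori_label = label,
               au_string = vapply(sets, format_au_string, character(1)))
  }
  rbind(build(counts_ct, 25L, "CT", 0L), build(counts_uct, 39L, "UCT", 25L))
}

#' Simulate a second coder's AU configurations with per-AU error
#'
#' Each free AU presence flag is flipped independently with probability
#' `eps`; with the same probability the mouth-opening code is swapped
#' between AU25+26 and AU25+27 (preserving mutual exclusivity).
#'
#' @param configs AU configurations (any form accepted by
#'   [one_hot_encode()]).
#' @param eps per-AU flip probability.
#' @param seed integer seed.
#' @return list of AU code vectors, one per input configuration.
#' @export
simulate_coder_pair <- function(configs, eps, seed = 1L) {
  configs <- .as_config_list(configs)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  vocab <- au_vocabulary()
  mouth <- c("AU25+26", "AU25+27")
  lapply(configs, function(cf) {
    out <- cf
    for (cd in setdiff(vocab, mouth))
      if (stats::runif(1L) < eps)
        out <- if (cd %in% out) setdiff(out, cd) else c(out, cd)
    if (any(mouth %in% cf) && stats::runif(1L) < eps)
      out <- c(setdiff(out, mouth), setdiff(mouth, intersect(mouth, cf)))
    vocab[vocab %in% out]
  })
}
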