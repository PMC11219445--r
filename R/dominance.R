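# Dominance: decided-conflict matrix and the Average Dominance Index (ADI).

#' Build the decided-conflict winner-by-loser matrix
#'
#' Counts only decided aggressive events (those where winner and victim were
#' clearly discernible). Contact and no-contact (threat) events count
#' equally by default.
#'
#' @param aggressions aggression table (`winner_id`, `loser_id`, `decided`,
#'   `intensity`).
#' @param subjects subject table or character vector of subject ids fixing
#'   the matrix order.
#' @param intensity count all decided events (`"all"`, default) or restrict
#'   to `"contact"` / `"no_contact"`.
#' @return square integer matrix `wins[i, j]` = decided conflicts in which
#'   `i` defeated `j`; zero diagonal.
#' @export
build_conflict_matrix <- function(aggressions, subjects,
                                  intensity = c("all", "contact", "no_contact")) {
  intensity <- match.arg(intensity)
  ids <- if (is.data.frame(subjects)) subjects$subject_id else subjects
  m <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (!nrow(aggressions)) return(m)
  keep <- as.logical(aggressions$decided)
  if (intensity != "all") keep <- keep & aggressions$intensity == intensity
  ag <- aggressions[keep, , drop = FALSE]
  if (any(ag$winner_id == ag$loser_id)) stop("winner_id equals loser_id")
  for (i in seq_len(nrow(ag)))
    m[ag$winner_id[i], ag$loser_id[i]] <- m[ag$winner_id[i], ag$loser_id[i]] + 1L
  m
}

#' Average Dominance Index
#'
#' For subject `i`, the ADI is the mean over opponents `j` with at least one
#' decided conflict in the dyad of the proportion of that dyad's decided
#' conflicts won by `i`. Dyads without decided conflicts (unknown
#' relationships) are excluded from the mean, which is what distinguishes
#' the ADI from score-based indices; subjects with no interacting opponent
#' have an undefined (`NA`) ADI.
#'
#' @param matrix square winner-by-loser count matrix from
#'   [build_conflict_matrix()].
#' @return data frame: `subject_id`, `adi` in `[0, 1]` or `NA`,
#'   `n_known_dyads`, `n_decided_conflicts`.
#' @export
adi <- function(matrix) {
  if (nrow(matrix) != ncol(matrix)) stop("conflict matrix must be square")
  ids <- rownames(matrix)
  tot <- matrix + t(matrix)
  res <- lapply(seq_along(ids), function(i) {
    known <- which(tot[i, ] > 0)
    known <- setdiff(known, i)
    data.frame(subject_id = ids[i],
               adi = if (length(known)) mean(matrix[i, known] / tot[i, known])
                     else NA_real_,
               n_known_dyads = length(known),
               n_decided_conflicts = sum(matrix[i, ]) + sum(matrix[, i]))
  })
  do.call(rbind, res)
}

#' ADI table straight from a bundle
#'
#' @param bundle an `ethogram_bundle`.
#' @param intensity see [build_conflict_matrix()].
#' @return per-subject ADI data frame, see [adi()].
#' @export
adi_table <- function(bundle, intensity = "all") {
  adi(build_conflict_matrix(bundle$aggressions, bundle$subjects,
                            intensity = intensity))
}
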