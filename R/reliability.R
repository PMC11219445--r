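# Inter-observer reliability: Cohen's kappa for paired categorical
# judgements and the FACS set-agreement index for paired AU configurations.

#' Cohen's kappa for two coders
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the product of the two coders' marginal
#' category frequencies. When both coders are constant and identical,
#' `p_e = 1` and kappa is defined as 1 with a warning (agreement is perfect
#' but chance-corrected agreement is undetermined).
#'
#' @param labels1,labels2 equal-length categorical vectors (>= 2 items).
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(labels1, labels2) {
  if (length(labels1) != length(labels2)) stop("length mismatch")
  if (length(labels1) < 2L) stop("need at least 2 items")
  cats <- union(unique(labels1), unique(labels2))
  f1 <- factor(labels1, levels = cats)
  f2 <- factor(labels2, levels = cats)
  n <- length(f1)
  p_o <- mean(f1 == f2)
  p_e <- sum((table(f1) / n) * (table(f2) / n))
  if (1 - p_e < .Machine$double.eps^0.5) {
    warning("both coders constant and equal; kappa defined as 1")
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}

#' FACS agreement index between two AU configurations
#'
#' `2 * |intersection| / (|set1| + |set2|)` — the Dice agreement of the two
#' coders' AU sets for one expression, ranging from 0 (no agreement) to 1
#' (total agreement). When both sets are empty the index is 1 with a
#' warning (no codable movement, nothing to disagree on).
#'
#' @param set1,set2 character vectors of AU vocabulary codes (or AU strings
#'   parsed with [parse_au_string()]).
#' @return agreement ratio in `[0, 1]`.
#' @export
facs_agreement <- function(set1, set2) {
  as_set <- function(s) {
    # a length-1 string that is not itself a vocabulary code is a
    # serialized configuration
    if (is.character(s) && length(s) == 1L && !s %in% au_vocabulary() &&
        (is.na(s) || !nzchar(s) || grepl("+", s, fixed = TRUE)))
      parse_au_string(s) else s
  }
  set1 <- as_set(set1)
  set2 <- as_set(set2)
  vocab <- au_vocabulary()
  if (length(bad <- setdiff(c(set1, set2), vocab)))
    stop("unknown AU code: ", paste(bad, collapse = ", "))
  set1 <- unique(set1)
  set2 <- unique(set2)
  if (!length(set1) && !length(set2)) {
    warning("both configurations empty; agreement defined as 1")
    return(1)
  }
  2 * length(intersect(set1, set2)) / (length(set1) + length(set2))
}

#' Mean FACS agreement over a coder pair's shared events
#'
#' @param configs1,configs2 lists of AU code vectors (or character vectors
#'   of AU strings), one element per shared event, same length and order.
#' @return unweighted mean agreement across events.
#' @export
mean_facs_agreement <- function(configs1, configs2) {
  if (is.character(configs1)) configs1 <- lapply(configs1, parse_au_string)
  if (is.character(configs2)) configs2 <- lapply(configs2, parse_au_string)
  if (length(configs1) != length(configs2)) stop("length mismatch")
  mean(mapply(facs_agreement, configs1, configs2))
}
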