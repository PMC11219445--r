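# FACS action-unit configurations and morph discovery: serialization,
# one-hot encoding, multiple correspondence analysis, k-means clustering,
# cluster purity and per-AU Fisher contrasts.

#' The 12-code action-unit vocabulary observed during yawning
#'
#' Ten action units, one action descriptor (AD101, scalp retraction) and one
#' ear action descriptor (EAD3, ears flattener). `AU25+26` (lips parted and
#' jaw drop) and `AU25+27` (lips parted and mouth stretch) are mutually
#' exclusive within one configuration; a codable yawn carries exactly one of
#' them (the mouth must open).
#'
#' @return ordered character vector of the 12 codes.
#' @export
au_vocabulary <- function() {
  c("AU1/2", "AU6", "AU8", "AU9+10", "AU12", "AU16",
    "AU25+26", "AU25+27", "AU43", "AU45", "AD101", "EAD3")
}

# compound vocabulary code -> primitive "+"-joined serialization tokens
.au_compound <- list("AU1/2" = c("AU1", "AU2"), "AU9+10" = c("AU9", "AU10"),
                     "AU25+26" = c("AU25", "AU26"), "AU25+27" = c("AU25", "AU27"))

#' Serialize an AU configuration to a "+"-joined code string
#'
#' Compound vocabulary codes are emitted as their primitive action units
#' (e.g. `AU25+26` becomes `AU25+AU26`), so `c("AU25+27","AU12","EAD3")`
#' serializes to `"AU25+AU27+AU12+EAD3"`.
#'
#' @param codes character vector of vocabulary codes (possibly empty).
#' @return single string, `""` for an empty configuration.
#' @export
format_au_string <- function(codes) {
  vocab <- au_vocabulary()
  if (length(bad <- setdiff(codes, vocab)))
    stop("unknown AU code: ", paste(bad, collapse = ", "))
  codes <- vocab[vocab %in% codes]  # canonical order
  toks <- unlist(lapply(codes, function(cd)
    if (cd %in% names(.au_compound)) .au_compound[[cd]] else cd))
  paste(toks, collapse = "+")
}

#' Parse a "+"-joined AU code string into vocabulary codes
#'
#' @param x single string as produced by [format_au_string()].
#' @return character vector of vocabulary codes (empty for `""`/`NA`).
#' @export
parse_au_string <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  toks <- strsplit(x, "+", fixed = TRUE)[[1L]]
  prim_map <- c(AU1 = "AU1/2", AU2 = "AU1/2", AU9 = "AU9+10", AU10 = "AU9+10")
  codes <- character(0)
  has25 <- "AU25" %in% toks
  for (tk in toks) {
    if (tk %in% names(prim_map)) codes <- c(codes, prim_map[[tk]])
    else if (tk == "AU25") next
    else if (tk %in% c("AU26", "AU27")) {
      if (!has25) stop("AU26/AU27 require AU25 in: ", x)
      codes <- c(codes, if (tk == "AU26") "AU25+26" else "AU25+27")
    } else if (tk %in% au_vocabulary()) codes <- c(codes, tk)
    else stop("unknown AU token: ", tk)
  }
  codes <- unique(codes)
  if (all(c("AU25+26", "AU25+27") %in% codes))
    stop("AU25+26 and AU25+27 are mutually exclusive in: ", x)
  vocab <- au_vocabulary()
  vocab[vocab %in% codes]
}

.as_config_list <- function(configs) {
  if (is.data.frame(configs)) configs <- configs$au_string
  if (is.character(configs)) configs <- lapply(configs, parse_au_string)
  configs
}

#' One-hot encode AU configurations
#'
#' Each vocabulary code contributes two dummy columns, `<code>=present` and
#' `<code>=absent`, so every row sums to the vocabulary size. This is the
#' full indicator (disjunctive) representation of 12 binary categorical
#' variables, the form consumed by both the correspondence analysis and the
#' k-means clustering.
#'
#' @param configs list of code vectors, character vector of AU strings, or a
#'   data frame with an `au_string` column.
#' @param vocab vocabulary (default [au_vocabulary()]).
#' @return binary matrix, `length(configs)` x `2 * length(vocab)`.
#' @export
one_hot_encode <- function(configs, vocab = au_vocabulary()) {
  configs <- .as_config_list(configs)
  for (cf in configs)
    if (length(bad <- setdiff(cf, vocab)))
      stop("unknown AU code: ", paste(bad, collapse = ", "))
  pres <- t(vapply(configs, function(cf) as.numeric(vocab %in% cf),
                   numeric(length(vocab))))
  out <- matrix(0, nrow = length(configs), ncol = 2L * length(vocab),
                dimnames = list(NULL, paste0(rep(vocab, each = 2L),
                                             c("=present", "=absent"))))
  out[, seq(1L, ncol(out), by = 2L)] <- pres
  out[, seq(2L, ncol(out), by = 2L)] <- 1 - pres
  out
}

#' Multiple correspondence analysis of a one-hot indicator matrix
#'
#' Principal coordinates and variance fractions from the correspondence
#' analysis of the indicator matrix: the all-categorical special case of
#' principal component analysis of mixed data. Computed by singular value
#' decomposition of the matrix of standardized residuals
#' `D_r^{-1/2} (P - r c') D_c^{-1/2}` where `P` is the indicator matrix
#' scaled to unit total and `r`, `c` its row and column masses.
#'
#' @param x one-hot matrix from [one_hot_encode()] (constant columns, i.e.
#'   codes absent or present in every event, carry no inertia and are kept;
#'   a fully constant matrix is rejected).
#' @param ndim number of dimensions to keep (default all non-null).
#' @return list with `coords` (row principal coordinates), `var_frac`
#'   (fraction of total inertia per kept dimension, non-increasing),
#'   `values` (principal inertias), `col_coords`.
#' @export
project_mixed_pca <- function(x, ndim = NULL) {
  if (nrow(x) < 3L) stop("need at least 3 events")
  nonconst <- apply(x, 2L, function(cc) length(unique(cc)) > 1L)
  if (sum(nonconst) < 2L) stop("degenerate_input: fewer than 2 non-constant dummies")
  P <- x / sum(x)
  r <- rowSums(P)
  cm <- colSums(P)
  keep <- cm > 0
  S <- (P[, keep, drop = FALSE] - tcrossprod(r, cm[keep])) /
    sqrt(tcrossprod(r, cm[keep]))
  sv <- svd(S)
  pos <- sv$d > 1e-12
  values <- sv$d[pos]^2
  if (is.null(ndim)) ndim <- length(values)
  ndim <- min(ndim, length(values))
  coords <- sweep(sv$u[, pos, drop = FALSE], 1L, sqrt(r), "/") %*%
    diag(sv$d[pos], nrow = sum(pos))
  col_coords <- sweep(sv$v[, pos, drop = FALSE], 1L, sqrt(cm[keep]), "/") %*%
    diag(sv$d[pos], nrow = sum(pos))
  colnames(coords) <- colnames(col_coords) <- paste0("Dim", seq_len(sum(pos)))
  rownames(col_coords) <- colnames(x)[keep]
  list(coords = coords[, seq_len(ndim), drop = FALSE],
       var_frac = values / sum(values),
       values = values,
       col_coords = col_coords[, seq_len(ndim), drop = FALSE])
}

#' Seeded k-means with restarts
#'
#' Lloyd-style k-means (`stats::kmeans`, Hartigan-Wong) on the rows of `x`
#' with `restarts` random initializations under a fixed seed; the caller's
#' RNG state is left untouched.
#'
#' @param x numeric matrix (typically the one-hot matrix).
#' @param k number of clusters (default 2).
#' @param seed integer seed.
#' @param restarts random restarts (default 10).
#' @return integer vector of cluster labels in `0:(k-1)`, with the fitted
#'   `stats::kmeans` object as attribute `"fit"`.
#' @export
cluster_kmeans <- function(x, k = 2L, seed = 1L, restarts = 10L) {
  n_distinct <- nrow(unique(as.data.frame(x)))
  if (k > n_distinct) stop("insufficient_distinct_points: k = ", k,
                           " > ", n_distinct, " distinct rows")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fit <- stats::kmeans(x, centers = k, nstart = restarts, iter.max = 100L)
  structure(fit$cluster - 1L, fit = fit)
}

#' Percent agreement between cluster labels and a-priori labels
#'
#' For two clusters the purity is the better of the two possible
#' cluster-to-label mappings; for `k > 2` clusters each cluster is mapped to
#' its majority a-priori label. Invariant under permutation of event order
#' and of cluster label names.
#'
#' @param labels cluster labels.
#' @param apriori a-priori class labels, same length.
#' @return percent agreement in `[0, 100]`.
#' @export
cluster_purity <- function(labels, apriori) {
  if (length(labels) != length(apriori)) stop("length mismatch")
  tab <- table(labels, apriori)
  if (nrow(tab) == 2L && ncol(tab) == 2L) {
    agree <- max(tab[1, 1] + tab[2, 2], tab[1, 2] + tab[2, 1])
  } else {
    agree <- sum(apply(tab, 1L, max))
  }
  100 * agree / length(labels)
}

#' Per-AU contrast table between the two morph classes
#'
#' For every vocabulary code, counts and within-class percentages of
#' presence in the covered-teeth (CT) and uncovered-teeth (UCT) classes, and
#' the two-sided Fisher exact p value of the 2x2 presence/absence x class
#' table.
#'
#' @param configs_ct,configs_uct configurations per class, in any form
#'   accepted by [one_hot_encode()].
#' @param vocab vocabulary (default [au_vocabulary()]).
#' @return data frame: `au`, `n_ct`, `pct_ct`, `n_uct`, `pct_uct`, `p_value`.
#' @export
au_contrast_table <- function(configs_ct, configs_uct,
                              vocab = au_vocabulary()) {
  configs_ct <- .as_config_list(configs_ct)
  configs_uct <- .as_config_list(configs_uct)
  n1 <- length(configs_ct)
  n2 <- length(configs_uct)
  if (!n1 || !n2) stop("both classes must be non-empty")
  rows <- lapply(vocab, function(cd) {
    a <- sum(vapply(configs_ct, function(cf) cd %in% cf, logical(1)))
    c_ <- sum(vapply(configs_uct, function(cf) cd %in% cf, logical(1)))
    data.frame(au = cd, n_ct = a, pct_ct = round(100 * a / n1, 2),
               n_uct = c_, pct_uct = round(100 * c_ / n2, 2),
               p_value = fisher_exact_2x2(a, n1 - a, c_, n2 - c_))
  })
  do.call(rbind, rows)
}

#' Morph discovery report: MCA projection, k-means clusters, purity
#'
#' @param configs data frame with `au_string` and `apriori_label` columns
#'   (labels `CT`/`UCT`), or list form plus `apriori` vector.
#' @param apriori a-priori labels when `configs` is not a data frame.
#' @param k,seed,restarts clustering controls, see [cluster_kmeans()].
#' @return list of class `morph_clustering`: `one_hot`, `mca`, `labels`,
#'   `purity`, `apriori`.
#' @export
discover_morphs <- function(configs, apriori = NULL, k = 2L, seed = 1L,
                            restarts = 10L) {
  if (is.data.frame(configs)) {
    apriori <- configs$apriori_label
    configs <- configs$au_string
  }
  x <- one_hot_encode(configs)
  mca <- project_mixed_pca(x, ndim = 2L)
  labels <- cluster_kmeans(x, k = k, seed = seed, restarts = restarts)
  structure(list(one_hot = x, mca = mca, labels = as.integer(labels),
                 purity = if (!is.null(apriori)) cluster_purity(labels, apriori),
                 apriori = apriori),
            class = "morph_clustering")
}

#' @export
print.morph_clustering <- function(x, ...) {
  cat("<morph_clustering> ", nrow(x$one_hot), "events,",
      length(unique(x$labels)), "clusters\n")
  cat("  dim 1/2 variance:",
      paste0(sprintf("%.2f%%", 100 * x$mca$var_frac[1:2]), collapse = " / "), "\n")
  if (!is.null(x$purity)) cat("  purity vs a-priori labels:",
                              sprintf("%.1f%%", x$purity), "\n")
  invisible(x)
}
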