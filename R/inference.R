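# Shared statistical machinery: exact 2x2 test, mixed-effects model fitting
# (maximum likelihood), likelihood-ratio model comparison, Tukey-adjusted
# pairwise contrasts, and collinearity diagnostics.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' The table is `rbind(c(a, b), c(c, d))` with rows = groups and columns =
#' present/absent. The two-sided p value is the sum of hypergeometric
#' probabilities, over all tables with the observed margins, that do not
#' exceed the observed table's probability (the convention of mainstream
#' statistical software; a relative tolerance of 1e-7 guards against
#' floating-point ties).
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return two-sided p value in `(0, 1]`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  if (sum(cells) == 0) {
    warning("all-zero table; p = 1")
    return(1)
  }
  m <- a + b          # group-1 size
  n <- c + d          # group-2 size
  k <- a + c          # total present
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Fit a mixed-effects model by maximum likelihood
#'
#' Gaussian responses are fit with [lme4::lmer()] (`REML = FALSE`, so that
#' likelihood-ratio tests on fixed effects are valid) and binomial responses
#' with [lme4::glmer()]. Non-convergence is reported in the result, never
#' silently ignored.
#'
#' @param formula `lme4` model formula with random-intercept terms.
#' @param data model dataset; rows with `NA` in model variables are dropped.
#' @param family `"gaussian"` or `"binomial"`.
#' @return object of class `yawn_fit`: `fit` (the merMod), `coefficients`
#'   (estimate, SE, z), `logLik`, `n`, `converged`, `vif` (generalized
#'   variance-inflation factors per fixed term), `r2` (marginal and
#'   conditional variance-explained on the latent scale), `family`.
#' @export
fit_mixed <- function(formula, data, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  fit <- if (family == "gaussian") {
    lme4::lmer(formula, data = data, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  } else {
    lme4::glmer(formula, data = data, family = stats::binomial(),
                control = lme4::glmerControl(check.conv.singular = "ignore"))
  }
  msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(msgs) || !any(grepl("failed to converge", msgs))
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1L], se = sm[, 2L],
                      z = sm[, 1L] / sm[, 2L], row.names = NULL)
  structure(list(fit = fit, coefficients = coefs,
                 logLik = as.numeric(stats::logLik(fit)),
                 n = stats::nobs(fit), converged = converged,
                 messages = msgs, vif = tryCatch(gvif(fit), error = function(e) NULL),
                 r2 = r2_mixed(fit, family), family = family,
                 formula = formula),
            class = "yawn_fit")
}

#' @export
print.yawn_fit <- function(x, ...) {
  cat("<yawn_fit> ", x$family, ", n = ", x$n,
      ", logLik = ", round(x$logLik, 3),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  print(x$coefficients, digits = 4)
  if (!is.null(x$r2))
    cat(sprintf("  R2 marginal = %.3f, conditional = %.3f\n",
                x$r2["marginal"], x$r2["conditional"]))
  invisible(x)
}

# marginal/conditional variance-explained decomposition: fixed-effect
# variance over fixed + random + residual, with distribution-specific
# residual variance (sigma^2 for Gaussian, pi^2/3 on the logit scale).
r2_mixed <- function(fit, family) {
  var_f <- stats::var(as.vector(lme4::getME(fit, "X") %*% lme4::fixef(fit)))
  vc <- lme4::VarCorr(fit)
  var_r <- sum(vapply(vc, function(v) sum(diag(v)), numeric(1)))
  var_e <- if (family == "gaussian") stats::sigma(fit)^2 else pi^2 / 3
  tot <- var_f + var_r + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

# car-style generalized VIF per fixed-effect term, from the correlation
# matrix of the fixed-effect model matrix (intercept removed).
gvif <- function(fit) {
  X <- lme4::getME(fit, "X")
  asg <- attr(X, "assign")
  if (is.null(asg)) asg <- attr(lme4::getME(fit, "X"), "assign")
  terms <- attr(stats::terms(fit), "term.labels")
  keep <- asg != 0
  X <- X[, keep, drop = FALSE]
  asg <- asg[keep]
  if (ncol(X) < 2L) return(NULL)
  R <- stats::cor(X)
  detR <- det(R)
  out <- vapply(unique(asg), function(j) {
    i1 <- asg == j
    det(R[i1, i1, drop = FALSE]) * det(R[!i1, !i1, drop = FALSE]) / detR
  }, numeric(1))
  stats::setNames(out, terms[unique(asg)])
}

#' Likelihood-ratio test between nested fits
#'
#' @param full,reduced `yawn_fit` objects on the same rows, `reduced` nested
#'   in `full`.
#' @return data frame: `chisq` (`2 * (logLik_full - logLik_reduced)`, clamped
#'   at 0 within optimizer tolerance), `df`, `p_value`.
#' @export
lrt <- function(full, reduced) {
  if (full$n != reduced$n)
    stop("models were fit to different numbers of rows")
  df <- length(lme4::fixef(full$fit)) - length(lme4::fixef(reduced$fit))
  if (df < 0 ||
      !all(names(lme4::fixef(reduced$fit)) %in% names(lme4::fixef(full$fit))))
    stop("reduced model is not nested in the full model")
  chisq <- 2 * (full$logLik - reduced$logLik)
  if (chisq < -1e-6) warning("negative LRT statistic beyond tolerance")
  chisq <- max(chisq, 0)
  p <- if (df == 0L) as.numeric(chisq <= 1e-6)  # identical specs
    else stats::pchisq(chisq, df, lower.tail = FALSE)
  data.frame(chisq = chisq, df = df, p_value = p)
}

#' Tukey-adjusted all-pairwise contrasts of a factor's levels
#'
#' Builds the `m(m-1)/2` pairwise contrasts of a fixed factor from the
#' fitted coefficients and their covariance, and adjusts the z tests with
#' the single-step multivariate-normal (studentized-range style) familywise
#' correction: the adjusted p of contrast `i` is
#' `1 - P(max_j |Z_j| < |z_i|)` under the joint null, evaluated with the
#' exact contrast correlation matrix (degrees of freedom treated as
#' infinite, as is conventional for mixed binomial models). With fewer than
#' three levels a plain two-sided z test is returned with a warning.
#'
#' @param fit a `yawn_fit`.
#' @param factor_name name of a factor among the fixed effects.
#' @return data frame: `contrast`, `estimate`, `se`, `z`, `p_adjusted`.
#' @export
tukey_pairwise <- function(fit, factor_name) {
  mm <- fit$fit
  beta <- lme4::fixef(mm)
  V <- as.matrix(stats::vcov(mm))
  X <- lme4::getME(mm, "X")
  fr <- stats::model.frame(mm)
  if (!factor_name %in% names(fr)) stop("unknown factor: ", factor_name)
  f <- fr[[factor_name]]
  if (!is.factor(f)) f <- factor(f)
  lev <- levels(droplevels(f))
  m <- length(lev)
  # level-effect rows: coefficient vector giving each level's adjusted mean
  # (other covariates at reference/zero; differences cancel them anyway)
  L <- matrix(0, m, length(beta), dimnames = list(lev, names(beta)))
  L[, "(Intercept)"] <- 1
  for (l in lev[-1L]) {
    cn <- paste0(factor_name, l)
    if (!cn %in% names(beta)) stop("coefficient not found for level ", l)
    L[l, cn] <- 1
  }
  pairs <- utils::combn(lev, 2L)
  K <- t(apply(pairs, 2L, function(pr) L[pr[1L], ] - L[pr[2L], ]))
  rownames(K) <- apply(pairs, 2L, paste, collapse = " - ")
  est <- as.vector(K %*% beta)
  se <- sqrt(diag(K %*% V %*% t(K)))
  z <- est / se
  if (m < 3L) {
    warning("fewer than 3 levels; returning unadjusted z test")
    return(data.frame(contrast = rownames(K), estimate = est, se = se, z = z,
                      p_adjusted = 2 * stats::pnorm(-abs(z))))
  }
  Sig <- K %*% V %*% t(K)
  R <- stats::cov2cor(Sig)
  p_adj <- vapply(abs(z), function(zz) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(20240401L)
    1 - mvtnorm::pmvnorm(lower = rep(-zz, nrow(R)), upper = rep(zz, nrow(R)),
                         corr = R,
                         algorithm = mvtnorm::GenzBretz(abseps = 5e-8,
                                                        maxpts = 4000000L))[1L]
  }, numeric(1))
  data.frame(contrast = rownames(K), estimate = est, se = se, z = z,
             p_adjusted = pmin(pmax(p_adj, 0), 1))
}

# ---- canned model stages ----------------------------------------------------

#' Fit one of the pipeline's standard models with its full-vs-control LRT
#'
#' The four inference stages share one design: a full model with the tested
#' fixed effects plus controls and a random intercept, compared by LRT to a
#' control model stripped of the tested effects.
#'
#' * `duration`: Gaussian, response `log(duration_s)`, tested effects
#'   context + sex + ADI + morph, control daytime, random intercept yawner.
#' * `morphology`: binomial, response morph (UCT = 1), tested context +
#'   sex + ADI, control daytime, random intercept yawner.
#' * `shift`: binomial, response shift, tested condition (C1/Y/C2/BL),
#'   controls ADI + sex + morph, random intercept yawner.
#' * `yhalf`: binomial, response shift over the two 30-s Y halves, tested
#'   half (pre/post), controls ADI + sex, random intercept yawner.
#' * `response`: binomial, response yawn response, tested seen, controls
#'   sex combination + |delta ADI| + morph + context, random intercept
#'   trigger x receiver pair.
#'
#' @param model stage name, see above.
#' @param data the stage's dataset (from [model_datasets()] or hand-built).
#' @param tukey compute the post hoc condition contrasts for the `shift`
#'   stage (default `TRUE`; the single-step adjustment is integration-heavy).
#' @return list of class `yawn_model_report`: `full`, `control` (both
#'   `yawn_fit`), `lrt`, and for the `shift` stage `tukey` (the six
#'   pairwise condition contrasts).
#' @export
fit_stage <- function(model = c("duration", "morphology", "shift", "yhalf",
                                "response"), data, tukey = TRUE) {
  model <- match.arg(model)
  spec <- switch(model,
    duration = list(
      full = log_duration ~ context + sex + adi + morph + daytime_bin +
        (1 | subject_id),
      control = log_duration ~ daytime_bin + (1 | subject_id),
      family = "gaussian"),
    morphology = list(
      full = is_uct ~ context + sex + adi + daytime_bin + (1 | subject_id),
      control = is_uct ~ daytime_bin + (1 | subject_id),
      family = "binomial"),
    shift = list(
      full = shift ~ condition + adi + sex + morph + (1 | subject_id),
      control = shift ~ adi + sex + morph + (1 | subject_id),
      family = "binomial"),
    yhalf = list(
      full = shift ~ half + adi + sex + (1 | subject_id),
      control = shift ~ adi + sex + (1 | subject_id),
      family = "binomial"),
    response = list(
      full = response ~ seen + sex_combination + delta_adi + trigger_morph +
        trigger_context + (1 | pair_id),
      control = response ~ sex_combination + delta_adi + trigger_morph +
        trigger_context + (1 | pair_id),
      family = "binomial"))
  vars <- unique(c(all.vars(spec$full)))
  data <- stats::na.omit(data[, intersect(vars, names(data)), drop = FALSE])
  for (v in names(data))
    if (is.character(data[[v]]) || is.factor(data[[v]]))
      data[[v]] <- droplevels(factor(data[[v]]))
  # degenerate covariates (single level / constant after row exclusion, as
  # happens in reduced synthetic datasets) are pruned from both formulas
  prune <- function(f) {
    rhs <- attr(stats::terms(f), "term.labels")
    fixed <- rhs[!grepl("\\|", rhs)]
    ran <- rhs[grepl("\\|", rhs)]
    drop <- vapply(fixed, function(tm)
      tm %in% names(data) && length(unique(data[[tm]])) < 2L, logical(1))
    stats::reformulate(c(fixed[!drop], paste0("(", ran, ")")),
                       response = as.character(f)[2L])
  }
  full <- fit_mixed(prune(spec$full), data, spec$family)
  control <- fit_mixed(prune(spec$control), data, spec$family)
  out <- list(model = model, full = full, control = control,
              lrt = lrt(full, control), n = full$n)
  if (model == "shift" && tukey)
    out$tukey <- tryCatch(tukey_pairwise(full, "condition"),
                          error = function(e) NULL)
  structure(out, class = "yawn_model_report")
}

#' @export
print.yawn_model_report <- function(x, ...) {
  cat("<yawn_model_report> stage:", x$model, " n =", x$n, "\n")
  cat(sprintf("  full vs control LRT: chisq = %.3f, df = %d, p = %.4g\n",
              x$lrt$chisq, x$lrt$df, x$lrt$p_value))
  print(x$full$coefficients, digits = 4)
  if (!is.null(x$tukey)) {
    cat("  Tukey pairwise condition contrasts:\n")
    print(x$tukey, digits = 4)
  }
  invisible(x)
}

#' Assemble the model datasets of every inference stage from a bundle
#'
#' Runs the whole upstream pipeline: annotation, ADI, contagion attribution,
#' slot construction; then builds the per-stage datasets. Yawner rows with
#' undefined ADI (infants) are excluded, as are yawns labeled `response`
#' from the spontaneous-yawn stages.
#'
#' @param bundle an `ethogram_bundle`.
#' @param seed seed for baseline selection.
#' @return list: `duration`, `morphology` (per spontaneous yawn), `shift`,
#'   `yhalf` (from [build_shift_dataset()]), `response` (from
#'   [build_response_dataset()]), plus `adi`, `contagion`, `shift_data`.
#' @export
model_datasets <- function(bundle, seed = 1L) {
  bundle <- annotate_yawns(bundle)
  adi_tab <- adi_table(bundle)
  ctg <- attribute_responses(bundle$yawns, bundle$exposures, bundle$subjects,
                             adi_tab)
  bundle$yawns$status <- unname(ctg$status)
  sd_ <- build_shift_dataset(bundle, adi_tab, seed = seed)
  yw <- bundle$yawns[bundle$yawns$status == "spontaneous", , drop = FALSE]
  yw$log_duration <- log(yw$end_s - yw$start_s)
  yw$is_uct <- as.integer(yw$morph == "UCT")
  yw$sex <- bundle$subjects$sex[match(yw$subject_id, bundle$subjects$subject_id)]
  yw$adi <- adi_tab$adi[match(yw$subject_id, adi_tab$subject_id)]
  yw$context[yw$context == "unclassified"] <- NA
  yw$morph[yw$morph == "unknown"] <- NA
  # undefined ADI (infants) propagates as missing and excludes those rows
  drop_na_adi <- function(d) d[!is.na(d$adi), , drop = FALSE]
  list(duration = drop_na_adi(yw), morphology = drop_na_adi(yw),
       shift = drop_na_adi(sd_$slots), yhalf = drop_na_adi(sd_$yhalf),
       response = build_response_dataset(ctg),
       adi = adi_tab, contagion = ctg, shift_data = sd_)
}
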