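#' Fit the sex-by-signal interaction mixed model
#'
#' Linear mixed model `outcome ~ predictor + sex + predictor:sex` with a
#' random intercept per subject, fitted by maximum likelihood (not REML, so
#' the likelihood-ratio test across fixed-effect structures is valid). The
#' interaction is tested by an LRT against the model without it:
#' `chi2 = 2 * (logLik_full - logLik_reduced)` on 1 df, clamped at zero
#' (with a note) when optimizer noise yields a tiny negative value. Sex
#' reference level is female, so the `predictor` coefficient is the female
#' slope and the interaction coefficient is the male-minus-female slope
#' difference.
#'
#' @param data Table with columns `subject_id`, `conspecific_sex`
#'   (`"F"`/`"M"`), the outcome and the predictor. Each subject contributes
#'   at most two rows (one per conspecific sex); rows with missing outcome
#'   or predictor are dropped listwise (count reported in the result).
#' @param outcome,predictor Column names (strings).
#' @return Object of class `sex_interaction_fit`: coefficient table
#'   (`estimates`), `lrt_chi2`, `lrt_p`, `loglik_full`, `loglik_reduced`,
#'   `n_obs`, `n_groups`, `n_dropped`, `singular`, plus the two `lme4`
#'   fits (`fit_full`, `fit_reduced`) and the model frame (`data`).
#' @export
fit_sex_interaction <- function(data, outcome, predictor) {
  dt <- as.data.table(data)
  stopifnot(all(c("subject_id", "conspecific_sex", outcome, predictor)
                %in% names(dt)))
  d <- dt[, .(subject_id,
              sex = factor(conspecific_sex, levels = c("F", "M")),
              y = get(outcome), pred = get(predictor))]
  keep <- is.finite(d$y) & is.finite(d$pred) & !is.na(d$sex)
  n_dropped <- sum(!keep)
  d <- d[keep]
  if (max(table(d$subject_id)) > 2L) {
    stop("a subject contributes more than two rows")
  }
  if (uniqueN(d$subject_id) < 5L) stop("need at least 5 subjects")
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  full <- lme4::lmer(y ~ pred * sex + (1 | subject_id), data = d,
                     REML = FALSE, control = ctrl)
  red <- lme4::lmer(y ~ pred + sex + (1 | subject_id), data = d,
                    REML = FALSE, control = ctrl)
  ll_f <- as.numeric(stats::logLik(full))
  ll_r <- as.numeric(stats::logLik(red))
  chi2 <- 2 * (ll_f - ll_r)
  note <- NULL
  if (chi2 < 0) {
    note <- sprintf("LRT statistic %.3g clamped to 0 (optimizer noise)",
                    chi2)
    chi2 <- 0
  }
  cf <- lme4::fixef(full)
  se <- sqrt(diag(as.matrix(stats::vcov(full))))
  est <- data.table(term = names(cf), estimate = as.numeric(cf),
                    se = as.numeric(se))
  structure(list(
    outcome = outcome, predictor = predictor,
    estimates = est,
    lrt_chi2 = chi2, lrt_df = 1L,
    lrt_p = pchisq(chi2, 1, lower.tail = FALSE),
    loglik_full = ll_f, loglik_reduced = ll_r,
    n_obs = nrow(d), n_groups = uniqueN(d$subject_id),
    n_dropped = n_dropped,
    singular = lme4::isSingular(full),
    note = note,
    fit_full = full, fit_reduced = red, data = d
  ), class = "sex_interaction_fit")
}

#' @export
print.sex_interaction_fit <- function(x, ...) {
  cat(sprintf("Sex x %s on %s (LMM, ML, random intercept by subject)\n",
              x$predictor, x$outcome))
  cat(sprintf("  n = %d rows, %d subjects%s\n", x$n_obs, x$n_groups,
              if (x$singular) " [singular fit: zero subject variance]"
              else ""))
  print(x$estimates, digits = 3)
  cat(sprintf("  interaction LRT: chi2(1) = %.2f, p = %.3g\n",
              x$lrt_chi2, x$lrt_p))
  invisible(x)
}

#' Per-sex post hoc slopes from an interaction fit
#'
#' Linear contrasts of the full model's `(predictor, predictor:sex)`
#' coefficients: the female slope is the `predictor` coefficient, the male
#' slope adds the interaction. Each contrast gets a Wald chi-square on
#' 1 df. By default this is gated on the interaction LRT being significant
#' (`p < gate_p`), the pipeline's policy for testing specific variables.
#'
#' @param fit A [fit_sex_interaction()] result.
#' @param gate_p Significance gate on the interaction (default 0.05).
#' @param force Bypass the gate.
#' @return `data.table`: `sex`, `slope`, `se`, `chi2`, `p_value`.
#' @export
posthoc_by_sex <- function(fit, gate_p = 0.05, force = FALSE) {
  if (!inherits(fit, "sex_interaction_fit")) {
    stop("post hoc requested without a fitted interaction model")
  }
  if (!force && fit$lrt_p >= gate_p) {
    stop("interaction LRT p = ", format(fit$lrt_p, digits = 3),
         " >= gate (", gate_p, "); use force = TRUE to bypass")
  }
  V <- as.matrix(stats::vcov(fit$fit_full))
  cf <- lme4::fixef(fit$fit_full)
  terms <- names(cf)
  ip <- match("pred", terms)
  ii <- match("pred:sexM", terms)
  contrasts <- list(F = c(ip), M = c(ip, ii))
  out <- rbindlist(lapply(names(contrasts), function(s) {
    cv <- rep(0, length(cf)); cv[contrasts[[s]]] <- 1
    est <- sum(cv * cf)
    v <- drop(t(cv) %*% V %*% cv)
    chi2 <- est^2 / v
    data.table(sex = s, slope = est, se = sqrt(v), chi2 = chi2,
               p_value = pchisq(chi2, 1, lower.tail = FALSE))
  }))
  out[]
}

#' Influence diagnostics by subject deletion
#'
#' Refits the full model deleting each subject in turn (the random effect
#' is per subject, so influence is assessed at the group level). Cook's
#' distance for subject i is
#' `(b - b_(-i))' V^-1 (b - b_(-i)) / p` with `V` the fixed-effect
#' covariance of the full fit and `p` the number of fixed effects. A
#' subject is flagged iff any of its rows has |standardized residual| > 2
#' AND its Cook's distance strictly exceeds `4 / n_groups`.
#'
#' @param fit A [fit_sex_interaction()] result.
#' @return `data.table`: `subject_id`, `max_abs_std_resid`, `cooks_d`,
#'   `flagged`.
#' @export
influence_check <- function(fit) {
  stopifnot(inherits(fit, "sex_interaction_fit"))
  d <- fit$data
  full <- fit$fit_full
  b <- lme4::fixef(full)
  V <- as.matrix(stats::vcov(full))
  Vinv <- solve(V)
  p <- length(b)
  sg <- stats::sigma(full)
  # exactly deterministic data: residuals are numerical zeros, not outliers
  sr <- if (sg > 1e-10) resid(full) / sg else rep(0, nrow(d))
  subjects <- unique(d$subject_id)
  thr <- 4 / length(subjects)
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  out <- rbindlist(lapply(subjects, function(s) {
    di <- d[subject_id != s]
    refit <- lme4::lmer(y ~ pred * sex + (1 | subject_id), data = di,
                        REML = FALSE, control = ctrl)
    db <- b - lme4::fixef(refit)[names(b)]
    cd <- drop(t(db) %*% Vinv %*% db) / p
    msr <- max(abs(sr[d$subject_id == s]))
    data.table(subject_id = s, max_abs_std_resid = msr, cooks_d = cd,
               flagged = msr > 2 && cd > thr)
  }))
  out[]
}

#' Rank-transform an outcome
#'
#' Average ranks for ties; missing values are excluded from ranking and
#' stay missing.
#'
#' @param values Numeric vector (length >= 1).
#' @return Ranks, same length.
#' @export
rank_transform <- function(values) {
  if (length(values) < 1L) stop("need at least one value")
  rank(values, na.last = "keep", ties.method = "average")
}

#' Paired Wilcoxon signed-rank Z (normal approximation)
#'
#' Drops zero differences, ranks absolute differences with average ranks
#' for ties, and returns the standardized statistic
#' `Z = (W+ - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24 - tie_correction)` with the
#' usual tie correction `sum(t^3 - t)/48`. All-zero differences give Z = 0
#' with a warning.
#'
#' @param x,y Paired samples.
#' @return List: `z`, `p_value`, `n` (non-zero pairs).
#' @export
wilcoxon_signed_z <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; Z treated as 0")
    return(list(z = 0, p_value = 1, n = 0L))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w - mu) / sqrt(sig2)
  list(z = z, p_value = 2 * pnorm(-abs(z)), n = n)
}

#' Univariate tests on the scored subject table
#'
#' The battery of simple tests around the component scores: Welch two-sample
#' t tests of age class against the vocal score and the time spent near the
#' speaker, Pearson correlations of body condition with the same two, a
#' Pearson correlation of exploration with the vocal score and a Spearman
#' correlation of exploration with the spatial score. When a neighbourhood
#' response table is supplied, paired Wilcoxon signed-rank tests (normal
#' approximation) compare pre vs post associate counts and mean association
#' times per conspecific sex.
#'
#' @param scored Scored subject table from [score_responses()] (needs
#'   `pc1_vocal`, `pc2_spatial`, `age_class`, `condition`, `exploration`,
#'   `time_within_5m_s`).
#' @param neighbor Optional [neighbor_response()] table.
#' @return Nested list of test results (each `htest`-like or a
#'   [wilcoxon_signed_z()] list).
#' @export
univariate_tests <- function(scored, neighbor = NULL) {
  sc <- as.data.table(scored)
  if (min(table(sc$age_class)) < 3L) {
    stop("need at least 3 observations per age class")
  }
  age <- factor(sc$age_class, levels = c("2cy", "older"))
  out <- list(
    age_vs_pc1 = t.test(sc$pc1_vocal ~ age, var.equal = FALSE),
    age_vs_time_near = t.test(sc$time_within_5m_s ~ age, var.equal = FALSE),
    condition_vs_pc1 = cor.test(sc$condition, sc$pc1_vocal),
    condition_vs_time_near = cor.test(sc$condition, sc$time_within_5m_s),
    exploration_vs_pc1 = cor.test(sc$exploration, sc$pc1_vocal),
    exploration_vs_pc2 = suppressWarnings(
      cor.test(sc$exploration, sc$pc2_spatial, method = "spearman"))
  )
  if (!is.null(neighbor)) {
    nb <- as.data.table(neighbor)
    out$assoc_prepost <- lapply(c("M", "F"), function(s) {
      sub <- nb[conspecific_sex == s]
      cc <- stats::complete.cases(sub$mean_time_pre, sub$mean_time_post)
      list(
        sex = s,
        n_associates = wilcoxon_signed_z(sub$n_assoc_post, sub$n_assoc_pre),
        mean_time = wilcoxon_signed_z(sub$mean_time_post[cc],
                                      sub$mean_time_pre[cc])
      )
    })
    names(out$assoc_prepost) <- c("M", "F")
  }
  out
}
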