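# Study-scale model table: one subject-level predictor, two rows per
# subject (conspecific sexes), random intercept sd 10 m, residual sd 15 m.
sim_lmm_data <- function(n_subjects = 13, beta_int = 0, beta_pred = -5,
                         beta_sex = 3, re_sd = 10, resid_sd = 15,
                         seed = NULL) {
  gen <- function() {
    pred <- rnorm(n_subjects)
    u <- rnorm(n_subjects, 0, re_sd)
    dt <- data.table::CJ(i = seq_len(n_subjects), sexM = 0:1)
    dt[, `:=`(
      subject_id = sprintf("s%02d", i),
      conspecific_sex = ifelse(sexM == 1, "M", "F"),
      pred0 = pred[i],
      y = beta_pred * pred[i] + beta_sex * sexM +
        beta_int * pred[i] * sexM + u[i] + rnorm(.N, 0, resid_sd)
    )]
    data.table::setnames(dt, "pred0", "x")
    dt
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

test_that("interaction fit reports coefficients, LRT and grouping sizes", {
  d <- sim_lmm_data(13, beta_int = 13.5, seed = 1)
  f <- fit_sex_interaction(d, "y", "x")
  expect_s3_class(f, "sex_interaction_fit")
  expect_equal(f$n_obs, 26L)
  expect_equal(f$n_groups, 13L)
  expect_gte(f$lrt_chi2, 0)
  expect_equal(f$lrt_chi2, 2 * (f$loglik_full - f$loglik_reduced),
               tolerance = 1e-8)
  expect_equal(f$estimates$term,
               c("(Intercept)", "pred", "sexM", "pred:sexM"))
  expect_output(print(f), "interaction LRT")
  expect_error(fit_sex_interaction(d[1:6], "y", "x"), "at least 5")
})

test_that("fits are invariant to subject relabeling and row order", {
  d <- sim_lmm_data(13, beta_int = 10, seed = 2)
  f1 <- fit_sex_interaction(d, "y", "x")
  d2 <- data.table::copy(d)[sample(.N)]
  d2[, subject_id := paste0("zz_", subject_id)]
  f2 <- fit_sex_interaction(d2, "y", "x")
  expect_equal(f1$estimates$estimate, f2$estimates$estimate,
               tolerance = 1e-6)
  expect_equal(f1$lrt_chi2, f2$lrt_chi2, tolerance = 1e-6)
})

test_that("nesting holds: full ML log-likelihood is never below reduced", {
  for (s in 1:10) {
    d <- sim_lmm_data(13, beta_int = ifelse(s %% 2, 0, 8), seed = 100 + s)
    f <- fit_sex_interaction(d, "y", "x")
    expect_gte(f$loglik_full, f$loglik_reduced - 1e-6)
  }
})

test_that("post hoc contrasts follow the reference-level algebra", {
  d <- sim_lmm_data(20, beta_int = 25, seed = 3)
  f <- fit_sex_interaction(d, "y", "x")
  ph <- posthoc_by_sex(f, force = TRUE)
  cf <- f$estimates
  # female slope = predictor coefficient; male adds the interaction
  expect_equal(ph[ph$sex == "F", slope],
               cf[cf$term == "pred", estimate], tolerance = 1e-10)
  expect_equal(ph[ph$sex == "M", slope],
               cf[cf$term == "pred", estimate] +
                 cf[cf$term == "pred:sexM", estimate], tolerance = 1e-10)
  expect_true(all(ph$chi2 >= 0))

  # exchangeable sexes: mirror every subject with sexes swapped, so the
  # pooled data are invariant under relabeling and the slopes must agree
  dsym <- sim_lmm_data(15, beta_int = 0, beta_sex = 0, seed = 4)
  mirror <- data.table::copy(dsym)
  mirror[, `:=`(subject_id = paste0("b", subject_id),
                conspecific_sex = ifelse(conspecific_sex == "F", "M", "F"))]
  fs <- fit_sex_interaction(rbind(dsym, mirror), "y", "x")
  phs <- posthoc_by_sex(fs, force = TRUE)
  expect_equal(phs[phs$sex == "F", slope], phs[phs$sex == "M", slope],
               tolerance = 1e-6)

  expect_error(posthoc_by_sex(list()), "without a fitted")
  dnull <- sim_lmm_data(30, beta_int = 0, seed = 5)
  fnull <- fit_sex_interaction(dnull, "y", "x")
  if (fnull$lrt_p >= 0.05) expect_error(posthoc_by_sex(fnull), "gate")
})

test_that("power splits by sex when only females respond", {
  # female-only effect at |beta|/sigma = 1.2: female contrast powered,
  # male contrast near nominal
  rejF <- rejM <- 0L
  nrep <- 60
  for (s in 1:nrep) {
    d <- sim_lmm_data(40, beta_int = 12, beta_pred = -12, beta_sex = 0,
                      re_sd = 5, resid_sd = 10, seed = 700 + s)
    # male slope = -12 + 12 = 0; female slope = -12; resid sd 10
    f <- fit_sex_interaction(d, "y", "x")
    ph <- posthoc_by_sex(f, force = TRUE)
    if (ph[ph$sex == "F", p_value] < 0.05) rejF <- rejF + 1L
    if (ph[ph$sex == "M", p_value] < 0.05) rejM <- rejM + 1L
  }
  expect_gte(rejF / nrep, 0.8)
  expect_lte(rejM / nrep, 0.15)
})

test_that("influence diagnostics flag a planted outlier subject only", {
  d <- sim_lmm_data(13, beta_int = 0, beta_pred = 0, beta_sex = 0,
                    re_sd = 0.5, resid_sd = 1, seed = 6)
  # ~10-sigma outlier in one row of one subject (a whole-subject shift
  # would be absorbed by its random intercept)
  d[subject_id == "s01" & conspecific_sex == "M", y := y + 25]
  f <- fit_sex_interaction(d, "y", "x")
  ic <- influence_check(f)
  expect_true(ic[subject_id == "s01", flagged])
  expect_equal(sum(ic$flagged), 1L)

  # perfectly linear noiseless data: nothing flagged
  dlin <- sim_lmm_data(10, beta_int = 2, beta_pred = 1, beta_sex = 1,
                       re_sd = 0, resid_sd = 0, seed = 7)
  flin <- suppressWarnings(suppressMessages(
    fit_sex_interaction(dlin, "y", "x")))
  expect_equal(sum(influence_check(flin)$flagged), 0L)
})

test_that("rank transform averages ties and ignores monotone warping", {
  expect_equal(rank_transform(c(5, 1, 3)), c(3, 1, 2))
  expect_equal(rank_transform(c(2, 2, 7)), c(1.5, 1.5, 3))
  x <- c(0.1, 2, 0.5, 9, 4)
  expect_equal(rank_transform(x), rank_transform(exp(x)))
  expect_equal(rank_transform(c(1, NA, 3)), c(1, NA, 2))
  expect_error(rank_transform(numeric(0)), "at least one")
})

test_that("signed-rank Z matches the normal-approximation Wilcoxon", {
  withr::with_seed(8, {
    x <- rnorm(20); y <- rnorm(20, 0.5)
  })
  w <- wilcoxon_signed_z(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                            correct = FALSE)
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
  # anti-symmetric differences give Z = 0 (integer base keeps the
  # differences exactly equal in magnitude)
  xi <- as.numeric(1:20)
  y2 <- xi + c(rep(2, 10), rep(-2, 10))
  expect_equal(wilcoxon_signed_z(xi, y2)$z, 0)
  expect_warning(w0 <- wilcoxon_signed_z(x, x), "zero")
  expect_equal(w0$z, 0)
})

test_that("welch t and correlations match closed-form fixtures", {
  a <- c(4.1, 5.2, 6.3, 5.8, 4.9)
  b <- c(7.4, 8.1, 6.9, 9.0)
  tt <- t.test(a, b, var.equal = FALSE)
  se2 <- var(a) / 5 + var(b) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 5)^2 / 4 + (var(b) / 4)^2 / 3)
  expect_equal(unname(tt$statistic), t_hand, tolerance = 1e-8)
  expect_equal(unname(tt$parameter), df_hand, tolerance = 1e-8)

  rt <- simulate_response_table(40, seed = 9)
  sc <- score_responses(rt)
  ut <- univariate_tests(sc$scored)
  expect_named(ut, c("age_vs_pc1", "age_vs_time_near", "condition_vs_pc1",
                     "condition_vs_time_near", "exploration_vs_pc1",
                     "exploration_vs_pc2"))
  expect_equal(unname(ut$condition_vs_pc1$estimate),
               cor(sc$scored$condition, sc$scored$pc1_vocal),
               tolerance = 1e-10)
  # older birds respond more strongly (negative t with 2cy first)
  expect_lt(unname(ut$age_vs_pc1$statistic), 0)
})
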