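#' Body condition as a weight-on-tarsus residual
#'
#' Ordinary least-squares regression of body weight on tarsus length across
#' the cohort; a bird's condition is its residual (g). Rows with a missing
#' measure get `NA` and do not enter the fit.
#'
#' @param weight Body weights (g).
#' @param tarsus Tarsus lengths (mm), same length.
#' @return Residuals (g), aligned with the input.
#' @export
body_condition <- function(weight, tarsus) {
  stopifnot(length(weight) == length(tarsus))
  ok <- is.finite(weight) & is.finite(tarsus)
  if (sum(ok) < 3L) stop("need at least 3 birds with both measures")
  if (sd(tarsus[ok]) < 1e-12) {
    stop("zero tarsus variance: regression is degenerate")
  }
  fit <- lm(weight ~ tarsus, subset = ok)
  out <- rep(NA_real_, length(weight))
  out[ok] <- resid(fit)
  out
}

#' Bartlett's test of sphericity
#'
#' Tests a correlation matrix against the identity:
#' `chi2 = -(n - 1 - (2p + 5)/6) * log(det(R))` on `p(p-1)/2` degrees of
#' freedom.
#'
#' @param R Symmetric positive-definite correlation matrix (p x p).
#' @param n Sample size (> p).
#' @return List: `chi2`, `df`, `p_value`.
#' @export
bartlett_sphericity <- function(R, n) {
  p <- ncol(R)
  stopifnot(is.matrix(R), nrow(R) == p, n > p)
  if (max(abs(R - t(R))) > 1e-8) stop("`R` must be symmetric")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("`R` is not positive definite (smallest eigenvalue ",
         format(min(ev)), ")")
  }
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * sum(log(ev))
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df, p_value = pchisq(chi2, df, lower.tail = FALSE))
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' With `Q` the anti-image partial correlations from the inverse of `R`
#' (`q_ij = -inv_ij / sqrt(inv_ii * inv_jj)`),
#' `KMO = sum r_ij^2 / (sum r_ij^2 + sum q_ij^2)` over off-diagonal cells.
#'
#' @param R Invertible correlation matrix.
#' @return Overall KMO in `[0, 1]`, with per-variable measures in the
#'   `"msa"` attribute.
#' @export
kmo <- function(R) {
  p <- ncol(R)
  inv <- tryCatch(solve(R), error = function(e) {
    stop("`R` is singular; KMO undefined")
  })
  sq <- sqrt(diag(inv))
  Q <- -inv / tcrossprod(sq)
  diag(Q) <- 0
  R0 <- R; diag(R0) <- 0
  r2 <- R0^2; q2 <- Q^2
  overall <- sum(r2) / (sum(r2) + sum(q2))
  msa <- colSums(r2) / (colSums(r2) + colSums(q2))
  structure(overall, msa = msa)
}

#' Principal components with varimax rotation and Kaiser normalization
#'
#' PCA on the correlation matrix (variables standardized). Components with
#' eigenvalue > 1 are retained (Kaiser criterion) and their loadings
#' varimax-rotated with Kaiser row normalization (rows scaled to unit
#' communality before rotation, rescaled after). Scores use the regression
#' method, `Z %*% solve(R) %*% L`, and each component's sign is fixed so
#' its largest-|loading| variable loads positively. Rotated components are
#' ordered by explained variance. Sampling-adequacy diagnostics (KMO,
#' Bartlett sphericity) are computed on the same correlation matrix.
#'
#' A warning flags unstable retention when the largest eigenvalue does not
#' exceed `1 + 3 * sqrt(p / n)` (the Kaiser rule is then driven by sampling
#' noise), and another flags small samples (`n < 3p`).
#'
#' @param x Numeric matrix or data frame (n x p), n >= 3, no constant
#'   column.
#' @return Object of class `pca_varimax`: `eigenvalues` (all p),
#'   `variance_explained` (% per eigenvalue, sums to 100), `k` retained,
#'   `loadings` (p x k, rotated), `rotated_ss` (% variance per rotated
#'   component), `scores` (n x k), `kmo`, `bartlett`, `R`, `n`.
#' @export
pca_varimax <- function(x) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (n < 3) stop("need at least 3 rows")
  sds <- apply(X, 2, sd)
  if (any(sds < 1e-12)) {
    stop("constant column(s): ",
         paste(colnames(X)[sds < 1e-12], collapse = ", "))
  }
  if (n <= p) {
    stop("need more rows than variables (n > p): the correlation matrix ",
         "is singular and regression scores are undefined")
  }
  if (n < 3 * p) warning("small sample (n < 3p): retention is fragile")
  R <- cor(X)
  eg <- eigen(R, symmetric = TRUE)
  ev <- eg$values
  k <- sum(ev > 1)
  if (ev[1] <= 1 + 3 * sqrt(p / n)) {
    warning("no eigenvalue clearly exceeds 1: component retention by the ",
            "Kaiser rule is unstable for this data")
  }
  if (k < 1) k <- 1L
  L <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k)
  rotmat <- diag(k)
  if (k >= 2) {
    vm <- varimax(L, normalize = TRUE)
    L <- unclass(vm$loadings)
    rotmat <- vm$rotmat
  }
  # order by explained variance after rotation, then fix signs
  ssl <- colSums(L^2)
  ord <- order(ssl, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  ssl <- ssl[ord]
  for (j in seq_len(k)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  rownames(L) <- colnames(X)
  colnames(L) <- paste0("PC", seq_len(k))
  Z <- scale(X)
  scores <- Z %*% solve(R, L)
  colnames(scores) <- colnames(L)
  structure(list(
    eigenvalues = ev,
    variance_explained = ev / p * 100,
    k = k,
    loadings = L,
    rotated_ss = ssl / p * 100,
    scores = scores,
    kmo = as.numeric(kmo(R)),
    bartlett = bartlett_sphericity(R, n),
    R = R, n = n
  ), class = "pca_varimax")
}

#' @export
print.pca_varimax <- function(x, ...) {
  cat("Varimax-rotated PCA (correlation matrix), n =", x$n, "\n")
  cat("Eigenvalues:", paste(sprintf("%.2f", x$eigenvalues), collapse = " "),
      "\n")
  cat("Retained:", x$k, "component(s);",
      paste(sprintf("%.0f%%", x$rotated_ss), collapse = " + "),
      "of total variance\n")
  cat(sprintf("KMO = %.2f; Bartlett chi2(%d) = %.1f, p = %.3g\n",
              x$kmo, x$bartlett$df, x$bartlett$chi2, x$bartlett$p_value))
  cat("Rotated loadings:\n")
  print(round(x$loadings, 2))
  invisible(x)
}

#' Score playback responses: condition and rotated component scores
#'
#' Runs [pca_varimax()] on the six playback-response variables, labels the
#' rotated component carrying the four vocal variables `pc1_vocal` and the
#' other `pc2_spatial`, and adds body condition from weight and tarsus.
#'
#' @param responses Table with the six response variables plus `subject_id`,
#'   `age_class`, `weight_g`, `tarsus_mm` (e.g. from
#'   [simulate_response_table()]).
#' @return List: `scored` (input plus `condition`, `pc1_vocal`,
#'   `pc2_spatial`), `pca` (the `pca_varimax` object).
#' @export
score_responses <- function(responses) {
  resp <- as.data.table(responses)
  vars <- c("n_overlaps", "n_songs_total", "n_songs_during",
            "sing_duration_s", "time_within_5m_s", "latency_s")
  missing_cols <- setdiff(vars, names(resp))
  if (length(missing_cols)) {
    stop("missing response variables: ", paste(missing_cols, collapse = ", "))
  }
  pca <- pca_varimax(resp[, ..vars])
  if (pca$k < 2) stop("fewer than 2 components retained; cannot separate ",
                      "vocal and spatial responses")
  vocal_ss <- colSums(pca$loadings[vars[1:4], , drop = FALSE]^2)
  vocal_pc <- which.max(vocal_ss)
  spatial_pc <- which.max(colSums(
    pca$loadings[vars[5:6], , drop = FALSE]^2))
  if (spatial_pc == vocal_pc) spatial_pc <- setdiff(seq_len(pca$k),
                                                    vocal_pc)[1]
  scored <- copy(resp)
  scored[, condition := body_condition(weight_g, tarsus_mm)]
  scored[, pc1_vocal := pca$scores[, vocal_pc]]
  scored[, pc2_spatial := pca$scores[, spatial_pc]]
  list(scored = scored[], pca = pca)
}
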