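# Downstream statistics: partial correlations of IdC means with
# demographics/CSF measures, regressions of PLS brain scores on CSF
# biomarkers, Bonferroni correction, and an AIC interaction screen for the
# CSF-to-MRI delay.

#' Partial correlation
#'
#' Residualizes `x` and `y` on an intercept plus the covariates, then
#' Pearson-correlates the residuals. `t = r sqrt(df / (1 - r^2))` with
#' `df = n - 2 - k`; two-tailed p. With no covariates this is the plain
#' Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional `n x k` matrix/data.frame (e.g. age, sex,
#'   education).
#' @return List with `r`, `t`, `p`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= k + 3) stop("need n > k + 3 observations")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (k > 0) {
    D <- cbind(1, as.matrix(covariates))
    qrD <- qr(D)
    x <- qr.resid(qrD, x)
    y <- qr.resid(qrD, y)
  } else {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  # residuals that are pure numerical dust mean the variable was fully
  # explained by the covariates; correlating dust is meaningless
  if (stats::sd(x) < 1e-10 * max(sx, .Machine$double.eps) ||
      stats::sd(y) < 1e-10 * max(sy, .Machine$double.eps)) {
    stop("zero residual variance")
  }
  r <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  df <- n - 2L - k
  tt <- r * sqrt(df / (1 - r^2))
  list(r = r, t = tt, p = 2 * stats::pt(-abs(tt), df), df = df, n = n)
}

#' Regression of a PLS brain score on a CSF biomarker
#'
#' OLS of the brain score on the biomarker with sex and years of education
#' as covariates. Continuous variables (score, biomarker, education) are
#' z-scored so the biomarker coefficient is a standardized beta; sex stays
#' 0/1. Age is never a covariate here: the maps entering the PLS already had
#' age residualized out. The biomarker p-value is Bonferroni-adjusted for
#' `m` tests (default 2: pTau181 and A-beta-42 per brain score).
#'
#' @param score Brain-score vector (dependent variable).
#' @param biomarker CSF biomarker concentrations.
#' @param sex 0/1 vector (1 = male).
#' @param education Years of education.
#' @param m Number of tests for the Bonferroni correction.
#' @return List with `beta`, `t`, `p`, `p_adj`, `aic`, `n`, and the fitted
#'   `model`.
#' @export
brainscore_biomarker_regression <- function(score, biomarker, sex, education,
                                            m = 2) {
  d <- data.frame(score = score, biomarker = biomarker, sex = sex,
                  education = education)
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 20) stop("need at least 20 complete cases")
  if (stats::sd(d$biomarker) == 0) stop("biomarker is constant")
  zs <- function(v) (v - mean(v)) / stats::sd(v)
  d$score <- zs(d$score); d$biomarker <- zs(d$biomarker)
  d$education <- zs(d$education)
  fit <- stats::lm(score ~ biomarker + sex + education, data = d)
  sm <- summary(fit)$coefficients
  list(beta = sm["biomarker", "Estimate"],
       t = sm["biomarker", "t value"],
       p = sm["biomarker", "Pr(>|t|)"],
       p_adj = min(1, m * sm["biomarker", "Pr(>|t|)"]),
       coefficients = sm,
       aic = stats::AIC(fit), n = nrow(d), model = fit)
}

#' AIC screen for a biomarker-by-delay interaction
#'
#' Compares the base brain-score model against the same model plus a single
#' biomarker x CSF-to-MRI-delay product term (both factors z-scored before
#' multiplication, so exactly one parameter is added). The interaction is
#' kept iff it lowers the AIC.
#'
#' @param score,biomarker,sex,education As in
#'   [brainscore_biomarker_regression()].
#' @param delay Days between CSF collection and MRI.
#' @return List with `keep` (logical), `aic_base`, `aic_interaction`, and
#'   the two fits.
#' @export
interaction_aic_check <- function(score, biomarker, sex, education, delay) {
  d <- data.frame(score = score, biomarker = biomarker, sex = sex,
                  education = education, delay = delay)
  d <- d[stats::complete.cases(d), ]
  zs <- function(v) (v - mean(v)) / stats::sd(v)
  d$score <- zs(d$score); d$biomarker <- zs(d$biomarker)
  d$education <- zs(d$education)
  d$bxd <- d$biomarker * zs(d$delay)
  base <- stats::lm(score ~ biomarker + sex + education, data = d)
  inter <- stats::lm(score ~ biomarker + sex + education + bxd, data = d)
  aic_b <- stats::AIC(base); aic_i <- stats::AIC(inter)
  list(keep = aic_i < aic_b, aic_base = aic_b, aic_interaction = aic_i,
       base = base, interaction = inter)
}
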