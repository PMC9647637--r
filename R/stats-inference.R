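# Classical inference used throughout the analysis: Wald odds ratios,
# Fisher exact tests, Box-Cox transforms, random-intercept linear mixed
# models with Wald tests, Spearman screens, Mann-Whitney U and t tests.

#' Odds ratio with Wald confidence interval from a 2x2 table
#'
#' OR = ad/bc with CI exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d)).
#' When any cell is zero the Haldane-Anscombe 0.5 continuity correction is
#' applied to every cell and flagged.
#'
#' @param a,b,c,d nonnegative integer cells: rows = exposure
#'   (present/absent), columns = outcome (TRUE/FALSE), so `a` = exposed
#'   with outcome and `d` = unexposed without.
#' @param level confidence level (default 0.95).
#' @return list with `or`, `lower`, `upper`, `corrected` flag.
#' @export
odds_ratio_wald <- function(a, b, c, d, level = 0.95) {
  stopifnot(all(c(a, b, c, d) >= 0), a + b + c + d > 0)
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or = or, lower = exp(log(or) - z * se), upper = exp(log(or) + z * se),
       corrected = corrected)
}

#' Two-sided Fisher exact test for a 2x2 table
#' @inheritParams odds_ratio_wald
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, c, b, d), 2, 2))$p.value
}

#' Box-Cox transform with profile-likelihood lambda selection
#'
#' Transform (y^l - 1)/l for l != 0 and log(y) for l = 0. Counts of zero
#' are shifted by +0.5 before transforming (flagged in the result). When
#' `lambda` is NULL it is chosen by maximum profile likelihood on the grid
#' `[-2, 2]` in steps of 0.01.
#'
#' @param y positive (after shift) numeric vector.
#' @param lambda fixed lambda, or NULL to estimate.
#' @param shift value added when any y is <= 0 (default 0.5).
#' @return list with `values`, `lambda`, `shifted`.
#' @export
boxcox_transform <- function(y, lambda = NULL, shift = 0.5) {
  shifted <- any(y <= 0)
  if (shifted) y <- y + shift
  stopifnot(all(y > 0))
  if (is.null(lambda)) {
    prof <- MASS::boxcox(y ~ 1, lambda = seq(-2, 2, 0.01), plotit = FALSE)
    lambda <- prof$x[which.max(prof$y)]
  }
  vals <- if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
  list(values = vals, lambda = lambda, shifted = shifted)
}

#' Random-intercept linear mixed model with Wald tests
#'
#' Fits `response ~ fixed + (1 | group)` by REML (lme4) and reports Wald
#' z statistics (estimate / SE, two-sided normal p) for every fixed
#' effect, the random-intercept and residual variances.
#'
#' @param response numeric vector (transform upstream: Box-Cox or log).
#' @param fixed data.frame or matrix of fixed-effect covariates (no
#'   intercept column; one is added).
#' @param group grouping labels (length of response; >= 2 distinct).
#' @return object of class `mixed_fit`: list with `coefficients`
#'   (data.frame: term, estimate, se, z, p), `var_intercept`,
#'   `var_residual`, `n_groups`, `model`.
#' @export
fit_random_intercept_lmm <- function(response, fixed, group) {
  fixed <- as.data.frame(fixed)
  stopifnot(length(response) == nrow(fixed),
            length(group) == length(response))
  if (length(unique(group)) < 2)
    stop("need at least 2 groups for a random intercept")
  X <- stats::model.matrix(~ ., data = fixed)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  dat <- data.frame(.y = response, fixed, .g = factor(group),
                    check.names = TRUE)
  form <- stats::as.formula(paste(".y ~",
    paste(colnames(dat)[2:(1 + ncol(fixed))], collapse = " + "),
    "+ (1 | .g)"))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = dat, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  vc <- lme4::VarCorr(fit)
  structure(list(
    coefficients = data.frame(term = names(est), estimate = unname(est),
                              se = unname(se), z = unname(z), p = unname(p)),
    var_intercept = as.numeric(vc$.g[1, 1]),
    var_residual = attr(vc, "sc")^2,
    n_groups = length(unique(group)),
    model = fit), class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat("<mixed_fit> random-intercept LMM,", x$n_groups, "groups\n")
  cat("  var(intercept) =", signif(x$var_intercept, 4),
      " var(residual) =", signif(x$var_residual, 4), "\n")
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Spearman correlation screen of fiber metrics against an outcome
#'
#' Rank correlations on pairwise-complete rows (average ranks on ties)
#' among the columns of `cbind(X, outcome)`, with a significance mask at
#' unadjusted alpha (no multiplicity adjustment by default; a
#' Benjamini-Hochberg switch is available).
#'
#' @param X numeric data.frame/matrix of metrics.
#' @param y outcome vector (e.g. TIL counts); may be NULL to screen X
#'   alone.
#' @param alpha significance cutoff (default 0.05).
#' @param adjust "none" (default) or "BH".
#' @return list with `rho` matrix, `p` matrix, `significant` logical mask.
#' @export
spearman_matrix <- function(X, y = NULL, alpha = 0.05, adjust = "none") {
  X <- as.data.frame(X)
  if (!is.null(y)) X$outcome <- y
  M <- as.matrix(X)
  p <- ncol(M)
  rho <- matrix(NA_real_, p, p, dimnames = list(colnames(M), colnames(M)))
  pv <- rho
  for (i in 1:p) for (j in i:p) {
    ok <- stats::complete.cases(M[, i], M[, j])
    if (sum(ok) >= 3) {
      ct <- suppressWarnings(stats::cor.test(M[ok, i], M[ok, j],
                                             method = "spearman"))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      pv[i, j] <- pv[j, i] <- ct$p.value
    }
  }
  diag(pv) <- 0
  if (adjust == "BH") {
    up <- upper.tri(pv)
    pv[up] <- stats::p.adjust(pv[up], "BH")
    pv[lower.tri(pv)] <- t(pv)[lower.tri(pv)]
  }
  list(rho = rho, p = pv, significant = pv < alpha)
}

#' Mann-Whitney U test
#'
#' Exact p by enumeration for small samples without ties (n_x + n_y <=
#' 20), normal approximation with tie correction otherwise.
#'
#' @param x,y numeric samples.
#' @param alternative "two.sided" (default), "less" or "greater".
#' @return list with `U` (for the first sample) and `p`.
#' @export
mann_whitney_u <- function(x, y, alternative = "two.sided") {
  exact <- (length(x) + length(y) <= 20) &&
    !any(duplicated(c(x, y)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = exact, correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Student's (or Welch's) two-sample t test with normality helper
#'
#' @param x,y numeric samples.
#' @param variant "student" (pooled variance, default) or "welch".
#' @return list with `t`, `p`, `df`, `normality_p` (Shapiro-Wilk p per
#'   sample, a check that the Gaussian assumption is reasonable).
#' @export
welch_or_student_t <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  tt <- stats::t.test(x, y, var.equal = variant == "student")
  np <- c(x = tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA),
          y = tryCatch(stats::shapiro.test(y)$p.value, error = function(e) NA))
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), normality_p = np)
}
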