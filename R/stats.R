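# Statistical procedures over tidy session/trial tables: linear
# mixed-effects models with Satterthwaite degrees of freedom, post hoc
# contrasts, trialwise rank-sum masks, and the standard nonparametric and
# paired tests. Fitting is by REML through lme4/lmerTest; the asinh
# transform handles zero-valued normalized scores.

#' Inverse hyperbolic sine transform
#'
#' Elementwise asinh(x) = log(x + sqrt(x^2 + 1)); defined at zero (unlike
#' log), odd-symmetric, and logarithmic for large |x|. Applied to
#' normalized success-rate and trial-count series before mixed-model
#' fitting.
#'
#' @param values Numeric vector.
#' @return Transformed vector.
#' @export
asinh_transform <- function(values) {
  asinh(values)
}

#' Specify a linear mixed-effects analysis
#'
#' @param response Response column name.
#' @param fixed One-sided formula for the fixed effects, e.g.
#'   `~ laser * session`.
#' @param random Random-effects structure per rat: "intercept" (random
#'   intercepts), or the name of a column whose effect varies between rats
#'   (e.g. "laser", "session", "trial_in_block"), giving correlated random
#'   intercepts and slopes.
#' @param transform "none" or "asinh" (applied to the response).
#' @param group_col Grouping-factor column (default "rat").
#' @return An `lmm_spec`.
#' @export
lmm_spec <- function(response, fixed, random = "intercept",
                     transform = c("none", "asinh"), group_col = "rat") {
  transform <- match.arg(transform)
  stopifnot(inherits(fixed, "formula"))
  structure(list(response = response, fixed = fixed, random = random,
                 transform = transform, group_col = group_col),
            class = "lmm_spec")
}

#' Fit a linear mixed-effects model
#'
#' REML fit with random intercepts (or intercepts + slopes) per rat and the
#' requested fixed effects; per-coefficient t statistics use Satterthwaite
#' approximate degrees of freedom, matching the fractional df convention of
#' behavioural mixed-model reports. Singular random-effects fits are
#' flagged but their fixed effects are still returned.
#'
#' @param table Data frame containing the response, fixed-effect, and
#'   grouping columns.
#' @param spec An [lmm_spec()].
#' @return An `lmm_fit`: list with `fit` (the lmerMod), `coefficients`
#'   (data frame: term, estimate, se, df, stat, p), `singular`, `spec`.
#' @export
fit_lmm <- function(table, spec) {
  stopifnot(inherits(spec, "lmm_spec"))
  need <- c(spec$response, all.vars(spec$fixed), spec$group_col)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("columns missing from table: ", paste(miss, collapse = ", "))
  if (length(unique(table[[spec$group_col]])) < 2) {
    stop("need at least 2 grouping units (rats)")
  }
  tab <- table
  tab$.y <- tab[[spec$response]]
  if (spec$transform == "asinh") tab$.y <- asinh_transform(tab$.y)
  ran <- if (identical(spec$random, "intercept")) {
    sprintf("(1 | %s)", spec$group_col)
  } else {
    sprintf("(1 + %s | %s)", spec$random, spec$group_col)
  }
  fx <- paste(deparse(spec$fixed[[2]]), collapse = " ")
  form <- stats::as.formula(paste(".y ~", fx, "+", ran))
  fit <- lmerTest::lmer(form, data = tab, REML = TRUE,
                        control = lme4::lmerControl(
                          optimizer = "bobyqa",
                          check.conv.singular = "ignore",
                          optCtrl = list(maxfun = 100000)))
  co <- as.data.frame(summary(fit)$coefficients)
  coefficients <- data.frame(term = rownames(co),
                             estimate = co[, "Estimate"],
                             se = co[, "Std. Error"],
                             df = co[, "df"],
                             stat = co[, "t value"],
                             p = co[, "Pr(>|t|)"],
                             row.names = NULL)
  structure(list(fit = fit, coefficients = coefficients,
                 singular = lme4::isSingular(fit), spec = spec),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Linear mixed-effects fit: %s (%s transform)%s\n",
              x$spec$response, x$spec$transform,
              if (x$singular) " [singular random effects]" else ""))
  df <- x$coefficients
  df$estimate <- signif(df$estimate, 4)
  df$se <- signif(df$se, 3)
  df$df <- round(df$df, 1)
  df$stat <- round(df$stat, 2)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.lmm_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Post hoc contrast test on a mixed-model fit
#'
#' Tests c' beta = 0 for a fixed-effect contrast vector, with Satterthwaite
#' degrees of freedom (the same machinery used for single-coefficient
#' tests). The all-zero contrast returns estimate 0 with p = 1.
#'
#' @param fit An `lmm_fit`.
#' @param contrast Numeric vector, one entry per fixed-effect coefficient
#'   (in the order of `fit$coefficients$term`).
#' @return A `test_result`: list with `estimate`, `se`, `df`, `statistic`,
#'   `p`, `method`.
#' @export
contrast_test <- function(fit, contrast) {
  stopifnot(inherits(fit, "lmm_fit"))
  k <- nrow(fit$coefficients)
  if (length(contrast) != k) {
    stop("contrast length ", length(contrast),
         " does not match the ", k, " fixed-effect coefficients")
  }
  if (all(contrast == 0)) {
    return(test_result(estimate = 0, se = 0, df = NA_real_, statistic = 0,
                       p = 1, method = "mixed-model contrast (zero vector)"))
  }
  ct <- lmerTest::contest1D(fit$fit, contrast)
  test_result(estimate = ct$Estimate, se = ct$`Std. Error`, df = ct$df,
              statistic = ct$`t value`, p = ct$`Pr(>|t|)`,
              method = "mixed-model contrast (Satterthwaite df)")
}

test_result <- function(estimate = NA_real_, se = NA_real_, df = NA_real_,
                        statistic = NA_real_, p = NA_real_, method = "") {
  structure(list(estimate = estimate, se = se, df = df,
                 statistic = statistic, p = p, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: stat = %.4g, df = %s, p = %.4g\n", x$method, x$statistic,
              if (is.finite(x$df)) sprintf("%.1f", x$df) else "NA", x$p))
  if (is.finite(x$estimate) && nzchar(x$method)) {
    cat(sprintf("  estimate %.4g (se %.3g)\n", x$estimate, x$se))
  }
  invisible(x)
}

#' Trialwise Wilcoxon rank-sum significance mask
#'
#' Two-sample rank-sum test between groups at each trial position of
#' carry-forward-aligned per-rat series, with a raw p cutoff (no
#' multiple-comparison correction). Positions with fewer than 2 values in
#' either group are not tested.
#'
#' @param group_a,group_b Matrices (rats x trials) of aligned per-rat
#'   series.
#' @param alpha Significance cutoff (default 0.01).
#' @return List with `p` (per-trial p values, NA where untestable) and
#'   `mask` (p < alpha, FALSE where untestable).
#' @export
trialwise_ranksum <- function(group_a, group_b, alpha = 0.01) {
  group_a <- as.matrix(group_a)
  group_b <- as.matrix(group_b)
  if (ncol(group_a) != ncol(group_b)) stop("groups must cover the same trials")
  nt <- ncol(group_a)
  p <- rep(NA_real_, nt)
  for (j in seq_len(nt)) {
    a <- group_a[, j][is.finite(group_a[, j])]
    b <- group_b[, j][is.finite(group_b[, j])]
    if (length(a) < 2 || length(b) < 2) next
    p[j] <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL)$p.value)
  }
  list(p = p, mask = !is.na(p) & p < alpha)
}

#' Kruskal-Wallis test across groups
#'
#' @param groups List of numeric vectors, one per group.
#' @return A `test_result` (chi-squared statistic).
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  kt <- stats::kruskal.test(groups)
  test_result(statistic = unname(kt$statistic), df = unname(kt$parameter),
              p = kt$p.value, method = "Kruskal-Wallis rank sum test")
}

#' Paired t test
#'
#' @param a,b Paired numeric vectors (NA pairs dropped).
#' @return A `test_result` with the mean difference as estimate.
#' @export
paired_t <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  tt <- stats::t.test(a[ok], b[ok], paired = TRUE)
  test_result(estimate = unname(tt$estimate), se = unname(tt$stderr),
              df = unname(tt$parameter), statistic = unname(tt$statistic),
              p = tt$p.value, method = "paired t-test")
}

#' Paired t tests within extent bins
#'
#' Compares two conditions bin by bin (e.g. laser-on vs retraining at each
#' final z_digit2 extent), pairing rats within each bin.
#'
#' @param a,b Matrices (rats x bins) of per-rat bin means for the two
#'   conditions.
#' @return Data frame with one row per bin: `bin`, `n`, `estimate`,
#'   `statistic`, `df`, `p` (NA where fewer than 2 complete pairs).
#' @export
paired_t_by_bin <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)))
  rows <- lapply(seq_len(ncol(a)), function(j) {
    ok <- is.finite(a[, j]) & is.finite(b[, j])
    if (sum(ok) < 2 || stats::sd(a[ok, j] - b[ok, j]) == 0) {
      return(data.frame(bin = j, n = sum(ok), estimate = NA_real_,
                        statistic = NA_real_, df = NA_real_, p = NA_real_))
    }
    tt <- paired_t(a[, j], b[, j])
    data.frame(bin = j, n = sum(ok), estimate = tt$estimate,
               statistic = tt$statistic, df = tt$df, p = tt$p)
  })
  do.call(rbind, rows)
}

#' Sign test for paired samples
#'
#' Exact binomial test on the signs of the paired differences; ties are
#' dropped. All-tied input is undefined and reported as such.
#'
#' @param a,b Paired numeric vectors.
#' @return A `test_result` (statistic = number of positive differences);
#'   p is NA with method noting "undefined" when every pair is tied.
#' @export
sign_test <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  d <- a[ok] - b[ok]
  d <- d[d != 0]
  if (!length(d)) {
    return(test_result(method = "sign test (undefined: all pairs tied)"))
  }
  bt <- stats::binom.test(sum(d > 0), length(d))
  test_result(estimate = unname(bt$estimate), statistic = sum(d > 0),
              df = length(d), p = bt$p.value, method = "sign test")
}
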