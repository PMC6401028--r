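# Univariate screening, normality-gated two-sample tests, GAM/GLM fitting
# and model comparison.

shapiro_p_safe <- function(x) {
  # A constant sample has no defensible normality claim; treat as failing
  # the gate so the distribution-free path is taken.
  if (length(unique(x)) < 2L) return(0)
  shapiro.test(x)$p.value
}

#' Two-sample test with a Shapiro-Wilk normality gate
#'
#' Runs a Shapiro-Wilk test on each sample; if both pass at `gate_alpha`,
#' the difference in means is tested with Welch's t-test (two-sided).
#' Otherwise a permutation test on the difference in group means is used:
#' exact enumeration of all assignments when there are at most `max_exact`
#' arrangements, Monte Carlo otherwise with
#' p = (1 + #\{|d*| >= |d_obs|\}) / (1 + B).
#'
#' @param x,y Numeric samples, each of length >= 3.
#' @param method `"auto"` (default) applies the normality gate;
#'   `"welch_t"` or `"permutation"` forces the corresponding test.
#' @param gate_alpha Normality-gate significance level (default 0.05).
#' @param B Number of Monte Carlo permutations (default 9999).
#' @param max_exact Largest number of arrangements enumerated exhaustively
#'   (default 1e5).
#' @param seed Optional integer seed for the Monte Carlo draw.
#' @return List with `method` ("welch_t" or "permutation"), `statistic`
#'   (t statistic or observed mean difference), `p_value`, `n1`, `n2`,
#'   `shapiro_p` (length-2), and `exact` (logical, permutation path only).
#' @export
two_sample_test <- function(x, y, method = c("auto", "welch_t",
                                             "permutation"),
                            gate_alpha = 0.05, B = 9999,
                            max_exact = 1e5, seed = NULL) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 3L || length(y) < 3L) {
    stop_rp("each sample needs >= 3 observations")
  }
  sw <- c(shapiro_p_safe(x), shapiro_p_safe(y))
  use_welch <- switch(method, auto = all(sw >= gate_alpha),
                      welch_t = TRUE, permutation = FALSE)
  if (use_welch) {
    tt <- t.test(x, y)
    return(list(method = "welch_t", statistic = unname(tt$statistic),
                p_value = tt$p.value, n1 = length(x), n2 = length(y),
                shapiro_p = sw))
  }
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  d_obs <- mean(x) - mean(y)
  eps <- 1e-12 * max(1, abs(d_obs))
  if (choose(n, n1) <= max_exact) {
    idx <- combn(n, n1)
    d_perm <- apply(idx, 2L, function(i) {
      mean(pooled[i]) - mean(pooled[-i])
    })
    p <- mean(abs(d_perm) >= abs(d_obs) - eps)
    exact <- TRUE
  } else {
    if (!is.null(seed)) set.seed(seed)
    d_perm <- replicate(B, {
      i <- sample.int(n, n1)
      mean(pooled[i]) - mean(pooled[-i])
    })
    p <- (1 + sum(abs(d_perm) >= abs(d_obs) - eps)) / (1 + B)
    exact <- FALSE
  }
  list(method = "permutation", statistic = d_obs, p_value = p,
       n1 = n1, n2 = length(y), shapiro_p = sw, exact = exact)
}

#' Bonferroni-screened univariate regressions
#'
#' Regresses the response on each candidate predictor separately by
#' ordinary least squares and reports a signed correlation of fit
#' (R carries the slope's sign), the root-mean-square residual, the raw
#' slope p-value, and Bonferroni-corrected significance flags at
#' alpha / m for alpha in \{0.01, 0.05, 0.10\}.
#'
#' @param response Numeric response vector.
#' @param predictors Data.frame of candidate predictors (numeric columns),
#'   rows aligned with `response`.
#' @param family_size Bonferroni family size m; defaults to the number of
#'   predictors screened.
#' @param min_cases Minimum complete cases per predictor (default 4).
#' @return A data.frame with one row per predictor: `predictor, n, R, RMSE,
#'   p_raw, sig_raw_05, sig_bonf_01, sig_bonf_05, sig_bonf_10, degenerate`;
#'   the family size used is stored in attribute `family_size`.
#' @export
univariate_screen <- function(response, predictors, family_size = NULL,
                              min_cases = 4L) {
  stopifnot(is.data.frame(predictors))
  m <- family_size %||% ncol(predictors)
  rows <- lapply(names(predictors), function(v) {
    xi <- as.numeric(predictors[[v]])
    ok <- !is.na(xi) & !is.na(response)
    if (sum(ok) < min_cases) {
      stop_rp("predictor %s has %d complete cases (< %d)", v, sum(ok),
              min_cases)
    }
    if (length(unique(xi[ok])) < 2L) {
      return(data.frame(predictor = v, n = sum(ok), R = 0, RMSE = NA_real_,
                        p_raw = NA_real_, sig_raw_05 = FALSE,
                        sig_bonf_01 = FALSE, sig_bonf_05 = FALSE,
                        sig_bonf_10 = FALSE, degenerate = TRUE))
    }
    fit <- lm(response[ok] ~ xi[ok])
    sm <- summary(fit)
    slope <- coef(fit)[2]
    r_signed <- sign(slope) * sqrt(sm$r.squared)
    p <- sm$coefficients[2, 4]
    data.frame(predictor = v, n = sum(ok), R = unname(r_signed),
               RMSE = sqrt(mean(sm$residuals^2)), p_raw = unname(p),
               sig_raw_05 = p < 0.05,
               sig_bonf_01 = p < 0.01 / m,
               sig_bonf_05 = p < 0.05 / m,
               sig_bonf_10 = p < 0.10 / m,
               degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "family_size") <- m
  out
}

#' Second-order Akaike Information Criterion
#'
#' AICc = -2 log L + 2k + 2k(k + 1) / (n - k - 1), with k the number of
#' effective parameters (for penalized fits, the effective degrees of
#' freedom of the likelihood, scale parameter included).
#'
#' @param fit A fitted model with `logLik` and `nobs` methods, or `NULL`
#'   when `loglik`, `k`, `n` are given directly.
#' @param loglik,k,n Optional explicit log-likelihood, parameter count and
#'   sample size (override extraction from `fit`).
#' @return The AICc value (infinite when n <= k + 1).
#' @export
aicc <- function(fit = NULL, loglik = NULL, k = NULL, n = NULL) {
  if (!is.null(fit)) {
    ll <- logLik(fit)
    loglik <- loglik %||% as.numeric(ll)
    k <- k %||% attr(ll, "df")
    n <- n %||% stats::nobs(fit)
  }
  if (n <= k + 1) return(Inf)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a GAM/GLM response model with shrinkage splines
#'
#' Builds and fits a generalized additive model in which each smooth term
#' is a penalized cubic regression spline with shrinkage (basis dimension
#' `k` = 3 by default, so smooths can be shrunk out of the model entirely),
#' optionally combined with linear terms and one pairwise linear
#' interaction. With no smooth terms the fit is an ordinary GLM.
#'
#' @param data Data.frame holding the response and predictors.
#' @param response Name of the response column.
#' @param smooth Character vector of predictors entering as smooths.
#' @param linear Character vector of predictors entering linearly.
#' @param interaction Optional length-2 character vector naming a pairwise
#'   product term, e.g. `c("PAR", "fDHW4")` (the two main effects are added
#'   as linear terms if not already present).
#' @param family A `family` object (default `gaussian()`).
#' @param basis Smooth basis: `"cs"` cubic shrinkage spline (default) or
#'   `"ts"` thin-plate with shrinkage.
#' @param k Basis dimension per smooth (default 3).
#' @param method Smoothness-selection criterion passed to [mgcv::gam()]:
#'   `"REML"` (default; stable at small sample sizes) or `"GCV.Cp"`. The
#'   generalized cross-validation score is reported either way.
#' @return An object of class `rp_model_fit`: the mgcv fit plus a summary
#'   with `r2_adj`, `deviance_explained`, `GCV`, `AICc`, `edf` per smooth,
#'   and `effect_direction` (sign of the partial effect's association with
#'   each predictor).
#' @export
fit_response_model <- function(data, response, smooth = character(),
                               linear = character(), interaction = NULL,
                               family = gaussian(), basis = c("cs", "ts"),
                               k = 3, method = c("REML", "GCV.Cp")) {
  basis <- match.arg(basis)
  method <- match.arg(method)
  vars <- c(smooth, linear, interaction)
  assert_cols(data, c(response, vars), "model table")
  # a smooth needs more unique covariate values than basis functions;
  # coarse covariates (e.g. frequencies over few baseline years) fall back
  # to a linear term
  demote <- vapply(smooth, function(v) {
    length(unique(data[[v]][!is.na(data[[v]])])) <= k
  }, logical(1))
  if (any(demote)) {
    linear <- c(linear, smooth[demote])
    smooth <- smooth[!demote]
  }
  terms <- c(
    sprintf("s(%s, bs = \"%s\", k = %d)", smooth, basis, k),
    linear,
    if (!is.null(interaction)) {
      stopifnot(length(interaction) == 2L)
      c(setdiff(interaction, c(smooth, linear)),
        paste(interaction, collapse = ":"))
    })
  if (!length(terms)) stop_rp("model has no terms")
  fml <- stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
  n <- sum(stats::complete.cases(data[c(response, vars)]))
  fit <- mgcv::gam(fml, data = data, family = family, method = method)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop_rp("rank-deficient model; collinear term(s): %s",
            paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  edf <- if (length(smooth)) setNames(sm$edf, smooth) else numeric()

  # direction of each term's partial effect, for sign-recovery diagnostics
  term_mat <- predict(fit, type = "terms")
  direction <- vapply(vars[vars %in% c(smooth, linear)], function(v) {
    col <- grep(paste0("(^|\\()", v, "(\\)|$)"), colnames(term_mat))
    if (length(col) != 1L) return(NA_real_)
    contrib <- term_mat[, col]
    # a smooth shrunk to (numerically) nothing has no direction
    if (sd(contrib) < 1e-8 * max(sd(fit$y), 1e-8)) return(0)
    sign(cor(contrib, fit$model[[v]]))
  }, numeric(1))

  structure(list(
    fit = fit, formula = fml, response = response, n = n,
    terms = list(smooth = smooth, linear = linear,
                 interaction = interaction),
    r2_adj = sm$r.sq, deviance_explained = sm$dev.expl,
    GCV = length(fit$y) * stats::deviance(fit) /
      (length(fit$y) - sum(fit$edf))^2,
    AICc = aicc(fit), edf = edf,
    effect_direction = direction), class = "rp_model_fit")
}

#' @export
print.rp_model_fit <- function(x, ...) {
  cat(sprintf("<rp_model_fit> %s\n", deparse(x$formula)))
  cat(sprintf("  n = %d | adj r2 = %.3f | deviance explained = %.1f%% | AICc = %.2f\n",
              x$n, x$r2_adj, 100 * x$deviance_explained, x$AICc))
  invisible(x)
}

#' Rank candidate models and compare nested pairs by analysis of deviance
#'
#' @param fits Named list of `rp_model_fit` objects sharing the same
#'   response data.
#' @param nested_pairs Optional list of length-2 character vectors
#'   `c(reduced, full)` naming nested models in `fits`; each pair gets an
#'   F-test on the deviance drop against the full model's residual
#'   deviance. A non-positive deviance drop reports F = 0, p = 1.
#' @return List with `ranking` (data.frame model, AICc, delta_AICc,
#'   deviance_explained, r2_adj, sorted by AICc) and `anova` (data.frame of
#'   the nested F-tests, or `NULL`).
#' @export
compare_models <- function(fits, nested_pairs = NULL) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "rp_model_fit")))
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  aic <- vapply(fits, `[[`, numeric(1), "AICc")
  ranking <- data.frame(
    model = names(fits), AICc = aic, delta_AICc = aic - min(aic),
    deviance_explained = vapply(fits, `[[`, numeric(1),
                                "deviance_explained"),
    r2_adj = vapply(fits, `[[`, numeric(1), "r2_adj"), row.names = NULL)
  ranking <- ranking[order(ranking$AICc), , drop = FALSE]
  rownames(ranking) <- NULL

  anova_tab <- NULL
  if (!is.null(nested_pairs)) {
    rows <- lapply(nested_pairs, function(pair) {
      red <- fits[[pair[1]]]$fit; full <- fits[[pair[2]]]$fit
      d_red <- stats::deviance(red); d_full <- stats::deviance(full)
      df_red <- red$df.residual; df_full <- full$df.residual
      df_diff <- df_red - df_full
      if (d_red - d_full <= 0 || df_diff <= 0) {
        f <- 0; p <- 1
      } else {
        f <- ((d_red - d_full) / df_diff) / (d_full / df_full)
        p <- pf(f, df_diff, df_full, lower.tail = FALSE)
      }
      data.frame(reduced = pair[1], full = pair[2],
                 deviance_drop = d_red - d_full, df = df_diff,
                 F = f, p_value = p)
    })
    anova_tab <- do.call(rbind, rows)
    rownames(anova_tab) <- NULL
  }
  list(ranking = ranking, anova = anova_tab)
}
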