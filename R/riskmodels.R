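#' Build a matched-pair frame from an exposure and a sample sheet
#'
#' Joins a per-sample exposure onto the pair structure of the sample
#' sheet, giving one row per pair with case and control exposure, ages,
#' and stratum variables (time to diagnosis from the case; any extra
#' columns requested).
#'
#' @param exposure Named per-sample exposure vector.
#' @param sheet Validated sample sheet.
#' @param extra Extra sheet columns to carry over (taken from the case
#'   member).
#' @return A `matched_pair_frame` data.frame.
#' @export
make_matched_pairs <- function(exposure, sheet, extra = character()) {
  sheet <- sheet[sheet$sample_id %in% names(exposure), , drop = FALSE]
  sheet <- validate_sample_sheet(sheet)
  cases <- sheet[sheet$status == "case", , drop = FALSE]
  ctrls <- sheet[sheet$status == "control", , drop = FALSE]
  ctrls <- ctrls[match(cases$pair_id, ctrls$pair_id), , drop = FALSE]
  out <- data.frame(pair_id = cases$pair_id,
                    case_exposure = unname(exposure[cases$sample_id]),
                    control_exposure = unname(exposure[ctrls$sample_id]),
                    case_age = cases$age_at_draw,
                    control_age = ctrls$age_at_draw)
  if ("time_to_diagnosis" %in% names(sheet)) {
    out$time_to_diagnosis <- cases$time_to_diagnosis
  }
  for (col in extra) out[[col]] <- cases[[col]]
  if (any(!is.finite(out$case_exposure)) || any(!is.finite(out$control_exposure))) {
    stop("non-finite exposures in matched pairs")
  }
  class(out) <- c("matched_pair_frame", "data.frame")
  out
}

# Newton-Raphson maximiser of the 1:1 conditional logistic likelihood.
# D: matrix of within-pair (case - control) differences, one row per pair.
clogit_diff_fit <- function(D, tol = 1e-8, max_iter = 50L) {
  D <- as.matrix(D)
  beta <- numeric(ncol(D))
  for (it in seq_len(max_iter)) {
    eta <- drop(D %*% beta)
    p <- stats::plogis(eta)
    grad <- drop(crossprod(D, 1 - p))
    W <- p * (1 - p)
    H <- crossprod(D * W, D)
    if (sqrt(sum(grad^2)) < tol) break
    step <- tryCatch(solve(H, grad), error = function(e) {
      stop("singular information matrix in conditional logistic fit")
    })
    beta <- beta + step
    if (any(abs(beta) > 1e3)) {
      stop("conditional logistic fit diverged (separation or near-separation)")
    }
  }
  eta <- drop(D %*% beta)
  loglik <- sum(eta - log1p(exp(eta)))
  vcov <- solve(crossprod(D * (stats::plogis(eta) * (1 - stats::plogis(eta))), D))
  list(coef = beta, vcov = vcov, loglik = loglik, iterations = it)
}

new_effect_estimate <- function(coef, se, n_pairs, n_informative,
                                label = "exposure") {
  coef <- unname(coef)
  se <- unname(se)
  z <- coef / se
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  structure(list(label = label, coef = coef, se = se, or = exp(coef),
                 ci_lower = exp(coef - 1.959964 * se),
                 ci_upper = exp(coef + 1.959964 * se),
                 p_value = p, n_pairs = n_pairs,
                 n_informative = n_informative),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s: OR %.3f (95%% CI %.3f-%.3f), p = %.3g [%d pairs, %d informative]\n",
              x$label, x$or, x$ci_lower, x$ci_upper, x$p_value,
              x$n_pairs, x$n_informative))
  invisible(x)
}

#' Conditional logistic regression for 1:1 matched pairs
#'
#' Maximises the pairwise conditional likelihood, which for 1:1 matching
#' is a no-intercept binary logistic model on within-pair (case - control)
#' differences with the outcome fixed at 1. Age adjustment (the default)
#' enters as the within-pair age difference. Complete separation of the
#' informative exposure differences is detected before optimisation and
#' raised as an error rather than returned as a huge finite estimate.
#'
#' @param pairs A `matched_pair_frame`.
#' @param adjust_age Include the within-pair age difference as covariate.
#' @return An `effect_estimate` for the exposure (per unit of exposure).
#' @export
clogit_pairs <- function(pairs, adjust_age = TRUE) {
  d <- pairs$case_exposure - pairs$control_exposure
  informative <- d != 0
  n_inf <- sum(informative)
  if (nrow(pairs) == 0L) stop("no pairs")
  if (n_inf == 0L) {
    est <- new_effect_estimate(0, Inf, nrow(pairs), 0L)
    est$degenerate <- TRUE
    return(est)
  }
  if (all(d[informative] > 0) || all(d[informative] < 0)) {
    stop("complete separation: all informative exposure differences have one sign")
  }
  D <- cbind(exposure = d)
  if (adjust_age) D <- cbind(D, age = pairs$case_age - pairs$control_age)
  fit <- clogit_diff_fit(D)
  est <- new_effect_estimate(fit$coef[1L], sqrt(fit$vcov[1L, 1L]),
                             nrow(pairs), n_inf)
  est$fit <- fit
  est
}

#' Quartile odds ratios versus Q1
#'
#' Conditional logistic regression with indicator contrasts for quartiles
#' 2-4 (within-pair indicator differences); Q1 is the reference with OR
#' fixed at 1.
#'
#' @param pairs A `matched_pair_frame`.
#' @param labels Named quartile labels per sample (factor Q1..Q4).
#' @param sheet Sample sheet mapping samples to pairs.
#' @param adjust_age Adjust for within-pair age difference.
#' @return data.frame with one row per quartile: `or`, `ci_lower`,
#'   `ci_upper`, `p_value`, case/control counts.
#' @export
or_by_quartile <- function(pairs, labels, sheet, adjust_age = TRUE) {
  sheet <- sheet[sheet$sample_id %in% names(labels), , drop = FALSE]
  cases <- sheet[sheet$status == "case", ]
  ctrls <- sheet[sheet$status == "control", ]
  ctrls <- ctrls[match(cases$pair_id, ctrls$pair_id), ]
  lc <- labels[cases$sample_id]
  l0 <- labels[ctrls$sample_id]
  counts <- data.frame(quartile = paste0("Q", 1:4),
                       n_cases = as.integer(table(factor(lc, paste0("Q", 1:4)))),
                       n_controls = as.integer(table(factor(l0, paste0("Q", 1:4)))))
  if (any(counts$n_cases + counts$n_controls == 0L)) {
    stop("empty quartile among cases + controls")
  }
  D <- sapply(paste0("Q", 2:4), function(q) (lc == q) - (l0 == q))
  if (adjust_age) {
    D <- cbind(D, age = cases$age_at_draw - ctrls$age_at_draw)
  }
  fit <- clogit_diff_fit(D)
  se <- sqrt(diag(fit$vcov))
  out <- counts
  out$or <- c(1, exp(fit$coef[1:3]))
  out$ci_lower <- c(NA, exp(fit$coef[1:3] - 1.959964 * se[1:3]))
  out$ci_upper <- c(NA, exp(fit$coef[1:3] + 1.959964 * se[1:3]))
  z <- fit$coef[1:3] / se[1:3]
  out$p_value <- c(NA, 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  out
}

#' Robust (cluster-sandwich) logistic regression confirmation
#'
#' Unconditional logistic regression of case status on the exposure (and
#' age), with a pair-clustered sandwich covariance. Used as a confirmation
#' analysis alongside the conditional model.
#'
#' @param exposure Named per-sample exposure.
#' @param sheet Sample sheet.
#' @param adjust_age Include age at draw.
#' @return An `effect_estimate` (sandwich SE); the model-based SE is kept
#'   in `$model_se`.
#' @export
robust_logistic <- function(exposure, sheet, adjust_age = TRUE) {
  sheet <- sheet[sheet$sample_id %in% names(exposure), , drop = FALSE]
  df <- data.frame(y = as.integer(sheet$status == "case"),
                   x = unname(exposure[sheet$sample_id]),
                   age = sheet$age_at_draw, pair = sheet$pair_id)
  fml <- if (adjust_age) y ~ x + age else y ~ x
  fit <- stats::glm(fml, family = stats::binomial(), data = df)
  vc <- sandwich::vcovCL(fit, cluster = df$pair)
  est <- new_effect_estimate(stats::coef(fit)[["x"]], sqrt(vc["x", "x"]),
                             nrow(df) / 2L, nrow(df) / 2L)
  est$model_se <- sqrt(stats::vcov(fit)["x", "x"])
  est
}

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank test on within-pair differences: zero differences are
#' dropped, ties take mid-ranks; the exact null distribution is used for
#' n <= `exact_limit` tie-free differences, otherwise the normal
#' approximation with continuity and tie correction.
#'
#' @param case_values,control_values Paired value vectors.
#' @param exact_limit Largest n for the exact null (default 25).
#' @param ... Passed to [stats::wilcox.test()] (e.g. `alternative`).
#' @return List with `statistic` (V), `p_value`, `n_used`.
#' @export
paired_wilcoxon <- function(case_values, control_values, exact_limit = 25L,
                            ...) {
  stopifnot(length(case_values) == length(control_values))
  d <- case_values - control_values
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) == 0L) stop("all within-pair differences are zero")
  exact <- length(nz) <= exact_limit && !any(duplicated(abs(nz)))
  ht <- suppressWarnings(stats::wilcox.test(case_values, control_values,
                                            paired = TRUE, exact = exact,
                                            correct = TRUE, ...))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_used = length(nz), exact = exact)
}

#' Individual risk distribution from a spline conditional model
#'
#' Fits the conditional logistic model on a cubic B-spline basis of the
#' continuous exposure, evaluates each subject's fitted log relative risk,
#' centres the population (mean or median log-RR = 0), and summarises the
#' implied RR distribution.
#'
#' @param exposure Named per-sample continuous exposure.
#' @param sheet Sample sheet.
#' @param df Spline degrees of freedom (>= 3, default 4); interior knots
#'   at exposure quantiles.
#' @param center `"mean"` (default) or `"median"` subject as reference.
#' @return List with `log_rr` (named per subject), `rr_median`,
#'   `rr_lower`, `rr_upper` (2.5/97.5 percentiles), `fit`.
#' @export
spline_risk_distribution <- function(exposure, sheet, df = 4L,
                                     center = c("mean", "median")) {
  center <- match.arg(center)
  stopifnot(df >= 3L)
  if (stats::sd(exposure) == 0) stop("exposure has zero variance")
  if (length(unique(exposure)) <= df) {
    stop("too few distinct exposure values for knot placement")
  }
  basis <- splines::bs(exposure, df = df)
  rownames(basis) <- names(exposure)
  sheet <- sheet[sheet$sample_id %in% names(exposure), , drop = FALSE]
  cases <- sheet[sheet$status == "case", ]
  ctrls <- sheet[sheet$status == "control", ]
  ctrls <- ctrls[match(cases$pair_id, ctrls$pair_id), ]
  D <- basis[cases$sample_id, , drop = FALSE] -
    basis[ctrls$sample_id, , drop = FALSE]
  fit <- clogit_diff_fit(D)
  lp <- drop(basis %*% fit$coef)
  ref <- if (center == "mean") mean(lp) else stats::median(lp)
  log_rr <- lp - ref
  names(log_rr) <- names(exposure)
  qs <- stats::quantile(exp(log_rr), c(0.025, 0.5, 0.975), names = FALSE)
  list(log_rr = log_rr, rr_lower = qs[1L], rr_median = qs[2L],
       rr_upper = qs[3L], fit = fit)
}

#' ROC area under the curve with DeLong confidence interval
#'
#' AUC is the Mann-Whitney concordance P(score_case > score_control) with
#' ties counted half; the 95% CI uses the DeLong variance.
#'
#' @param scores Numeric classification scores.
#' @param status Case/control status (factor or character).
#' @return List with `auc`, `ci_lower`, `ci_upper`.
#' @export
roc_auc <- function(scores, status) {
  status <- as.character(status)
  if (!all(status %in% c("case", "control")) ||
      length(unique(status)) < 2L) {
    stop("status must contain both 'case' and 'control'")
  }
  r <- pROC::roc(response = status, predictor = scores,
                 levels = c("control", "case"), direction = "<",
                 quiet = TRUE)
  ci <- pROC::ci.auc(r, method = "delong")
  list(auc = as.numeric(pROC::auc(r)), ci_lower = ci[1L], ci_upper = ci[3L])
}

#' Stratified conditional analysis with heterogeneity test
#'
#' Fits the conditional logistic model separately within strata of the
#' pairs (e.g. time to diagnosis above/below a split point, or tumour ER
#' status) and tests homogeneity of the stratum log odds ratios with
#' Cochran's Q on (strata - 1) degrees of freedom.
#'
#' @param pairs A `matched_pair_frame`.
#' @param stratum Per-pair stratum labels (aligned with `pairs`).
#' @param adjust_age Adjust for within-pair age difference.
#' @return List with `estimates` (data.frame per stratum), `Q`, `df`,
#'   `p_het`.
#' @export
stratified_analysis <- function(pairs, stratum, adjust_age = TRUE) {
  stopifnot(length(stratum) == nrow(pairs))
  stratum <- as.factor(stratum)
  if (nlevels(stratum) < 2L) stop("need >= 2 strata")
  ests <- lapply(levels(stratum), function(s) {
    clogit_pairs(pairs[stratum == s, , drop = FALSE], adjust_age = adjust_age)
  })
  logor <- vapply(ests, `[[`, numeric(1), "coef")
  se <- vapply(ests, `[[`, numeric(1), "se")
  het <- cochran_q(logor, se)
  list(estimates = data.frame(stratum = levels(stratum), logor = logor,
                              se = se, or = exp(logor),
                              n_pairs = as.integer(table(stratum))),
       Q = het$Q, df = het$df, p_het = het$p)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' @param case_values,control_values Value vectors for the two groups.
#' @return List with `D` (sup ECDF difference) and `p_value` (asymptotic).
#' @export
ks_compare <- function(case_values, control_values) {
  if (length(case_values) == 0L || length(control_values) == 0L) {
    stop("both groups must be nonempty")
  }
  ht <- suppressWarnings(stats::ks.test(case_values, control_values,
                                        exact = FALSE))
  list(D = unname(ht$statistic), p_value = ht$p.value)
}
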