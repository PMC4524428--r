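#' One study's effect record for meta-analysis
#'
#' @param label Study label.
#' @param or Per-1-SD odds ratio.
#' @param l95,u95 95% confidence limits (0 < l95 <= or <= u95).
#' @param n_cases,n_controls Subject counts.
#' @return A `study_effect` list.
#' @export
study_effect <- function(label, or, l95, u95, n_cases = NA_integer_,
                         n_controls = NA_integer_) {
  if (!(l95 > 0 && l95 <= or && or <= u95)) {
    stop("study '", label, "': need 0 < l95 <= OR <= u95")
  }
  structure(list(label = label, or = or, l95 = l95, u95 = u95,
                 n_cases = n_cases, n_controls = n_controls),
            class = "study_effect")
}

#' Recover log-OR and its SE from a printed confidence interval
#'
#' log-OR = ln(OR); SE = (ln(u95) - ln(l95)) / (2 * 1.959964). A
#' zero-width interval is flagged degenerate (SE 0).
#'
#' @param effect A `study_effect`, or an OR when `l95`/`u95` are given.
#' @param l95,u95 Confidence limits when `effect` is a bare OR.
#' @return List with `logor`, `se`, `degenerate`.
#' @export
ci_to_se <- function(effect, l95 = NULL, u95 = NULL) {
  if (inherits(effect, "study_effect")) {
    or <- effect$or; l95 <- effect$l95; u95 <- effect$u95
  } else {
    or <- effect
    if (is.null(l95) || is.null(u95)) stop("need l95 and u95")
    if (!(l95 > 0 && l95 <= or && or <= u95)) {
      stop("need 0 < l95 <= OR <= u95")
    }
  }
  se <- (log(u95) - log(l95)) / (2 * 1.959964)
  list(logor = log(or), se = se, degenerate = se == 0)
}

#' Cochran's Q heterogeneity test
#'
#' Inverse-variance weights; Q = sum w_i (theta_i - theta_FE)^2, referred
#' to chi-square with k - 1 degrees of freedom.
#'
#' @param logor Study log odds ratios (>= 2).
#' @param se Their standard errors (> 0).
#' @return List with `Q`, `df`, `p`, `fixed` (the fixed-effect summary
#'   log-OR).
#' @export
cochran_q <- function(logor, se) {
  if (length(logor) < 2L) stop("need >= 2 studies")
  stopifnot(length(se) == length(logor), all(se > 0))
  w <- 1 / se^2
  fe <- sum(w * logor) / sum(w)
  Q <- sum(w * (logor - fe)^2)
  df <- length(logor) - 1L
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE),
       fixed = fe)
}

#' DerSimonian-Laird random-effects summary
#'
#' tau^2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w)) with
#' inverse-variance w; random-effects weights 1/(se^2 + tau^2).
#'
#' @param logor Study log odds ratios (>= 2).
#' @param se Their standard errors.
#' @return List with `tau2`, `logor` (summary), `se`, `ci_lower`,
#'   `ci_upper` (on the OR scale), `or`, and the fixed-effect summary
#'   (`fixed_logor`, `fixed_se`).
#' @export
dersimonian_laird <- function(logor, se) {
  het <- cochran_q(logor, se)
  w <- 1 / se^2
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (het$Q - het$df) / denom)
  wr <- 1 / (se^2 + tau2)
  summ <- sum(wr * logor) / sum(wr)
  sse <- sqrt(1 / sum(wr))
  list(tau2 = tau2, logor = summ, se = sse, or = exp(summ),
       ci_lower = exp(summ - 1.959964 * sse),
       ci_upper = exp(summ + 1.959964 * sse),
       fixed_logor = het$fixed, fixed_se = sqrt(1 / sum(w)),
       Q = het$Q, p_het = het$p)
}

#' Forest-plot table for a set of studies
#'
#' One row per study plus a random-effects summary row, with the study
#' sizes carried through; the numeric columns round-trip through CSV.
#'
#' @param effects List of `study_effect` objects.
#' @return data.frame with columns `label`, `or`, `l95`, `u95`,
#'   `n_cases`, `n_controls`, `weight_pct` (random-effects weights) and a
#'   final `summary` row; heterogeneity Q/p in attributes.
#' @export
forest_table <- function(effects) {
  stopifnot(length(effects) >= 2L)
  parts <- lapply(effects, ci_to_se)
  logor <- vapply(parts, `[[`, numeric(1), "logor")
  se <- vapply(parts, `[[`, numeric(1), "se")
  dl <- dersimonian_laird(logor, se)
  wr <- 1 / (se^2 + dl$tau2)
  tab <- data.frame(
    label = vapply(effects, `[[`, character(1), "label"),
    or = vapply(effects, `[[`, numeric(1), "or"),
    l95 = vapply(effects, `[[`, numeric(1), "l95"),
    u95 = vapply(effects, `[[`, numeric(1), "u95"),
    n_cases = vapply(effects, function(e) as.integer(e$n_cases), integer(1)),
    n_controls = vapply(effects, function(e) as.integer(e$n_controls),
                        integer(1)),
    weight_pct = 100 * wr / sum(wr))
  tab <- rbind(tab, data.frame(label = "summary (random effects)",
                               or = dl$or, l95 = dl$ci_lower,
                               u95 = dl$ci_upper, n_cases = sum(tab$n_cases),
                               n_controls = sum(tab$n_controls),
                               weight_pct = 100))
  attr(tab, "Q") <- dl$Q
  attr(tab, "p_het") <- dl$p_het
  attr(tab, "tau2") <- dl$tau2
  tab
}
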