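# Beta-regression fit (logit mean link, constant precision) by alternating
# Fisher scoring on the mean coefficients and Newton steps on log(phi).
# Lean on purpose: it is called once per probe in genome-wide scans.
betareg_fit <- function(y, X, tol = 1e-8, max_iter = 100L) {
  n <- length(y)
  ystar <- log(y / (1 - y))
  l1y <- log(1 - y)
  # moment start
  beta <- tryCatch(qr.coef(qr(X), ystar), error = function(e) numeric(ncol(X)))
  beta[is.na(beta)] <- 0
  mu <- stats::plogis(drop(X %*% beta))
  v <- stats::var(y - mu) # residual variance on the beta scale
  phi <- max(mean(mu * (1 - mu)) / max(v, 1e-10) - 1, 1)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- stats::plogis(drop(X %*% beta))
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    a <- mu * phi
    b <- phi - a
    mustar <- digamma(a) - digamma(b)
    dmude <- mu * (1 - mu)
    u <- ystar - mustar
    g_beta <- drop(crossprod(X, phi * u * dmude))
    g_phi <- sum(mu * u + l1y - digamma(b)) + n * digamma(phi)
    if (sqrt(sum(g_beta^2) + (phi * g_phi)^2) < tol) {
      converged <- TRUE
      break
    }
    t_a <- trigamma(a)
    t_b <- trigamma(b)
    w <- phi * (t_a + t_b) * dmude^2
    H <- phi * crossprod(X * w, X)
    beta <- beta + tryCatch(solve(H, g_beta), error = function(e) {
      stop("singular information in beta regression")
    })
    i_phi <- sum(mu^2 * t_a + (1 - mu)^2 * t_b) - n * trigamma(phi)
    # Newton on log(phi), guarded step
    step <- (phi * g_phi) / max(phi^2 * i_phi, 1e-10)
    step <- max(min(step, 2), -2)
    phi <- phi * exp(step)
    phi <- min(max(phi, 1e-3), 1e8)
  }
  if (!converged) stop("beta regression did not converge")
  mu <- stats::plogis(drop(X %*% beta))
  ll <- sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
              (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * l1y)
  list(coef = beta, phi = phi, fitted = mu, loglik = ll, iterations = it)
}

#' Technical adjustment of one probe by beta regression
#'
#' Fits a maximum-likelihood beta regression (logit mean link, constant
#' precision) of the probe's beta values on technical covariates (chip,
#' position on chip) and returns response residuals (observed - fitted
#' mean), which carry the biological signal into the second-stage
#' incidence model.
#'
#' @param beta_vec Beta values for one probe (clamped into
#'   \[1e-6, 1-1e-6\] before likelihood evaluation).
#' @param covariates data.frame of technical covariates (factors or
#'   numerics); `NULL` fits an intercept-only model.
#' @return Numeric residual vector with attributes `fit` (coefficients,
#'   phi, loglik).
#' @export
beta_glm_residuals <- function(beta_vec, covariates = NULL) {
  y <- pmin(pmax(beta_vec, 1e-6), 1 - 1e-6)
  if (is.null(covariates)) {
    X <- matrix(1, length(y), 1L)
  } else {
    covariates <- as.data.frame(covariates)
    for (j in seq_along(covariates)) {
      cj <- covariates[[j]]
      if (!is.numeric(cj) && length(unique(cj)) < 2L) {
        stop("technical covariate '", names(covariates)[j],
             "' has fewer than 2 levels")
      }
    }
    X <- stats::model.matrix(~ ., data = covariates)
  }
  fit <- betareg_fit(y, X)
  res <- y - fit$fitted
  attr(res, "fit") <- fit[c("coef", "phi", "loglik", "iterations")]
  res
}

#' Incidence association via a Poisson model with person-years offset
#'
#' Poisson GLM (log link) of the case indicator on the residual
#' methylation and age, with log person-years of follow-up as offset; the
#' Wald test of the methylation coefficient approximates the Cox
#' log-hazard-ratio test for rare events.
#'
#' @param residuals Stage-1 residual methylation per subject.
#' @param event 0/1 case indicator.
#' @param person_years Positive follow-up time per subject.
#' @param age Optional age at draw (included as covariate when given).
#' @return List with `coef`, `se`, `p_value`, `fit` (glm.fit output
#'   pieces).
#' @export
poisson_offset_assoc <- function(residuals, event, person_years, age = NULL) {
  if (any(person_years <= 0)) stop("person_years must be positive")
  if (sum(event) == 0L) stop("no events")
  X <- cbind(`(Intercept)` = 1, meth = residuals)
  if (!is.null(age)) X <- cbind(X, age = age)
  off <- log(person_years)
  # IRLS for the log-link Poisson likelihood (lean: called genome-wide)
  beta <- c(log(sum(event) / sum(person_years)), numeric(ncol(X) - 1L))
  dev_old <- Inf
  converged <- FALSE
  for (it in 1:50) {
    eta <- drop(X %*% beta) + off
    mu <- exp(eta)
    z <- eta - off + (event - mu) / mu
    XtW <- t(X * mu)
    beta <- tryCatch(solve(XtW %*% X, XtW %*% z)[, 1L],
                     error = function(e) stop("singular Poisson fit"))
    dev <- -2 * sum(event * (drop(X %*% beta) + off) -
                      exp(drop(X %*% beta) + off))
    if (is.finite(dev) && abs(dev - dev_old) < 1e-10 * (abs(dev) + 0.1)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  mu <- exp(drop(X %*% beta) + off)
  vcov <- solve(crossprod(X * mu, X))
  se <- sqrt(vcov["meth", "meth"])
  coef <- beta[["meth"]]
  zstat <- coef / se
  list(coef = coef, se = se,
       p_value = 2 * stats::pnorm(abs(zstat), lower.tail = FALSE),
       converged = converged, coefficients = beta)
}

#' Bonferroni-corrected significance threshold
#'
#' @param n_tests Number of tests (>= 1).
#' @param alpha Family-wise error rate (default 0.05).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1, alpha > 0, alpha < 1)
  alpha / n_tests
}

#' Two-stage probe-wise association scan
#'
#' For each probe: (1) technical adjustment by beta regression on the
#' given covariates, (2) Poisson person-years-offset model of case status
#' on the stage-1 residuals, age-adjusted. Probes with
#' p < alpha / n_probes are flagged; a per-direction tally (hypo- vs
#' hypermethylated in cases) is reported. Per-probe failures are caught,
#' logged and returned as `NA` rows; the scan continues.
#'
#' @param m Beta matrix (preprocessed).
#' @param sheet Sample sheet covering the matrix samples.
#' @param alpha Family-wise error rate (default 0.05).
#' @param technical Sheet columns used as stage-1 technical covariates
#'   (defaults to `chip_id` and `position_on_chip` where present).
#' @param adjust_age Include age in stage 2.
#' @return An `ewas_result` list: `table` (per-probe data.frame sorted by
#'   p), `threshold`, `n_significant`, `direction` (signed tally among
#'   significant probes), `failures`.
#' @export
ewas_scan <- function(m, sheet, alpha = 0.05,
                      technical = intersect(c("chip_id", "position_on_chip"),
                                            names(sheet)),
                      adjust_age = TRUE) {
  sheet <- sheet[match(colnames(m), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id)) stop("sample sheet does not cover matrix samples")
  covs <- if (length(technical)) {
    cv <- sheet[, technical, drop = FALSE]
    cv[] <- lapply(cv, function(x) if (is.numeric(x)) x else factor(x))
    cv
  } else NULL
  event <- as.integer(sheet$status == "case")
  py <- sheet$followup
  age <- if (adjust_age) sheet$age_at_draw else NULL
  thr <- bonferroni_threshold(nrow(m), alpha)

  ids <- rownames(m)
  coefs <- ses <- ps <- rep(NA_real_, nrow(m))
  failures <- character()
  # stage-1 design is shared across probes; build it once
  X1 <- if (is.null(covs)) matrix(1, ncol(m), 1L) else
    stats::model.matrix(~ ., data = covs)
  for (i in seq_len(nrow(m))) {
    out <- tryCatch({
      y <- pmin(pmax(m[i, ], 1e-6), 1 - 1e-6)
      fit1 <- betareg_fit(y, X1)
      poisson_offset_assoc(y - fit1$fitted, event, py, age)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      failures <- c(failures, paste0(ids[i], ": ", conditionMessage(out)))
    } else {
      coefs[i] <- out$coef; ses[i] <- out$se; ps[i] <- out$p_value
    }
  }
  tab <- data.frame(probe_id = ids, coef = coefs, se = ses, p_value = ps,
                    significant = !is.na(ps) & ps < thr)
  tab <- tab[order(tab$p_value), ]
  sig <- tab[tab$significant, , drop = FALSE]
  structure(list(table = tab, threshold = thr,
                 n_significant = nrow(sig),
                 direction = c(hypo = sum(sig$coef < 0),
                               hyper = sum(sig$coef > 0)),
                 failures = failures),
            class = "ewas_result")
}

#' @export
print.ewas_result <- function(x, ...) {
  cat("Probe-wise scan:", nrow(x$table), "probes, threshold",
      format(x$threshold, digits = 3), "->", x$n_significant,
      "significant (", x$direction[["hypo"]], "hypo /",
      x$direction[["hyper"]], "hyper in cases );",
      length(x$failures), "failures\n")
  invisible(x)
}
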