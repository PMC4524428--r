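make_pairs_from <- function(case_x, ctrl_x, seed = 1) {
  set.seed(seed)
  n <- length(case_x)
  structure(data.frame(pair_id = sprintf("P%03d", seq_len(n)),
                       case_exposure = case_x, control_exposure = ctrl_x,
                       case_age = rnorm(n, 55, 3),
                       control_age = rnorm(n, 55, 3)),
            class = c("matched_pair_frame", "data.frame"))
}

test_that("conditional logistic estimate equals the grid-search maximiser
           of the conditional likelihood", {
  set.seed(70)
  d <- rnorm(20, 0.3, 1)
  pairs <- make_pairs_from(d, rep(0, 20))
  est <- clogit_pairs(pairs, adjust_age = FALSE)
  oracle <- grid_clogit(d)
  expect_equal(est$coef, oracle, tolerance = 1e-4)
})

test_that("conditional logistic matches the survival package and obeys
           exact invariances", {
  skip_if_not_installed("survival")
  set.seed(71)
  n <- 40
  case_x <- rnorm(n, 0.2); ctrl_x <- rnorm(n)
  pairs <- make_pairs_from(case_x, ctrl_x)
  est <- clogit_pairs(pairs)
  df <- data.frame(y = rep(c(1, 0), each = n), x = c(case_x, ctrl_x),
                   age = c(pairs$case_age, pairs$control_age),
                   strat = rep(seq_len(n), 2))
  ref <- survival::coxph(survival::Surv(rep(1, 2 * n), y) ~ x + age +
                           survival::strata(strat),
                         data = df, method = "exact")
  expect_equal(est$coef, unname(coef(ref)["x"]), tolerance = 1e-6)
  expect_equal(est$se, sqrt(vcov(ref)["x", "x"]), tolerance = 1e-6)

  # multiplying the exposure by c rescales the coefficient by 1/c exactly
  scaled <- make_pairs_from(10 * case_x, 10 * ctrl_x)
  est10 <- clogit_pairs(scaled)
  expect_equal(est10$coef, est$coef / 10, tolerance = 1e-8)

  # adding a constant to all exposures changes nothing
  shifted <- make_pairs_from(case_x + 5, ctrl_x + 5)
  expect_equal(clogit_pairs(shifted)$coef, est$coef, tolerance = 1e-8)
})

test_that("degenerate and separated difference patterns are handled
           explicitly", {
  # identically zero differences: coefficient 0 with infinite SE, flagged
  z <- make_pairs_from(rep(1, 6), rep(1, 6))
  est0 <- clogit_pairs(z)
  expect_equal(est0$coef, 0)
  expect_true(is.infinite(est0$se))
  expect_true(isTRUE(est0$degenerate))

  # antisymmetric differences: coefficient exactly 0 by symmetry
  sym <- make_pairs_from(c(1, 1, 1, -1, -1, -1), rep(0, 6))
  expect_equal(clogit_pairs(sym, adjust_age = FALSE)$coef, 0,
               tolerance = 1e-10)

  # one-signed differences: explicit separation error
  sep <- make_pairs_from(c(2, 1, 3, 0.5), rep(0, 4))
  expect_error(clogit_pairs(sep, adjust_age = FALSE), "separation")
})

test_that("quartile odds ratios have Q1 fixed at 1 and track a planted
           monotone effect", {
  set.seed(72)
  n <- 200
  # controls uniform across quartiles; cases pushed down
  sheet <- make_sheet(n)
  x <- setNames(rnorm(2 * n, 0.53, 0.01), sheet$sample_id)
  ci <- sheet$sample_id[sheet$status == "case"]
  x[ci] <- x[ci] - 0.008
  q <- quartile_categorize(x, sheet$sample_id[sheet$status == "control"])
  pairs <- make_matched_pairs(x, sheet)
  tab <- or_by_quartile(pairs, q$labels, sheet)
  expect_identical(tab$or[1], 1)
  expect_true(is.na(tab$p_value[1]))
  expect_equal(nrow(tab), 4L)
  # planted protective gradient: Q4 OR clearly below 1
  expect_lt(tab$or[4], 1)
  expect_lt(tab$ci_upper[4], 1)
})

test_that("robust logistic reduces to ordinary logistic for independent
           singletons and is near-null on balanced data", {
  set.seed(73)
  sheet <- make_sheet(100)
  x <- setNames(rnorm(200), sheet$sample_id)
  est <- robust_logistic(x, sheet, adjust_age = FALSE)
  expect_lt(abs(est$coef), 3 * est$se)

  # pairs that are singletons in effect: cluster = subject
  sheet_s <- sheet
  sheet_s$pair_id <- sheet_s$sample_id # each cluster has one member
  df <- data.frame(y = as.integer(sheet_s$status == "case"),
                   x = unname(x[sheet_s$sample_id]))
  fit <- glm(y ~ x, family = binomial, data = df)
  sw <- sandwich::vcovCL(fit, cluster = sheet_s$sample_id)
  # sandwich SE with singleton clusters ~ model SE (asymptotically equal)
  expect_equal(sqrt(sw["x", "x"]), sqrt(vcov(fit)["x", "x"]),
               tolerance = 0.1)
})

test_that("paired Wilcoxon p equals full sign enumeration for small n", {
  # all differences +1, n = 6: one-sided exact p = 1/2^6
  res <- paired_wilcoxon(rep(1, 6) + (1:6) * 1e-9, rep(0, 6),
                         alternative = "greater")
  expect_equal(res$p_value, 1 / 64, tolerance = 1e-12)

  # enumeration oracle on n = 10 arbitrary tie-free differences
  set.seed(74)
  d <- round(rnorm(10), 3)
  d <- d[abs(d) > 0]
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  V_all <- signs %*% r
  p_oracle <- mean(abs(V_all - n * (n + 1) / 4) >=
                     abs(V_obs - n * (n + 1) / 4) - 1e-12)
  res2 <- paired_wilcoxon(d, rep(0, n))
  expect_equal(res2$p_value, p_oracle, tolerance = 1e-10)

  # antisymmetric differences -> two-sided p = 1
  res3 <- paired_wilcoxon(c(1, -1, 2, -2), rep(0, 4))
  expect_equal(res3$p_value, 1)

  expect_error(paired_wilcoxon(rep(0, 4), rep(0, 4)), "zero")
})

test_that("spline risk distribution is centred and agrees with the linear
           fit when the truth is linear", {
  set.seed(75)
  n <- 500
  sheet <- make_sheet(n)
  ctrl <- sheet$sample_id[sheet$status == "control"]
  x <- setNames(rnorm(2 * n), sheet$sample_id)
  # planted linear log-OR 0.5 per unit via conditional assignment
  b <- 0.5
  for (p in unique(sheet$pair_id)) {
    ids <- sheet$sample_id[sheet$pair_id == p]
    pr <- plogis(b * (x[ids[1]] - x[ids[2]]))
    if (runif(1) > pr) { # swap: second member becomes the case
      sheet[sheet$sample_id %in% ids, "status"] <-
        rev(sheet[sheet$sample_id %in% ids, "status"])
    }
  }
  sr <- spline_risk_distribution(x, sheet, df = 4)
  expect_equal(mean(sr$log_rr), 0, tolerance = 1e-10)

  lin <- clogit_pairs(make_matched_pairs(x, sheet), adjust_age = FALSE)
  # fitted spline curve close to the linear fit over the bulk of exposure
  bulk <- x > quantile(x, 0.05) & x < quantile(x, 0.95)
  lin_lp <- lin$coef * x - mean(lin$coef * x)
  expect_lt(max(abs(sr$log_rr[bulk] - lin_lp[bulk])), 4 * lin$se)

  # null effect: narrow RR range containing 1
  sheet0 <- make_sheet(n, seed = 76)
  x0 <- setNames(rnorm(2 * n), sheet0$sample_id)
  sr0 <- spline_risk_distribution(x0, sheet0, df = 4)
  expect_gt(1, sr0$rr_lower)
  expect_lt(1, sr0$rr_upper)
  expect_gte(sr0$rr_lower, 0.8 * 0.9)
  expect_lte(sr0$rr_upper, 1.25 / 0.9)

  expect_error(spline_risk_distribution(
    setNames(rep(c(1, 2), n), sheet0$sample_id), sheet0, df = 4),
    "distinct")
})

test_that("AUC equals brute-force concordance and hits its edge cases", {
  set.seed(77)
  status <- rep(c("case", "control"), each = 15)
  scores <- c(rnorm(15, 1), rnorm(15, 0))
  res <- roc_auc(scores, status)
  ca <- scores[status == "case"]; co <- scores[status == "control"]
  conc <- mean(outer(ca, co, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(res$auc, conc, tolerance = 1e-12)

  sep <- suppressWarnings(
    roc_auc(c(rep(1, 5), rep(0, 5)), rep(c("case", "control"), each = 5)))
  expect_equal(sep$auc, 1.0)

  same <- roc_auc(rep(1:10, 2), rep(c("case", "control"), each = 10))
  expect_equal(same$auc, 0.5)

  expect_error(roc_auc(1:4, rep("case", 4)), "both")
})

test_that("stratified heterogeneity follows the closed-form Q", {
  set.seed(78)
  n <- 60
  case_x <- rnorm(n, 0.2); ctrl_x <- rnorm(n)
  pairs <- make_pairs_from(case_x, ctrl_x)
  stratum <- rep(c("early", "late"), each = n / 2)
  res <- stratified_analysis(pairs, stratum, adjust_age = FALSE)
  expect_equal(res$df, 1L)

  # closed form for two strata
  th <- res$estimates$logor; se <- res$estimates$se
  Q_hand <- (th[1] - th[2])^2 / (se[1]^2 + se[2]^2)
  expect_equal(res$Q, Q_hand, tolerance = 1e-10)
  expect_equal(res$p_het, pchisq(Q_hand, 1, lower.tail = FALSE))

  # identical strata -> Q = 0, p = 1 (duplicate the pairs)
  dup <- rbind(pairs, pairs)
  dup$pair_id <- sprintf("P%03d", seq_len(nrow(dup)))
  res0 <- stratified_analysis(dup, rep(c("a", "b"), each = n),
                              adjust_age = FALSE)
  expect_equal(res0$Q, 0, tolerance = 1e-10)
  expect_equal(res0$p_het, 1, tolerance = 1e-8)
})

test_that("KS comparison equals the brute-force ECDF sup difference", {
  set.seed(79)
  a <- rnorm(15); b <- rnorm(15, 0.5)
  res <- ks_compare(a, b)
  grid <- sort(c(a, b))
  D_hand <- max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
  expect_equal(res$D, D_hand, tolerance = 1e-12)

  expect_equal(ks_compare(a, a)$D, 0)
  expect_equal(ks_compare(1:5, 11:15)$D, 1)
})

test_that("per-SD Wald test holds its nominal size under the null", {
  set.seed(80)
  reps <- 400
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    d <- rnorm(100) # null within-pair differences
    pairs <- make_pairs_from(d, rep(0, 100), seed = r)
    est <- clogit_pairs(pairs, adjust_age = FALSE)
    rej[r] <- est$p_value < 0.05
  }
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})
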