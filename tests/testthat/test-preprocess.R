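test_that("exclusion ledger reproduces the published QC arithmetic", {
  epic_probes <- exclusion_ledger(485577, 332, list(
    list(label = "SNP loci", probes_removed = 65),
    list(label = "prior cancer", samples_removed = 2),
    list(label = "pair not on same chip", samples_removed = 2),
    list(label = "missing in >20% of samples", probes_removed = 36655),
    list(label = "missing >5% of CpGs", samples_removed = 3),
    list(label = "incomplete pair", samples_removed = 1),
    list(label = "non-specific CpGs", probes_removed = 40108)))
  expect_identical(attr(epic_probes, "final_probes"), 408749L)
  expect_identical(attr(epic_probes, "final_samples"), 324L)

  nowac <- exclusion_ledger(485577, 384, list(
    list(label = "SNP loci", probes_removed = 65),
    list(label = "post-ComBat", probes_removed = 224),
    list(label = "missing covariates", samples_removed = 9),
    list(label = "missing in >20% of samples", probes_removed = 28459),
    list(label = "missing >5% of CpGs", samples_removed = 14),
    list(label = "incomplete pair", samples_removed = 23),
    list(label = "non-specific CpGs", probes_removed = 40417)))
  expect_identical(attr(nowac, "final_probes"), 416412L)
  expect_identical(attr(nowac, "final_samples"), 338L)

  # remaining counts decrease by exactly the removals at each step
  expect_true(all(diff(c(485577L, nowac$probes_remaining)) ==
                    -nowac$probes_removed))
  expect_error(
    exclusion_ledger(100, 10, list(list(label = "too many",
                                        probes_removed = 101))),
    "only 100 remain")
})

test_that("missingness filters use strict thresholds on the stated side", {
  m <- make_beta(4, 10, seed = 3)
  m[1, 1:3] <- NA  # 30% missing -> removed at 0.20
  m[2, 1:2] <- NA  # 20% missing -> kept (not > 0.20)
  f <- filter_probes_by_missingness(m, 0.20)
  expect_identical(f$removed, "cg00001")
  expect_equal(nrow(f$matrix), 3L)

  m2 <- make_beta(100, 3, seed = 4)
  m2[1:6, 1] <- NA   # 6% -> removed at 0.05
  m2[1:5, 2] <- NA   # 5% exactly -> kept
  f2 <- filter_samples_by_missingness(m2, 0.05)
  expect_identical(f2$removed, "S001")

  complete <- make_beta(5, 5, seed = 5)
  expect_identical(filter_probes_by_missingness(complete)$matrix, complete)
  expect_length(filter_samples_by_missingness(complete)$removed, 0L)
})

test_that("incomplete pairs are dropped and ledger arithmetic reconciles", {
  sheet <- make_sheet(3)
  m <- make_beta(5, 6, seed = 6)
  colnames(m) <- sheet$sample_id
  m_orphan <- m[, -2, drop = FALSE]  # drop P001's control
  res <- drop_incomplete_pairs(m_orphan, sheet)
  expect_identical(res$removed, "S001")
  expect_equal(ncol(res$matrix), 4L)
  expect_true(all(table(res$sheet$pair_id) == 2L))

  intact <- drop_incomplete_pairs(m, sheet)
  expect_identical(intact$matrix, m)

  led <- exclusion_ledger(5, 6, list(
    list(label = "orphan control", samples_removed = 1),
    list(label = "incomplete pair", samples_removed = 1)))
  expect_silent(reconcile_ledger(led, res$matrix))
  expect_error(reconcile_ledger(led, m), "do not match")
})

test_that("kNN imputation averages the nearest probes and stays in bounds", {
  # duplicate probe present: k = 1 imputes exactly the duplicate's value
  m <- make_beta(20, 6, seed = 7)
  m[2, ] <- m[1, ]
  m[1, 3] <- NA
  imp <- knn_impute(m, k = 1L)
  expect_equal(imp[1, 3], m[2, 3])
  expect_identical(imp[-1, ], m[-1, ])

  complete <- make_beta(15, 5, seed = 8)
  expect_identical(knn_impute(complete, k = 3L), complete)

  # brute-force neighbour search on a 20-probe fixture: the imputed value
  # lies within the range of its k nearest complete neighbours
  m3 <- make_beta(20, 6, seed = 9)
  m3[5, 2] <- NA
  k <- 4L
  imp3 <- knn_impute(m3, k = k)
  obs <- setdiff(seq_len(6), 2)
  cand <- setdiff(seq_len(20), 5)
  d <- sapply(cand, function(j) sqrt(mean((m3[j, obs] - m3[5, obs])^2)))
  nb <- cand[order(d)][seq_len(k)]
  expect_equal(imp3[5, 2], mean(m3[nb, 2]))
  expect_gte(imp3[5, 2], min(m3[nb, 2]))
  expect_lte(imp3[5, 2], max(m3[nb, 2]))

  expect_error(knn_impute(matrix(c(NA, 0.5), 1, 2,
                                 dimnames = list("p1", c("a", "b"))), k = 1L),
               "neighbour")
})

test_that("beta/M conversions are exact and inverse to each other", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)  # log2(4)
  b <- seq(0.01, 0.99, by = 0.01)
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-12)
  expect_error(beta_to_m(c(0, 0.5)), "strictly inside")
})

test_that("empirical-Bayes batch adjustment removes injected offsets while
           preserving per-probe means", {
  set.seed(21)
  m <- matrix(rnorm(50 * 40, 0, 1), 50, 40,
              dimnames = list(sprintf("p%02d", 1:50), sprintf("s%02d", 1:40)))
  batch <- rep(c("A", "B"), each = 20)
  delta <- 1.5
  m_off <- m
  m_off[, batch == "B"] <- m_off[, batch == "B"] + delta

  adj <- combat_adjust(m_off, batch)
  gap <- abs(mean(adj[, batch == "B"]) - mean(adj[, batch == "A"]))
  expect_lt(gap, 0.05 * delta)
  expect_equal(rowMeans(adj), rowMeans(m_off), tolerance = 1e-6)

  # single batch: identity up to round-off
  expect_equal(combat_adjust(m, rep("A", 40)), m)
  expect_error(combat_adjust(m, c(rep("A", 39), "B")), "singleton")
})

test_that("batch adjustment agrees with the reference empirical-Bayes
           implementation on mean structure", {
  skip_if_not_installed("sva")
  set.seed(22)
  m <- matrix(rnorm(60 * 30), 60, 30,
              dimnames = list(sprintf("p%02d", 1:60), sprintf("s%02d", 1:30)))
  batch <- rep(c("A", "B", "C"), each = 10)
  m[, batch == "B"] <- m[, batch == "B"] + 0.8
  mine <- combat_adjust(m, batch)
  ref <- suppressMessages(sva::ComBat(m, batch = batch))
  # both must flatten the batch means; compare the residual batch contrasts
  for (b in c("A", "B", "C")) {
    expect_lt(abs(mean(mine[, batch == b]) - mean(mine[, batch != b])), 0.05)
    expect_lt(abs(mean(mine[, batch == b]) - mean(ref[, batch == b])), 0.05)
  }
  expect_gt(cor(as.vector(mine), as.vector(ref)), 0.99)
})

test_that("peak-based correction aligns type II modes with type I", {
  set.seed(23)
  n1 <- 400; n2 <- 600
  design <- c(rep("I", n1), rep("II", n2))
  # bimodal M-value populations; type II compressed by 0.8 towards 0
  draw <- function(n, lo, hi) {
    comp <- rbinom(n, 1, 0.5)
    rnorm(n, ifelse(comp == 1, hi, lo), 0.4)
  }
  m_I <- draw(n1, -3, 3)
  m_II <- 0.8 * draw(n2, -3, 3)
  beta <- m_to_beta(c(m_I, m_II))
  m <- cbind(s1 = beta, s2 = m_to_beta(c(draw(n1, -3, 3), 0.8 * draw(n2, -3, 3))))
  rownames(m) <- sprintf("cg%04d", seq_len(n1 + n2))

  corr <- peak_correct_type2(m, design)
  expect_true(all(corr > 0 & corr < 1))
  expect_equal(corr[design == "I", ], m[design == "I", ])
  for (s in 1:2) {
    mv <- beta_to_m(corr[, s], clamp = TRUE)
    p1 <- methrisk:::find_two_modes(mv[design == "I"])
    p2 <- methrisk:::find_two_modes(mv[design == "II"])
    expect_lt(max(abs(p1 - p2)), 0.05 * diff(p1) + 0.2)
  }

  # idempotency within tolerance
  corr2 <- peak_correct_type2(corr, design)
  mv_a <- beta_to_m(corr[design == "II", 1], clamp = TRUE)
  mv_b <- beta_to_m(corr2[design == "II", 1], clamp = TRUE)
  expect_lt(max(abs(mv_a - mv_b)), 1e-1)

  # identity case: type II already aligned
  m_same <- cbind(s1 = m_to_beta(c(draw(n1, -3, 3), draw(n2, -3, 3))))
  rownames(m_same) <- sprintf("cg%04d", seq_len(n1 + n2))
  corr_same <- peak_correct_type2(m_same, design)
  mv0 <- beta_to_m(m_same[design == "II", 1])
  mv1 <- beta_to_m(corr_same[design == "II", 1], clamp = TRUE)
  expect_lt(median(abs(mv1 - mv0)), 0.25)

  # unimodal sample -> error naming the sample
  uni <- cbind(bad = m_to_beta(rnorm(n1 + n2, 0, 0.3)))
  rownames(uni) <- sprintf("cg%04d", seq_len(n1 + n2))
  expect_error(peak_correct_type2(uni, design), "bad")
})
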