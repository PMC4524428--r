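#' Convert beta values to M-values
#'
#' M = log2(beta / (1 - beta)). Beta values must lie strictly inside (0,1);
#' use `clamp = TRUE` to nudge boundary values inward first.
#'
#' @param beta Numeric vector/matrix of methylation fractions.
#' @param clamp If `TRUE`, clamp into \[eps, 1-eps\] before transforming.
#' @param eps Clamp width.
#' @return M-values, same shape as input.
#' @export
beta_to_m <- function(beta, clamp = FALSE, eps = 1e-6) {
  if (clamp) beta <- pmin(pmax(beta, eps), 1 - eps)
  if (any(beta <= 0 | beta >= 1, na.rm = TRUE)) {
    stop("beta values must be strictly inside (0,1); use clamp = TRUE")
  }
  log2(beta / (1 - beta))
}

#' Convert M-values to beta values
#'
#' @param m M-values (log2 scale).
#' @return Beta values in (0,1), same shape as input.
#' @export
m_to_beta <- function(m) {
  1 / (1 + 2^(-m))
}

#' Build a sequential probe/sample exclusion ledger
#'
#' Quality-control exclusions in array studies are applied in a stated
#' order; the ledger records, per step, how many probes and samples were
#' removed and how many remain, so the final matrix dimensions can always
#' be reconciled against the raw input.
#'
#' @param initial_probes,initial_samples Counts before any exclusion.
#' @param steps A list of steps, each a list/vector with elements `label`,
#'   `probes_removed`, `samples_removed` (missing counts default to 0).
#' @return An `exclusion_ledger`: data.frame with one row per step plus
#'   attributes `final_probes`, `final_samples`.
#' @export
exclusion_ledger <- function(initial_probes, initial_samples, steps) {
  stopifnot(initial_probes >= 0, initial_samples >= 0)
  p <- as.integer(initial_probes)
  s <- as.integer(initial_samples)
  rows <- vector("list", length(steps))
  for (i in seq_along(steps)) {
    st <- as.list(steps[[i]])
    pr <- as.integer(if (is.null(st$probes_removed)) 0L else st$probes_removed)
    sr <- as.integer(if (is.null(st$samples_removed)) 0L else st$samples_removed)
    if (pr < 0 || sr < 0) stop("negative removal count at step ", i)
    if (pr > p) stop("step '", st$label, "' removes ", pr,
                     " probes but only ", p, " remain")
    if (sr > s) stop("step '", st$label, "' removes ", sr,
                     " samples but only ", s, " remain")
    p <- p - pr
    s <- s - sr
    rows[[i]] <- data.frame(step = i, label = as.character(st$label),
                            probes_removed = pr, probes_remaining = p,
                            samples_removed = sr, samples_remaining = s)
  }
  led <- do.call(rbind, rows)
  attr(led, "initial_probes") <- as.integer(initial_probes)
  attr(led, "initial_samples") <- as.integer(initial_samples)
  attr(led, "final_probes") <- p
  attr(led, "final_samples") <- s
  class(led) <- c("exclusion_ledger", "data.frame")
  led
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat("Exclusion ledger:", attr(x, "initial_probes"), "probes /",
      attr(x, "initial_samples"), "samples ->", attr(x, "final_probes"),
      "probes /", attr(x, "final_samples"), "samples\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Check that a ledger's final counts match a matrix
#'
#' @param ledger An `exclusion_ledger`.
#' @param m Beta matrix the ledger should describe.
#' @return `TRUE` invisibly, or an error.
#' @export
reconcile_ledger <- function(ledger, m) {
  if (attr(ledger, "final_probes") != nrow(m) ||
      attr(ledger, "final_samples") != ncol(m)) {
    stop("ledger totals (", attr(ledger, "final_probes"), " x ",
         attr(ledger, "final_samples"), ") do not match matrix (",
         nrow(m), " x ", ncol(m), ")")
  }
  invisible(TRUE)
}

#' Remove probes undetected in too many samples
#'
#' A probe is excluded when its missing-value fraction strictly exceeds
#' `threshold` (a probe missing in exactly `threshold` of samples is kept).
#'
#' @param m Beta matrix.
#' @param threshold Missing fraction above which a probe is dropped
#'   (default 0.20).
#' @return List with `matrix` (filtered) and `removed` (probe IDs).
#' @export
filter_probes_by_missingness <- function(m, threshold = 0.20) {
  stopifnot(threshold > 0, threshold < 1)
  frac <- rowMeans(is.na(m))
  drop <- frac > threshold
  list(matrix = m[!drop, , drop = FALSE], removed = rownames(m)[drop])
}

#' Remove samples with too many missing probes
#'
#' @param m Beta matrix.
#' @param threshold Missing fraction above which a sample is dropped
#'   (default 0.05).
#' @return List with `matrix` and `removed` (sample IDs).
#' @export
filter_samples_by_missingness <- function(m, threshold = 0.05) {
  stopifnot(threshold > 0, threshold < 1)
  frac <- colMeans(is.na(m))
  drop <- frac > threshold
  list(matrix = m[, !drop, drop = FALSE], removed = colnames(m)[drop])
}

#' Drop samples whose matched pair is incomplete
#'
#' After sample-level exclusions some pairs retain only one member; the
#' conditional analysis cannot use them, so they are removed and the sheet
#' subset accordingly.
#'
#' @param m Beta matrix.
#' @param sheet Sample sheet covering at least the matrix samples.
#' @return List with `matrix`, `sheet` (complete pairs only) and `removed`
#'   (orphaned sample IDs).
#' @export
drop_incomplete_pairs <- function(m, sheet) {
  sheet <- sheet[sheet$sample_id %in% colnames(m), , drop = FALSE]
  if (!all(colnames(m) %in% sheet$sample_id)) {
    stop("sample sheet does not cover all matrix samples")
  }
  tab <- table(sheet$pair_id, sheet$status)
  ok <- rownames(tab)[tab[, "case"] == 1L & tab[, "control"] == 1L]
  keep <- sheet$pair_id %in% ok
  removed <- sheet$sample_id[!keep]
  sheet <- sheet[keep, , drop = FALSE]
  list(matrix = m[, sheet$sample_id, drop = FALSE], sheet = sheet,
       removed = removed)
}

#' k-nearest-neighbour imputation of missing beta values
#'
#' For each probe with missing entries, the k nearest probes (Euclidean
#' distance over the samples where both probes are observed, scaled to a
#' common number of dimensions) that are observed in the missing sample are
#' averaged. Observed values are never altered.
#'
#' @param m Beta matrix with missing values as `NA`.
#' @param k Number of neighbour probes (default 10).
#' @return Complete beta matrix.
#' @export
knn_impute <- function(m, k = 10L) {
  stopifnot(k >= 1L)
  if (!anyNA(m)) return(m)
  miss_rows <- which(rowSums(is.na(m)) > 0L)
  complete <- m[rowSums(is.na(m)) == 0L, , drop = FALSE]
  out <- m
  for (i in miss_rows) {
    x <- m[i, ]
    obs <- !is.na(x)
    if (nrow(complete) < k) {
      stop("probe ", rownames(m)[i], ": only ", nrow(complete),
           " complete neighbour probes available, need k = ", k)
    }
    # distance over shared (observed) samples, complete probes only
    d2 <- rowMeans((complete[, obs, drop = FALSE] -
                      rep(x[obs], each = nrow(complete)))^2)
    nb <- order(d2)[seq_len(k)]
    fill <- colMeans(complete[nb, !obs, drop = FALSE])
    out[i, !obs] <- fill
  }
  stopifnot(!anyNA(out))
  out
}

#' Empirical-Bayes batch adjustment of M-values
#'
#' Location/scale adjustment in the style of the standard empirical-Bayes
#' batch method: per-probe standardisation, normal prior on batch means and
#' inverse-gamma prior on batch variances estimated across probes by
#' moments, shrunken batch effects removed, and data rescaled. After
#' adjustment each probe is recentred so its pooled mean is preserved
#' exactly.
#'
#' @param m M-value matrix (probes x samples), complete.
#' @param batch Batch label per sample (length `ncol(m)`); every batch must
#'   contain at least two samples.
#' @param shrink If `FALSE`, use the raw per-batch estimates (no
#'   empirical-Bayes shrinkage).
#' @return Adjusted M-value matrix, same dimnames.
#' @export
combat_adjust <- function(m, batch, shrink = TRUE) {
  stopifnot(is.matrix(m), length(batch) == ncol(m))
  if (anyNA(m)) stop("combat_adjust requires a complete matrix; impute first")
  batch <- as.factor(droplevels(as.factor(batch)))
  nb <- table(batch)
  if (any(nb < 2L)) {
    stop("singleton batch(es): ", paste(names(nb)[nb < 2L], collapse = ", "))
  }
  if (nlevels(batch) < 2L) return(m)

  grand <- rowMeans(m)
  lev <- levels(batch)
  batch_means <- vapply(lev, function(b) rowMeans(m[, batch == b, drop = FALSE]),
                        numeric(nrow(m)))
  # pooled residual variance about batch means
  resid <- m - batch_means[, as.integer(batch)]
  pooled_var <- rowSums(resid^2) / ncol(m)
  pooled_var[pooled_var < 1e-12] <- 1e-12
  sd_j <- sqrt(pooled_var)

  z <- (m - grand) / sd_j
  adj <- z
  for (bi in seq_along(lev)) {
    cols <- which(batch == lev[bi])
    n_b <- length(cols)
    zb <- z[, cols, drop = FALSE]
    g_hat <- rowMeans(zb)
    d_hat <- rowSums((zb - g_hat)^2) / (n_b - 1L)
    if (shrink) {
      g_bar <- mean(g_hat)
      t2 <- stats::var(g_hat)
      # inverse-gamma moments across probes for the variance prior
      v_bar <- mean(d_hat)
      s2 <- stats::var(d_hat)
      lambda <- (v_bar^2 + 2 * s2) / max(s2, 1e-12)
      theta <- (v_bar^3 + v_bar * s2) / max(s2, 1e-12)
      g_star <- g_hat
      d_star <- d_hat
      for (it in 1:100) {
        g_new <- (n_b * t2 * g_hat + d_star * g_bar) / (n_b * t2 + d_star)
        ss <- rowSums((zb - g_new)^2)
        d_new <- (theta + 0.5 * ss) / (n_b / 2 + lambda - 1)
        if (max(abs(g_new - g_star)) < 1e-8 && max(abs(d_new - d_star)) < 1e-8) {
          g_star <- g_new; d_star <- d_new
          break
        }
        g_star <- g_new; d_star <- d_new
      }
    } else {
      g_star <- g_hat
      d_star <- d_hat
    }
    d_star[d_star < 1e-12] <- 1e-12
    adj[, cols] <- (zb - g_star) / sqrt(d_star)
  }
  out <- adj * sd_j + grand
  # preserve the per-probe pooled mean exactly
  out <- out - (rowMeans(out) - grand)
  dimnames(out) <- dimnames(m)
  out
}

# Locate the unmethylated and methylated density modes of a set of M-values.
# Returns c(low, high) or raises if two well-separated modes are not found.
find_two_modes <- function(mv, bw = 0.5, min_sep = 2, who = "sample") {
  mv <- mv[is.finite(mv)]
  d <- stats::density(mv, bw = bw, n = 1024)
  y <- d$y
  locmax <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(locmax) < 2L) {
    stop("mode detection failure (unimodal M distribution) for ", who)
  }
  # the two tallest maxima separated by at least min_sep
  ord <- locmax[order(y[locmax], decreasing = TRUE)]
  top <- d$x[ord[1L]]
  second <- NA_real_
  for (i in ord[-1L]) {
    if (abs(d$x[i] - top) >= min_sep) { second <- d$x[i]; break }
  }
  if (is.na(second)) {
    stop("mode detection failure (modes closer than ", min_sep, " M) for ", who)
  }
  sort(c(top, second))
}

#' Peak-based rescaling of Infinium type II probes
#'
#' The two Infinium chemistries have systematically different beta
#' distributions. Per sample, the unmethylated and methylated density modes
#' of type I and type II probes are located on the M-value scale (kernel
#' density, fixed bandwidth) and type II M-values are linearly rescaled so
#' their two modes align with type I's; type I values are unchanged.
#'
#' @param m Beta matrix.
#' @param design Design type per probe (length `nrow(m)`), values "I"/"II".
#' @param bw Kernel bandwidth in M units (default 0.5).
#' @param min_sep Minimum separation between the two modes in M units
#'   (default 2).
#' @return Corrected beta matrix.
#' @export
peak_correct_type2 <- function(m, design, bw = 0.5, min_sep = 2) {
  stopifnot(length(design) == nrow(m))
  design <- as.character(design)
  if (!all(design %in% c("I", "II"))) stop("design types must be 'I' or 'II'")
  i1 <- design == "I"
  i2 <- design == "II"
  if (!any(i1) || !any(i2)) stop("both design types must be present")
  out <- m
  for (s in seq_len(ncol(m))) {
    who <- if (!is.null(colnames(m))) colnames(m)[s] else paste("sample", s)
    mv <- beta_to_m(m[, s], clamp = TRUE)
    p1 <- find_two_modes(mv[i1], bw, min_sep, paste0(who, " (type I)"))
    p2 <- find_two_modes(mv[i2], bw, min_sep, paste0(who, " (type II)"))
    scale <- (p1[2L] - p1[1L]) / (p2[2L] - p2[1L])
    mv2 <- p1[1L] + (mv[i2] - p2[1L]) * scale
    out[i2, s] <- m_to_beta(mv2)
  }
  keep_na <- is.na(m)
  out[keep_na] <- NA
  out
}
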