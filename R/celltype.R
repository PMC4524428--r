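#' Identify white-cell discriminating probes
#'
#' For each purified cell type, each probe's beta values are regressed on
#' a type-vs-baseline indicator across the panel replicates (simple linear
#' regression, equivalent to an equal-variance two-sample t test). A probe
#' is flagged for a cell type when the regression p value is below
#' `p_threshold` and the absolute mean beta difference exceeds
#' `delta_threshold`; the union over cell types is the removal set.
#'
#' @param panel A `reference_panel` (see [generate_reference_panel()]).
#' @param p_threshold Regression p-value cutoff (default 1e-7).
#' @param delta_threshold Absolute delta-beta cutoff (default 0.05).
#' @param baseline Baseline group label; `"PBMC"` (default) or
#'   `"panel_mean"` to compare against the average of all purified types.
#' @return A `celltype_filter` list: `per_type` (named list of probe ID
#'   vectors), `union` (probe IDs), `stats` (per probe x type p and
#'   delta-beta).
#' @export
find_celltype_probes <- function(panel, p_threshold = 1e-7,
                                 delta_threshold = 0.05,
                                 baseline = c("PBMC", "panel_mean")) {
  baseline <- match.arg(baseline)
  reps <- panel$replicates
  rt <- panel$replicate_type
  if (baseline == "PBMC") {
    base_cols <- rt == "PBMC"
    if (!any(base_cols)) stop("panel has no PBMC baseline replicates")
    base_mat <- reps[, base_cols, drop = FALSE]
  } else {
    base_mat <- NULL # built per probe below from all purified replicates
  }
  per_type <- list()
  stats_list <- list()
  for (ct in panel$cell_types) {
    x <- reps[, rt == ct, drop = FALSE]
    y <- if (is.null(base_mat)) reps[, rt != "PBMC", drop = FALSE] else base_mat
    if (ncol(x) < 2L || ncol(y) < 2L) {
      stop("need >=2 replicates per group for cell type ", ct)
    }
    res <- rowwise_two_group_test(x, y)
    flag <- res$p < p_threshold & abs(res$delta) > delta_threshold
    flag[is.na(flag)] <- FALSE
    per_type[[ct]] <- rownames(reps)[flag]
    stats_list[[ct]] <- data.frame(probe_id = rownames(reps),
                                   cell_type = ct, p_value = res$p,
                                   delta_beta = res$delta)
  }
  structure(list(per_type = per_type,
                 union = sort(unique(unlist(per_type, use.names = FALSE))),
                 stats = do.call(rbind, stats_list),
                 p_threshold = p_threshold,
                 delta_threshold = delta_threshold,
                 baseline = baseline),
            class = "celltype_filter")
}

# Vectorised per-probe two-group comparison: slope p value of the
# regression of beta on a group indicator == pooled-variance t test.
rowwise_two_group_test <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2)
  vy <- rowSums((y - my)^2)
  df <- nx + ny - 2L
  sp2 <- (vx + vy) / df
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  tstat <- (mx - my) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  list(delta = mx - my, p = p, t = tstat)
}

#' Remove a probe set from a beta matrix
#'
#' @param m Beta matrix.
#' @param probes Probe IDs to drop.
#' @return Beta matrix without those probes; dropping every probe is an
#'   error.
#' @export
remove_probes <- function(m, probes) {
  keep <- !(rownames(m) %in% probes)
  if (!any(keep)) stop("removal would leave an empty matrix")
  m[keep, , drop = FALSE]
}

# Lawson-Hanson style nonnegative least squares for small systems.
nnls_fit <- function(A, b, tol = 1e-10, max_iter = NULL) {
  n <- ncol(A)
  if (is.null(max_iter)) max_iter <- 10L * n
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      Ap <- A[, passive, drop = FALSE]
      s[passive] <- qr.coef(qr(Ap), b)
      s[is.na(s)] <- 0
      if (all(s[passive] > tol)) break
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      if (!any(passive)) { s <- numeric(n); break }
    }
    x <- s
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' Estimate white-cell proportions by constrained projection
#'
#' Least-squares projection of a sample's beta profile (restricted to
#' discriminating probes) onto the reference mean profiles, under
#' proportions >= 0 and sum <= 1 (reference-based deconvolution). The sum
#' cap is imposed through a slack component on an augmented
#' nonnegative-least-squares system.
#'
#' @param sample_beta Named beta vector for one sample (or a vector aligned
#'   with `profiles` rows).
#' @param profiles Reference mean-beta matrix, probes x cell types,
#'   restricted to discriminating probes.
#' @return List with `proportions` (named, >= 0, sum <= 1) and
#'   `residual_norm`.
#' @export
estimate_cell_proportions <- function(sample_beta, profiles) {
  stopifnot(is.matrix(profiles))
  if (nrow(profiles) < ncol(profiles)) {
    stop("need at least as many probes as cell types")
  }
  if (!is.null(names(sample_beta)) && !is.null(rownames(profiles))) {
    common <- intersect(names(sample_beta), rownames(profiles))
    if (length(common) < ncol(profiles)) stop("too few shared probes")
    sample_beta <- sample_beta[common]
    profiles <- profiles[common, , drop = FALSE]
  }
  ok <- !is.na(sample_beta)
  sample_beta <- sample_beta[ok]
  profiles <- profiles[ok, , drop = FALSE]
  if (qr(profiles)$rank < ncol(profiles)) {
    stop("rank-deficient reference profiles")
  }
  p <- tryCatch(nnls_fit(profiles, sample_beta), error = function(e) NULL)
  if (is.null(p) || sum(p) > 1 + 1e-9) {
    # re-solve with sum-to-one-with-slack enforced via a heavy equality row
    w <- 1e6 * max(abs(profiles))
    A <- rbind(cbind(profiles, 0), w)
    b <- c(sample_beta, w)
    p <- nnls_fit(A, b)[seq_len(ncol(profiles))]
  }
  names(p) <- colnames(profiles)
  list(proportions = p,
       residual_norm = sqrt(sum((sample_beta - profiles %*% p)^2)))
}
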