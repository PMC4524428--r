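#' Principal components of sample methylation profiles
#'
#' PCA on the samples, i.e. on the transpose of the (complete) M-value
#' matrix with probes centred. Used to screen for batch structure and
#' covariate associations.
#'
#' @param m Complete M-value matrix (probes x samples); missing values
#'   are an error (impute first).
#' @param k Number of components to return (default 3).
#' @return List with `scores` (samples x k), `rotation`,
#'   `var_fraction` (all components), `k`.
#' @export
pca_samples <- function(m, k = 3L) {
  if (anyNA(m)) stop("matrix has missing values; run knn_impute first")
  k <- min(k, ncol(m) - 1L)
  pr <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  vf <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = pr$x[, seq_len(k), drop = FALSE],
       rotation = pr$rotation[, seq_len(k), drop = FALSE],
       var_fraction = vf, k = k)
}

# p value of the univariate regression of score on x (numeric slope test,
# identical to the Pearson correlation test).
slope_p <- function(score, x) {
  ok <- stats::complete.cases(score, x)
  if (sum(ok) < 3L || stats::sd(x[ok]) == 0) return(NA_real_)
  f <- stats::lm(score[ok] ~ x[ok])
  stats::coef(summary(f))[2L, 4L]
}

#' Associations between principal components and subject covariates
#'
#' Continuous covariates are tested by the univariate regression slope;
#' categorical covariates per level against the reference (first) level;
#' the chip variable is summarised as the minimum p over chip indicators
#' (a small minimum chip p flags a residual batch effect).
#'
#' @param scores Sample scores from [pca_samples()].
#' @param sheet Sample sheet aligned with the score rows.
#' @param covariates Sheet columns to test (default: all except
#'   identifiers and chip).
#' @param chip_col Name of the chip column (default `chip_id`; `NULL` to
#'   skip).
#' @return A `pc_association` list: `table` (long data.frame PC x
#'   covariate/level x p), `min_chip_p` (named per PC),
#'   `var_fraction` (for the returned PCs).
#' @export
pc_covariate_assoc <- function(scores, sheet,
                               covariates = setdiff(names(sheet),
                                                    c("sample_id", "pair_id",
                                                      "chip_id",
                                                      "position_on_chip")),
                               chip_col = "chip_id") {
  sheet <- sheet[match(rownames(scores), sheet$sample_id), , drop = FALSE]
  rows <- list()
  for (pc in seq_len(ncol(scores))) {
    sc <- scores[, pc]
    for (cv in covariates) {
      x <- sheet[[cv]]
      if (is.numeric(x)) {
        rows[[length(rows) + 1L]] <- data.frame(
          pc = pc, covariate = cv, level = NA_character_,
          p_value = slope_p(sc, x))
      } else {
        x <- as.factor(x)
        if (nlevels(droplevels(x)) < 2L) {
          rows[[length(rows) + 1L]] <- data.frame(
            pc = pc, covariate = cv, level = "(constant)",
            p_value = NA_real_)
          next
        }
        ref <- levels(x)[1L]
        for (lev in levels(x)[-1L]) {
          sel <- x %in% c(ref, lev)
          rows[[length(rows) + 1L]] <- data.frame(
            pc = pc, covariate = cv, level = lev,
            p_value = slope_p(sc[sel], as.integer(x[sel] == lev)))
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  min_chip <- NULL
  if (!is.null(chip_col) && chip_col %in% names(sheet)) {
    chip <- as.factor(sheet[[chip_col]])
    min_chip <- vapply(seq_len(ncol(scores)), function(pc) {
      ps <- vapply(levels(chip), function(lev) {
        slope_p(scores[, pc], as.integer(chip == lev))
      }, numeric(1))
      min(ps, na.rm = TRUE)
    }, numeric(1))
    names(min_chip) <- colnames(scores)
  }
  structure(list(table = tab, min_chip_p = min_chip),
            class = "pc_association")
}
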