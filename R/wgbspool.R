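#' Coverage-dependent site weight for pooled bisulphite data
#'
#' Sites at or above the pool's median coverage get full weight 1; below
#' the median the weight drops by 0.1 for each complete 10%-of-median
#' decrement (0.9, 0.8, ...), floored at 0. With `rule = "started"` every
#' started decrement counts instead. Exact integer arithmetic is used so
#' that a site exactly 10% below the median gets 0.9 under the default
#' rule.
#'
#' @param coverage Nonnegative read counts (vectorised).
#' @param median_coverage Pool median coverage (> 0).
#' @param rule `"completed"` (default) or `"started"` decrements.
#' @param at_median Weight assigned when coverage equals the median
#'   (default 1).
#' @return Weights in \[0, 1\].
#' @export
coverage_weight <- function(coverage, median_coverage,
                            rule = c("completed", "started"), at_median = 1) {
  rule <- match.arg(rule)
  stopifnot(median_coverage > 0)
  if (any(coverage < 0)) stop("negative coverage")
  # k = number of 10%-of-median decrements below the median, in exact
  # rational arithmetic on counts: (1 - c/m)/0.1 = 10 (m - c) / m
  frac <- 10 * (median_coverage - coverage) / median_coverage
  k <- if (rule == "completed") floor(frac + 1e-9) else ceiling(frac - 1e-9)
  w <- pmax(1 - 0.1 * k, 0)
  w[coverage > median_coverage] <- 1
  w[coverage == median_coverage] <- at_median
  w
}

#' Coverage-weighted mean methylation
#'
#' Wmean = sum(M_i w_i) / sum(w_i) with weights from [coverage_weight()].
#'
#' @param meth_fraction Per-site methylation fractions.
#' @param coverage Per-site read coverage.
#' @param median_coverage The pool's median coverage.
#' @param ... Passed to [coverage_weight()].
#' @return Weighted mean in \[0, 1\].
#' @export
weighted_mean_methylation <- function(meth_fraction, coverage,
                                      median_coverage, ...) {
  stopifnot(length(meth_fraction) == length(coverage))
  w <- coverage_weight(coverage, median_coverage, ...)
  if (sum(w) == 0) stop("all site weights are zero")
  sum(meth_fraction * w, na.rm = FALSE) / sum(w)
}

#' Pool median coverage
#'
#' Computed once over all sites in the pool, before any feature
#' subsetting.
#'
#' @param pool A `wgbs_pool`.
#' @return Median of total read counts.
#' @export
pool_median_coverage <- function(pool) {
  stats::median(pool$total)
}

# Feature table (feature, chrom, start, end; 1-based inclusive) -> GRanges
features_to_granges <- function(features) {
  if (methods::is(features, "GRanges")) return(features)
  stopifnot(all(c("feature", "chrom", "start", "end") %in% names(features)))
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start, end = features$end))
  names(gr) <- NULL
  gr$feature <- features$feature
  gr
}

#' Coverage-weighted methylation per genomic feature
#'
#' Summarises a pool over interval sets (e.g. islands, gene bodies):
#' per feature, the coverage-weighted mean methylation of the contained
#' sites, using the pool-wide median coverage for the weights. Features
#' containing no sites are reported with `n_sites = 0` and `NA` mean.
#'
#' @param pool A `wgbs_pool`.
#' @param features A GRanges with a `feature` metadata column, or a
#'   data.frame with columns `feature`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param ... Passed to [coverage_weight()].
#' @return data.frame: `feature`, `n_sites`, `weighted_mean`,
#'   `median_coverage` (of the contained sites).
#' @export
summarize_by_feature <- function(pool, features, ...) {
  gr <- features_to_granges(features)
  med <- pool_median_coverage(pool)
  lev <- union(as.character(GenomeInfoDb::seqlevels(gr)),
               unique(pool$chrom))
  GenomeInfoDb::seqlevels(gr) <- lev
  sites <- GenomicRanges::GRanges(
    seqnames = factor(pool$chrom, levels = lev),
    ranges = IRanges::IRanges(start = pool$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(gr, sites)
  labs <- unique(gr$feature)
  out <- lapply(labs, function(f) {
    rows <- which(gr$feature == f)
    idx <- unique(S4Vectors::subjectHits(
      hits[S4Vectors::queryHits(hits) %in% rows]))
    if (length(idx) == 0L) {
      return(data.frame(feature = f, n_sites = 0L,
                        weighted_mean = NA_real_,
                        median_coverage = NA_real_))
    }
    data.frame(feature = f, n_sites = length(idx),
               weighted_mean = weighted_mean_methylation(
                 pool$meth_fraction[idx], pool$total[idx], med, ...),
               median_coverage = stats::median(pool$total[idx]))
  })
  do.call(rbind, out)
}

#' Restrict a pool to array CpG positions
#'
#' @param pool A `wgbs_pool`.
#' @param array_positions data.frame with columns `chrom`, `pos` (the
#'   array manifest coordinates).
#' @return The pool restricted to sites at the listed coordinates.
#' @export
subset_to_array_sites <- function(pool, array_positions) {
  stopifnot(all(c("chrom", "pos") %in% names(array_positions)))
  key <- paste(pool$chrom, pool$pos)
  keep <- key %in% paste(array_positions$chrom, array_positions$pos)
  out <- pool[keep, , drop = FALSE]
  attr(out, "label") <- attr(pool, "label")
  class(out) <- class(pool)
  out
}

#' Case-vs-control pool contrast per feature
#'
#' Per feature, the difference (mean over case pools) - (mean over control
#' pools) of the coverage-weighted mean methylation, in percentage points.
#' Each pool uses its own median coverage for the weights.
#'
#' @param case_pools,control_pools Lists of `wgbs_pool` objects.
#' @param features Feature intervals (see [summarize_by_feature()]).
#' @param ... Passed to [coverage_weight()].
#' @return data.frame: `feature`, `case_mean_pct`, `control_mean_pct`,
#'   `diff_pct`.
#' @export
pool_contrast <- function(case_pools, control_pools, features, ...) {
  if (inherits(case_pools, "wgbs_pool")) case_pools <- list(case_pools)
  if (inherits(control_pools, "wgbs_pool")) control_pools <- list(control_pools)
  per_pool <- function(pools) {
    tabs <- lapply(pools, summarize_by_feature, features = features, ...)
    feats <- tabs[[1L]]$feature
    means <- sapply(tabs, function(t) t$weighted_mean[match(feats, t$feature)])
    data.frame(feature = feats, mean = rowMeans(cbind(means)))
  }
  ca <- per_pool(case_pools)
  co <- per_pool(control_pools)
  co <- co[match(ca$feature, co$feature), ]
  data.frame(feature = ca$feature,
             case_mean_pct = 100 * ca$mean,
             control_mean_pct = 100 * co$mean,
             diff_pct = 100 * (ca$mean - co$mean))
}
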