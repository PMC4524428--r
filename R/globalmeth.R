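#' Per-sample mean methylation over a probe subset
#'
#' The genome-wide (or per-feature) methylation exposure: the arithmetic
#' mean beta over the non-missing entries of the given probe subset, per
#' sample.
#'
#' @param m Beta matrix.
#' @param subset Probe IDs (default: all probes).
#' @return Named per-sample mean vector.
#' @export
sample_mean_methylation <- function(m, subset = rownames(m)) {
  subset <- intersect(subset, rownames(m))
  if (length(subset) == 0L) stop("empty probe subset")
  colMeans(m[subset, , drop = FALSE], na.rm = TRUE)
}

#' Per-sample median methylation over a probe subset
#'
#' @inheritParams sample_mean_methylation
#' @return Named per-sample median vector.
#' @export
sample_median_methylation <- function(m, subset = rownames(m)) {
  subset <- intersect(subset, rownames(m))
  if (length(subset) == 0L) stop("empty probe subset")
  apply(m[subset, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
}

#' Build feature-defined probe subsets from an annotation
#'
#' Returns probe lists for the island-relation partition (island, shore,
#' shelf, none), the gene-region categories, the combined "promoter"
#' region (TSS200 + TSS1500 + 5'UTR + 1st exon), and the SNP /
#' cross-reactive exclusion flags, plus "all" and "all_no_snp".
#'
#' @param annotation A probe annotation.
#' @return A `feature_subsets` named list of probe-ID vectors with a
#'   `counts` attribute.
#' @export
build_feature_subsets <- function(annotation) {
  if (anyNA(annotation$island_relation) ||
      !all(annotation$island_relation %in% ISLAND_CATEGORIES)) {
    stop("every probe needs an island-relation label")
  }
  id <- annotation$probe_id
  subs <- list(all = id)
  for (cat in ISLAND_CATEGORIES) {
    subs[[cat]] <- id[annotation$island_relation == cat]
  }
  for (gr in GENE_REGIONS) {
    key <- switch(gr, "Body" = "gene_body", "3'UTR" = "utr3",
                  "5'UTR" = "utr5", "1stExon" = "first_exon", gr)
    subs[[key]] <- id[annotation$gene_region == gr]
  }
  subs$promoter <- id[annotation$gene_region %in%
                        c("TSS200", "TSS1500", "5'UTR", "1stExon")]
  subs$snp_probe <- id[annotation$snp_flag]
  subs$crossreactive <- id[annotation$crossreactive_flag]
  subs$all_no_snp <- setdiff(id, subs$snp_probe)
  attr(subs, "counts") <- vapply(subs, length, integer(1))
  class(subs) <- "feature_subsets"
  subs
}

#' Quartile categorisation against the control distribution
#'
#' Quartile boundaries are the 25/50/75% sample quantiles (linear
#' interpolation) of the **control** values only; all samples are then
#' labelled by those boundaries, with values exactly on a boundary
#' assigned to the lower quartile.
#'
#' @param values Named per-sample exposure vector.
#' @param control_ids Sample IDs of the controls (>= 4, non-degenerate).
#' @return List with `labels` (factor Q1..Q4 per sample) and `boundaries`
#'   (length-3 numeric).
#' @export
quartile_categorize <- function(values, control_ids) {
  ctrl <- values[intersect(names(values), control_ids)]
  if (length(ctrl) < 4L) stop("need >= 4 controls for quartile boundaries")
  if (stats::sd(ctrl) == 0) stop("degenerate (zero-variance) control distribution")
  b <- stats::quantile(ctrl, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  labels <- cut(values, breaks = c(-Inf, b, Inf),
                labels = paste0("Q", 1:4), right = TRUE)
  names(labels) <- names(values)
  list(labels = labels, boundaries = b)
}

#' Pseudo-continuous per-SD exposure from quartile labels
#'
#' Each sample's exposure becomes the median of its quartile's control
#' values ("pseudo-continuous" quartile medians), then centred and scaled
#' by the mean and SD of the per-sample methylation distribution so a
#' one-unit change is one SD. By default the mean/SD come from controls
#' only; `scale_on = "all"` uses all subjects.
#'
#' @param labels Quartile labels from [quartile_categorize()].
#' @param values The underlying per-sample exposure values.
#' @param control_ids Control sample IDs.
#' @param scale_on `"controls"` (default) or `"all"`: whose mean/SD define
#'   the standardisation.
#' @return List with `exposure` (named standardized vector, exactly 4
#'   distinct values), `quartile_medians`, `center`, `scale`.
#' @export
pseudo_continuous <- function(labels, values, control_ids,
                              scale_on = c("controls", "all")) {
  scale_on <- match.arg(scale_on)
  ctrl <- values[intersect(names(values), control_ids)]
  med <- vapply(paste0("Q", 1:4), function(q) {
    v <- ctrl[labels[names(ctrl)] == q]
    if (length(v) == 0L) stop("empty quartile ", q, " among controls")
    stats::median(v)
  }, numeric(1))
  ref <- if (scale_on == "controls") ctrl else values
  ctr <- mean(ref)
  scl <- stats::sd(ref)
  expo <- (med[as.character(labels)] - ctr) / scl
  names(expo) <- names(labels)
  list(exposure = expo, quartile_medians = med, center = ctr, scale = scl)
}
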