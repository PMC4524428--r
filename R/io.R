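#' Read a beta-value matrix from TSV
#'
#' The on-disk layout is one row per probe: a `probe_id` column followed by
#' one column per sample, values in \[0,1\] or `NA` for missing.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix (probes x samples) with probe IDs as rownames and
#'   sample IDs as colnames; missing values are `NA`.
#' @export
read_beta_matrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA",
                          colClasses = list(character = 1))
  if (ncol(dt) < 2L) stop("beta matrix file needs a probe_id column plus >=1 sample column")
  ids <- dt[[1L]]
  if (anyDuplicated(ids)) stop("duplicated probe IDs in ", path)
  m <- as.matrix(dt[, -1L, with = FALSE])
  if (!is.numeric(m)) stop("non-numeric beta values in ", path)
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("beta value outside [0,1] at probe ", ids[bad[1L, 1L]],
         ", sample ", colnames(m)[bad[1L, 2L]])
  }
  rownames(m) <- ids
  m
}

#' Write a beta-value matrix to TSV
#'
#' @param m Numeric probes x samples matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  dt <- data.table::data.table(probe_id = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' Required columns: `sample_id`, `pair_id`, `status` (case/control),
#' `age_at_draw`, `followup` (person-years). Cases may carry
#' `time_to_diagnosis`; `chip_id` and `position_on_chip` are used as
#' technical covariates when present. Every `pair_id` must appear exactly
#' twice, once as a case and once as a control, and follow-up must be
#' positive.
#'
#' @param path CSV path.
#' @return A `data.frame` with `status` as a factor (control, case).
#' @export
read_sample_sheet <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = ",", header = TRUE))
  validate_sample_sheet(df)
}

#' Validate an in-memory sample sheet
#'
#' @param df A data frame with the columns documented in
#'   [read_sample_sheet()].
#' @return The validated data frame, `status` coerced to factor.
#' @export
validate_sample_sheet <- function(df) {
  req <- c("sample_id", "pair_id", "status", "age_at_draw", "followup")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in sample sheet")
  if (!all(df$status %in% c("case", "control"))) {
    stop("status must be 'case' or 'control'")
  }
  if (anyNA(df$followup) || any(df$followup <= 0)) {
    stop("followup must be present and > 0 for every sample")
  }
  tab <- table(df$pair_id, df$status)
  bad <- rownames(tab)[tab[, "case"] != 1L | tab[, "control"] != 1L]
  if (length(bad)) {
    stop("pairs without exactly one case and one control: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  df$status <- factor(df$status, levels = c("control", "case"))
  df
}

#' Read a Bismark-style coverage file as a WGBS pool
#'
#' Expects six tab-separated columns: chromosome, start, end (1-based
#' inclusive), methylation percentage, methylated read count, unmethylated
#' read count. Counts are authoritative; a methylation percentage that
#' disagrees with the counts by more than 0.1 raises a warning and the
#' counts win.
#'
#' @param path Coverage TSV path.
#' @param label Pool label stored on the result.
#' @return A `wgbs_pool`: data.frame with columns `chrom`, `pos`,
#'   `methylated`, `total`, `meth_fraction`.
#' @export
read_coverage_file <- function(path, label = basename(path)) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "meth_pct",
                                        "count_meth", "count_unmeth"))
  if (nrow(dt) == 0L) {
    return(new_wgbs_pool(character(), integer(), integer(), integer(), label))
  }
  if (any(dt$count_meth < 0 | dt$count_unmeth < 0)) {
    stop("negative read count in ", path)
  }
  total <- dt$count_meth + dt$count_unmeth
  pct <- ifelse(total > 0, 100 * dt$count_meth / total, 0)
  off <- abs(pct - dt$meth_pct) > 0.1
  if (any(off)) {
    warning(sum(off), " site(s) in ", path,
            " have methylation% inconsistent with counts; counts used")
  }
  new_wgbs_pool(as.character(dt$chrom), dt$start, dt$count_meth, total, label)
}

#' Construct a WGBS pool object
#'
#' @param chrom Chromosome per site.
#' @param pos 1-based CpG position per site.
#' @param methylated Methylated read counts.
#' @param total Total read counts.
#' @param label Pool label.
#' @return A `wgbs_pool` data.frame.
#' @export
new_wgbs_pool <- function(chrom, pos, methylated, total, label = "pool") {
  stopifnot(length(chrom) == length(pos), length(pos) == length(methylated),
            length(methylated) == length(total))
  if (any(methylated > total)) stop("methylated reads exceed total reads")
  if (anyDuplicated(paste(chrom, pos))) stop("duplicate positions in pool")
  pool <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                     methylated = as.integer(methylated),
                     total = as.integer(total))
  pool$meth_fraction <- ifelse(pool$total > 0, pool$methylated / pool$total, NA_real_)
  attr(pool, "label") <- label
  class(pool) <- c("wgbs_pool", "data.frame")
  pool
}

#' Write a WGBS pool in Bismark coverage layout
#'
#' @param pool A `wgbs_pool`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_file <- function(pool, path) {
  stopifnot(inherits(pool, "wgbs_pool"))
  dt <- data.table::data.table(
    chrom = pool$chrom, start = pool$pos, end = pool$pos,
    meth_pct = round(ifelse(pool$total > 0, 100 * pool$methylated / pool$total, 0), 6),
    count_meth = pool$methylated,
    count_unmeth = pool$total - pool$methylated)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' @param path YAML file with paths, thresholds and the seed for a run.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Log one pipeline stage with in/out counts
#'
#' @param stage Stage label.
#' @param n_in,n_out Item counts entering and leaving the stage.
#' @param what What is being counted ("probes", "samples", ...).
#' @return Invisibly, the formatted line.
#' @export
log_stage <- function(stage, n_in, n_out, what = "items") {
  line <- sprintf("[%s] %s: %d -> %d %s (%d removed)",
                  format(Sys.time(), "%H:%M:%S"), stage, n_in, n_out, what,
                  n_in - n_out)
  message(line)
  invisible(line)
}
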