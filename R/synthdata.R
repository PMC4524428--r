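#' Simulation configuration for a matched case-control methylation study
#'
#' Defaults emulate a prospective nested case-control design of the size
#' and structure used in blood-based 450k studies of breast cancer risk:
#' 162 matched pairs, an injected case hypomethylation concentrated in
#' gene-body/shelf/open-sea probes of about -0.2% genome-wide mean beta,
#' chip batch effects, within-pair correlation, variable white-cell
#' composition and missingness.
#'
#' @param n_pairs Number of matched case-control pairs (>= 2).
#' @param n_probes Number of array probes (>= 100).
#' @param effect_logor_per_sd Log odds of case status per 1 SD of
#'   genome-wide mean methylation (0 disables conditional case
#'   assignment). ln(0.61) reproduces a protective per-SD OR of 0.61.
#' @param mean_shift_by_category Named numeric: additive case shift on the
#'   natural-logit scale per island-relation category
#'   (island/shore/shelf/none) and/or gene-region category. Categories not
#'   named get 0. The default (-0.029 on gene-body, shelf and open-sea
#'   probes) yields a genome-wide mean beta difference of about -0.2
#'   percentage points in cases.
#' @param batch_count Number of chips/batches.
#' @param batch_sd SD of the per-probe, per-batch logit offsets.
#' @param pair_sd SD of the shared within-pair random effect (logit scale).
#' @param subject_global_sd SD of the per-subject genome-wide methylation
#'   offset (logit scale, shared across all probes of one subject). Together
#'   with `pair_sd` this sets the per-sample genome-wide mean SD (defaults
#'   give about 0.4 percentage points at genome scale) and the within-pair
#'   correlation of the mean exposure (about 0.4 at genome scale).
#' @param subject_sd SD of the residual per-probe subject noise (logit
#'   scale).
#' @param missing_rate Completely-at-random missingness fraction.
#' @param celltype_count Number of white-cell types in the composition
#'   model.
#' @param seed Integer RNG seed; a fixed seed makes every generator
#'   bit-reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pairs = 162L, n_probes = 2000L,
                       effect_logor_per_sd = 0,
                       mean_shift_by_category = c(body = -0.029,
                                                  shelf = -0.029,
                                                  none = -0.029),
                       batch_count = 4L, batch_sd = 0.05,
                       pair_sd = 0.024, subject_global_sd = 0.029,
                       subject_sd = 0.35,
                       missing_rate = 0.01, celltype_count = 3L,
                       seed = 1L) {
  stopifnot(n_pairs >= 2L, n_probes >= 100L,
            missing_rate >= 0, missing_rate < 1,
            batch_count >= 1L, batch_sd >= 0, pair_sd >= 0,
            subject_global_sd >= 0, subject_sd > 0)
  structure(list(n_pairs = as.integer(n_pairs),
                 n_probes = as.integer(n_probes),
                 effect_logor_per_sd = effect_logor_per_sd,
                 mean_shift_by_category = mean_shift_by_category,
                 batch_count = as.integer(batch_count), batch_sd = batch_sd,
                 pair_sd = pair_sd, subject_global_sd = subject_global_sd,
                 subject_sd = subject_sd,
                 missing_rate = missing_rate,
                 celltype_count = as.integer(celltype_count),
                 seed = as.integer(seed)),
            class = "sim_config")
}

GENE_REGIONS <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR",
                  "Intergenic")
ISLAND_CATEGORIES <- c("island", "shore", "shelf", "none")

#' Generate a synthetic probe annotation table
#'
#' Assigns each probe one island-relation category, one gene-region
#' category, an Infinium design type, a chromosome with strictly
#' increasing coordinates, and SNP / cross-reactive exclusion flags.
#' Default island-relation weights follow the approximate composition of
#' the 450k array (~31% island, 24% shore, 9% shelf, 36% open sea).
#'
#' @param n_probes Number of probes.
#' @param category_weights Nonnegative weights for island/shore/shelf/none.
#' @param region_weights Nonnegative weights over the gene-region
#'   categories (TSS1500, TSS200, 5'UTR, 1stExon, Body, 3'UTR, Intergenic).
#' @param seed RNG seed.
#' @return `probe_annotation` data.frame with columns `probe_id`, `chrom`,
#'   `pos`, `design`, `island_relation`, `gene_region`, `snp_flag`,
#'   `crossreactive_flag`.
#' @export
generate_annotation <- function(n_probes,
                                category_weights = c(island = 0.31,
                                                     shore = 0.24,
                                                     shelf = 0.09,
                                                     none = 0.36),
                                region_weights = c(TSS1500 = 0.15,
                                                   TSS200 = 0.11,
                                                   "5'UTR" = 0.09,
                                                   "1stExon" = 0.05,
                                                   Body = 0.34,
                                                   "3'UTR" = 0.04,
                                                   Intergenic = 0.22),
                                seed = 1L) {
  stopifnot(n_probes >= 1L)
  if (any(category_weights < 0) || sum(category_weights) <= 0) {
    stop("category weights must be nonnegative with positive sum")
  }
  if (any(region_weights < 0) || sum(region_weights) <= 0) {
    stop("region weights must be nonnegative with positive sum")
  }
  cw <- rep(0, 4); names(cw) <- ISLAND_CATEGORIES
  cw[names(category_weights)] <- category_weights
  rw <- rep(0, length(GENE_REGIONS)); names(rw) <- GENE_REGIONS
  rw[names(region_weights)] <- region_weights

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  island <- sample(ISLAND_CATEGORIES, n_probes, replace = TRUE,
                   prob = cw / sum(cw))
  region <- sample(GENE_REGIONS, n_probes, replace = TRUE, prob = rw / sum(rw))
  design <- sample(c("I", "II"), n_probes, replace = TRUE, prob = c(0.28, 0.72))
  chrom <- sort(sample(paste0("chr", 1:22), n_probes, replace = TRUE))
  # strictly increasing positions within chromosome
  pos <- integer(n_probes)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- cumsum(sample(50:5000, length(idx), replace = TRUE))
  }
  ann <- data.frame(
    probe_id = sprintf("cg%08d", seq_len(n_probes)),
    chrom = chrom, pos = pos, design = design,
    island_relation = island, gene_region = region,
    snp_flag = stats::runif(n_probes) < 0.012,
    crossreactive_flag = stats::runif(n_probes) < 0.06)
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Per-probe baseline on the natural-logit scale: three-component mixture
# (unmethylated / intermediate / methylated), with category-dependent
# mixing so islands are mostly unmethylated and gene bodies mostly
# methylated, as on the real array.
probe_baseline_logit <- function(annotation) {
  n <- nrow(annotation)
  mix <- matrix(c(0.15, 0.15, 0.70), n, 3, byrow = TRUE) # default: mostly high
  isl <- annotation$island_relation == "island"
  sho <- annotation$island_relation == "shore"
  mix[isl, ] <- rep(c(0.75, 0.15, 0.10), each = sum(isl))
  mix[sho, ] <- rep(c(0.40, 0.25, 0.35), each = sum(sho))
  body <- annotation$gene_region %in% c("Body", "3'UTR")
  mix[body & !isl, ] <- rep(c(0.08, 0.12, 0.80), each = sum(body & !isl))
  u <- stats::runif(n)
  comp <- 1L + (u > mix[, 1L]) + (u > mix[, 1L] + mix[, 2L])
  mu <- c(-2.6, 0, 2.2)[comp] + stats::rnorm(n, 0, 0.4)
  mu
}

#' Generate a matched-pair beta matrix and sample sheet
#'
#' Subjects are generated in case-control pairs sharing an age and a pair
#' random effect. Per-probe baselines come from a three-component logit
#' mixture with category-dependent mixing; chips add per-probe random
#' offsets; case status is assigned within each pair either at random or,
#' when `effect_logor_per_sd` is nonzero, with conditional probability
#' determined by the pair members' genome-wide mean methylation (so the
#' per-SD conditional log odds ratio equals `effect_logor_per_sd`). Cases
#' then receive `mean_shift_by_category` on the logit scale. Missingness
#' is applied completely at random.
#'
#' @param cfg A [sim_config()].
#' @param annotation A probe annotation from [generate_annotation()];
#'   defaults to one generated from `cfg`.
#' @return List with `beta` (probes x 2*n_pairs matrix), `sheet` (sample
#'   sheet data.frame) and `truth` (list of injected parameters).
#' @export
generate_pairs <- function(cfg, annotation = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  if (is.null(annotation)) {
    annotation <- generate_annotation(cfg$n_probes, seed = cfg$seed + 1L)
  }
  set.seed(cfg$seed)
  np <- cfg$n_pairs
  nprobe <- nrow(annotation)
  n <- 2L * np

  mu <- probe_baseline_logit(annotation)

  # pairs are laid out on chips; chip = batch
  chip <- rep(seq_len(cfg$batch_count), length.out = np)
  chip <- chip[order(chip)]
  batch_off <- matrix(stats::rnorm(nprobe * cfg$batch_count, 0, cfg$batch_sd),
                      nprobe, cfg$batch_count)

  pair_eff <- stats::rnorm(np, 0, cfg$pair_sd)
  age_pair <- stats::rnorm(np, 55, 8)

  # member A and B logit matrices (probes x pairs); each subject carries a
  # genome-wide offset (individual global methylation level) on top of the
  # shared pair effect and per-probe noise
  globA <- stats::rnorm(np, 0, cfg$subject_global_sd)
  globB <- stats::rnorm(np, 0, cfg$subject_global_sd)
  noiseA <- matrix(stats::rnorm(nprobe * np, 0, cfg$subject_sd), nprobe, np)
  noiseB <- matrix(stats::rnorm(nprobe * np, 0, cfg$subject_sd), nprobe, np)
  base <- mu + rep(pair_eff, each = nprobe) + batch_off[, chip]
  logitA <- base + rep(globA, each = nprobe) + noiseA
  logitB <- base + rep(globB, each = nprobe) + noiseB

  xbarA <- colMeans(stats::plogis(logitA))
  xbarB <- colMeans(stats::plogis(logitB))
  if (cfg$effect_logor_per_sd != 0) {
    sd_x <- stats::sd(c(xbarA, xbarB))
    b <- cfg$effect_logor_per_sd / sd_x
    p_A_case <- stats::plogis(b * (xbarA - xbarB))
    a_is_case <- stats::runif(np) < p_A_case
  } else {
    a_is_case <- stats::runif(np) < 0.5
  }

  # case shift by category, natural-logit scale
  shift <- numeric(nprobe)
  sh <- cfg$mean_shift_by_category
  for (nm in names(sh)) {
    hit <- annotation$island_relation == nm |
      tolower(annotation$gene_region) == tolower(nm) |
      (nm %in% c("body", "gene_body") & annotation$gene_region == "Body")
    shift[hit] <- shift[hit] + sh[[nm]]
  }
  case_logit <- ifelse(rep(a_is_case, each = nprobe), logitA, logitB) + shift
  ctrl_logit <- ifelse(rep(a_is_case, each = nprobe), logitB, logitA)
  beta_case <- stats::plogis(matrix(case_logit, nprobe, np))
  beta_ctrl <- stats::plogis(matrix(ctrl_logit, nprobe, np))

  beta <- matrix(NA_real_, nprobe, n)
  beta[, seq(1L, n, by = 2L)] <- beta_case
  beta[, seq(2L, n, by = 2L)] <- beta_ctrl
  rownames(beta) <- annotation$probe_id
  sample_id <- sprintf("S%04d_%s", rep(seq_len(np), each = 2L),
                       rep(c("case", "ctrl"), np))
  colnames(beta) <- sample_id

  if (cfg$missing_rate > 0) {
    mask <- stats::runif(length(beta)) < cfg$missing_rate
    beta[mask] <- NA_real_
  }

  ttd <- stats::runif(np, 0.5, 15)
  fu_ctrl <- stats::runif(np, 5, 16)
  sheet <- data.frame(
    sample_id = sample_id,
    pair_id = sprintf("P%04d", rep(seq_len(np), each = 2L)),
    status = rep(c("case", "control"), np),
    age_at_draw = round(rep(age_pair, each = 2L) +
                          stats::runif(n, -2.5, 2.5), 1),
    followup = as.vector(rbind(ttd, fu_ctrl)),
    time_to_diagnosis = as.vector(rbind(ttd, rep(NA_real_, np))),
    chip_id = sprintf("chip%02d", rep(chip, each = 2L)),
    position_on_chip = rep(c("R01", "R02", "R03", "R04", "R05", "R06"),
                           length.out = n))
  sheet <- validate_sample_sheet(sheet)
  list(beta = beta, sheet = sheet,
       truth = list(effect_logor_per_sd = cfg$effect_logor_per_sd,
                    mean_shift_by_category = cfg$mean_shift_by_category,
                    chip = chip, annotation = annotation))
}

#' Generate a matched case-control pool of WGBS coverage data
#'
#' Per-site read depth is drawn from a negative binomial (mean
#' `depth_mean`, mild overdispersion); methylated reads are binomial given
#' the site's true methylation. Sites carry island/body/other labels; the
#' case pool's true methylation is shifted by `case_shift` (probability
#' scale) at gene-body sites.
#'
#' @param n_sites Number of CpG sites.
#' @param depth_mean Mean read depth (e.g. 50 for 50x pools).
#' @param case_shift Additive case shift in methylation fraction at
#'   gene-body sites (e.g. -0.004 for -0.4 percentage points).
#' @param seed RNG seed.
#' @param nb_size Negative-binomial size (dispersion) parameter.
#' @return List with `case` and `control` (`wgbs_pool` objects) and
#'   `sites` (data.frame chrom/pos/feature with the true methylation).
#' @export
generate_wgbs_pools <- function(n_sites, depth_mean = 50, case_shift = 0,
                                seed = 1L, nb_size = 20) {
  stopifnot(depth_mean > 0, n_sites >= 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  chrom <- sort(sample(paste0("chr", 1:22), n_sites, replace = TRUE))
  pos <- integer(n_sites)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- cumsum(sample(20:2000, length(idx), replace = TRUE))
  }
  feature <- sample(c("island", "body", "other"), n_sites, replace = TRUE,
                    prob = c(0.25, 0.4, 0.35))
  p_true <- numeric(n_sites)
  p_true[feature == "island"] <- stats::rbeta(sum(feature == "island"), 2, 8)
  p_true[feature == "body"] <- stats::rbeta(sum(feature == "body"), 8, 4)
  p_true[feature == "other"] <- stats::rbeta(sum(feature == "other"), 5, 5)

  p_case <- p_true
  p_case[feature == "body"] <- pmin(pmax(
    p_case[feature == "body"] + case_shift, 0), 1)

  draw_pool <- function(p, label) {
    total <- stats::rnbinom(n_sites, size = nb_size, mu = depth_mean)
    meth <- stats::rbinom(n_sites, total, p)
    new_wgbs_pool(chrom, pos, meth, total, label)
  }
  case <- draw_pool(p_case, "case_pool")
  control <- draw_pool(p_true, "control_pool")
  list(case = case, control = control,
       sites = data.frame(chrom = chrom, pos = pos, feature = feature,
                          p_true = p_true))
}

#' Generate a synthetic purified-cell reference panel
#'
#' Exactly `n_discriminating` probes receive a cell-type-specific beta
#' offset larger than 0.05 against the panel average; all other probes
#' differ between cell types only by measurement noise. Subject replicates
#' (default 6) are drawn per cell type, and a panel-average pseudo-sample
#' ("PBMC") is included as the regression baseline.
#'
#' @param annotation Probe annotation (defines probe IDs).
#' @param n_celltypes Number of purified cell types (>= 2).
#' @param n_discriminating Number of planted discriminating probes.
#' @param seed RNG seed.
#' @param n_replicates Subject replicates per cell type (default 6).
#' @param noise_sd Replicate measurement noise SD on the beta scale
#'   (default 0.01).
#' @param delta Planted absolute beta offset (default 0.2).
#' @return A `reference_panel`: list with `cell_types`, `profiles`
#'   (probe x celltype mean beta), `replicates` (probe x (celltype x rep)
#'   beta matrix), `replicate_type`, `discriminating` (planted probe IDs),
#'   `n_replicates`.
#' @export
generate_reference_panel <- function(annotation, n_celltypes = 3L,
                                     n_discriminating = 500L, seed = 1L,
                                     n_replicates = 6L, noise_sd = 0.01,
                                     delta = 0.2) {
  stopifnot(n_celltypes >= 2L, n_replicates >= 2L,
            n_discriminating <= nrow(annotation))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  nprobe <- nrow(annotation)
  base <- stats::plogis(probe_baseline_logit(annotation))
  base <- pmin(pmax(base, 0.05), 0.95)
  types <- paste0("CT", seq_len(n_celltypes))
  profiles <- matrix(base, nprobe, n_celltypes,
                     dimnames = list(annotation$probe_id, types))
  disc <- sort(sample.int(nprobe, n_discriminating))
  if (n_discriminating > 0L) {
    which_type <- sample.int(n_celltypes, n_discriminating, replace = TRUE)
    sign <- ifelse(base[disc] > 0.5, -1, 1)
    for (i in seq_len(n_discriminating)) {
      profiles[disc[i], which_type[i]] <- base[disc[i]] + sign[i] * delta
    }
  }
  profiles <- pmin(pmax(profiles, 0.001), 0.999)

  rep_type <- rep(types, each = n_replicates)
  reps <- profiles[, rep(seq_len(n_celltypes), each = n_replicates)] +
    matrix(stats::rnorm(nprobe * n_celltypes * n_replicates, 0, noise_sd),
           nprobe, n_celltypes * n_replicates)
  reps <- pmin(pmax(reps, 0), 1)
  colnames(reps) <- paste0(rep_type, "_rep", rep(seq_len(n_replicates),
                                                 n_celltypes))
  # baseline pseudo-samples: average the r-th replicate of each cell type
  pbmc <- vapply(seq_len(n_replicates), function(r) {
    rowMeans(reps[, (seq_len(n_celltypes) - 1L) * n_replicates + r,
                  drop = FALSE])
  }, numeric(nprobe))
  colnames(pbmc) <- paste0("PBMC_rep", seq_len(n_replicates))
  structure(list(cell_types = types, profiles = profiles,
                 replicates = cbind(reps, pbmc),
                 replicate_type = c(rep_type, rep("PBMC", n_replicates)),
                 discriminating = annotation$probe_id[disc],
                 n_replicates = as.integer(n_replicates)),
            class = "reference_panel")
}
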