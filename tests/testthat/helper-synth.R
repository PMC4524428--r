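# Shared fixture builders (all generated in code, no files).

make_sheet <- function(n_pairs, seed = 1L, chips = 2L) {
  set.seed(seed)
  n <- 2L * n_pairs
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    pair_id = rep(sprintf("P%03d", seq_len(n_pairs)), each = 2L),
    status = rep(c("case", "control"), n_pairs),
    age_at_draw = rnorm(n, 55, 5),
    followup = runif(n, 1, 12),
    # chips assigned per pair so chip is never confounded with status
    chip_id = rep(sprintf("chip%d", rep(seq_len(chips),
                                        length.out = n_pairs)), each = 2L))
}

make_beta <- function(n_probes, n_samples, seed = 1L, mean_logit = 0.4,
                      sd_logit = 0.3) {
  set.seed(seed)
  matrix(plogis(rnorm(n_probes * n_samples, mean_logit, sd_logit)),
         n_probes, n_samples,
         dimnames = list(sprintf("cg%05d", seq_len(n_probes)),
                         sprintf("S%03d", seq_len(n_samples))))
}

# Dense grid maximiser of the 1:1 conditional log-likelihood (univariate),
# the brute-force oracle for clogit_pairs.
grid_clogit <- function(d, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, function(b) sum(b * d - log1p(exp(b * d))), numeric(1))
  grid[which.max(ll)]
}
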