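# Fixture builders and independent oracles shared across the test files.
# Everything is generated in code; no data files.

# Bare harmonized-pairs data.frame for the estimator layer.
make_pairs <- function(beta_exp, beta_out, se_exp = 0.01, se_out = 0.01,
                       snp_id = NULL) {
  J <- length(beta_exp)
  data.frame(
    snp_id = snp_id %||% sprintf("snp%02d", seq_len(J)),
    beta_exp = beta_exp, se_exp = rep_len(se_exp, J),
    beta_out = beta_out, se_out = rep_len(se_out, J),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_sumstats <- function(snp_id, beta, se, pval, eaf = 0.3,
                          effect_allele = "A", other_allele = "G",
                          chrom = "1", pos = NULL, n = 1e5,
                          trait_id = "trait") {
  J <- length(snp_id)
  sumstats(data.frame(
    snp_id = snp_id, chrom = rep_len(chrom, J),
    pos = pos %||% (1e6 + (seq_len(J) - 1) * 1e5),
    effect_allele = rep_len(effect_allele, J),
    other_allele = rep_len(other_allele, J),
    eaf = rep_len(eaf, J), beta = rep_len(beta, J),
    se = rep_len(se, J), pval = rep_len(pval, J), n = rep_len(n, J),
    stringsAsFactors = FALSE), trait_id = trait_id)
}

# Independent IVW oracle: weighted least squares through the origin via lm().
ivw_oracle <- function(p) {
  fit <- stats::lm(beta_out ~ 0 + beta_exp, data = p,
                   weights = 1 / p$se_out^2)
  unname(stats::coef(fit)[1])
}

# Independent Cochran's Q oracle via the WLS residual form.
q_oracle <- function(p) {
  beta <- ivw_oracle(p)
  sum((p$beta_out - beta * p$beta_exp)^2 / p$se_out^2)
}

# Brute-force clumping oracle for small J: enumerate every maximal
# conflict-free subset and return the one a greedy-by-p (ties: snp_id)
# sweep prefers, i.e. the lexicographically smallest by p-rank sequence.
clump_oracle_ids <- function(df, r2, r2_threshold, window_kb) {
  J <- nrow(df)
  stopifnot(J <= 14)
  conflict <- matrix(FALSE, J, J)
  for (a in seq_len(J)) {
    for (b in seq_len(J)) {
      if (a == b) next
      conflict[a, b] <- df$chrom[a] == df$chrom[b] &&
        abs(df$pos[a] - df$pos[b]) <= window_kb * 1000 &&
        r2[df$snp_id[a], df$snp_id[b]] >= r2_threshold
    }
  }
  rank_order <- order(df$pval, df$snp_id)
  rank_of <- match(seq_len(J), rank_order)
  lex_less <- function(a, b) {
    n <- max(length(a), length(b))
    a <- c(a, rep(Inf, n - length(a)))
    b <- c(b, rep(Inf, n - length(b)))
    d <- which(a != b)
    length(d) > 0 && a[d[1]] < b[d[1]]
  }
  best <- NULL
  best_key <- NULL
  for (mask in seq_len(2^J) - 1) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(J) - 1L)) != 0L)
    if (length(idx) == 0) next
    if (length(idx) > 1 && any(conflict[idx, idx])) next
    outside <- setdiff(seq_len(J), idx)
    maximal <- all(vapply(outside, function(o) any(conflict[o, idx]),
                          logical(1)))
    if (!maximal) next
    key <- sort(rank_of[idx])
    if (is.null(best_key) || lex_less(key, best_key)) {
      best <- idx
      best_key <- key
    }
  }
  df$snp_id[sort(best)]
}

random_clump_instance <- function(seed) {
  set.seed(seed)
  J <- sample(3:12, 1)
  ids <- sprintf("v%02d", sample(seq_len(99), J))
  df <- data.frame(
    snp_id = ids,
    chrom = as.character(sample(1:2, J, replace = TRUE)),
    pos = sample(seq(1e6, 3e7, by = 1e5), J),
    pval = stats::runif(J, 1e-12, 1e-4),
    stringsAsFactors = FALSE)
  r2 <- matrix(0, J, J, dimnames = list(ids, ids))
  n_pairs <- sample(0:(J * 2), 1)
  for (k in seq_len(n_pairs)) {
    ab <- sample(J, 2)
    r2[ab[1], ab[2]] <- r2[ab[2], ab[1]] <- stats::runif(1)
  }
  diag(r2) <- 1
  ds <- make_sumstats(df$snp_id, beta = 0.05, se = 0.005,
                      pval = df$pval, chrom = df$chrom, pos = df$pos)
  # make_sumstats recycles; restore per-row values
  ds$chrom <- df$chrom
  ds$pos <- df$pos
  ds$pval <- df$pval
  list(ds = ds, df = df, ld = ld_matrix(r2, ids))
}

# Selection-pipeline audit fixture: 20 variants, two planted failures per
# filter stage (p, clump, outcome-association, MAF, F), ten survivors.
fixture_selection <- function() {
  ids <- sprintf("s%02d", 1:20)
  pval <- rep(1e-20, 20)
  eaf <- rep(0.30, 20)
  beta <- rep(0.050, 20)
  se <- rep(0.005, 20)
  pval[1:2] <- 1e-4                       # fail the p < 1e-5 filter
  pval[3] <- 1e-10; pval[4] <- 1e-20      # s03 clumped out by s04
  pval[5] <- 1e-10; pval[6] <- 1e-20      # s05 clumped out by s06
  eaf[9] <- 0.005; eaf[10] <- 0.996       # fail MAF >= 0.01
  beta[11:12] <- 0.010; se[11:12] <- 0.0045  # F = 4.94 < 10
  exposure <- make_sumstats(ids, beta = beta, se = se, pval = pval,
                            eaf = eaf, pos = 1e6 + (0:19) * 1e5,
                            trait_id = "exposure")
  exposure$beta <- beta; exposure$se <- se
  exposure$pval <- pval; exposure$eaf <- eaf
  out_p <- rep(0.5, 20)
  out_p[7:8] <- 1e-7                      # outcome-associated
  outcome <- make_sumstats(ids, beta = 0.001, se = 0.005, pval = out_p,
                           pos = 1e6 + (0:19) * 1e5, trait_id = "outcome")
  outcome$pval <- out_p
  r2 <- diag(20)
  dimnames(r2) <- list(ids, ids)
  r2["s03", "s04"] <- r2["s04", "s03"] <- 0.9
  r2["s05", "s06"] <- r2["s06", "s05"] <- 0.9
  expected <- rep("kept", 20)
  expected[1:2] <- "failed-p"
  expected[3] <- "clumped-out-by:s04"
  expected[5] <- "clumped-out-by:s06"
  expected[7:8] <- "outcome-associated"
  expected[9:10] <- "failed-maf"
  expected[11:12] <- "failed-f"
  list(exposure = exposure, outcome = outcome, ld = ld_matrix(r2, ids),
       expected = stats::setNames(expected, ids))
}

# Minimal mr_sensitivity object for decision-layer tests.
make_sensitivity <- function(q_pval = 0.5, intercept_pval = 0.5,
                             presso = NULL) {
  structure(list(q_stat = 1, q_df = 9, q_pval = q_pval,
                 egger_intercept = 0, egger_intercept_se = 0.01,
                 egger_intercept_pval = intercept_pval,
                 presso = presso, loo = NULL, not_computed = character()),
            class = "mr_sensitivity")
}

make_result <- function(ivw_p = 0.01, wm_p = 0.01, egger_p = 0.2,
                        beta = 0.1, egger_beta = beta, wm_beta = beta,
                        exposure_id = "X", outcome_id = "Y") {
  z <- function(p) stats::qnorm(1 - p / 2)
  mk <- function(m, b, p) mr_estimate(m, 10, b, abs(b) / z(p))
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 estimates = list(ivw = mk("IVW", beta, ivw_p),
                                  egger = mk("MR-Egger", egger_beta, egger_p),
                                  weighted_median = mk("Weighted median",
                                                       wm_beta, wm_p)),
                 not_computed = character()),
            class = "mr_result")
}

# Plain data.frame view (attributes stripped) for equality checks.
ss_frame <- function(d) {
  d <- as.data.frame(d)
  out <- data.frame(d, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- "data.frame"
  attr(out, "trait_id") <- NULL
  attr(out, "trait_name") <- NULL
  attr(out, "metadata") <- NULL
  out
}
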