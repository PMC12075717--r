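# Synthetic GWAS summary statistics with known causal structure, simulated
# directly in summary space: per-variant true effects plus sampling noise
# with standard errors driven by allele frequency and GWAS sample size.

#' Define a simulation scenario
#'
#' The generative model: `n_snp` exposure instruments receive true
#' exposure effects `gamma_j ~ N(0, gamma_sd^2)`; an optional further
#' `n_snp_med` mediator-specific instruments receive true mediator effects
#' `delta_j ~ N(0, delta_sd^2)` and no exposure effect. True per-variant
#' effects on the three traits are then
#' exposure `gamma_j`;
#' mediator `beta_xm * gamma_j + delta_j`;
#' outcome `(beta_direct + beta_xm * beta_my) * gamma_j +
#'          beta_my * delta_j + sign(gamma_j) * alpha_j`,
#' where `alpha_j ~ N(pleiotropy_mean, pleiotropy_sd^2)` are direct
#' (horizontal-pleiotropy) variant-outcome effects on the exposure
#' instruments, stated on the exposure-increasing allele orientation (the
#' convention under which a non-zero `pleiotropy_mean` is directional in
#' the MR-Egger sense rather than cancelling across allele codings). Observed effects add sampling noise with
#' `se = 1 / sqrt(2 * maf * (1 - maf) * n_trait)` (the standardized-trait
#' approximation; for a binary outcome read `n` as effective sample size).
#' `outlier_count` planted outliers shift the observed outcome effect by
#' `outlier_shift_se` outcome standard errors. LD is block-diagonal with
#' `ld_within_r2` off-diagonal within blocks of `ld_block_size`.
#'
#' @param n_snp number of exposure instruments.
#' @param n_snp_med number of mediator-specific instruments (0 unless the
#'   scenario exercises mediation).
#' @param gamma_sd SD of true variant-exposure effects.
#' @param delta_sd SD of true mediator-specific effects.
#' @param maf_range minor-allele-frequency interval, within (0, 0.5].
#' @param n_exp,n_med,n_out GWAS sample sizes for the three traits.
#' @param beta_xm true exposure->mediator effect (the mediation beta1).
#' @param beta_my true mediator->outcome effect (beta2).
#' @param beta_direct direct exposure->outcome effect not through the
#'   mediator; the true total effect is
#'   `beta_all_true = beta_direct + beta_xm * beta_my`.
#' @param pleiotropy_mean,pleiotropy_sd mean and SD of direct
#'   variant-outcome effects (balanced pleiotropy: mean 0, sd > 0;
#'   directional: mean != 0).
#' @param outlier_count,outlier_shift_se planted outliers and their shift
#'   in outcome-SE units.
#' @param ld_block_size,ld_within_r2 block LD structure.
#' @param include_palindromic also draw strand-ambiguous (A/T, C/G) allele
#'   pairs with probability 0.2 per variant (default FALSE).
#' @param label scenario name carried through to datasets.
#' @return A list of class `sim_scenario`.
#' @seealso [sim_preset()] for the documented named scenarios.
#' @export
sim_scenario <- function(n_snp = 30, n_snp_med = 0, gamma_sd = 0.05,
                         delta_sd = 0.15, maf_range = c(0.1, 0.4),
                         n_exp = 5e5, n_med = 2e4, n_out = 1e5,
                         beta_xm = 0, beta_my = 0, beta_direct = 0,
                         pleiotropy_mean = 0, pleiotropy_sd = 0,
                         outlier_count = 0, outlier_shift_se = 0,
                         ld_block_size = 1, ld_within_r2 = 0,
                         include_palindromic = FALSE, label = "custom") {
  if (n_snp < 1) stop("n_snp must be >= 1", call. = FALSE)
  if (n_snp_med < 0) stop("n_snp_med must be >= 0", call. = FALSE)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be an interval within (0, 0.5]", call. = FALSE)
  }
  for (nm in c("n_exp", "n_med", "n_out")) {
    if (get(nm) < 2) stop(nm, " must be >= 2", call. = FALSE)
  }
  if (outlier_count > n_snp) {
    stop("outlier_count cannot exceed n_snp", call. = FALSE)
  }
  if (ld_within_r2 < 0 || ld_within_r2 > 1) {
    stop("ld_within_r2 must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_snp = as.integer(n_snp),
                 n_snp_med = as.integer(n_snp_med),
                 gamma_sd = gamma_sd, delta_sd = delta_sd,
                 maf_range = maf_range, n_exp = n_exp, n_med = n_med,
                 n_out = n_out, beta_xm = beta_xm, beta_my = beta_my,
                 beta_direct = beta_direct,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 outlier_count = as.integer(outlier_count),
                 outlier_shift_se = outlier_shift_se,
                 ld_block_size = as.integer(ld_block_size),
                 ld_within_r2 = ld_within_r2,
                 include_palindromic = isTRUE(include_palindromic),
                 label = label),
            class = "sim_scenario")
}

#' Named simulation presets
#'
#' Fixed, documented scenarios used throughout calibration and validation:
#' \describe{
#'   \item{null}{no causal effect, no pleiotropy; type-I-error and
#'     coverage calibration.}
#'   \item{effect}{direct exposure->outcome effect `log(1.17)`, the size
#'     of a modest microbial-taxon association with disease risk.}
#'   \item{balanced-pleiotropy}{zero-mean direct variant-outcome effects
#'     (InSIDE holds; Egger intercept should stay null-calibrated).}
#'   \item{directional-strong}{mean pleiotropy 0.01 per variant; the Egger
#'     intercept test should reject in most replicates.}
#'   \item{single-outlier}{one variant whose outcome effect is displaced
#'     by 10 SE; MR-PRESSO should flag it.}
#'   \item{paper-mediation}{an exposure->mediator->outcome chain with
#'     beta1 = -0.19, beta2 = -0.05 and direct effect 0.147, so the true
#'     total effect is about log(1.17) and the true mediated proportion
#'     about 6.1\% — the magnitude of a gut-microbiota effect on
#'     colorectal-cancer risk partially mediated by an immune-cell
#'     phenotype.}
#'   \item{suppression}{indirect and total effects of opposite sign
#'     (beta1 = 0.2, beta2 = 0.1, direct = -0.1), the degenerate case a
#'     signed mediated proportion must flag rather than hide.}
#' }
#'
#' @param name one of the preset names above.
#' @return A [sim_scenario()].
#' @export
sim_preset <- function(name) {
  switch(name,
    "null" = sim_scenario(label = "null"),
    "effect" = sim_scenario(beta_direct = log(1.17), label = "effect"),
    "balanced-pleiotropy" = sim_scenario(pleiotropy_sd = 0.005,
                                         label = "balanced-pleiotropy"),
    "directional-strong" = sim_scenario(pleiotropy_mean = 0.01,
                                        pleiotropy_sd = 0.005,
                                        label = "directional-strong"),
    "single-outlier" = sim_scenario(outlier_count = 1,
                                    outlier_shift_se = 10,
                                    label = "single-outlier"),
    "paper-mediation" = sim_scenario(n_snp_med = 30, beta_xm = -0.19,
                                     beta_my = -0.05, beta_direct = 0.147,
                                     label = "paper-mediation"),
    "suppression" = sim_scenario(n_snp_med = 30, beta_xm = 0.2,
                                 beta_my = 0.1, beta_direct = -0.1,
                                 label = "suppression"),
    stop("unknown preset: ", name, call. = FALSE))
}

NONPALINDROMIC_PAIRS <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                                 "G", "A", "C", "A", "G", "T", "C", "T"),
                               ncol = 2, byrow = TRUE)
PALINDROMIC_PAIRS <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                            ncol = 2, byrow = TRUE)

#' Simulate a three-trait summary-statistics study
#'
#' Draws one synthetic study — exposure, mediator and outcome summary
#' statistics over a shared variant panel, a block LD matrix, and the full
#' generative truth — from a [sim_scenario()]. Fully deterministic given
#' `(scenario, seed)`.
#'
#' @param scenario a [sim_scenario()].
#' @param seed integer seed.
#' @return A list of class `sim_study` with elements `exposure`,
#'   `mediator`, `outcome` (each a [sumstats()]), `ld` (an
#'   [ld_matrix()]) and `truth` (scenario, per-variant true effects,
#'   planted outlier ids, `beta_all_true` and `prop_true`).
#' @export
simulate_study <- function(scenario, seed = 1) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  set.seed(as.integer(seed))
  J <- sc$n_snp + sc$n_snp_med
  is_med_snp <- c(rep(FALSE, sc$n_snp), rep(TRUE, sc$n_snp_med))
  snp_id <- sprintf("rs%05d", seq_len(J))
  maf <- stats::runif(J, sc$maf_range[1], sc$maf_range[2])
  eaf <- ifelse(stats::runif(J) < 0.5, maf, 1 - maf)

  gamma <- ifelse(is_med_snp, 0, stats::rnorm(J, 0, sc$gamma_sd))
  delta <- ifelse(is_med_snp, stats::rnorm(J, 0, sc$delta_sd), 0)
  alpha <- ifelse(is_med_snp, 0,
                  if (sc$pleiotropy_sd > 0 || sc$pleiotropy_mean != 0) {
                    stats::rnorm(J, sc$pleiotropy_mean, sc$pleiotropy_sd)
                  } else 0)

  beta_all_true <- sc$beta_direct + sc$beta_xm * sc$beta_my
  true_exp <- gamma
  true_med <- sc$beta_xm * gamma + delta
  # Pleiotropy is defined on the exposure-increasing allele orientation
  # (the convention under which "directional" pleiotropy is detectable by
  # the Egger intercept); in raw effect-allele space it enters with the
  # sign of the variant's exposure effect.
  true_out <- beta_all_true * gamma + sc$beta_my * delta +
    ifelse(gamma < 0, -alpha, alpha)

  het <- 2 * maf * (1 - maf)
  se_exp <- 1 / sqrt(het * sc$n_exp)
  se_med <- 1 / sqrt(het * sc$n_med)
  se_out <- 1 / sqrt(het * sc$n_out)

  beta_exp <- stats::rnorm(J, true_exp, se_exp)
  beta_med <- stats::rnorm(J, true_med, se_med)
  beta_out <- stats::rnorm(J, true_out, se_out)

  outlier_ids <- character()
  if (sc$outlier_count > 0) {
    oi <- which(!is_med_snp)[sample.int(sc$n_snp, sc$outlier_count)]
    beta_out[oi] <- beta_out[oi] + sc$outlier_shift_se * se_out[oi]
    outlier_ids <- snp_id[oi]
  }

  pair_pool <- if (sc$include_palindromic) {
    rbind(NONPALINDROMIC_PAIRS, PALINDROMIC_PAIRS)
  } else NONPALINDROMIC_PAIRS
  draw <- if (sc$include_palindromic) {
    # 20% palindromic on average
    ifelse(stats::runif(J) < 0.2,
           nrow(NONPALINDROMIC_PAIRS) + sample.int(4, J, replace = TRUE),
           sample.int(nrow(NONPALINDROMIC_PAIRS), J, replace = TRUE))
  } else {
    sample.int(nrow(NONPALINDROMIC_PAIRS), J, replace = TRUE)
  }
  effect_allele <- pair_pool[draw, 1]
  other_allele <- pair_pool[draw, 2]

  block <- (seq_len(J) - 1) %/% sc$ld_block_size
  chrom <- as.character(1 + block %% 22)
  pos <- 1e6 + (seq_len(J) - 1) * 5e5
  r2 <- outer(block, block, function(a, b) {
    ifelse(a == b, sc$ld_within_r2, 0)
  })
  diag(r2) <- 1
  ld <- ld_matrix(r2, snp_id)

  mk <- function(beta, se, trait, n) {
    sumstats(data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                        effect_allele = effect_allele,
                        other_allele = other_allele, eaf = eaf,
                        beta = beta, se = se,
                        pval = p_from_z(beta / se), n = n,
                        stringsAsFactors = FALSE),
             trait_id = trait,
             trait_name = paste0(sc$label, " ", trait),
             metadata = list(scenario = sc$label, seed = seed))
  }
  truth <- list(scenario = sc, seed = seed, gamma = gamma, delta = delta,
                alpha = alpha, true_exp = true_exp, true_med = true_med,
                true_out = true_out, outlier_ids = outlier_ids,
                beta_all_true = beta_all_true,
                prop_true = if (beta_all_true != 0) {
                  100 * sc$beta_xm * sc$beta_my / beta_all_true
                } else NA_real_)
  structure(list(exposure = mk(beta_exp, se_exp, "exposure", sc$n_exp),
                 mediator = mk(beta_med, se_med, "mediator", sc$n_med),
                 outcome = mk(beta_out, se_out, "outcome", sc$n_out),
                 ld = ld, truth = truth),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  sc <- x$truth$scenario
  cat(sprintf(
    "Synthetic study '%s' (seed %s): %d+%d variants, beta_all_true = %.4f\n",
    sc$label, format(x$truth$seed), sc$n_snp, sc$n_snp_med,
    x$truth$beta_all_true))
  invisible(x)
}

#' Replicate an analysis stage over simulated studies
#'
#' Runs a named pipeline stage on `n_reps` independent studies drawn from
#' one scenario, with per-replicate seeds derived deterministically from
#' the root seed, and summarizes estimates against the generative truth.
#'
#' Stages: `"ivw"` (harmonize exposure/outcome, IVW), `"egger"`
#' (MR-Egger slope), `"egger_intercept"` (intercept test),
#' `"weighted_median"`, `"presso"` (MR-PRESSO; records the global p and
#' whether every planted outlier was flagged) and `"mediation"` (full
#' [run_mediation()] pipeline with instrument selection; records the
#' decomposition).
#'
#' @param scenario a [sim_scenario()].
#' @param n_reps number of replicates.
#' @param stage stage name, see above.
#' @param seed root seed.
#' @param n_sim MR-PRESSO simulations (stage `"presso"`).
#' @param config [selection_config()] (stage `"mediation"`).
#' @param alpha nominal test level used for the rejection-rate summary.
#' @return A list of class `mr_replication`: `reps` (one row per
#'   replicate) and `summary` (means, SDs, rejection rate, coverage of the
#'   true effect where applicable).
#' @export
mr_replicate <- function(scenario, n_reps, stage = "ivw", seed = 1,
                         n_sim = 1000, config = selection_config(),
                         alpha = 0.05) {
  stopifnot(inherits(scenario, "sim_scenario"), n_reps >= 1)
  truth_beta <- scenario$beta_direct + scenario$beta_xm * scenario$beta_my
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    rep_seed <- derive_seed(seed, i)
    study <- simulate_study(scenario, rep_seed)
    rows[[i]] <- tryCatch(switch(stage,
      ivw = , egger = , weighted_median = {
        hd <- harmonize(study$exposure, study$outcome)
        e <- switch(stage,
                    ivw = mr_ivw(hd),
                    egger = mr_egger(hd),
                    weighted_median =
                      mr_weighted_median(hd, n_boot = 500,
                                         seed = derive_seed(rep_seed, 7)))
        data.frame(rep = i, beta = e$beta, se = e$se, pval = e$pval,
                   reject = e$pval < alpha,
                   covered = e$ci_low <= truth_beta &
                     truth_beta <= e$ci_high)
      },
      egger_intercept = {
        hd <- harmonize(study$exposure, study$outcome)
        t <- egger_intercept_test(hd)
        data.frame(rep = i, beta = t$alpha, se = t$se_alpha,
                   pval = t$pval, reject = t$pval < alpha, covered = NA)
      },
      presso = {
        hd <- harmonize(study$exposure, study$outcome)
        pr <- mr_presso(hd, n_sim = n_sim,
                        seed = derive_seed(rep_seed, 7))
        data.frame(rep = i, beta = pr$estimate_raw$beta,
                   se = pr$estimate_raw$se, pval = pr$global_pval,
                   reject = pr$global_pval < alpha,
                   covered = length(study$truth$outlier_ids) > 0 &&
                     all(study$truth$outlier_ids %in% pr$outlier_ids),
                   n_outliers = length(pr$outlier_ids))
      },
      mediation = {
        m <- run_mediation(study$exposure, study$mediator, study$outcome,
                           ld = study$ld, config = config,
                           seed = derive_seed(rep_seed, 7))
        data.frame(rep = i, beta = m$beta_all, se = m$se_all,
                   pval = NA_real_, reject = NA, covered = NA,
                   beta1 = m$beta1, beta2 = m$beta2, beta12 = m$beta12,
                   prop = m$prop_mediated, prop_abs = m$prop_abs,
                   direction_consistent = m$direction_consistent)
      },
      stop("unknown stage: ", stage, call. = FALSE)),
      error = function(e) {
        data.frame(rep = i, beta = NA_real_, se = NA_real_,
                   pval = NA_real_, reject = NA, covered = NA)
      })
  }
  reps <- do.call(rbind, lapply(rows, function(r) {
    # pad columns so rbind succeeds across stages/errors
    all_cols <- unique(unlist(lapply(rows, names)))
    for (cn in setdiff(all_cols, names(r))) r[[cn]] <- NA
    r[all_cols]
  }))
  rownames(reps) <- NULL
  summary <- list(stage = stage, n_reps = n_reps,
                  n_failed = sum(is.na(reps$beta)),
                  mean_beta = mean(reps$beta, na.rm = TRUE),
                  sd_beta = stats::sd(reps$beta, na.rm = TRUE),
                  rejection_rate = mean(reps$reject, na.rm = TRUE),
                  coverage = mean(reps$covered, na.rm = TRUE),
                  truth_beta = truth_beta)
  if (stage == "mediation") {
    summary$mean_prop <- mean(reps$prop, na.rm = TRUE)
    summary$mean_prop_abs <- mean(reps$prop_abs, na.rm = TRUE)
    summary$prop_true <- if (truth_beta != 0) {
      100 * scenario$beta_xm * scenario$beta_my / truth_beta
    } else NA_real_
  }
  structure(list(reps = reps, summary = summary),
            class = "mr_replication")
}

#' @export
print.mr_replication <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Replication (%s, %d reps): mean beta %.4f (SD %.4f), reject %.3f, coverage %.3f\n",
    s$stage, s$n_reps, s$mean_beta, s$sd_beta, s$rejection_rate,
    s$coverage))
  if (!is.null(s$mean_prop)) {
    cat(sprintf("  mean mediated proportion %.2f%% (true %.2f%%)\n",
                s$mean_prop, s$prop_true))
  }
  invisible(x)
}

#' Write a simulated study to a directory
#'
#' Emits the three TSV datasets, the LD matrix and a JSON file with the
#' generative truth — the file layout the command-line `simulate`
#' subcommand produces.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sumstats(study$exposure, file.path(dir, "exposure.tsv"))
  write_sumstats(study$mediator, file.path(dir, "mediator.tsv"))
  write_sumstats(study$outcome, file.path(dir, "outcome.tsv"))
  write_ld_matrix(study$ld, file.path(dir, "ld.tsv"))
  tr <- study$truth
  jsonlite::write_json(
    list(scenario = unclass(tr$scenario), seed = tr$seed,
         beta_all_true = tr$beta_all_true, prop_true = tr$prop_true,
         outlier_ids = tr$outlier_ids,
         gamma = tr$gamma, delta = tr$delta, alpha = tr$alpha),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
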