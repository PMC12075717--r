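# Heterogeneity, pleiotropy, outlier and influence diagnostics.

#' Cochran's Q heterogeneity test
#'
#' Q = sum of `w_j (ratio_j - beta_IVW)^2` over per-variant Wald ratios
#' with inverse-variance weights, referred to a chi-square distribution on
#' J - 1 degrees of freedom. Excess heterogeneity among ratio estimates
#' suggests pleiotropy or otherwise invalid instruments.
#'
#' @param hd an [harmonize()]d dataset or data.frame of pairs (J >= 2).
#' @return List with `q_stat`, `q_df`, `q_pval`.
#' @examples
#' hd <- data.frame(beta_exp = 1, se_exp = 0.01,
#'                  beta_out = c(0, 1), se_out = 0.1)
#' cochran_q(hd)$q_stat  # 50
#' @export
cochran_q <- function(hd) {
  p <- hd_pairs(hd)
  J <- nrow(p)
  if (J < 2) stop("Cochran's Q requires at least 2 instruments",
                  call. = FALSE)
  wr <- wald_ratio(p)
  beta <- sum(wr$weight * wr$ratio) / sum(wr$weight)
  q <- sum(wr$weight * (wr$ratio - beta)^2)
  list(q_stat = q, q_df = J - 1,
       q_pval = stats::pchisq(q, df = J - 1, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Re-exports the intercept fields of [mr_egger()]: the intercept estimate,
#' its standard error and a two-sided t-test on J - 2 degrees of freedom.
#' A non-zero intercept indicates that the average pleiotropic effect of
#' the instruments differs from zero.
#'
#' @param hd an [harmonize()]d dataset or data.frame of pairs (J >= 3).
#' @return List with `alpha`, `se_alpha`, `pval`.
#' @export
egger_intercept_test <- function(hd) {
  e <- mr_egger(hd)
  list(alpha = e$extras$intercept, se_alpha = e$extras$intercept_se,
       pval = e$extras$intercept_pval)
}

# Leave-one-out IVW slopes through the origin with weights 1/se_out^2,
# computed for every variant at once from the full sums.
loo_slopes <- function(bx, by, w) {
  s1 <- sum(w * bx * by)
  s2 <- sum(w * bx^2)
  (s1 - w * bx * by) / (s2 - w * bx^2)
}

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Simulation-based detection of pleiotropic outlier instruments. For each
#' variant j the expected outcome effect is `b_(-j) * beta_exp_j`, where
#' `b_(-j)` is the IVW slope with variant j left out; the observed
#' residual sum of squares (RSS, weighted by `1/se_out^2`) is compared
#' against `n_sim` parametric replicates in which both exposure and
#' outcome effects are redrawn from their sampling distributions around
#' the leave-one-out expectations.
#'
#' The global test p-value uses the add-one Monte-Carlo estimator
#' `(1 + #\{RSS* >= RSS_obs\}) / (n_sim + 1)` and is therefore bounded
#' below by `1/(n_sim + 1)`. Per-variant outlier p-values are the plain
#' empirical exceedance proportions of each squared residual (they can
#' reach zero, as in the method's original formulation), Bonferroni
#' multiplied by J and capped at 1; variants with adjusted p below
#' `significance` are flagged as outliers. When outliers are found, the
#' IVW estimate is recomputed once without them, and a distortion test
#' compares the raw-vs-corrected difference against the distribution of
#' that difference when random pseudo-outlier sets of the same size are
#' removed.
#'
#' @param hd an [harmonize()]d dataset or data.frame of pairs (J >= 4).
#' @param n_sim simulated replicates (default 1000).
#' @param significance outlier significance threshold on the adjusted
#'   p-value (default 0.05).
#' @param seed simulation seed; supply one for reproducible runs.
#' @param n_distortion random pseudo-outlier subsets for the distortion
#'   reference distribution (default 1000).
#' @return An object of class `mr_presso_result`: list with
#'   `global_rss_observed`, `global_pval`, `outlier_pvals` (adjusted,
#'   named), `outlier_ids`, `distortion_pval`, `estimate_raw`,
#'   `estimate_outlier_corrected`, `n_sim`, `seed`.
#' @export
mr_presso <- function(hd, n_sim = 1000, significance = 0.05, seed = NULL,
                      n_distortion = 1000) {
  p <- hd_pairs(hd)
  J <- nrow(p)
  if (J < 4) stop("MR-PRESSO requires at least 4 instruments", call. = FALSE)
  bx <- p$beta_exp; by <- p$beta_out
  sx <- p$se_exp; sy <- p$se_out
  w <- 1 / sy^2
  b_loo <- loo_slopes(bx, by, w)
  res_obs <- by - b_loo * bx
  wres2_obs <- w * res_obs^2
  rss_obs <- sum(wres2_obs)

  if (!is.null(seed)) set.seed(seed)
  bxs <- matrix(stats::rnorm(n_sim * J, mean = rep(bx, each = n_sim),
                             sd = rep(sx, each = n_sim)), nrow = n_sim)
  bys <- matrix(stats::rnorm(n_sim * J, mean = rep(b_loo * bx, each = n_sim),
                             sd = rep(sy, each = n_sim)), nrow = n_sim)
  wm <- matrix(w, n_sim, J, byrow = TRUE)
  s1 <- rowSums(wm * bxs * bys)
  s2 <- rowSums(wm * bxs^2)
  bloo_s <- (s1 - wm * bxs * bys) / (s2 - wm * bxs^2)
  res_s <- bys - bloo_s * bxs
  wres2_s <- wm * res_s^2
  rss_sim <- rowSums(wres2_s)
  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  exceed <- colMeans(wres2_s >= matrix(wres2_obs, n_sim, J, byrow = TRUE))
  outlier_pvals <- stats::setNames(pmin(1, exceed * J), p$snp_id)
  outlier_ids <- p$snp_id[outlier_pvals < significance]

  estimate_raw <- mr_ivw(p)
  estimate_corrected <- NULL
  distortion_pval <- NA_real_
  if (length(outlier_ids) == J) {
    stop("all instruments flagged as outliers; no corrected estimate",
         call. = FALSE)
  }
  if (length(outlier_ids) > 0) {
    keep <- !(p$snp_id %in% outlier_ids)
    estimate_corrected <- mr_ivw(p[keep, , drop = FALSE])
    k <- length(outlier_ids)
    d_obs <- estimate_raw$beta - estimate_corrected$beta
    d_ref <- vapply(seq_len(n_distortion), function(i) {
      drop_idx <- sample.int(J, k)
      estimate_raw$beta - mr_ivw(p[-drop_idx, , drop = FALSE])$beta
    }, numeric(1))
    distortion_pval <- (1 + sum(abs(d_ref) >= abs(d_obs))) /
      (n_distortion + 1)
  }
  structure(list(global_rss_observed = rss_obs, global_pval = global_pval,
                 outlier_pvals = outlier_pvals, outlier_ids = outlier_ids,
                 distortion_pval = distortion_pval,
                 estimate_raw = estimate_raw,
                 estimate_outlier_corrected = estimate_corrected,
                 n_sim = n_sim, seed = seed),
            class = "mr_presso_result")
}

#' @export
print.mr_presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global RSS %.4g, global p = %.4g (%d sims)\n",
              x$global_rss_observed, x$global_pval, x$n_sim))
  if (length(x$outlier_ids)) {
    cat("Outliers:", paste(x$outlier_ids, collapse = ", "),
        sprintf("(distortion p = %.3g)\n", x$distortion_pval))
  } else {
    cat("No outliers detected\n")
  }
  invisible(x)
}

#' Leave-one-out influence analysis
#'
#' Recomputes the IVW estimate J times, omitting each instrument in turn,
#' and flags omissions that flip the sign of the estimate or its
#' significance at 0.05 relative to the full-set IVW.
#'
#' @param hd an [harmonize()]d dataset or data.frame of pairs (J >= 2).
#' @param effects_model IVW effects model, see [mr_ivw()].
#' @return data.frame with one row per omitted variant: `snp_id`, `beta`,
#'   `se`, `pval`, `flag_sign_flip`, `flag_significance_flip`; the full-set
#'   IVW is stored in `attr(, "full")`.
#' @export
leave_one_out <- function(hd, effects_model = "mre") {
  p <- hd_pairs(hd)
  J <- nrow(p)
  if (J < 2) stop("leave-one-out requires at least 2 instruments",
                  call. = FALSE)
  full <- mr_ivw(p, effects_model)
  rows <- lapply(seq_len(J), function(j) {
    e <- mr_ivw(p[-j, , drop = FALSE], effects_model)
    data.frame(snp_id = p$snp_id[j], beta = e$beta, se = e$se,
               pval = e$pval,
               flag_sign_flip = sign(e$beta) != sign(full$beta),
               flag_significance_flip =
                 (e$pval < 0.05) != (full$pval < 0.05),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "full") <- full
  out
}

#' Assemble the full sensitivity report
#'
#' Runs Cochran's Q, the Egger intercept test, MR-PRESSO and leave-one-out
#' on one harmonized dataset; diagnostics whose minimum instrument count is
#' not met are recorded as `NULL` with a reason instead of raising.
#'
#' @param hd an [harmonize()]d dataset.
#' @param n_sim MR-PRESSO simulation count.
#' @param seed seed for MR-PRESSO.
#' @param significance outlier threshold for MR-PRESSO.
#' @return An object of class `mr_sensitivity`: list with `q_stat`, `q_df`,
#'   `q_pval`, `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_pval`, `presso`, `loo`, `not_computed`.
#' @export
sensitivity_report <- function(hd, n_sim = 1000, seed = NULL,
                               significance = 0.05) {
  not_computed <- character()
  q <- tryCatch(cochran_q(hd), error = function(e) {
    not_computed["cochran_q"] <<- conditionMessage(e); NULL
  })
  eg <- tryCatch(egger_intercept_test(hd), error = function(e) {
    not_computed["egger_intercept"] <<- conditionMessage(e); NULL
  })
  pr <- tryCatch(mr_presso(hd, n_sim = n_sim, seed = seed,
                           significance = significance),
                 error = function(e) {
                   not_computed["presso"] <<- conditionMessage(e); NULL
                 })
  loo <- tryCatch(leave_one_out(hd), error = function(e) {
    not_computed["leave_one_out"] <<- conditionMessage(e); NULL
  })
  structure(list(q_stat = q$q_stat %||% NA_real_,
                 q_df = q$q_df %||% NA_integer_,
                 q_pval = q$q_pval %||% NA_real_,
                 egger_intercept = eg$alpha %||% NA_real_,
                 egger_intercept_se = eg$se_alpha %||% NA_real_,
                 egger_intercept_pval = eg$pval %||% NA_real_,
                 presso = pr, loo = loo, not_computed = not_computed),
            class = "mr_sensitivity")
}

#' @export
print.mr_sensitivity <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f (df %d), p = %.3g\n",
              x$q_stat, x$q_df, x$q_pval))
  cat(sprintf("Egger intercept = %.4f (SE %.4f), p = %.3g\n",
              x$egger_intercept, x$egger_intercept_se,
              x$egger_intercept_pval))
  if (!is.null(x$presso)) print(x$presso)
  if (length(x$not_computed)) {
    cat("Not computed:", paste(names(x$not_computed), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-variant source data for funnel and scatter diagnostics
#'
#' Emits the plotting source tables: funnel (`snp_id`, `ratio`,
#' `se_ratio`) and scatter (`snp_id`, `beta_exp`, `se_exp`, `beta_out`,
#' `se_out`), so any plotting layer can reproduce the standard funnel and
#' scatter diagnostics.
#'
#' @param hd an [harmonize()]d dataset.
#' @return List of two data.frames, `funnel` and `scatter`.
#' @export
diagnostic_tables <- function(hd) {
  p <- hd_pairs(hd)
  wr <- wald_ratio(p)
  list(funnel = wr[c("snp_id", "ratio", "se_ratio")],
       scatter = p[c("snp_id", "beta_exp", "se_exp", "beta_out", "se_out")])
}
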