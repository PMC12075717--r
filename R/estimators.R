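# The causal-effect estimators run per exposure-outcome pair: per-variant
# Wald ratios, inverse-variance weighted (IVW) meta-analysis, MR-Egger
# regression, the weighted median, and mode-based estimators.

#' Construct an MR estimate object
#'
#' @param method estimator label.
#' @param n_snp number of instruments used.
#' @param beta,se causal log-odds estimate and standard error.
#' @param df when non-`NULL`, p-value and confidence limits use a
#'   t-distribution on `df` degrees of freedom instead of the normal.
#' @param ci_level confidence level (default 0.95).
#' @param extras named list of method-specific extras (Egger intercept,
#'   bootstrap replicate count, random-effects scale, ...).
#' @return An object of class `mr_estimate` with fields `method`, `n_snp`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `pval`, and the odds-ratio scale
#'   `or`, `or_ci_low`, `or_ci_high` (`exp` of the beta fields).
#' @export
mr_estimate <- function(method, n_snp, beta, se, df = NULL,
                        ci_level = 0.95, extras = list()) {
  a <- (1 - ci_level) / 2
  crit <- if (is.null(df)) stats::qnorm(1 - a) else stats::qt(1 - a, df = df)
  pval <- if (is.null(df)) p_from_z(beta / se) else p_from_t(beta / se, df)
  structure(list(method = method, n_snp = as.integer(n_snp),
                 beta = beta, se = se,
                 ci_low = beta - crit * se, ci_high = beta + crit * se,
                 pval = pval,
                 or = exp(beta), or_ci_low = exp(beta - crit * se),
                 or_ci_high = exp(beta + crit * se),
                 extras = extras),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "%s (%d SNP%s): beta = %.4f (SE %.4f), OR = %.3f [%.3f, %.3f], p = %.3g\n",
    x$method, x$n_snp, if (x$n_snp == 1) "" else "s", x$beta, x$se,
    x$or, x$or_ci_low, x$or_ci_high, x$pval))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snp = x$n_snp, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             or = x$or, or_ci_low = x$or_ci_low, or_ci_high = x$or_ci_high,
             stringsAsFactors = FALSE)
}

#' Per-variant Wald ratios
#'
#' The single-instrument causal estimate: the variant-outcome effect
#' divided by the variant-exposure effect, with first-order delta-method
#' standard error `se_out / |beta_exp|` and inverse-variance weight.
#' Variants with a zero exposure effect have no defined ratio (upstream
#' the F filter removes them) and raise an error.
#'
#' @param hd an [harmonize()]d dataset or data.frame of pairs.
#' @return data.frame with `snp_id`, `ratio`, `se_ratio`, `weight`.
#' @examples
#' wald_ratio(data.frame(beta_exp = 0.2, se_exp = 0.01,
#'                       beta_out = 0.1, se_out = 0.02))
#' @export
wald_ratio <- function(hd) {
  p <- hd_pairs(hd)
  if (any(p$beta_exp == 0)) {
    stop("Wald ratio undefined for zero exposure effect (",
         paste(p$snp_id[p$beta_exp == 0], collapse = ", "), ")",
         call. = FALSE)
  }
  se_ratio <- p$se_out / abs(p$beta_exp)
  data.frame(snp_id = p$snp_id, ratio = p$beta_out / p$beta_exp,
             se_ratio = se_ratio, weight = 1 / se_ratio^2,
             stringsAsFactors = FALSE)
}

#' Inverse-variance weighted estimator
#'
#' The primary two-sample MR estimator: the inverse-variance weighted
#' average of per-variant Wald ratios, equivalently a weighted regression
#' of outcome effects on exposure effects through the origin with weights
#' `1/se_out^2`. The default multiplicative random-effects model inflates
#' the fixed-effect standard error by `max(1, sqrt(Q/(J-1)))`, so
#' overdispersion (heterogeneity) widens intervals while underdispersion is
#' floored at the fixed-effect value. P-values are two-sided normal.
#'
#' @param hd an [harmonize()]d dataset or data.frame of pairs.
#' @param effects_model `"mre"` (multiplicative random effects, default) or
#'   `"fixed"`.
#' @return An [mr_estimate()]; with a single instrument the Wald ratio is
#'   returned, labelled `IVW`.
#' @examples
#' hd <- data.frame(beta_exp = c(0.1, 0.2), se_exp = 0.005,
#'                  beta_out = c(0.05, 0.10), se_out = 0.01)
#' mr_ivw(hd)$beta           # 0.5
#' mr_ivw(hd, "fixed")$se    # sqrt(1/500)
#' @export
mr_ivw <- function(hd, effects_model = c("mre", "fixed")) {
  effects_model <- match.arg(effects_model)
  p <- hd_pairs(hd)
  J <- nrow(p)
  if (J == 0) stop("no instruments", call. = FALSE)
  wr <- wald_ratio(p)
  w <- wr$weight
  beta <- sum(w * wr$ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  if (J == 1) {
    return(mr_estimate("IVW", 1, beta, se_fixed,
                       extras = list(effects_model = "wald",
                                     q_stat = 0, q_df = 0)))
  }
  q_stat <- sum(w * (wr$ratio - beta)^2)
  scale <- max(1, sqrt(q_stat / (J - 1)))
  se <- if (effects_model == "mre") se_fixed * scale else se_fixed
  mr_estimate("IVW", J, beta, se,
              extras = list(effects_model = effects_model,
                            q_stat = q_stat, q_df = J - 1,
                            re_scale = scale, se_fixed = se_fixed))
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of outcome effects on exposure
#' effects with a free intercept (weights `1/se_out^2`), after orienting
#' every pair so the exposure effect is non-negative. The slope is the
#' causal estimate; a non-zero intercept indicates directional horizontal
#' pleiotropy, and under the InSIDE assumption the slope remains consistent
#' even when all instruments are pleiotropic. Standard errors use the WLS
#' residual scale floored at 1 (multiplicative random effects) and
#' t-distribution inference on J - 2 degrees of freedom.
#'
#' @param hd an [harmonize()]d dataset or data.frame of pairs (J >= 3).
#' @return An [mr_estimate()] whose `extras` carry the intercept
#'   (`intercept`, `intercept_se`, `intercept_pval`) and residual scale.
#' @export
mr_egger <- function(hd) {
  p <- hd_pairs(hd)
  J <- nrow(p)
  if (J < 3) stop("MR-Egger requires at least 3 instruments", call. = FALSE)
  if (any(p$beta_exp == 0)) stop("zero exposure effect", call. = FALSE)
  s <- sign(p$beta_exp)
  bx <- p$beta_exp * s
  by <- p$beta_out * s
  w <- 1 / p$se_out^2
  sw <- sum(w); swx <- sum(w * bx); swx2 <- sum(w * bx^2)
  swy <- sum(w * by); swxy <- sum(w * bx * by)
  det <- sw * swx2 - swx^2
  if (abs(det) < .Machine$double.eps * sw * swx2) {
    stop("exposure effects are numerically constant; Egger fit is singular",
         call. = FALSE)
  }
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swx2 * swy - swx * swxy) / det
  resid <- by - intercept - slope * bx
  sigma <- sqrt(sum(w * resid^2) / (J - 2))
  infl <- max(1, sigma)
  se_slope <- infl * sqrt(sw / det)
  se_int <- infl * sqrt(swx2 / det)
  mr_estimate("MR-Egger", J, slope, se_slope, df = J - 2,
              extras = list(intercept = intercept, intercept_se = se_int,
                            intercept_pval = p_from_t(intercept / se_int,
                                                      J - 2),
                            residual_scale = sigma))
}

# Weighted-median point estimate: sorted ratios, normalized weights,
# linear interpolation of the cumulative weight midpoints at 1/2.
weighted_median_point <- function(ratio, weight) {
  o <- order(ratio)
  r <- ratio[o]
  w <- weight[o] / sum(weight)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

# Parametric bootstrap: resample per-variant effects from their sampling
# distributions and return the SD of the re-estimated statistic.
bootstrap_se <- function(p, n_boot, seed, point_fun) {
  if (!is.null(seed)) set.seed(seed)
  J <- nrow(p)
  bxs <- matrix(stats::rnorm(n_boot * J, mean = rep(p$beta_exp, each = n_boot),
                             sd = rep(p$se_exp, each = n_boot)), nrow = n_boot)
  bys <- matrix(stats::rnorm(n_boot * J, mean = rep(p$beta_out, each = n_boot),
                             sd = rep(p$se_out, each = n_boot)), nrow = n_boot)
  est <- vapply(seq_len(n_boot), function(b) {
    bx <- bxs[b, ]
    bx[bx == 0] <- .Machine$double.eps  # degenerate resample guard
    ratio <- bys[b, ] / bx
    weight <- (bx / p$se_out)^2
    point_fun(ratio, weight)
  }, numeric(1))
  stats::sd(est)
}

#' Weighted-median estimator
#'
#' Consistent when instruments contributing at least half of the total
#' inverse-variance weight are valid. The point estimate interpolates the
#' weighted cumulative distribution of sorted Wald ratios at its midpoint;
#' the standard error is the spread of the estimate over parametric
#' bootstrap resamples of the per-variant effects.
#'
#' @param hd an [harmonize()]d dataset or data.frame of pairs (J >= 3).
#' @param n_boot bootstrap replicates for the standard error (default 1000).
#' @param seed seed for the bootstrap; supply one for reproducible runs.
#' @return An [mr_estimate()].
#' @export
mr_weighted_median <- function(hd, n_boot = 1000, seed = NULL) {
  p <- hd_pairs(hd)
  J <- nrow(p)
  if (J < 3) {
    stop("weighted median requires at least 3 instruments", call. = FALSE)
  }
  wr <- wald_ratio(p)
  beta <- weighted_median_point(wr$ratio, wr$weight)
  se <- bootstrap_se(p, n_boot, seed, weighted_median_point)
  mr_estimate("Weighted median", J, beta, se,
              extras = list(n_boot = n_boot, seed = seed))
}

# Mode of a weighted normal-kernel density over ratio estimates.
mode_point <- function(ratio, weight, phi = 1) {
  w <- weight / sum(weight)
  if (length(unique(ratio)) == 1) return(ratio[1])
  disp <- min(stats::sd(ratio), stats::IQR(ratio) / 1.349)
  if (!is.finite(disp) || disp <= 0) disp <- stats::sd(ratio)
  h <- phi * 0.9 * disp * length(ratio)^(-1 / 5)
  dens <- function(x) {
    vapply(x, function(xi) sum(w * stats::dnorm((xi - ratio) / h)),
           numeric(1))
  }
  grid <- seq(min(ratio) - h, max(ratio) + h, length.out = 512)
  best <- which.max(dens(grid))
  lo <- grid[max(1, best - 1)]
  hi <- grid[min(length(grid), best + 1)]
  stats::optimize(dens, c(lo, hi), maximum = TRUE)$maximum
}

#' Mode-based estimators (weighted and simple mode)
#'
#' The estimate is the argmax of a normal-kernel density over the
#' per-variant Wald ratios, with modified-Silverman bandwidth
#' `phi * 0.9 * min(sd, IQR/1.349) * J^(-1/5)`. The weighted variant
#' scales each kernel by its normalized inverse-variance weight; the
#' simple variant uses equal weights. Consistent when the largest group of
#' instruments sharing the same ratio is valid. Standard errors by
#' parametric bootstrap as in [mr_weighted_median()].
#'
#' @param hd an [harmonize()]d dataset or data.frame of pairs (J >= 3).
#' @param weighted use inverse-variance kernel weights (`TRUE`, default)
#'   or equal weights (simple mode).
#' @param phi bandwidth inflation factor (default 1).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed bootstrap seed.
#' @return An [mr_estimate()] labelled `"Weighted mode"` or
#'   `"Simple mode"`.
#' @export
mr_mode <- function(hd, weighted = TRUE, phi = 1, n_boot = 1000,
                    seed = NULL) {
  p <- hd_pairs(hd)
  J <- nrow(p)
  if (J < 3) {
    stop("mode estimator requires at least 3 instruments", call. = FALSE)
  }
  wr <- wald_ratio(p)
  pfun <- if (weighted) {
    function(r, w) mode_point(r, w, phi)
  } else {
    function(r, w) mode_point(r, rep(1, length(r)), phi)
  }
  beta <- pfun(wr$ratio, wr$weight)
  se <- bootstrap_se(p, n_boot, seed, pfun)
  mr_estimate(if (weighted) "Weighted mode" else "Simple mode", J, beta, se,
              extras = list(phi = phi, n_boot = n_boot, seed = seed))
}

#' Run the full estimator battery
#'
#' Computes IVW (primary), MR-Egger, weighted median, weighted mode and
#' simple mode on one harmonized exposure-outcome pair. Methods whose
#' minimum instrument count is not met are reported as not computed rather
#' than raising, so two-instrument pairs still yield IVW.
#'
#' @param hd an [harmonize()]d dataset.
#' @param effects_model IVW effects model, see [mr_ivw()].
#' @param n_boot,phi bootstrap replicates and mode bandwidth factor.
#' @param seed root seed for the bootstrap-based methods; each method gets
#'   a deterministic child seed.
#' @return An object of class `mr_result`: list with `exposure_id`,
#'   `outcome_id`, `estimates` (named list of [mr_estimate()]s, IVW first)
#'   and `not_computed` (named character of skip reasons).
#' @export
mr_all <- function(hd, effects_model = c("mre", "fixed"), n_boot = 1000,
                   phi = 1, seed = NULL) {
  effects_model <- match.arg(effects_model)
  p <- hd_pairs(hd)
  if (nrow(p) == 0) stop("no instruments", call. = FALSE)
  estimates <- list()
  not_computed <- character()
  run <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) conditionMessage(e))
    if (inherits(res, "mr_estimate")) {
      estimates[[name]] <<- res
    } else {
      not_computed[[name]] <<- res
    }
  }
  run("ivw", function() mr_ivw(p, effects_model))
  run("egger", function() mr_egger(p))
  run("weighted_median", function()
    mr_weighted_median(p, n_boot, seed = if (is.null(seed)) NULL
                       else derive_seed(seed, 1)))
  run("weighted_mode", function()
    mr_mode(p, TRUE, phi, n_boot, seed = if (is.null(seed)) NULL
            else derive_seed(seed, 2)))
  run("simple_mode", function()
    mr_mode(p, FALSE, phi, n_boot, seed = if (is.null(seed)) NULL
            else derive_seed(seed, 3)))
  structure(list(exposure_id = hd_label(hd, "exposure_id"),
                 outcome_id = hd_label(hd, "outcome_id"),
                 estimates = estimates, not_computed = not_computed),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR estimates %s -> %s\n", x$exposure_id, x$outcome_id))
  for (e in x$estimates) print(e)
  if (length(x$not_computed)) {
    cat("Not computed:",
        paste(names(x$not_computed), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  rows <- do.call(rbind, lapply(x$estimates, as.data.frame))
  rownames(rows) <- NULL
  cbind(data.frame(exposure_id = x$exposure_id %||% NA_character_,
                   outcome_id = x$outcome_id %||% NA_character_,
                   stringsAsFactors = FALSE),
        rows)
}
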