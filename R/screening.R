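# Candidate-selection decision procedure over many exposure-outcome pairs:
# primary IVW significance, a corroboration rule in place of multiplicity
# correction, direction/magnitude consistency, sensitivity gates and
# reverse-direction MR.

#' Screening criteria for candidate exposure-outcome pairs
#'
#' A pair passes when: (1) the primary IVW p-value is below `p_primary`;
#' (2) corroboration: at least one of the MR-Egger and weighted-median
#' estimates is significant at `p_secondary` (this rule substitutes for
#' multiple-testing correction across the exposure panel — an optional
#' false-discovery-rate switch exists in [run_screen()] but is off by
#' default); (3) direction/magnitude: the IVW, Egger and weighted-median
#' estimates share a sign and their 95% confidence intervals pairwise
#' overlap; (4) sensitivity: Cochran's Q p > `p_heterogeneity`, Egger
#' intercept p > `p_pleiotropy`, and MR-PRESSO finds no outliers (or, if it
#' does, the once-corrected estimate keeps the sign and the distortion test
#' is non-significant); (5) reverse MR, when available, is non-significant
#' at `p_reverse`.
#'
#' @param p_primary IVW significance threshold (default 0.05).
#' @param p_secondary corroboration threshold for Egger / weighted median
#'   (default 0.05).
#' @param p_heterogeneity minimum acceptable Cochran's Q p (default 0.05).
#' @param p_pleiotropy minimum acceptable Egger intercept p (default 0.05).
#' @param p_reverse reverse-MR p at or above which reverse causation is
#'   considered absent (default 0.05).
#' @param require_direction enforce rule (3) (default TRUE).
#' @param require_sensitivity enforce rule (4) (default TRUE).
#' @return A list of class `screening_criteria`.
#' @export
screening_criteria <- function(p_primary = 0.05, p_secondary = 0.05,
                               p_heterogeneity = 0.05, p_pleiotropy = 0.05,
                               p_reverse = 0.05, require_direction = TRUE,
                               require_sensitivity = TRUE) {
  for (nm in c("p_primary", "p_secondary", "p_heterogeneity",
               "p_pleiotropy", "p_reverse")) {
    v <- get(nm)
    assert_scalar_number(v, nm, positive = TRUE)
    if (v >= 1) stop(nm, " must lie in (0, 1)", call. = FALSE)
  }
  structure(list(p_primary = p_primary, p_secondary = p_secondary,
                 p_heterogeneity = p_heterogeneity,
                 p_pleiotropy = p_pleiotropy, p_reverse = p_reverse,
                 require_direction = isTRUE(require_direction),
                 require_sensitivity = isTRUE(require_sensitivity)),
            class = "screening_criteria")
}

ci_overlap <- function(a, b) a$ci_low <= b$ci_high && b$ci_low <= a$ci_high

#' Evaluate the screening rules for one exposure-outcome pair
#'
#' Pure decision function over already-computed estimates: applies each
#' rule of [screening_criteria()], enumerating every failed rule, so a
#' replay from saved estimates reproduces the decision exactly.
#'
#' @param estimates an `mr_result` from [mr_all()] (must contain `ivw`,
#'   `egger` and `weighted_median`).
#' @param sensitivity an `mr_sensitivity` from [sensitivity_report()].
#' @param reverse_estimate reverse-MR [mr_estimate()], or `NULL` when no
#'   reverse instruments were available (treated as no evidence of reverse
#'   causation, with a note).
#' @param criteria a [screening_criteria()].
#' @return An object of class `screening_decision`: list with
#'   `exposure_id`, `outcome_id`, `passed`, `failed_rules` (character),
#'   `notes`, plus the inputs.
#' @export
evaluate_pair <- function(estimates, sensitivity, reverse_estimate = NULL,
                          criteria = screening_criteria()) {
  stopifnot(inherits(criteria, "screening_criteria"))
  est <- if (inherits(estimates, "mr_result")) estimates$estimates
         else estimates
  need <- c("ivw", "egger", "weighted_median")
  if (!all(need %in% names(est))) {
    stop("estimates must include: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!inherits(sensitivity, "mr_sensitivity")) {
    stop("a sensitivity report is required", call. = FALSE)
  }
  ivw <- est$ivw; egger <- est$egger; wm <- est$weighted_median
  failed <- character()
  notes <- character()

  if (!(ivw$pval < criteria$p_primary)) failed <- c(failed, "p_primary")
  if (!(egger$pval < criteria$p_secondary ||
        wm$pval < criteria$p_secondary)) {
    failed <- c(failed, "corroboration")
  }
  if (criteria$require_direction) {
    same_sign <- sign(ivw$beta) == sign(egger$beta) &&
      sign(ivw$beta) == sign(wm$beta)
    overlap <- ci_overlap(ivw, egger) && ci_overlap(ivw, wm) &&
      ci_overlap(egger, wm)
    if (!(same_sign && overlap)) failed <- c(failed, "direction")
  }
  if (criteria$require_sensitivity) {
    if (is.finite(sensitivity$q_pval) &&
        sensitivity$q_pval <= criteria$p_heterogeneity) {
      failed <- c(failed, "heterogeneity")
    }
    if (is.finite(sensitivity$egger_intercept_pval) &&
        sensitivity$egger_intercept_pval <= criteria$p_pleiotropy) {
      failed <- c(failed, "pleiotropy")
    }
    pr <- sensitivity$presso
    if (!is.null(pr) && length(pr$outlier_ids) > 0) {
      stable <- !is.null(pr$estimate_outlier_corrected) &&
        sign(pr$estimate_outlier_corrected$beta) ==
          sign(pr$estimate_raw$beta) &&
        (is.na(pr$distortion_pval) || pr$distortion_pval > 0.05)
      if (!stable) failed <- c(failed, "presso-outliers")
      else notes <- c(notes, "presso outliers removed; estimate stable")
    }
  }
  if (is.null(reverse_estimate)) {
    notes <- c(notes, "no reverse-MR instruments; reverse rule not applicable")
  } else if (reverse_estimate$pval < criteria$p_reverse) {
    failed <- c(failed, "reverse-causation")
  }

  structure(list(exposure_id = if (inherits(estimates, "mr_result"))
                   estimates$exposure_id else NA_character_,
                 outcome_id = if (inherits(estimates, "mr_result"))
                   estimates$outcome_id else NA_character_,
                 passed = length(failed) == 0, failed_rules = failed,
                 notes = notes, estimates = estimates,
                 sensitivity = sensitivity, reverse = reverse_estimate),
            class = "screening_decision")
}

#' @export
print.screening_decision <- function(x, ...) {
  cat(sprintf("%s -> %s: %s", x$exposure_id, x$outcome_id,
              if (x$passed) "PASSED" else "failed"))
  if (!x$passed) cat(" [", paste(x$failed_rules, collapse = ", "), "]")
  cat("\n")
  invisible(x)
}

#' Reverse-direction MR
#'
#' Runs the identical selection + estimation pipeline with the roles
#' swapped: instruments are selected from the original outcome trait and
#' their effects on the original exposure estimated. Used to rule out
#' reverse causation. Returns `NULL` when the outcome trait yields no
#' instruments, which is common for modestly powered disease GWAS at
#' stringent instrument thresholds.
#'
#' @param outcome_ds the original outcome `sumstats` (instrument source
#'   for the reverse analysis).
#' @param exposure_ds the original exposure `sumstats` (reverse outcome).
#' @param ld an [ld_matrix()] or `NULL`.
#' @param config a [selection_config()].
#' @param effects_model IVW effects model.
#' @return An [mr_estimate()], or `NULL` when no instruments survive.
#' @export
reverse_mr <- function(outcome_ds, exposure_ds, ld = NULL,
                       config = selection_config(),
                       effects_model = "mre") {
  sel <- select_instruments(outcome_ds, exposure_ds, ld, config)
  if (nrow(sel$instruments) == 0) return(NULL)
  hd <- suppressWarnings(harmonize(sel$instruments, exposure_ds))
  if (nrow(hd$pairs) == 0) return(NULL)
  mr_ivw(hd, effects_model)
}

#' Screen a panel of exposures against one outcome
#'
#' For each exposure: select instruments, harmonize, run the five-method
#' battery, the sensitivity diagnostics and reverse MR, then apply
#' [evaluate_pair()]. Per-exposure failures (e.g. no instruments) are
#' recorded as failed decisions, not fatal to the batch, and decisions are
#' independent across exposures.
#'
#' @param exposures named list of exposure `sumstats`.
#' @param outcome outcome `sumstats`.
#' @param ld an [ld_matrix()] or `NULL`.
#' @param criteria a [screening_criteria()].
#' @param config a [selection_config()].
#' @param seed root seed; each exposure gets a deterministic child seed.
#' @param n_sim MR-PRESSO simulations per pair.
#' @param n_boot bootstrap replicates per pair.
#' @param fdr apply a Benjamini-Hochberg correction to the IVW p-values
#'   across the panel before the primary rule (off by default; the
#'   corroboration rule is the default multiplicity control).
#' @return A list of class `screening_batch`: `decisions` (list of
#'   `screening_decision`) and `table` (one summary row per exposure).
#' @export
run_screen <- function(exposures, outcome, ld = NULL,
                       criteria = screening_criteria(),
                       config = selection_config(), seed = 1,
                       n_sim = 1000, n_boot = 1000, fdr = FALSE) {
  if (length(exposures) == 0) {
    return(structure(list(decisions = list(),
                          table = data.frame()), class = "screening_batch"))
  }
  if (is.null(names(exposures))) {
    names(exposures) <- vapply(exposures, trait_id, character(1))
  }
  decisions <- vector("list", length(exposures))
  names(decisions) <- names(exposures)
  for (i in seq_along(exposures)) {
    ex <- exposures[[i]]
    child <- derive_seed(seed, i)
    decisions[[i]] <- tryCatch({
      sel <- select_instruments(ex, outcome, ld, config)
      if (nrow(sel$instruments) == 0) stop("no instruments", call. = FALSE)
      hd <- harmonize(sel$instruments, outcome)
      if (nrow(hd$pairs) == 0) {
        stop("no harmonizable instruments", call. = FALSE)
      }
      ests <- mr_all(hd, n_boot = n_boot, seed = child)
      sens <- sensitivity_report(hd, n_sim = n_sim,
                                 seed = derive_seed(child, 99))
      rev <- reverse_mr(outcome, ex, ld, config)
      evaluate_pair(ests, sens, rev, criteria)
    }, error = function(e) {
      structure(list(exposure_id = trait_id(ex),
                     outcome_id = trait_id(outcome), passed = FALSE,
                     failed_rules = conditionMessage(e),
                     notes = character(), estimates = NULL,
                     sensitivity = NULL, reverse = NULL),
                class = "screening_decision")
    })
    decisions[[i]]$exposure_id <- names(exposures)[i]
  }
  if (fdr) {
    pvals <- vapply(decisions, function(d) {
      if (is.null(d$estimates)) NA_real_ else d$estimates$estimates$ivw$pval
    }, numeric(1))
    padj <- stats::p.adjust(pvals, method = "BH")
    for (i in seq_along(decisions)) {
      d <- decisions[[i]]
      if (is.null(d$estimates)) next
      fails_fdr <- !(padj[i] < criteria$p_primary)
      has <- "p_primary" %in% d$failed_rules
      if (fails_fdr && !has) {
        d$failed_rules <- c(d$failed_rules, "p_primary")
      } else if (!fails_fdr && has) {
        d$failed_rules <- setdiff(d$failed_rules, "p_primary")
      }
      d$passed <- length(d$failed_rules) == 0
      decisions[[i]] <- d
    }
  }
  table <- do.call(rbind, lapply(decisions, function(d) {
    ivw <- if (!is.null(d$estimates)) d$estimates$estimates$ivw
    data.frame(exposure_id = d$exposure_id, outcome_id = d$outcome_id,
               passed = d$passed,
               failed_rules = paste(d$failed_rules, collapse = ";"),
               ivw_or = if (!is.null(ivw)) ivw$or else NA_real_,
               ivw_ci_low = if (!is.null(ivw)) ivw$or_ci_low else NA_real_,
               ivw_ci_high = if (!is.null(ivw)) ivw$or_ci_high else NA_real_,
               ivw_p = if (!is.null(ivw)) ivw$pval else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(table) <- NULL
  structure(list(decisions = decisions, table = table),
            class = "screening_batch")
}

#' @export
print.screening_batch <- function(x, ...) {
  cat(sprintf("Screening batch: %d exposure(s), %d passed\n",
              nrow(x$table), sum(x$table$passed)))
  print(x$table)
  invisible(x)
}
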