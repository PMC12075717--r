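# Instrument selection: genome-wide significance filter, greedy LD
# clumping, outcome-association exclusion, exclusion lists, MAF filter and
# the per-variant F-statistic strength filter, with a per-SNP audit report.

#' Instrument-selection configuration
#'
#' Thresholds for the instrument-selection pipeline. Defaults follow common
#' two-sample MR practice for sub-genome-wide instruments: association
#' p < 1e-5, LD clumping at r-squared 0.001 within 10,000 kb, exclusion of
#' instruments associated with the outcome at p < 1e-5, minor allele
#' frequency at least 0.01, and F-statistic above 10.
#'
#' @param p_instrument exposure association p-value threshold (strict `<`).
#' @param clump_r2 squared-correlation threshold at or above which a
#'   variant is clumped away by a better instrument.
#' @param clump_kb physical window, in kilobases, on either side of the
#'   index variant within which clumping applies.
#' @param p_outcome_exclude instruments with outcome p below this are
#'   excluded as potentially outcome-associated.
#' @param min_maf minimum minor allele frequency, `min(eaf, 1 - eaf)`.
#' @param min_f minimum per-variant F-statistic, `(beta/se)^2` (strict `>`).
#' @param exclusion_ids character vector of variant identifiers to remove
#'   unconditionally (e.g. variants a trait-lookup service links to the
#'   outcome).
#' @return A list of class `selection_config`.
#' @export
selection_config <- function(p_instrument = 1e-5, clump_r2 = 0.001,
                             clump_kb = 10000, p_outcome_exclude = 1e-5,
                             min_maf = 0.01, min_f = 10,
                             exclusion_ids = character()) {
  assert_scalar_number(p_instrument, "p_instrument", positive = TRUE)
  assert_scalar_number(clump_r2, "clump_r2", positive = TRUE)
  if (clump_r2 > 1) stop("clump_r2 must lie in (0, 1]", call. = FALSE)
  assert_scalar_number(clump_kb, "clump_kb", positive = TRUE)
  assert_scalar_number(p_outcome_exclude, "p_outcome_exclude", positive = TRUE)
  assert_scalar_number(min_maf, "min_maf", positive = TRUE)
  assert_scalar_number(min_f, "min_f", positive = TRUE)
  structure(list(p_instrument = p_instrument, clump_r2 = clump_r2,
                 clump_kb = clump_kb, p_outcome_exclude = p_outcome_exclude,
                 min_maf = min_maf, min_f = min_f,
                 exclusion_ids = as.character(exclusion_ids)),
            class = "selection_config")
}

#' Pairwise LD matrix
#'
#' Wraps a symmetric matrix of squared correlations (r-squared) between
#' variants, with unit diagonal, used by [clump()].
#'
#' @param r2 square numeric matrix of r-squared values in \[0, 1\].
#' @param snp_ids variant identifiers; defaults to the matrix dimnames.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(r2, snp_ids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(snp_ids)) stop("snp_ids required", call. = FALSE)
  if (nrow(r2) != ncol(r2) || nrow(r2) != length(snp_ids)) {
    stop("r2 must be square with one row per snp_id", call. = FALSE)
  }
  if (any(!is.finite(r2)) || any(r2 < 0) || any(r2 > 1)) {
    stop("r2 values must lie in [0, 1]", call. = FALSE)
  }
  if (max(abs(r2 - t(r2))) > 1e-8) stop("r2 must be symmetric", call. = FALSE)
  if (max(abs(diag(r2) - 1)) > 1e-8) {
    stop("r2 must have unit diagonal", call. = FALSE)
  }
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = as.character(snp_ids), r2 = r2),
            class = "ld_matrix")
}

#' Read an LD matrix from TSV
#'
#' Accepts either a square layout (header row and first column of variant
#' identifiers) or a long layout with columns `snp_a`, `snp_b`, `r2`
#' (missing pairs default to r-squared 0).
#'
#' @param path input file.
#' @param format `"auto"` (default), `"square"` or `"long"`.
#' @return An [ld_matrix()] object.
#' @export
read_ld_matrix <- function(path, format = c("auto", "square", "long")) {
  format <- match.arg(format)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (format == "auto") {
    format <- if (all(c("snp_a", "snp_b", "r2") %in% names(df)))
      "long" else "square"
  }
  if (format == "long") {
    ids <- sort(unique(c(df$snp_a, df$snp_b)))
    m <- diag(length(ids))
    dimnames(m) <- list(ids, ids)
    m[cbind(match(df$snp_a, ids), match(df$snp_b, ids))] <- df$r2
    m[cbind(match(df$snp_b, ids), match(df$snp_a, ids))] <- df$r2
    diag(m) <- 1
    ld_matrix(m, ids)
  } else {
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    mode(m) <- "numeric"
    ld_matrix(m, ids)
  }
}

#' Write an LD matrix to TSV (square layout)
#' @param ld an [ld_matrix()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  df <- data.frame(snp_id = ld$snp_ids, ld$r2, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter variants by association p-value
#'
#' Keeps records with `pval` strictly below `threshold`.
#' @param ds a `sumstats` dataset.
#' @param threshold p-value threshold (default 1e-5).
#' @return The filtered dataset.
#' @export
filter_by_pvalue <- function(ds, threshold = 1e-5) {
  ss_keep(ds, ds$pval < threshold)
}

#' Per-variant F-statistic
#'
#' Instrument-strength measure computed from summary statistics as
#' `(beta/se)^2`; values above 10 conventionally indicate a non-weak
#' instrument.
#'
#' @param beta effect estimate(s), or a `sumstats` dataset (then `se` is
#'   taken from it).
#' @param se standard error(s), > 0.
#' @return Numeric vector of F values.
#' @examples
#' f_statistic(0.1, 0.01)  # 100
#' @export
f_statistic <- function(beta, se = NULL) {
  if (is.data.frame(beta)) {
    se <- beta$se
    beta <- beta$beta
  }
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("se must be > 0", call. = FALSE)
  }
  (beta / se)^2
}

#' Filter variants by minor allele frequency
#'
#' Keeps records with `min(eaf, 1 - eaf) >= min_maf`. Records with missing
#' allele frequency cannot demonstrate that they pass and are dropped.
#' @param ds a `sumstats` dataset.
#' @param min_maf MAF threshold (default 0.01).
#' @return The filtered dataset.
#' @export
filter_by_maf <- function(ds, min_maf = 0.01) {
  maf <- pmin(ds$eaf, 1 - ds$eaf)
  keep <- !is.na(maf) & maf >= min_maf
  ss_keep(ds, keep)
}

#' Exclude instruments associated with the outcome
#'
#' Removes candidate instruments whose outcome-association p-value falls
#' below `threshold`, guarding the exclusion-restriction assumption.
#' Instruments absent from the outcome dataset are retained here (they drop
#' later at harmonization if still unmatched).
#'
#' @param instruments candidate-instrument `sumstats`.
#' @param outcome outcome `sumstats`.
#' @param threshold outcome p-value threshold (default 1e-5).
#' @return The filtered instrument set.
#' @export
exclude_outcome_associated <- function(instruments, outcome,
                                       threshold = 1e-5) {
  p_out <- outcome$pval[match(instruments$snp_id, outcome$snp_id)]
  keep <- is.na(p_out) | p_out >= threshold
  ss_keep(instruments, keep)
}

#' Remove explicitly excluded variants
#'
#' Drops instruments whose `snp_id` appears in `exclusion_ids`, e.g.
#' variants a trait-catalogue lookup links to the outcome through pathways
#' other than the exposure.
#'
#' @param instruments candidate-instrument `sumstats`.
#' @param exclusion_ids character vector of identifiers to remove.
#' @return The filtered instrument set.
#' @export
apply_exclusion_list <- function(instruments, exclusion_ids) {
  ss_keep(instruments, !(instruments$snp_id %in% exclusion_ids))
}

#' Greedy LD clumping
#'
#' Prunes variants to an approximately independent set: repeatedly take the
#' remaining variant with the smallest p-value (ties broken by
#' lexicographically smaller `snp_id`), keep it as an index variant, and
#' remove every remaining variant on the same chromosome within
#' `window_kb` kilobases whose r-squared with the index is at or above
#' `r2_threshold`. The kept set is returned in the original dataset order.
#'
#' @param ds a `sumstats` dataset with chromosome and position filled in.
#' @param ld an [ld_matrix()] covering every variant in `ds`.
#' @param r2_threshold clumping r-squared threshold (default 0.001).
#' @param window_kb physical window in kilobases (default 10,000),
#'   inclusive on both sides of the index variant.
#' @return The clumped dataset; the per-variant index assignment is
#'   available in `attr(, "clumped_by")` (named character, `NA` for kept).
#' @export
clump <- function(ds, ld, r2_threshold = 0.001, window_kb = 10000) {
  stopifnot(inherits(ld, "ld_matrix"))
  df <- as.data.frame(ds)
  missing_ld <- setdiff(df$snp_id, ld$snp_ids)
  if (length(missing_ld)) {
    stop("variant(s) absent from the LD matrix: ",
         paste(missing_ld, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(df$pos)) || any(is.na(df$chrom))) {
    stop("clumping requires chrom and pos for every variant", call. = FALSE)
  }
  r2 <- ld$r2[df$snp_id, df$snp_id, drop = FALSE]
  ord <- order(df$pval, df$snp_id)
  alive <- rep(TRUE, nrow(df))
  clumped_by <- stats::setNames(rep(NA_character_, nrow(df)), df$snp_id)
  window_bp <- window_kb * 1000
  for (i in ord) {
    if (!alive[i]) next
    victims <- alive & seq_len(nrow(df)) != i &
      df$chrom == df$chrom[i] &
      abs(df$pos - df$pos[i]) <= window_bp &
      r2[i, ] >= r2_threshold
    clumped_by[victims] <- df$snp_id[i]
    alive[victims] <- FALSE
  }
  out <- ss_keep(ds, alive)
  attr(out, "clumped_by") <- clumped_by
  out
}

#' Run the full instrument-selection pipeline
#'
#' Applies, in order: exposure p-value filter, LD clumping,
#' outcome-association exclusion, explicit exclusion list, MAF filter and
#' F-statistic filter. The stage order matters for clumping (only
#' significant variants compete as index variants) and is fixed; every
#' input variant receives exactly one disposition in the report.
#'
#' @param exposure exposure `sumstats` (instrument source).
#' @param outcome outcome `sumstats` used for the outcome-association
#'   exclusion; may be `NULL` to skip that stage.
#' @param ld an [ld_matrix()]; may be `NULL` to skip clumping (all
#'   variants treated as independent).
#' @param config a [selection_config()].
#' @return A list with `instruments` (the selected `sumstats`) and
#'   `report` (data.frame `snp_id`, `disposition`, `f_stat`), where
#'   disposition is one of kept / failed-p / clumped-out-by:<id> /
#'   outcome-associated / excluded-list / failed-maf / failed-f.
#' @export
select_instruments <- function(exposure, outcome = NULL, ld = NULL,
                               config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  all_ids <- exposure$snp_id
  disposition <- stats::setNames(rep("kept", length(all_ids)), all_ids)
  f_all <- stats::setNames(f_statistic(exposure$beta, exposure$se), all_ids)

  cur <- filter_by_pvalue(exposure, config$p_instrument)
  disposition[setdiff(all_ids, cur$snp_id)] <- "failed-p"

  if (!is.null(ld) && nrow(cur) > 0) {
    clumped <- clump(cur, ld, config$clump_r2, config$clump_kb)
    cb <- attr(clumped, "clumped_by")
    gone <- names(cb)[!is.na(cb)]
    disposition[gone] <- paste0("clumped-out-by:", cb[gone])
    cur <- clumped
  }

  if (!is.null(outcome) && nrow(cur) > 0) {
    kept <- exclude_outcome_associated(cur, outcome,
                                       config$p_outcome_exclude)
    disposition[setdiff(cur$snp_id, kept$snp_id)] <- "outcome-associated"
    cur <- kept
  }

  if (length(config$exclusion_ids) && nrow(cur) > 0) {
    kept <- apply_exclusion_list(cur, config$exclusion_ids)
    disposition[setdiff(cur$snp_id, kept$snp_id)] <- "excluded-list"
    cur <- kept
  }

  if (nrow(cur) > 0) {
    kept <- filter_by_maf(cur, config$min_maf)
    disposition[setdiff(cur$snp_id, kept$snp_id)] <- "failed-maf"
    cur <- kept
  }

  if (nrow(cur) > 0) {
    keep <- f_statistic(cur$beta, cur$se) > config$min_f
    disposition[cur$snp_id[!keep]] <- "failed-f"
    cur <- ss_keep(cur, keep)
  }

  report <- data.frame(snp_id = all_ids,
                       disposition = unname(disposition[all_ids]),
                       f_stat = unname(f_all[all_ids]),
                       stringsAsFactors = FALSE)
  cur <- ss_metadata_set(cur, "selection_counts",
                         as.list(table(report$disposition)))
  list(instruments = cur, report = report)
}

#' Write a selection report to TSV
#' @param report the `report` element of [select_instruments()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
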