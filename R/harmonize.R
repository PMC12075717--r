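# Exposure/outcome harmonization: put the SNP-outcome effect on the same
# effect allele as the SNP-exposure effect, drop variants whose orientation
# cannot be resolved, and keep a full per-SNP disposition log.

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects the two datasets on `snp_id` and aligns each outcome record
#' to the exposure record's effect allele, so that downstream Wald ratios
#' compare effects of the same allele. Outcome records stated on the
#' swapped orientation have `beta` negated and `eaf` complemented.
#' Palindromic variants (A/T, C/G) are dropped by default because their
#' strand cannot be resolved from alleles; with
#' `palindromic = "infer"` they are kept when both allele frequencies are
#' clearly on the same side of 0.5 (both below `eaf_limit` or both above
#' `1 - eaf_limit`, directly or after flipping). Any other allele-set
#' disagreement (including strand-complement pairs) is conservatively
#' dropped as a mismatch.
#'
#' @param exposure,outcome `sumstats` datasets.
#' @param palindromic `"drop"` (default) removes all palindromic variants;
#'   `"infer"` resolves them from allele frequencies where unambiguous.
#' @param eaf_limit frequency bound used by the `"infer"` policy
#'   (default 0.42): a palindromic variant is kept only when both studies
#'   place its effect-allele frequency outside (eaf_limit, 1 - eaf_limit).
#' @return An object of class `mr_harmonized`: a list with `exposure_id`,
#'   `outcome_id`, `pairs` (data.frame of `snp_id`, alleles, `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`, `eaf_exp`, `eaf_out`, `pval_exp`,
#'   `pval_out`) and `log` (per-SNP disposition: kept / flipped /
#'   dropped-palindromic / dropped-allele-mismatch / dropped-missing).
#' @examples
#' exp <- sumstats(data.frame(snp_id = "rs1", effect_allele = "A",
#'   other_allele = "G", beta = 0.1, se = 0.01, pval = 1e-8, eaf = 0.3))
#' out <- sumstats(data.frame(snp_id = "rs1", effect_allele = "G",
#'   other_allele = "A", beta = 0.05, se = 0.02, pval = 0.01, eaf = 0.7))
#' harmonize(exp, out)$pairs$beta_out  # -0.05 after the flip
#' @export
harmonize <- function(exposure, outcome, palindromic = c("drop", "infer"),
                      eaf_limit = 0.42) {
  palindromic <- match.arg(palindromic)
  ex <- as.data.frame(exposure)
  ou <- as.data.frame(outcome)
  idx <- match(ex$snp_id, ou$snp_id)
  n <- nrow(ex)

  disposition <- rep("kept", n)
  detail <- rep("", n)
  beta_out <- se_out <- eaf_out <- pval_out <- rep(NA_real_, n)

  present <- !is.na(idx)
  disposition[!present] <- "dropped-missing"
  detail[!present] <- "absent from outcome dataset"

  if (any(present)) {
    j <- idx[present]
    pal <- is_palindromic(ex$effect_allele[present], ex$other_allele[present])
    same <- ex$effect_allele[present] == ou$effect_allele[j] &
      ex$other_allele[present] == ou$other_allele[j]
    swap <- ex$effect_allele[present] == ou$other_allele[j] &
      ex$other_allele[present] == ou$effect_allele[j]

    status <- rep("mismatch", sum(present))
    status[same] <- "same"
    status[swap & !same] <- "swap"

    if (any(pal)) {
      if (palindromic == "drop") {
        status[pal] <- "palindromic"
      } else {
        # For palindromic variants "same" and "swap" are indistinguishable
        # from alleles; use allele frequencies where decisive.
        fe <- ex$eaf[present]
        fo <- ou$eaf[j]
        lo_e <- fe < eaf_limit
        hi_e <- fe > 1 - eaf_limit
        lo_o <- fo < eaf_limit
        hi_o <- fo > 1 - eaf_limit
        concord <- (lo_e & lo_o) | (hi_e & hi_o)
        discord <- (lo_e & hi_o) | (hi_e & lo_o)
        resolved_same <- pal & !is.na(concord) & concord
        resolved_swap <- pal & !is.na(discord) & discord
        status[pal] <- "palindromic"
        status[resolved_same] <- "same"
        status[resolved_swap] <- "pal-flip"
      }
    }

    pi <- which(present)
    keep_same <- status %in% "same"
    keep_swap <- status %in% c("swap", "pal-flip")
    beta_out[pi[keep_same]] <- ou$beta[j[keep_same]]
    se_out[pi[keep_same | keep_swap]] <- ou$se[j[keep_same | keep_swap]]
    pval_out[pi[keep_same | keep_swap]] <- ou$pval[j[keep_same | keep_swap]]
    eaf_out[pi[keep_same]] <- ou$eaf[j[keep_same]]
    beta_out[pi[keep_swap]] <- -ou$beta[j[keep_swap]]
    eaf_out[pi[keep_swap]] <- 1 - ou$eaf[j[keep_swap]]

    disposition[pi[keep_swap]] <- "flipped"
    disposition[pi[status == "palindromic"]] <- "dropped-palindromic"
    disposition[pi[status == "mismatch"]] <- "dropped-allele-mismatch"
    detail[pi[status == "pal-flip"]] <- "palindromic, resolved by eaf"
    detail[pi[status == "mismatch"]] <-
      paste0("outcome alleles ", ou$effect_allele[j[status == "mismatch"]],
             "/", ou$other_allele[j[status == "mismatch"]])

    # Positions are matched by identifier only; disagreements are warnings.
    pos_known <- !is.na(ex$pos[present]) & !is.na(ou$pos[j]) &
      !is.na(ex$chrom[present]) & !is.na(ou$chrom[j])
    clash <- pos_known & (ex$chrom[present] != ou$chrom[j] |
                            ex$pos[present] != ou$pos[j])
    if (any(clash)) {
      warning(sum(clash), " variant(s) matched by snp_id but with ",
              "differing chrom/pos between datasets", call. = FALSE)
      detail[pi[clash]] <- paste0(detail[pi[clash]],
                                  " [chrom/pos disagreement]")
    }
  }

  kept <- disposition %in% c("kept", "flipped")
  pairs <- data.frame(
    snp_id = ex$snp_id[kept],
    effect_allele = ex$effect_allele[kept],
    other_allele = ex$other_allele[kept],
    beta_exp = ex$beta[kept], se_exp = ex$se[kept],
    beta_out = beta_out[kept], se_out = se_out[kept],
    eaf_exp = ex$eaf[kept], eaf_out = eaf_out[kept],
    pval_exp = ex$pval[kept], pval_out = pval_out[kept],
    stringsAsFactors = FALSE)
  rownames(pairs) <- NULL

  log <- data.frame(snp_id = ex$snp_id, disposition = disposition,
                    detail = detail, stringsAsFactors = FALSE)
  extra <- setdiff(ou$snp_id, ex$snp_id)
  if (length(extra)) {
    log <- rbind(log, data.frame(snp_id = extra,
                                 disposition = "dropped-missing",
                                 detail = "absent from exposure dataset",
                                 stringsAsFactors = FALSE))
  }
  if (nrow(pairs) == 0) {
    warning("no harmonizable variants shared between '",
            trait_id(exposure), "' and '", trait_id(outcome), "'",
            call. = FALSE)
  }
  new_harmonized(pairs, log, trait_id(exposure), trait_id(outcome))
}

new_harmonized <- function(pairs, log, exposure_id, outcome_id) {
  structure(list(exposure_id = exposure_id, outcome_id = outcome_id,
                 pairs = pairs, log = log),
            class = "mr_harmonized")
}

#' @export
print.mr_harmonized <- function(x, ...) {
  cat(sprintf("Harmonized dataset %s -> %s: %d pair(s)\n",
              x$exposure_id, x$outcome_id, nrow(x$pairs)))
  tab <- table(x$log$disposition)
  cat(paste(sprintf("  %s: %d", names(tab), tab), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
as.data.frame.mr_harmonized <- function(x, ...) x$pairs

# Accept either an mr_harmonized object or a bare data.frame of pairs.
hd_pairs <- function(hd) {
  if (inherits(hd, "mr_harmonized")) return(hd$pairs)
  df <- as.data.frame(hd)
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  if (!all(need %in% names(df))) {
    stop("harmonized pairs need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$snp_id)) df$snp_id <- paste0("snp", seq_len(nrow(df)))
  df
}

hd_label <- function(hd, which) {
  if (inherits(hd, "mr_harmonized")) hd[[which]] else NA_character_
}

#' Write a harmonization disposition log to TSV
#' @param hd an `mr_harmonized` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_harmonization_log <- function(hd, path) {
  stopifnot(inherits(hd, "mr_harmonized"))
  utils::write.table(hd$log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
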