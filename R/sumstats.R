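# GWAS summary-statistics container and TSV I/O.
#
# A `sumstats` object is a data.frame with the canonical columns
# snp_id, chrom, pos, effect_allele, other_allele, eaf, beta, se, pval, n
# plus attributes trait_id, trait_name and metadata. Effects (`beta`) are
# per effect-allele copies; for binary traits they are log-odds.

SUMSTATS_COLS <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n")
SUMSTATS_MANDATORY <- c("snp_id", "effect_allele", "other_allele",
                        "beta", "se", "pval")
ALLELES <- c("A", "C", "G", "T")
ALLELE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Construct a GWAS summary-statistics dataset
#'
#' Builds a validated `sumstats` object from a data.frame holding one row
#' per variant. Mandatory columns are `snp_id`, `effect_allele`,
#' `other_allele`, `beta`, `se` and `pval`; `chrom`, `pos`, `eaf` and `n`
#' are optional and filled with `NA` when absent. Rows violating the type
#' invariants (non-ACGT or identical alleles, `se <= 0`, `pval` outside
#' (0, 1], `eaf` outside \[0, 1\], duplicated `snp_id`) raise an error;
#' use [read_sumstats()] for tolerant parsing that drops and counts bad
#' rows instead.
#'
#' @param df data.frame of per-variant associations.
#' @param trait_id short machine identifier for the trait.
#' @param trait_name human-readable trait name.
#' @param metadata named list of free-form metadata (ancestry, case/control
#'   counts, provenance of the summary statistics, ...).
#' @return A `sumstats` object (data.frame subclass).
#' @examples
#' ss <- sumstats(data.frame(
#'   snp_id = c("rs1", "rs2"), effect_allele = c("A", "C"),
#'   other_allele = c("G", "T"), beta = c(0.1, -0.05),
#'   se = c(0.01, 0.02), pval = c(1e-8, 1e-3)), trait_id = "exposure")
#' nrow(ss)
#' @export
sumstats <- function(df, trait_id = "trait", trait_name = trait_id,
                     metadata = list()) {
  df <- coerce_sumstats_frame(df)
  bad <- sumstats_row_problems(df)
  if (any(nzchar(bad))) {
    i <- which(nzchar(bad))[1]
    stop("invalid summary-statistics row ", i, " (",
         df$snp_id[i], "): ", bad[i], call. = FALSE)
  }
  if (anyDuplicated(df$snp_id)) {
    stop("duplicated snp_id: ",
         paste(unique(df$snp_id[duplicated(df$snp_id)]), collapse = ", "),
         call. = FALSE)
  }
  new_sumstats(df, trait_id, trait_name, metadata)
}

new_sumstats <- function(df, trait_id, trait_name, metadata) {
  rownames(df) <- NULL
  structure(df[SUMSTATS_COLS],
            trait_id = trait_id,
            trait_name = trait_name,
            metadata = metadata,
            class = c("sumstats", "data.frame"))
}

coerce_sumstats_frame <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(SUMSTATS_MANDATORY, names(df))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(SUMSTATS_COLS, names(df))) df[[col]] <- NA
  chr_cols <- c("snp_id", "chrom", "effect_allele", "other_allele")
  for (col in chr_cols) df[[col]] <- as.character(df[[col]])
  df$effect_allele <- toupper(df$effect_allele)
  df$other_allele <- toupper(df$other_allele)
  num_cols <- c("pos", "eaf", "beta", "se", "pval", "n")
  for (col in num_cols) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df[SUMSTATS_COLS]
}

# One short problem string per row; "" when the row is valid.
sumstats_row_problems <- function(df) {
  problem <- character(nrow(df))
  set <- function(cond, msg) {
    cond[is.na(cond)] <- TRUE
    problem[cond & !nzchar(problem)] <<- msg
  }
  set(is.na(df$snp_id) | !nzchar(df$snp_id), "missing snp_id")
  set(!(df$effect_allele %in% ALLELES), "effect_allele not one of A/C/G/T")
  set(!(df$other_allele %in% ALLELES), "other_allele not one of A/C/G/T")
  set(df$effect_allele == df$other_allele, "identical alleles")
  set(!is.finite(df$beta), "non-numeric beta")
  set(!is.finite(df$se) | df$se <= 0, "se must be > 0")
  set(!is.finite(df$pval) | df$pval <= 0 | df$pval > 1,
      "pval must lie in (0, 1]")
  ok_eaf <- is.na(df$eaf) | (df$eaf >= 0 & df$eaf <= 1)
  problem[!ok_eaf & !nzchar(problem)] <- "eaf outside [0, 1]"
  ok_n <- is.na(df$n) | df$n > 0
  problem[!ok_n & !nzchar(problem)] <- "n must be > 0"
  problem
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics for '%s' (%s): %d variant(s)\n",
              attr(x, "trait_id"), attr(x, "trait_name"), nrow(x)))
  NextMethod()
}

#' Trait identifier of a summary-statistics dataset
#' @param ds a `sumstats` object.
#' @return The `trait_id` attribute (character scalar).
#' @export
trait_id <- function(ds) attr(ds, "trait_id") %||% "trait"

# Subset rows of a sumstats object while preserving its attributes.
ss_keep <- function(ds, keep) {
  out <- as.data.frame(ds)[keep, , drop = FALSE]
  new_sumstats(out, attr(ds, "trait_id"), attr(ds, "trait_name"),
               attr(ds, "metadata") %||% list())
}

ss_metadata_set <- function(ds, key, value) {
  md <- attr(ds, "metadata") %||% list()
  md[[key]] <- value
  attr(ds, "metadata") <- md
  ds
}

#' Default column dialect for summary-statistics files
#'
#' Named character vector mapping the canonical column names to the column
#' headers expected in the file. Override entries to read files whose
#' headers differ, e.g. `c(default_dialect(), snp_id = "rsid")`.
#' @return Named character vector (canonical name -> file header).
#' @export
default_dialect <- function() {
  stats::setNames(SUMSTATS_COLS, SUMSTATS_COLS)
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' Parses a TSV with a header row into a [sumstats()] dataset. Rows whose
#' mandatory fields are missing or unparseable (e.g. `se = "NA"`) are
#' dropped and counted in `metadata$n_dropped`; duplicated `snp_id` rows
#' beyond the first are dropped and counted in `metadata$n_duplicated`.
#'
#' @param path path to a tab-separated file with a header row.
#' @param dialect named character vector mapping canonical column names to
#'   the file's headers; defaults to [default_dialect()]. Only mandatory
#'   columns must resolve; optional columns absent from the file are `NA`.
#' @param trait_id,trait_name trait labels stored on the result.
#' @return A `sumstats` object.
#' @seealso [write_sumstats()] for the inverse operation.
#' @export
read_sumstats <- function(path, dialect = default_dialect(),
                          trait_id = basename(path), trait_name = trait_id) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      na.strings = c("NA", "")),
    error = function(e) stop("cannot parse '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(raw) == 0) stop("empty summary-statistics file: ", path,
                           call. = FALSE)
  full <- stats::setNames(SUMSTATS_COLS, SUMSTATS_COLS)
  full[names(dialect)] <- dialect
  missing_cols <- full[SUMSTATS_MANDATORY][
    !(full[SUMSTATS_MANDATORY] %in% names(raw))]
  if (length(missing_cols)) {
    stop("missing mandatory column(s) in '", path, "': ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in SUMSTATS_COLS) {
    src <- full[[canon]]
    df[[canon]] <- if (src %in% names(raw)) raw[[src]] else NA
  }
  df <- coerce_sumstats_frame(df)
  problems <- sumstats_row_problems(df)
  df <- df[!nzchar(problems), , drop = FALSE]
  dup <- duplicated(df$snp_id)
  df <- df[!dup, , drop = FALSE]
  ds <- new_sumstats(df, trait_id, trait_name,
                     list(source = path,
                          n_dropped = sum(nzchar(problems)),
                          n_duplicated = sum(dup)))
  ds
}

#' Write GWAS summary statistics to a tab-separated file
#'
#' Emits the canonical column order (`snp_id`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`) with
#' missing values encoded as `NA` and rows in input order, so that
#' `read_sumstats(write_sumstats(ds, f))` round-trips field-identically.
#'
#' @param ds a `sumstats` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ds, path) {
  stopifnot(inherits(ds, "sumstats") || is.data.frame(ds))
  df <- as.data.frame(ds)[SUMSTATS_COLS]
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Test whether an allele pair is palindromic
#'
#' A variant is palindromic when its two alleles are reverse complements of
#' one another ({A,T} or {C,G}); for such variants the strand cannot be
#' resolved from the alleles alone and effect alignment between two studies
#' is ambiguous.
#'
#' @param effect_allele,other_allele allele letters (A/C/G/T), vectorised.
#' @return Logical vector.
#' @examples
#' is_palindromic("A", "T")  # TRUE
#' is_palindromic("A", "G")  # FALSE
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  effect_allele <- toupper(effect_allele)
  other_allele <- toupper(other_allele)
  if (!all(effect_allele %in% ALLELES) || !all(other_allele %in% ALLELES)) {
    stop("alleles must be one of A/C/G/T", call. = FALSE)
  }
  unname(ALLELE_COMPLEMENT[effect_allele] == other_allele)
}

#' Align association records to a target effect allele
#'
#' Re-expresses each record on the orientation given by
#' (`target_effect`, `target_other`). When the target orientation is the
#' record's own, the record is returned unchanged; when it is the swapped
#' orientation, the alleles are swapped, `beta` is negated and `eaf`
#' replaced by `1 - eaf`. Applying the same flip twice restores the
#' original record. Palindromic records and allele-set mismatches are
#' errors; harmonization ([harmonize()]) handles those dispositions.
#'
#' @param ds a `sumstats` object (or data.frame with the canonical columns).
#' @param target_effect,target_other target alleles, recycled along rows.
#' @return The aligned dataset, same class as the input.
#' @export
align_to_effect_allele <- function(ds, target_effect, target_other) {
  df <- as.data.frame(ds)
  target_effect <- rep(toupper(target_effect), length.out = nrow(df))
  target_other <- rep(toupper(target_other), length.out = nrow(df))
  if (any(is_palindromic(df$effect_allele, df$other_allele))) {
    stop("cannot align palindromic variants by allele identity", call. = FALSE)
  }
  same <- df$effect_allele == target_effect & df$other_allele == target_other
  swapped <- df$effect_allele == target_other & df$other_allele == target_effect
  if (!all(same | swapped)) {
    bad <- df$snp_id[!(same | swapped)]
    stop("allele set mismatch for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df$beta[swapped] <- -df$beta[swapped]
  df$eaf[swapped] <- 1 - df$eaf[swapped]
  ea <- df$effect_allele
  df$effect_allele[swapped] <- df$other_allele[swapped]
  df$other_allele[swapped] <- ea[swapped]
  if (inherits(ds, "sumstats")) {
    new_sumstats(df, attr(ds, "trait_id"), attr(ds, "trait_name"),
                 attr(ds, "metadata") %||% list())
  } else {
    df
  }
}
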