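# Data model, TSV I/O, palindrome logic, allele alignment, harmonization.

test_that("TSV round trip preserves every field and drops bad rows", {
  ds <- make_sumstats(c("rs1", "rs2", "rs3"), beta = c(0.1, -0.2, 0.05),
                      se = c(0.01, 0.02, 0.03), pval = c(1e-8, 1e-6, 1e-4),
                      eaf = c(0.1, 0.5, NA))
  ds$eaf <- c(0.1, 0.5, NA)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(ds, f)
  back <- read_sumstats(f, trait_id = "trait")
  expect_equal(nrow(back), 3)
  expect_equal(ss_frame(back), ss_frame(ds))

  # a row with se = "NA" is unparseable for a mandatory field: dropped
  raw <- utils::read.delim(f, colClasses = "character")
  raw$se[2] <- "NA"
  f2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(raw, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- read_sumstats(f2)
  expect_equal(nrow(back2), 2)
  expect_equal(attr(back2, "metadata")$n_dropped, 1)
})

test_that("reader reports missing mandatory columns and dialects remap", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp_id\tbeta", "rs1\t0.1"), f)
  expect_error(read_sumstats(f), "mandatory column")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tA1\tA2\tb\ts\tp",
               "rs1\tA\tG\t0.1\t0.01\t1e-8"), f2)
  ds <- read_sumstats(f2, dialect = c(snp_id = "rsid", effect_allele = "A1",
                                      other_allele = "A2", beta = "b",
                                      se = "s", pval = "p"))
  expect_equal(ds$snp_id, "rs1")
  expect_equal(ds$beta, 0.1)
  expect_true(is.na(ds$eaf))
})

test_that("writing an empty dataset yields a header-only file", {
  ds <- make_sumstats(character(), beta = numeric(), se = numeric(),
                      pval = numeric())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(ds, f)
  expect_length(readLines(f), 1)
  ds1 <- make_sumstats("rs1", beta = 0.1, se = 0.01, pval = 1e-6)
  write_sumstats(ds1, f)
  expect_length(readLines(f), 2)
})

test_that("constructor enforces the record invariants", {
  base <- data.frame(snp_id = "rs1", effect_allele = "A",
                     other_allele = "G", beta = 0.1, se = 0.01,
                     pval = 1e-6, stringsAsFactors = FALSE)
  expect_s3_class(sumstats(base), "sumstats")
  bad_se <- transform(base, se = 0)
  expect_error(sumstats(bad_se), "se")
  bad_al <- transform(base, other_allele = "A")
  expect_error(sumstats(bad_al), "identical alleles")
  bad_p <- transform(base, pval = 0)
  expect_error(sumstats(bad_p), "pval")
  expect_error(sumstats(rbind(base, base)), "duplicated")
})

test_that("palindrome detection covers complement pairs only", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("C", "G"))
  expect_true(is_palindromic("G", "C"))
  expect_false(is_palindromic("A", "G"))
  expect_false(is_palindromic("C", "T"))
  expect_error(is_palindromic("A", "N"), "A/C/G/T")
})

test_that("allele alignment flips beta and eaf and is an involution", {
  ds <- make_sumstats("rs1", beta = 0.10, se = 0.01, pval = 1e-6, eaf = 0.3)
  flipped <- align_to_effect_allele(ds, "G", "A")
  expect_equal(flipped$beta, -0.10)
  expect_equal(flipped$eaf, 0.7)
  expect_equal(flipped$effect_allele, "G")
  same <- align_to_effect_allele(ds, "A", "G")
  expect_equal(ss_frame(same), ss_frame(ds))
  twice <- align_to_effect_allele(flipped, "A", "G")
  expect_equal(ss_frame(twice), ss_frame(ds))
  expect_error(align_to_effect_allele(ds, "A", "C"), "mismatch")
})

test_that("harmonization aligns, flips, and logs every disposition", {
  exp <- make_sumstats(c("rs1", "rs2", "rs3", "rs4"),
                       beta = 0.1, se = 0.01, pval = 1e-6,
                       effect_allele = c("A", "A", "A", "A"),
                       other_allele = c("G", "T", "G", "G"))
  out_df <- data.frame(
    snp_id = c("rs1", "rs2", "rs3", "rs9"), chrom = "1",
    pos = 1e6 + (0:3) * 1e5,
    effect_allele = c("G", "A", "C", "A"),
    other_allele = c("A", "T", "T", "G"),
    eaf = 0.4, beta = c(0.05, 0.02, 0.01, 0.01), se = 0.02,
    pval = 0.5, n = 1e5, stringsAsFactors = FALSE)
  out <- sumstats(out_df, trait_id = "outcome")
  hd <- harmonize(exp, out)
  log <- hd$log
  expect_equal(log$disposition[log$snp_id == "rs1"], "flipped")
  expect_equal(log$disposition[log$snp_id == "rs2"], "dropped-palindromic")
  expect_equal(log$disposition[log$snp_id == "rs3"],
               "dropped-allele-mismatch")
  expect_equal(log$disposition[log$snp_id == "rs4"], "dropped-missing")
  expect_equal(log$disposition[log$snp_id == "rs9"], "dropped-missing")
  expect_equal(hd$pairs$snp_id, "rs1")
  expect_equal(hd$pairs$beta_out, -0.05)
  expect_equal(hd$pairs$eaf_out, 0.6)
})

test_that("disjoint SNP sets harmonize to zero pairs with a warning", {
  a <- make_sumstats("rs1", beta = 0.1, se = 0.01, pval = 1e-6)
  b <- make_sumstats("rs2", beta = 0.1, se = 0.01, pval = 1e-6,
                     trait_id = "outcome")
  expect_warning(hd <- harmonize(a, b), "no harmonizable")
  expect_equal(nrow(hd$pairs), 0)
  expect_true(all(hd$log$disposition == "dropped-missing"))
})

test_that("harmonization conserves counts and is idempotent", {
  for (seed in 1:5) {
    study <- simulate_study(sim_scenario(n_snp = 40,
                                         include_palindromic = TRUE,
                                         label = "pal"), seed)
    hd <- harmonize(study$exposure, study$outcome)
    shared <- intersect(study$exposure$snp_id, study$outcome$snp_id)
    dropped_shared <- sum(hd$log$disposition %in%
                            c("dropped-palindromic",
                              "dropped-allele-mismatch") &
                            hd$log$snp_id %in% shared)
    expect_equal(nrow(hd$pairs) + dropped_shared, length(shared))
    # feeding the harmonized pairs back through changes nothing
    p <- hd$pairs
    exp2 <- sumstats(data.frame(
      snp_id = p$snp_id, effect_allele = p$effect_allele,
      other_allele = p$other_allele, beta = p$beta_exp, se = p$se_exp,
      pval = p$pval_exp, eaf = p$eaf_exp), trait_id = "exp2")
    out2 <- sumstats(data.frame(
      snp_id = p$snp_id, effect_allele = p$effect_allele,
      other_allele = p$other_allele, beta = p$beta_out, se = p$se_out,
      pval = p$pval_out, eaf = p$eaf_out), trait_id = "out2")
    hd2 <- harmonize(exp2, out2)
    expect_equal(hd2$pairs$beta_out, p$beta_out)
    expect_true(all(hd2$log$disposition == "kept"))
  }
})

test_that("frequency inference can rescue unambiguous palindromic SNPs", {
  exp <- make_sumstats(c("rs1", "rs2"), beta = c(0.1, 0.1), se = 0.01,
                       pval = 1e-6, effect_allele = "A", other_allele = "T",
                       eaf = c(0.1, 0.1))
  out_df <- data.frame(snp_id = c("rs1", "rs2"), chrom = "1",
                       pos = c(1e6, 1.1e6), effect_allele = "A",
                       other_allele = "T", eaf = c(0.12, 0.88),
                       beta = c(0.05, 0.05), se = 0.02, pval = 0.5,
                       n = 1e5)
  out <- sumstats(out_df, trait_id = "outcome")
  expect_warning(hd_drop <- harmonize(exp, out), "no harmonizable")
  expect_equal(nrow(hd_drop$pairs), 0)
  hd_infer <- harmonize(exp, out, palindromic = "infer")
  expect_equal(nrow(hd_infer$pairs), 2)
  # rs1 concordant (kept as-is), rs2 discordant (flipped)
  expect_equal(hd_infer$pairs$beta_out, c(0.05, -0.05))
})

test_that("Wald ratios are invariant to joint allele reorientation", {
  p <- make_pairs(c(0.1, -0.2), c(0.05, 0.08), se_out = c(0.01, 0.02))
  flipped <- p
  flipped$beta_exp <- -p$beta_exp
  flipped$beta_out <- -p$beta_out
  expect_equal(wald_ratio(p)$ratio, wald_ratio(flipped)$ratio)
  expect_equal(wald_ratio(p)$se_ratio, wald_ratio(flipped)$se_ratio)
})
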