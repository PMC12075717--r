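# Instrument-selection filters, clumping, and the end-to-end audit report.

test_that("p-value filter is strict and handles edge thresholds", {
  ds <- make_sumstats(c("a", "b", "c"), beta = 0.1, se = 0.01,
                      pval = c(1e-6, 1e-5, 1e-4))
  ds$pval <- c(1e-6, 1e-5, 1e-4)
  expect_equal(filter_by_pvalue(ds, 1e-5)$snp_id, "a")
  expect_equal(nrow(filter_by_pvalue(ds[0, ], 1e-5)), 0)
  expect_equal(nrow(filter_by_pvalue(ds, 1.0)), 3)
})

test_that("F-statistic is (beta/se)^2 and guards its domain", {
  expect_equal(f_statistic(0.1, 0.01), 100)
  expect_equal(f_statistic(0, 0.02), 0)
  expect_lt(f_statistic(0.0316, 0.01), 10)  # just under the F > 10 rule
  expect_error(f_statistic(0.1, 0), "se")
})

test_that("MAF filter applies min(eaf, 1 - eaf) and drops missing eaf", {
  ds <- make_sumstats(c("a", "b", "c", "d"), beta = 0.1, se = 0.01,
                      pval = 1e-6, eaf = c(0.005, 0.5, 0.995, NA))
  ds$eaf <- c(0.005, 0.5, 0.995, NA)
  expect_equal(filter_by_maf(ds, 0.01)$snp_id, "b")
})

test_that("outcome-association exclusion removes only significant overlap", {
  inst <- make_sumstats(c("a", "b", "c"), beta = 0.1, se = 0.01,
                        pval = 1e-8)
  out <- make_sumstats(c("a", "b"), beta = 0.01, se = 0.01,
                       pval = c(1e-7, 0.5), trait_id = "outcome")
  out$pval <- c(1e-7, 0.5)
  kept <- exclude_outcome_associated(inst, out, 1e-5)
  expect_setequal(kept$snp_id, c("b", "c"))  # "c" absent from outcome: kept
})

test_that("exclusion lists remove named variants only", {
  inst <- make_sumstats(c("rs3184504", "rs1446585", "rs42"),
                        beta = 0.1, se = 0.01, pval = 1e-8)
  expect_setequal(apply_exclusion_list(inst, "rs3184504")$snp_id,
                  c("rs1446585", "rs42"))
  expect_setequal(apply_exclusion_list(inst, "rs1446585")$snp_id,
                  c("rs3184504", "rs42"))
  expect_equal(apply_exclusion_list(inst, character())$snp_id, inst$snp_id)
})

test_that("greedy clumping keeps the best instrument per LD cluster", {
  ids <- c("s1", "s2", "s3")
  ds <- make_sumstats(ids, beta = 0.1, se = 0.01,
                      pval = c(1e-8, 1e-6, 1e-7),
                      pos = c(1e6, 1.1e6, 1.2e6))
  ds$pval <- c(1e-8, 1e-6, 1e-7)
  r2 <- diag(3)
  dimnames(r2) <- list(ids, ids)
  r2["s1", "s2"] <- r2["s2", "s1"] <- 0.5
  r2["s1", "s3"] <- r2["s3", "s1"] <- 0.0005
  r2["s2", "s3"] <- r2["s3", "s2"] <- 0.0005
  kept <- clump(ds, ld_matrix(r2, ids), 0.001, 10000)
  expect_setequal(kept$snp_id, c("s1", "s3"))

  # independent variants all survive
  expect_equal(nrow(clump(ds, ld_matrix(diag(3) + 0, ids), 0.001, 10000)), 3)

  # perfect proxies at the same position: smaller p wins
  two <- make_sumstats(c("a", "b"), beta = 0.1, se = 0.01,
                       pval = c(1e-9, 1e-6), pos = c(1e6, 1e6))
  two$pval <- c(1e-9, 1e-6)
  r2b <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(clump(two, ld_matrix(r2b), 0.001, 10000)$snp_id, "a")

  expect_error(clump(ds, ld_matrix(r2b), 0.001, 10000), "absent from the LD")
})

test_that("clumping respects the physical window", {
  ds <- make_sumstats(c("a", "b"), beta = 0.1, se = 0.01,
                      pval = c(1e-9, 1e-6), pos = c(1e6, 1e6 + 2e7))
  ds$pval <- c(1e-9, 1e-6)
  r2 <- matrix(c(1, 0.9, 0.9, 1), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  # 20 Mb apart: outside a 10,000 kb window, both kept despite high r2
  expect_equal(nrow(clump(ds, ld_matrix(r2), 0.001, 10000)), 2)
  expect_equal(clump(ds, ld_matrix(r2), 0.001, 30000)$snp_id, "a")
})

test_that("clumping matches the brute-force maximal-set oracle", {
  for (seed in 1:40) {
    inst <- random_clump_instance(seed)
    kept <- clump(inst$ds, inst$ld, 0.1, 5000)
    oracle <- clump_oracle_ids(inst$df, inst$ld$r2, 0.1, 5000)
    expect_setequal(kept$snp_id, oracle)
    # kept set is conflict-free
    ids <- kept$snp_id
    if (length(ids) > 1) {
      for (a in seq_along(ids)) for (b in seq_along(ids)) {
        if (a >= b) next
        ra <- which(inst$df$snp_id == ids[a])
        rb <- which(inst$df$snp_id == ids[b])
        conflict <- inst$df$chrom[ra] == inst$df$chrom[rb] &&
          abs(inst$df$pos[ra] - inst$df$pos[rb]) <= 5000 * 1000 &&
          inst$ld$r2[ids[a], ids[b]] >= 0.1
        expect_false(conflict)
      }
    }
  }
})

test_that("MAF and F filters commute", {
  set.seed(1)
  ds <- make_sumstats(sprintf("m%02d", 1:30),
                      beta = stats::rnorm(30, 0, 0.03),
                      se = stats::runif(30, 0.004, 0.02),
                      pval = 1e-8, eaf = stats::runif(30, 0, 0.5))
  ds$beta <- stats::rnorm(30, 0, 0.03)
  ds$eaf <- stats::runif(30, 0, 0.5)
  a <- filter_by_maf(ds, 0.05)
  a <- a[f_statistic(a$beta, a$se) > 10, ]
  b <- ds[f_statistic(ds$beta, ds$se) > 10, ]
  b <- filter_by_maf(b, 0.05)
  expect_equal(a$snp_id, b$snp_id)
})

test_that("the selection pipeline reproduces planted dispositions", {
  fx <- fixture_selection()
  sel <- select_instruments(fx$exposure, fx$outcome, fx$ld,
                            selection_config())
  got <- stats::setNames(sel$report$disposition, sel$report$snp_id)
  expect_equal(got[names(fx$expected)], fx$expected)
  expect_equal(nrow(sel$instruments), 10)
  # dispositions partition the input
  expect_equal(sum(got == "kept") + sum(got != "kept"), 20)
  expect_setequal(sel$instruments$snp_id,
                  names(fx$expected)[fx$expected == "kept"])
})

test_that("selection handles the all-pass and none-pass extremes", {
  ds <- make_sumstats(c("a", "b"), beta = 0.1, se = 0.01, pval = 1e-8,
                      pos = c(1e6, 2e8))
  sel <- select_instruments(ds, NULL, NULL, selection_config())
  expect_equal(nrow(sel$instruments), 2)
  none <- select_instruments(ds, NULL, NULL,
                             selection_config(p_instrument = 1e-12))
  expect_equal(nrow(none$instruments), 0)
  expect_true(all(none$report$disposition == "failed-p"))
})
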