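# Estimator layer: Wald ratios, IVW, MR-Egger, weighted median, modes.

test_that("Wald ratio arithmetic and degenerate cases", {
  wr <- wald_ratio(make_pairs(0.2, 0.1, se_out = 0.02))
  expect_equal(wr$ratio, 0.5)
  expect_equal(wr$se_ratio, 0.1)
  expect_equal(wr$weight, 100)
  expect_equal(wald_ratio(make_pairs(0.2, 0))$ratio, 0)
  expect_error(wald_ratio(make_pairs(0, 0.1)), "zero exposure")
})

test_that("IVW matches its closed form and a WLS-through-origin oracle", {
  hd <- make_pairs(c(0.1, 0.2), c(0.05, 0.10), se_out = 0.01)
  e <- mr_ivw(hd, "fixed")
  expect_equal(e$beta, 0.5)
  expect_equal(e$se, sqrt(1 / 500))
  for (seed in 1:25) {
    set.seed(seed)
    J <- sample(2:20, 1)
    p <- make_pairs(stats::rnorm(J, 0, 0.1) + 0.2,
                    stats::rnorm(J, 0, 0.05),
                    se_out = stats::runif(J, 0.005, 0.05))
    expect_equal(mr_ivw(p, "fixed")$beta, ivw_oracle(p), tolerance = 1e-10)
  }
})

test_that("IVW reduces to the Wald ratio at J = 1 and is flip-invariant", {
  p1 <- make_pairs(0.2, 0.1, se_out = 0.02)
  e1 <- mr_ivw(p1)
  expect_equal(e1$beta, 0.5)
  expect_equal(e1$se, 0.1)
  expect_equal(e1$n_snp, 1L)
  p <- make_pairs(c(0.1, -0.2, 0.15), c(0.05, 0.04, -0.02),
                  se_out = c(0.01, 0.02, 0.015))
  flip <- p
  s <- c(-1, 1, -1)
  flip$beta_exp <- p$beta_exp * s
  flip$beta_out <- p$beta_out * s
  expect_equal(mr_ivw(p)$beta, mr_ivw(flip)$beta)
  expect_equal(mr_ivw(p)$se, mr_ivw(flip)$se)
})

test_that("exact proportional data collapse the effects models", {
  p <- make_pairs(c(0.1, 0.2, 0.3), 0.7 * c(0.1, 0.2, 0.3),
                  se_out = c(0.01, 0.02, 0.03))
  fixed <- mr_ivw(p, "fixed")
  mre <- mr_ivw(p, "mre")
  expect_equal(fixed$beta, 0.7, tolerance = 1e-12)
  expect_equal(fixed$extras$q_stat, 0, tolerance = 1e-20)
  expect_equal(mre$se, fixed$se)  # underdispersion floored at 1
})

test_that("Egger recovers an exact linear relation to machine precision", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  p <- make_pairs(bx, 0.02 + 0.5 * bx,
                  se_out = c(0.01, 0.03, 0.02, 0.05))
  e <- mr_egger(p)
  expect_equal(e$beta, 0.5, tolerance = 1e-10)
  expect_equal(e$extras$intercept, 0.02, tolerance = 1e-10)
  expect_equal(e$extras$residual_scale, 0, tolerance = 1e-6)
  # orientation: flipping some exposure signs must not change the fit
  flip <- p
  s <- c(1, -1, 1, -1)
  flip$beta_exp <- p$beta_exp * s
  flip$beta_out <- p$beta_out * s
  e2 <- mr_egger(flip)
  expect_equal(e2$beta, e$beta, tolerance = 1e-12)
  expect_equal(e2$extras$intercept, e$extras$intercept, tolerance = 1e-12)
  expect_error(mr_egger(make_pairs(c(0.1, 0.2), c(0.1, 0.2))), "at least 3")
})

test_that("weighted median interpolates the weighted CDF midpoint", {
  p <- make_pairs(c(1, 1, 1), c(0.1, 0.5, 0.9), se_out = 0.1)
  wm <- mr_weighted_median(p, n_boot = 200, seed = 1)
  expect_equal(wm$beta, 0.5)
  # equal weights, odd J: the plain sample median (property over draws)
  for (seed in 1:10) {
    set.seed(seed)
    J <- sample(c(3, 5, 7, 9), 1)
    ratios <- stats::rnorm(J)
    p2 <- make_pairs(rep(1, J), ratios, se_out = 0.1)
    wm2 <- mr_weighted_median(p2, n_boot = 2, seed = 1)
    expect_equal(wm2$beta, stats::median(ratios))
  }
  # near-total weight domination pins the estimate to that ratio
  p3 <- make_pairs(c(1, 1, 1), c(0.2, 0.8, 1.4),
                   se_out = c(0.001, 1, 1))
  wm3 <- mr_weighted_median(p3, n_boot = 2, seed = 1)
  expect_equal(wm3$beta, 0.2, tolerance = 1e-3)
})

test_that("weighted median bootstrap SE is reproducible under a seed", {
  p <- make_pairs(c(0.1, 0.2, 0.3, 0.15), c(0.05, 0.1, 0.14, 0.08),
                  se_exp = 0.02, se_out = 0.02)
  a <- mr_weighted_median(p, n_boot = 300, seed = 7)
  b <- mr_weighted_median(p, n_boot = 300, seed = 7)
  c <- mr_weighted_median(p, n_boot = 300, seed = 8)
  expect_identical(a$se, b$se)
  expect_false(identical(a$se, c$se))
})

test_that("mode estimators find the dominant ratio cluster", {
  p <- make_pairs(rep(1, 4), c(0.5, 0.5, 0.5, 5.0), se_out = 0.1)
  sm <- mr_mode(p, weighted = FALSE, n_boot = 50, seed = 1)
  # brute-force grid oracle for the kernel-density argmax
  r <- c(0.5, 0.5, 0.5, 5.0)
  h <- 0.9 * min(stats::sd(r), stats::IQR(r) / 1.349) * 4^(-1 / 5)
  grid <- seq(min(r) - h, max(r) + h, length.out = 20001)
  dens <- vapply(grid, function(x) sum(stats::dnorm((x - r) / h)),
                 numeric(1))
  expect_equal(sm$beta, grid[which.max(dens)], tolerance = 1e-3)
  expect_equal(sm$beta, 0.5, tolerance = 0.05)

  same <- mr_mode(make_pairs(rep(1, 3), rep(0.3, 3)), n_boot = 20, seed = 1)
  expect_equal(same$beta, 0.3)

  dom <- mr_mode(make_pairs(rep(1, 4), c(0.2, 1, 2, 3),
                            se_out = c(0.001, 5, 5, 5)),
                 weighted = TRUE, n_boot = 20, seed = 1)
  expect_equal(dom$beta, 0.2, tolerance = 0.05)
})

test_that("mr_all degenerates gracefully and agrees on exact-fit data", {
  bx <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  p <- make_pairs(bx, 0.6 * bx, se_out = 0.01)
  res <- mr_all(p, n_boot = 50, seed = 3)
  betas <- vapply(res$estimates, function(e) e$beta, numeric(1))
  expect_length(betas, 5)
  expect_true(all(abs(betas - 0.6) < 1e-6))

  p2 <- make_pairs(c(0.1, 0.2), c(0.05, 0.12))
  res2 <- mr_all(p2, n_boot = 20, seed = 3)
  expect_true("ivw" %in% names(res2$estimates))
  expect_setequal(names(res2$not_computed),
                  c("egger", "weighted_median", "weighted_mode",
                    "simple_mode"))
})

test_that("confidence intervals bracket the estimate on both scales", {
  p <- make_pairs(c(0.1, 0.2, 0.3), c(0.02, 0.05, 0.09),
                  se_out = c(0.01, 0.02, 0.01))
  for (e in list(mr_ivw(p), mr_egger(p))) {
    expect_lte(e$ci_low, e$beta)
    expect_gte(e$ci_high, e$beta)
    expect_equal(e$or, exp(e$beta))
    expect_equal(e$or_ci_low, exp(e$ci_low))
  }
})
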