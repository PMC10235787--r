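test_that("ratio estimates are elementwise Wald ratios", {
  h <- h_set(bx = c(0.2, -0.2), by = c(0.1, 0.1), sy = c(0.02, 0.02))
  r <- ratio_estimates(h)
  expect_equal(r$theta, c(0.5, -0.5))
  expect_equal(r$se, c(0.1, 0.1))

  set.seed(5)
  J <- 10
  bx <- rnorm(J, 0.1, 0.03); by <- rnorm(J, 0.05, 0.02)
  sy <- runif(J, 0.005, 0.02)
  r2 <- ratio_estimates(h_set(bx, by, sy))
  expect_equal(r2$theta, by / bx)
  expect_equal(r2$se, sy / abs(bx))

  hz <- h_set(bx = c(0.2, 0), by = c(0.1, 0.1), sy = c(0.02, 0.02))
  expect_warning(rz <- ratio_estimates(hz), class = "mr_zero_exposure_beta")
  expect_equal(nrow(rz), 1)
})

test_that("IVW: single-variant collapse, homogeneity, and WLS equivalence", {
  h1 <- h_set(0.2, 0.1, 0.02)
  expect_warning(e1 <- mr_ivw(h1), class = "mr_single_variant")
  expect_equal(e1$method, "wald_ratio")
  expect_equal(e1$theta, 0.5)

  # identical ratios: Q = 0, random SE equals fixed SE
  h2 <- h_set(c(0.1, 0.2, 0.4), c(0.05, 0.10, 0.20), c(0.01, 0.01, 0.01))
  er <- mr_ivw(h2, model = "random")
  ef <- mr_ivw(h2, model = "fixed")
  expect_equal(er$Q, 0, tolerance = 1e-12)
  expect_equal(er$se, ef$se)

  # 8 hand-specified pairs match the intercept-free weighted regression
  set.seed(8)
  bx <- rnorm(8, 0.15, 0.05); by <- 0.4 * bx + rnorm(8, 0, 0.01)
  sy <- runif(8, 0.005, 0.02)
  h3 <- h_set(bx, by, sy)
  est <- mr_ivw(h3)
  orc <- ivw_oracle(bx, by, sy)
  expect_equal(est$theta, orc$theta, tolerance = 1e-12)
  expect_equal(mr_ivw(h3, "fixed")$se, orc$se_fixed, tolerance = 1e-12)
  # OR triple is the exponentiated estimate
  expect_equal(est$or, exp(est$theta))
  expect_equal(est$or_ci_low, exp(est$ci_low))
})

test_that("weighted median: trivial cases and cumulative-weight oracle", {
  h <- h_set(rep(0.1, 4), rep(0.03, 4), rep(0.01, 4))
  wm <- mr_weighted_median(h, n_boot = 50, seed = 1)
  expect_equal(wm$theta, 0.3, tolerance = 1e-12)

  # theta = 1..5 with equal weights -> 3
  h2 <- h_set(rep(0.1, 5), 0.1 * (1:5), rep(0.01, 5))
  expect_equal(mr_weighted_median(h2, n_boot = 50, seed = 1)$theta, 3)

  # unequal weights match the analytic scan oracle
  set.seed(17)
  for (i in 1:5) {
    J <- 5 + i
    bx <- runif(J, 0.05, 0.3); by <- rnorm(J, 0.2 * bx, 0.01)
    sy <- runif(J, 0.004, 0.03)
    est <- mr_weighted_median(h_set(bx, by, sy), n_boot = 10, seed = i)
    expect_equal(est$theta, wm_oracle(by / bx, (bx / sy)^2),
                 tolerance = 1e-12)
  }

  expect_error(mr_weighted_median(h_set(0.1, 0.1, 0.1), seed = 1),
               class = "mr_method_unavailable")
  expect_error(mr_weighted_median(h2, n_boot = 10),
               class = "mr_usage_error")
})

test_that("MR-Egger: exact-fit recovery and normal-equations oracle", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  by <- 0.02 + 0.5 * bx
  sy <- c(0.01, 0.02, 0.015, 0.012)
  eg <- mr_egger(h_set(bx, by, sy))
  expect_equal(eg$intercept$theta, 0.02, tolerance = 1e-10)
  expect_equal(eg$slope$theta, 0.5, tolerance = 1e-10)

  set.seed(7)
  for (i in 1:5) {
    J <- sample(4:12, 1)
    bx <- rnorm(J, 0.1, 0.08)   # mixed signs exercise orientation
    by <- 0.01 + 0.3 * abs(bx) * sign(bx) + rnorm(J, 0, 0.02)
    sy <- runif(J, 0.005, 0.03)
    eg <- mr_egger(h_set(bx, by, sy))
    orc <- egger_oracle(bx, by, sy)
    expect_equal(eg$slope$theta, orc$slope, tolerance = 1e-10)
    expect_equal(eg$intercept$theta, orc$intercept, tolerance = 1e-10)
    expect_equal(eg$slope$se, orc$se_slope, tolerance = 1e-10)
    expect_equal(eg$intercept$se, orc$se_intercept, tolerance = 1e-10)
  }

  expect_error(mr_egger(h_set(c(0.1, 0.2), c(0.1, 0.1), c(0.01, 0.01))),
               class = "mr_method_unavailable")
})

test_that("Egger intercept test holds its size under a no-pleiotropy model", {
  set.seed(19)
  J <- 50
  rej <- vapply(1:400, function(i) {
    bx <- runif(J, 0.05, 0.3)
    sy <- rep(0.01, J)
    by <- rnorm(J, 0.3 * bx, sy)
    mr_egger(h_set(bx, by, sy))$intercept$pval < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.09)
})

test_that("estimators are scale-equivariant and orientation-invariant", {
  set.seed(23)
  J <- 12
  bx <- runif(J, 0.05, 0.3); by <- rnorm(J, 0.25 * bx, 0.01)
  sy <- runif(J, 0.005, 0.02); sx <- runif(J, 0.002, 0.005)
  h <- h_set(bx, by, sy, sx)
  cc <- 2.5
  hs <- h_set(cc * bx, by, sy, cc * sx)
  expect_equal(mr_ivw(hs)$theta, mr_ivw(h)$theta / cc, tolerance = 1e-12)
  expect_equal(mr_weighted_median(hs, n_boot = 10, seed = 3)$theta,
               mr_weighted_median(h, n_boot = 10, seed = 3)$theta / cc,
               tolerance = 1e-12)
  expect_equal(mr_egger(hs)$slope$theta, mr_egger(h)$slope$theta / cc,
               tolerance = 1e-12)

  flip <- rep(1, J); flip[c(2, 7)] <- -1
  hf <- h_set(flip * bx, flip * by, sy, sx)
  expect_equal(mr_ivw(hf)$theta, mr_ivw(h)$theta, tolerance = 1e-12)
  expect_equal(mr_ivw(hf)$se, mr_ivw(h)$se, tolerance = 1e-12)
  expect_equal(mr_weighted_median(hf, n_boot = 10, seed = 3)$theta,
               mr_weighted_median(h, n_boot = 10, seed = 3)$theta,
               tolerance = 1e-12)
  expect_equal(mr_egger(hf)$slope$theta, mr_egger(h)$slope$theta,
               tolerance = 1e-12)
  expect_equal(mr_egger(hf)$intercept$theta, mr_egger(h)$intercept$theta,
               tolerance = 1e-12)
})

test_that("IVW coverage and unbiasedness under the no-pleiotropy generator", {
  cfg <- truth_config(J = 50, theta_direct = 0.2)
  truth <- 0.2
  res <- vapply(1:150, function(i) {
    st <- simulate_study(cfg, seed = 40000 + i)
    est <- mr_ivw(total_effect_hset(st))
    c(est$theta, est$ci_low <= truth && truth <= est$ci_high)
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) - truth), 3 * sd(res[1, ]) / sqrt(150))
  expect_gte(mean(res[2, ]), 0.90)
})

test_that("balanced pleiotropy leaves IVW ~unbiased; directional pleiotropy
           is recovered by the Egger intercept under InSIDE", {
  suite <- scenario_suite()
  bal <- vapply(1:60, function(i) {
    st <- simulate_study(suite$balanced_pleiotropy, seed = 50000 + i)
    mr_ivw(total_effect_hset(st))$theta
  }, numeric(1))
  expect_lt(abs(mean(bal) - 0.2), 3 * sd(bal) / sqrt(60) + 0.005)

  dir_res <- vapply(1:60, function(i) {
    st <- simulate_study(suite$directional_pleiotropy, seed = 60000 + i)
    h <- total_effect_hset(st)
    eg <- mr_egger(h)
    tr <- st$truth[match(h$variant_ids, st$truth$variant_id), ]
    c(eg$intercept$theta, eg$slope$theta, mean(tr$alpha))
  }, numeric(3))
  # intercept estimates the mean pleiotropic effect; slope the causal effect
  # (the regression recovers a precision-weighted rather than arithmetic
  # mean of alpha, so allow a small systematic margin on top of MC error)
  expect_lt(abs(mean(dir_res[1, ] - dir_res[3, ])),
            3 * sd(dir_res[1, ]) / sqrt(60) + 0.0015)
  expect_lt(abs(mean(dir_res[2, ]) - 0.2),
            3 * sd(dir_res[2, ]) / sqrt(60) + 0.01)
})

test_that("MR-PRESSO flags a planted outlier and is consistent without one", {
  suite <- scenario_suite()
  cfg <- utils::modifyList(suite$one_outlier, list(J = 20, J_med = 0))
  class(cfg) <- "truth_config"
  st <- simulate_study(cfg, seed = 77)
  h <- total_effect_hset(st)
  pr <- mr_presso(h, n_sim = 1000, seed = 78)
  truth_out <- st$truth$variant_id[st$truth$outlier]
  expect_true(truth_out %in% pr$outliers$variant_id[pr$outliers$flagged])
  expect_lt(pr$global_rss_p, 0.05)
  expect_equal(pr$corrected$n_snps, pr$raw$n_snps - sum(pr$outliers$flagged))
  expect_false(is.na(pr$distortion_p))

  # clean data: corrected estimate is exactly the raw IVW
  cfg2 <- truth_config(J = 20, J_med = 0, theta_direct = 0.2)
  st2 <- simulate_study(cfg2, seed = 79)
  h2 <- total_effect_hset(st2)
  pr2 <- mr_presso(h2, n_sim = 500, seed = 80)
  if (!any(pr2$outliers$flagged)) {
    expect_identical(pr2$corrected$theta, pr2$raw$theta)
  }
  expect_error(mr_presso(h_set(1:3 / 10, 1:3 / 10, rep(0.01, 3)), seed = 1),
               class = "mr_method_unavailable")
  # simulation count too small for the Bonferroni threshold -> warning
  expect_warning(mr_presso(h2, n_sim = 100, seed = 81),
                 class = "mr_presso_resolution")
})
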