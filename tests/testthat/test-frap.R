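test_that("trace validation catches malformed series", {
  expect_error(frap_trace(c(0, 1), c(1, 1, 1), c(1, 1), c(0, 0), 1),
               "same length")
  expect_error(frap_trace(c(0, 0), c(1, 1), c(1, 1), c(0, 0), 1),
               "strictly increasing")
  expect_error(frap_trace(c(-1, 0, 1), rep(1, 3), rep(1, 3), rep(0, 3), 3),
               "n_pre")
})

test_that("double normalization reduces to the identity cases", {
  t <- c(-2, -1, seq(0, 20))
  roi <- c(1, 1, 0.5 + 0.25 * (1 - 2^(-seq(0, 20) / 5)))
  # constant reference, zero background: I_dn = roi / mean_pre(roi)
  tr <- frap_trace(t, roi, rep(2, length(t)), rep(0, length(t)), 2)
  expect_equal(normalize_trace(tr)$normalized, roi / mean(roi[1:2]))
  # roi identical to reference: normalized curve is flat 1
  tr2 <- frap_trace(t, rep(3, length(t)), rep(3, length(t)),
                    rep(0.5, length(t)), 2)
  expect_equal(normalize_trace(tr2)$normalized, rep(1, length(t)))
  # nonpositive reference - background is rejected
  tr3 <- frap_trace(t, roi, rep(1, length(t)), rep(1, length(t)), 2)
  expect_error(normalize_trace(tr3), "strictly positive")
})

test_that("normalization cancels shared acquisition decay exactly", {
  base <- frap_sim_config(post_bleach_floor = 0.4, plateau = 0.85,
                          half_time_s = 8, reference_decay_rate = 0,
                          background_level = 0, noise_sd = 0)
  with_decay <- frap_sim_config(post_bleach_floor = 0.4, plateau = 0.85,
                                half_time_s = 8, reference_decay_rate = 0.02,
                                background_level = 0.1, noise_sd = 0)
  n0 <- normalize_trace(render_frap_trace(base))
  n1 <- normalize_trace(render_frap_trace(with_decay))
  expect_equal(n1$normalized, n0$normalized, tolerance = 1e-12)
})

test_that("exponential fits are exact on noiseless curves", {
  t <- seq(0, 120)
  y <- 0.5 + 0.25 * (1 - exp(-log(2) / 10 * t))
  norm <- data.frame(time_s = t, normalized = y,
                     is_pre_bleach = FALSE)
  fit <- fit_recovery(norm)
  expect_true(fit$fit_ok)
  expect_equal(fit$I0, 0.5, tolerance = 1e-6)
  expect_equal(fit$amplitude, 0.25, tolerance = 1e-6)
  expect_equal(fit$rate, log(2) / 10, tolerance = 1e-6)
  # flat series: amplitude ~ 0, fallback plateau engaged
  flat <- data.frame(time_s = t, normalized = rep(0.6, length(t)),
                     is_pre_bleach = FALSE)
  ff <- fit_recovery(flat)
  expect_false(ff$fit_ok)
  expect_equal(ff$plateau, 0.6)
  expect_error(fit_recovery(norm[1:4, ]), "at least 5")
})

test_that("metrics match their defining formulas", {
  cfg <- frap_sim_config(post_bleach_floor = 0.52, plateau = 0.74,
                         half_time_s = 10, noise_sd = 0,
                         background_level = 0)
  m <- compute_metrics(normalize_trace(render_frap_trace(cfg)))
  expect_equal(m$mobile_fraction_pct, 100 * (0.74 - 0.52) / (1 - 0.52),
               tolerance = 0.1)   # 45.8%
  expect_equal(m$max_recovery, 0.74, tolerance = 1e-3)
  # interpolated and fitted half-times agree within one frame
  expect_equal(m$t_half_s, 10, tolerance = 1)
  expect_lt(abs(m$t_half_s - m$t_half_fit_s), 1)
  # fully immobile: m.f. = 0
  frozen <- frap_sim_config(post_bleach_floor = 0.5, plateau = 0.5 + 1e-9,
                            half_time_s = 10, noise_sd = 0,
                            background_level = 0)
  mf <- compute_metrics(normalize_trace(render_frap_trace(frozen)))
  expect_equal(mf$mobile_fraction_pct, 0, tolerance = 0.01)
})

test_that("a curve pinned at 1 integrates to the window length", {
  t <- c(-3, -2, -1, seq(0, 120))
  tr <- frap_trace(t, rep(1, length(t)), rep(1, length(t)),
                   rep(0, length(t)), 3)
  m <- compute_metrics(normalize_trace(tr))
  expect_equal(m$auc, 120)
  expect_true(is.na(m$mobile_fraction_pct))
})

test_that("AUC is bounded by the curve extrema over the window", {
  set.seed(7)
  for (i in 1:20) {
    cfg <- frap_sim_config(post_bleach_floor = runif(1, 0.1, 0.6),
                           plateau = runif(1, 0.65, 1),
                           half_time_s = runif(1, 3, 40), noise_sd = 0.02,
                           seed = i)
    n <- normalize_trace(render_frap_trace(cfg))
    m <- compute_metrics(n)
    post <- n$normalized[n$time_s >= 0 & n$time_s <= 120]
    expect_gte(m$auc, 120 * min(post) - 1e-9)
    expect_lte(m$auc, 120 * max(post) + 1e-9)
  }
})

test_that("parameters are recovered from noisy trace ensembles", {
  set.seed(11)
  res <- t(sapply(1:50, function(i) {
    cfg <- frap_sim_config(post_bleach_floor = 0.3, plateau = 0.8,
                           half_time_s = 12, reference_decay_rate = 0.003,
                           background_level = 0.05, noise_sd = 0.02)
    m <- compute_metrics(normalize_trace(render_frap_trace(cfg)))
    c(t_half = m$t_half_fit_s, mf = m$mobile_fraction_pct)
  }))
  expect_lt(abs(median(res[, "t_half"]) - 12) / 12, 0.05)
  expect_lt(abs(median(res[, "mf"]) - 100 * 0.5 / 0.7), 3)
})

test_that("analyze_frap tabulates multiple traces", {
  trs <- list(
    fast = render_frap_trace(frap_sim_config(half_time_s = 5, seed = 1)),
    slow = render_frap_trace(frap_sim_config(half_time_s = 30, seed = 2)))
  out <- analyze_frap(trs)
  expect_equal(out$trace, c("fast", "slow"))
  expect_lt(out$t_half_s[1], out$t_half_s[2])
})
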