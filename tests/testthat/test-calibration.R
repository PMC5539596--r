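test_that("psychophysical law fit recovers exact lines", {
  reg <- default_registry()
  # two exact points determine the line
  two <- data.frame(odorant = "Acetaldehyde",
                    concentration_mg_m3 = 0.039 * exp(c(0, 1)),
                    oi = c(-5.6, 0))
  law <- fit_psychophysical_law(two, reg, drop_zero_oi = FALSE)
  expect_equal(law$k, 5.6)
  expect_equal(law$b, -5.6)
  # 18 noiseless records across three odorants recover the generator
  grid <- rep(seq(1, 3, length.out = 6), 3)
  ods <- rep(c("Acetaldehyde", "Propionaldehyde", "n-Butyraldehyde"),
             each = 6)
  thr <- vapply(ods, function(o) get_odorant(reg, o)$odor_threshold,
                numeric(1))
  rec <- data.frame(odorant = ods, concentration_mg_m3 = thr * exp(grid),
                    oi = 5.6 * grid - 5.6)
  law <- fit_psychophysical_law(rec, reg)
  expect_equal(law$k, 5.6, tolerance = 1e-9)
  expect_equal(law$b, -5.6, tolerance = 1e-9)
  expect_equal(law$diagnostics$r_squared, 1)
  expect_equal(nrow(law$diagnostics$per_odorant), 3)
  # all records at one abscissa cannot be fitted
  degen <- data.frame(odorant = "Acetaldehyde",
                      concentration_mg_m3 = rep(0.39, 3), oi = c(7, 7.5, 7))
  expect_error(fit_psychophysical_law(degen, reg), "degenerate")
})

test_that("zero-OI records are censored out with a message", {
  reg <- default_registry()
  rec <- data.frame(odorant = "Acetaldehyde",
                    concentration_mg_m3 = 0.039 * exp(c(0.5, 2, 3)),
                    oi = c(0, 5.6, 11.2))
  expect_message(law <- fit_psychophysical_law(rec, reg), "1 record")
  expect_equal(law$diagnostics$n_dropped, 1L)
  expect_equal(law$diagnostics$n, 2L)
  expect_equal(law$k, 5.6)
})

test_that("mixture slope is the exact through-origin least-squares", {
  rec <- data.frame(oi_sum = c(10, 20), oi_mix = c(6.2, 12.4))
  expect_equal(fit_mixture_slope(rec)$slope, 0.62)
  expect_equal(fit_mixture_slope(
    data.frame(oi_sum = 10, oi_mix = 10))$slope, 1.0)
  expect_error(fit_mixture_slope(
    data.frame(oi_sum = c(0, 0), oi_mix = c(0, 0))), "degenerate")
  # closed form sum(xy)/sum(x^2), cross-checked by a brute-force grid search
  set.seed(5)
  x <- runif(8, 1, 20)
  y <- 0.7 * x + rnorm(8, 0, 0.4)
  s_hat <- fit_mixture_slope(data.frame(oi_sum = x, oi_mix = pmax(y, 0)))$slope
  expect_equal(s_hat, sum(x * pmax(y, 0)) / sum(x^2))
  grid <- seq(0.2, 1.2, by = 1e-5)
  sse <- vapply(grid, function(s) sum((pmax(y, 0) - s * x)^2), numeric(1))
  expect_equal(s_hat, grid[which.min(sse)], tolerance = 1e-4)
  # the sensitivity-analysis variant frees the intercept
  fit_i <- fit_mixture_slope(data.frame(oi_sum = x, oi_mix = 0.7 * x + 1),
                             intercept = TRUE)
  expect_equal(fit_i$slope, 0.7)
  expect_equal(fit_i$intercept, 1)
})

test_that("mixture_records sums components and validates shape", {
  rec <- mixture_records(cbind(c(3, 5), c(4, 5)), c(5, 6.2))
  expect_equal(rec$oi_sum, c(7, 10))
  expect_equal(rec$oi_mix, c(5, 6.2))
  expect_error(mixture_records(cbind(c(3, 5)), c(5, 6)), "two components")
  expect_error(mixture_records(cbind(c(3, 5), c(4, 5)), 5), "per component")
})

test_that("family calibration recovers both preset model constants", {
  for (fam_name in c("aldehydes", "esters")) {
    cfg <- exact_panel_config(fam_name)
    singles <- gen_single_odorant_panel(cfg)
    mixtures <- gen_mixture_panel(cfg)
    fam <- suppressMessages(
      calibrate_family(singles, mixtures, name = fam_name))
    preset <- family_preset(fam_name)
    expect_equal(fam$law$k, preset$law$k, tolerance = 1e-9)
    expect_equal(fam$law$b, preset$law$b, tolerance = 1e-9)
    expect_equal(fam$slope, preset$slope, tolerance = 1e-9)
    expect_equal(fam$cos_alpha, preset$cos_alpha, tolerance = 1e-9)
    expect_setequal(fam$members$name, preset$members$name)
  }
  expect_equal(family_preset("aldehydes")$cos_alpha, -0.2312)
  expect_equal(family_preset("esters")$cos_alpha, 0.2482)
  # no mixture data, no model
  cfg <- exact_panel_config("aldehydes")
  expect_error(suppressMessages(calibrate_family(
    gen_single_odorant_panel(cfg),
    data.frame(oi_sum = numeric(0), oi_mix = numeric(0)))), "degenerate")
})

test_that("noiseless generate-refit recovers arbitrary (k, b, s)", {
  set.seed(61)
  for (i in 1:10) {
    k <- runif(1, 0.5, 8); b <- runif(1, -6, 1); s <- runif(1, 0.3, 1)
    cfg <- panel_sim_config(list(k = k, b = b, slope = s),
                            odorants = c("Acetaldehyde", "Propionaldehyde"),
                            assessor_sd = 0, n_assessors = 1L,
                            oirs_resolution = 0, seed = i)
    fam <- suppressMessages(calibrate_family(
      gen_single_odorant_panel(cfg), gen_mixture_panel(cfg)))
    expect_equal(fam$law$k, k, tolerance = 1e-6)
    expect_equal(fam$law$b, b, tolerance = 1e-6)
    expect_equal(fam$cos_alpha, 2 * s^2 - 1, tolerance = 1e-6)
  }
})

test_that("noisy panels at the study's sample sizes recover k reliably", {
  # 3 odorants x 6 singles = 18 records, 3 pairs x 5 mixtures = 15 records,
  # assessor sd 0.5: k within 15% of truth in >= 90% of 200 replicates
  hits <- vapply(1:200, function(i) {
    cfg <- panel_sim_config("aldehydes", assessor_sd = 0.5, seed = i)
    law <- suppressMessages(fit_psychophysical_law(
      gen_single_odorant_panel(cfg)))
    abs(law$k - 5.6) / 5.6 <= 0.15
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
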