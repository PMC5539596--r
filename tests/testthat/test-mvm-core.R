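test_that("OAV is concentration over threshold", {
  a <- odorant("Acetaldehyde", 0.039)
  expect_equal(compute_oav(0.39, a), 10.0)
  expect_equal(compute_oav(0, a), 0.0)
  expect_equal(compute_oav(0.052, odorant("n-Butyraldehyde", 0.052)), 1.0)
  expect_error(compute_oav(-0.1, a), "non-negative")
  expect_error(odorant("X", 0), "positive")
})

test_that("single-odorant OI follows the log-linear law with a zero clamp", {
  a <- odorant("Acetaldehyde", 0.039)
  law <- aldehyde_law()
  expect_equal(oi_single(0.39, a, law), 5.6 * log(10) - 5.6)
  expect_equal(round(oi_single(0.39, a, law), 4), 7.2945)
  # at threshold (OAV = 1) a negative intercept clamps to zero
  expect_equal(oi_single(0.039, a, law), 0.0)
  expect_equal(oi_single(0, a, law), 0.0)
  # ester law at OAV = e^2: 1.4 * 2 - 2.7 = 0.1
  e <- odorant("Ethyl acetate", 0.276)
  expect_equal(oi_single(0.276 * exp(2), e, ester_law()), 0.1)
})

test_that("binary vector sum reproduces worked values", {
  expect_equal(mixture_oi_binary(5, 5, 1), 10.0)
  expect_equal(mixture_oi_binary(3, 4, 0), 5.0)
  expect_equal(mixture_oi_binary(5, 5, -0.2312), 6.2)
  expect_error(mixture_oi_binary(5, 5, 1.5), "\\[-1, 1\\]")
  expect_error(mixture_oi_binary(-1, 5, 0), "non-negative")
})

test_that("n-component vector sum matches worked values and edge cases", {
  expect_equal(mixture_oi(c(5, 5, 5), 0), sqrt(75))
  expect_equal(mixture_oi(c(5, 5, 5), -0.2312), sqrt(25 * (3 + 6 * -0.2312)))
  expect_equal(round(mixture_oi(c(5, 5, 5), -0.2312), 4), 6.3498)
  # zero components drop out; singletons pass through
  expect_equal(mixture_oi(c(5, 5, 0), -0.3), mixture_oi_binary(5, 5, -0.3))
  expect_equal(mixture_oi(7.25, 0.1), 7.25)
  expect_error(mixture_oi(numeric(0), 0), "at least one")
  # complete counteraction clamps the radicand with a warning
  expect_warning(oi <- mixture_oi(c(5, 5, 5), -1), "counteraction")
  expect_equal(oi, 0)
})

test_that("interaction coefficient recovers from measurements and slope", {
  expect_equal(cos_alpha_from_measurement(10, 5, 5), 1.0)
  expect_equal(cos_alpha_from_measurement(5, 3, 4), 0.0)
  expect_equal(cos_alpha_from_measurement(6.2, 5, 5), -0.2312)
  expect_error(cos_alpha_from_measurement(5, 0, 4), "positive")

  expect_equal(cos_alpha_from_slope(1), 1.0)
  expect_equal(cos_alpha_from_slope(1 / sqrt(2)), 0.0)
  expect_equal(cos_alpha_from_slope(0.62), -0.2312)
  expect_equal(cos_alpha_from_slope(0.79), 0.2482)
  expect_error(cos_alpha_from_slope(0), "\\(0, 1\\]")
  expect_error(cos_alpha_from_slope(1.01), "\\(0, 1\\]")

  expect_equal(slope_from_cos_alpha(1), 1.0)
  expect_equal(slope_from_cos_alpha(0), sqrt(0.5))
  expect_equal(slope_from_cos_alpha(-0.2312), 0.62)
  expect_error(slope_from_cos_alpha(-1), "\\(-1, 1\\]")
})

test_that("slope and cos(alpha) round-trip and satisfy the slope identity", {
  for (s in seq(0.05, 1, by = 0.05)) {
    expect_equal(slope_from_cos_alpha(cos_alpha_from_slope(s)), s)
  }
  # equal-intensity mixing at coefficient 2s^2 - 1 yields OI_mix = 2 s o
  set.seed(11)
  for (i in 1:50) {
    o <- runif(1, 0.1, 12)
    s <- runif(1, 0.05, 1)
    expect_equal(mixture_oi_binary(o, o, cos_alpha_from_slope(s)), 2 * s * o)
  }
})

test_that("vector sum respects norm bounds, symmetry, and degeneracy", {
  set.seed(23)
  for (i in 1:200) {
    a <- runif(1, 0, 10); b <- runif(1, 0, 10); cc <- runif(1, -1, 1)
    m <- mixture_oi_binary(a, b, cc)
    expect_gte(m, abs(a - b) - 1e-12)
    expect_lte(m, a + b + 1e-12)
  }
  expect_equal(mixture_oi_binary(3, 7, 1), 10)
  expect_equal(mixture_oi_binary(3, 7, -1), 4)
  set.seed(29)
  for (i in 1:50) {
    ois <- runif(sample(2:6, 1), 0, 10)
    cc <- runif(1, -0.25, 1)
    m <- mixture_oi(ois, cc)
    expect_gte(m, 0)
    expect_equal(mixture_oi(sample(ois), cc), m)
    expect_equal(mixture_oi(c(ois, 0), cc), m)
  }
})

test_that("n-component sum matches literal binary/ternary transcriptions", {
  set.seed(37)
  for (i in 1:50) {
    cc <- runif(1, -0.3, 1)
    ab <- runif(2, 0, 10)
    expect_equal(mixture_oi(ab, cc), binary_vector_sum(ab[1], ab[2], cc))
    abc <- runif(3, 0, 10)
    expect_equal(mixture_oi(abc, cc),
                 ternary_vector_sum(abc[1], abc[2], abc[3], cc, cc, cc))
  }
})

test_that("full sample prediction composes law and vector sum", {
  fam <- family_preset("aldehydes")
  expect_equal(fam$cos_alpha, 2 * 0.62^2 - 1)
  s <- odor_sample(c(Acetaldehyde = 0.39, Propionaldehyde = 0.41))
  oi_each <- 5.6 * log(10) - 5.6
  expect_equal(predict_mixture_oi(s, fam),
               mixture_oi_binary(oi_each, oi_each, fam$cos_alpha))
  expect_equal(round(predict_mixture_oi(s, fam), 4), 9.0452)
  # equal-intensity pair: 2 * s * o = 1.24 * 7.2945
  expect_equal(predict_mixture_oi(s, fam), 2 * 0.62 * oi_each)
  # single constituent reduces to the single-odorant law
  expect_equal(predict_mixture_oi(odor_sample(c(Acetaldehyde = 0.39)), fam),
               oi_each)
  # both constituents at threshold are imperceptible
  expect_equal(predict_mixture_oi(
    odor_sample(c(Acetaldehyde = 0.039, Propionaldehyde = 0.041)), fam), 0)
  # abbreviations resolve; unknown odorants do not
  expect_equal(predict_mixture_oi(odor_sample(c(A = 0.39)), fam), oi_each)
  expect_error(predict_mixture_oi(odor_sample(c(Limonene = 1)), fam),
               "Limonene")
  bd <- predict_mixture_oi(s, fam, breakdown = TRUE)
  expect_equal(bd$constituents$oav, c(10, 10))
  expect_equal(bd$constituents$oi, rep(oi_each, 2))
})

test_that("OIRS levels form an exact geometric progression", {
  twelve <- oirs_scale(10, 2, 12)
  expect_identical(oirs_concentration(1, twelve), 10)
  expect_identical(oirs_concentration(8, twelve), 1280)
  expect_identical(oirs_concentration(12, twelve), 20480)
  eight <- oirs_scale(12, 2, 8)
  expect_identical(oirs_concentration(3, eight), 48)
  expect_error(oirs_concentration(13, twelve), "1\\.\\.12")
  expect_error(oirs_concentration(0, twelve), "1\\.\\.12")
  for (l in 1:11) {
    expect_equal(oirs_concentration(l + 1, twelve) /
                   oirs_concentration(l, twelve), 2)
  }
})

test_that("quantization rounds to the scale resolution with ties up", {
  expect_equal(nearest_oirs_level(7.2945, 0.5), 7.5)
  expect_equal(nearest_oirs_level(7.2945, 1.0), 7.0)
  expect_equal(nearest_oirs_level(0.25, 0.5), 0.5)
  expect_equal(nearest_oirs_level(c(1.2, 3.74, 3.75), 0.5), c(1, 3.5, 4))
  expect_error(nearest_oirs_level(1, 0), "positive")
})
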