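test_that("slope-efficiency conversion matches the dilution-curve formula", {
  expect_equal(efficiency_from_slope(-3.32193), 1, tolerance = 1e-4)
  expect_equal(efficiency_from_slope(-3.139), 1.082, tolerance = 1e-3)
  expect_equal(efficiency_from_slope(-3.45), 0.949, tolerance = 1e-3)
  expect_error(efficiency_from_slope(3.3), "negative")
  expect_error(efficiency_from_slope(0), "negative")
  # round trip is the identity over the whole plausible efficiency range
  e <- seq(0.5, 1.2, by = 0.001)
  expect_equal(efficiency_from_slope(slope_from_efficiency(e)), e,
               tolerance = 1e-12)
})

test_that("standard curves recover slope, efficiency and linearity", {
  ser <- data.frame(log10_input = c(0, 1, 2),
                    ct = c(30, 26.6781, 23.3562))
  fit <- fit_standard_curve(ser)
  expect_equal(fit$slope, -3.32190, tolerance = 1e-5)
  expect_equal(fit$efficiency, 1, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # any exact line has R^2 = 1
  ser2 <- data.frame(log10_input = c(-1, 0, 1, 2), ct = 28 - 3.1 * c(-1, 0, 1, 2))
  expect_equal(fit_standard_curve(ser2)$r_squared, 1, tolerance = 1e-10)
  expect_error(fit_standard_curve(ser[1:2, ]), "3 distinct")
  expect_error(fit_standard_curve(data.frame(log10_input = 1, ct = 2)),
               "3 distinct")
  expect_error(fit_standard_curve(data.frame(x = 1:3, ct = 1:3)),
               "log10_input")
})

test_that("a noise-free dilution series round-trips the simulator efficiency", {
  ta <- prelid1_qpcr(e = 1.0823)
  cfg <- exact_config()
  inputs <- c(0.02, 0.2, 2, 20, 200)
  cts <- vapply(inputs, function(ng) {
    simulate_ct(list(true_cn = 2, input_mass = ng,
                     mean_fragment_length = Inf), ta, cfg)
  }, numeric(1))
  fit <- fit_standard_curve(data.frame(log10_input = log10(inputs),
                                       ct = cts))
  expect_equal(fit$slope, -1 / log10(2.0823), tolerance = 1e-6)
  expect_equal(fit$efficiency, 1.0823, tolerance = 1e-4)
  expect_gt(fit$r_squared, 0.99)
})

test_that("delta-Ct averages usable replicates and drops incomplete ones", {
  tab <- tibble::tibble(
    sample_id = c("a", rep("b", 3), rep("c", 3)),
    replicate_index = c(1, 1:3, 1:3),
    ct_target = c(25, 25, 25, 25, 25, 25, NA),
    ct_reference = c(24, 24, 24, 24, 24, 24, 23),
    input_mass = 5
  )
  rec <- delta_ct_table(tab)
  expect_equal(rec$delta_ct, c(1, 1, 1))
  expect_equal(rec$n_replicates_used, c(1, 3, 2))

  tab$ct_reference[1] <- NA
  expect_warning(rec2 <- delta_ct_table(tab), "excluded")
  expect_equal(rec2$sample_id, c("b", "c"))
  expect_equal(attr(rec2, "excluded")$sample_id, "a")
  expect_equal(attr(rec2, "excluded")$reason, "NO_USABLE_REPLICATES")
})

test_that("continuous copy number is anchored to the cohort median", {
  rec <- tibble::tibble(sample_id = letters[1:5], delta_ct = rep(1.7, 5),
                        input_mass = 5)
  expect_equal(continuous_cn_qpcr(rec, 2)$continuous_cn, rep(2, 5))

  rec$delta_ct <- c(1.7, 1.7, 1.7, 1.7, 0.7)  # one sample one cycle below
  out <- continuous_cn_qpcr(rec, 2)
  expect_equal(out$continuous_cn[5], 4)

  rec$delta_ct <- c(1.7, 1.7, 1.7, 1.7, 1.7 + 0.585)
  out <- continuous_cn_qpcr(rec, 2)
  expect_equal(out$continuous_cn[5], 2 * 2^(-0.585), tolerance = 1e-12)
  expect_equal(out$continuous_cn[5], 1.3333, tolerance = 1e-4)

  expect_error(continuous_cn_qpcr(rec[1:2, ], 2), ">= 3")
})

test_that("median anchoring holds exactly for odd and even cohorts", {
  for (n in c(9, 10, 37, 40)) {
    set.seed(n)
    rec <- tibble::tibble(sample_id = sprintf("s%02d", 1:n),
                          delta_ct = rnorm(n, 1.5, 0.4), input_mass = 5)
    out <- continuous_cn_qpcr(rec, 2)
    expect_equal(median(out$continuous_cn), 2, tolerance = 1e-12)
    out4 <- continuous_cn_qpcr(rec, 4)
    expect_equal(median(out4$continuous_cn), 4, tolerance = 1e-12)
  }
})

test_that("adding a constant to every Ct leaves copy numbers unchanged", {
  cfg <- sim_config(30, c("1" = 0.2, "2" = 0.6, "3" = 0.2), seed = 41)
  co <- make_cohort(cfg)
  tab <- simulate_qpcr_plate(co, prelid1_qpcr(), rnasep_qpcr(), cfg)
  shifted <- tab
  shifted$ct_target <- shifted$ct_target + 3.7
  shifted$ct_reference <- shifted$ct_reference + 3.7
  expect_equal(call_qpcr(tab, 2)$continuous_cn,
               call_qpcr(shifted, 2)$continuous_cn, tolerance = 1e-12)
})

test_that("delta-Ct drift prediction agrees with the noise-free simulator", {
  expect_equal(predict_dct_drift(1.05, 1.05)$dct_per_decade, 0)
  expect_equal(predict_dct_drift(1.05, 1.05)$cn_factor_per_decade, 1)
  expect_error(predict_dct_drift(-0.1, 1), "positive")

  for (pair in list(c(1.0823, 1.0228), c(1.0823, 1.1418))) {
    drift <- predict_dct_drift(pair[1], pair[2])
    cfg <- exact_config(n_replicates = 1)
    co <- toy_cohort(input_mass = c(1, 100))  # two decades
    tab <- simulate_qpcr_plate(co, prelid1_qpcr(e = pair[1]),
                               rnasep_qpcr(e = pair[2]), cfg)
    dct <- tab$ct_target - tab$ct_reference
    expect_equal(dct[2] - dct[1], 2 * drift$dct_per_decade,
                 tolerance = 1e-9)
  }

  # over the 2-120 ng input range the miscalling factor compounds to ~17%
  drift <- predict_dct_drift(1.0823, 1.0228)
  cumulative <- 2^(abs(drift$dct_per_decade) * log10(120 / 2))
  expect_equal(cumulative, 1.17, tolerance = 0.01)
  # a more efficient target deflates calls with input; a more efficient
  # reference inflates them
  expect_lt(predict_dct_drift(1.0823, 1.0228)$cn_factor_per_decade, 1)
  expect_gt(predict_dct_drift(1.0823, 1.1418)$cn_factor_per_decade, 1)
})

test_that("input-copy-number correlation handles exact and degenerate data", {
  calls <- tibble::tibble(input_mass = 1:10,
                          continuous_cn = 2 + 0.01 * (1:10))
  r <- input_cn_correlation(calls)
  expect_equal(r$pearson_r, 1, tolerance = 1e-12)
  expect_false(r$degenerate)

  const <- tibble::tibble(input_mass = 1:10, continuous_cn = 2)
  r0 <- input_cn_correlation(const)
  expect_equal(r0$pearson_r, 0)
  expect_equal(r0$p_value, 1)
  expect_true(r0$degenerate)

  expect_error(input_cn_correlation(const[1:2, ]), ">= 3")
})

test_that("a variable-input cohort recovers the predicted bias slope", {
  e_t <- 1.0823; e_r <- 1.1418
  drift <- predict_dct_drift(e_t, e_r)
  cfg <- sim_config(400, c("2" = 1),
                    input_model = input_lognormal(13.28), seed = 51)
  co <- make_cohort(cfg)
  tab <- simulate_qpcr_plate(co, prelid1_qpcr(e = e_t),
                             rnasep_qpcr(e = e_r), cfg)
  calls <- call_qpcr(tab, 2)
  fit <- summary(lm(log2(continuous_cn) ~ log10(input_mass), data = calls))
  est <- fit$coefficients["log10(input_mass)", ]
  expect_lt(abs(est["Estimate"] - (-drift$dct_per_decade)),
            3 * est["Std. Error"])
  # with a fixed input mass the regression slope is zero by construction
  cfg_n <- sim_config(400, c("2" = 1), input_model = input_normalized(5),
                      seed = 52)
  co_n <- make_cohort(cfg_n)
  calls_n <- call_qpcr(simulate_qpcr_plate(co_n, prelid1_qpcr(e = e_t),
                                           rnasep_qpcr(e = e_r), cfg_n), 2)
  expect_true(input_cn_correlation(calls_n)$degenerate)
})
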