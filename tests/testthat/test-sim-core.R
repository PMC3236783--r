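test_that("intact fraction follows the random-breakage closed form", {
  expect_identical(intact_fraction(107, Inf), 1)
  expect_equal(intact_fraction(500, 500), exp(-1))
  expect_equal(intact_fraction(299, 500), exp(-0.598))
  # monotone: longer amplicons lose more, longer fragments keep more
  L <- seq(60, 600, by = 60)
  expect_true(all(diff(intact_fraction(L, 300)) < 0))
  lambda <- c(100, 200, 400, 800, Inf)
  expect_true(all(diff(intact_fraction(299, lambda)) > 0))
  expect_error(intact_fraction(-1, 300), "positive")
  expect_error(intact_fraction(107, 0), "positive")
})

test_that("cohorts honour the copy-number distribution and seed", {
  cfg <- sim_config(10, c("2" = 1), input_model = input_normalized(5),
                    seed = 11)
  co <- make_cohort(cfg)
  expect_equal(nrow(co), 10)
  expect_true(all(co$true_cn == 2))
  expect_true(all(co$input_mass == 5))

  expect_identical(make_cohort(cfg), make_cohort(cfg))

  cfg2 <- sim_config(10000, c("1" = 0.1, "2" = 0.8, "3" = 0.1), seed = 12)
  freq <- prop.table(table(make_cohort(cfg2)$true_cn))
  expect_equal(as.numeric(freq[c("1", "2", "3")]), c(0.1, 0.8, 0.1),
               tolerance = 0.02)

  expect_error(sim_config(10, c("1" = 0.5, "2" = 0.4)), "sum to 1")
  expect_error(sim_config(10, c(0.5, 0.5)), "named")
})

test_that("lognormal input model matches its mean and respects its bounds", {
  cfg <- sim_config(20000, c("2" = 1),
                    input_model = input_lognormal(13.28, sdlog = 0.8,
                                                  min_ng = 2, max_ng = 120),
                    seed = 13)
  x <- make_cohort(cfg)$input_mass
  expect_true(all(x >= 2 & x <= 120))
  # clamping pulls the mean slightly up from 13.28; stay within 10%
  expect_equal(mean(x), 13.28, tolerance = 0.1 * 13.28)
})

test_that("threshold cycles follow the log-linear amplification model", {
  ta <- prelid1_qpcr(e = 1)
  # template exactly at the detection threshold amplifies in zero cycles
  cfg <- exact_config(detection_threshold = 5 * 303)
  s <- list(true_cn = 2, input_mass = 5, mean_fragment_length = Inf)
  expect_equal(simulate_ct(s, ta, cfg), 0)
  # ten perfect doublings from T/2^10
  cfg10 <- exact_config(detection_threshold = 5 * 303 * 2^10)
  expect_equal(simulate_ct(s, ta, cfg10), 10)
  # no amplifiable template is reported missing
  s_deg <- list(true_cn = 2, input_mass = 5, mean_fragment_length = 1e-3)
  expect_true(is.na(simulate_ct(s_deg, ta, exact_config())))
  expect_error(simulate_ct(s, prelid1_prt(), exact_config()), "role")
})

test_that("expected Ct drops by 1/log10(1+E) cycles per tenfold input", {
  ta <- prelid1_qpcr()
  cfg <- exact_config()
  ct1 <- simulate_ct(list(true_cn = 2, input_mass = 1,
                          mean_fragment_length = Inf), ta, cfg)
  ct10 <- simulate_ct(list(true_cn = 2, input_mass = 10,
                           mean_fragment_length = Inf), ta, cfg)
  expect_equal(ct1 - ct10, 1 / log10(1 + 1.0823), tolerance = 1e-12)
})

test_that("a simulated plate has one row per sample and replicate", {
  cfg <- sim_config(10, c("2" = 1), n_replicates = 3, seed = 14)
  co <- make_cohort(cfg)
  tab <- simulate_qpcr_plate(co, prelid1_qpcr(), rnasep_qpcr(), cfg)
  expect_equal(nrow(tab), 30)
  expect_equal(sort(unique(tab$replicate_index)), 1:3)
  expect_named(tab, c("sample_id", "replicate_index", "ct_target",
                      "ct_reference", "input_mass"))
  expect_error(simulate_qpcr_plate(co, rnasep_qpcr(), rnasep_qpcr(), cfg),
               "qpcr_target")
})

test_that("equal efficiencies make delta-Ct independent of input mass", {
  cfg <- exact_config(n_replicates = 1)
  co <- toy_cohort(input_mass = c(2, 5, 13.28, 50, 120))
  tab <- simulate_qpcr_plate(co, prelid1_qpcr(e = 1.02),
                             rnasep_qpcr(e = 1.02), cfg)
  dct <- tab$ct_target - tab$ct_reference
  expect_lt(max(dct) - min(dct), 1e-9)
})

test_that("unequal efficiencies shift delta-Ct by the two-slope closed form", {
  cfg <- exact_config(n_replicates = 1)
  co <- toy_cohort(input_mass = c(2, 120))
  tab <- simulate_qpcr_plate(co, prelid1_qpcr(e = 1.0823),
                             rnasep_qpcr(e = 1.0228), cfg)
  dct <- tab$ct_target - tab$ct_reference
  expected <- (-1 / log10(2.0823) + 1 / log10(2.0228)) * log10(120 / 2)
  expect_equal(dct[2] - dct[1], expected, tolerance = 1e-9)
  expect_equal(abs(expected), 0.23, tolerance = 0.005)
})

test_that("peak-area ratios equal cn/reference_copies in the exact limit", {
  cfg <- exact_config(n_replicates = 1)
  prt <- prelid1_prt()
  r_for_cn <- function(cn) {
    tab <- simulate_prt_run(toy_cohort(5, true_cn = cn), prt, cfg)
    tab$area_target / tab$area_paralog
  }
  expect_equal(r_for_cn(2), 1, tolerance = 1e-12)
  expect_equal(r_for_cn(4), 2, tolerance = 1e-12)
  expect_error(simulate_prt_run(toy_cohort(5), prelid1_qpcr(), cfg),
               "prt_pair")
})

test_that("degradation widens the PRT ratio spread without biasing it", {
  run_sd <- function(mfl, seed) {
    cfg <- sim_config(1000, c("2" = 1), mean_fragment_length = mfl,
                      seed = seed)
    tab <- simulate_prt_run(make_cohort(cfg), prelid1_prt(), cfg)
    ratios <- peak_ratios(tab)$ratio
    c(sd = sd(ratios), mean = mean(ratios))
  }
  intact <- run_sd(Inf, 21)
  degraded <- run_sd(300, 21)
  expect_gt(degraded["sd"], intact["sd"])
  expect_equal(unname(degraded["mean"]), 1, tolerance = 0.02)
})

test_that("simulated tables are bit-identical under a repeated seed", {
  cfg <- sim_config(25, c("1" = 0.1, "2" = 0.8, "3" = 0.1), seed = 31)
  co <- make_cohort(cfg)
  expect_identical(
    simulate_qpcr_plate(co, prelid1_qpcr(), rnasep_qpcr(), cfg),
    simulate_qpcr_plate(co, prelid1_qpcr(), rnasep_qpcr(), cfg)
  )
  expect_identical(simulate_prt_run(co, prelid1_prt(), cfg),
                   simulate_prt_run(co, prelid1_prt(), cfg))
  cfg2 <- sim_config(25, c("1" = 0.1, "2" = 0.8, "3" = 0.1), seed = 32)
  expect_false(identical(
    simulate_qpcr_plate(co, prelid1_qpcr(), rnasep_qpcr(), cfg),
    simulate_qpcr_plate(co, prelid1_qpcr(), rnasep_qpcr(), cfg2)
  ))
})
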