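flank_shape <- function() {
  x <- (1:800) * 10 - 4000
  exp(-(x - 1200)^2 / (2 * 250^2)) + exp(-(x + 1200)^2 / (2 * 250^2))
}

test_that("central fraction is the height-matched excess area", {
  fl <- flank_shape()
  base <- make_profile(fl / 2, fl / 2)
  # identical conditions: no central species, fraction 0
  expect_equal(central_fraction(base, base)$fraction, 0)
  # constructed pair: central delta carrying 11% of the total area
  delta <- numeric(800)
  delta[400:401] <- 0.11 * sum(fl) / (1 - 0.11) / 2
  full <- make_profile((fl + delta) / 2, (fl + delta) / 2)
  cf <- central_fraction(full, base)
  expect_equal(cf$fraction, 0.11, tolerance = 1e-12)
  expect_equal(cf$central_share, 1)
  # invariant to multiplying both profiles by the same constant
  full2 <- make_profile(5 * (fl + delta) / 2, 5 * (fl + delta) / 2)
  base2 <- make_profile(5 * fl / 2, 5 * fl / 2)
  expect_equal(central_fraction(full2, base2)$fraction, cf$fraction)
  # a sample with a different flank height is rescaled first
  half <- make_profile(fl / 4, fl / 4)
  expect_equal(central_fraction(full, half)$fraction, 0.11,
               tolerance = 1e-12)
})

test_that("WT-preset enzyme pair recovers the simulated SPO11-bound share", {
  p <- preset("WT", n_hotspots = 400, events_per_hotspot = 55,
              heat = "constant", seed = 51)
  sim <- simulate_library(p)
  full <- apply_enzyme_condition(sim$track, "ExoVII_ExoT")
  exot <- apply_enzyme_condition(sim$track, "ExoT_only")
  af <- aggregate_profile(bin_endpoints(full, sim$hotspots))
  ae <- aggregate_profile(bin_endpoints(exot, sim$hotspots))
  cf <- central_fraction(af, ae)
  # p_ri / 2 + p_cc = 11% of total signal is protein-bound central
  expect_equal(cf$fraction, 0.11, tolerance = 0.15)
  expect_gt(cf$central_share, 0.95)
})

test_that("decomposition arithmetic reproduces the worked estimate", {
  d <- decompose_central(f_full = 0.11, f_tdp2 = 0.017,
                         total_breaks_exot = 93,
                         ratio_tdp2_vs_exot = 0.02,
                         total_breaks_ref = 333)
  expect_equal(d$n_cc, 2)
  expect_equal(round(100 * d$cc_low, 1), 0.6)
  expect_equal(d$cc_high, 0.017)
  expect_equal(round(100 * d$ri_low, 1), 9.3)
  expect_equal(round(100 * d$ri_high, 1), 10.4)
  # exact complementarity of the bounds
  expect_equal(d$ri_low + d$cc_high, d$f_full)
  expect_equal(d$ri_high + d$cc_low, d$f_full)

  # boundary cases
  d0 <- decompose_central(0.11, 0, 93, 0, 333)
  expect_equal(d0$cc_high, 0)
  expect_equal(d0$ri_low, 0.11)
  expect_equal(d0$ri_high, 0.11)
  de <- decompose_central(0.11, 0.11, 93, 0.02, 333)
  expect_equal(de$ri_low, 0)
  expect_error(decompose_central(0.11, 0.12, 93, 0.02, 333),
               "inconsistent")
})

test_that("polarity shift matches the analytic emission geometry", {
  # SPO11-RI geometry: top reads at -30, bottom at +30 -> shift -60
  ri <- central_track(-30, 30)
  expect_equal(polarity_shift(ri$track, ri$hotspots)$shift, -60)
  # double-cut geometry: top at +25, bottom at -25 -> shift +50
  dc <- central_track(25, -25)
  expect_equal(polarity_shift(dc$track, dc$hotspots)$shift, 50)
  expect_equal(polarity_shift(dc$track, dc$hotspots,
                              estimator = "median")$shift, 50)
  # coincident strands -> no shift
  cc <- central_track(0, 0)
  expect_equal(polarity_shift(cc$track, cc$hotspots)$shift, 0)
  # a strand without central reads is undefined
  lop <- central_track(-30, 2000)
  expect_true(is.na(polarity_shift(lop$track, lop$hotspots)$shift))
})

test_that("polarity sign separates WT (RI) from ATM-null (double-cut)", {
  wt <- simulate_library(preset("WT", n_hotspots = 300,
                                events_per_hotspot = 40,
                                heat = "constant", seed = 52))
  expect_lt(polarity_shift(wt$track, wt$hotspots)$shift, 0)
  atm <- simulate_library(preset("Atm", n_hotspots = 300,
                                 events_per_hotspot = 40,
                                 heat = "constant", seed = 53))
  expect_gt(polarity_shift(atm$track, atm$hotspots)$shift, 0)
})

test_that("ExoT-only detection removes the central peak in every preset", {
  for (name in c("WT", "Atm", "Dmc1", "Exo1", "Prdm9", "hybrid")) {
    sim <- simulate_library(preset(name, n_hotspots = 150,
                                   events_per_hotspot = 40,
                                   heat = "constant",
                                   seed = 54))
    exot <- apply_enzyme_condition(sim$track, "ExoT_only")
    agg <- aggregate_profile(bin_endpoints(exot, sim$hotspots))
    central <- abs(agg$offset) <= 200
    share <- sum(agg$pooled[central]) / sum(agg$pooled)
    expect_lt(share, 0.01)
  }
})

test_that("TDP2+ExoT leaves no central signal on a pure SPO11-RI library", {
  p <- truth_params(n_hotspots = 200, events_per_hotspot = 40,
                    p_resected = 0, p_ri = 1, p_cc = 0,
                    heat = "constant", seed = 55)
  sim <- simulate_library(p)
  tdp2 <- apply_enzyme_condition(sim$track, "TDP2_ExoT")
  agg <- aggregate_profile(bin_endpoints(tdp2, sim$hotspots))
  central <- abs(agg$offset) <= 200
  expect_lt(sum(agg$pooled[central]) / sum(agg$pooled), 0.01)
})
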