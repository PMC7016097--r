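test_that("SPO11-RI emission follows the reversed-polarity convention", {
  p <- truth_params(n_hotspots = 20, events_per_hotspot = 30,
                    p_resected = 0, p_ri = 1, p_cc = 0,
                    cut_disp = 30, cut_disp_sd = 0,
                    background_rate = 0, seed = 7)
  sim <- simulate_library(p)
  r <- sim$track$records
  r <- r[r$chrom == "chrSim", , drop = FALSE]
  centers <- sim$hotspots$center[r$pos %/% p$hotspot_spacing + 1]
  off <- r$pos - centers
  ri <- r$flag == "ri"
  # motif-proximal (blocked) top-strand reads sit at cut = center - 30,
  # bottom-strand ones at center + 30
  expect_true(all(off[ri & r$strand == "+"] == -30))
  expect_true(all(off[ri & r$strand == "-"] == 30))
  # the motif-distal end is fully resected, beyond the gap
  expect_true(all(abs(off[!ri]) > 300))
  # one central and one distal end per event
  expect_equal(sum(ri), nrow(sim$truth))
})

test_that("double-cut emission gives a correct-polarity strand gap", {
  p <- truth_params(n_hotspots = 100, events_per_hotspot = 25,
                    p_resected = 0, p_ri = 0, p_cc = 0, p_doublecut = 1,
                    dc_spacing = c(49.5, 50.5),  # rounds to 50 exactly
                    background_rate = 0, seed = 8)
  sim <- simulate_library(p)
  ps <- polarity_shift(sim$track, sim$hotspots)
  expect_equal(ps$shift, 50)
  expect_true(all(sim$truth$cut2 - sim$truth$cut == 50))
})

test_that("fully resected events leave a read-less gap by construction", {
  p <- truth_params(n_hotspots = 50, events_per_hotspot = 40,
                    p_resected = 1, p_ri = 0, p_cc = 0,
                    gap_mean = 1000, gap_sd = 1e-9,
                    resect_mean = 0.1, resect_sd = 0.01,
                    cut_disp = 0, cut_disp_sd = 0,
                    background_rate = 0, seed = 9)
  sim <- simulate_library(p)
  r <- sim$track$records
  r <- r[r$chrom == "chrSim", , drop = FALSE]
  centers <- sim$hotspots$center[r$pos %/% p$hotspot_spacing + 1]
  expect_true(all(abs(r$pos - centers) >= 1000))
})

test_that("every break event emits exactly two endpoints", {
  sim <- simulate_library(preset("WT", n_hotspots = 50, seed = 10))
  fl <- sim$track$records$flag
  expect_equal(sum(!fl %in% c("bg", "spike")), 2 * nrow(sim$truth))
  expect_equal(sum(fl == "spike") %% 2, 0)
})

test_that("a fixed seed reproduces the library exactly", {
  a <- simulate_library(preset("WT", n_hotspots = 30, seed = 42))
  b <- simulate_library(preset("WT", n_hotspots = 30, seed = 42))
  expect_identical(a$track$records, b$track$records)
  expect_identical(a$truth, b$truth)
  c <- simulate_library(preset("WT", n_hotspots = 30, seed = 43))
  expect_false(identical(a$track$records, c$track$records))
})

test_that("invalid truth parameters are rejected", {
  expect_error(truth_params(p_resected = 0.8, p_ri = 0.3), "sum")
  expect_error(truth_params(p_ri = -0.1), "\\[0, 1\\]")
  expect_error(truth_params(dc_spacing = c(60, 40)), "low < high")
})

test_that("endpoint distances match the configured resection distribution", {
  p <- truth_params(n_hotspots = 200, events_per_hotspot = 50,
                    p_resected = 1, p_ri = 0, p_cc = 0,
                    cut_disp = 0, cut_disp_sd = 0,
                    background_rate = 0, seed = 11)
  sim <- simulate_library(p)
  r <- sim$track$records
  r <- r[r$chrom == "chrSim", , drop = FALSE]
  centers <- sim$hotspots$center[r$pos %/% p$hotspot_spacing + 1]
  emp <- abs(r$pos - centers)
  expect_gte(length(emp), 1e4)
  # reference sample drawn directly from the configured law
  set.seed(99)
  ref <- round(pmax(rnorm(2e4, p$gap_mean, p$gap_sd), 1) +
                 rgamma(2e4, shape = (p$resect_mean / p$resect_sd)^2,
                        rate = p$resect_mean / p$resect_sd^2))
  ks <- suppressWarnings(stats::ks.test(emp, ref))
  expect_gt(ks$p.value, 0.01)
})

test_that("enzymatic conditions detect the right DNA-end species", {
  mk <- function(...) simulate_library(truth_params(
    n_hotspots = 30, events_per_hotspot = 30, background_rate = 0,
    ...))
  # SPO11cc-only library: ExoT alone sees nothing (protein-bound ends)
  cc <- mk(p_resected = 0, p_ri = 0, p_cc = 1, seed = 1)
  expect_equal(apply_enzyme_condition(cc$track, "ExoT_only")$library_size, 0)
  # but TDP2 pretreatment recovers the cleavage complexes
  expect_equal(apply_enzyme_condition(cc$track, "TDP2_ExoT")$library_size,
               cc$track$library_size)

  # SPO11-RI-only library: TDP2+ExoT drops every blocked central end
  ri <- mk(p_resected = 0, p_ri = 1, p_cc = 0, seed = 2)
  tdp2 <- apply_enzyme_condition(ri$track, "TDP2_ExoT")
  expect_false(any(tdp2$records$flag == "ri"))
  expect_equal(tdp2$library_size, ri$track$library_size / 2)

  # protein-free ends pass every condition unchanged
  free <- mk(p_resected = 1, p_ri = 0, p_cc = 0, seed = 3)
  for (cond in c("ExoVII_ExoT", "ExoT_only", "TDP2_ExoT"))
    expect_equal(apply_enzyme_condition(free$track, cond)$records,
                 free$track$records)

  # MRN+CtIP pretreatment strips SPO11-bound ends at full efficiency
  mrn <- apply_enzyme_condition(cc$track, "MRN_CtIP_pre",
                                mrn_efficiency = 1)
  expect_equal(mrn$library_size, 0)

  expect_error(apply_enzyme_condition(cc$track, "ExoNuclease_X"),
               "unknown enzyme condition")
})

test_that("genotype presets encode the reported break biology", {
  wt <- preset("WT")
  # RI share of total signal (one central end of two per RI break) is ~10%,
  # SPO11cc share 0.6-1.7%
  expect_equal(wt$p_ri / 2, 0.10)
  expect_gte(wt$p_cc, 0.006)
  expect_lte(wt$p_cc, 0.017)
  # ATM-null: 4.5-fold break rate, no RI, double-cutting present
  atm <- preset("Atm")
  expect_equal(atm$breaks_per_cell / wt$breaks_per_cell, 4.5)
  expect_equal(atm$p_ri, 0)
  expect_gt(atm$p_doublecut, 0)
  # DMC1-null: no homolog engagement, no central RI, widened gap
  dmc1 <- preset("Dmc1")
  expect_equal(dmc1$p_ri, 0)
  expect_gt(dmc1$gap_mean, wt$gap_mean)
  # EXO1-null: modestly reduced mean resection
  expect_lt(preset("Exo1")$resect_mean, wt$resect_mean)
  expect_error(preset("Spo11"))
})
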