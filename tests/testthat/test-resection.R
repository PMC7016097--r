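test_that("mean resection E(x) follows the bin-midpoint expectation", {
  row <- numeric(800)
  # all mass in right-side bin 100 (column 500): delta at 995 bp
  row[500] <- 7
  expect_equal(mean_resection(row, "right"), 995)
  # uniform mass over bins 21-400: mean of 10i - 5 = 2100 bp
  row <- numeric(800)
  row[(400 + 21):(400 + 400)] <- 3.7
  expect_equal(mean_resection(row, "right"), 2100)
  # two-point distribution at bins 21 and 400: (205 + 3995) / 2
  row <- numeric(800)
  row[400 + 21] <- 5; row[400 + 400] <- 5
  expect_equal(mean_resection(row, "right"), 2100)
  # left side reads the mirrored columns
  row <- numeric(800)
  row[400 - 99] <- 1  # left-side bin 100
  expect_equal(mean_resection(row, "left"), 995)
  # bins 1-20 (distances < 210 bp) never contribute
  row <- numeric(800)
  row[401:420] <- 100
  expect_true(is.na(mean_resection(row, "right")))
})

test_that("mean resection is scale-invariant and matches a direct oracle", {
  set.seed(41)
  for (i in 1:20) {
    row <- random_profile_row(800, 10)
    e <- mean_resection(row, "right")
    expect_equal(mean_resection(row * 3.7, "right"), e)
    expect_equal(e, oracle_mean_resection(row, "right"))
    expect_equal(mean_resection(row, "left"),
                 oracle_mean_resection(row, "left"))
  }
})

test_that("minimum resection finds the edge of a step profile", {
  # RPM 10 at offsets 600-1500, zero inside: boundary at 600 +/- half
  # the 50-bp window
  row <- numeric(800)
  row[(400 + 61):(400 + 150)] <- 10
  b <- min_resection(row, "right")
  expect_lte(abs(b - 600), 25)
  expect_equal(b, oracle_min_resection(row, "right"))
  # flat profile equal to mu everywhere: no window tests below mu
  expect_true(is.na(min_resection(rep(4, 800), "right")))
})

test_that("maximum resection scans to the signal edge over background", {
  # triangle falling to zero at 1800 bp, zero background
  row <- numeric(1200)  # W = 6000, 20-bp bins
  idx <- 1:90
  row[600 + idx] <- pmax(0, 91 - idx)
  m <- max_resection(row, "right")
  expect_lte(abs(m - 1800), 20)
  expect_equal(m, oracle_max_resection(row, "right"))
  # profile never exceeding background is undefined
  row2 <- numeric(1200)
  row2[600 + idx] <- 1
  row2[600 + 251:300] <- 5  # background region dominates
  expect_true(is.na(max_resection(row2, "right")))
  expect_error(max_resection(numeric(400), "right"), "6000")
})

test_that("sliding-window estimators equal exhaustive brute force", {
  set.seed(42)
  for (i in 1:150) {
    row10 <- random_profile_row(800, 10)
    for (side in c("right", "left")) {
      expect_identical(min_resection(row10, side),
                       oracle_min_resection(row10, side))
    }
    row20 <- random_profile_row(600, 20)
    for (side in c("right", "left")) {
      expect_identical(max_resection(row20, side),
                       oracle_max_resection(row20, side))
    }
  }
})

test_that("min <= argmax offset <= max on unimodal profiles", {
  set.seed(43)
  for (i in 1:20) {
    peak <- sample(40:120, 1)
    x <- (1:300) * 20 - 10
    dens <- exp(-((1:300) - peak)^2 / (2 * 15^2))
    row <- c(rev(dens), dens) * 100
    mn <- min_resection(row, "right", bin = 20)
    mx <- max_resection(row, "right", bin = 20)
    if (!is.na(mn) && !is.na(mx)) {
      expect_lte(mn, x[peak])
      expect_gte(mx, x[peak])
    }
  }
})

test_that("widening the gap by 400 nt shifts minimum resection by ~400", {
  wt <- simulate_library(preset("WT", n_hotspots = 400,
                                events_per_hotspot = 50,
                                heat = "constant", seed = 44))
  wide <- simulate_library(preset("WT", n_hotspots = 400,
                                  events_per_hotspot = 50,
                                  heat = "constant", gap_mean = 1000,
                                  seed = 45))
  agg_min <- function(sim, side) {
    pm <- bin_endpoints(sim$track, sim$hotspots, W = 4000, bin = 10)
    row <- if (side == "right") colMeans(pm$top) else colMeans(pm$bottom)
    min_resection(row, side)
  }
  d_right <- agg_min(wide, "right") - agg_min(wt, "right")
  d_left <- agg_min(wide, "left") - agg_min(wt, "left")
  expect_lte(abs(d_right - 400), 150)
  expect_lte(abs(d_left - 400), 150)
})

test_that("offset t-test genotype comparison behaves over the null", {
  a <- stats::setNames(rep(1000, 50), paste0("h", 1:50))
  expect_gt(compare_resection(a, a, mu_offset = 10)$p_value, 0.9)
  # deterministic +500 shift: significant with median difference 500
  res <- compare_resection(a, a + 500, mu_offset = 10)
  expect_lt(res$p_value, 1e-6)
  expect_equal(res$median_diff, 500)
  # mismatched hotspot sets are intersected with a warning
  b <- stats::setNames(rep(1200, 60), paste0("h", 1:60))
  expect_warning(res2 <- compare_resection(a, b, 10), "shared")
  expect_equal(res2$n, 50)
  # null simulation: B = A + N(0, 5) vs mu = 10 stays non-significant
  set.seed(46)
  rejections <- 0L
  a0 <- stats::setNames(stats::rnorm(250, 1100, 200), paste0("h", 1:250))
  for (k in 1:100) {
    b0 <- a0 + stats::rnorm(250, 0, 5)
    if (compare_resection(a0, b0, mu_offset = 10)$p_value <= 0.01)
      rejections <- rejections + 1L
  }
  expect_lte(rejections, 5)
})
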