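#' DNA end-resection estimators
#'
#' Three per-hotspot, per-side estimators of meiotic DSB resection from a
#' binned endpoint profile row centered on the SPO11 summit:
#'
#' * **mean** long-range resection: the expected value of the resection
#'   endpoint distribution, `E(x) = sum_{i=21}^{400} x_i p_i` over 10 bp
#'   bins, with `x_i` the bin-midpoint distance from the summit
#'   (`10 i - 5` bp) and `p_i` the bin's share of the side's signal over
#'   bins 21–400 (distances below 210 bp never contribute);
#' * **minimum** resection (the read-less gap edge): a window of 10 bp bins
#'   slides from the long-range peak toward the center; the first window
#'   whose one-sided t-test (`H1:` window mean < `mu`, the mean of the bins
#'   within 500 bp of the peak) reaches `p <= alpha` marks the boundary;
#' * **maximum** resection: with a dynamic background (the maximum 20 bp
#'   bin at 5–6 kb from the summit on the same side), a window of 20 bp
#'   bins slides outward from the long-range peak until more than half its
#'   bins fall below background; the last preceding bin above background is
#'   the maximum endpoint.
#'
#' The top (+) strand measures the right side of the break, the bottom (-)
#' strand the left side. Undefined estimates are returned as `NA`, never 0.
#'
#' @name resection-estimators
NULL

# Distances and values of one side of a profile row. Row covers
# [-W, W) at `bin` resolution; right side = columns past the center in
# order, left side = columns before the center reversed, so index i on
# either side is the bin covering distances [ (i-1)*bin, i*bin ) and has
# midpoint distance i*bin - bin/2.
side_values <- function(row, side = c("right", "left")) {
  side <- match.arg(side)
  n <- length(row)
  half <- n / 2
  if (side == "right") row[(half + 1):n] else rev(row[1:half])
}

# Index of the long-range resection peak of a side profile: leftmost argmax
# of the smoothed profile at distances beyond `min_offset`.
long_range_peak <- function(vals, bin, min_offset = 300, smooth_sd = 2) {
  first <- floor(min_offset / bin) + 1L
  if (first > length(vals)) return(NA_integer_)
  sm <- gaussian_smooth(vals, smooth_sd)
  cand <- sm[first:length(vals)]
  if (max(cand) <= 0) return(NA_integer_)
  first + which_max_left(cand) - 1L
}

#' Mean long-range resection E(x)
#'
#' @param row numeric profile row over \[-4 kb, 4 kb) in 10 bp bins
#'   (length 800), raw or RPM (the estimate is scale-invariant).
#' @param side `"right"` (top strand) or `"left"` (bottom strand).
#' @param bin bin width bp (default 10).
#' @param bins_range bins entering the expectation (default 21–400, i.e.
#'   distances 210–4000 bp).
#' @return mean resection in bp, or `NA` if the side carries no signal in
#'   `bins_range`.
#' @rdname resection-estimators
#' @export
mean_resection <- function(row, side = c("right", "left"), bin = 10,
                           bins_range = c(21, 400)) {
  vals <- side_values(row, side)
  idx <- seq(bins_range[1], min(bins_range[2], length(vals)))
  v <- vals[idx]
  tot <- sum(v)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  x <- idx * bin - bin / 2
  sum(x * v) / tot
}

#' Minimum resection via sliding-window t-test
#'
#' @param row profile row as in [mean_resection()].
#' @param window_bins sliding-window width in bins (default 5).
#' @param alpha significance threshold of the one-sided t-test (default
#'   0.05).
#' @param peak_min_offset smallest distance (bp) at which the long-range
#'   peak may sit (default 300).
#' @param mu_halfwidth half-width (bp) of the reference region around the
#'   peak whose bin mean defines `mu` (default 500).
#' @return boundary distance in bp (midpoint of the first significant
#'   window), or `NA` if no window reaches significance.
#' @rdname resection-estimators
#' @export
min_resection <- function(row, side = c("right", "left"), bin = 10,
                          window_bins = 5, alpha = 0.05,
                          peak_min_offset = 300, mu_halfwidth = 500) {
  vals <- side_values(row, side)
  peak <- long_range_peak(vals, bin, peak_min_offset)
  if (is.na(peak)) return(NA_real_)
  hw <- floor(mu_halfwidth / bin)
  mu <- mean(vals[max(1, peak - hw):min(length(vals), peak + hw)])
  w <- window_bins
  j_start <- peak - w + 1L
  if (j_start < 1L) return(NA_real_)
  for (j in seq(j_start, 1L)) {
    p <- t_test_p(vals[j:(j + w - 1L)], mu, "less")
    if (p <= alpha) return((j + (w - 1) / 2) * bin - bin / 2)
  }
  NA_real_
}

#' Maximum resection via dynamic-background outward scan
#'
#' @param row profile row over \[-6 kb, 6 kb) in 20 bp bins (length 600).
#' @param bg_range distance range (bp) defining the dynamic background
#'   (default 5000–6000; the background is the maximum bin there).
#' @return distance (bp) of the last bin above background before the scan
#'   stops, or `NA` when the background reaches the peak intensity.
#' @rdname resection-estimators
#' @export
max_resection <- function(row, side = c("right", "left"), bin = 20,
                          window_bins = 5, bg_range = c(5000, 6000),
                          peak_min_offset = 300) {
  vals <- side_values(row, side)
  nb <- length(vals)
  if (nb * bin < bg_range[2]) stop("profile must extend to ", bg_range[2],
                                   " bp on each side")
  bg_idx <- seq(floor(bg_range[1] / bin) + 1L, min(nb, bg_range[2] / bin))
  bg <- max(vals[bg_idx])
  peak <- long_range_peak(vals, bin, peak_min_offset)
  if (is.na(peak)) return(NA_real_)
  if (bg >= max(vals[peak])) return(NA_real_)
  w <- window_bins
  stop_at <- nb + 1L  # first bin of the stopping window
  for (j in seq(peak, nb - w + 1L)) {
    if (sum(vals[j:(j + w - 1L)] < bg) > w / 2) { stop_at <- j; break }
  }
  above <- which(vals > bg)
  above <- above[above < stop_at]
  if (length(above) == 0) return(NA_real_)
  max(above) * bin - bin / 2
}

#' Per-hotspot resection table
#'
#' Applies the three estimators to every hotspot and side. The right side
#' is measured on the top-strand profile, the left side on the bottom
#' strand. Minimum and mean use the 10 bp matrix, maximum the 20 bp/6 kb
#' matrix.
#'
#' @param pm10 `ProfileMatrix` with `W = 4000`, `bin = 10`.
#' @param pm20 `ProfileMatrix` with `W >= 6000`, `bin = 20` (may be `NULL`
#'   to skip maximum resection).
#' @param ... passed to the estimators.
#' @return data.frame: `hotspot`, `side`, `min_resection`,
#'   `mean_resection`, `max_resection`, `background`.
#' @export
resection_table <- function(pm10, pm20 = NULL, ...) {
  n <- nrow(pm10$top)
  res <- vector("list", 2 * n)
  for (k in seq_len(n)) {
    for (side in c("right", "left")) {
      row10 <- if (side == "right") pm10$top[k, ] else pm10$bottom[k, ]
      mn <- min_resection(row10, side, bin = pm10$bin, ...)
      me <- mean_resection(row10, side, bin = pm10$bin)
      mx <- NA_real_; bg <- NA_real_
      if (!is.null(pm20)) {
        row20 <- if (side == "right") pm20$top[k, ] else pm20$bottom[k, ]
        vals <- side_values(row20, side)
        bg_idx <- seq(floor(5000 / pm20$bin) + 1L,
                      min(length(vals), 6000 / pm20$bin))
        bg <- max(vals[bg_idx])
        mx <- max_resection(row20, side, bin = pm20$bin)
      }
      res[[2 * (k - 1) + (side == "left") + 1]] <-
        data.frame(hotspot = k, side = side, min_resection = mn,
                   mean_resection = me, max_resection = mx,
                   background = bg, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Compare per-hotspot resection between genotypes with an offset t-test
#'
#' One-sample t-test on the paired per-hotspot differences `b - a` against
#' a null offset `mu_offset` (`H1:` differences exceed `mu_offset`), the
#' offset being an allowance for technical variation between replicates.
#' Hotspots absent from either group are dropped with a warning.
#'
#' @param a,b named numeric vectors of per-hotspot estimates (names =
#'   hotspot ids; unnamed vectors are paired by position).
#' @param mu_offset null offset in bp (default 10).
#' @return list: `p_value`, `statistic`, `median_diff`, `n`, `mu_offset`.
#' @export
compare_resection <- function(a, b, mu_offset = 10) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be nonempty")
  if (is.null(names(a)) || is.null(names(b))) {
    if (length(a) != length(b))
      stop("unnamed groups must have equal length")
  } else {
    ids <- intersect(names(a), names(b))
    if (length(ids) < length(a) || length(ids) < length(b))
      warning("restricting comparison to ", length(ids),
              " shared hotspot(s)")
    a <- a[ids]; b <- b[ids]
  }
  keep <- is.finite(a) & is.finite(b)
  d <- (b - a)[keep]
  if (length(d) == 0) stop("no complete pairs")
  s <- stats::sd(d)
  if (is.na(s) || s == 0) {
    stat <- NA_real_
    p <- if (mean(d) > mu_offset) 0 else 1
  } else {
    tt <- stats::t.test(d, mu = mu_offset, alternative = "greater")
    stat <- unname(tt$statistic); p <- tt$p.value
  }
  list(p_value = p, statistic = stat, median_diff = stats::median(d),
       n = length(d), mu_offset = mu_offset)
}
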