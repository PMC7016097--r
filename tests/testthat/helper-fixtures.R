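# Small builders used across test files.

tiny_genome <- c(chr1 = 10000, chr2 = 5000)

# Track from parallel vectors on the tiny genome.
make_track <- function(chrom, pos, strand, weight = 1, flag = "free",
                       genome = tiny_genome) {
  endpoint_track(data.frame(chrom = chrom, pos = pos, strand = strand,
                            weight = rep(weight, length.out = length(chrom)),
                            flag = rep(flag, length.out = length(chrom)),
                            stringsAsFactors = FALSE), genome)
}

write_bed6 <- function(lines) {
  path <- tempfile(fileext = ".bed")
  writeLines(lines, path)
  path
}

# AggregateProfile from raw per-strand vectors (bin midpoints as offsets).
make_profile <- function(top, bottom, bin = 10) {
  n <- length(top)
  W <- n * bin / 2
  out <- data.frame(offset = seq(-W, W - bin, by = bin) + bin / 2,
                    top = top, bottom = bottom, pooled = top + bottom)
  attr(out, "bin") <- bin
  class(out) <- c("AggregateProfile", "data.frame")
  out
}

# Track whose central reads sit at fixed offsets around every hotspot
# center; used for analytic polarity checks.
central_track <- function(top_offset, bottom_offset, n_hotspots = 50,
                          reads = 20) {
  spacing <- 16000
  genome <- c(chrSim = n_hotspots * spacing)
  centers <- as.integer(spacing / 2 + (seq_len(n_hotspots) - 1) * spacing)
  hs <- hotspot_set(rep("chrSim", n_hotspots), centers - 2000L,
                    centers + 2000L, center = centers)
  rec <- data.frame(
    chrom = "chrSim",
    pos = c(rep(centers + top_offset, each = reads),
            rep(centers + bottom_offset, each = reads)),
    strand = rep(c("+", "-"), each = n_hotspots * reads),
    stringsAsFactors = FALSE)
  list(track = endpoint_track(rec, genome), hotspots = hs)
}

# Brute-force oracles for the sliding-window resection estimators; written
# against stats::t.test directly and an explicit window enumeration.
oracle_min_resection <- function(row, side, bin = 10, w = 5, alpha = 0.05) {
  n <- length(row)
  vals <- if (side == "right") row[(n / 2 + 1):n] else rev(row[1:(n / 2)])
  first <- floor(300 / bin) + 1
  sm <- endseqr:::gaussian_smooth(vals, 2)
  cand <- sm[first:length(vals)]
  if (max(cand) <= 0) return(NA_real_)
  peak <- first + which(cand == max(cand))[1] - 1
  hw <- floor(500 / bin)
  mu <- mean(vals[max(1, peak - hw):min(length(vals), peak + hw)])
  starts <- seq(peak - w + 1, 1)
  if (peak - w + 1 < 1) return(NA_real_)
  for (j in starts) {
    x <- vals[j:(j + w - 1)]
    p <- if (sd(x) == 0) {
      if (mean(x) < mu) 0 else 1
    } else stats::t.test(x, mu = mu, alternative = "less")$p.value
    if (p <= alpha) return((j + (w - 1) / 2) * bin - bin / 2)
  }
  NA_real_
}

oracle_max_resection <- function(row, side, bin = 20, w = 5) {
  n <- length(row)
  vals <- if (side == "right") row[(n / 2 + 1):n] else rev(row[1:(n / 2)])
  nb <- length(vals)
  bg <- max(vals[(floor(5000 / bin) + 1):min(nb, 6000 / bin)])
  first <- floor(300 / bin) + 1
  sm <- endseqr:::gaussian_smooth(vals, 2)
  cand <- sm[first:nb]
  if (max(cand) <= 0) return(NA_real_)
  peak <- first + which(cand == max(cand))[1] - 1
  if (bg >= max(vals[peak])) return(NA_real_)
  stop_at <- nb + 1
  for (j in seq(peak, nb - w + 1)) {
    if (sum(vals[j:(j + w - 1)] < bg) > w / 2) { stop_at <- j; break }
  }
  above <- which(vals > bg & seq_len(nb) < stop_at)
  if (length(above) == 0) return(NA_real_)
  max(above) * bin - bin / 2
}

oracle_mean_resection <- function(row, side, bin = 10) {
  n <- length(row)
  vals <- if (side == "right") row[(n / 2 + 1):n] else rev(row[1:(n / 2)])
  i <- 21:400
  if (sum(vals[i]) <= 0) return(NA_real_)
  stats::weighted.mean(i * bin - bin / 2, vals[i])
}

# Random profile rows with hotspot-like structure (gap + flank bump +
# noise) for the estimator-vs-oracle property suite.
random_profile_row <- function(n_bins, bin) {
  side <- function() {
    nb <- n_bins / 2
    v <- numeric(nb)
    gap <- sample(20:100, 1)
    peak <- gap + sample(10:60, 1)
    width <- sample(10:80, 1)
    lo <- min(peak, nb - 1)
    hi <- min(peak + width, nb)
    v[lo:hi] <- stats::rpois(hi - lo + 1, stats::runif(1, 2, 30))
    noise <- stats::rbinom(nb, 1, stats::runif(1, 0, 0.05)) *
      stats::rpois(nb, 1)
    v + noise
  }
  c(rev(side()), side())
}
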