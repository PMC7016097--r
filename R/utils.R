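# Internal helpers shared across modules.

#' @importFrom GenomicRanges GRanges findOverlaps reduce
#' @importFrom IRanges IRanges
NULL

# GRanges from 0-based half-open intervals.
gr_from_bed0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L, end = end))
}

# GRanges of 1-bp endpoint positions (0-based input).
gr_from_pos0 <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos + 1L, width = 1L))
}

# Gaussian kernel smoothing; symmetric kernel so a delta keeps its argmax.
# x: numeric vector; sd in units of vector indices. sd = 0 is the identity.
gaussian_smooth <- function(x, sd) {
  if (sd <= 0 || length(x) < 2) return(x)
  half <- max(1L, ceiling(3 * sd))
  k <- stats::dnorm(seq(-half, half), sd = sd)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))  # edge padding by replication
  out <- stats::filter(xp, k, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

# Leftmost argmax.
which_max_left <- function(x) which(x == max(x))[1L]

# Weighted median of values v with nonnegative weights w.
weighted_median <- function(v, w) {
  o <- order(v)
  v <- v[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  v[which(cw >= 0.5)[1L]]
}

# One-sample t-test p-value (closed form, equal to stats::t.test), robust
# to zero-variance samples: a constant window below/above mu is treated as
# an extreme (p = 0) or null (p = 1) outcome.
# alternative "less": H1 mean(x) < mu; "greater": H1 mean(x) > mu.
t_test_p <- function(x, mu, alternative) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) {
    m <- mean(x)
    hit <- if (alternative == "less") m < mu else m > mu
    return(if (hit) 0 else 1)
  }
  tstat <- (mean(x) - mu) / (s / sqrt(length(x)))
  if (alternative == "less") stats::pt(tstat, length(x) - 1)
  else stats::pt(tstat, length(x) - 1, lower.tail = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
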