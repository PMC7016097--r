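#' Central (SPO11-bound) signal fraction from paired enzyme conditions
#'
#' The ExoT-only profile, which carries no protein-bound central signal, is
#' height-matched to the full (ExoVII+ExoT) profile on the distal resection
#' flanks; the central fraction is the area of the (per-offset,
#' zero-clipped) difference divided by the total area of the full profile.
#' The clipped difference should sit in the central window; its share there
#' is reported as a diagnostic.
#'
#' @param full `AggregateProfile` of the ExoVII+ExoT (full detection)
#'   condition.
#' @param exot_only `AggregateProfile` of the ExoT-only condition, same
#'   offsets.
#' @param flank_range `|offset|` range (bp) used for height matching
#'   (default `c(800, 3000)`).
#' @param central_range central window half-width in bp (default 200; the
#'   central peak is ~400 bp wide).
#' @return list: `fraction`, `central_share` (share of the difference lying
#'   within the central window), `scale` (height-match factor),
#'   `negative_share` (unclipped negative mass relative to the total area;
#'   a warning is raised above 0.1).
#' @export
central_fraction <- function(full, exot_only, flank_range = c(800, 3000),
                             central_range = 200) {
  scaled <- match_heights(exot_only, full, flank_range)
  diff <- full$pooled - scaled$pooled
  total <- sum(full$pooled)
  if (total <= 0) stop("full profile carries no signal")
  neg <- sum(pmax(-diff, 0)) / total
  if (neg > 0.1)
    warning(sprintf(
      "negative difference mass (%.1f%% of total area) exceeds 10%%: the two conditions may not share flank shape", 100 * neg))
  pos <- pmax(diff, 0)
  central <- abs(full$offset) <= central_range
  list(fraction = sum(pos) / total,
       central_share = if (sum(pos) > 0) sum(pos[central]) / sum(pos) else NA_real_,
       scale = attr(scaled, "height_scale"),
       negative_share = neg)
}

#' Decompose the central fraction into SPO11-RI and unresected SPO11cc
#'
#' Bounds the unresected SPO11 cleavage complex (SPO11cc) fraction of total
#' DSB signal from two directions and assigns the remainder of the
#' ExoVII+ExoT central fraction to SPO11-RI:
#' * upper bound: if ExoT detects SPO11cc and SPO11-RI equally, the
#'   TDP2+ExoT central fraction `f_tdp2` is all SPO11cc (`cc_high`);
#' * lower bound: if ExoT captures every SPO11cc, the implied SPO11cc break
#'   count is `n_cc = round(total_breaks_exot * ratio_tdp2_vs_exot)` and
#'   `cc_low = n_cc / total_breaks_ref`.
#'
#' The SPO11-RI bounds are the order-reversed complements:
#' `ri_low = f_full - cc_high`, `ri_high = f_full - cc_low`, so
#' `ri_low + cc_high = ri_high + cc_low = f_full` exactly.
#'
#' @param f_full central fraction under ExoVII+ExoT (of total DSB signal).
#' @param f_tdp2 central fraction under TDP2+ExoT.
#' @param total_breaks_exot spike-in-normalized total break number of the
#'   ExoT-only sample.
#' @param ratio_tdp2_vs_exot central signal of TDP2+ExoT relative to
#'   ExoT-only total signal.
#' @param total_breaks_ref reference total break number for the lower
#'   bound (default 333, the total implied by a ~0.6% share of 2 breaks).
#' @return list of class `CentralDecomposition`: `f_full`, `f_tdp2`,
#'   `cc_low`, `cc_high`, `ri_low`, `ri_high`, `n_cc`.
#' @export
decompose_central <- function(f_full, f_tdp2, total_breaks_exot,
                              ratio_tdp2_vs_exot, total_breaks_ref = 333) {
  stopifnot(f_full >= 0, f_full <= 1, f_tdp2 >= 0,
            total_breaks_exot >= 0, ratio_tdp2_vs_exot >= 0,
            total_breaks_ref > 0)
  if (f_tdp2 > f_full)
    stop("inconsistent inputs: TDP2+ExoT central fraction exceeds the ",
         "ExoVII+ExoT fraction")
  cc_high <- f_tdp2
  n_cc <- round(total_breaks_exot * ratio_tdp2_vs_exot)
  cc_low <- n_cc / total_breaks_ref
  if (cc_low > cc_high) {
    # bounds cross when the reference total is small; keep them ordered
    tmp <- cc_low; cc_low <- cc_high; cc_high <- tmp
  }
  if (cc_high > f_full)
    stop("inconsistent inputs: SPO11cc bound exceeds the total central ",
         "fraction")
  structure(list(f_full = f_full, f_tdp2 = f_tdp2,
                 cc_low = cc_low, cc_high = cc_high,
                 ri_low = f_full - cc_high, ri_high = f_full - cc_low,
                 n_cc = n_cc),
            class = "CentralDecomposition")
}

#' @export
print.CentralDecomposition <- function(x, ...) {
  cat(sprintf(
    paste0("Central-signal decomposition\n",
           "  central fraction (ExoVII+ExoT): %.1f%%\n",
           "  central fraction (TDP2+ExoT):   %.1f%%\n",
           "  unresected SPO11cc: %.1f%% - %.1f%% (~%d breaks)\n",
           "  SPO11-RI:           %.1f%% - %.1f%%\n"),
    100 * x$f_full, 100 * x$f_tdp2, 100 * x$cc_low, 100 * x$cc_high,
    x$n_cc, 100 * x$ri_low, 100 * x$ri_high))
  invisible(x)
}

#' Strand-polarity shift of the central peak
#'
#' Locates the top- and bottom-strand central endpoint distributions within
#' `|offset| <= window` of the hotspot centers (pooled over hotspots) and
#' returns `shift = location(top) - location(bottom)`. Negative values are
#' the "wrong" polarity signature of SPO11-RI (top-strand reads left of
#' center); positive values the "correct" polarity of unresected /
#' double-cut SPO11 ends.
#'
#' @param track [endpoint_track()].
#' @param hotspots [hotspot_set()].
#' @param window central half-width in bp (default 300).
#' @param estimator `"mode"` (argmax of the Gaussian-smoothed 1 bp offset
#'   histogram, leftmost tie; default) or `"median"` (weighted median of
#'   the offsets).
#' @param smooth_sd mode-smoothing sd in bp (default 5).
#' @return list: `shift` (signed bp), `magnitude`, `top`, `bottom`
#'   (per-strand locations), `n_top`, `n_bottom`. `shift` is `NA` when a
#'   strand has no central reads.
#' @export
polarity_shift <- function(track, hotspots, window = 300,
                           estimator = c("mode", "median"), smooth_sd = 5) {
  estimator <- match.arg(estimator)
  hs <- hotspots[!hotspots$blacklisted, , drop = FALSE]
  r <- track$records
  offs <- list("+" = numeric(), "-" = numeric())
  wts <- list("+" = numeric(), "-" = numeric())
  by_chrom <- split(r, r$chrom)
  by_chrom <- lapply(by_chrom, function(d) d[order(d$pos), , drop = FALSE])
  for (k in seq_len(nrow(hs))) {
    d <- by_chrom[[hs$chrom[k]]]
    if (is.null(d)) next
    lo <- findInterval(hs$center[k] - window - 0.5, d$pos) + 1L
    hi <- findInterval(hs$center[k] + window + 0.5, d$pos)
    if (hi < lo) next
    dd <- d[lo:hi, , drop = FALSE]
    for (s in c("+", "-")) {
      j <- dd$strand == s
      offs[[s]] <- c(offs[[s]], dd$pos[j] - hs$center[k])
      wts[[s]] <- c(wts[[s]], dd$weight[j])
    }
  }
  if (length(offs[["+"]]) == 0 || length(offs[["-"]]) == 0)
    return(list(shift = NA_real_, magnitude = NA_real_, top = NA_real_,
                bottom = NA_real_, n_top = length(offs[["+"]]),
                n_bottom = length(offs[["-"]])))
  locate <- function(o, w) {
    if (estimator == "median") return(weighted_median(o, w))
    grid <- seq(-window, window)
    h <- numeric(length(grid))
    acc <- rowsum(w, o)
    h[as.integer(rownames(acc)) + window + 1L] <- acc[, 1]
    grid[which_max_left(gaussian_smooth(h, smooth_sd))]
  }
  top <- locate(offs[["+"]], wts[["+"]])
  bottom <- locate(offs[["-"]], wts[["-"]])
  list(shift = top - bottom, magnitude = abs(top - bottom),
       top = top, bottom = bottom,
       n_top = length(offs[["+"]]), n_bottom = length(offs[["-"]]))
}
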