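#' Spike-in normalization of total break numbers
#'
#' Spike-in cells carrying exactly one defined DSB are mixed into the
#' sample at a known ratio (1:50 by default, i.e. 2%). The total hotspot
#' signal (sum of endpoint weights within +/- `window` of the union of
#' hotspot centers) divided by the spike-locus signal, divided by the
#' mixing divisor, is the number of breaks per bulk cell-equivalent. The
#' estimate is a ratio: invariant to sequencing depth and to raw vs RPM
#' weights.
#'
#' @param track [endpoint_track()].
#' @param hotspots [hotspot_set()].
#' @param spike_chrom,spike_pos spike-in DSB locus (0-based position).
#' @param divisor mixing divisor (default 50 for a 2% spike-in).
#' @param window half-width in bp of the signal windows (default 5000).
#' @return list of class `SpikeInScale`: `total_signal`, `spike_signal`,
#'   `divisor`, `total_breaks` (breaks per bulk cell-equivalent).
#' @export
spike_in_total_breaks <- function(track, hotspots, spike_chrom, spike_pos,
                                  divisor = 50, window = 5000) {
  hs <- hotspots[!hotspots$blacklisted, , drop = FALSE]
  r <- track$records
  gr <- gr_from_pos0(r$chrom, r$pos)
  hs_win <- GenomicRanges::reduce(gr_from_bed0(
    hs$chrom, pmax(hs$center - window, 0), hs$center + window))
  # endpoints may span chromosomes absent from either window set
  total <- sum(r$weight[suppressWarnings(IRanges::overlapsAny(gr, hs_win))])
  spike_win <- gr_from_bed0(spike_chrom, max(spike_pos - window, 0),
                            spike_pos + window)
  spike <- sum(r$weight[suppressWarnings(IRanges::overlapsAny(gr, spike_win))])
  if (spike <= 0)
    stop("no spike-in signal at ", spike_chrom, ":", spike_pos)
  structure(list(total_signal = total, spike_signal = spike,
                 divisor = divisor,
                 total_breaks = (total / spike) / divisor),
            class = "SpikeInScale")
}

#' @export
print.SpikeInScale <- function(x, ...) {
  cat(sprintf("Spike-in scale: total %.4g / spike %.4g / %g = %.3g breaks per cell\n",
              x$total_signal, x$spike_signal, x$divisor, x$total_breaks))
  invisible(x)
}

#' Fraction of reads in peaks (FRiP)
#'
#' Weighted fraction of endpoints overlapping any peak interval, without
#' any read filtering. FRiP is monotone nondecreasing under peak-set union.
#'
#' @param track [endpoint_track()]; must be nonempty.
#' @param peaks [hotspot_set()] or any data.frame with `chrom`, `start`,
#'   `end` (0-based half-open).
#' @return fraction in \[0, 1\].
#' @export
frip <- function(track, peaks) {
  if (track$library_size == 0) stop("FRiP undefined on an empty track")
  if (nrow(peaks) == 0) return(0)
  gr <- gr_from_pos0(track$records$chrom, track$records$pos)
  pk <- GenomicRanges::reduce(gr_from_bed0(peaks$chrom, peaks$start,
                                           peaks$end))
  sum(track$records$weight[IRanges::overlapsAny(gr, pk)]) /
    track$library_size
}

#' Strand cross-correlation profile and NSC/RSC quality metrics
#'
#' Pearson correlation of binned top- and bottom-strand endpoint coverage
#' after shifting the bottom (minus) strand by each lag in `shift_range`
#' (`cc(s)` pairs `plus[i]` with `minus[i + s/bin]`, pooled over
#' chromosomes). For ChIP-seq-like data the fragment peak sits at a
#' positive shift; END-seq has the opposite orientation — bottom-strand
#' resection endpoints lie left of top-strand ones — so the fragment peak
#' `CCfrag` is the maximum over *negative* shifts, and its location tracks
#' the distance between the two long-range resection flanks. `CCread` is
#' the value at `+read_length`; `CCmin` the minimum over the range.
#' `NSC = CCfrag / CCmin` (requires a positive correlation baseline;
#' reported `NA` otherwise) and `RSC = (CCfrag - CCmin) / (CCread - CCmin)`.
#'
#' @param track [endpoint_track()]; both strands must be nonempty and
#'   non-constant.
#' @param shift_range length-2 numeric in bp, spanning negative shifts and
#'   the read length (default `c(-4000, 1000)`).
#' @param bin coverage bin width in bp (default 10; shifts are evaluated on
#'   this grid).
#' @param read_length nominal read length in bp (default 75).
#' @param blacklist optional intervals excluded from the coverage vectors.
#' @param nsc_min,rsc_min pass thresholds (defaults 1.05 and 0.8).
#' @return list of class `QCReport`: `curve` (data.frame `shift`, `cc`),
#'   `cc_frag`, `cc_read`, `cc_min`, `fragment_shift`, `nsc`, `rsc`,
#'   `nsc_pass`, `rsc_pass`.
#' @export
cross_correlation <- function(track, shift_range = c(-4000, 1000), bin = 10,
                              read_length = 75, blacklist = NULL,
                              nsc_min = 1.05, rsc_min = 0.8) {
  r <- track$records
  if (!is.null(blacklist)) {
    gr <- gr_from_pos0(r$chrom, r$pos)
    bl <- gr_from_bed0(blacklist$chrom, blacklist$start, blacklist$end)
    r <- r[!IRanges::overlapsAny(gr, bl), , drop = FALSE]
  }
  if (sum(r$strand == "+") == 0 || sum(r$strand == "-") == 0)
    stop("both strands must carry endpoints")
  shifts_bins <- seq(floor(shift_range[1] / bin),
                     ceiling(shift_range[2] / bin))
  vecs <- lapply(names(track$genome), function(chrom) {
    d <- r[r$chrom == chrom, , drop = FALSE]
    nb <- as.integer(ceiling(track$genome[[chrom]] / bin))
    mk <- function(s) {
      v <- numeric(nb)
      dd <- d[d$strand == s, , drop = FALSE]
      if (nrow(dd) > 0) {
        acc <- rowsum(dd$weight, pmin(dd$pos %/% bin, nb - 1L) + 1L)
        v[as.integer(rownames(acc))] <- acc[, 1]
      }
      v
    }
    list(p = mk("+"), m = mk("-"))
  })
  cc <- vapply(shifts_bins, function(k) {
    sp <- sm <- spp <- smm <- spm <- 0; n <- 0
    for (v in vecs) {
      nb <- length(v$p)
      if (k >= 0) { i <- seq_len(nb - k); j <- i + k }
      else { j <- seq_len(nb + k); i <- j - k }
      if (length(i) < 2) next
      p <- v$p[i]; m <- v$m[j]
      n <- n + length(i)
      sp <- sp + sum(p); sm <- sm + sum(m)
      spp <- spp + sum(p * p); smm <- smm + sum(m * m)
      spm <- spm + sum(p * m)
    }
    varp <- spp - sp^2 / n; varm <- smm - sm^2 / n
    if (n < 2 || varp <= 0 || varm <= 0) return(NA_real_)
    (spm - sp * sm / n) / sqrt(varp * varm)
  }, numeric(1))
  if (all(is.na(cc)))
    stop("cross-correlation undefined: constant coverage on a strand")
  shifts <- shifts_bins * bin
  neg <- which(shifts < 0 & !is.na(cc))
  if (length(neg) == 0) stop("shift_range must include negative shifts")
  cc_frag <- max(cc[neg])
  fragment_shift <- shifts[neg[which_max_left(cc[neg])]]
  cc_read <- cc[which.min(abs(shifts - read_length))]
  cc_min <- min(cc, na.rm = TRUE)
  nsc <- if (cc_min > 0) cc_frag / cc_min else NA_real_
  rsc <- if (is.finite(cc_read) && (cc_read - cc_min) > 1e-12)
    (cc_frag - cc_min) / (cc_read - cc_min) else NA_real_
  structure(list(curve = data.frame(shift = shifts, cc = cc),
                 cc_frag = cc_frag, cc_read = cc_read, cc_min = cc_min,
                 fragment_shift = fragment_shift, nsc = nsc, rsc = rsc,
                 nsc_pass = isTRUE(nsc >= nsc_min),
                 rsc_pass = isTRUE(rsc >= rsc_min)),
            class = "QCReport")
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf(paste0(
    "END-seq cross-correlation QC\n",
    "  CCfrag %.4f at shift %d bp | CCread %.4f | CCmin %.4f\n",
    "  NSC %.3f (%s) | RSC %.3f (%s)\n"),
    x$cc_frag, x$fragment_shift, x$cc_read, x$cc_min,
    x$nsc, if (isTRUE(x$nsc_pass)) "pass" else "fail",
    x$rsc, if (isTRUE(x$rsc_pass)) "pass" else "fail"))
  invisible(x)
}
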