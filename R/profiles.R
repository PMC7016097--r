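#' Bin endpoints into strand-separated per-hotspot profiles
#'
#' For every hotspot, endpoints within `W` bp of the center are binned at
#' `bin` bp resolution: an endpoint at offset `o = pos - center`
#' (`-W <= o < W`) lands in column `floor((o + W) / bin) + 1`. Rows are
#' hotspots, columns offsets; top (+) and bottom (-) strands are kept in
#' separate matrices.
#'
#' @param track [endpoint_track()].
#' @param hotspots [hotspot_set()]; blacklisted rows are skipped.
#' @param W window half-width in bp (default 4000); must be a multiple of
#'   `bin`.
#' @param bin bin width in bp (default 10).
#' @param normalize `"raw"` counts or `"RPM"` (counts scaled by
#'   `1e6 / library_size`).
#' @return list of class `ProfileMatrix`: `hotspot` (row ids), `offsets`
#'   (bin midpoints relative to the center), matrices `top` and `bottom`,
#'   `bin`, `W`, `normalize`.
#' @export
bin_endpoints <- function(track, hotspots, W = 4000, bin = 10,
                          normalize = c("raw", "RPM")) {
  normalize <- match.arg(normalize)
  if (W %% bin != 0) stop("W must be a multiple of bin")
  hs <- hotspots[!hotspots$blacklisted, , drop = FALSE]
  n <- nrow(hs)
  ncol <- as.integer(2 * W / bin)
  top <- matrix(0, n, ncol)
  bottom <- matrix(0, n, ncol)
  r <- track$records
  by_chrom <- split(r[, c("pos", "strand", "weight")], r$chrom)
  by_chrom <- lapply(by_chrom, function(d) d[order(d$pos), , drop = FALSE])
  truncated <- 0L
  for (k in seq_len(n)) {
    if (hs$center[k] - W < 0 ||
        hs$center[k] + W > track$genome[[hs$chrom[k]]])
      truncated <- truncated + 1L
    d <- by_chrom[[hs$chrom[k]]]
    if (is.null(d) || nrow(d) == 0) next
    lo <- findInterval(hs$center[k] - W - 0.5, d$pos) + 1L
    hi <- findInterval(hs$center[k] + W - 0.5, d$pos)
    if (hi < lo) next
    rr <- d[lo:hi, , drop = FALSE]
    col <- (rr$pos - hs$center[k] + W) %/% bin + 1L
    for (s in c("+", "-")) {
      j <- rr$strand == s
      if (!any(j)) next
      acc <- rowsum(rr$weight[j], col[j])
      idx <- as.integer(rownames(acc))
      if (s == "+") top[k, idx] <- top[k, idx] + acc[, 1]
      else bottom[k, idx] <- bottom[k, idx] + acc[, 1]
    }
  }
  if (truncated > 0)
    warning(truncated, " hotspot window(s) exceed chromosome bounds; ",
            "counts truncated at the boundary")
  if (normalize == "RPM") {
    sc <- 1e6 / track$library_size
    top <- top * sc; bottom <- bottom * sc
  }
  structure(list(hotspot = seq_len(n), offsets = seq(-W, W - bin, by = bin) +
                   bin / 2,
                 top = top, bottom = bottom, bin = bin, W = W,
                 normalize = normalize),
            class = "ProfileMatrix")
}

#' Aggregate a profile matrix across hotspots
#'
#' Column means per strand; `pooled = top + bottom` at every offset (before
#' any smoothing). Optional Gaussian low-pass smoothing whose symmetric
#' kernel keeps the argmax of an isolated peak in its bin, and optional
#' height normalization rescaling the pooled maximum to 1.
#'
#' @param pm `ProfileMatrix` from [bin_endpoints()].
#' @param smooth logical; smooth the aggregate columns.
#' @param smooth_sd kernel sd in bins (default 2).
#' @param normalize_height logical; divide all columns by the pooled
#'   maximum.
#' @return data.frame of class `AggregateProfile` with columns `offset`,
#'   `top`, `bottom`, `pooled`; attributes `bin` and `smooth`.
#' @export
aggregate_profile <- function(pm, smooth = FALSE, smooth_sd = 2,
                              normalize_height = FALSE) {
  stopifnot(inherits(pm, "ProfileMatrix"))
  if (nrow(pm$top) == 0) stop("empty profile matrix")
  top <- colMeans(pm$top)
  bottom <- colMeans(pm$bottom)
  pooled <- top + bottom
  if (smooth) {
    top <- gaussian_smooth(top, smooth_sd)
    bottom <- gaussian_smooth(bottom, smooth_sd)
    pooled <- gaussian_smooth(pooled, smooth_sd)
  }
  if (normalize_height) {
    mx <- max(pooled)
    if (mx <= 0) stop("cannot height-normalize an all-zero profile")
    top <- top / mx; bottom <- bottom / mx; pooled <- pooled / mx
  }
  out <- data.frame(offset = pm$offsets, top = top, bottom = bottom,
                    pooled = pooled)
  attr(out, "bin") <- pm$bin
  attr(out, "smooth") <- if (smooth) smooth_sd else 0
  class(out) <- c("AggregateProfile", "data.frame")
  out
}

#' Rescale one aggregate profile to the height of a reference
#'
#' The scale factor is `reference max / sample max` computed over the
#' distal resection flanks only (`|offset|` within `flank_range`), so that
#' after matching, central-window differences between conditions are
#' directly comparable by subtraction. Matching twice is the same as
#' matching once.
#'
#' @param sample,reference `AggregateProfile`s over the same offsets.
#' @param flank_range length-2 numeric, `|offset|` range in bp of the
#'   flanks (default `c(800, 3000)`).
#' @param stat `"max"` (default) or `"area"` flank statistic.
#' @return `sample` with `top`, `bottom`, `pooled` scaled; attribute
#'   `height_scale` records the factor.
#' @export
match_heights <- function(sample, reference, flank_range = c(800, 3000),
                          stat = c("max", "area")) {
  stat <- match.arg(stat)
  if (!isTRUE(all.equal(sample$offset, reference$offset)))
    stop("profiles are not on the same offsets")
  fl <- abs(sample$offset) >= flank_range[1] &
    abs(sample$offset) <= flank_range[2]
  if (!any(fl)) stop("flank_range selects no offsets")
  f <- if (stat == "max") max else sum
  ref_stat <- f(reference$pooled[fl])
  smp_stat <- f(sample$pooled[fl])
  if (ref_stat <= 0) stop("reference has no positive flank signal")
  if (smp_stat <= 0) stop("sample has no positive flank signal")
  sc <- ref_stat / smp_stat
  sample$top <- sample$top * sc
  sample$bottom <- sample$bottom * sc
  sample$pooled <- sample$pooled * sc
  attr(sample, "height_scale") <- sc
  sample
}

#' Write / read a profile matrix as TSV (one file per strand)
#'
#' @param pm `ProfileMatrix`.
#' @param prefix output path prefix; writes `<prefix>_top.tsv` and
#'   `<prefix>_bottom.tsv` (hotspots x bins, offsets as header).
#' @return character vector of the two paths, invisibly.
#' @export
write_profile_matrix <- function(pm, prefix) {
  paths <- paste0(prefix, c("_top.tsv", "_bottom.tsv"))
  for (i in 1:2) {
    m <- if (i == 1) pm$top else pm$bottom
    colnames(m) <- pm$offsets
    utils::write.table(m, paths[i], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}
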