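#' Hotspot sets
#'
#' A hotspot set is a data.frame with one row per DSB hotspot: columns
#' `chrom`, `start`, `end` (0-based half-open interval), `center` (SPO11
#' summit or interval midpoint, 0-based), `heat` (nonnegative score) and
#' `blacklisted` (logical). Invariant: `start <= center < end`.
#'
#' @param chrom,start,end,center,heat vectors of equal length; `center`
#'   defaults to the interval midpoint, `heat` to 0.
#' @return data.frame of class `HotspotSet`.
#' @export
hotspot_set <- function(chrom, start, end, center = NULL, heat = NULL) {
  if (any(end <= start)) stop("zero- or negative-length hotspot interval")
  if (is.null(center)) center <- floor((start + end) / 2)
  if (is.null(heat)) heat <- rep(0, length(start))
  if (any(center < start | center >= end))
    stop("hotspot center outside its interval")
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), center = as.integer(center),
                   heat = as.numeric(heat),
                   blacklisted = rep(FALSE, length(start)),
                   stringsAsFactors = FALSE)
  class(df) <- c("HotspotSet", "data.frame")
  df
}

#' Read hotspots from a BED file
#'
#' @param path BED file (>= 3 columns; column 5 used as heat when present,
#'   column 7 as summit offset from `start` under
#'   `center_rule = "summit_column"`, narrowPeak-style).
#' @param center_rule `"midpoint"` (default) or `"summit_column"`.
#' @return [hotspot_set()].
#' @export
read_hotspots <- function(path, center_rule = c("midpoint", "summit_column")) {
  center_rule <- match.arg(center_rule)
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  start <- as.integer(df[[2]]); end <- as.integer(df[[3]])
  heat <- if (ncol(df) >= 5) suppressWarnings(as.numeric(df[[5]])) else NULL
  if (!is.null(heat) && anyNA(heat)) heat <- NULL
  center <- if (center_rule == "summit_column") {
    if (ncol(df) < 7) stop("summit_column requested but file has < 7 columns")
    start + as.integer(df[[7]])
  } else NULL
  hotspot_set(df[[1]], start, end, center = center, heat = heat)
}

#' Flag and drop hotspots overlapping a blacklist
#'
#' Overlap means any shared base under half-open semantics, so an abutting
#' blacklist interval does not exclude a hotspot. Blacklisted hotspots are
#' flagged and removed from the returned set.
#'
#' @param hotspots [hotspot_set()].
#' @param blacklist data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), or path to a BED file.
#' @return filtered [hotspot_set()] with attribute `n_blacklisted`.
#' @export
apply_blacklist <- function(hotspots, blacklist) {
  if (is.character(blacklist)) {
    df <- utils::read.table(blacklist, sep = "\t", stringsAsFactors = FALSE)
    blacklist <- data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]])
  }
  if (nrow(blacklist) == 0 || nrow(hotspots) == 0) {
    attr(hotspots, "n_blacklisted") <- 0L
    return(hotspots)
  }
  hits <- GenomicRanges::findOverlaps(
    gr_from_bed0(hotspots$chrom, hotspots$start, hotspots$end),
    gr_from_bed0(blacklist$chrom, blacklist$start, blacklist$end))
  bad <- unique(S4Vectors::queryHits(hits))
  hotspots$blacklisted[bad] <- TRUE
  out <- hotspots[!hotspots$blacklisted, , drop = FALSE]
  attr(out, "n_blacklisted") <- length(bad)
  out
}

#' Write a hotspot set to BED
#'
#' Heat goes in the score column, the center (as offset from start) in a
#' 7th, narrowPeak-style summit column.
#'
#' @param hotspots [hotspot_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hotspots <- function(hotspots, path) {
  df <- data.frame(hotspots$chrom, hotspots$start, hotspots$end,
                   seq_len(nrow(hotspots)), hotspots$heat, ".",
                   hotspots$center - hotspots$start)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
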