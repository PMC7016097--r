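#' Call DSB hotspots by fold enrichment over genome background
#'
#' A deliberately simple, deterministic fold-enrichment scanner (not a MACS
#' re-implementation): pooled-strand endpoint counts in sliding windows
#' (50% overlap) are compared with the expected background count
#' `library_size * window / genome_length`; qualifying windows are merged
#' into peaks, blacklist-overlapping peaks dropped, and the summit placed at
#' the leftmost argmax of the 50 bp running-mean-smoothed pooled signal.
#'
#' @param track [endpoint_track()].
#' @param window sliding-window width in bp (default 2000, matching the
#'   ~2 kb separation of the two long-range resection flanks).
#' @param min_fold minimum fold enrichment over expectation (default 2.5).
#' @param blacklist optional blacklist data.frame/BED path (see
#'   [apply_blacklist()]).
#' @return [hotspot_set()] with `heat` = fold enrichment of the peak's best
#'   sliding window over its background expectation, `center` = summit, and
#'   extra columns `count`, `count_top`, `count_bottom`.
#' @export
call_hotspots <- function(track, window = 2000, min_fold = 2.5,
                          blacklist = NULL) {
  stopifnot(window > 0)
  if (track$library_size == 0) {
    warning("empty track: no peaks called")
    return(hotspot_set(character(), integer(), integer()))
  }
  glen <- sum(track$genome)
  expected_per_bp <- track$library_size / glen
  hw <- as.integer(window / 2)
  out <- list()
  for (chrom in names(track$genome)) {
    r <- track$records[track$records$chrom == chrom, , drop = FALSE]
    if (nrow(r) == 0) next
    clen <- track$genome[[chrom]]
    nb <- as.integer(ceiling(clen / hw))
    cnt <- numeric(nb + 1)
    half_bin <- pmin(r$pos %/% hw, nb - 1L) + 1L
    agg <- rowsum(r$weight, half_bin)
    cnt[as.integer(rownames(agg))] <- agg[, 1]
    win_cnt <- cnt[seq_len(nb)] + cnt[seq_len(nb) + 1]  # [b*hw, b*hw+window)
    hit <- which(win_cnt > min_fold * expected_per_bp * window)
    if (length(hit) == 0) next
    # merge windows that overlap or abut (indices within 2 of each other)
    grp <- cumsum(c(TRUE, diff(hit) > 2))
    for (g in split(hit, grp)) {
      start <- (min(g) - 1L) * hw
      end <- min((max(g) - 1L) * hw + as.integer(window), clen)
      inside <- r$pos >= start & r$pos < end
      rr <- r[inside, , drop = FALSE]
      peak_win <- max(win_cnt[g])
      cov <- numeric(end - start)
      acc <- rowsum(rr$weight, rr$pos - start + 1L)
      cov[as.integer(rownames(acc))] <- acc[, 1]
      sm <- as.numeric(stats::filter(cov, rep(1 / 51, 51), sides = 2))
      sm[is.na(sm)] <- 0
      summit <- start + which_max_left(sm) - 1L
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = start, end = end, center = summit,
        count = sum(rr$weight), peak_win = peak_win,
        count_top = sum(rr$weight[rr$strand == "+"]),
        count_bottom = sum(rr$weight[rr$strand == "-"]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(hotspot_set(character(), integer(), integer()))
  pk <- do.call(rbind, out)
  # fold enrichment at the peak: best sliding window vs its expectation
  fold <- pk$peak_win / (expected_per_bp * window)
  hs <- hotspot_set(pk$chrom, pk$start, pk$end, center = pk$center,
                    heat = fold)
  hs$count <- pk$count
  hs$count_top <- pk$count_top
  hs$count_bottom <- pk$count_bottom
  if (!is.null(blacklist)) hs <- apply_blacklist(hs, blacklist)
  hs
}

#' Split a peak profile into subpeak summits
#'
#' Local maxima of a nonnegative per-base (or binned) signal whose height
#' reaches at least `min_prominence` times the global maximum, returned
#' left to right (plateaus contribute their leftmost base). A flat profile
#' yields a single summit at the midpoint.
#'
#' @param profile numeric vector of nonnegative signal.
#' @param min_prominence fraction of the global maximum a summit must reach
#'   (default 0.2).
#' @return integer vector of summit indices (1-based).
#' @export
split_subpeaks <- function(profile, min_prominence = 0.2) {
  stopifnot(all(profile >= 0))
  n <- length(profile)
  if (n == 0) return(integer())
  if (length(unique(profile)) == 1) return(as.integer(ceiling(n / 2)))
  # collapse plateaus: compare each run of equal values with its neighbours
  runs <- rle(profile)
  v <- runs$values
  starts <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
  k <- length(v)
  left <- c(-Inf, v[-k])
  right <- c(v[-1], -Inf)
  is_max <- v > left & v > right
  summits <- starts[is_max & v >= min_prominence * max(profile)]
  as.integer(summits)
}

#' Distances between successive subpeak summits
#'
#' @param summits integer vector from [split_subpeaks()] (or any ordered
#'   summit positions).
#' @return integer vector of successive spacings (empty for < 2 summits).
#' @export
summit_spacing <- function(summits) {
  if (length(summits) < 2) return(integer())
  as.integer(diff(sort(summits)))
}

#' Compare two hotspot sets by interval overlap
#'
#' Symmetric any-overlap matching after expanding every interval by `slop`
#' bp on each side.
#'
#' @param a,b [hotspot_set()] data.frames (columns `chrom`, `start`, `end`).
#' @param slop expansion in bp (default 0).
#' @return list with `shared` (intervals of `a` overlapping `b`),
#'   `shared_b`, `a_only`, `b_only` and `jaccard` =
#'   `shared / (|a| + |b| - shared)`.
#' @export
overlap_sets <- function(a, b, slop = 0) {
  stopifnot(slop >= 0)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(list(shared = 0L, shared_b = 0L, a_only = nrow(a),
                b_only = nrow(b), jaccard = 0))
  }
  ga <- gr_from_bed0(a$chrom, pmax(a$start - slop, 0), a$end + slop)
  gb <- gr_from_bed0(b$chrom, pmax(b$start - slop, 0), b$end + slop)
  hits <- GenomicRanges::findOverlaps(ga, gb)
  shared <- length(unique(S4Vectors::queryHits(hits)))
  shared_b <- length(unique(S4Vectors::subjectHits(hits)))
  list(shared = shared, shared_b = shared_b,
       a_only = nrow(a) - shared, b_only = nrow(b) - shared_b,
       jaccard = shared / (nrow(a) + nrow(b) - shared))
}
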