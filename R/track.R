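#' Endpoint tracks
#'
#' An `EndpointTrack` holds the strand-annotated genomic positions of
#' adapter-ligated read 5' ends, the unit END-seq observation. Positions are
#' 0-based and must satisfy `0 <= pos < genome[chrom]`. Each record carries a
#' positive integer weight (collapsed duplicates) and a species flag used by
#' the simulator and the enzymatic-condition filters (`"free"`, `"ri"`,
#' `"cc"`, `"bg"`, `"spike"`; file input defaults to the BED name column).
#'
#' @param records data.frame with columns `chrom` (character), `pos`
#'   (0-based integer), `strand` (`"+"`/`"-"`), and optionally `weight`
#'   (default 1) and `flag` (default `"free"`).
#' @param genome named numeric vector of chromosome lengths in bp.
#' @return An object of class `EndpointTrack`: a list with elements
#'   `records`, `genome` and `library_size` (sum of weights).
#' @export
endpoint_track <- function(records, genome) {
  stopifnot(is.data.frame(records), !is.null(names(genome)))
  if (nrow(records) == 0) {
    records <- data.frame(chrom = character(), pos = integer(),
                          strand = character(), weight = numeric(),
                          flag = character(), stringsAsFactors = FALSE)
  }
  if (is.null(records$weight)) records$weight <- rep(1, nrow(records))
  if (is.null(records$flag)) records$flag <- rep("free", nrow(records))
  records <- records[, c("chrom", "pos", "strand", "weight", "flag")]
  records$chrom <- as.character(records$chrom)
  records$pos <- as.integer(records$pos)
  bad_chrom <- setdiff(unique(records$chrom), names(genome))
  if (length(bad_chrom) > 0)
    stop("chromosome(s) not in genome: ", paste(bad_chrom, collapse = ", "))
  if (nrow(records) > 0) {
    len <- unname(genome[records$chrom])
    oob <- records$pos < 0 | records$pos >= len
    if (any(oob))
      stop("endpoint position outside [0, chrom length) for ",
           sum(oob), " record(s), first at ",
           records$chrom[which(oob)[1]], ":", records$pos[which(oob)[1]])
  }
  if (any(records$strand != "+" & records$strand != "-"))
    stop("strand must be '+' or '-'")
  if (any(records$weight <= 0)) stop("weights must be positive")
  structure(list(records = records, genome = genome,
                 library_size = sum(records$weight)),
            class = "EndpointTrack")
}

#' @export
print.EndpointTrack <- function(x, ...) {
  cat("EndpointTrack:", nrow(x$records), "records, library size",
      x$library_size, "on", length(x$genome), "chromosome(s)\n")
  invisible(x)
}

#' Read endpoint records from a BED6 file
#'
#' One endpoint per line; the start coordinate (0-based) is the endpoint
#' position, the name column is kept as the species flag and the score
#' column is ignored (weight 1 per line).
#'
#' @param path BED6 file.
#' @param genome named numeric vector of chromosome lengths, or the path to
#'   a two-column TSV (`chrom  length`).
#' @return [endpoint_track()] object.
#' @export
read_endpoints <- function(path, genome) {
  genome <- resolve_genome(genome)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(endpoint_track(data.frame(chrom = character(), pos = integer(),
                                     strand = character()), genome))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col < 6))
    stop("malformed BED6 (fewer than 6 fields) at line ", which(n_col < 6)[1])
  get <- function(i) vapply(fields, `[[`, "", i)
  start <- suppressWarnings(as.integer(get(2)))
  if (anyNA(start))
    stop("malformed BED6 (non-numeric start) at line ", which(is.na(start))[1])
  strand <- get(6)
  bad <- strand != "+" & strand != "-"
  if (any(bad))
    stop("malformed BED6 (strand not '+'/'-') at line ", which(bad)[1])
  endpoint_track(data.frame(chrom = get(1), pos = start, strand = strand,
                            flag = get(4), stringsAsFactors = FALSE),
                 genome)
}

#' Write endpoint records to BED6
#'
#' Inverse of [read_endpoints()]: each record becomes a 1-bp interval with
#' the species flag in the name column and the weight in the score column.
#'
#' @param track [endpoint_track()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_endpoints <- function(track, path) {
  r <- track$records
  df <- data.frame(r$chrom, r$pos, r$pos + 1L, r$flag, r$weight, r$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

resolve_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    df <- utils::read.table(genome, sep = "\t", stringsAsFactors = FALSE)
    genome <- stats::setNames(as.numeric(df[[2]]), df[[1]])
  }
  genome
}

#' Rescale endpoint weights to reads per million (RPM)
#'
#' Multiplies weights by `1e6 / library_size`. Scaling twice (with the
#' recomputed library size) is equivalent to scaling once.
#'
#' @param track [endpoint_track()]; must be nonempty.
#' @return rescaled `EndpointTrack`.
#' @export
rpm_scale <- function(track) {
  if (track$library_size == 0) stop("cannot RPM-scale an empty track")
  track$records$weight <- track$records$weight * 1e6 / track$library_size
  track$library_size <- sum(track$records$weight)
  track
}

# Per-base endpoint coverage of one strand selection, as a data.frame
# chrom/pos/value sorted by chrom then pos.
per_base_counts <- function(track, strand = c("both", "+", "-")) {
  strand <- match.arg(strand)
  r <- track$records
  if (strand != "both") r <- r[r$strand == strand, , drop = FALSE]
  if (nrow(r) == 0)
    return(data.frame(chrom = character(), pos = integer(), value = numeric()))
  key <- paste(r$chrom, r$pos, sep = "\r")
  agg <- rowsum(r$weight, key)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[[`, "", 1),
                    pos = as.integer(vapply(parts, `[[`, "", 2)),
                    value = as.numeric(agg[, 1]),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Write endpoint coverage as bedGraph
#'
#' Per-base coverage of endpoint positions; consecutive bases with equal
#' value are merged into one interval. `normalize = "RPM"` writes
#' `count * 1e6 / library_size` (library size of the whole track, both
#' strands, before strand selection).
#'
#' @param track [endpoint_track()].
#' @param path output file.
#' @param strand `"both"`, `"+"` or `"-"` — restrict to one strand's records.
#' @param normalize `"raw"` or `"RPM"`.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, strand = c("both", "+", "-"),
                           normalize = c("raw", "RPM")) {
  strand <- match.arg(strand)
  normalize <- match.arg(normalize)
  if (normalize == "RPM" && track$library_size == 0)
    stop("RPM normalization requested on an empty track")
  cov <- per_base_counts(track, strand)
  if (normalize == "RPM") cov$value <- cov$value * 1e6 / track$library_size
  # merge runs of consecutive positions with identical value
  if (nrow(cov) > 0) {
    new_run <- c(TRUE, !(cov$chrom[-1] == cov$chrom[-nrow(cov)] &
                         cov$pos[-1] == cov$pos[-nrow(cov)] + 1L &
                         cov$value[-1] == cov$value[-nrow(cov)]))
    run <- cumsum(new_run)
    start <- cov$pos[new_run]
    end <- vapply(split(cov$pos, run), max, 0) + 1L
    out <- data.frame(chrom = cov$chrom[new_run], start = start,
                      end = as.integer(end), value = cov$value[new_run])
  } else {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), value = numeric())
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file back as per-base values
#'
#' Expands intervals to per-base rows; used for round-trip checks and for
#' consuming externally produced coverage.
#'
#' @param path bedGraph file.
#' @return data.frame with columns `chrom`, `pos` (0-based), `value`.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "value"))
  if (nrow(df) == 0)
    return(data.frame(chrom = character(), pos = integer(), value = numeric()))
  n <- df$end - df$start
  out <- data.frame(chrom = rep(df$chrom, n),
                    pos = unlist(mapply(seq, df$start, df$end - 1,
                                        SIMPLIFY = FALSE)),
                    value = rep(df$value, n))
  out[order(out$chrom, out$pos), , drop = FALSE]
}

# Subset a track's records by a logical index, keeping genome metadata.
subset_track <- function(track, keep) {
  endpoint_track(track$records[keep, , drop = FALSE], track$genome)
}
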