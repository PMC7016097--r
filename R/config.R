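#' Run configuration
#'
#' Shared defaults for window sizes, bin sizes, thresholds and the spike-in
#' locus. Values can be overridden by arguments, by a YAML config file, or
#' by CLI flags (in that order of precedence).
#'
#' @param ... named overrides of the defaults listed below.
#' @return list of class `RunConfig`.
#' @details Defaults: profile window `W = 4000` bp at 1 bp native / 10 bp
#'   resection bins, 20 bp bins over a 6 kb window for maximum resection;
#'   peak-calling window 2000 bp with fold-enrichment threshold 2.5;
#'   sliding-window t-test alpha 0.05; spike-in mixing ratio 1:50 (2%);
#'   height-matching flank `|offset|` in \[800, 3000\] bp; central window
#'   200 bp; QC thresholds FRiP > 0.01, NSC >= 1.05, RSC >= 0.8.
#' @export
run_config <- function(...) {
  cfg <- list(
    profile_window = 4000, profile_bin = 10,
    max_window = 6000, max_bin = 20,
    peak_window = 2000, min_fold = 2.5,
    alpha = 0.05, window_bins = 5,
    flank_range = c(800, 3000), central_range = 200,
    spike_divisor = 50, spike_window = 5000,
    spike_chrom = NA_character_, spike_pos = NA_integer_,
    frip_min = 0.01, nsc_min = 1.05, rsc_min = 0.8,
    seed = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = "RunConfig")
}

validate_config <- function(cfg) {
  lens <- c("profile_window", "profile_bin", "max_window", "max_bin",
            "peak_window", "spike_window")
  for (f in lens)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) stop(f, " must be positive")
  ratio <- 1 / cfg$spike_divisor
  if (ratio <= 0 || ratio > 1) stop("spike mixing ratio must be in (0, 1]")
  invisible(cfg)
}

#' Read a YAML run configuration
#'
#' Fields in the file override [run_config()] defaults; unknown fields are
#' an error so typos do not pass silently.
#'
#' @param path YAML file.
#' @return [run_config()] list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}
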