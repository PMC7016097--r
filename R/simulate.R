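#' Ground-truth parameters for the END-seq library simulator
#'
#' Describes the mechanistic DSB-processing model used to emit synthetic
#' endpoint tracks. Every DSB event at a hotspot belongs to one of four
#' categories: fully resected on both sides, SPO11-bound recombination
#' intermediate (`ri`: one end blocked by motif-bound PRDM9 and still
#' carrying SPO11, the other fully resected), unresected SPO11 cleavage
#' complex (`cc`: both ends protein-bound at the cut), or double-cut (two
#' adjacent SPO11 cuts, both outer ends protein-bound). Remaining
#' probability mass is "no break". Each break event emits exactly two
#' endpoint records, one per DNA end.
#'
#' Per-side resection endpoint distances are `R = gap + L` with
#' `gap ~ Normal(gap_mean, gap_sd)` (the read-less minimum-resection gap
#' edge; per-side split of the population gap is a model parameter) and `L`
#' a positive right-skewed long-range extension (gamma by default),
#' parameterized by mean and sd.
#'
#' @param n_hotspots number of hotspots placed on the simulated chromosome.
#' @param hotspot_spacing distance between hotspot centers (bp).
#' @param heat `"exponential"` (rate-1 exponential hotspot heats, mean
#'   normalized to 1) or `"constant"`.
#' @param events_per_hotspot expected DSB-event draws per unit-heat hotspot
#'   (Poisson).
#' @param p_resected,p_ri,p_cc,p_doublecut per-event category
#'   probabilities; must sum to at most 1, remainder is "no break".
#' @param cut_disp,cut_disp_sd SPO11 cut displacement from the hotspot
#'   center: magnitude `cut_disp` (default 30 bp, half the reversed-polarity
#'   strand shift) jittered by `cut_disp_sd`, sign random per event. Applies
#'   to single-cut events; double-cut pairs are centered on the hotspot.
#' @param gap_mean,gap_sd per-side minimum-resection gap distribution (bp).
#' @param resect_family `"gamma"` (default) or `"lognormal"` long-range
#'   extension family.
#' @param resect_mean,resect_sd mean and sd of the long-range extension (bp).
#' @param dc_spacing length-2 numeric, uniform low/high inter-cut spacing
#'   of double-cut events (bp).
#' @param spike_fraction fraction of cell-equivalents that are spike-in
#'   cells carrying exactly one fixed blunt DSB (default 0.02, a 1:50 mix).
#' @param breaks_per_cell DSB events per bulk cell-equivalent; fixes the
#'   number of cell-equivalents implied by the event count and hence the
#'   spike-in count.
#' @param background_rate uniform background endpoint rate per bp per
#'   strand.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return list of class `TruthParameters`.
#' @export
truth_params <- function(n_hotspots = 100,
                         hotspot_spacing = 16000,
                         heat = c("exponential", "constant"),
                         events_per_hotspot = 50,
                         p_resected = 0.79, p_ri = 0.20, p_cc = 0.01,
                         p_doublecut = 0,
                         cut_disp = 30, cut_disp_sd = 5,
                         gap_mean = 600, gap_sd = 30,
                         resect_family = c("gamma", "lognormal"),
                         resect_mean = 529, resect_sd = 247,
                         dc_spacing = c(40, 60),
                         spike_fraction = 0.02,
                         breaks_per_cell = 200,
                         background_rate = 1e-5,
                         seed = NULL) {
  heat <- match.arg(heat)
  resect_family <- match.arg(resect_family)
  p <- c(p_resected, p_ri, p_cc, p_doublecut)
  if (any(p < 0) || any(p > 1))
    stop("category probabilities must lie in [0, 1]")
  if (sum(p) > 1 + 1e-12)
    stop("category probabilities sum to more than 1")
  if (gap_mean <= 0 || resect_mean <= 0)
    stop("distance parameters must be positive")
  if (dc_spacing[1] >= dc_spacing[2])
    stop("double-cut spacing must satisfy low < high")
  if (spike_fraction < 0 || spike_fraction > 1)
    stop("spike_fraction must be in [0, 1]")
  structure(list(
    n_hotspots = n_hotspots, hotspot_spacing = hotspot_spacing,
    heat = heat, events_per_hotspot = events_per_hotspot,
    p_resected = p_resected, p_ri = p_ri, p_cc = p_cc,
    p_doublecut = p_doublecut,
    cut_disp = cut_disp, cut_disp_sd = cut_disp_sd,
    gap_mean = gap_mean, gap_sd = gap_sd,
    resect_family = resect_family,
    resect_mean = resect_mean, resect_sd = resect_sd,
    dc_spacing = dc_spacing,
    spike_fraction = spike_fraction, breaks_per_cell = breaks_per_cell,
    background_rate = background_rate, seed = seed
  ), class = "TruthParameters")
}

#' Genotype presets for the simulator
#'
#' Documented parameter sets emulating the genotypes studied with END-seq.
#' `p_ri`/`p_cc` are per-event probabilities; because each break emits two
#' ends and an RI break contributes one central end, the RI share of total
#' signal is `p_ri / 2` and the SPO11cc share is `p_cc`. The WT preset
#' therefore uses `p_ri = 0.20`, `p_cc = 0.01`, giving a 10% RI + 1%
#' SPO11cc = 11% central signal fraction. WT resection is calibrated so the
#' per-side endpoint distance has mean 1129 nt and the expected per-hotspot
#' maximum at 50 resected ends per side is 1845 nt.
#'
#' @param name one of `"WT"`, `"Atm"`, `"Dmc1"`, `"Exo1"`, `"Prdm9"`,
#'   `"hybrid"`.
#' @param ... overrides passed on to [truth_params()] (e.g. `n_hotspots`,
#'   `seed`).
#' @return [truth_params()] object.
#' @details
#' * `WT`: 20% RI / 1% SPO11cc events, 200 breaks per cell-equivalent,
#'   gap 600 +/- 30, long-range extension gamma(mean 529, sd 247).
#' * `Atm`: no RI, elevated SPO11cc and double-cutting, 4.5-fold break
#'   rate (900 per cell-equivalent), hyper-resection and a narrower,
#'   leakier gap.
#' * `Dmc1`: no RI (no homolog engagement), gap widened by ~400 nt and
#'   inflated long-range resection.
#' * `Exo1`: WT with mean resection reduced to ~996 nt.
#' * `Prdm9` / `hybrid`: RI absent / strongly reduced, otherwise WT-like.
#' @export
preset <- function(name = c("WT", "Atm", "Dmc1", "Exo1", "Prdm9", "hybrid"),
                   ...) {
  name <- match.arg(name)
  base <- switch(name,
    WT = list(),
    Atm = list(p_resected = 0.40, p_ri = 0, p_cc = 0.30, p_doublecut = 0.30,
               breaks_per_cell = 900, gap_mean = 350, gap_sd = 120,
               resect_mean = 1300, resect_sd = 550),
    Dmc1 = list(p_resected = 0.99, p_ri = 0, p_cc = 0.01,
                gap_mean = 1000, resect_mean = 700, resect_sd = 330),
    Exo1 = list(resect_mean = 396, resect_sd = 230),
    Prdm9 = list(p_resected = 0.99, p_ri = 0, p_cc = 0.01),
    hybrid = list(p_resected = 0.94, p_ri = 0.05, p_cc = 0.01))
  do.call(truth_params, utils::modifyList(base, list(...)))
}

# Long-range extension draws for the configured family.
draw_extension <- function(n, params) {
  mu <- params$resect_mean; s <- params$resect_sd
  switch(params$resect_family,
    gamma = stats::rgamma(n, shape = (mu / s)^2, rate = mu / s^2),
    lognormal = {
      sig2 <- log(1 + (s / mu)^2)
      stats::rlnorm(n, meanlog = log(mu) - sig2 / 2, sdlog = sqrt(sig2))
    })
}

# Per-side resection endpoint distance: gap + long-range extension, >= 1 bp.
draw_resection <- function(n, params) {
  gap <- pmax(stats::rnorm(n, params$gap_mean, params$gap_sd), 1)
  round(gap + draw_extension(n, params))
}

# Simulated genome: one hotspot chromosome plus a spike-in chromosome.
sim_genome <- function(params) {
  c(chrSim = params$n_hotspots * params$hotspot_spacing,
    chrSpike = 20000)
}

sim_hotspots <- function(params, heat) {
  sp <- params$hotspot_spacing
  centers <- as.integer(sp / 2 + (seq_len(params$n_hotspots) - 1) * sp)
  hotspot_set(rep("chrSim", params$n_hotspots),
              centers - 2000L, centers + 2000L,
              center = centers, heat = heat)
}

#' Simulate an END-seq endpoint library with known ground truth
#'
#' Emits one endpoint track following the strand conventions of the
#' DSB-processing model:
#' * fully resected: top-strand endpoint at `cut + R_right`, bottom at
#'   `cut - R_left` ("correct" polarity), flag `free`;
#' * SPO11cc: top at `cut + 1`, bottom at `cut - 1`, flag `cc`;
#' * SPO11-RI: the motif-proximal end keeps SPO11 and is sequenced from the
#'   cut itself — a cut left of the hotspot center yields a top-strand
#'   central read, a cut right of center a bottom-strand central read
#'   (reversed polarity), flag `ri`; the motif-distal end is fully resected
#'   (flag `free`);
#' * double-cut (cuts `c1 < c2` straddling the center): bottom-strand at
#'   `c1`, top-strand at `c2`, flag `cc`;
#' * spike-in cells: one fixed blunt break at the spike locus, flag
#'   `spike`; uniform background on both strands, flag `bg`.
#'
#' @param params [truth_params()] or [preset()].
#' @return list with `track` ([endpoint_track()]), `truth` (one row per
#'   break event: hotspot, category, cut positions, per-side resection
#'   endpoints), `hotspots` ([hotspot_set()] of true centers), `genome`,
#'   `spike` (list `chrom`/`pos`) and `params`.
#' @export
simulate_library <- function(params) {
  stopifnot(inherits(params, "TruthParameters"))
  if (!is.null(params$seed)) set.seed(params$seed)
  genome <- sim_genome(params)
  spike <- list(chrom = "chrSpike", pos = 10000L)

  n <- params$n_hotspots
  heat <- if (params$heat == "exponential") stats::rexp(n) else rep(1, n)
  heat <- heat / mean(heat)
  hotspots <- sim_hotspots(params, heat)

  m <- stats::rpois(n, params$events_per_hotspot * heat)
  hs_id <- rep(seq_len(n), m)
  total <- sum(m)
  probs <- c(params$p_resected, params$p_ri, params$p_cc, params$p_doublecut)
  cat_lab <- c("resected", "ri", "cc", "doublecut", "none")
  category <- sample(cat_lab, total, replace = TRUE,
                     prob = c(probs, 1 - sum(probs)))
  keep <- category != "none"
  hs_id <- hs_id[keep]; category <- category[keep]
  n_ev <- length(hs_id)
  center <- hotspots$center[hs_id]

  sgn <- sample(c(-1L, 1L), n_ev, replace = TRUE)
  disp <- round(params$cut_disp + stats::rnorm(n_ev, 0, params$cut_disp_sd))
  cut <- center + sgn * disp

  r_left <- rep(NA_real_, n_ev); r_right <- rep(NA_real_, n_ev)
  cut2 <- rep(NA_integer_, n_ev)
  top_pos <- integer(n_ev); bot_pos <- integer(n_ev)
  top_flag <- character(n_ev); bot_flag <- character(n_ev)

  i <- category == "resected"
  if (any(i)) {
    r_left[i] <- draw_resection(sum(i), params)
    r_right[i] <- draw_resection(sum(i), params)
    top_pos[i] <- cut[i] + r_right[i]; top_flag[i] <- "free"
    bot_pos[i] <- cut[i] - r_left[i]; bot_flag[i] <- "free"
  }
  i <- category == "ri"
  if (any(i)) {
    r <- draw_resection(sum(i), params)
    left_cut <- sgn[i] < 0  # cut left of center: right end blocked by PRDM9
    r_left[i][left_cut] <- r[left_cut]
    r_right[i][!left_cut] <- r[!left_cut]
    # blocked, motif-proximal end reads from the cut with reversed polarity
    top_pos[i] <- ifelse(left_cut, cut[i], cut[i] + r)
    top_flag[i] <- ifelse(left_cut, "ri", "free")
    bot_pos[i] <- ifelse(left_cut, cut[i] - r, cut[i])
    bot_flag[i] <- ifelse(left_cut, "free", "ri")
  }
  i <- category == "cc"
  if (any(i)) {
    top_pos[i] <- cut[i] + 1L; bot_pos[i] <- cut[i] - 1L
    top_flag[i] <- "cc"; bot_flag[i] <- "cc"
  }
  i <- category == "doublecut"
  if (any(i)) {
    sp <- round(stats::runif(sum(i), params$dc_spacing[1],
                             params$dc_spacing[2]))
    c1 <- center[i] - sp %/% 2L
    c2 <- c1 + sp
    cut[i] <- c1; cut2[i] <- c2
    bot_pos[i] <- c1; top_pos[i] <- c2
    top_flag[i] <- "cc"; bot_flag[i] <- "cc"
  }

  chrom <- rep("chrSim", n_ev)
  rec <- data.frame(
    chrom = c(chrom, chrom),
    pos = c(top_pos, bot_pos),
    strand = rep(c("+", "-"), each = n_ev),
    flag = c(top_flag, bot_flag),
    stringsAsFactors = FALSE)

  # spike-in cells: cell-equivalents implied by total break events
  cells <- n_ev / params$breaks_per_cell
  n_spike <- stats::rpois(1, cells * params$spike_fraction)
  if (n_spike > 0) {
    rec <- rbind(rec, data.frame(
      chrom = "chrSpike",
      pos = c(rep(spike$pos + 1L, n_spike), rep(spike$pos - 1L, n_spike)),
      strand = rep(c("+", "-"), each = n_spike),
      flag = "spike", stringsAsFactors = FALSE))
  }

  n_bg <- stats::rpois(1, params$background_rate * sum(genome) * 2)
  if (n_bg > 0) {
    u <- floor(stats::runif(n_bg, 0, sum(genome)))
    on_spike <- u >= genome[["chrSim"]]
    rec <- rbind(rec, data.frame(
      chrom = ifelse(on_spike, "chrSpike", "chrSim"),
      pos = as.integer(ifelse(on_spike, u - genome[["chrSim"]], u)),
      strand = sample(c("+", "-"), n_bg, replace = TRUE),
      flag = "bg", stringsAsFactors = FALSE))
  }

  rec$pos <- pmin(pmax(rec$pos, 0L), unname(genome[rec$chrom]) - 1L)
  truth <- data.frame(event = seq_len(n_ev), hotspot = hs_id,
                      category = category, cut = cut, cut2 = cut2,
                      r_left = r_left, r_right = r_right,
                      stringsAsFactors = FALSE)
  list(track = endpoint_track(rec, genome), truth = truth,
       hotspots = hotspots, genome = genome, spike = spike, params = params)
}

#' Construct a count-level library for spike-in normalization
#'
#' A deliberately simple companion to [simulate_library()] for absolute
#' break-number questions: per-hotspot break-end read counts are drawn at
#' the molecule level (Poisson around `cells * breaks_per_cell /
#' n_hotspots` per hotspot and strand) and emitted as weighted endpoint
#' records at the hotspot flanks, while spike-in cells (a fraction
#' `spike_fraction` of `cells`) each contribute one fixed blunt break at
#' the spike locus. Event-level structure (resection shapes, species flags)
#' is not modeled — only the signal totals that spike-in normalization
#' consumes — which allows realistic cell-equivalent numbers without
#' per-event records.
#'
#' @param n_hotspots number of hotspots.
#' @param breaks_per_cell DSB events per bulk cell-equivalent.
#' @param cells number of bulk cell-equivalents.
#' @param spike_fraction spike-in mixing fraction (default 0.02).
#' @param flank distance from the hotspot center at which break-end reads
#'   concentrate (default 800 bp, inside the +/- 5 kb signal window).
#' @param seed optional integer seed.
#' @return list with `track`, `hotspots`, `spike` (list `chrom`/`pos`) and
#'   `genome`, as in [simulate_library()].
#' @export
construct_spike_library <- function(n_hotspots, breaks_per_cell, cells,
                                    spike_fraction = 0.02, flank = 800,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spacing <- 16000L
  genome <- c(chrSim = n_hotspots * spacing, chrSpike = 20000)
  spike <- list(chrom = "chrSpike", pos = 10000L)
  centers <- as.integer(spacing / 2 + (seq_len(n_hotspots) - 1) * spacing)
  hotspots <- hotspot_set(rep("chrSim", n_hotspots),
                          centers - 2000L, centers + 2000L,
                          center = centers)
  # each break contributes one top- and one bottom-strand end
  per_hs_strand <- cells * breaks_per_cell / n_hotspots
  top_n <- stats::rpois(n_hotspots, per_hs_strand)
  bot_n <- stats::rpois(n_hotspots, per_hs_strand)
  spike_top <- stats::rpois(1, cells * spike_fraction)
  spike_bot <- stats::rpois(1, cells * spike_fraction)
  rec <- data.frame(
    chrom = c(rep("chrSim", 2 * n_hotspots), "chrSpike", "chrSpike"),
    pos = c(centers + flank, centers - flank,
            spike$pos + 1L, spike$pos - 1L),
    strand = c(rep("+", n_hotspots), rep("-", n_hotspots), "+", "-"),
    weight = c(top_n, bot_n, spike_top, spike_bot),
    flag = c(rep("free", 2 * n_hotspots), "spike", "spike"),
    stringsAsFactors = FALSE)
  rec <- rec[rec$weight > 0, , drop = FALSE]
  list(track = endpoint_track(rec, genome), hotspots = hotspots,
       spike = spike, genome = genome)
}

#' Apply an enzymatic blunting/pretreatment condition to a simulated track
#'
#' Filters endpoints by their species flag, emulating which DNA-end
#' structures each enzyme cocktail can ligate an adapter to:
#' * `ExoVII_ExoT`: protein-free ends plus SPO11-RI and SPO11cc ends, each
#'   with its own detection efficiency (default 1);
#' * `ExoT_only`: protein-free ends only (no central signal);
#' * `TDP2_ExoT`: protein-free ends plus SPO11cc (TDP2 hydrolyses the
#'   phosphotyrosyl bond of the cleavage complex but does not act on
#'   SPO11-RI);
#' * `MRN_CtIP_pre`: MRN+CtIP pretreatment removes SPO11-bound central
#'   ends with probability `mrn_efficiency` (default 0.9) before the
#'   `ExoVII_ExoT` rules apply.
#'
#' Background and spike-in endpoints count as protein-free.
#'
#' @param track simulated [endpoint_track()] carrying species flags.
#' @param condition one of `"ExoVII_ExoT"`, `"ExoT_only"`, `"TDP2_ExoT"`,
#'   `"MRN_CtIP_pre"`.
#' @param efficiency named numeric detection efficiencies for `free`, `ri`,
#'   `cc` ends (defaults all 1).
#' @param mrn_efficiency removal probability of SPO11-bound ends under
#'   `MRN_CtIP_pre`.
#' @return filtered [endpoint_track()].
#' @export
apply_enzyme_condition <- function(track,
                                   condition = c("ExoVII_ExoT", "ExoT_only",
                                                 "TDP2_ExoT", "MRN_CtIP_pre"),
                                   efficiency = c(free = 1, ri = 1, cc = 1),
                                   mrn_efficiency = 0.9) {
  condition <- tryCatch(match.arg(condition),
                        error = function(e) stop("unknown enzyme condition: ",
                                                 condition[1]))
  eff <- c(free = 1, ri = 1, cc = 1)
  eff[names(efficiency)] <- efficiency
  fl <- track$records$flag
  cls <- ifelse(fl %in% c("free", "bg", "spike", "."), "free", fl)
  if (any(!cls %in% c("free", "ri", "cc")))
    stop("unknown species flag(s): ",
         paste(unique(cls[!cls %in% c("free", "ri", "cc")]), collapse = ", "))
  n <- length(cls)
  keep <- rep(TRUE, n)
  if (condition == "MRN_CtIP_pre") {
    bound <- cls %in% c("ri", "cc")
    keep[bound] <- stats::runif(sum(bound)) >= mrn_efficiency
    cls[bound & keep] <- cls[bound & keep]  # survivors stay SPO11-bound
  }
  detected <- switch(condition,
    ExoVII_ExoT = , MRN_CtIP_pre = stats::runif(n) < eff[cls],
    ExoT_only = cls == "free",
    TDP2_ExoT = (cls != "ri") & (stats::runif(n) < eff[cls]))
  subset_track(track, keep & detected)
}
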