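#' @import methods
#' @importClassesFrom S4Vectors DFrame
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## ---------------------------------------------------------------------------
## OpticsConfig
## ---------------------------------------------------------------------------

#' Optical / measurement-noise configuration
#'
#' Describes how true per-cell quantities are converted into measured
#' list-mode signals: per-channel gains (arbitrary units per unit of true
#' signal), additive backgrounds (autofluorescence plus nonspecific secondary
#' antibody), multiplicative log-normal noise parameterised by a coefficient
#' of variation, the doublet model, and the Pacific-Blue barcoding levels.
#'
#' @slot gain named numeric, entries \code{dna}, \code{mcm}, \code{rb1};
#'   all strictly positive.
#' @slot background named numeric, entries \code{dna}, \code{mcm},
#'   \code{rb1}; all non-negative.
#' @slot cv named numeric, entries \code{dna}, \code{width}, \code{mcm},
#'   \code{rb1}; coefficients of variation of the multiplicative log-normal
#'   noise, all non-negative.
#' @slot base_width numeric(1), singlet DNA pulse width in width units.
#' @slot doublet_rate numeric(1) in [0,1], fraction of output events that are
#'   synthetic aggregates.
#' @slot doublet_width_factor numeric(1) > 1, width multiplier for doublets.
#' @slot barcode_levels numeric, strictly decreasing geometric-mean barcode
#'   intensities. Defaults follow the printed 4-fold Pacific-Blue dilution
#'   series (0.125, 0.031, 0.0062, 0.00078 ng/ul), scaled to arbitrary units.
#' @slot barcode_cv numeric(1) >= 0, sdlog of the barcode log-normal.
#'
#' @seealso [opticsConfig()] for the user constructor.
#' @exportClass OpticsConfig
setClass("OpticsConfig", representation(
  gain = "numeric",
  background = "numeric",
  cv = "numeric",
  base_width = "numeric",
  doublet_rate = "numeric",
  doublet_width_factor = "numeric",
  barcode_levels = "numeric",
  barcode_cv = "numeric"
))

setValidity("OpticsConfig", function(object) {
  msg <- character()
  need <- function(x, nm) all(nm %in% names(x))
  if (!need(object@gain, c("dna", "mcm", "rb1")))
    msg <- c(msg, "gain must have entries dna, mcm, rb1")
  if (!need(object@background, c("dna", "mcm", "rb1")))
    msg <- c(msg, "background must have entries dna, mcm, rb1")
  if (!need(object@cv, c("dna", "width", "mcm", "rb1")))
    msg <- c(msg, "cv must have entries dna, width, mcm, rb1")
  if (any(object@gain <= 0)) msg <- c(msg, "all gains must be > 0")
  if (any(object@background < 0)) msg <- c(msg, "backgrounds must be >= 0")
  if (any(object@cv < 0)) msg <- c(msg, "cvs must be >= 0")
  if (object@base_width <= 0) msg <- c(msg, "base_width must be > 0")
  if (object@doublet_rate < 0 || object@doublet_rate > 1)
    msg <- c(msg, "doublet_rate must be in [0,1]")
  if (object@doublet_width_factor <= 1)
    msg <- c(msg, "doublet_width_factor must be > 1")
  if (length(object@barcode_levels) &&
      (any(diff(object@barcode_levels) >= 0) || any(object@barcode_levels <= 0)))
    msg <- c(msg, "barcode_levels must be strictly decreasing and positive")
  if (object@barcode_cv < 0) msg <- c(msg, "barcode_cv must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an OpticsConfig
#'
#' Defaults place the G1 (2N) DNA peak at 200 linear units, a fully loaded
#' MCM signal at 100 units over a background of 5, and the anchored-RB1
#' signal at 1000 units over a background of 10, with log-scale spreads
#' typical of immunofluorescence flow data. Barcode levels follow the 4-fold
#' Pacific-Blue dilution series.
#'
#' @param gain named numeric; arbitrary units per unit of true signal for
#'   channels \code{dna}, \code{mcm}, \code{rb1}.
#' @param background named numeric; additive background for the same channels.
#' @param cv named numeric; log-normal coefficients of variation for
#'   \code{dna}, \code{width}, \code{mcm}, \code{rb1}.
#' @param base_width singlet DNA pulse width (independent of DNA content).
#' @param doublet_rate fraction of events that are doublets after
#'   [injectDoublets()].
#' @param doublet_width_factor width multiplier applied to doublets.
#' @param barcode_levels strictly decreasing geometric means of the barcode
#'   staining levels.
#' @param barcode_cv sdlog of the barcode intensity log-normal.
#' @return An [OpticsConfig-class] object.
#' @examples
#' opt <- opticsConfig(doublet_rate = 0)
#' opt
#' @export
opticsConfig <- function(gain = c(dna = 100, mcm = 100, rb1 = 1000),
                         background = c(dna = 0, mcm = 5, rb1 = 10),
                         cv = c(dna = 0.03, width = 0.05, mcm = 0.25, rb1 = 0.25),
                         base_width = 100,
                         doublet_rate = 0.05,
                         doublet_width_factor = 1.6,
                         barcode_levels = c(1000, 250, 62.5, 15.625),
                         barcode_cv = 0.15) {
  new("OpticsConfig", gain = gain, background = background, cv = cv,
      base_width = base_width, doublet_rate = doublet_rate,
      doublet_width_factor = doublet_width_factor,
      barcode_levels = barcode_levels, barcode_cv = barcode_cv)
}

## ---------------------------------------------------------------------------
## ScenarioConfig
## ---------------------------------------------------------------------------

#' Experimental-scenario configuration for the synthetic generator
#'
#' Holds the cell-kinetic ground truth for one of the four emulated
#' experiments: asynchronous exponential growth, release from G0 (contact
#' inhibition), the same release with an irradiation-induced arrest before the
#' restriction point, and release from a nocodazole mitotic block. Times are
#' hours from the scenario origin (release / mitotic exit; cell birth for the
#' exponential kind).
#'
#' @slot kind one of \code{"exponential"}, \code{"g0_release"},
#'   \code{"nocodazole_release"}, \code{"irradiated_g0_release"}.
#' @slot T_G1,T_S,T_G2M phase durations in hours, all > 0.
#' @slot t_rp_mean,t_rp_sd restriction-point passage time (RB1
#'   hyper-phosphorylation), truncated-Gaussian per-cell jitter.
#' @slot t_load_mean,t_load_sd MCM loading onset time.
#' @slot load_duration hours over which the loaded fraction ramps 0 to 1.
#' @slot frac_pre_rp_loaders fraction of cells whose loading onset precedes
#'   their restriction-point time. Pre-RP loaders carry a full MCM load from
#'   mitotic exit (licensing observed already in G2/M in cycling cells).
#' @slot t_hypo,t_hypo_sd time of initial RB1 hypo-phosphorylation
#'   (anchoring) after G0 exit or mitosis.
#' @slot t_exit_mean,t_exit_sd time of G0 exit (g0 kinds) or mitotic exit
#'   (nocodazole).
#' @slot s_offload_complete S-phase fraction by which MCM offloading is
#'   complete (chromatin-bound signal reaches zero at the S/G2 border).
#' @slot frac_noexit fraction of cells that never exit G0 (release
#'   efficiency below 1; g0 kinds only).
#' @slot load_delay extra hours added to the loading onset when
#'   \code{rp_blocked} (irradiation delays licensing).
#' @slot g2m_loading logical; if TRUE, pre-RP loaders also display loaded
#'   MCM (with anchored RB1) during G2/M.
#' @slot waves list of nocodazole two-wave parameters (see
#'   [scenarioConfig()]).
#' @slot timepoints strictly increasing sampling times in hours.
#' @slot n_cells number of cells per timepoint.
#' @slot seed integer seed; all randomness derives from it.
#' @slot rp_blocked logical; no cell ever passes the restriction point.
#'
#' @seealso [scenarioConfig()] for per-kind defaults.
#' @exportClass ScenarioConfig
setClass("ScenarioConfig", representation(
  kind = "character",
  T_G1 = "numeric", T_S = "numeric", T_G2M = "numeric",
  t_rp_mean = "numeric", t_rp_sd = "numeric",
  t_load_mean = "numeric", t_load_sd = "numeric",
  load_duration = "numeric",
  frac_pre_rp_loaders = "numeric",
  t_hypo = "numeric", t_hypo_sd = "numeric",
  t_exit_mean = "numeric", t_exit_sd = "numeric",
  s_offload_complete = "numeric",
  frac_noexit = "numeric",
  load_delay = "numeric",
  g2m_loading = "logical",
  waves = "list",
  timepoints = "numeric",
  n_cells = "integer",
  seed = "integer",
  rp_blocked = "logical"
))

.scenario_kinds <- c("exponential", "g0_release", "nocodazole_release",
                     "irradiated_g0_release")

setValidity("ScenarioConfig", function(object) {
  msg <- character()
  if (!object@kind %in% .scenario_kinds)
    msg <- c(msg, paste0("unknown kind '", object@kind, "'"))
  dur <- c(object@T_G1, object@T_S, object@T_G2M, object@load_duration)
  if (any(!is.finite(dur)) || any(dur <= 0))
    msg <- c(msg, "all durations must be strictly positive")
  if (object@frac_pre_rp_loaders < 0 || object@frac_pre_rp_loaders > 1)
    msg <- c(msg, "frac_pre_rp_loaders must be in [0,1]")
  if (object@frac_noexit < 0 || object@frac_noexit > 1)
    msg <- c(msg, "frac_noexit must be in [0,1]")
  if (length(object@timepoints) && any(diff(object@timepoints) <= 0))
    msg <- c(msg, "timepoints must be strictly increasing")
  if (any(object@timepoints < 0))
    msg <- c(msg, "timepoints must be >= 0")
  if (object@n_cells < 0L) msg <- c(msg, "n_cells must be >= 0")
  if (object@kind == "irradiated_g0_release" && !object@rp_blocked)
    msg <- c(msg, "irradiated_g0_release requires rp_blocked = TRUE")
  if (object@s_offload_complete <= 0 || object@s_offload_complete > 1)
    msg <- c(msg, "s_offload_complete must be in (0,1]")
  if (length(msg)) msg else TRUE
})

#' Construct a ScenarioConfig with per-kind defaults
#'
#' Defaults encode the study conditions of the four experiments:
#' \describe{
#'   \item{exponential}{Asynchronous growth with T_G1/T_S/T_G2M = 10/8/4 h;
#'     ages drawn from the exponential-growth age density. Restriction point
#'     at 5 h and loading onset at 6.5 h after birth; 15\% of cells load
#'     before the restriction point.}
#'   \item{g0_release}{BJ-like release from contact inhibition: anchoring
#'     from ~3 h, restriction-point passage from ~9 h, MCM loading from
#'     ~11 h ramping over 4 h, hence S entry from ~15 h; 5\% of cells never
#'     exit G0.}
#'   \item{irradiated_g0_release}{As g0_release but no cell ever passes the
#'     restriction point and loading is delayed by \code{load_delay} (10 h);
#'     cells never enter S.}
#'   \item{nocodazole_release}{U2OS-like release from a mitotic block with
#'     two waves: a fast wave (50\%) hyper-phosphorylating RB1 immediately
#'     and loading MCM at 1.5-4 h (entering Q1), entering S by ~10.5 h, and
#'     a slow wave anchoring RB1 at ~1 h and loading at 6-8 h (entering
#'     Q2), passing the restriction point only at ~13 h.}
#' }
#'
#' @param kind scenario kind, see [ScenarioConfig-class].
#' @param timepoints,n_cells,seed sampling design; defaults per kind.
#' @param ... override any slot listed in [ScenarioConfig-class]
#'   (for example \code{frac_pre_rp_loaders}, \code{t_rp_mean}, \code{waves}).
#' @return A validated [ScenarioConfig-class] object.
#' @examples
#' sc <- scenarioConfig("g0_release", n_cells = 1000L, seed = 1L)
#' sc
#' @export
scenarioConfig <- function(kind = c("exponential", "g0_release",
                                    "nocodazole_release",
                                    "irradiated_g0_release"),
                           timepoints = NULL, n_cells = 20000L,
                           seed = 1L, ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    exponential = list(
      T_G1 = 10, T_S = 8, T_G2M = 4,
      t_rp_mean = 5, t_rp_sd = 0.5,
      t_load_mean = 6.5, t_load_sd = 0.5,
      load_duration = 1,
      frac_pre_rp_loaders = 0.15,
      t_hypo = 0.5, t_hypo_sd = 0.3,
      t_exit_mean = 0, t_exit_sd = 0,
      frac_noexit = 0, load_delay = 0,
      rp_blocked = FALSE,
      timepoints = 0
    ),
    g0_release = list(
      T_G1 = 14, T_S = 8, T_G2M = 4,
      t_rp_mean = 9, t_rp_sd = 0.5,
      t_load_mean = 11, t_load_sd = 0.5,
      load_duration = 4,
      frac_pre_rp_loaders = 0,
      t_hypo = 3, t_hypo_sd = 0.3,
      t_exit_mean = 1, t_exit_sd = 0.3,
      frac_noexit = 0.05, load_delay = 0,
      rp_blocked = FALSE,
      timepoints = c(0, 3, 6, 9, 11, 13, 15, 20)
    ),
    irradiated_g0_release = list(
      T_G1 = 14, T_S = 8, T_G2M = 4,
      t_rp_mean = 9, t_rp_sd = 0.5,
      t_load_mean = 11, t_load_sd = 0.5,
      load_duration = 4,
      frac_pre_rp_loaders = 0,
      t_hypo = 3, t_hypo_sd = 0.3,
      t_exit_mean = 1, t_exit_sd = 0.3,
      frac_noexit = 0.05, load_delay = 10,
      rp_blocked = TRUE,
      timepoints = c(0, 3, 6, 10, 13, 16, 20, 24)
    ),
    nocodazole_release = list(
      T_G1 = 12, T_S = 8, T_G2M = 4,
      t_rp_mean = 13, t_rp_sd = 1,
      t_load_mean = 7, t_load_sd = 0.6,
      load_duration = 1,
      frac_pre_rp_loaders = 0.5,
      t_hypo = 1, t_hypo_sd = 0.3,
      t_exit_mean = 0.25, t_exit_sd = 0.1,
      frac_noexit = 0, load_delay = 0,
      rp_blocked = FALSE,
      timepoints = c(0.5, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12)
    ))
  defaults$waves <- if (kind == "nocodazole_release") list(
    frac_fast = 0.5,
    fast = list(t_rp = 1, t_rp_sd = 0.3, t_load = 2.75, t_load_sd = 0.7,
                t_s = 10.5, t_s_sd = 1),
    slow = list(t_hypo = 1, t_hypo_sd = 0.3, t_load = 7, t_load_sd = 0.6,
                t_rp = 13, t_rp_sd = 1, t_s = 16, t_s_sd = 1)
  ) else list()
  defaults$s_offload_complete <- 0.8
  defaults$g2m_loading <- FALSE
  over <- list(...)
  bad <- setdiff(names(over), slotNames("ScenarioConfig"))
  if (length(bad))
    stop("unknown ScenarioConfig fields: ", paste(bad, collapse = ", "))
  defaults[names(over)] <- over
  if (!is.null(timepoints)) defaults$timepoints <- timepoints
  if (identical(kind, "nocodazole_release"))
    defaults$frac_pre_rp_loaders <- 1 - defaults$waves$frac_fast
  do.call(new, c(list("ScenarioConfig", kind = kind,
                      n_cells = as.integer(n_cells), seed = as.integer(seed)),
                 defaults))
}

## ---------------------------------------------------------------------------
## EventTable
## ---------------------------------------------------------------------------

.required_channels <- c("dna_area", "dna_width", "mcm_signal", "rb1_signal")
.truth_columns <- c("phase", "s_fraction", "rb1_state", "rp_passed",
                    "mcm_loaded_fraction", "dna_content", "sample_id",
                    "is_doublet", "cell_id")

#' Measured list-mode events
#'
#' A [S4Vectors::DFrame]-derived table with one row per event. Measured
#' columns are \code{dna_area} (DNA pulse area, FL2A, linear scale),
#' \code{dna_width} (pulse width, FL2W), \code{mcm_signal},
#' \code{rb1_signal}, and optionally \code{barcode_signal}. Simulated tables
#' additionally carry ground-truth columns (\code{phase}, \code{s_fraction},
#' \code{rb1_state}, \code{rp_passed}, \code{mcm_loaded_fraction},
#' \code{dna_content}, \code{sample_id}, \code{is_doublet}, \code{cell_id})
#' which no gating operation may consume. \code{metadata()} holds the channel
#' map, sample label and timepoint.
#'
#' @seealso [EventTable()], [dropTruth()], [readEvents()]
#' @exportClass EventTable
setClass("EventTable", contains = "DFrame")

# Constrains only the signal columns that are present; required-column
# presence is checked by the constructor and the gating entry points (S4Vectors
# internally builds single-column intermediates of derived DataFrame classes,
# which must stay valid).
setValidity("EventTable", function(object) {
  msg <- character()
  for (cn in intersect(c(.required_channels, "barcode_signal"), colnames(object))) {
    v <- object[[cn]]
    if (!is.numeric(v)) msg <- c(msg, paste(cn, "must be numeric"))
    else if (length(v) && (any(!is.finite(v)) || any(v < 0)))
      msg <- c(msg, paste(cn, "must be finite and >= 0"))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EventTable
#'
#' @param ... columns (as in [S4Vectors::DataFrame()]) or a single
#'   data.frame/DFrame.
#' @param label sample label stored in \code{metadata()}.
#' @param timepoint timepoint in hours stored in \code{metadata()}.
#' @param channels named character vector mapping logical roles to channel
#'   short names (see [channelMap()]).
#' @return An [EventTable-class].
#' @examples
#' ev <- EventTable(dna_area = c(200, 400), dna_width = c(100, 100),
#'                  mcm_signal = c(0, 5), rb1_signal = c(50, 0))
#' ev
#' @export
EventTable <- function(..., label = NA_character_, timepoint = NA_real_,
                       channels = channelMap()) {
  args <- list(...)
  df <- if (length(args) == 1L && (is.data.frame(args[[1]]) || is(args[[1]], "DataFrame")))
    DataFrame(args[[1]]) else DataFrame(...)
  miss <- setdiff(.required_channels, colnames(df))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  out <- new("EventTable", df)
  metadata(out) <- list(channels = channels, label = label,
                        timepoint = timepoint)
  out
}

#' Default logical-role to channel-name map
#'
#' @param dna_a,dna_w,mcm,rb1,barcode channel short names ($PnN) used in
#'   FCS/CSV files for each logical role.
#' @return Named character vector.
#' @export
channelMap <- function(dna_a = "FL2-A", dna_w = "FL2-W", mcm = "MCM-FITC",
                       rb1 = "RB1-A647", barcode = "PB-450") {
  c(dna_a = dna_a, dna_w = dna_w, mcm = mcm, rb1 = rb1, barcode = barcode)
}

## ---------------------------------------------------------------------------
## GateSet
## ---------------------------------------------------------------------------

#' Derived gates and thresholds
#'
#' Holds the full gating scheme: the singlet width rule, the G1/G2 DNA peak
#' positions, the left-side G1 gate, the S interval and S/G2-border window,
#' and the MCM/RB1 positivity thresholds. The G1 gate is closed at the peak
#' (\code{[lo, g1_peak]}); \code{s_interval} and \code{sg2_border} are
#' half-open, lower-inclusive.
#'
#' @slot singlet_rule numeric(2): width center (median) and upper cut.
#' @slot g1_peak,g2_peak DNA-area peak positions.
#' @slot g1_gate numeric(2): the G1 gate \code{[lo, hi]}, hi = g1_peak.
#' @slot s_interval numeric(2): half-open S-phase band in dna_area units.
#' @slot sg2_border numeric(2): half-open window just below the G2 peak
#'   where MCM offloading is presumed complete.
#' @slot mcm_threshold,rb1_threshold positivity thresholds (strictly greater
#'   than the threshold means positive); NA until derived.
#' @slot threshold_mode \code{"population"} or \code{"control"}.
#' @slot flags named list of diagnostic flags (for example
#'   \code{g2_inferred}, \code{g1_ambiguous}, \code{rb1_fallback}).
#' @exportClass GateSet
setClass("GateSet", representation(
  singlet_rule = "numeric",
  g1_peak = "numeric", g2_peak = "numeric",
  g1_gate = "numeric",
  s_interval = "numeric",
  sg2_border = "numeric",
  mcm_threshold = "numeric",
  rb1_threshold = "numeric",
  threshold_mode = "character",
  flags = "list"
), prototype(
  singlet_rule = c(NA_real_, NA_real_),
  g1_peak = NA_real_, g2_peak = NA_real_,
  g1_gate = c(NA_real_, NA_real_),
  s_interval = c(NA_real_, NA_real_),
  sg2_border = c(NA_real_, NA_real_),
  mcm_threshold = NA_real_, rb1_threshold = NA_real_,
  threshold_mode = "population", flags = list()
))

setValidity("GateSet", function(object) {
  msg <- character()
  gp <- object@g1_peak; g2 <- object@g2_peak
  if (!is.na(gp) && !is.na(g2)) {
    r <- g2 / gp
    if (r < 1.85 || r > 2.15)
      msg <- c(msg, "g2_peak/g1_peak must be in [1.85, 2.15]")
  }
  gg <- object@g1_gate
  if (!any(is.na(gg))) {
    if (gg[2] > gp + 1e-9) msg <- c(msg, "g1_gate.hi must be <= g1_peak")
    if (gg[1] >= gg[2]) msg <- c(msg, "g1_gate must be a nonempty interval")
  }
  sb <- object@sg2_border
  if (!any(is.na(sb)) && !is.na(g2)) {
    if (!(gp < sb[1] && sb[1] < sb[2] && sb[2] <= g2 * 1.02))
      msg <- c(msg, "sg2_border must satisfy g1_peak < lo < hi <= 1.02*g2_peak")
  }
  for (thr in c(object@mcm_threshold, object@rb1_threshold))
    if (!is.na(thr) && thr < 0) msg <- c(msg, "thresholds must be >= 0")
  if (!object@threshold_mode %in% c("population", "control"))
    msg <- c(msg, "threshold_mode must be 'population' or 'control'")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## QuadrantResult
## ---------------------------------------------------------------------------

#' Quadrant classification of G1 events
#'
#' Counts and fractions of G1-gated events in the four MCM/RB1 quadrants:
#' Q1 = MCM+/RB1- (loaded, past the restriction point), Q2 = MCM+/RB1+
#' (loaded with anchored RB1, before the restriction point), Q3 = MCM-/RB1+
#' (anchored, not yet loaded), Q4 = MCM-/RB1- (ambiguous: either past the
#' restriction point and not yet loaded, or very early G1 with RB1 not yet
#' hypo-phosphorylated).
#'
#' @slot counts integer(4) named q1..q4.
#' @slot n_total total number of G1-gated events.
#' @slot fractions numeric(4), counts / n_total.
#' @slot ci 4x2 matrix of 95\% Wilson score intervals.
#' @slot gates the [GateSet-class] used (provenance).
#' @slot label sample/timepoint tag.
#' @exportClass QuadrantResult
setClass("QuadrantResult", representation(
  counts = "integer", n_total = "integer", fractions = "numeric",
  ci = "matrix", gates = "GateSet", label = "character"
))

setValidity("QuadrantResult", function(object) {
  msg <- character()
  if (length(object@counts) != 4L) msg <- c(msg, "counts must have length 4")
  if (sum(object@counts) != object@n_total)
    msg <- c(msg, "quadrant counts must sum to n_total")
  if (object@n_total > 0L) {
    if (abs(sum(object@fractions) - 1) > 1e-9)
      msg <- c(msg, "fractions must sum to 1")
    ok <- object@ci[, 1] <= object@fractions + 1e-12 &
      object@ci[, 2] >= object@fractions - 1e-12 &
      object@ci[, 1] >= -1e-12 & object@ci[, 2] <= 1 + 1e-12
    if (!all(ok)) msg <- c(msg, "each CI must lie in [0,1] and contain its fraction")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## DemuxResult
## ---------------------------------------------------------------------------

#' Barcode demultiplexing result
#'
#' @slot assignment integer per event: sample index in 1..k (sorted so that
#'   component 1 is the dimmest level) or NA for unassigned.
#' @slot level_means estimated geometric means on the linear scale, strictly
#'   increasing.
#' @slot confidence per-event maximum posterior probability.
#' @slot unassigned_fraction fraction with confidence below the cutoff.
#' @slot k number of components.
#' @slot merged logical; TRUE when fitted components were not distinguishable.
#' @exportClass DemuxResult
setClass("DemuxResult", representation(
  assignment = "integer", level_means = "numeric", confidence = "numeric",
  unassigned_fraction = "numeric", k = "integer", merged = "logical"
))

setValidity("DemuxResult", function(object) {
  msg <- character()
  if (length(object@level_means) > 1 && any(diff(object@level_means) <= 0))
    msg <- c(msg, "level_means must be strictly increasing")
  n <- length(object@assignment)
  if (length(object@confidence) != n)
    msg <- c(msg, "assignment and confidence lengths differ")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## TimecourseResult / OrderSummary
## ---------------------------------------------------------------------------

#' Time-course summary with onset estimates
#'
#' @slot table a [S4Vectors::DFrame] with one row per timepoint: the four
#'   quadrant fractions with Wilson CIs, \code{mcm_positive_frac}
#'   (= frac_q1 + frac_q2), \code{rb1_released_frac} (fraction of G1 events
#'   RB1-negative, = frac_q1 + frac_q4), \code{s_phase_frac} and counts.
#' @slot onsets named list with entries \code{rp_onset}, \code{mcm_onset},
#'   \code{s_onset}; each a list with \code{onset}, \code{ci},
#'   \code{detected} and fit diagnostics as returned by [estimateOnset()].
#' @exportClass TimecourseResult
setClass("TimecourseResult", representation(
  table = "DFrame", onsets = "list"
))

#' Loading-order summary for one quadrant result
#'
#' Reports the fraction of G1 cells loading MCM before the restriction point.
#' The point estimate \code{pre_rp_loading_frac} is Q2/(Q2+Q3): among cells
#' demonstrably before the restriction point (anchored RB1), the fraction
#' already loaded. Q4 is intrinsically ambiguous and never attributed.
#'
#' @slot q1_frac,q2_frac fractions of G1 events with 95\% Wilson CIs
#'   (numeric(3): estimate, lo, hi).
#' @slot q4_frac fraction in Q4, reported but flagged ambiguous.
#' @slot pre_rp_loading_frac numeric(3): Q2/(Q2+Q3) with Wilson CI.
#' @slot misclass_floor the assumed misclassification floor.
#' @slot verdict one of \code{"loading_after_rp_dominant"}, \code{"mixed"},
#'   \code{"loading_before_rp_detected"}.
#' @exportClass OrderSummary
setClass("OrderSummary", representation(
  q1_frac = "numeric", q2_frac = "numeric", q4_frac = "numeric",
  pre_rp_loading_frac = "numeric", misclass_floor = "numeric",
  verdict = "character"
))

setValidity("OrderSummary", function(object) {
  if (!object@verdict %in% c("loading_after_rp_dominant", "mixed",
                             "loading_before_rp_detected"))
    "invalid verdict" else TRUE
})
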