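#' @include AllClasses.R utils.R
NULL

#' Gate single cells on DNA pulse width
#'
#' Discriminates single cells from aggregates using the DNA pulse width
#' (FL2W): singlet widths are independent of DNA content while doublets are
#' systematically wider. Events are retained when
#' \code{dna_width <= median + k_mad * MAD}. If the width distribution is
#' degenerate (MAD = 0), a fixed relative cut of 1.3 times the median is used
#' and a warning is signalled.
#'
#' @param events an [EventTable-class] with >= 50 events.
#' @param k_mad positive multiplier of the MAD (default 4: retains >= 99\%
#'   of log-normal singlet widths at CV <= 8\% while excluding 1.6x-wide
#'   doublets).
#' @return A list with \code{events} (the retained subset),
#'   \code{singlet_rule} (numeric(2): width center, width cut) and
#'   \code{excluded_fraction}.
#' @examples
#' sc <- scenarioConfig("exponential", n_cells = 2000L, seed = 1L)
#' ev <- applyMeasurementModel(simulateCells(sc), opticsConfig(), seed = 1L)
#' ev <- injectDoublets(ev, opticsConfig(), seed = 2L)
#' g <- gateSinglets(ev)
#' g$singlet_rule
#' @export
gateSinglets <- function(events, k_mad = 4) {
  stopifnot(k_mad > 0)
  if (nrow(events) < 50L)
    stop("gateSinglets requires at least 50 events")
  w <- dnaWidth(events)
  ctr <- stats::median(w)
  spread <- stats::mad(w)
  if (spread == 0) {
    warning("degenerate width distribution (MAD = 0); ",
            "falling back to a fixed relative cut of 1.3 * median")
    cut <- ctr * 1.3
  } else {
    cut <- ctr + k_mad * spread
  }
  keep <- w <= cut
  out <- events[keep, , drop = FALSE]
  metadata(out) <- metadata(events)
  list(events = out, singlet_rule = c(width_center = ctr, width_cut = cut),
       excluded_fraction = 1 - mean(keep))
}

# Locate local maxima of a kernel density estimate; returns positions and
# heights of modes with height >= min_height_frac of the tallest.
.densityModes <- function(x, min_height_frac = 0.05, bw = "nrd0", n = 2048) {
  if (length(unique(x)) < 5L) {
    tab <- sort(table(x), decreasing = TRUE)
    pos <- as.numeric(names(tab))
    return(list(pos = pos, height = as.numeric(tab) / max(tab)))
  }
  d <- stats::density(x, bw = bw, n = n)
  y <- d$y
  im <- which(diff(sign(diff(y))) == -2) + 1L
  if (!length(im)) im <- which.max(y)
  keep <- y[im] >= min_height_frac * max(y[im])
  im <- im[keep]
  ord <- order(d$y[im], decreasing = TRUE)
  list(pos = d$x[im][ord], height = y[im][ord] / max(y[im]))
}

#' Locate the G1 and G2 peaks of the DNA-content histogram
#'
#' Smooths the \code{dna_area} distribution and identifies the dominant
#' mode. If a secondary mode sits near half the dominant position, the
#' dominant mode is the G2 peak of a G2/M-rich sample and the half-position
#' mode is G1. Otherwise the dominant mode is taken as G1 and the G2 peak is
#' sought within [1.85, 2.15] times its position; when no G2 mode exists
#' (pure G0/G1 sample) it is inferred as exactly twice the G1 peak and
#' flagged. A sample with a single mode and no half- or double-position
#' companion is additionally flagged \code{g1_ambiguous} (it could equally
#' be a pure G2/M population).
#'
#' @param events a singlet-gated [EventTable-class] with >= 200 events.
#' @return A list with \code{g1_peak}, \code{g2_peak}, and logical flags
#'   \code{g2_inferred} and \code{g1_ambiguous}.
#' @export
findDnaPeaks <- function(events) {
  if (nrow(events) < 200L)
    stop("findDnaPeaks requires at least 200 events")
  x <- dnaArea(events)
  x <- x[is.finite(x) & x > 0]
  if (!length(x)) stop("no usable dna_area values in channel dna_area")
  m <- .densityModes(x)
  dom <- m$pos[1]
  g2_inferred <- FALSE
  g1_ambiguous <- FALSE
  half <- m$pos[m$pos >= 0.46 * dom & m$pos <= 0.54 * dom]
  if (length(half)) {
    g1 <- half[1]
    g2 <- dom
  } else {
    dbl <- m$pos[m$pos >= 1.85 * dom & m$pos <= 2.15 * dom]
    g1 <- dom
    if (length(dbl)) {
      g2 <- dbl[1]
    } else {
      g2 <- 2 * dom
      g2_inferred <- TRUE
      if (length(m$pos) == 1L || all(abs(m$pos / dom - 1) < 0.3))
        g1_ambiguous <- TRUE
    }
  }
  if (!is.finite(g1)) stop("no identifiable G1 mode in channel dna_area")
  # degenerate (noise-free) samples place a point mass at the true peak; snap
  # the kernel-density position to the atom when one dominates its window
  snap <- function(peak) {
    w <- x[abs(x - peak) <= 0.03 * peak]
    if (!length(w)) return(peak)
    tb <- table(w)
    if (max(tb) >= 0.5 * length(w)) as.numeric(names(tb)[which.max(tb)])
    else peak
  }
  g1 <- snap(g1)
  if (!g2_inferred) g2 <- snap(g2) else g2 <- 2 * g1
  list(g1_peak = g1, g2_peak = g2, g2_inferred = g2_inferred,
       g1_ambiguous = g1_ambiguous)
}

#' Assemble the DNA gates from peak positions
#'
#' The G1 gate covers only the left side of the G1 peak
#' (\code{[g1_peak * (1 - w_lo), g1_peak]}, closed at the peak) to minimize
#' contamination by early-S cells. The S/G2-border window, where MCM
#' offloading is presumed complete, is \code{[0.90, 0.98) * g2_peak}; the
#' S interval is \code{[g1_peak * (1 + w_hi), 0.90 * g2_peak)}.
#'
#' @param events an [EventTable-class] (used only for the singlet rule if
#'   \code{singlet_rule} is NULL).
#' @param peaks result of [findDnaPeaks()] (or a list with \code{g1_peak},
#'   \code{g2_peak}).
#' @param w_lo relative width of the G1 gate below the peak (default 0.10).
#' @param w_hi relative offset above the G1 peak where the S interval starts.
#' @param border numeric(2), the S/G2-border window as fractions of the G2
#'   peak.
#' @param singlet_rule optional numeric(2) from [gateSinglets()].
#' @return A [GateSet-class] without thresholds (derive them with
#'   [deriveMcmThreshold()] / [deriveRb1Threshold()]).
#' @export
defineGates <- function(events, peaks, w_lo = 0.10, w_hi = 0.10,
                        border = c(0.90, 0.98), singlet_rule = NULL) {
  g1 <- peaks$g1_peak; g2 <- peaks$g2_peak
  if (!is.finite(g1) || !is.finite(g2)) stop("invalid peaks")
  g1_gate <- c(g1 * (1 - w_lo), g1)
  sg2 <- border * g2
  s_int <- c(g1 * (1 + w_hi), border[1] * g2)
  if (g1_gate[1] >= g1_gate[2] || s_int[1] >= s_int[2] || sg2[1] >= sg2[2])
    stop("empty or inverted gate interval; check peaks and options")
  new("GateSet",
      singlet_rule = if (is.null(singlet_rule)) c(NA_real_, NA_real_)
                     else unname(singlet_rule),
      g1_peak = g1, g2_peak = g2, g1_gate = g1_gate,
      s_interval = s_int, sg2_border = sg2,
      flags = list(g2_inferred = isTRUE(peaks$g2_inferred),
                   g1_ambiguous = isTRUE(peaks$g1_ambiguous)))
}

# G1 gate membership: closed interval [lo, g1_peak].
.inG1 <- function(events, gates) {
  a <- dnaArea(events)
  a >= gates@g1_gate[1] & a <= gates@g1_gate[2]
}

#' Derive the MCM positivity threshold from S/G2-border events
#'
#' MCM-positive cells are defined as those whose MCM signal exceeds that of
#' cells at the S/G2 border, where offloading is presumed complete. The
#' threshold is the \code{q}-quantile of \code{mcm_signal} among events whose
#' DNA area falls in the border window.
#'
#' @param events singlet-gated [EventTable-class].
#' @param gates a [GateSet-class] with a valid \code{sg2_border}.
#' @param q quantile in (0,1); default 0.99 ("exceeding" read as above
#'   essentially all border cells).
#' @return The threshold (numeric(1)).
#' @export
deriveMcmThreshold <- function(events, gates, q = 0.99) {
  stopifnot(q > 0, q < 1)
  border <- inInterval(dnaArea(events), gates@sg2_border)
  if (sum(border) < 30L)
    stop("only ", sum(border), " events in the S/G2-border window; ",
         "too few to derive a population MCM threshold - consider ",
         "deriveThresholdFromControl() with a secondary-antibody control")
  unname(stats::quantile(mcmSignal(events)[border], q))
}

# Mode of log10 signal; eps guards exact zeros on noise-free data.
.logMode <- function(x, from = NULL) {
  pos <- x[x > 0]
  eps <- if (length(pos)) max(min(pos), 1e-12) / 10 else 1e-12
  lx <- log10(pmax(x, eps))
  m <- .densityModes(lx, min_height_frac = 0.1)
  m$pos
}

#' Derive the RB1 positivity threshold from the S-phase negative reference
#'
#' Hyper-phosphorylated RB1 is washed out by the pre-fixation extraction, so
#' S-phase cells provide the negative reference. The threshold is the
#' geometric midpoint between the mode of the S-phase RB1 signal and the
#' upper (anchored) mode among G1 events. When the G1 distribution has no
#' separate anchored mode above the negative reference, the threshold falls
#' back to the \code{q_rb} quantile of the S-phase distribution and the
#' result carries attribute \code{fallback = TRUE}.
#'
#' @param events singlet-gated [EventTable-class].
#' @param gates a [GateSet-class] with valid \code{s_interval} and
#'   \code{g1_gate}.
#' @param q_rb fallback quantile of the S-phase (negative) distribution.
#' @return The threshold, with attribute \code{fallback}.
#' @export
deriveRb1Threshold <- function(events, gates, q_rb = 0.995) {
  in_s <- inInterval(dnaArea(events), gates@s_interval)
  in_g1 <- .inG1(events, gates)
  if (sum(in_s) < 30L)
    stop("only ", sum(in_s), " events in the S interval; too few for the ",
         "S-phase negative reference - consider ",
         "deriveThresholdFromControl() with a secondary-antibody control")
  if (sum(in_g1) < 30L)
    stop("fewer than 30 events inside the G1 gate")
  rb_s <- rb1Signal(events)[in_s]
  rb_g1 <- rb1Signal(events)[in_g1]
  neg_mode <- .logMode(rb_s)[1]
  g1_modes <- .logMode(rb_g1)
  upper <- max(g1_modes)
  if (upper <= neg_mode + 0.5) {
    # no anchored population distinguishable from the negative reference
    thr <- unname(stats::quantile(rb_s, q_rb))
    attr(thr, "fallback") <- TRUE
    return(thr)
  }
  thr <- 10^((neg_mode + upper) / 2)
  attr(thr, "fallback") <- FALSE
  thr
}

#' Derive a positivity threshold from a secondary-antibody control
#'
#' The control sample is stained with secondary antibodies only, so its
#' signal distribution is pure background; the threshold is its
#' \code{q}-quantile. Used as a cross-check of, or fallback for, the
#' population-based MCM and RB1 thresholds (the two placements agree on
#' matched samples).
#'
#' @param control_events [EventTable-class] of the control sample
#'   (>= 100 events).
#' @param q quantile in (0,1).
#' @param channel \code{"mcm"} or \code{"rb1"}.
#' @return The threshold (numeric(1)).
#' @export
deriveThresholdFromControl <- function(control_events, q = 0.995,
                                       channel = c("mcm", "rb1")) {
  channel <- match.arg(channel)
  if (nrow(control_events) < 100L)
    stop("control sample must contain at least 100 events")
  x <- if (channel == "mcm") mcmSignal(control_events)
       else rb1Signal(control_events)
  unname(stats::quantile(x, q))
}

#' Classify G1 events into the four MCM/RB1 quadrants
#'
#' Operates only on events inside the G1 gate. Positivity is strict
#' (\code{signal > threshold}; ties at the threshold are negative). Q1 =
#' MCM+/RB1-, Q2 = MCM+/RB1+, Q3 = MCM-/RB1+, Q4 = MCM-/RB1-. Fractions come
#' with 95\% Wilson score intervals and the result records the gate
#' provenance.
#'
#' @param events singlet-gated [EventTable-class].
#' @param gates a complete [GateSet-class] (both thresholds set).
#' @param label sample/timepoint tag stored in the result.
#' @return A [QuadrantResult-class].
#' @export
classifyQuadrants <- function(events, gates, label = NA_character_) {
  if (is.na(gates@mcm_threshold) || is.na(gates@rb1_threshold))
    stop("gates are incomplete: derive MCM and RB1 thresholds first")
  g1 <- events[.inG1(events, gates), , drop = FALSE]
  n <- nrow(g1)
  if (n == 0L) stop("zero events inside the G1 gate")
  mcm_pos <- mcmSignal(g1) > gates@mcm_threshold
  rb1_pos <- rb1Signal(g1) > gates@rb1_threshold
  counts <- c(q1 = sum(mcm_pos & !rb1_pos),
              q2 = sum(mcm_pos & rb1_pos),
              q3 = sum(!mcm_pos & rb1_pos),
              q4 = sum(!mcm_pos & !rb1_pos))
  ci <- wilsonCI(counts, n)
  rownames(ci) <- names(counts)
  new("QuadrantResult", counts = as.integer(counts), n_total = n,
      fractions = unname(counts / n), ci = ci, gates = gates,
      label = as.character(label))
}

#' Fraction of events with S-phase DNA content
#'
#' The fraction of (singlet-gated) events whose DNA area falls in the S
#' interval, with a 95\% Wilson interval. An increase marks S entry.
#'
#' @param events singlet-gated [EventTable-class].
#' @param gates a [GateSet-class] with a valid \code{s_interval}.
#' @return A list with \code{fraction}, \code{ci} (numeric(2)) and \code{n}.
#' @export
fractionSPhase <- function(events, gates) {
  n <- nrow(events)
  x <- sum(inInterval(dnaArea(events), gates@s_interval))
  ci <- wilsonCI(x, n)
  list(fraction = if (n > 0) x / n else NA_real_, ci = ci[1, ], n = n)
}
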