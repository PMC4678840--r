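#' @include AllClasses.R utils.R
NULL

# Per-cell event-time representation shared by all scenario kinds. Each cell
# is described by: exits (logical, FALSE = permanent G0), t_exit (G0 exit /
# mitotic exit), t_anchor (RB1 hypo-phosphorylation = anchoring), t_rp
# (hyper-phosphorylation = restriction-point passage), t_load (MCM loading
# onset), load_duration, t_s (S entry), preloaded (full MCM load carried from
# mitotic exit). State at time t follows deterministically.
.cellTimes <- function(scenario, n) {
  sc <- scenario
  exits <- stats::runif(n) >= sc@frac_noexit
  t_exit <- rtnorm0(n, sc@t_exit_mean, sc@t_exit_sd)
  t_anchor <- pmax(rtnorm0(n, sc@t_hypo, sc@t_hypo_sd), t_exit)
  t_rp <- pmax(rtnorm0(n, sc@t_rp_mean, sc@t_rp_sd), t_anchor + 1e-6)
  pre <- stats::runif(n) < sc@frac_pre_rp_loaders
  t_load <- rtnorm0(n, sc@t_load_mean, sc@t_load_sd) + sc@load_delay
  # non-pre-RP loaders by definition start loading after their own RP time
  t_load <- ifelse(pre, t_exit, pmax(t_load, t_rp + 1e-6))
  t_s <- t_load + sc@load_duration
  if (sc@rp_blocked) {
    t_rp <- rep(Inf, n)    # arrested before the restriction point
    t_s <- rep(Inf, n)     # no S entry during the experiment
  }
  data.frame(exits = exits, t_exit = t_exit, t_anchor = t_anchor,
             t_rp = t_rp, t_load = t_load, t_s = t_s, preloaded = pre,
             pre_phase = rep("G0", n), stringsAsFactors = FALSE)
}

.cellTimesNocodazole <- function(scenario, n) {
  w <- scenario@waves
  fast <- stats::runif(n) < w$frac_fast
  t_exit <- rtnorm0(n, scenario@t_exit_mean, scenario@t_exit_sd)
  t_anchor <- t_rp <- t_load <- t_s <- numeric(n)
  nf <- sum(fast); ns <- n - nf
  # fast wave: high CDK at mitotic exit, RB1 never anchored (unphosphorylated
  # straight to hyper-phosphorylated), early loading, S entry by ~10 h
  t_anchor[fast] <- Inf
  t_rp[fast] <- pmax(rtnorm0(nf, w$fast$t_rp, w$fast$t_rp_sd), t_exit[fast])
  t_load[fast] <- pmax(rtnorm0(nf, w$fast$t_load, w$fast$t_load_sd),
                       t_exit[fast])
  t_s[fast] <- pmax(rtnorm0(nf, w$fast$t_s, w$fast$t_s_sd),
                    t_load[fast] + scenario@load_duration)
  # slow wave: anchors RB1 early, loads at 6-8 h while still before the
  # restriction point (Q2), passes RP late
  t_anchor[!fast] <- pmax(rtnorm0(ns, w$slow$t_hypo, w$slow$t_hypo_sd),
                          t_exit[!fast])
  t_load[!fast] <- pmax(rtnorm0(ns, w$slow$t_load, w$slow$t_load_sd),
                        t_anchor[!fast])
  t_rp[!fast] <- pmax(rtnorm0(ns, w$slow$t_rp, w$slow$t_rp_sd),
                      t_anchor[!fast] + 1e-6)
  t_s[!fast] <- pmax(rtnorm0(ns, w$slow$t_s, w$slow$t_s_sd),
                     t_load[!fast] + scenario@load_duration)
  t_rp <- pmin(t_rp, t_s)  # RP passage precedes S entry
  data.frame(exits = TRUE, t_exit = t_exit, t_anchor = t_anchor, t_rp = t_rp,
             t_load = t_load, t_s = t_s, preloaded = FALSE,
             pre_phase = "G2M", stringsAsFactors = FALSE)
}

# Resolve per-cell state at absolute time t from the event-time table.
.stateAt <- function(tm, t, scenario) {
  n <- nrow(tm)
  phase <- rep("G1", n)
  in_s <- tm$exits & t >= tm$t_s & t < tm$t_s + scenario@T_S
  post_s <- tm$exits & t >= tm$t_s + scenario@T_S
  pre_exit <- !tm$exits | t < tm$t_exit
  phase[in_s] <- "S"
  phase[post_s] <- "G2M"
  phase[pre_exit] <- tm$pre_phase[pre_exit]
  s_fraction <- ifelse(in_s, (t - tm$t_s) / scenario@T_S, 0)

  rp_passed <- tm$exits & t >= tm$t_rp & t >= tm$t_exit
  rp_passed <- rp_passed | phase %in% c("S") | post_s |
    (pre_exit & tm$pre_phase == "G2M")  # mitotic cells carry hyper-phos RB1
  anchored <- !rp_passed & tm$exits & t >= tm$t_anchor & t >= tm$t_exit &
    phase == "G1"
  rb1_state <- ifelse(rp_passed, "hyper_phosphorylated",
                      ifelse(anchored, "hypo_phosphorylated",
                             "unphosphorylated"))

  # chromatin-bound MCM fraction
  ramp <- function(tt) pmin(pmax((tt - tm$t_load) / scenario@load_duration, 0), 1)
  l_g1 <- ifelse(tm$preloaded, 1, ramp(t))
  l_entry <- ifelse(tm$preloaded, 1, ramp(tm$t_s))
  l_s <- l_entry * pmax(0, 1 - s_fraction / scenario@s_offload_complete)
  loaded <- ifelse(phase == "G1" & !pre_exit, l_g1,
                   ifelse(phase == "S", l_s, 0))
  if (scenario@g2m_loading)
    loaded[(post_s | (pre_exit & tm$pre_phase == "G2M")) & tm$preloaded] <- 1
  loaded[pre_exit & tm$pre_phase == "G0"] <- 0

  dna <- ifelse(phase == "S", 2 * (1 + s_fraction),
                ifelse(phase == "G2M", 4, 2))
  list(phase = phase, s_fraction = s_fraction, rb1_state = rb1_state,
       rp_passed = rp_passed, mcm_loaded_fraction = loaded, dna_content = dna)
}

#' Simulate ground-truth cell states
#'
#' Draws \code{n_cells} cells under the scenario's kinetic model and returns
#' their biological ground truth at the requested timepoint. For the
#' \code{exponential} kind, cell ages follow the exponential-growth age
#' density p(a) = (2 log 2 / T) 2^(-a/T) on [0, T] with
#' T = T_G1 + T_S + T_G2M, and the timepoint is ignored (steady state). For
#' the synchronized kinds all cells start at the scenario origin (G0 or
#' mitotic exit) and progress deterministically with truncated-Gaussian
#' per-cell jitter on anchoring, restriction-point and loading times.
#'
#' @param scenario a [ScenarioConfig-class].
#' @param timepoint hours since the scenario origin.
#' @param seed optional integer overriding the seed derived from
#'   \code{scenario@seed} and the timepoint.
#' @return A [S4Vectors::DFrame] with one row per cell and columns
#'   \code{cell_id}, \code{phase} (G0/G1/S/G2M), \code{s_fraction},
#'   \code{rb1_state}, \code{rp_passed}, \code{mcm_loaded_fraction},
#'   \code{dna_content}, \code{sample_id}.
#' @examples
#' sc <- scenarioConfig("g0_release", n_cells = 500L, seed = 7L)
#' cells <- simulateCells(sc, timepoint = 6)
#' table(cells$phase)
#' @export
simulateCells <- function(scenario, timepoint = 0, seed = NULL) {
  stopifnot(is(scenario, "ScenarioConfig"))
  validObject(scenario)
  n <- scenario@n_cells
  if (is.null(seed))
    seed <- subSeed(scenario@seed, round(timepoint * 1000))
  empty <- DataFrame(cell_id = integer(), phase = character(),
                     s_fraction = numeric(), rb1_state = character(),
                     rp_passed = logical(), mcm_loaded_fraction = numeric(),
                     dna_content = numeric(), sample_id = integer())
  if (n == 0L) return(empty)
  withSeed(seed, {
    if (scenario@kind == "exponential") {
      Tc <- scenario@T_G1 + scenario@T_S + scenario@T_G2M
      # inverse CDF of the exponential-growth age density
      u <- stats::runif(n)
      age <- -Tc * log2(1 - u / 2)
      tm <- .cellTimes(scenario, n)
      tm$exits <- TRUE
      tm$t_exit <- 0
      # cells enter S at age T_G1 regardless of jitter; keep event times
      # consistent with that boundary
      tm$t_rp <- pmin(tm$t_rp, scenario@T_G1)
      tm$t_load <- ifelse(tm$preloaded, 0,
                          pmin(tm$t_load,
                               scenario@T_G1 - scenario@load_duration))
      tm$t_s <- scenario@T_G1
      st <- .stateAtAges(tm, age, scenario)
    } else {
      tm <- if (scenario@kind == "nocodazole_release")
        .cellTimesNocodazole(scenario, n) else .cellTimes(scenario, n)
      st <- .stateAt(tm, timepoint, scenario)
    }
    DataFrame(cell_id = seq_len(n), phase = st$phase,
              s_fraction = st$s_fraction, rb1_state = st$rb1_state,
              rp_passed = st$rp_passed,
              mcm_loaded_fraction = st$mcm_loaded_fraction,
              dna_content = st$dna_content, sample_id = 1L)
  })
}

# Like .stateAt but with a per-cell time vector (cell ages).
.stateAtAges <- function(tm, age, scenario) {
  n <- nrow(tm)
  in_s <- age >= tm$t_s & age < tm$t_s + scenario@T_S
  post_s <- age >= tm$t_s + scenario@T_S
  phase <- ifelse(in_s, "S", ifelse(post_s, "G2M", "G1"))
  s_fraction <- ifelse(in_s, (age - tm$t_s) / scenario@T_S, 0)
  rp_passed <- age >= tm$t_rp | in_s | post_s
  anchored <- !rp_passed & age >= tm$t_anchor & phase == "G1"
  rb1_state <- ifelse(rp_passed, "hyper_phosphorylated",
                      ifelse(anchored, "hypo_phosphorylated",
                             "unphosphorylated"))
  ramp <- pmin(pmax((age - tm$t_load) / scenario@load_duration, 0), 1)
  l_g1 <- ifelse(tm$preloaded, 1, ramp)
  l_entry <- ifelse(tm$preloaded, 1,
                    pmin(pmax((tm$t_s - tm$t_load) / scenario@load_duration, 0), 1))
  l_s <- l_entry * pmax(0, 1 - s_fraction / scenario@s_offload_complete)
  loaded <- ifelse(phase == "G1", l_g1, ifelse(phase == "S", l_s, 0))
  if (scenario@g2m_loading) loaded[post_s & tm$preloaded] <- 1
  dna <- ifelse(phase == "S", 2 * (1 + s_fraction),
                ifelse(phase == "G2M", 4, 2))
  list(phase = phase, s_fraction = s_fraction, rb1_state = rb1_state,
       rp_passed = rp_passed, mcm_loaded_fraction = loaded, dna_content = dna)
}

#' Convert cell states into measured list-mode events
#'
#' Applies the measurement model: \code{dna_area = gain_dna * dna_content *
#' lognoise(cv_dna) + background_dna}; \code{dna_width = base_width *
#' lognoise(cv_width)} (independent of DNA content for singlets);
#' \code{mcm_signal = gain_mcm * mcm_loaded_fraction * lognoise(cv_mcm) +
#' background_mcm * lognoise(cv_mcm)}; \code{rb1_signal = gain_rb1 *
#' [rb1_state == hypo_phosphorylated] * lognoise(cv_rb1) + background_rb1 *
#' lognoise(cv_rb1)}. Only anchored (hypo-phosphorylated) RB1 survives the
#' pre-fixation extraction, so both unphosphorylated and hyper-phosphorylated
#' cells show background-only RB1 signal. Ground-truth columns are carried
#' through into the output.
#'
#' @param cells a DFrame of cell states from [simulateCells()].
#' @param optics an [OpticsConfig-class].
#' @param seed integer seed; the output is bit-identical for a fixed seed.
#' @param label,timepoint metadata stamped on the result.
#' @return An [EventTable-class] with one event per cell.
#' @examples
#' sc <- scenarioConfig("exponential", n_cells = 100L, seed = 1L)
#' ev <- applyMeasurementModel(simulateCells(sc), opticsConfig(), seed = 1L)
#' ev
#' @export
applyMeasurementModel <- function(cells, optics = opticsConfig(), seed = 1L,
                                  label = NA_character_, timepoint = NA_real_) {
  stopifnot(is(optics, "OpticsConfig"))
  validObject(optics)
  n <- nrow(cells)
  withSeed(seed, {
    anchored <- cells$rb1_state == "hypo_phosphorylated"
    df <- DataFrame(
      dna_area = optics@gain["dna"] * cells$dna_content * lognoise(n, optics@cv["dna"]) +
        optics@background["dna"],
      dna_width = optics@base_width * lognoise(n, optics@cv["width"]),
      mcm_signal = optics@gain["mcm"] * cells$mcm_loaded_fraction *
        lognoise(n, optics@cv["mcm"]) +
        optics@background["mcm"] * lognoise(n, optics@cv["mcm"]),
      rb1_signal = optics@gain["rb1"] * as.numeric(anchored) *
        lognoise(n, optics@cv["rb1"]) +
        optics@background["rb1"] * lognoise(n, optics@cv["rb1"])
    )
    for (cn in c("phase", "s_fraction", "rb1_state", "rp_passed",
                 "mcm_loaded_fraction", "dna_content", "sample_id", "cell_id"))
      if (cn %in% colnames(cells)) df[[cn]] <- cells[[cn]]
    df$is_doublet <- rep(FALSE, n)
    out <- new("EventTable", df)
    metadata(out) <- list(channels = channelMap(), label = label,
                          timepoint = timepoint)
    out
  })
}

#' Inject synthetic doublets
#'
#' Appends aggregate events so that a fraction \code{doublet_rate} of the
#' output are doublets: DNA area and the MCM/RB1 signals are sums of two
#' randomly paired singlet events, and the pulse width is
#' \code{doublet_width_factor} times the mean of the pair's widths. The
#' ground-truth column \code{is_doublet} marks the synthetic aggregates.
#'
#' @param events an [EventTable-class] of singlets.
#' @param optics an [OpticsConfig-class] providing \code{doublet_rate} and
#'   \code{doublet_width_factor}.
#' @param seed integer seed.
#' @return An [EventTable-class] with \code{floor(n * rate / (1 - rate))}
#'   doublets appended.
#' @export
injectDoublets <- function(events, optics = opticsConfig(), seed = 1L) {
  rate <- optics@doublet_rate
  n <- nrow(events)
  if (rate == 0) return(events)
  if (n < 2L) stop("need at least 2 events to form doublets")
  n_d <- floor(n * rate / (1 - rate))
  if (n_d == 0L) return(events)
  withSeed(seed, {
    i <- sample.int(n, n_d, replace = TRUE)
    j <- sample.int(n, n_d, replace = TRUE)
    same <- which(i == j)
    if (length(same)) j[same] <- (j[same] %% n) + 1L
    dbl <- events[i, , drop = FALSE]
    dbl[["dna_area"]] <- events[["dna_area"]][i] + events[["dna_area"]][j]
    dbl[["mcm_signal"]] <- events[["mcm_signal"]][i] + events[["mcm_signal"]][j]
    dbl[["rb1_signal"]] <- events[["rb1_signal"]][i] + events[["rb1_signal"]][j]
    dbl[["dna_width"]] <- optics@doublet_width_factor *
      (events[["dna_width"]][i] + events[["dna_width"]][j]) / 2
    if ("is_doublet" %in% colnames(dbl)) dbl[["is_doublet"]] <- TRUE
    if ("phase" %in% colnames(dbl)) dbl[["phase"]] <- "doublet"
    out <- rbind(events, dbl)
    metadata(out) <- metadata(events)
    out
  })
}

#' Barcode samples and pool them into one tube
#'
#' Emulates fluorescent cell barcoding: each input table's events receive a
#' \code{barcode_signal} drawn log-normally (sdlog \code{barcode_cv}) around
#' that sample's staining level, the tables are concatenated and the row
#' order is shuffled. \code{sample_id} ground truth is set to the table index
#' and preserved through pooling.
#'
#' @param tables list of [EventTable-class], one per barcoded sample; must
#'   match \code{length(optics@barcode_levels)}.
#' @param optics an [OpticsConfig-class]; \code{barcode_levels} must be
#'   strictly decreasing (brightest sample first).
#' @param seed integer seed.
#' @return A pooled [EventTable-class] whose size is the sum of input sizes.
#' @export
barcodeAndPool <- function(tables, optics = opticsConfig(), seed = 1L) {
  k <- length(tables)
  if (k != length(optics@barcode_levels))
    stop("number of tables (", k, ") must equal number of barcode_levels (",
         length(optics@barcode_levels), ")")
  withSeed(seed, {
    for (i in seq_len(k)) {
      tab <- tables[[i]]
      ni <- nrow(tab)
      noise <- if (optics@barcode_cv > 0)
        exp(stats::rnorm(ni, 0, optics@barcode_cv)) else rep(1, ni)
      tab[["barcode_signal"]] <- optics@barcode_levels[i] * noise
      tab[["sample_id"]] <- rep(i, ni)
      tables[[i]] <- tab
    }
    out <- do.call(rbind, tables)
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    metadata(out) <- metadata(tables[[1]])
    out
  })
}

#' Closed-form G1 fraction under exponential growth
#'
#' For the exponential-growth age density, the expected fraction of cells
#' with age below \code{T_G1} is \code{2 * (1 - 2^(-T_G1 / T))}.
#'
#' @param T_G1,T_S,T_G2M phase durations in hours.
#' @return Expected G1 fraction.
#' @export
expectedG1Fraction <- function(T_G1, T_S, T_G2M) {
  T <- T_G1 + T_S + T_G2M
  2 * (1 - 2^(-T_G1 / T))
}
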