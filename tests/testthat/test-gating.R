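test_that("singlet width cut keeps singlets and excludes wide events", {
  # forced by the cut rule: widths clustered at 100/102 plus one 1.6x event
  ev <- EventTable(dna_area = rep(200, 51),
                   dna_width = c(rep(c(100, 102), 25), 160),
                   mcm_signal = rep(1, 51), rb1_signal = rep(1, 51))
  g <- gateSinglets(ev)
  expect_equal(nrow(g$events), 50L)
  expect_true(all(dnaWidth(g$events) <= 102))
  expect_lt(g$singlet_rule["width_cut"], 160)

  # degenerate width distribution falls back to a relative cut with warning
  evc <- EventTable(dna_area = rep(200, 60), dna_width = rep(100, 60),
                    mcm_signal = rep(1, 60), rb1_signal = rep(1, 60))
  expect_warning(gc <- gateSinglets(evc), "MAD")
  expect_equal(nrow(gc$events), 60L)
  expect_error(gateSinglets(ev[1:10, ]), "50")
})

test_that("singlet gate separates simulated doublets from singlets", {
  sc <- scenarioConfig("exponential", n_cells = 10000L, seed = 14L)
  opt <- opticsConfig(doublet_rate = 0.05, doublet_width_factor = 1.6)
  ev <- applyMeasurementModel(simulateCells(sc), opt, seed = 14L)
  ev <- injectDoublets(ev, opt, seed = 15L)
  g <- gateSinglets(ev)
  kept <- g$events
  singlet_kept <- sum(!kept$is_doublet) / sum(!ev$is_doublet)
  doublet_removed <- 1 - sum(kept$is_doublet) / sum(ev$is_doublet)
  expect_gte(singlet_kept, 0.98)
  expect_gte(doublet_removed, 0.95)
})

test_that("DNA peak finder recovers G1/G2 modes and flags special cases", {
  mkev <- function(area) EventTable(
    dna_area = area, dna_width = rep(100, length(area)),
    mcm_signal = rep(1, length(area)), rb1_signal = rep(1, length(area)))

  withr::with_seed(31, {
    # pure G1 population: G2 inferred at exactly twice the peak
    pure <- mkev(200 * exp(rnorm(5000, 0, 0.03)))
    pk <- findDnaPeaks(pure)
    expect_equal(pk$g1_peak, 200, tolerance = 0.02)
    expect_equal(pk$g2_peak, 2 * pk$g1_peak)
    expect_true(pk$g2_inferred)

    # 60% G1 / 30% G2 / 10% S mixture: both peaks within 2%
    mix <- mkev(c(200 * exp(rnorm(6000, 0, 0.03)),
                  400 * exp(rnorm(3000, 0, 0.03)),
                  runif(1000, 210, 390)))
    pk2 <- findDnaPeaks(mix)
    expect_equal(pk2$g1_peak, 200, tolerance = 0.02)
    expect_equal(pk2$g2_peak, 400, tolerance = 0.02)
    expect_false(pk2$g2_inferred)
    expect_gte(pk2$g2_peak / pk2$g1_peak, 1.85)
    expect_lte(pk2$g2_peak / pk2$g1_peak, 2.15)

    # G2-dominant sample with a half-position mode: dominant mode is G2
    g2dom <- mkev(c(400 * exp(rnorm(7000, 0, 0.03)),
                    200 * exp(rnorm(2500, 0, 0.03))))
    pk3 <- findDnaPeaks(g2dom)
    expect_equal(pk3$g1_peak, 200, tolerance = 0.03)
    expect_equal(pk3$g2_peak, 400, tolerance = 0.02)

    # all-G2M sample (mitotic block at t=0): single mode, flagged ambiguous
    allg2 <- mkev(400 * exp(rnorm(5000, 0, 0.03)))
    pk4 <- findDnaPeaks(allg2)
    expect_equal(pk4$g1_peak, 400, tolerance = 0.02)
    expect_true(pk4$g1_ambiguous)
  })
  expect_error(findDnaPeaks(mkev(rep(200, 100))), "200")
})

test_that("gate arithmetic follows the stated rules", {
  peaks <- list(g1_peak = 200, g2_peak = 400, g2_inferred = FALSE,
                g1_ambiguous = FALSE)
  g <- defineGates(NULL, peaks, w_lo = 0.10)
  expect_equal(g@g1_gate, c(180, 200))
  expect_equal(g@sg2_border, c(360, 392))
  expect_equal(g@s_interval, c(220, 360))

  # only the left side of the G1 peak: 205 is excluded, 190 retained
  g@mcm_threshold <- 80; g@rb1_threshold <- 100
  ev <- EventTable(dna_area = c(190, 205), dna_width = c(100, 100),
                   mcm_signal = c(200, 200), rb1_signal = c(30, 30))
  q <- classifyQuadrants(ev, g)
  expect_equal(q@n_total, 1L)
  expect_error(defineGates(NULL, list(g1_peak = 200, g2_peak = 400),
                           w_lo = 0), "empty or inverted")
})

test_that("MCM threshold matches closed-form quantiles and is monotone in q", {
  border_area <- function(n) runif(n, 360, 391.9)
  # degenerate border distribution: threshold equals the constant
  evc <- EventTable(dna_area = border_area(100), dna_width = rep(100, 100),
                    mcm_signal = rep(42, 100), rb1_signal = rep(1, 100))
  g <- defineGates(NULL, list(g1_peak = 200, g2_peak = 400))
  for (q in c(0.5, 0.9, 0.99))
    expect_equal(deriveMcmThreshold(evc, g, q), 42)

  # log-normal closed form: gm 50, sdlog 0.2, q = 0.99 -> 50*exp(0.2*2.3263)
  withr::with_seed(77, {
    n <- 40000
    ev <- EventTable(dna_area = border_area(n), dna_width = rep(100, n),
                     mcm_signal = 50 * exp(rnorm(n, 0, 0.2)),
                     rb1_signal = rep(1, n))
    thr <- deriveMcmThreshold(ev, g, q = 0.99)
    expect_equal(thr, 50 * exp(0.2 * qnorm(0.99)), tolerance = 0.03)
    qs <- c(0.5, 0.9, 0.95, 0.99, 0.999)
    thrs <- vapply(qs, function(q) deriveMcmThreshold(ev, g, q), numeric(1))
    expect_true(all(diff(thrs) >= 0))  # threshold monotone in q
  })
  expect_error(deriveMcmThreshold(evc[1:10, ], g), "control")
})

test_that("RB1 threshold sits at the geometric midpoint of the two modes", {
  g <- defineGates(NULL, list(g1_peak = 200, g2_peak = 400))
  withr::with_seed(12, {
    n_s <- 2000; n_g1 <- 4000
    ev <- EventTable(
      dna_area = c(runif(n_s, 221, 359), 190 + runif(n_g1, -5, 5)),
      dna_width = rep(100, n_s + n_g1),
      mcm_signal = rep(1, n_s + n_g1),
      rb1_signal = c(10 * exp(rnorm(n_s, 0, 0.2)),
                     ifelse(runif(n_g1) < 0.5,
                            10 * exp(rnorm(n_g1, 0, 0.2)),
                            1000 * exp(rnorm(n_g1, 0, 0.2)))))
    thr <- deriveRb1Threshold(ev, g)
    expect_equal(as.numeric(thr), sqrt(10 * 1000), tolerance = 0.25)
    expect_false(attr(thr, "fallback"))

    # unimodal G1 (no anchored population): quantile fallback, flagged
    ev2 <- EventTable(
      dna_area = c(runif(n_s, 221, 359), 190 + runif(n_g1, -5, 5)),
      dna_width = rep(100, n_s + n_g1),
      mcm_signal = rep(1, n_s + n_g1),
      rb1_signal = 10 * exp(rnorm(n_s + n_g1, 0, 0.2)))
    thr2 <- deriveRb1Threshold(ev2, g)
    expect_true(attr(thr2, "fallback"))
    expect_gt(as.numeric(thr2), 10)
  })
  empty_s <- EventTable(dna_area = rep(190, 100), dna_width = rep(100, 100),
                        mcm_signal = rep(1, 100), rb1_signal = rep(1, 100))
  expect_error(deriveRb1Threshold(empty_s, g), "control")
})

test_that("control-based thresholds match closed forms and population placement", {
  mk <- function(x) EventTable(dna_area = rep(200, length(x)),
                               dna_width = rep(100, length(x)),
                               mcm_signal = x, rb1_signal = x)
  expect_equal(deriveThresholdFromControl(mk(rep(3, 200)), 0.9, "mcm"), 3)
  withr::with_seed(5, {
    ctl <- mk(10 * exp(rnorm(50000, 0, 0.3)))
    thr <- deriveThresholdFromControl(ctl, q = 0.995, channel = "mcm")
    expect_equal(thr, 10 * exp(0.3 * qnorm(0.995)), tolerance = 0.03)
  })
  expect_error(deriveThresholdFromControl(mk(rep(1, 10)), 0.9, "mcm"), "100")

  # population (S/G2-border) and control routes place the MCM region in the
  # same spot on matched simulations; accurate border membership (small DNA
  # CV) keeps mid-S cells with residual load out of the negative reference
  sc <- scenarioConfig("exponential", n_cells = 30000L, seed = 19L)
  cells <- simulateCells(sc)
  opt <- cleanOptics(cv = c(dna = 0.01, width = 0.05, mcm = 0.25, rb1 = 0.25))
  ev <- applyMeasurementModel(cells, opt, seed = 19L)
  gs <- gateSample(ev)
  ctrl_opt <- opt
  ctrl_opt@gain[c("mcm", "rb1")] <- c(1e-9, 1e-9)
  ctrl <- applyMeasurementModel(cells, ctrl_opt, seed = 20L)
  thr_ctrl <- deriveThresholdFromControl(ctrl, q = 0.99, channel = "mcm")
  ratio <- gs$gates@mcm_threshold / thr_ctrl
  expect_gt(ratio, 1 / 1.5)
  expect_lt(ratio, 1.5)
})

test_that("quadrant classification implements the definitions with conservation", {
  g <- defineGates(NULL, list(g1_peak = 200, g2_peak = 400))
  g@mcm_threshold <- 80; g@rb1_threshold <- 100
  ev <- EventTable(dna_area = rep(190, 4), dna_width = rep(100, 4),
                   mcm_signal = c(200, 200, 10, 10),
                   rb1_signal = c(30, 300, 300, 30))
  q <- classifyQuadrants(ev, g)
  expect_equal(q@counts, c(1L, 1L, 1L, 1L))
  expect_equal(q@n_total, 4L)
  expect_equal(sum(q@fractions), 1)
  expect_true(all(q@ci[, 1] <= q@fractions & q@fractions <= q@ci[, 2]))

  # ties at the threshold are negative
  ev_tie <- EventTable(dna_area = 190, dna_width = 100,
                       mcm_signal = 80, rb1_signal = 100)
  qt <- classifyQuadrants(ev_tie, g)
  expect_equal(qt@counts[4], 1L)

  out_of_gate <- EventTable(dna_area = 300, dna_width = 100,
                            mcm_signal = 1, rb1_signal = 1)
  expect_error(classifyQuadrants(out_of_gate, g), "zero events")
  g_incomplete <- defineGates(NULL, list(g1_peak = 200, g2_peak = 400))
  expect_error(classifyQuadrants(ev, g_incomplete), "incomplete")
})

test_that("quadrant fractions recover ground truth within 2 points at n=50k", {
  sc <- scenarioConfig("exponential", n_cells = 50000L, seed = 23L)
  ev <- applyMeasurementModel(simulateCells(sc), cleanOptics(), seed = 23L)
  gs <- gateSample(ev)
  q <- classifyQuadrants(gs$events, gs$gates)
  g1ev <- gs$events[inG1Gate(gs$events, gs$gates), ]
  truth <- truthQuadrant(g1ev)
  truth_frac <- tabulate(truth, 4) / length(truth)
  expect_true(all(abs(q@fractions - truth_frac) <= 0.02))
})

test_that("MCM and RB1 positivity calls agree with per-cell ground truth", {
  sc <- scenarioConfig("exponential", n_cells = 40000L, seed = 29L)
  ev <- applyMeasurementModel(simulateCells(sc), cleanOptics(), seed = 29L)
  gs <- gateSample(ev)
  g1ev <- gs$events[inG1Gate(gs$events, gs$gates), ]
  called <- mcmSignal(g1ev) > gs$gates@mcm_threshold
  truth <- g1ev$mcm_loaded_fraction > 0
  sens <- mean(called[truth]); spec <- mean(!called[!truth])
  expect_gte((sens + spec) / 2, 0.95)   # balanced accuracy, default optics

  s_ev <- gs$events[dnaArea(gs$events) >= gs$gates@s_interval[1] &
                      dnaArea(gs$events) < gs$gates@s_interval[2], ]
  expect_gte(mean(rb1Signal(s_ev) <= gs$gates@rb1_threshold), 0.99)
})

test_that("irradiated samples classify RB1-positive under control-derived gates", {
  # thresholds from the unirradiated control transfer to the arrested sample
  ctrl_sc <- scenarioConfig("g0_release", n_cells = 20000L, seed = 33L,
                            timepoints = c(0, 20))
  pooled <- do.call(rbind, lapply(c(6, 20), function(tp)
    applyMeasurementModel(simulateCells(ctrl_sc, tp), cleanOptics(),
                          seed = 33L + tp)))
  gs <- gateSample(pooled)
  # full release efficiency: every G1 cell in the arrested sample is anchored
  irr <- scenarioConfig("irradiated_g0_release", n_cells = 10000L, seed = 34L,
                        frac_noexit = 0)
  ev_irr <- applyMeasurementModel(simulateCells(irr, 13), cleanOptics(),
                                  seed = 35L)
  g1 <- ev_irr[inG1Gate(ev_irr, gs$gates), ]
  expect_gte(mean(rb1Signal(g1) > gs$gates@rb1_threshold), 0.98)
})

test_that("gating is blind to ground-truth columns", {
  sc <- scenarioConfig("exponential", n_cells = 20000L, seed = 37L)
  ev <- applyMeasurementModel(simulateCells(sc), opticsConfig(), seed = 37L)
  ev <- injectDoublets(ev, opticsConfig(), seed = 38L)
  blind <- dropTruth(ev)
  expect_false(hasTruth(blind))
  gs1 <- gateSample(ev)
  gs2 <- gateSample(blind)
  expect_identical(gs1$gates@mcm_threshold, gs2$gates@mcm_threshold)
  expect_identical(gs1$gates@rb1_threshold, gs2$gates@rb1_threshold)
  expect_identical(gs1$gates@g1_gate, gs2$gates@g1_gate)
  q1 <- classifyQuadrants(gs1$events, gs1$gates)
  q2 <- classifyQuadrants(gs2$events, gs2$gates)
  expect_identical(q1@counts, q2@counts)
})

test_that("derived thresholds are stable across independent simulations", {
  thr <- lapply(c(41L, 42L), function(s) {
    sc <- scenarioConfig("exponential", n_cells = 50000L, seed = s)
    ev <- applyMeasurementModel(simulateCells(sc), cleanOptics(), seed = s)
    gs <- gateSample(ev)
    c(gs$gates@mcm_threshold, gs$gates@rb1_threshold)
  })
  rel <- abs(thr[[1]] - thr[[2]]) / thr[[1]]
  expect_true(all(rel < 0.05))
})

test_that("S-phase fraction tracks DNA content", {
  g <- defineGates(NULL, list(g1_peak = 200, g2_peak = 400))
  withr::with_seed(51, {
    pure_g1 <- EventTable(dna_area = 200 * exp(rnorm(5000, 0, 0.03)),
                          dna_width = rep(100, 5000),
                          mcm_signal = rep(1, 5000), rb1_signal = rep(1, 5000))
    expect_lte(fractionSPhase(pure_g1, g)$fraction, 0.02)

    mixed <- EventTable(dna_area = c(200 * exp(rnorm(2500, 0, 0.02)),
                                     runif(2500, 230, 350)),
                        dna_width = rep(100, 5000),
                        mcm_signal = rep(1, 5000), rb1_signal = rep(1, 5000))
    fs <- fractionSPhase(mixed, g)
    expect_lt(abs(fs$fraction - 0.5), 3 * sqrt(0.25 / 5000))
    expect_true(fs$ci[1] <= fs$fraction && fs$fraction <= fs$ci[2])
  })

  sc <- scenarioConfig("g0_release", n_cells = 20000L, seed = 53L)
  pooled <- do.call(rbind, lapply(c(6, 18), function(tp)
    applyMeasurementModel(simulateCells(sc, tp), cleanOptics(), seed = 60L + tp)))
  gates <- defineGates(pooled, findDnaPeaks(pooled))
  ev6 <- applyMeasurementModel(simulateCells(sc, 6), cleanOptics(), seed = 66L)
  ev18 <- applyMeasurementModel(simulateCells(sc, 18), cleanOptics(), seed = 78L)
  expect_lte(fractionSPhase(ev6, gates)$fraction, 0.02)
  expect_gt(fractionSPhase(ev18, gates)$fraction, 0.10)
})
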