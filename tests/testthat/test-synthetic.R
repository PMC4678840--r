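test_that("empty populations and determinism contracts hold", {
  sc <- scenarioConfig("g0_release", n_cells = 0L, seed = 1L)
  expect_equal(nrow(simulateCells(sc, 6)), 0L)

  sc2 <- scenarioConfig("exponential", n_cells = 500L, seed = 42L)
  a <- simulateCells(sc2)
  b <- simulateCells(sc2)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- simulateCells(scenarioConfig("exponential", n_cells = 500L, seed = 43L))
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))

  opt <- cleanOptics()
  e1 <- applyMeasurementModel(a, opt, seed = 9L)
  e2 <- applyMeasurementModel(a, opt, seed = 9L)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  expect_equal(nrow(e1), nrow(a))  # one event per cell

  expect_error(scenarioConfig("g0_release", T_S = -1), "positive")
  expect_error(simulateCells("not a scenario"))
})

test_that("exponential scenario reproduces the growth age distribution", {
  # independent oracle: numerical integration of the age density
  T_G1 <- 10; T_S <- 8; T_G2M <- 4
  Tc <- T_G1 + T_S + T_G2M
  dens <- function(a) (2 * log(2) / Tc) * 2^(-a / Tc)
  f_g1 <- integrate(dens, 0, T_G1)$value
  f_s <- integrate(dens, T_G1, T_G1 + T_S)$value
  f_g2m <- integrate(dens, T_G1 + T_S, Tc)$value
  expect_equal(f_g1 + f_s + f_g2m, 1, tolerance = 1e-8)
  expect_equal(expectedG1Fraction(T_G1, T_S, T_G2M), f_g1, tolerance = 1e-8)
  expect_equal(f_g1, 0.5406, tolerance = 2e-4)  # closed form 2*(1-2^(-10/22))

  n <- 100000L
  cells <- simulateCells(scenarioConfig("exponential", n_cells = n, seed = 7L))
  for (ph in c("G1", "S", "G2M")) {
    f_true <- switch(ph, G1 = f_g1, S = f_s, G2M = f_g2m)
    se <- sqrt(f_true * (1 - f_true) / n)
    expect_lt(abs(mean(cells$phase == ph) - f_true), 3 * se)
  }
})

test_that("G0-release kinetics follow the configured onsets", {
  sc <- scenarioConfig("g0_release", n_cells = 5000L, seed = 3L)
  at6 <- simulateCells(sc, 6)
  expect_equal(sum(at6$rp_passed), 0L)           # restriction point from ~9 h
  expect_true(all(at6$phase %in% c("G0", "G1")))
  expect_true(all(at6$dna_content == 2))
  expect_gt(mean(at6$rb1_state == "hypo_phosphorylated"), 0.8)

  at15 <- simulateCells(sc, 15)
  expect_gt(mean(at15$phase == "S"), 0)          # S cells visible from ~15 h
  expect_gt(mean(at15$rp_passed), 0.5)

  at0 <- simulateCells(sc, 0)
  expect_true(all(at0$phase == "G0"))
  expect_true(all(at0$rb1_state == "unphosphorylated"))
  expect_true(all(at0$mcm_loaded_fraction == 0))
})

test_that("irradiated release never passes the restriction point", {
  sc <- scenarioConfig("irradiated_g0_release", n_cells = 3000L, seed = 5L)
  for (tp in sc@timepoints) {
    cells <- simulateCells(sc, tp)
    expect_true(all(cells$rb1_state != "hyper_phosphorylated"))
    expect_true(all(!cells$rp_passed))
    expect_true(all(cells$phase != "S"))
  }
})

test_that("state invariants hold across scenarios and timepoints", {
  for (kind in c("exponential", "g0_release", "nocodazole_release",
                 "irradiated_g0_release")) {
    sc <- scenarioConfig(kind, n_cells = 4000L, seed = 11L)
    tps <- if (kind == "exponential") 0 else sc@timepoints
    for (tp in tps[seq(1, length(tps), by = 2)]) {
      cells <- simulateCells(sc, tp)
      expect_true(all(cells$mcm_loaded_fraction >= 0 &
                        cells$mcm_loaded_fraction <= 1))
      g01 <- cells$phase %in% c("G0", "G1")
      expect_true(all(cells$dna_content[g01] == 2))
      expect_true(all(cells$dna_content[cells$phase == "G2M"] == 4))
      s <- cells$phase == "S"
      expect_equal(cells$dna_content[s], 2 * (1 + cells$s_fraction[s]))
      expect_identical(cells$rp_passed,
                       cells$rb1_state == "hyper_phosphorylated")
    }
  }
})

test_that("MCM offloading is non-increasing along the S-phase trajectory", {
  # deterministic trajectory: zero jitter => every cell follows one path
  sc <- scenarioConfig("g0_release", n_cells = 200L, seed = 2L,
                       t_rp_sd = 0, t_load_sd = 0, t_hypo_sd = 0,
                       t_exit_sd = 0, frac_noexit = 0,
                       timepoints = seq(0, 23, by = 0.5))
  loaded_in_s <- vapply(seq(15, 23, by = 0.25), function(tp) {
    cells <- simulateCells(sc, tp)
    s <- cells$phase == "S"
    if (!any(s)) NA_real_ else mean(cells$mcm_loaded_fraction[s])
  }, numeric(1))
  traj <- loaded_in_s[!is.na(loaded_in_s)]
  expect_gt(length(traj), 10)
  expect_true(all(diff(traj) <= 1e-9))
  expect_equal(traj[length(traj)], 0)  # offloading complete by the S/G2 border
})

test_that("measurement model is an exact pass-through without noise", {
  cells <- S4Vectors::DataFrame(
    cell_id = 1:3,
    phase = c("G1", "S", "G1"),
    s_fraction = c(0, 0.5, 0),
    rb1_state = c("hypo_phosphorylated", "hyper_phosphorylated",
                  "unphosphorylated"),
    rp_passed = c(FALSE, TRUE, FALSE),
    mcm_loaded_fraction = c(0, 0.4, 1),
    dna_content = c(2, 3, 2),
    sample_id = 1L)
  opt <- opticsConfig(gain = c(dna = 100, mcm = 1, rb1 = 50),
                      background = c(dna = 0, mcm = 0, rb1 = 7),
                      cv = c(dna = 0, width = 0, mcm = 0, rb1 = 0),
                      doublet_rate = 0)
  ev <- applyMeasurementModel(cells, opt, seed = 1L)
  expect_equal(dnaArea(ev), c(200, 300, 200))
  expect_equal(mcmSignal(ev), c(0, 0.4, 1))
  # anchored RB1 only survives extraction: specific signal for the
  # hypo-phosphorylated cell, background only for hyper and unphosphorylated
  expect_equal(rb1Signal(ev), c(50 + 7, 7, 7))
  expect_equal(dnaWidth(ev), rep(100, 3))
})

test_that("log-normal noise reproduces the requested coefficient of variation", {
  cells <- S4Vectors::DataFrame(
    cell_id = seq_len(50000L), phase = "G1", s_fraction = 0,
    rb1_state = "unphosphorylated", rp_passed = FALSE,
    mcm_loaded_fraction = 1, dna_content = 2, sample_id = 1L)
  opt <- opticsConfig(gain = c(dna = 100, mcm = 100, rb1 = 1000),
                      background = c(dna = 0, mcm = 0, rb1 = 0),
                      cv = c(dna = 0, width = 0, mcm = 0.03, rb1 = 0),
                      doublet_rate = 0)
  ev <- applyMeasurementModel(cells, opt, seed = 21L)
  x <- mcmSignal(ev)
  expect_gt(sd(x) / mean(x), 0.025)
  expect_lt(sd(x) / mean(x), 0.035)
  expect_equal(mean(x), 100, tolerance = 0.01)
})

test_that("doublet injection follows the stated construction", {
  sc <- scenarioConfig("exponential", n_cells = 10000L, seed = 8L)
  ev <- applyMeasurementModel(simulateCells(sc), cleanOptics(), seed = 8L)

  opt0 <- cleanOptics()
  expect_identical(as.data.frame(injectDoublets(ev, opt0, seed = 1L)),
                   as.data.frame(ev))  # rate 0 is a no-op

  # forced pair arithmetic on two singlets
  pair <- EventTable(dna_area = c(200, 200), dna_width = c(100, 100),
                     mcm_signal = c(3, 5), rb1_signal = c(10, 20))
  optp <- opticsConfig(doublet_rate = 0.4, doublet_width_factor = 1.6)
  out <- injectDoublets(pair, optp, seed = 2L)
  expect_equal(nrow(out), 3L)
  expect_equal(dnaArea(out)[3], 400)
  expect_equal(dnaWidth(out)[3], 160)
  expect_equal(mcmSignal(out)[3], 8)

  opt <- opticsConfig(doublet_rate = 0.05)
  d1 <- injectDoublets(ev, opt, seed = 5L)
  expect_equal(nrow(d1), 10000L + floor(10000 * 0.05 / 0.95))
  expect_equal(sum(d1$is_doublet), floor(10000 * 0.05 / 0.95))
  d2 <- injectDoublets(ev, opt, seed = 5L)
  expect_identical(as.data.frame(d1), as.data.frame(d2))  # bit-identical rerun
  expect_error(injectDoublets(pair[1, ], optp, seed = 1L), "at least 2")
})

test_that("barcoding assigns levels and pooling conserves events", {
  sc <- scenarioConfig("exponential", n_cells = 300L, seed = 4L)
  opt1 <- opticsConfig(barcode_levels = 500, barcode_cv = 0)
  tab <- applyMeasurementModel(simulateCells(sc), opt1, seed = 2L)
  pooled1 <- barcodeAndPool(list(tab), opt1, seed = 3L)
  expect_true(all(barcodeSignal(pooled1) == 500))  # noise-free single level
  expect_true(all(pooled1$sample_id == 1L))

  opt4 <- opticsConfig(barcode_cv = 0)
  tabs <- lapply(1:4, function(i)
    applyMeasurementModel(simulateCells(sc, seed = i), opt4, seed = 10 + i))
  pooled <- barcodeAndPool(tabs, opt4, seed = 5L)
  expect_equal(nrow(pooled), 4L * 300L)
  for (i in 1:4)
    expect_true(all(barcodeSignal(pooled)[pooled$sample_id == i] ==
                      opt4@barcode_levels[i]))
  expect_error(barcodeAndPool(tabs[1:3], opt4, seed = 1L), "barcode_levels")
})
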