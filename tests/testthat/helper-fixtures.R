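# Shared fixtures: small scenario/optics builders used across test files.

noiseFreeOptics <- function() {
  opticsConfig(
    gain = c(dna = 100, mcm = 100, rb1 = 1000),
    background = c(dna = 0, mcm = 0, rb1 = 0),
    cv = c(dna = 0, width = 0, mcm = 0, rb1 = 0),
    doublet_rate = 0
  )
}

cleanOptics <- function(...) opticsConfig(doublet_rate = 0, ...)

# Full population-threshold gating on one simulated sample; returns gates
# and the singlet-gated events.
gateSample <- function(events, k_mad = 4, mcm_q = 0.99) {
  sg <- suppressWarnings(gateSinglets(events, k_mad = k_mad))
  peaks <- findDnaPeaks(sg$events)
  gates <- defineGates(sg$events, peaks, singlet_rule = sg$singlet_rule)
  gates@mcm_threshold <- deriveMcmThreshold(sg$events, gates, q = mcm_q)
  gates@rb1_threshold <- as.numeric(deriveRb1Threshold(sg$events, gates))
  list(gates = gates, events = sg$events)
}

# Ground-truth quadrant labels for G1-gated events (the brute-force
# classifier used as the oracle: positivity straight from rp_passed and
# mcm_loaded_fraction > 0).
truthQuadrant <- function(events) {
  mcm_pos <- events$mcm_loaded_fraction > 0
  rb1_pos <- events$rb1_state == "hypo_phosphorylated"
  ifelse(mcm_pos & !rb1_pos, 1L,
         ifelse(mcm_pos & rb1_pos, 2L,
                ifelse(!mcm_pos & rb1_pos, 3L, 4L)))
}

# Predicted quadrant labels from signals and thresholds.
signalQuadrant <- function(events, gates) {
  mcm_pos <- mcmSignal(events) > gates@mcm_threshold
  rb1_pos <- rb1Signal(events) > gates@rb1_threshold
  ifelse(mcm_pos & !rb1_pos, 1L,
         ifelse(mcm_pos & rb1_pos, 2L,
                ifelse(!mcm_pos & rb1_pos, 3L, 4L)))
}

inG1Gate <- function(events, gates) {
  a <- dnaArea(events)
  a >= gates@g1_gate[1] & a <= gates@g1_gate[2]
}
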