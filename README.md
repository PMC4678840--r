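# flowLicense

Simultaneous scoring of replication licensing (chromatin-bound MCM2–7) and
restriction-point state (anchored RB1) in single G1 cells by flow cytometry.

## The problem

Two G1 events shape a cell's commitment to replication: passage through the
RB1-dependent **restriction point**, marked by CDK2–cyclinE
hyper-phosphorylation of RB1, and **licensing**, the loading of MCM2–7
helicases onto chromatin. Pre-extraction with salt and detergent before
fixation removes unbound MCM and hyper-phosphorylated (unanchored) RB1, so
one cytometric measurement scores both states per cell alongside DNA
content. Among G1-gated cells the MCM × RB1 plane then splits into four
quadrants:

| | RB1⁺ (anchored, pre-RP) | RB1⁻ |
|---|---|---|
| **MCM⁺** | Q2 — loaded *before* the restriction point | Q1 — loaded after |
| **MCM⁻** | Q3 — not yet loaded | Q4 — ambiguous |

Q2 occupancy is the evidence that licensing can precede restriction-point
passage; Q4 is intrinsically ambiguous (post-RP unloaded *or* very early G1)
and is never attributed.

`flowLicense` automates the full analysis for cell-cycle labs using this
assay: singlet gating on DNA pulse area/width
(`median + 4·MAD` width cut), DNA-histogram G1/G2 peak detection with a
left-side G1 gate `[0.9, 1.0]·G1peak`, an MCM positivity threshold at the
0.99 quantile of S/G2-border cells (where offloading is complete), an RB1
threshold at the geometric midpoint of the S-phase (negative) and anchored
G1 modes, Wilson-interval quadrant statistics, Pacific-Blue barcoding
demultiplexing by a 1-D Gaussian mixture, and onset estimation for
restriction-point passage, MCM loading and S entry from time courses: a
sigmoid `b + A·Φ((t−m)/s)` is fitted to each rising fraction and the onset
is read at the 10%-of-amplitude crossing, with bootstrap CIs.

Because the underlying raw flow data for this assay class are not publicly
deposited, the package includes a first-class, ground-truthed **synthetic
cytometry generator** for four experimental designs — asynchronous
exponential growth, G0 release (restriction point ~9 h, loading ~11 h,
S entry ~15 h), irradiation arrest, and nocodazole release with two loading
waves — so every stage of the pipeline is quantitatively verifiable.

## A worked example

```r
library(flowLicense)

## asynchronous population, 50k cells, 15% of cells licensing before the RP
sc <- scenarioConfig("exponential", n_cells = 50000L, seed = 5L)
ev <- applyMeasurementModel(simulateCells(sc), opticsConfig(doublet_rate = 0), seed = 2L)

sg    <- gateSinglets(ev)
gates <- defineGates(sg$events, findDnaPeaks(sg$events), singlet_rule = sg$singlet_rule)
gates@mcm_threshold <- deriveMcmThreshold(sg$events, gates)
gates@rb1_threshold <- as.numeric(deriveRb1Threshold(sg$events, gates))

(q <- classifyQuadrants(sg$events, gates))
#> QuadrantResult - 14434 G1 events
#>   Q1 (MCM+/RB1-):   5021   34.79%  [34.01, 35.57]%
#>   Q2 (MCM+/RB1+):   1013    7.02%  [6.61, 7.45]%
#>   Q3 (MCM-/RB1+):   5677   39.33%  [38.54, 40.13]%
#>   Q4 (MCM-/RB1-):   2723   18.87%  [18.24, 19.51]%

summarizeOrder(q)
#> OrderSummary
#>   ...
#>   pre-RP loading fraction: 15.14% [14.30, 16.02]  (Q2/(Q2+Q3))
#>   verdict: loading_before_rp_detected
```

The Q2/(Q2+Q3) estimator — among cells demonstrably before the restriction
point, the fraction already loaded — recovers the simulated 15% dial at
15.14%. A full release time course runs through one call:

```r
scg <- scenarioConfig("g0_release", n_cells = 20000L, seed = 11L)
res <- analyzeScenario(scg, opticsConfig(), seed = 11L, n_boot = 100L)
res$timecourse
#> TimecourseResult over 8 timepoints
#>   rp_onset : 8.63 h  [8.59, 8.70]
#>   mcm_onset: 10.88 h  [10.73, 10.95]
#>   s_onset  : 15.01 h  [15.01, 15.19]
```

The estimated onsets recover the configured kinetics (restriction point 9 h,
loading 11 h, S entry 15 h; the 10%-crossing convention reads the first
appearance of each population, hence slightly before the population mean).

Real data come in through `readEvents()` (FCS 3.0/3.1 or CSV, channel roles
bound by name), and `runPipeline()` drives the whole analysis from a YAML
scenario file. A command-line front end with verbs
`simulate | gate | quadrants | demux | timecourse | run` is installed at
`inst/scripts/flowlicense`.

## Documentation

The methods vignette (`vignettes/flowLicense-methods.Rmd`) describes the
model and its assumptions, every tunable parameter with its default and
rationale, what the generator does and does not emulate, numerical
conventions, and known limitations.
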