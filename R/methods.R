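#' @include AllClasses.R
NULL

## ----- generics -------------------------------------------------------------

#' @rdname EventTable-accessors
#' @export
setGeneric("dnaArea", function(x) standardGeneric("dnaArea"))
#' @rdname EventTable-accessors
#' @export
setGeneric("dnaWidth", function(x) standardGeneric("dnaWidth"))
#' @rdname EventTable-accessors
#' @export
setGeneric("mcmSignal", function(x) standardGeneric("mcmSignal"))
#' @rdname EventTable-accessors
#' @export
setGeneric("rb1Signal", function(x) standardGeneric("rb1Signal"))
#' @rdname EventTable-accessors
#' @export
setGeneric("barcodeSignal", function(x) standardGeneric("barcodeSignal"))
#' @rdname EventTable-accessors
#' @export
setGeneric("hasTruth", function(x) standardGeneric("hasTruth"))
#' @rdname EventTable-accessors
#' @export
setGeneric("dropTruth", function(x) standardGeneric("dropTruth"))

#' @rdname QuadrantResult-accessors
#' @export
setGeneric("quadrantCounts", function(x) standardGeneric("quadrantCounts"))
#' @rdname QuadrantResult-accessors
#' @export
setGeneric("quadrantFractions", function(x) standardGeneric("quadrantFractions"))
#' @rdname QuadrantResult-accessors
#' @export
setGeneric("quadrantCI", function(x) standardGeneric("quadrantCI"))

#' @rdname TimecourseResult-accessors
#' @export
setGeneric("timecourseTable", function(x) standardGeneric("timecourseTable"))
#' @rdname TimecourseResult-accessors
#' @export
setGeneric("onsets", function(x) standardGeneric("onsets"))

#' @rdname DemuxResult-accessors
#' @export
setGeneric("assignments", function(x) standardGeneric("assignments"))
#' @rdname DemuxResult-accessors
#' @export
setGeneric("levelMeans", function(x) standardGeneric("levelMeans"))

## ----- EventTable accessors -------------------------------------------------

#' Accessors for EventTable columns and metadata
#'
#' @param x an [EventTable-class].
#' @return Numeric vectors for the signal accessors; \code{hasTruth} returns
#'   a logical, \code{dropTruth} an [EventTable-class] with all ground-truth
#'   columns removed.
#' @name EventTable-accessors
#' @aliases dnaArea dnaWidth mcmSignal rb1Signal barcodeSignal hasTruth dropTruth
NULL

#' @rdname EventTable-accessors
setMethod("dnaArea", "EventTable", function(x) x[["dna_area"]])
#' @rdname EventTable-accessors
setMethod("dnaWidth", "EventTable", function(x) x[["dna_width"]])
#' @rdname EventTable-accessors
setMethod("mcmSignal", "EventTable", function(x) x[["mcm_signal"]])
#' @rdname EventTable-accessors
setMethod("rb1Signal", "EventTable", function(x) x[["rb1_signal"]])
#' @rdname EventTable-accessors
setMethod("barcodeSignal", "EventTable", function(x) x[["barcode_signal"]])
#' @rdname EventTable-accessors
setMethod("hasTruth", "EventTable", function(x)
  any(.truth_columns %in% colnames(x)))
#' @rdname EventTable-accessors
setMethod("dropTruth", "EventTable", function(x) {
  keep <- setdiff(colnames(x), .truth_columns)
  x[, keep, drop = FALSE]
})

setMethod("show", "EventTable", function(object) {
  md <- metadata(object)
  cat("EventTable with", nrow(object), "events,", ncol(object), "columns\n")
  if (!is.null(md$label) && !is.na(md$label)) cat("  label:", md$label, "\n")
  if (!is.null(md$timepoint) && !is.na(md$timepoint))
    cat("  timepoint:", md$timepoint, "h\n")
  cat("  measured:", paste(intersect(colnames(object),
      c(.required_channels, "barcode_signal")), collapse = ", "), "\n")
  tr <- intersect(.truth_columns, colnames(object))
  if (length(tr)) cat("  ground truth:", paste(tr, collapse = ", "), "\n")
})

## ----- GateSet --------------------------------------------------------------

setMethod("show", "GateSet", function(object) {
  cat("GateSet\n")
  cat(sprintf("  singlet rule : width <= %.4g (center %.4g)\n",
              object@singlet_rule[2], object@singlet_rule[1]))
  cat(sprintf("  DNA peaks    : G1 = %.4g, G2 = %.4g%s\n", object@g1_peak,
              object@g2_peak,
              if (isTRUE(object@flags$g2_inferred)) " (inferred)" else ""))
  cat(sprintf("  G1 gate      : [%.4g, %.4g]\n", object@g1_gate[1],
              object@g1_gate[2]))
  cat(sprintf("  S interval   : [%.4g, %.4g)\n", object@s_interval[1],
              object@s_interval[2]))
  cat(sprintf("  S/G2 border  : [%.4g, %.4g)\n", object@sg2_border[1],
              object@sg2_border[2]))
  cat(sprintf("  thresholds   : MCM > %.4g, RB1 > %.4g (%s)\n",
              object@mcm_threshold, object@rb1_threshold,
              object@threshold_mode))
  fl <- names(Filter(isTRUE, object@flags))
  if (length(fl)) cat("  flags        :", paste(fl, collapse = ", "), "\n")
})

## ----- QuadrantResult -------------------------------------------------------

#' Accessors for QuadrantResult
#'
#' @param x a [QuadrantResult-class].
#' @name QuadrantResult-accessors
#' @aliases quadrantCounts quadrantFractions quadrantCI
#' @return \code{quadrantCounts}/\code{quadrantFractions} return named
#'   numeric(4); \code{quadrantCI} a 4x2 matrix.
NULL

#' @rdname QuadrantResult-accessors
setMethod("quadrantCounts", "QuadrantResult", function(x) x@counts)
#' @rdname QuadrantResult-accessors
setMethod("quadrantFractions", "QuadrantResult", function(x) x@fractions)
#' @rdname QuadrantResult-accessors
setMethod("quadrantCI", "QuadrantResult", function(x) x@ci)

setMethod("show", "QuadrantResult", function(object) {
  cat("QuadrantResult")
  if (length(object@label) && !is.na(object@label))
    cat(" [", object@label, "]", sep = "")
  cat(" -", object@n_total, "G1 events\n")
  lab <- c("Q1 (MCM+/RB1-)", "Q2 (MCM+/RB1+)", "Q3 (MCM-/RB1+)",
           "Q4 (MCM-/RB1-)")
  for (i in 1:4)
    cat(sprintf("  %s: %6d  %6.2f%%  [%.2f, %.2f]%%\n", lab[i],
                object@counts[i], 100 * object@fractions[i],
                100 * object@ci[i, 1], 100 * object@ci[i, 2]))
})

## ----- DemuxResult ----------------------------------------------------------

#' Accessors for DemuxResult
#'
#' @param x a [DemuxResult-class].
#' @name DemuxResult-accessors
#' @aliases assignments levelMeans
#' @return \code{assignments} returns the per-event sample index (NA =
#'   unassigned); \code{levelMeans} the estimated geometric means (increasing).
NULL

#' @rdname DemuxResult-accessors
setMethod("assignments", "DemuxResult", function(x) x@assignment)
#' @rdname DemuxResult-accessors
setMethod("levelMeans", "DemuxResult", function(x) x@level_means)

setMethod("show", "DemuxResult", function(object) {
  cat("DemuxResult -", length(object@assignment), "events,", object@k,
      "components\n")
  cat("  level means :", paste(signif(object@level_means, 4), collapse = ", "),
      "\n")
  cat(sprintf("  unassigned  : %.2f%%\n", 100 * object@unassigned_fraction))
  if (object@merged) cat("  WARNING: merged components detected\n")
})

## ----- TimecourseResult / OrderSummary --------------------------------------

#' Accessors for TimecourseResult
#'
#' @param x a [TimecourseResult-class].
#' @name TimecourseResult-accessors
#' @aliases timecourseTable onsets
#' @return \code{timecourseTable} returns the per-timepoint DFrame;
#'   \code{onsets} the named list of onset fits.
NULL

#' @rdname TimecourseResult-accessors
setMethod("timecourseTable", "TimecourseResult", function(x) x@table)
#' @rdname TimecourseResult-accessors
setMethod("onsets", "TimecourseResult", function(x) x@onsets)

setMethod("show", "TimecourseResult", function(object) {
  cat("TimecourseResult over", nrow(object@table), "timepoints\n")
  for (nm in names(object@onsets)) {
    o <- object@onsets[[nm]]
    if (isTRUE(o$detected))
      cat(sprintf("  %-9s: %.2f h  [%.2f, %.2f]\n", nm, o$onset,
                  o$ci[1], o$ci[2]))
    else cat(sprintf("  %-9s: not detected\n", nm))
  }
})

setMethod("show", "OrderSummary", function(object) {
  cat("OrderSummary\n")
  cat(sprintf("  Q2 (loaded before RP)  : %.2f%% [%.2f, %.2f]\n",
              100 * object@q2_frac[1], 100 * object@q2_frac[2],
              100 * object@q2_frac[3]))
  cat(sprintf("  Q1 (loaded after RP)   : %.2f%% [%.2f, %.2f]\n",
              100 * object@q1_frac[1], 100 * object@q1_frac[2],
              100 * object@q1_frac[3]))
  cat(sprintf("  Q4 (ambiguous)         : %.2f%%\n", 100 * object@q4_frac[1]))
  cat(sprintf("  pre-RP loading fraction: %.2f%% [%.2f, %.2f]  (Q2/(Q2+Q3))\n",
              100 * object@pre_rp_loading_frac[1],
              100 * object@pre_rp_loading_frac[2],
              100 * object@pre_rp_loading_frac[3]))
  cat("  verdict:", object@verdict, "\n")
})
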