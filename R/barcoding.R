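#' @include AllClasses.R utils.R
NULL

# One-dimensional Gaussian-mixture EM with deterministic quantile
# initialisation. Returns weights, means, sds, per-point posteriors and the
# log-likelihood. Order-independent up to floating-point summation.
.gmm1dEM <- function(x, k, max_iter = 300L, tol = 1e-8) {
  n <- length(x)
  qs <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
  mu <- as.numeric(qs)
  sg <- rep(max(stats::sd(x) / max(k, 1), 1e-3), k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  resp <- matrix(1 / k, n, k)
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sg[j]),
                   numeric(n))
    tot <- rowSums(dens)
    tot[tot <= 0 | !is.finite(tot)] <- .Machine$double.xmin
    resp <- dens / tot
    ll <- sum(log(tot))
    nk <- colSums(resp)
    nk[nk < 1e-10] <- 1e-10
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sg <- sqrt(colSums(resp * (outer(x, mu, "-")^2)) / nk)
    sg <- pmax(sg, 1e-4)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
  }
  list(w = w, mu = mu, sigma = sg, resp = resp, loglik = ll)
}

#' Demultiplex barcoded, pooled samples
#'
#' Fits a k-component one-dimensional Gaussian mixture to the log10 barcode
#' signal (expectation-maximization with deterministic quantile-based
#' initialisation) and assigns each event to its maximum-posterior component.
#' Components are reported sorted by intensity, so component 1 is always the
#' dimmest staining level. Events whose maximum posterior falls below
#' \code{min_confidence} are left unassigned: barcoding exists to remove
#' staining variation between samples, so purity is preferred over yield.
#'
#' @param events an [EventTable-class] with a \code{barcode_signal} column.
#' @param k number of barcoded samples (>= 1).
#' @param min_confidence posterior cutoff in [0,1] below which events are
#'   unassigned (default 0.90).
#' @param seed integer seed (reserved for optional random restarts; the
#'   default fit is deterministic).
#' @return A [DemuxResult-class]. A warning is raised and \code{merged} set
#'   when \code{k} exceeds the number of distinguishable intensity modes.
#' @examples
#' sc <- scenarioConfig("exponential", n_cells = 500L, seed = 1L)
#' opt <- opticsConfig()
#' tabs <- lapply(1:4, function(i)
#'   applyMeasurementModel(simulateCells(sc, seed = i), opt, seed = i))
#' pooled <- barcodeAndPool(tabs, opt, seed = 9L)
#' dm <- demultiplex(pooled, k = 4)
#' dm
#' @export
demultiplex <- function(events, k, min_confidence = 0.90, seed = 1L) {
  if (!"barcode_signal" %in% colnames(events))
    stop("no barcode_signal channel in the input; was the barcode channel ",
         "mapped when the file was read?")
  stopifnot(k >= 1L, min_confidence >= 0, min_confidence <= 1)
  x <- log10(pmax(barcodeSignal(events), .Machine$double.xmin))
  n <- length(x)
  if (k == 1L) {
    return(new("DemuxResult", assignment = rep(1L, n),
               level_means = 10^mean(x), confidence = rep(1, n),
               unassigned_fraction = 0, k = 1L, merged = FALSE))
  }
  fit <- .gmm1dEM(x, k)
  ord <- order(fit$mu)
  mu <- fit$mu[ord]
  resp <- fit$resp[, ord, drop = FALSE]
  merged <- any(diff(mu) < 0.1) || any(fit$w < 1e-3)
  if (merged)
    warning("fitted barcode components are not all distinguishable; ",
            "k may exceed the number of separable staining levels")
  conf <- apply(resp, 1L, max)
  assign <- max.col(resp, ties.method = "first")
  assign[conf < min_confidence] <- NA_integer_
  # strictly increasing level means required; nudge exact ties
  mu_lin <- 10^mu
  if (any(diff(mu_lin) <= 0))
    mu_lin <- mu_lin + seq_len(k) * 1e-9 * max(mu_lin)
  new("DemuxResult", assignment = as.integer(assign), level_means = mu_lin,
      confidence = conf, unassigned_fraction = mean(is.na(assign)),
      k = as.integer(k), merged = merged)
}

#' Split a pooled EventTable by demultiplexing assignment
#'
#' @param events the pooled [EventTable-class].
#' @param demux a [DemuxResult-class] for the same events.
#' @return A list of [EventTable-class], one per assigned component; events
#'   with NA assignment are dropped.
#' @export
splitByAssignment <- function(events, demux) {
  stopifnot(nrow(events) == length(demux@assignment))
  lapply(seq_len(demux@k), function(i) {
    out <- events[!is.na(demux@assignment) & demux@assignment == i, ,
                  drop = FALSE]
    metadata(out) <- metadata(events)
    out
  })
}
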