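#' @include AllClasses.R utils.R
NULL

# ---------------------------------------------------------------------------
# Minimal FCS 3.0/3.1 list-mode reader/writer (float data). No spillover,
# no analysis segment, single data set. Written from the published keyword
# layout: HEADER (version + ASCII segment offsets), delimited TEXT segment,
# binary DATA segment.
# ---------------------------------------------------------------------------

.fcs_delim <- "/"

.writeFCS <- function(mat, channels, path) {
  stopifnot(is.matrix(mat), is.character(channels),
            ncol(mat) == length(channels))
  npar <- ncol(mat)
  tot <- nrow(mat)
  rng <- function(x) if (length(x)) max(x, 1) else 1
  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$DATATYPE" = "F", "$MODE" = "L", "$BYTEORD" = "1,2,3,4",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(npar), "$TOT" = as.character(tot)
  )
  for (i in seq_len(npar)) {
    kw[sprintf("$P%dN", i)] <- channels[i]
    kw[sprintf("$P%dB", i)] <- "32"
    kw[sprintf("$P%dE", i)] <- "0,0"
    kw[sprintf("$P%dR", i)] <- format(ceiling(rng(mat[, i])), scientific = FALSE)
  }
  # fixed-width data offsets so the TEXT length is independent of their value
  data_kw <- c("$BEGINDATA" = "%010d", "$ENDDATA" = "%010d")
  textFor <- function(begin, end) {
    kv <- c(kw, c("$BEGINDATA" = sprintf("%010d", begin),
                  "$ENDDATA" = sprintf("%010d", end)))
    paste0(.fcs_delim,
           paste0(names(kv), .fcs_delim, unname(kv), .fcs_delim,
                  collapse = ""))
  }
  header_len <- 58L  # version(6) + 4 spaces + 6 offsets x 8 chars
  text0 <- textFor(0L, 0L)
  text_begin <- header_len
  text_end <- text_begin + nchar(text0, type = "bytes") - 1L
  data_begin <- text_end + 1L
  data_len <- 4L * npar * tot
  data_end <- if (data_len > 0) data_begin + data_len - 1L else 0L
  text <- textFor(data_begin, data_end)
  off <- function(x) {
    if (x > 99999999) return(sprintf("%8d", 0L))
    sprintf("%8d", as.integer(x))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("FCS3.1    ", con, eos = NULL)
  writeChar(paste0(off(text_begin), off(text_end),
                   off(if (data_len > 0) data_begin else 0),
                   off(data_end)), con, eos = NULL)
  writeChar(paste0(off(0), off(0)), con, eos = NULL)  # analysis segment
  writeChar(text, con, eos = NULL)
  if (tot > 0)
    writeBin(as.numeric(t(mat)), con, size = 4L, endian = "little")
  invisible(path)
}

.parseFCSText <- function(raw_text) {
  txt <- rawToChar(raw_text)
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  stats::setNames(trimws(vals), toupper(trimws(keys)))
}

.readFCS <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58L))
  version <- trimws(substr(header, 1, 6))
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("malformed or unsupported FCS header: '", version, "'")
  # offsets live at 1-based character positions 11..18, 19..26, ...
  offs <- suppressWarnings(vapply(0:5, function(i)
    as.integer(trimws(substr(header, 11 + 8 * i, 18 + 8 * i))), integer(1)))
  if (any(is.na(offs[1:2]))) stop("malformed FCS header: bad TEXT offsets")
  text_begin <- offs[1]; text_end <- offs[2]
  seek(con, text_begin)
  kw <- .parseFCSText(readBin(con, "raw", text_end - text_begin + 1L))
  data_begin <- offs[3]; data_end <- offs[4]
  getkw <- function(nm) {
    v <- unname(kw[nm])
    if (length(v) != 1L || is.na(v)) NA_character_ else v
  }
  npar <- as.integer(getkw("$PAR"))
  tot <- as.integer(getkw("$TOT"))
  dtype <- toupper(getkw("$DATATYPE"))
  if (!dtype %in% c("F", "D"))
    stop("unsupported FCS $DATATYPE '", dtype, "' (only F and D list mode)")
  byteord <- getkw("$BYTEORD")
  endian <- if (identical(byteord, "4,3,2,1")) "big" else "little"
  size <- if (dtype == "F") 4L else 8L
  chan <- vapply(seq_len(npar), function(i) {
    nm <- getkw(sprintf("$P%dN", i))
    if (is.na(nm)) sprintf("P%d", i) else nm
  }, character(1))
  short <- vapply(seq_len(npar), function(i) getkw(sprintf("$P%dS", i)),
                  character(1))
  mat <- matrix(numeric(0), nrow = 0, ncol = npar)
  if (tot > 0) {
    seek(con, data_begin)
    vals <- readBin(con, "numeric", n = npar * tot, size = size,
                    endian = endian)
    mat <- matrix(vals, nrow = tot, ncol = npar, byrow = TRUE)
  }
  colnames(mat) <- chan
  list(data = mat, channels = chan, alt_names = short, keywords = kw)
}

# ---------------------------------------------------------------------------
# EventTable-level I/O
# ---------------------------------------------------------------------------

.role_columns <- c(dna_a = "dna_area", dna_w = "dna_width",
                   mcm = "mcm_signal", rb1 = "rb1_signal",
                   barcode = "barcode_signal")

.truthSidecarPath <- function(path)
  paste0(tools::file_path_sans_ext(path), "_truth.csv")

#' Read list-mode events from FCS or CSV
#'
#' Binds file channels to the logical roles of an [EventTable-class] through
#' a channel map. For FCS input both the short name ($PnN) and the optional
#' stain name ($PnS) are honoured when matching; linear values are passed
#' through unscaled. For simulated data written by [writeEvents()], a truth
#' sidecar CSV (\code{<path>_truth.csv}) is read back automatically when
#' present.
#'
#' @param path input file.
#' @param format \code{"fcs"} or \code{"csv"}; default guessed from the
#'   file extension.
#' @param channels named character vector mapping roles (\code{dna_a},
#'   \code{dna_w}, \code{mcm}, \code{rb1}, optionally \code{barcode}) to
#'   channel names in the file; see [channelMap()]. Roles \code{dna_a} and
#'   \code{dna_w} are mandatory; others are bound only when present.
#' @param truth_sidecar logical; read the ground-truth sidecar if it exists.
#' @return An [EventTable-class].
#' @export
readEvents <- function(path, format = c("auto", "fcs", "csv"),
                       channels = channelMap(), truth_sidecar = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "fcs") {
    fcs <- .readFCS(path)
    avail <- fcs$channels
    alt <- fcs$alt_names
    findCol <- function(nm) {
      i <- match(nm, avail)
      if (is.na(i)) i <- match(nm, alt)
      i
    }
    dat <- fcs$data
    getcol <- function(nm) dat[, findCol(nm)]
  } else {
    df <- data.table::fread(path, data.table = FALSE)
    avail <- colnames(df)
    findCol <- function(nm) match(nm, avail)
    getcol <- function(nm) df[[findCol(nm)]]
  }
  need <- c("dna_a", "dna_w")
  for (role in need)
    if (!role %in% names(channels) || is.na(findCol(channels[[role]])))
      stop("channel for role '", role, "' (",
           channels[role] %||% "<unmapped>",
           ") not found; available channels: ",
           paste(avail, collapse = ", "))
  cols <- list()
  for (role in names(.role_columns)) {
    nm <- channels[role]
    if (!is.na(nm) && !is.null(nm) && role %in% names(channels) &&
        !is.na(findCol(nm)))
      cols[[.role_columns[[role]]]] <- as.numeric(getcol(nm))
  }
  df_out <- do.call(DataFrame, cols)
  out <- new("EventTable", df_out)
  metadata(out) <- list(channels = channels, label = basename(path),
                        timepoint = NA_real_)
  sidecar <- .truthSidecarPath(path)
  if (truth_sidecar && file.exists(sidecar)) {
    tr <- data.table::fread(sidecar, data.table = FALSE)
    if (nrow(tr) == nrow(out))
      for (cn in setdiff(colnames(tr), "event_index"))
        out[[cn]] <- tr[[cn]]
  }
  out
}

#' Write list-mode events to FCS 3.1 or CSV
#'
#' Measured channels are written under their mapped names; ground-truth
#' columns never enter the FCS/CSV channels and go to a sidecar CSV
#' (\code{<path>_truth.csv}, keyed by event index) instead. FCS output is
#' float (32-bit) list mode.
#'
#' @param events an [EventTable-class].
#' @param path output file.
#' @param format \code{"fcs"} or \code{"csv"}; default guessed from the
#'   extension.
#' @param channels role-to-name map used for the output header.
#' @param truth_sidecar logical; write the sidecar when truth columns exist.
#' @return The path, invisibly.
#' @export
writeEvents <- function(events, path, format = c("auto", "fcs", "csv"),
                        channels = metadata(events)$channels %||% channelMap(),
                        truth_sidecar = TRUE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  roles <- names(.role_columns)[.role_columns %in% colnames(events)]
  cols <- .role_columns[roles]
  nms <- unname(channels[roles])
  mat <- as.matrix(as.data.frame(lapply(cols, function(cn) events[[cn]]),
                                 optional = TRUE))
  if (nrow(events) == 0L) mat <- matrix(numeric(0), 0, length(cols))
  colnames(mat) <- nms
  if (format == "fcs") {
    .writeFCS(mat, nms, path)
  } else {
    data.table::fwrite(as.data.frame(mat), path)
  }
  if (truth_sidecar && hasTruth(events)) {
    tr <- intersect(.truth_columns, colnames(events))
    trdf <- as.data.frame(events[, tr, drop = FALSE])
    trdf <- cbind(event_index = seq_len(nrow(trdf)), trdf)
    data.table::fwrite(trdf, .truthSidecarPath(path))
  }
  invisible(path)
}
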