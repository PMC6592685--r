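#' Per-event cytometry table
#'
#' An `event_table` is a validated data frame with one row per acquisition
#' event. Columns are `event_id` (unique integer), any number of numeric
#' channels (scatter pulse parameters `FSC_A/H/W`, `SSC_A/H/W`, marker
#' fluorescence such as `CD3`, `CD14`, optional imaging-flow brightfield
#' columns `bf_area` and `bf_aspect_ratio`), and an optional `truth_label`
#' column that is present only on simulated tables and records each event's
#' latent composition.
#'
#' Invariants enforced: all channel values finite, `event_id` unique,
#' `bf_aspect_ratio` in (0, 1] where present.
#'
#' @param df A data frame of events. If `event_id` is absent it is added as
#'   the row sequence.
#' @return An object of class `event_table` (also a `data.frame`).
#' @export
#' @examples
#' tab <- event_table(data.frame(FSC_A = c(1e4, 2e4), FSC_H = c(9e3, 1.9e4),
#'                               CD3 = c(900, 12), CD14 = c(8, 1100)))
#' channels(tab)
event_table <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"event_id" %in% names(df)) df$event_id <- seq_len(nrow(df))
  if (anyDuplicated(df$event_id)) stop("event_id values must be unique", call. = FALSE)
  ch <- setdiff(names(df), c("event_id", "truth_label"))
  for (cn in ch) {
    v <- df[[cn]]
    if (!is.numeric(v)) stop(sprintf("channel '%s' is not numeric", cn), call. = FALSE)
    if (nrow(df) > 0 && !all(is.finite(v))) {
      stop(sprintf("channel '%s' contains non-finite values (row %d)",
                   cn, which(!is.finite(v))[1]), call. = FALSE)
    }
  }
  if ("bf_aspect_ratio" %in% names(df) && nrow(df) > 0) {
    ar <- df$bf_aspect_ratio
    if (any(ar <= 0 | ar > 1)) {
      stop("bf_aspect_ratio must lie in (0, 1]", call. = FALSE)
    }
  }
  if ("truth_label" %in% names(df)) df$truth_label <- as.character(df$truth_label)
  class(df) <- c("event_table", "data.frame")
  df
}

#' Channel names of an event table
#'
#' @param x An `event_table`.
#' @return Character vector of channel column names (excludes `event_id` and
#'   `truth_label`).
#' @export
channels <- function(x) {
  stopifnot(is.data.frame(x))
  setdiff(names(x), c("event_id", "truth_label"))
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d events, %d channels%s\n", nrow(x),
              length(channels(x)),
              if ("truth_label" %in% names(x)) " (+ truth_label)" else ""))
  cat("  channels:", paste(channels(x), collapse = ", "), "\n")
  if ("truth_label" %in% names(x) && nrow(x) > 0) {
    tl <- sort(table(x$truth_label), decreasing = TRUE)
    top <- utils::head(tl, 6)
    cat("  truth:", paste(sprintf("%s=%d", names(top), top), collapse = ", "),
        if (length(tl) > 6) "..." else "", "\n")
  }
  invisible(x)
}

#' Read a per-event cytometry table
#'
#' Reads delimited text (the canonical on-disk form: CSV with a header row of
#' channel names) into an [event_table()]. FCS is recognized as a dialect but
#' requires an external FCS reader, which this package does not bundle; CSV
#' export from acquisition software is the supported on-ramp.
#'
#' @param path File path.
#' @param dialect `"csv"` (default) or `"fcs"`.
#' @param required_channels Optional character vector; an error names the
#'   first missing channel.
#' @param channel_map Optional named character vector mapping instrument
#'   column names to canonical names (`c(instrument = "canonical")` applied as
#'   `names(map)[i] -> map[i]`). The applied mapping is recorded in the
#'   `provenance` attribute.
#' @return An `event_table`; attribute `provenance` records path and mapping.
#' @export
read_event_table <- function(path, dialect = c("csv", "fcs"),
                             required_channels = NULL, channel_map = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "fcs") {
    stop("dialect 'fcs' requires an FCS reader; export events to CSV instead",
         call. = FALSE)
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE,
                          colClasses = NULL, showProgress = FALSE)
  if (!is.null(channel_map)) {
    hit <- names(dt) %in% names(channel_map)
    names(dt)[hit] <- unname(channel_map[names(dt)[hit]])
  }
  for (cn in setdiff(names(dt), c("event_id", "truth_label"))) {
    if (!is.numeric(dt[[cn]])) {
      asnum <- suppressWarnings(as.numeric(dt[[cn]]))
      bad <- which(is.na(asnum) & !is.na(dt[[cn]]) & dt[[cn]] != "")
      if (length(bad)) {
        stop(sprintf("non-numeric value in channel '%s' at row %d", cn, bad[1]),
             call. = FALSE)
      }
      dt[[cn]] <- asnum
    }
  }
  if (!is.null(required_channels)) {
    missing <- setdiff(required_channels, names(dt))
    if (length(missing)) {
      stop(sprintf("required channel '%s' missing from %s", missing[1], path),
           call. = FALSE)
    }
  }
  out <- event_table(dt)
  attr(out, "provenance") <- list(path = path, dialect = dialect,
                                  channel_map = channel_map)
  out
}

#' Write a per-event cytometry table
#'
#' Writes CSV with full numeric precision so that a write/read round trip
#' reproduces values to better than 1e-9 relative.
#'
#' @param table An `event_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(table, path) {
  stopifnot(inherits(table, "event_table"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop(sprintf("directory does not exist: %s", dir), call. = FALSE)
  data.table::fwrite(as.data.frame(table), path, sep = ",", na = "NA")
  invisible(path)
}
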