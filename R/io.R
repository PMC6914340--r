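#' Localization table
#'
#' A per-frame table of single-molecule point detections for one spectral
#' channel: 0-based frame index, position in nm (origin at the field's
#' top-left, x rightward, y downward), spot intensity in arbitrary units, and
#' the channel tag. Extra columns (e.g. a ground-truth `molecule_id` from the
#' simulator) are carried along untouched.
#'
#' @param frame integer vector of 0-based frame indices.
#' @param x_nm,y_nm numeric positions in nm.
#' @param intensity numeric spot intensities (arbitrary units).
#' @param channel single channel tag, `"A"` or `"B"`.
#' @param registered `TRUE` when the coordinates already live in the common
#'   (channel A) frame — simulated streams are born registered; real channel-B
#'   data acquire the flag through [apply_transform()].
#' @param ... further equal-length columns to carry along.
#' @return a `localization_table` (data.frame subclass) sorted by frame.
#' @export
localization_table <- function(frame = integer(0), x_nm = numeric(0),
                               y_nm = numeric(0), intensity = numeric(0),
                               channel = "A", registered = FALSE, ...) {
  channel <- as.character(channel)
  if (length(channel) != 1 || !channel %in% c("A", "B"))
    stopf("'channel' must be a single tag, \"A\" or \"B\"")
  df <- data.frame(frame = as.integer(frame), x_nm = as.numeric(x_nm),
                   y_nm = as.numeric(y_nm), intensity = as.numeric(intensity),
                   ...)
  df$channel <- rep_len(channel, nrow(df))
  validate_localizations(df)
  df <- df[order(df$frame), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("localization_table", "data.frame"),
            channel = channel, units = "nm",
            registered = if (isTRUE(registered)) TRUE else NULL)
}

validate_localizations <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(df$frame < 0)
  if (length(bad)) stopf("negative frame index at row %d", bad[1])
  bad <- which(!is.finite(df$x_nm) | !is.finite(df$y_nm))
  if (length(bad)) stopf("non-finite coordinate at row %d", bad[1])
  if (length(unique(df$channel)) > 1)
    stopf("all rows of a localization table must share one channel tag")
  invisible(df)
}

loc_channel <- function(table) attr(table, "channel") %||% unique(table$channel)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a localization table from CSV
#'
#' The dialect is comma-separated, dot-decimal, UTF-8, with one header line and
#' optional leading `#` comment lines. Required columns: `frame`, `x_nm`,
#' `y_nm`, `intensity`, `channel` — or `x_px`/`y_px` in pixel units together
#' with `pixel_size_nm`.
#'
#' @param path file path.
#' @param pixel_size_nm pixel pitch used to convert `x_px`/`y_px` columns to
#'   nm; the default 107 nm/px corresponds to a 16 um EMCCD pixel behind 150x
#'   magnification.
#' @return a [localization_table()].
#' @export
read_localizations <- function(path, pixel_size_nm = 107) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (all(c("x_px", "y_px") %in% names(df)) && !("x_nm" %in% names(df))) {
    df$x_nm <- df$x_px * pixel_size_nm
    df$y_nm <- df$y_px * pixel_size_nm
  }
  required <- c("frame", "x_nm", "y_nm", "intensity", "channel")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stopf("localization file '%s' lacks column(s): %s", path,
          paste(missing, collapse = ", "))
  for (col in c("frame", "x_nm", "y_nm", "intensity")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) stopf("non-numeric value in column '%s' at row %d", col, bad[1])
    df[[col]] <- v
  }
  ch <- unique(df$channel)
  if (length(ch) > 1)
    stopf("file '%s' mixes channel tags: %s", path, paste(ch, collapse = ", "))
  if (length(ch) == 0) ch <- "A"
  if (!ch %in% c("A", "B")) stopf("unknown channel tag '%s' in '%s'", ch, path)
  registered <- any(grepl("^#\\s*registered:\\s*true", readLines(path, n = 10),
                          ignore.case = TRUE))
  extra <- setdiff(names(df), c(required, "x_px", "y_px"))
  args <- c(list(frame = df$frame, x_nm = df$x_nm, y_nm = df$y_nm,
                 intensity = df$intensity, channel = ch,
                 registered = registered),
            df[extra])
  do.call(localization_table, args)
}

#' Write a localization table to CSV
#'
#' Values are written sorted by frame with a comment header recording the
#' units and channel; the round trip through [read_localizations()] is
#' lossless for finite values.
#'
#' @param table a [localization_table()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_localizations <- function(table, path) {
  df <- as.data.frame(table)
  df <- df[order(df$frame), , drop = FALSE]
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("# smcotrack localization table",
               "# units: nm",
               sprintf("# channel: %s", loc_channel(table)),
               sprintf("# registered: %s",
                       tolower(isTRUE(attr(table, "registered"))))), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
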