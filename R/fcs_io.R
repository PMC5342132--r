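#' Channel metadata for a cytometry parameter
#'
#' Describes one measured parameter of a list-mode file: the mandatory short
#' name (`$PnN`), the optional stain label (`$PnS`, e.g. `"CD7 FITC"`), the
#' stored range (`$PnR`) and the logarithmic amplification (`$PnE`, a
#' `decades,offset` pair; `decades = 0` means linear storage).
#'
#' @param short_name Non-empty channel key; must be unique within a specimen.
#' @param stain_name Optional display label, or `NA`.
#' @param range Positive full-scale range of the stored values.
#' @param decades Log-amplification decades (`>= 0`; `0` = linear).
#' @param offset Log-amplification offset (`$PnE` second field).
#' @return A one-row `data.frame` with columns `short_name`, `stain_name`,
#'   `range`, `decades`, `offset`.
#' @export
channel_info <- function(short_name, stain_name = NA_character_,
                         range = 262144, decades = 0, offset = 0) {
  if (!is.character(short_name) || length(short_name) != 1L || !nzchar(short_name))
    stop_flowmrd("channel short_name must be a nonempty string")
  if (!is.finite(range) || range <= 0)
    stop_flowmrd("channel '%s': range must be > 0", short_name)
  if (!is.finite(decades) || decades < 0)
    stop_flowmrd("channel '%s': amplification decades must be >= 0", short_name)
  data.frame(short_name = short_name,
             stain_name = as.character(stain_name),
             range = as.numeric(range),
             decades = as.numeric(decades),
             offset = as.numeric(offset),
             stringsAsFactors = FALSE)
}

#' List-mode event matrix
#'
#' The central container: an `n_events x n_channels` matrix of finite
#' intensities plus ordered channel metadata and a specimen identifier.
#' Channel `short_name`s are the join key throughout the pipeline and must be
#' unique.
#'
#' @param values Numeric matrix (rows = events, columns = channels), all finite.
#' @param channels Either a character vector of channel names or a
#'   `data.frame` of [channel_info()] rows, one per column of `values`.
#' @param specimen_id Specimen label carried through to results.
#' @return An object of class `event_matrix` with elements `values`
#'   (colnames set to the short names), `channels`, `specimen_id`.
#' @export
event_matrix <- function(values, channels, specimen_id = "specimen") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.character(channels))
    channels <- do.call(rbind, lapply(channels, channel_info))
  if (!is.data.frame(channels) || nrow(channels) != ncol(values))
    stop_flowmrd("channel metadata (%d) does not match column count (%d)",
                 if (is.data.frame(channels)) nrow(channels) else length(channels),
                 ncol(values))
  if (ncol(values) < 2L)
    stop_flowmrd("an event matrix needs at least 2 channels, got %d", ncol(values))
  if (anyDuplicated(channels$short_name))
    stop_flowmrd("duplicate channel short_name: %s",
                 paste(unique(channels$short_name[duplicated(channels$short_name)]),
                       collapse = ", "))
  if (nrow(values) > 0L && !all(is.finite(values)))
    stop_flowmrd("event matrix contains non-finite values")
  colnames(values) <- channels$short_name
  structure(list(values = values, channels = channels,
                 specimen_id = as.character(specimen_id)),
            class = "event_matrix")
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("event_matrix '%s': %d events x %d channels\n",
              x$specimen_id, nrow(x$values), ncol(x$values)))
  cat("  channels:", paste(x$channels$short_name, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.event_matrix <- function(x) dim(x$values)

# ---- FCS 3.0 ---------------------------------------------------------------
# Layout: 58-byte HEADER ("FCS3.0" + 4 spaces + six 8-byte ASCII offsets for
# TEXT begin/end, DATA begin/end, ANALYSIS begin/end), a delimited TEXT
# segment of keyword/value pairs, and a binary list-mode DATA segment.

fcs_delim <- "/"

fcs_text_segment <- function(keywords) {
  d <- fcs_delim
  paste0(d, paste(names(keywords), unlist(keywords), sep = d, collapse = d), d)
}

parse_fcs_text <- function(raw_text) {
  txt <- rawToChar(raw_text)
  d <- substr(txt, 1L, 1L)
  body <- substr(txt, 2L, nchar(txt))
  parts <- strsplit(body, d, fixed = TRUE)[[1]]
  if (length(parts) %% 2L != 0L) parts <- parts[-length(parts)]
  kw <- parts[seq(1L, length(parts), by = 2L)]
  val <- parts[seq(2L, length(parts), by = 2L)]
  stats::setNames(as.list(val), toupper(trimws(kw)))
}

fcs_keyword <- function(kw, name, path, default = NULL) {
  v <- kw[[toupper(name)]]
  if (is.null(v)) {
    if (!is.null(default)) return(default)
    stop_flowmrd("FCS parse error in '%s': required keyword %s missing", path, name)
  }
  v
}

#' Read an FCS 3.0 list-mode file
#'
#' Supports `$DATATYPE` `F` (32-bit float), `D` (64-bit float) and `I`
#' (unsigned integer, 8/16/32-bit), both byte orders, single data segment.
#' Integer-stored channels with log amplification (`$PnE` decades `d > 0`)
#' are decoded to scale units as `offset * 10^(d * x / $PnR)` (an offset of 0
#' is treated as 1, per the standard's convention); linear values pass
#' through unchanged.
#'
#' @param path Path to an FCS 3.0 file.
#' @param specimen_id Specimen label; defaults to the file name.
#' @return An [event_matrix()].
#' @export
read_fcs <- function(path, specimen_id = NULL) {
  if (!file.exists(path)) stop_flowmrd("file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 58L)
  if (length(header) < 58L) stop_flowmrd("FCS parse error in '%s': truncated HEADER", path)
  version <- trimws(rawToChar(header[1:10]))
  if (!identical(version, "FCS3.0"))
    stop_flowmrd("unsupported FCS version '%s' in '%s': only FCS3.0 is supported",
                 version, path)
  offs <- vapply(0:5, function(i) {
    as.numeric(trimws(rawToChar(header[(11 + 8 * i):(18 + 8 * i)])))
  }, numeric(1))
  text_beg <- offs[1]; text_end <- offs[2]
  seek(con, text_beg)
  kw <- parse_fcs_text(readBin(con, "raw", text_end - text_beg + 1))

  mode <- fcs_keyword(kw, "$MODE", path)
  if (toupper(mode) != "L")
    stop_flowmrd("FCS parse error in '%s': $MODE '%s' is not list mode", path, mode)
  dtype <- toupper(fcs_keyword(kw, "$DATATYPE", path))
  if (!dtype %in% c("F", "D", "I"))
    stop_flowmrd("FCS parse error in '%s': unsupported $DATATYPE '%s'", path, dtype)
  n_par <- as.integer(fcs_keyword(kw, "$PAR", path))
  n_tot <- as.integer(fcs_keyword(kw, "$TOT", path))
  byteord <- fcs_keyword(kw, "$BYTEORD", path)
  endian <- if (startsWith(byteord, "1")) "little" else "big"

  bits <- vapply(seq_len(n_par), function(i)
    as.integer(fcs_keyword(kw, sprintf("$P%dB", i), path)), integer(1))
  ranges <- vapply(seq_len(n_par), function(i)
    as.numeric(fcs_keyword(kw, sprintf("$P%dR", i), path)), numeric(1))
  pne <- lapply(seq_len(n_par), function(i) {
    v <- fcs_keyword(kw, sprintf("$P%dE", i), path, default = "0,0")
    as.numeric(strsplit(v, ",", fixed = TRUE)[[1]][1:2])
  })
  names_n <- vapply(seq_len(n_par), function(i)
    fcs_keyword(kw, sprintf("$P%dN", i), path), character(1))
  names_s <- vapply(seq_len(n_par), function(i)
    fcs_keyword(kw, sprintf("$P%dS", i), path, default = NA_character_), character(1))

  data_beg <- as.numeric(fcs_keyword(kw, "$BEGINDATA", path, default = offs[3]))
  data_end <- as.numeric(fcs_keyword(kw, "$ENDDATA", path, default = offs[4]))
  if (data_beg == 0) { data_beg <- offs[3]; data_end <- offs[4] }
  n_bytes <- if (n_tot == 0L) 0 else data_end - data_beg + 1

  if (dtype %in% c("F", "D")) {
    size <- if (dtype == "F") 4L else 8L
    if (any(bits != size * 8L))
      stop_flowmrd("FCS parse error in '%s': $PnB inconsistent with $DATATYPE %s",
                   path, dtype)
    expected <- as.numeric(n_tot) * n_par * size
    if (n_tot > 0 && n_bytes < expected)
      stop_flowmrd("FCS parse error in '%s': DATA segment (%d bytes) shorter than $TOT x $PAR (%d expected)",
                   path, n_bytes, expected)
    seek(con, data_beg)
    vals <- readBin(con, "double", n = n_tot * n_par, size = size, endian = endian)
    if (length(vals) < n_tot * n_par)
      stop_flowmrd("FCS parse error in '%s': truncated DATA segment ($TOT=%d)", path, n_tot)
    mat <- matrix(vals, nrow = n_tot, ncol = n_par, byrow = TRUE)
  } else {
    if (length(unique(bits)) != 1L || !bits[1] %in% c(8L, 16L, 32L))
      stop_flowmrd("FCS parse error in '%s': integer $PnB must be uniform 8/16/32", path)
    size <- bits[1] %/% 8L
    expected <- as.numeric(n_tot) * n_par * size
    if (n_tot > 0 && n_bytes < expected)
      stop_flowmrd("FCS parse error in '%s': DATA segment (%d bytes) shorter than $TOT x $PAR (%d expected)",
                   path, n_bytes, expected)
    seek(con, data_beg)
    vals <- readBin(con, "integer", n = n_tot * n_par, size = size,
                    signed = size == 4L, endian = endian)
    if (length(vals) < n_tot * n_par)
      stop_flowmrd("FCS parse error in '%s': truncated DATA segment ($TOT=%d)", path, n_tot)
    vals <- as.double(vals)
    vals[vals < 0] <- vals[vals < 0] + 4294967296  # 32-bit values are unsigned
    mat <- matrix(vals, nrow = n_tot, ncol = n_par, byrow = TRUE)
    for (j in seq_len(n_par)) {
      d <- pne[[j]][1]
      if (is.finite(d) && d > 0) {
        a0 <- pne[[j]][2]
        if (!is.finite(a0) || a0 == 0) a0 <- 1
        mat[, j] <- a0 * 10^(d * mat[, j] / ranges[j])
      }
    }
  }

  ch <- do.call(rbind, lapply(seq_len(n_par), function(i)
    channel_info(names_n[i], names_s[i], ranges[i], pne[[i]][1], pne[[i]][2])))
  if (is.null(specimen_id))
    specimen_id <- sub("\\.fcs$", "", basename(path), ignore.case = TRUE)
  event_matrix(mat, ch, specimen_id)
}

#' Write an FCS 3.0 list-mode file
#'
#' Emits a minimal single-data-segment FCS 3.0 file: HEADER, TEXT with
#' `$TOT/$PAR/$PnN/$PnS/$PnB/$PnE/$PnR/$DATATYPE/$BYTEORD/$MODE`, little-endian
#' floating-point DATA. With `datatype = "F"` values are stored as 32-bit
#' floats (sufficient for instrument-scale intensities); `"D"` stores 64-bit
#' doubles so that [read_fcs()] round-trips values bit-exactly.
#'
#' @param events An [event_matrix()].
#' @param path Output path.
#' @param datatype `"F"` (default) or `"D"`.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path, datatype = c("F", "D")) {
  stopifnot(inherits(events, "event_matrix"))
  datatype <- match.arg(datatype)
  size <- if (datatype == "F") 4L else 8L
  m <- events$values
  n_tot <- nrow(m); n_par <- ncol(m)

  kwl <- list("$MODE" = "L", "$DATATYPE" = datatype, "$BYTEORD" = "1,2,3,4",
              "$NEXTDATA" = "0", "$PAR" = as.character(n_par),
              "$TOT" = as.character(n_tot),
              "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
              "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0")
  for (i in seq_len(n_par)) {
    ch <- events$channels[i, ]
    kwl[[sprintf("$P%dN", i)]] <- ch$short_name
    if (!is.na(ch$stain_name)) kwl[[sprintf("$P%dS", i)]] <- ch$stain_name
    kwl[[sprintf("$P%dB", i)]] <- as.character(size * 8L)
    kwl[[sprintf("$P%dE", i)]] <- "0,0"
    kwl[[sprintf("$P%dR", i)]] <- format(ch$range, scientific = FALSE, trim = TRUE)
  }
  # Two-pass offset fixing: reserve fixed-width fields for the data offsets.
  data_len <- as.numeric(n_tot) * n_par * size
  placeholder <- list("$BEGINDATA" = strrep("0", 12), "$ENDDATA" = strrep("0", 12))
  text0 <- fcs_text_segment(c(kwl, placeholder))
  text_beg <- 58L
  text_end <- text_beg + nchar(text0) - 1L
  data_beg <- text_end + 1L
  data_end <- if (n_tot > 0L) data_beg + data_len - 1 else data_beg
  kwl[["$BEGINDATA"]] <- formatC(data_beg, width = 12, flag = "0", format = "d")
  kwl[["$ENDDATA"]] <- formatC(data_end, width = 12, flag = "0", format = "d")
  text <- fcs_text_segment(kwl)
  stopifnot(nchar(text) == nchar(text0))

  hdr_off <- function(x) formatC(x, width = 8, format = "d")
  # HEADER offsets are 8 ASCII chars; large files point via $BEGINDATA/$ENDDATA.
  hd_beg <- if (data_beg <= 99999999) data_beg else 0
  hd_end <- if (data_end <= 99999999) data_end else 0
  header <- paste0("FCS3.0    ", hdr_off(text_beg), hdr_off(text_end),
                   hdr_off(hd_beg), hdr_off(hd_end), hdr_off(0), hdr_off(0))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  if (n_tot > 0L)
    writeBin(as.vector(t(m)), con, size = size, endian = "little")
  invisible(path)
}

# ---- CSV event tables ------------------------------------------------------

#' Export events as a CSV table
#'
#' First row holds the channel short names, then one row per event; comma
#' separator, `.` decimal, no index column. Inverse of [read_events_csv()]
#' up to floating-point text round-trip.
#'
#' @param events An [event_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_csv <- function(events, path) {
  stopifnot(inherits(events, "event_matrix"))
  df <- as.data.frame(events$values)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = events$channels$short_name)
  invisible(path)
}

#' Read a CSV event table
#'
#' @param path CSV file with a header row of channel names.
#' @param specimen_id Specimen label; defaults to the file name.
#' @return An [event_matrix()] with default channel metadata.
#' @export
read_events_csv <- function(path, specimen_id = NULL) {
  if (!file.exists(path)) stop_flowmrd("file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop_flowmrd("CSV parse error in '%s': empty file", path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  p <- length(header)
  n <- length(lines) - 1L
  cells <- strsplit(lines[-1], ",", fixed = TRUE)
  lens <- lengths(cells)
  if (any(lens != p)) {
    bad <- which(lens != p)[1]
    stop_flowmrd("CSV parse error in '%s': row %d has %d cells, expected %d",
                 path, bad, lens[bad], p)
  }
  flat <- suppressWarnings(as.numeric(unlist(cells, use.names = FALSE)))
  if (anyNA(flat)) {
    bad <- ceiling(which(is.na(flat))[1] / p)
    stop_flowmrd("CSV parse error in '%s': non-numeric cell in row %d", path, bad)
  }
  mat <- matrix(flat, nrow = n, ncol = p, byrow = TRUE)
  if (is.null(specimen_id))
    specimen_id <- sub("\\.csv$", "", basename(path), ignore.case = TRUE)
  event_matrix(mat, trimws(header), specimen_id)
}
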