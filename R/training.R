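#' Assemble a labeled per-patient training set
#'
#' Concatenates the diagnosis blast events (flag 1) with all pooled
#' healthy-donor events (flag 0), restricted to the requested channels in
#' the requested order. Each event keeps its originating specimen id so a
#' later subsample can stratify by source file.
#'
#' @param blasts [event_matrix()] of the patient's diagnosis blast
#'   population (the manually selected leukemic cells).
#' @param donors List of healthy-donor [event_matrix()] objects.
#' @param channels Channel names to use as features; default: all channels
#'   of the blast matrix.
#' @return A `training_set`: list with `features` (n x p matrix), `flags`
#'   (integer 0/1), `sources` (character).
#' @export
build_training_set <- function(blasts, donors, channels = blasts$channels$short_name) {
  stopifnot(inherits(blasts, "event_matrix"))
  if (nrow(blasts$values) == 0L) stop_flowmrd("blast matrix is empty")
  if (length(donors) == 0L) stop_flowmrd("donor list is empty")
  pick <- function(ev, who) {
    missing <- setdiff(channels, ev$channels$short_name)
    if (length(missing))
      stop_flowmrd("%s ('%s') lacks channel(s): %s", who, ev$specimen_id,
                   paste(missing, collapse = ", "))
    ev$values[, channels, drop = FALSE]
  }
  feat <- list(pick(blasts, "blast file"))
  src <- rep(blasts$specimen_id, nrow(blasts$values))
  flags <- rep(1L, nrow(blasts$values))
  for (d in donors) {
    stopifnot(inherits(d, "event_matrix"))
    m <- pick(d, "donor file")
    feat <- c(feat, list(m))
    src <- c(src, rep(d$specimen_id, nrow(m)))
    flags <- c(flags, rep(0L, nrow(m)))
  }
  if (sum(flags == 0L) == 0L) stop_flowmrd("no donor events (all donors empty)")
  structure(list(features = do.call(rbind, feat), flags = flags, sources = src),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("training_set: %d events x %d features; %d leukemic (flag 1), %d normal; %d source file(s)\n",
              nrow(x$features), ncol(x$features), sum(x$flags == 1L),
              sum(x$flags == 0L), length(unique(x$sources))))
  invisible(x)
}

#' Stratified random subsample of a training set
#'
#' Strata are the distinct source files. Per-stratum quotas are the
#' largest-remainder apportionment of `n` by stratum size (so the
#' leukemic:normal and per-donor balance is preserved to within one event),
#' and events within each stratum are drawn uniformly without replacement
#' under `seed`. When `n` is at least the total size the set is returned
#' unchanged.
#'
#' @param ts A `training_set`.
#' @param n Target subsample size; default `1e4`, the size at which model
#'   quality matches the full training file at a fraction of the tuning cost.
#' @param seed RNG seed.
#' @return A `training_set` with exactly `n` events (or `ts` itself).
#' @export
stratified_sample <- function(ts, n = 1e4, seed = 1L) {
  stopifnot(inherits(ts, "training_set"))
  total <- nrow(ts$features)
  if (n >= total) return(ts)
  strata <- unique(ts$sources)
  if (n < length(strata))
    stop_flowmrd("n = %d is smaller than the number of strata (%d)", n, length(strata))
  sizes <- vapply(strata, function(s) sum(ts$sources == s), integer(1))
  quotas <- largest_remainder(as.integer(n), sizes)
  idx <- integer(0)
  with_seed(seed, {
    for (k in seq_along(strata)) {
      rows <- which(ts$sources == strata[k])
      idx <- c(idx, sort(sample(rows, quotas[k], replace = FALSE)))
    }
  })
  structure(list(features = ts$features[idx, , drop = FALSE],
                 flags = ts$flags[idx], sources = ts$sources[idx]),
            class = "training_set")
}

#' Fit a per-channel scaling range on training data
#'
#' Records each feature channel's training minimum and maximum together
#' with the target interval, for affine rescaling at training and again at
#' prediction time (the saved-range discipline of LIBSVM's `svm-scale`).
#'
#' @param ts A `training_set` (or bare feature matrix with colnames).
#' @param lo,hi Target interval, default `[-1, 1]`.
#' @return A `scaling_range`: list with `min`, `max` (named per channel),
#'   `lo`, `hi`.
#' @export
fit_scaling <- function(ts, lo = -1, hi = 1) {
  m <- if (inherits(ts, "training_set")) ts$features else as.matrix(ts)
  if (nrow(m) == 0L) stop_flowmrd("cannot fit a scaling range on an empty training set")
  if (lo >= hi) stop_flowmrd("target interval requires lo < hi")
  structure(list(min = apply(m, 2L, min), max = apply(m, 2L, max),
                 lo = lo, hi = hi, channels = colnames(m)),
            class = "scaling_range")
}

#' Apply a saved scaling range
#'
#' Per channel, `x' = lo + (hi - lo) * (x - min) / (max - min)`. Values
#' outside the training range extrapolate linearly (no clipping), matching
#' the reference scaler. A degenerate channel (`min == max`) maps to `lo`.
#'
#' @param x Feature matrix whose columns match the range.
#' @param range A `scaling_range`.
#' @return The rescaled matrix.
#' @export
apply_scaling <- function(x, range) {
  stopifnot(inherits(range, "scaling_range"))
  x <- as.matrix(x)
  if (ncol(x) != length(range$min))
    stop_flowmrd("feature matrix has %d columns but the scaling range has %d channels",
                 ncol(x), length(range$min))
  span <- range$max - range$min
  out <- x
  for (j in seq_len(ncol(x))) {
    if (span[j] > 0)
      out[, j] <- range$lo + (range$hi - range$lo) * (x[, j] - range$min[j]) / span[j]
    else
      out[, j] <- range$lo
  }
  out
}

#' Invert a saved scaling range
#'
#' @param x Scaled matrix.
#' @param range A `scaling_range`.
#' @return The matrix on the original intensity scale (degenerate channels
#'   recover their constant training value).
#' @export
invert_scaling <- function(x, range) {
  stopifnot(inherits(range, "scaling_range"))
  x <- as.matrix(x)
  span <- range$max - range$min
  out <- x
  for (j in seq_len(ncol(x))) {
    if (span[j] > 0)
      out[, j] <- range$min[j] + (x[, j] - range$lo) * span[j] / (range$hi - range$lo)
    else
      out[, j] <- range$min[j]
  }
  out
}

# ---- Persistence: plain-text range and training files ----------------------

#' Write / read a scaling-range file
#'
#' Versioned plain-text format: a header line, the target interval, then one
#' `channel min max` line per feature channel (the on-disk analogue of a
#' `.range` file).
#'
#' @param range A `scaling_range`.
#' @param path File path.
#' @return `path` (writer) or a `scaling_range` (reader).
#' @export
write_scaling_range <- function(range, path) {
  stopifnot(inherits(range, "scaling_range"))
  lines <- c("flowMRD-range v1",
             sprintf("target %.17g %.17g", range$lo, range$hi),
             sprintf("%s %.17g %.17g", range$channels, range$min, range$max))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scaling_range
#' @export
read_scaling_range <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "flowMRD-range"))
    stop_flowmrd("'%s' is not a flowMRD range file", path)
  tg <- strsplit(lines[2], " ", fixed = TRUE)[[1]]
  rows <- strsplit(lines[-(1:2)], " ", fixed = TRUE)
  ch <- vapply(rows, `[[`, character(1), 1L)
  mn <- as.numeric(vapply(rows, `[[`, character(1), 2L))
  mx <- as.numeric(vapply(rows, `[[`, character(1), 3L))
  structure(list(min = stats::setNames(mn, ch), max = stats::setNames(mx, ch),
                 lo = as.numeric(tg[2]), hi = as.numeric(tg[3]), channels = ch),
            class = "scaling_range")
}

#' Write / read a labeled training file
#'
#' Plain-text format with a versioned header, a channel-name line, then one
#' `flag source v1 v2 ...` line per event.
#'
#' @param ts A `training_set`.
#' @param path File path.
#' @return `path` (writer) or a `training_set` (reader).
#' @export
write_training_set <- function(ts, path) {
  stopifnot(inherits(ts, "training_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("flowMRD-train v1",
               paste(colnames(ts$features), collapse = " ")), con)
  body <- paste(ts$flags, ts$sources,
                apply(ts$features, 1L, function(r)
                  paste(sprintf("%.17g", r), collapse = " ")))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_training_set
#' @export
read_training_set <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "flowMRD-train"))
    stop_flowmrd("'%s' is not a flowMRD training file", path)
  channels <- strsplit(lines[2], " ", fixed = TRUE)[[1]]
  rows <- strsplit(lines[-(1:2)], " ", fixed = TRUE)
  flags <- as.integer(vapply(rows, `[[`, character(1), 1L))
  sources <- vapply(rows, `[[`, character(1), 2L)
  feat <- matrix(as.numeric(unlist(lapply(rows, `[`, -(1:2)), use.names = FALSE)),
                 ncol = length(channels), byrow = TRUE,
                 dimnames = list(NULL, channels))
  structure(list(features = feat, flags = flags, sources = sources),
            class = "training_set")
}
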